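count_el <- function(scene, pattern) sum(grepl(pattern, scene$svg))

simple_scene <- function(opts = render_options(), edges = NULL, n = 3) {
  m <- make_synthetic_map(4, seed = 8)
  db <- make_synthetic_db(n, m, seed = 8)
  pl <- place_proteins(db, m, mode = "ppi", seed = 2)
  render_scene(m, pl$placed, edges, opts)
}

test_that("SVG contains one circle per placed protein, filled with its compartment color", {
  m <- cell_map(200, 200, list(square_roi("vacuole")))
  rec <- protein_record("P1", localizations = list(localization("vacuole")))
  pl <- place_ppi_mode(rec, m, seed = 1)
  sc <- render_scene(m, pl$placed)
  expect_equal(count_el(sc, "<circle "), 1)
  expect_match(as.character(sc),
               sprintf("fill=\"%s\"", compartment_color("vacuole")$hex), fixed = TRUE)
  xml2::read_xml(as.character(sc))  # well-formed standalone SVG
})

test_that("element counts are conserved and hide_proteins drops circles and edges but not ROIs", {
  m <- make_synthetic_map(4, seed = 8)
  db <- make_synthetic_db(6, m, seed = 8)
  pl <- place_proteins(db, m, mode = "ppi", seed = 2)
  g <- global_edges(pl$placed, db)
  sc <- render_scene(m, pl$placed, g, render_options(show_rois = TRUE))
  expect_equal(count_el(sc, "<circle "), nrow(pl$placed))
  expect_equal(count_el(sc, "<line class=\"edge\""), nrow(g))
  expect_equal(count_el(sc, "<polygon "), length(m$rois))

  hid <- render_scene(m, pl$placed, g, render_options(show_rois = TRUE,
                                                      hide_proteins = TRUE))
  expect_equal(count_el(hid, "<circle "), 0)
  expect_equal(count_el(hid, "<line class=\"edge\""), 0)
  expect_equal(count_el(hid, "<polygon "), length(m$rois))
})

test_that("edges with unplaced endpoints are rejected", {
  m <- cell_map(200, 200, list(square_roi("vacuole")))
  rec <- protein_record("P1", localizations = list(localization("vacuole")))
  pl <- place_ppi_mode(rec, m, seed = 1)
  ghost <- data.frame(a = "P1", b = "GHOST", score_label = NA_character_,
                      x1 = 0, y1 = 0, x2 = 1, y2 = 1, stringsAsFactors = FALSE)
  expect_error(render_scene(m, pl$placed, ghost), "GHOST")
})

test_that("rendering is deterministic and options plumb through verbatim", {
  s1 <- simple_scene(render_options(base_opacity = 0.37, show_rois = TRUE))
  s2 <- simple_scene(render_options(base_opacity = 0.37, show_rois = TRUE))
  expect_identical(as.character(s1), as.character(s2))

  p1 <- withr::local_tempfile(fileext = ".svg")
  p2 <- withr::local_tempfile(fileext = ".svg")
  write_svg(s1, p1); write_svg(s2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  # opacity lands verbatim on the image element when a base image exists
  img <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(0.5, 30, 40), img)
  m <- cell_map(40, 30, image_ref = img)
  sc <- render_scene(m, opts = render_options(base_opacity = 0.37))
  expect_match(as.character(sc), "opacity=\"0.37\"", fixed = TRUE)

  m_missing <- cell_map(40, 30, image_ref = "/nonexistent/cell.png")
  expect_error(render_scene(m_missing), "base image not found")
})

test_that("labels are off by default and render accessions when enabled", {
  sc <- simple_scene()
  expect_equal(count_el(sc, "<text "), 0)
  lab <- simple_scene(render_options(show_labels = TRUE))
  expect_equal(count_el(lab, "<text "), nrow(lab$placed))
  expect_match(as.character(lab), "P00001", fixed = TRUE)
})

test_that("edge reliability labels honor the score-display threshold", {
  m <- cell_map(200, 200, list(square_roi("vacuole")))
  db <- protein_db(list(
    protein_record("A", interactions = list(ppi_interaction("B", score = 0.91),
                                            ppi_interaction("C", score = 0.40),
                                            ppi_interaction("D")),
                   localizations = list(localization("vacuole"))),
    protein_record("B", localizations = list(localization("vacuole"))),
    protein_record("C", localizations = list(localization("vacuole"))),
    protein_record("D", localizations = list(localization("vacuole")))
  ))
  pl <- place_proteins(db, m, mode = "ppi", seed = 1)
  e <- edges_for_focal(pl$placed, db, "A")
  all_lab <- render_scene(m, pl$placed, e)
  expect_equal(count_el(all_lab, "edge-label"), 2)  # unscored edge never labeled
  thr <- render_scene(m, pl$placed, e, render_options(score_label_min = 0.5))
  expect_equal(count_el(thr, "edge-label"), 1)
  none <- render_scene(m, pl$placed, e, render_options(show_edge_labels = FALSE))
  expect_equal(count_el(none, "edge-label"), 0)
})

test_that("PNG export produces canvas size times scale, on white for blank maps", {
  m <- cell_map(400, 300, list(square_roi("vacuole")))
  sc <- render_scene(m)
  p <- withr::local_tempfile(fileext = ".png")
  export_png(sc, p)
  expect_equal(dim(png::readPNG(p))[1:2], c(300, 400))
  export_png(sc, p, scale = 2)
  img <- png::readPNG(p)
  expect_equal(dim(img)[1:2], c(600, 800))
  expect_true(all(img[1:10, 1:10, 1:3] == 1))  # blank canvas is white
  expect_error(export_png(sc, p, scale = 0), "positive")

  # zoom as output scaling applies to the SVG canvas too
  sc2 <- render_scene(m, opts = render_options(scale = 2))
  expect_match(sc2$svg[2], "width=\"800.00\" height=\"600.00\"", fixed = TRUE)
  expect_match(sc2$svg[2], "viewBox=\"0 0 400.00 300.00\"", fixed = TRUE)
})
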