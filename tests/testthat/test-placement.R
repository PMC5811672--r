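two_comp_map <- function() {
  cell_map(400, 200, list(square_roi("nucleus", 10, 10, 100),
                          square_roi("cytoplasm", 250, 50, 100)))
}

rec_nuc_cyt <- protein_record("P00001",
  localizations = list(localization("nucleus"), localization("cytoplasm")))

test_that("map mode places one circle per localization with a matching ROI, in order", {
  rep <- place_map_mode(rec_nuc_cyt, two_comp_map(), seed = 1)
  expect_equal(nrow(rep$placed), 2)
  expect_equal(nrow(rep$skipped), 0)
  expect_equal(rep$placed$compartment, c("nucleus", "cytoplasm"))
  expect_equal(rep$placed$fill,
               c(compartment_color("nucleus")$hex, compartment_color("cytoplasm")$hex))
  expect_equal(rep$placed$mode, c("map", "map"))

  # missing ROI -> skipped, not dropped
  rec <- protein_record("P2", localizations = list(localization("vacuole")))
  rep2 <- place_map_mode(rec, two_comp_map(), seed = 1)
  expect_equal(nrow(rep2$placed), 0)
  expect_equal(rep2$skipped$reason, "no_roi")
  expect_equal(rep2$skipped$compartment, "vacuole")

  # no localizations -> empty report
  rep3 <- place_map_mode(protein_record("P3"), two_comp_map(), seed = 1)
  expect_equal(nrow(rep3$placed) + nrow(rep3$skipped), 0)
})

test_that("ppi mode places exactly one circle at the first available localization", {
  m <- two_comp_map()
  rep <- place_ppi_mode(rec_nuc_cyt, m, seed = 1)
  expect_equal(nrow(rep$placed), 1)
  expect_equal(rep$placed$compartment, "nucleus")
  expect_equal(rep$placed$mode, "ppi")

  # all four presence/absence combinations for localizations [vacuole, nucleus]
  rec <- protein_record("P9", localizations = list(localization("vacuole"),
                                                   localization("nucleus")))
  maps <- list(
    both = cell_map(400, 200, list(square_roi("vacuole"), square_roi("nucleus", 250, 50, 100))),
    vac_only = cell_map(400, 200, list(square_roi("vacuole"))),
    nuc_only = cell_map(400, 200, list(square_roi("nucleus"))),
    neither = cell_map(400, 200, list(square_roi("er")))
  )
  expected <- list(both = "vacuole", vac_only = "vacuole",
                   nuc_only = "nucleus", neither = NA)
  for (nm in names(maps)) {
    r <- place_ppi_mode(rec, maps[[nm]], seed = 3)
    if (is.na(expected[[nm]])) {
      expect_equal(nrow(r$placed), 0, info = nm)
      expect_equal(nrow(r$skipped), 2, info = nm)
    } else {
      expect_equal(r$placed$compartment, expected[[nm]], info = nm)
    }
  }
  # fallback records the skipped first localization
  r <- place_ppi_mode(rec, maps$nuc_only, seed = 3)
  expect_equal(r$skipped$compartment, "vacuole")
  expect_equal(r$skipped$reason, "no_roi")
})

test_that("ppi-mode override relocates to the chosen annotated compartment only", {
  m <- two_comp_map()
  rep <- place_ppi_mode(rec_nuc_cyt, m, seed = 1, override_compartment = "cytoplasm")
  expect_equal(rep$placed$compartment, "cytoplasm")
  # case-insensitive override matching
  rep2 <- place_ppi_mode(rec_nuc_cyt, m, seed = 1, override_compartment = "Cytoplasm")
  expect_equal(rep2$placed$compartment, "cytoplasm")
  expect_error(place_ppi_mode(rec_nuc_cyt, m, override_compartment = "golgi"),
               "not among the annotated localizations")
  # override to a compartment without an ROI: skipped, no fallback
  m1 <- cell_map(400, 200, list(square_roi("nucleus")))
  rep3 <- place_ppi_mode(rec_nuc_cyt, m1, seed = 1, override_compartment = "cytoplasm")
  expect_equal(nrow(rep3$placed), 0)
  expect_equal(rep3$skipped$compartment, "cytoplasm")
})

test_that("placements are deterministic per seed, contained, and order-independent across proteins", {
  m <- make_synthetic_map(6, seed = 11)
  db <- make_synthetic_db(30, m, seed = 12)
  r1 <- place_proteins(db, m, mode = "map", seed = 5)
  r2 <- place_proteins(db, m, mode = "map", seed = 5)
  expect_identical(r1$placed, r2$placed)

  # every center strictly inside an ROI of its compartment
  for (i in seq_len(nrow(r1$placed))) {
    p <- r1$placed[i, ]
    rois <- rois_for_compartment(m, p$compartment)
    expect_true(any(vapply(rois, function(r) point_in_roi(p$x, p$y, r), FALSE)))
  }

  # per-protein substreams: placing a subset reproduces the same positions
  sub <- place_proteins(db[names(db)[5:10]], m, mode = "map", seed = 5)
  full <- r1$placed[r1$placed$uniprot_id %in% names(db)[5:10], ]
  rownames(full) <- NULL; rownames(sub$placed) <- NULL
  expect_identical(sub$placed, full)
})

test_that("multi-polygon compartments place across polygons proportionally to area", {
  # one compartment, two squares with 4:1 area ratio
  m <- cell_map(500, 200, list(square_roi("cytoplasm", 10, 10, 160),
                               square_roi("cytoplasm", 300, 10, 80)))
  rec <- protein_record("PX", localizations = list(localization("cytoplasm")))
  hits_small <- 0L
  n <- 400
  for (i in seq_len(n)) {
    rep <- place_map_mode(rec, m, seed = i)
    if (rep$placed$x > 250) hits_small <- hits_small + 1L
  }
  p <- (80^2) / (80^2 + 160^2)  # 0.2
  sigma <- sqrt(n * p * (1 - p))
  expect_lt(abs(hits_small - n * p), 4 * sigma)
})
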