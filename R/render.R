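# Scene composition: base image, ROI overlay, interaction edges, protein
# circles and labels, in that fixed z-order, written as standalone SVG
# (canonical, diffable) or rasterized to PNG. Rendering is deterministic:
# identical inputs yield byte-identical SVG.

#' Rendering options
#'
#' The viewer controls, modeled as render options: base-map opacity, the
#' ROI overlay toggle, temporarily hiding loaded proteins (which also drops
#' their edges so nothing dangles), zoom as uniform output scaling, and
#' protein-identifier labels (off by default; the identifiers are otherwise
#' not visible on a static image).
#'
#' @param base_opacity opacity of the base cell image, in `[0,1]`.
#' @param show_rois draw the user-authored compartment polygons.
#' @param hide_proteins drop protein circles and their edges.
#' @param scale uniform output scaling factor (zoom), > 0.
#' @param show_labels draw each protein's accession above its circle.
#' @param show_edge_labels draw reliability scores at edge midpoints.
#' @param score_label_min only label edges with score >= this threshold
#'   (default 0: label every scored edge).
#' @return an object of class `render_options`.
#' @export
render_options <- function(base_opacity = 1, show_rois = FALSE,
                           hide_proteins = FALSE, scale = 1,
                           show_labels = FALSE, show_edge_labels = TRUE,
                           score_label_min = 0) {
  stopifnot(is.numeric(base_opacity), base_opacity >= 0, base_opacity <= 1,
            is.numeric(scale), scale > 0)
  structure(list(base_opacity = base_opacity, show_rois = show_rois,
                 hide_proteins = hide_proteins, scale = scale,
                 show_labels = show_labels,
                 show_edge_labels = show_edge_labels,
                 score_label_min = score_label_min),
            class = "render_options")
}

image_data_uri <- function(path) {
  if (!file.exists(path)) stop("base image not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  mime <- switch(ext, png = "image/png", jpg = , jpeg = "image/jpeg",
                 stop("unsupported base image format: .", ext, call. = FALSE))
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  paste0("data:", mime, ";base64,", jsonlite::base64_enc(bytes))
}

svg_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

renderable_edges <- function(edges, placed) {
  if (is.null(edges) || !nrow(edges)) return(empty_edges())
  ok <- edges$a %in% placed$uniprot_id & edges$b %in% placed$uniprot_id
  if (!all(ok)) {
    stop("edge endpoints must be placed proteins: ",
         paste(unique(c(edges$a[!ok], edges$b[!ok])), collapse = ", "),
         call. = FALSE)
  }
  edges
}

#' Compose a scene
#'
#' Builds the layered drawing — base image (or blank white canvas), optional
#' ROI overlay, interaction edges with optional reliability labels, protein
#' circles filled with their compartment color, optional accession labels —
#' and its SVG serialization. With `hide_proteins` both circles and edges
#' are dropped; the ROI layer is unaffected.
#'
#' @param map a `cellmap`.
#' @param placed data frame of placed circles ([place_proteins()]).
#' @param edges edge data frame ([edges_for_focal()], [global_edges()]), or
#'   `NULL` for none. Every endpoint must be placed.
#' @param opts a [render_options()] object.
#' @return an object of class `cellmap_scene`; `as.character()` yields the
#'   SVG document, [write_svg()] and [export_png()] write files.
#' @export
render_scene <- function(map, placed = NULL, edges = NULL,
                         opts = render_options()) {
  if (is.null(placed)) placed <- empty_placed()
  edges <- renderable_edges(edges, placed)
  if (opts$hide_proteins) {
    placed <- empty_placed()
    edges <- empty_edges()
  }
  w <- map$width; h <- map$height
  out_w <- w * opts$scale; out_h <- h * opts$scale
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%s\" ",
                   "height=\"%s\" viewBox=\"0 0 %s %s\">"),
            fmt_px(out_w), fmt_px(out_h), fmt_px(w), fmt_px(h)),
    "<g id=\"base\">",
    sprintf("<rect x=\"0\" y=\"0\" width=\"%s\" height=\"%s\" fill=\"#ffffff\"/>",
            fmt_px(w), fmt_px(h))
  )
  if (!is.null(map$image_ref)) {
    lines <- c(lines, sprintf(
      "<image x=\"0\" y=\"0\" width=\"%s\" height=\"%s\" opacity=\"%s\" href=\"%s\"/>",
      fmt_px(w), fmt_px(h), opts$base_opacity, image_data_uri(map$image_ref)))
  }
  lines <- c(lines, "</g>", "<g id=\"rois\">")
  if (opts$show_rois) {
    for (r in map$rois) {
      pts <- paste(fmt_px(r$polygon[, 1]), fmt_px(r$polygon[, 2]),
                   sep = ",", collapse = " ")
      lines <- c(lines, sprintf(
        paste0("<polygon points=\"%s\" fill=\"%s\" fill-opacity=\"0.25\" ",
               "stroke=\"%s\" stroke-width=\"1.5\"/>"),
        pts, compartment_color(r$compartment)$hex,
        compartment_color(r$compartment, "border")$hex))
    }
  }
  lines <- c(lines, "</g>", "<g id=\"edges\">")
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      e <- edges[i, ]
      lines <- c(lines, sprintf(
        paste0("<line class=\"edge\" x1=\"%s\" y1=\"%s\" x2=\"%s\" y2=\"%s\" ",
               "stroke=\"#555555\" stroke-width=\"1\"/>"),
        fmt_px(e$x1), fmt_px(e$y1), fmt_px(e$x2), fmt_px(e$y2)))
      if (opts$show_edge_labels && !is.na(e$score_label) &&
          as.numeric(e$score_label) >= opts$score_label_min) {
        mx <- (e$x1 + e$x2) / 2; my <- (e$y1 + e$y2) / 2
        # white halo behind the score so it stays readable over the map
        lines <- c(lines, sprintf(
          paste0("<text class=\"edge-label\" x=\"%s\" y=\"%s\" font-size=\"8\" ",
                 "text-anchor=\"middle\" stroke=\"#ffffff\" stroke-width=\"2.5\" ",
                 "paint-order=\"stroke\" fill=\"#333333\">%s</text>"),
          fmt_px(mx), fmt_px(my), e$score_label))
      }
    }
  }
  lines <- c(lines, "</g>", "<g id=\"proteins\">")
  if (nrow(placed)) {
    for (i in seq_len(nrow(placed))) {
      p <- placed[i, ]
      lines <- c(lines, sprintf(
        "<circle cx=\"%s\" cy=\"%s\" r=\"%s\" fill=\"%s\" stroke=\"%s\" stroke-width=\"1.5\"/>",
        fmt_px(p$x), fmt_px(p$y), fmt_px(p$radius), p$fill,
        compartment_color(p$compartment, "border")$hex))
    }
  }
  lines <- c(lines, "</g>", "<g id=\"labels\">")
  if (opts$show_labels && nrow(placed)) {
    for (i in seq_len(nrow(placed))) {
      p <- placed[i, ]
      lines <- c(lines, sprintf(
        paste0("<text x=\"%s\" y=\"%s\" font-size=\"10\" text-anchor=\"middle\" ",
               "fill=\"#000000\">%s</text>"),
        fmt_px(p$x), fmt_px(p$y - p$radius - 3), svg_escape(p$uniprot_id)))
    }
  }
  lines <- c(lines, "</g>", "</svg>")
  structure(list(svg = lines, width = w, height = h, map = map,
                 placed = placed, edges = edges, opts = opts),
            class = "cellmap_scene")
}

#' @export
as.character.cellmap_scene <- function(x, ...) paste(x$svg, collapse = "\n")

#' @export
print.cellmap_scene <- function(x, ...) {
  cat(sprintf("<cellmap_scene %g x %g px: %d circle(s), %d edge(s)>\n",
              x$width, x$height, nrow(x$placed), nrow(x$edges)))
  invisible(x)
}

#' Write a scene to SVG
#'
#' Byte-identical output for identical scenes.
#'
#' @param scene a `cellmap_scene`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_svg <- function(scene, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(scene$svg, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Export a scene to PNG
#'
#' Rasterizes the same scene description through R's PNG graphics device at
#' `canvas size x scale` pixels (zoom as output scaling): white or image
#' base, ROI overlay, edges, circles and labels drawn in the same z-order
#' as the SVG. PNG base images are supported.
#'
#' @param scene a `cellmap_scene`.
#' @param path output path.
#' @param scale positive scaling factor applied on top of the scene's own
#'   scale option.
#' @return the path, invisibly.
#' @export
export_png <- function(scene, path, scale = 1) {
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0) {
    stop("scale must be a positive number", call. = FALSE)
  }
  s <- scale * scene$opts$scale
  w <- scene$width; h <- scene$height
  grDevices::png(path, width = round(w * s), height = round(h * s))
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, w), ylim = c(h, 0))  # y down
  graphics::rect(0, h, w, 0, col = "#ffffff", border = NA)
  if (!is.null(scene$map$image_ref)) {
    if (tolower(tools::file_ext(scene$map$image_ref)) != "png") {
      stop("PNG export supports PNG base images only", call. = FALSE)
    }
    img <- png::readPNG(scene$map$image_ref)
    op <- scene$opts$base_opacity
    if (op < 1) {
      if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
      alpha <- if (dim(img)[3] >= 4) img[, , 4] * op else op
      img <- array(c(img[, , 1:3], alpha), c(dim(img)[1:2], 4))
    }
    graphics::rasterImage(img, 0, h, w, 0)
  }
  if (scene$opts$show_rois) {
    for (r in scene$map$rois) {
      fill <- grDevices::adjustcolor(compartment_color(r$compartment)$hex, 0.25)
      graphics::polygon(r$polygon[, 1], r$polygon[, 2], col = fill,
                        border = compartment_color(r$compartment, "border")$hex)
    }
  }
  e <- scene$edges
  if (nrow(e)) {
    graphics::segments(e$x1, e$y1, e$x2, e$y2, col = "#555555")
    if (scene$opts$show_edge_labels) {
      lab <- !is.na(e$score_label) &
        as.numeric(ifelse(is.na(e$score_label), "0", e$score_label)) >=
          scene$opts$score_label_min
      if (any(lab)) {
        graphics::text((e$x1[lab] + e$x2[lab]) / 2, (e$y1[lab] + e$y2[lab]) / 2,
                       e$score_label[lab], cex = 0.6, col = "#333333")
      }
    }
  }
  p <- scene$placed
  if (nrow(p)) {
    graphics::symbols(p$x, p$y, circles = p$radius, inches = FALSE, add = TRUE,
                      bg = p$fill,
                      fg = vapply(p$compartment,
                                  function(cm) compartment_color(cm, "border")$hex, ""))
    if (scene$opts$show_labels) {
      graphics::text(p$x, p$y - p$radius - 3, p$uniprot_id, cex = 0.7)
    }
  }
  invisible(path)
}
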