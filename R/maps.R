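# Cell maps: a reference image (or blank canvas) plus named polygonal
# regions of interest (ROIs), each delimiting one compartment's area, in
# image pixel coordinates (origin top-left, y increases downward).

#' Construct a region of interest
#'
#' @param compartment compartment name the polygon delimits.
#' @param polygon numeric matrix (n x 2) or data frame of vertex `(x, y)`
#'   pixel coordinates, ordered, implicitly closed. Must have at least 3
#'   vertices, nonzero area, and be simple (non-self-intersecting); winding
#'   direction is irrelevant.
#' @return an object of class `cellmap_roi`.
#' @export
roi <- function(compartment, polygon) {
  polygon <- as.matrix(polygon)
  storage.mode(polygon) <- "double"
  errs <- validate_roi_polygon(compartment, polygon)
  if (length(errs)) stop(paste(errs, collapse = "; "), call. = FALSE)
  structure(list(compartment = compartment, polygon = polygon),
            class = "cellmap_roi")
}

validate_roi_polygon <- function(compartment, polygon) {
  errs <- character()
  who <- sprintf("ROI '%s'", compartment)
  if (!is.matrix(polygon) || ncol(polygon) != 2 || !all(is.finite(polygon))) {
    return(sprintf("%s: polygon must be a finite n x 2 coordinate matrix", who))
  }
  if (nrow(polygon) < 3) {
    errs <- c(errs, sprintf("%s: polygon needs at least 3 vertices", who))
  } else {
    if (shoelace_area(polygon) <= EPS) {
      errs <- c(errs, sprintf("%s: polygon has zero area", who))
    }
    if (!polygon_is_simple(polygon)) {
      errs <- c(errs, sprintf("%s: polygon is self-intersecting", who))
    }
  }
  errs
}

#' Construct a cell map
#'
#' @param width,height canvas size in pixels (must match the base image when
#'   one is given).
#' @param rois list of [roi()] objects. Several ROIs may share one
#'   compartment name (e.g. two lobes of the cytoplasm); placement then
#'   samples across them proportionally to area.
#' @param image_ref path to a raster image of a cell to draw under the
#'   overlay, or `NULL` to render on a blank white canvas.
#' @return an object of class `cellmap`.
#' @export
#' @examples
#' m <- cell_map(200, 200, list(
#'   roi("vacuole", rbind(c(10, 10), c(110, 10), c(110, 110), c(10, 110)))))
cell_map <- function(width, height, rois = list(), image_ref = NULL) {
  stopifnot(is.numeric(width), is.numeric(height), width > 0, height > 0)
  for (r in rois) {
    p <- r$polygon
    if (any(p[, 1] < 0 | p[, 1] > width | p[, 2] < 0 | p[, 2] > height)) {
      stop(sprintf("ROI '%s': vertices outside the %g x %g canvas",
                   r$compartment, width, height), call. = FALSE)
    }
  }
  structure(list(image_ref = image_ref, width = width, height = height,
                 rois = rois),
            class = "cellmap")
}

#' @export
print.cellmap <- function(x, ...) {
  cat(sprintf("<cellmap %g x %g px, %d ROI(s)%s>\n", x$width, x$height,
              length(x$rois),
              if (is.null(x$image_ref)) ", blank canvas" else paste0(", image ", x$image_ref)))
  invisible(x)
}

#' Read / write a cell-map file
#'
#' The map format is a GeoJSON FeatureCollection dialect: one Polygon
#' feature per ROI carrying `properties.compartment`, plus a foreign member
#' `image` object `{path, width, height}` for the canvas. Coordinates are
#' declared to be image pixel space (origin top-left, y down) rather than
#' GeoJSON's geographic y-up; rings are written closed and reopened on load.
#' Format notes ship in
#' `system.file("extdata", "cellmap-format.md", package = "cellmapr")`.
#'
#' @param path file path (conventionally `*.cellmap.geojson`).
#' @return `load_map()`: a `cellmap`. `write_map()`: the path, invisibly.
#' @export
load_map <- function(path) {
  if (!file.exists(path)) stop("cannot read map file: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  img <- doc$image
  if (is.null(img$width) || is.null(img$height)) {
    stop("map file lacks an image {path,width,height} member", call. = FALSE)
  }
  rois <- lapply(doc$features %||% list(), function(f) {
    comp <- f$properties$compartment
    if (is.null(comp)) stop("map feature lacks properties.compartment", call. = FALSE)
    ring <- f$geometry$coordinates[[1]]
    coords <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    n <- nrow(coords)
    if (n >= 2 && all(coords[1, ] == coords[n, ])) coords <- coords[-n, , drop = FALSE]
    errs <- validate_roi_polygon(comp, coords)
    if (length(errs)) stop("invalid map: ", paste(errs, collapse = "; "), call. = FALSE)
    roi(comp, coords)
  })
  cell_map(width = img$width, height = img$height, rois = rois,
           image_ref = img$path %||% NULL)
}

#' @rdname load_map
#' @param map a `cellmap`.
#' @export
write_map <- function(map, path) {
  features <- lapply(map$rois, function(r) {
    ring <- rbind(r$polygon, r$polygon[1, ])
    list(
      type = "Feature",
      properties = list(compartment = r$compartment),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(i) as.numeric(ring[i, ])))
      )
    )
  })
  doc <- list(
    type = "FeatureCollection",
    image = list(path = map$image_ref, width = map$width, height = map$height),
    features = features
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17), pretty = TRUE, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Strict-interior point containment
#'
#' Tests whether a point lies strictly inside an ROI polygon (winding-number
#' test; points on the boundary count as outside, so circles are never drawn
#' straddling a compartment border).
#'
#' @param x,y point coordinates in pixels (vectors of equal length).
#' @param roi a `cellmap_roi`.
#' @return logical vector.
#' @export
point_in_roi <- function(x, y, roi) {
  stopifnot(length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  points_in_polygon(x, y, roi$polygon)
}

#' Uniform random points inside an ROI
#'
#' Draws points uniformly over the polygon's area by rejection sampling from
#' its bounding box. Deterministic given the R RNG state (seed it with
#' [withr::with_seed()] or `set.seed()`); a budget of 10,000 attempts per
#' requested point guards against pathological sliver polygons.
#'
#' @param roi a `cellmap_roi`.
#' @param n number of points.
#' @return an n x 2 matrix of `(x, y)` coordinates, every row strictly
#'   interior to the polygon.
#' @export
sample_points <- function(roi, n = 1L) {
  stopifnot(n >= 0)
  if (n == 0L) return(matrix(numeric(), ncol = 2))
  bb <- polygon_bbox(roi$polygon)
  budget <- 10000 * n
  used <- 0
  got <- matrix(numeric(), ncol = 2)
  batch <- max(64L, 2L * as.integer(n))
  while (nrow(got) < n) {
    if (used >= budget) {
      stop(sprintf("sampling budget exhausted for compartment '%s' (sliver polygon?)",
                   roi$compartment), call. = FALSE)
    }
    take <- min(batch, budget - used)
    px <- stats::runif(take, bb["xmin"], bb["xmax"])
    py <- stats::runif(take, bb["ymin"], bb["ymax"])
    used <- used + take
    keep <- points_in_polygon(px, py, roi$polygon)
    got <- rbind(got, cbind(px[keep], py[keep]))
  }
  got[seq_len(n), , drop = FALSE]
}

#' @rdname sample_points
#' @export
sample_point <- function(roi) {
  p <- sample_points(roi, 1L)
  c(x = p[1, 1], y = p[1, 2])
}

#' ROIs matching a compartment name
#'
#' Case-insensitive, whitespace-trimmed comparison, preserving file order.
#'
#' @param map a `cellmap`.
#' @param name compartment name.
#' @return list of matching `cellmap_roi` (possibly empty).
#' @export
rois_for_compartment <- function(map, name) {
  key <- norm_compartment(name)
  Filter(function(r) norm_compartment(r$compartment) == key, map$rois)
}
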