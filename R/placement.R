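# Placing proteins on a map under the two viewer modes.
#
# Map viewer: one circle per reported localization, simultaneously.
# PPI viewer: a single circle at the first localization (array order) that
# has an ROI on the map, or at a user-chosen annotated compartment.
#
# Positions come from per-protein RNG substreams derived from
# (seed, uniprot_id), so loading an additional protein never moves the
# circles of those already placed. Circles may overlap (no collision
# avoidance); that matches the visual model being emulated.

DEFAULT_RADIUS <- 12

empty_placed <- function() {
  data.frame(uniprot_id = character(), compartment = character(),
             x = numeric(), y = numeric(), radius = numeric(),
             fill = character(), mode = character(), stringsAsFactors = FALSE)
}

empty_skipped <- function() {
  data.frame(uniprot_id = character(), compartment = character(),
             reason = character(), stringsAsFactors = FALSE)
}

placement_report <- function(placed, skipped) {
  structure(list(placed = placed, skipped = skipped),
            class = "placement_report")
}

#' @export
print.placement_report <- function(x, ...) {
  cat(sprintf("<placement: %d placed, %d skipped>\n",
              nrow(x$placed), nrow(x$skipped)))
  invisible(x)
}

# Choose among a compartment's polygons with probability proportional to
# area, then sample uniformly inside the chosen one: uniform over the
# compartment's total extent.
place_in_compartment <- function(compartment, rois) {
  areas <- vapply(rois, function(r) shoelace_area(r$polygon), 0)
  pick <- if (length(rois) == 1L) 1L else sample.int(length(rois), 1L, prob = areas)
  sample_points(rois[[pick]], 1L)
}

placed_row <- function(uniprot_id, compartment, pt, radius, mode) {
  data.frame(uniprot_id = uniprot_id, compartment = compartment,
             x = pt[1, 1], y = pt[1, 2], radius = radius,
             fill = compartment_color(compartment)$hex, mode = mode,
             stringsAsFactors = FALSE)
}

record_compartments <- function(record) {
  vapply(record$localizations, function(l) as.character(l$compartment), "")
}

#' Place a protein in map-viewer mode
#'
#' Draws one circle per reported localization whose compartment has at least
#' one ROI on the map, in localization order. Localizations without a
#' matching ROI are reported as skipped (reason `"no_roi"`), never silently
#' dropped. Every circle is filled with its compartment's hash color.
#'
#' @param record a `protein_record`.
#' @param map a `cellmap`.
#' @param seed integer seed; the protein's own substream is derived from
#'   `(seed, uniprot_id)`.
#' @param radius circle radius in pixels at native image scale.
#' @return a `placement_report`: list with `placed` (data frame of circles:
#'   accession, compartment, center, radius, fill, mode) and `skipped`
#'   (accession, compartment, reason).
#' @export
place_map_mode <- function(record, map, seed = 1L, radius = DEFAULT_RADIUS) {
  comps <- record_compartments(record)
  placed <- empty_placed()
  skipped <- empty_skipped()
  withr::with_seed(substream_seed(seed, record$uniprot_id), {
    for (comp in comps) {
      rois <- rois_for_compartment(map, comp)
      if (!length(rois)) {
        skipped <- rbind(skipped, data.frame(
          uniprot_id = record$uniprot_id, compartment = comp,
          reason = "no_roi", stringsAsFactors = FALSE))
      } else {
        placed <- rbind(placed, placed_row(record$uniprot_id, comp,
                                           place_in_compartment(comp, rois),
                                           radius, "map"))
      }
    }
  })
  placement_report(placed, skipped)
}

#' Place a protein in PPI-viewer mode
#'
#' Draws exactly one circle: by default at the first localization in the
#' record's array that has an ROI on the map (localizations tried and found
#' without an ROI are reported as skipped), or at `override_compartment`
#' when the user re-locates the protein to another of its annotated
#' compartments. An override must name an annotated compartment; if the
#' override's compartment has no ROI the protein is skipped rather than
#' falling back elsewhere, since the override models an explicit choice.
#'
#' @inheritParams place_map_mode
#' @param override_compartment annotated compartment to use instead of the
#'   first localization, or `NULL`.
#' @return a `placement_report`; `nrow(placed)` is 0 or 1.
#' @export
place_ppi_mode <- function(record, map, seed = 1L,
                           override_compartment = NULL,
                           radius = DEFAULT_RADIUS) {
  comps <- record_compartments(record)
  if (!is.null(override_compartment)) {
    hit <- which(norm_compartment(comps) == norm_compartment(override_compartment))
    if (!length(hit)) {
      stop(sprintf("override '%s' is not among the annotated localizations of %s",
                   override_compartment, record$uniprot_id), call. = FALSE)
    }
    candidates <- comps[hit[1]]
  } else {
    candidates <- comps
  }
  placed <- empty_placed()
  skipped <- empty_skipped()
  withr::with_seed(substream_seed(seed, record$uniprot_id), {
    for (comp in candidates) {
      rois <- rois_for_compartment(map, comp)
      if (!length(rois)) {
        skipped <- rbind(skipped, data.frame(
          uniprot_id = record$uniprot_id, compartment = comp,
          reason = "no_roi", stringsAsFactors = FALSE))
      } else {
        placed <- placed_row(record$uniprot_id, comp,
                             place_in_compartment(comp, rois), radius, "ppi")
        break
      }
    }
  })
  placement_report(placed, skipped)
}

#' Place several proteins at once
#'
#' Convenience wrapper used by the renderer and the CLI: applies
#' [place_map_mode()] or [place_ppi_mode()] to each record and concatenates
#' the reports. Per-protein substreams make the result independent of the
#' order of `records`.
#'
#' @param records list of `protein_record`s.
#' @param map a `cellmap`.
#' @param mode `"map"` or `"ppi"`.
#' @param seed integer seed.
#' @param overrides named character vector, accession -> compartment
#'   (PPI mode only).
#' @param radius circle radius in pixels.
#' @return a `placement_report` covering all records.
#' @export
place_proteins <- function(records, map, mode = c("ppi", "map"), seed = 1L,
                           overrides = NULL, radius = DEFAULT_RADIUS) {
  mode <- match.arg(mode)
  reports <- lapply(records, function(rec) {
    if (mode == "map") {
      place_map_mode(rec, map, seed = seed, radius = radius)
    } else {
      ov <- if (rec$uniprot_id %in% names(overrides)) overrides[[rec$uniprot_id]] else NULL
      place_ppi_mode(rec, map, seed = seed, override_compartment = ov,
                     radius = radius)
    }
  })
  placement_report(
    placed = do.call(rbind, c(list(empty_placed()), lapply(reports, `[[`, "placed"))),
    skipped = do.call(rbind, c(list(empty_skipped()), lapply(reports, `[[`, "skipped")))
  )
}
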