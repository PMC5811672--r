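# Synthetic fixtures: cell maps and protein databases generated in code, so
# every module is exercisable without external downloads. The generator
# emulates the shape of the real instance being modeled — a hand-drawn cell
# cartoon with polygonal compartments, and a proteome-scale document store
# with reliability-scored interactions — at whatever size a test needs.

#' Compartment vocabulary used by the fixture generator
#'
#' Twelve common subcellular compartments; fixed so color-collision and
#' naming tests are stable.
#' @export
COMPARTMENT_VOCABULARY <- c(
  "nucleus", "cytoplasm", "vacuole", "mitochondrion", "er", "golgi",
  "membrane", "peroxisome", "lysosome", "secreted", "nucleolus",
  "cytoskeleton")

# Star-shaped polygon around (cx, cy): regular angles with bounded jitter so
# every angular gap stays below pi, which guarantees a simple polygon for any
# radii (each edge is confined to its own convex angular wedge). Concave
# whenever the radii vary enough.
star_polygon <- function(cx, cy, rx, ry, n_vertices, concave) {
  step <- 2 * pi / n_vertices
  ang <- (seq_len(n_vertices) - 1) * step + stats::runif(n_vertices, 0, step)
  rad <- if (concave) stats::runif(n_vertices, 0.45, 1) else stats::runif(n_vertices, 0.85, 1)
  cbind(cx + rx * rad * cos(ang), cy + ry * rad * sin(ang))
}

l_polygon <- function(x0, y0, w, h) {
  # axis-aligned L: full-width bottom bar plus left column
  cut_x <- x0 + w * stats::runif(1, 0.4, 0.6)
  cut_y <- y0 + h * stats::runif(1, 0.4, 0.6)
  rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, cut_y), c(cut_x, cut_y),
        c(cut_x, y0 + h), c(x0, y0 + h))
}

#' Generate a synthetic cell map
#'
#' Lays out `n_compartments` pairwise-disjoint simple polygons — a mix of
#' convex blobs, concave blobs and L-shapes — on a blank canvas, one per
#' compartment name drawn in order from [COMPARTMENT_VOCABULARY].
#' Disjointness holds by construction: each polygon is confined to its own
#' grid cell with a margin. Deterministic per seed.
#'
#' @param n_compartments number of compartments (1 to 12).
#' @param seed integer seed.
#' @param width,height canvas size in pixels.
#' @return a `cellmap` with `image_ref = NULL`.
#' @export
#' @examples
#' m <- make_synthetic_map(4, seed = 1)
#' vapply(m$rois, function(r) r$compartment, "")
make_synthetic_map <- function(n_compartments, seed = 1L,
                               width = 800, height = 600) {
  if (n_compartments < 1 || n_compartments > length(COMPARTMENT_VOCABULARY)) {
    stop("n_compartments must be between 1 and ", length(COMPARTMENT_VOCABULARY),
         call. = FALSE)
  }
  withr::with_seed(seed, {
    ncol_ <- ceiling(sqrt(n_compartments))
    nrow_ <- ceiling(n_compartments / ncol_)
    cw <- width / ncol_; ch <- height / nrow_
    margin <- 0.08
    rois <- vector("list", n_compartments)
    for (k in seq_len(n_compartments)) {
      col <- (k - 1L) %% ncol_
      row <- (k - 1L) %/% ncol_
      x0 <- col * cw + margin * cw
      y0 <- row * ch + margin * ch
      w <- cw * (1 - 2 * margin)
      h <- ch * (1 - 2 * margin)
      shape <- k %% 3L
      poly <- if (shape == 0L) {
        l_polygon(x0, y0, w, h)
      } else {
        star_polygon(x0 + w / 2, y0 + h / 2, w / 2, h / 2,
                     n_vertices = sample(6:10, 1), concave = shape == 2L)
      }
      rois[[k]] <- roi(COMPARTMENT_VOCABULARY[k], poly)
    }
    cell_map(width, height, rois)
  })
}

fixture_accessions <- function(n, hub) {
  acc <- sprintf("P%05d", seq_len(n))
  if (hub) acc[1] <- "HUB00001"
  acc
}

#' Generate a synthetic protein database
#'
#' Builds `n_proteins` protein records whose localizations are drawn from
#' the map's compartments; a `multi_localized_fraction` of records carry 2-4
#' localizations, the rest one. A sparse background interactome (0-3
#' partners per protein, scores uniform on `[0,1]` with a fifth of edges
#' unscored) is stored one-sided at random — on one endpoint's record only —
#' to exercise edge symmetrization. If `hub_degree` is set, the record
#' `HUB00001` lists exactly that many partners, all present in the database,
#' with scores uniform on `[0.5, 1]`. Deterministic per seed; timestamps are
#' fixed so database writes are byte-stable.
#'
#' @param n_proteins number of records.
#' @param map a `cellmap` supplying compartment names (>= 1 ROI).
#' @param seed integer seed.
#' @param multi_localized_fraction fraction of records with 2-4 localizations.
#' @param hub_degree partner count of the hub record, or `NULL` for no hub;
#'   must be < `n_proteins`.
#' @return a `protein_db`.
#' @export
#' @examples
#' m <- make_synthetic_map(4, seed = 1)
#' db <- make_synthetic_db(50, m, seed = 2, hub_degree = 10)
#' length(neighborhood(db, "HUB00001")$records)
make_synthetic_db <- function(n_proteins, map, seed = 1L,
                              multi_localized_fraction = 0.3,
                              hub_degree = NULL) {
  stopifnot(n_proteins >= 1, multi_localized_fraction >= 0,
            multi_localized_fraction <= 1)
  comps <- unique(vapply(map$rois, function(r) r$compartment, ""))
  if (!length(comps)) stop("map must have at least one ROI", call. = FALSE)
  if (!is.null(hub_degree) && hub_degree >= n_proteins) {
    stop("hub_degree must be smaller than n_proteins", call. = FALSE)
  }
  ts <- "2024-01-01T00:00:00Z"
  withr::with_seed(seed, {
    acc <- fixture_accessions(n_proteins, !is.null(hub_degree))
    interactions <- stats::setNames(rep(list(list()), n_proteins), acc)
    add_edge <- function(owner, partner, score) {
      interactions[[owner]][[length(interactions[[owner]]) + 1L]] <<-
        if (is.na(score)) ppi_interaction(partner, source = "synthetic")
        else ppi_interaction(partner, score = score, source = "synthetic")
    }
    seen <- new.env(parent = emptyenv())
    has_hub <- !is.null(hub_degree)
    # background interactome, stored one-sided at random; the hub stays out
    # of it so its interaction array lists exactly hub_degree partners
    for (i in seq_len(n_proteins)) {
      if (has_hub && i == 1L) next
      k <- sample(0:3, 1)
      pool <- if (has_hub) setdiff(acc[-i], "HUB00001") else acc[-i]
      if (!k || !length(pool)) next
      partners <- sample(pool, min(k, length(pool)))
      for (p in partners) {
        key <- paste(sort(c(acc[i], p)), collapse = "|")
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        score <- if (stats::runif(1) < 0.2) NA_real_ else stats::runif(1)
        owner <- if (stats::runif(1) < 0.5) acc[i] else p
        add_edge(owner, setdiff(c(acc[i], p), owner), score)
      }
    }
    if (has_hub && hub_degree > 0) {
      hub_partners <- sample(acc[-1], hub_degree)
      for (p in hub_partners) add_edge("HUB00001", p, stats::runif(1, 0.5, 1))
    }
    records <- lapply(seq_len(n_proteins), function(i) {
      n_loc <- if (length(comps) >= 2 && stats::runif(1) < multi_localized_fraction) {
        hi <- min(4L, length(comps))
        if (hi == 2L) 2L else sample(2:hi, 1)
      } else 1L
      locs <- lapply(sample(comps, n_loc), localization, source = "synthetic")
      protein_record(
        uniprot_id = acc[i],
        gene_name = if (acc[i] == "HUB00001") "HUB1" else sprintf("GENE%04d", i),
        protein_name = sprintf("Synthetic protein %04d", i),
        interactions = interactions[[acc[i]]],
        localizations = locs,
        created_at = ts, updated_at = ts)
    })
    protein_db(records)
  })
}
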