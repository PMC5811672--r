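# Independent oracles, deliberately implemented with different algorithms
# than the package internals they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Ray-casting (crossing number) containment oracle; the package uses the
# winding number. Boundary handled separately, as in the package contract
# (boundary = outside).
oracle_point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  on_boundary <- function(x, y) {
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      x1 <- poly[i, 1]; y1 <- poly[i, 2]; x2 <- poly[j, 1]; y2 <- poly[j, 2]
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cross) < 1e-9 &&
          x >= min(x1, x2) - 1e-9 && x <= max(x1, x2) + 1e-9 &&
          y >= min(y1, y2) - 1e-9 && y <= max(y1, y2) + 1e-9) return(TRUE)
    }
    FALSE
  }
  vapply(seq_along(px), function(k) {
    x <- px[k]; y <- py[k]
    if (on_boundary(x, y)) return(FALSE)
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      yi <- poly[i, 2]; yj <- poly[j, 2]
      if ((yi > y) != (yj > y)) {
        xint <- (poly[j, 1] - poly[i, 1]) * (y - yi) / (yj - yi) + poly[i, 1]
        if (x < xint) inside <- !inside
      }
      j <- i
    }
    inside
  }, FALSE)
}

# FNV-1a 32-bit oracle built from 8-bit limb multiplication, a different
# decomposition than the package's 16-bit split.
oracle_fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(enc2utf8(s)))
  prime_limbs <- c(147, 1, 0, 1)  # 16777619 = 0x01000193, little-endian limbs
  h <- c(197, 157, 28, 129)       # 2166136261 = 0x811C9DC5, little-endian limbs
  for (b in bytes) {
    h[1] <- bitwXor(h[1], b)
    # schoolbook multiply of two 4-limb base-256 numbers, mod 2^32
    out <- numeric(4)
    for (i in 1:4) {
      for (j in 1:4) {
        if (i + j - 1 > 4) next
        out[i + j - 1] <- out[i + j - 1] + h[i] * prime_limbs[j]
      }
    }
    for (i in 1:3) {  # carry propagation
      out[i + 1] <- out[i + 1] + out[i] %/% 256
      out[i] <- out[i] %% 256
    }
    out[4] <- out[4] %% 256
    h <- out
  }
  h[1] + h[2] * 256 + h[3] * 65536 + h[4] * 16777216
}

# Brute-force O(n^2) pair scan over placed proteins (edge existence only).
oracle_global_pairs <- function(placed_ids, db) {
  lists <- lapply(db, function(r)
    vapply(r$interactions, function(it) it$partner_id, ""))
  pairs <- character()
  ids <- sort(unique(placed_ids))
  for (a in ids) for (b in ids) {
    if (a >= b) next
    if ((a %in% names(lists) && b %in% lists[[a]]) ||
        (b %in% names(lists) && a %in% lists[[b]])) {
      pairs <- c(pairs, paste(a, b, sep = "|"))
    }
  }
  sort(pairs)
}

# Naive full scan for search: every record x the three primary fields.
oracle_search_ids <- function(db, query) {
  q <- tolower(trimws(query))
  hits <- character()
  for (rec in db) {
    for (f in c("uniprot_id", "gene_name", "protein_name")) {
      v <- rec[[f]]
      if (!is.null(v) && nzchar(v) && grepl(q, tolower(v), fixed = TRUE)) {
        hits <- c(hits, rec$uniprot_id)
        break
      }
    }
  }
  sort(hits)
}

# Random simple polygon: jittered regular angles around a center keep every
# angular gap below pi, which guarantees simplicity for any radii (each edge
# stays inside its own convex angular wedge).
random_simple_polygon <- function(n_vertices = 12, cx = 100, cy = 100, r = 80) {
  step <- 2 * pi / n_vertices
  ang <- (seq_len(n_vertices) - 1) * step + runif(n_vertices, 0, step)
  rad <- runif(n_vertices, 0.3, 1) * r
  cbind(cx + rad * cos(ang), cy + rad * sin(ang))
}

square_roi <- function(compartment = "vacuole", x0 = 10, y0 = 10, side = 100) {
  roi(compartment, rbind(c(x0, y0), c(x0 + side, y0),
                         c(x0 + side, y0 + side), c(x0, y0 + side)))
}
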