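# Drawable interaction edges among loaded proteins.
#
# Interactions are stored per-record and may be one-sided (A lists B but not
# vice versa); edges are undirected and symmetrized. In map mode a
# multi-localized protein anchors all its edges at its first placed circle,
# which keeps hub neighborhoods legible instead of multiplying edges per
# localization pair.

empty_edges <- function() {
  data.frame(a = character(), b = character(), score_label = character(),
             x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric(),
             stringsAsFactors = FALSE)
}

# first placed circle per accession: the anchor every edge attaches to
edge_anchors <- function(placed) {
  placed[!duplicated(placed$uniprot_id), , drop = FALSE]
}

format_score <- function(score) {
  if (is.null(score) || is.na(score)) NA_character_ else sprintf("%.2f", score)
}

interaction_score <- function(record, partner_id) {
  for (it in record$interactions) {
    if (identical(it$partner_id, partner_id)) return(it$score %||% NULL)
  }
  NULL
}

partner_ids <- function(record) {
  vapply(record$interactions, function(it) as.character(it$partner_id), "")
}

#' Direct interaction neighborhood of a protein
#'
#' Returns the focal protein together with every interaction partner listed
#' in its record that exists in the database (the ego network of a hub, for
#' instance). Partners referenced but absent from the database are reported,
#' not silently dropped.
#'
#' @param db a `protein_db`.
#' @param focal accession of the protein of interest.
#' @return a list with `records` (focal first, then partners in interaction
#'   order) and `missing` (character vector of absent partner accessions).
#' @export
neighborhood <- function(db, focal) {
  if (!focal %in% names(db)) stop("unknown accession: ", focal, call. = FALSE)
  partners <- partner_ids(db[[focal]])
  partners <- partners[!duplicated(partners) & partners != focal]
  present <- partners[partners %in% names(db)]
  list(records = c(db[focal], db[present]),
       missing = partners[!partners %in% names(db)])
}

#' Edge overlay for a focal protein
#'
#' One edge per (focal, partner) pair where both proteins are placed in the
#' current scene, with the interaction's experimental reliability formatted
#' to two decimals as the edge label (`NA` label for unscored edges).
#'
#' @param placed data frame of placed circles (see [place_proteins()]).
#' @param db a `protein_db`.
#' @param focal accession; must be placed.
#' @return edge data frame: accessions `a`, `b`, `score_label`, endpoint
#'   coordinates `x1, y1, x2, y2`.
#' @export
edges_for_focal <- function(placed, db, focal) {
  anchors <- edge_anchors(placed)
  if (!focal %in% anchors$uniprot_id) {
    stop("focal protein is not placed: ", focal, call. = FALSE)
  }
  fa <- anchors[anchors$uniprot_id == focal, ]
  partners <- partner_ids(db[[focal]])
  partners <- partners[!duplicated(partners) & partners != focal]
  partners <- partners[partners %in% anchors$uniprot_id]
  if (!length(partners)) return(empty_edges())
  rows <- lapply(partners, function(p) {
    pa <- anchors[anchors$uniprot_id == p, ]
    data.frame(a = focal, b = p,
               score_label = format_score(interaction_score(db[[focal]], p) %||% NA),
               x1 = fa$x, y1 = fa$y, x2 = pa$x, y2 = pa$y,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Global edge overlay among all placed proteins
#'
#' One undirected, deduplicated edge per pair of placed proteins that either
#' record lists as interacting — the stored direction never matters. The
#' label comes from whichever record carries the score (the lexicographically
#' smaller accession's record wins if both do).
#'
#' @inheritParams edges_for_focal
#' @return edge data frame as in [edges_for_focal()].
#' @export
global_edges <- function(placed, db) {
  anchors <- edge_anchors(placed)
  ids <- sort(anchors$uniprot_id)
  if (length(ids) < 2) return(empty_edges())
  rows <- list()
  for (i in seq_len(length(ids) - 1L)) {
    for (j in seq(i + 1L, length(ids))) {
      a <- ids[i]; b <- ids[j]
      ab <- a %in% names(db) && b %in% partner_ids(db[[a]])
      ba <- b %in% names(db) && a %in% partner_ids(db[[b]])
      if (!ab && !ba) next
      score <- if (ab) interaction_score(db[[a]], b) %||% NA else NA
      if ((is.null(score) || is.na(score)) && ba) {
        score <- interaction_score(db[[b]], a) %||% NA
      }
      pa <- anchors[anchors$uniprot_id == a, ]
      pb <- anchors[anchors$uniprot_id == b, ]
      rows[[length(rows) + 1L]] <- data.frame(
        a = a, b = b, score_label = format_score(score),
        x1 = pa$x, y1 = pa$y, x2 = pb$x, y2 = pb$y,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) empty_edges() else do.call(rbind, rows)
}
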