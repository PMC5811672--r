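# Search over the protein database, mirroring the result-grid semantics:
# each hit reports its localization chips, its interaction-partner count,
# and — for proteins annotated in exactly one compartment — the compartment
# color to paint the result box border with.

SEARCH_FIELDS <- c("uniprot_id", "gene_name", "protein_name")

#' Search the protein database
#'
#' Case-insensitive substring match of the query against UniProt accession,
#' primary gene name and primary protein name. `matched_field` records the
#' first of those three fields (in that fixed order) that matched; results
#' are ordered by accession.
#'
#' @param db a `protein_db`.
#' @param query non-empty search text.
#' @return a data frame with one row per hit: `uniprot_id`, `matched_field`,
#'   `compartments` (list column, ordered annotation names), `partner_count`,
#'   and `border_color` (hex string when the protein has exactly one
#'   annotated compartment, `NA` otherwise).
#' @export
#' @examples
#' db <- protein_db(list(protein_record("P34932", gene_name = "HSPA4")))
#' search_proteins(db, "hspa")
search_proteins <- function(db, query) {
  q <- tolower(trimws(query))
  if (!nzchar(q)) stop("search query must be non-empty", call. = FALSE)
  hits <- list()
  for (rec in db) {
    matched <- NA_character_
    for (f in SEARCH_FIELDS) {
      val <- rec[[f]] %||% ""
      if (nzchar(val) && grepl(q, tolower(val), fixed = TRUE)) {
        matched <- f
        break
      }
    }
    if (is.na(matched)) next
    comps <- record_compartments(rec)
    hits[[length(hits) + 1L]] <- data.frame(
      uniprot_id = rec$uniprot_id,
      matched_field = matched,
      compartments = I(list(comps)),
      partner_count = length(rec$interactions),
      border_color = if (length(comps) == 1L) compartment_color(comps)$hex else NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(empty_search_results())
  out <- do.call(rbind, hits)
  out[order(out$uniprot_id), , drop = FALSE]
}

empty_search_results <- function() {
  data.frame(uniprot_id = character(), matched_field = character(),
             compartments = I(list()), partner_count = integer(),
             border_color = character(), stringsAsFactors = FALSE)
}

#' Filter search results by compartment
#'
#' Keeps the results annotated (anywhere in their localization array) with
#' the given compartment, case-insensitively; order is preserved. This is
#' the "click a compartment chip" interaction: idempotent, and always a
#' subset of its input.
#'
#' @param results a data frame from [search_proteins()].
#' @param name compartment name.
#' @return the filtered data frame.
#' @export
filter_by_compartment <- function(results, name) {
  key <- norm_compartment(name)
  keep <- vapply(results$compartments,
                 function(cs) any(norm_compartment(cs) == key), FALSE)
  results[keep, , drop = FALSE]
}
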