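# Protein document database.
#
# One JSON document per protein: identifiers, an ordered array of
# interaction partners (with optional experimental reliability score) and an
# ordered array of localization annotations. Localization order is semantic:
# the PPI viewer places a protein at its *first* localization, so round-trips
# must preserve array order exactly. Timestamps are carried verbatim and
# never interpreted.

#' Construct a protein record
#'
#' @param uniprot_id UniProt accession (primary key, e.g. `"P34932"`).
#' @param gene_name primary gene name.
#' @param protein_name primary protein name.
#' @param interactions list of interactions, each a list with `partner_id`,
#'   optional `score` (reliability in `[0,1]`; absent means unscored, which
#'   is distinct from zero) and optional `source`.
#' @param localizations ordered list of annotations, each a list with
#'   `compartment` and optional `source`. Order is significant: the first
#'   entry is the protein's primary localization.
#' @param created_at,updated_at ISO-8601 timestamps, carried but not used.
#' @return an object of class `protein_record`.
#' @export
#' @examples
#' protein_record("P34932", "HSPA4", "Heat shock 70 kDa protein 4",
#'   interactions = list(ppi_interaction("P11142", score = 0.89)),
#'   localizations = list(localization("cytoplasm"), localization("nucleus")))
protein_record <- function(uniprot_id, gene_name = "", protein_name = "",
                           interactions = list(), localizations = list(),
                           created_at = "1970-01-01T00:00:00Z",
                           updated_at = created_at) {
  structure(
    list(uniprot_id = uniprot_id, gene_name = gene_name,
         protein_name = protein_name, interactions = interactions,
         localizations = localizations, created_at = created_at,
         updated_at = updated_at),
    class = "protein_record"
  )
}

#' @rdname protein_record
#' @param partner_id partner accession.
#' @param score experimental reliability in `[0,1]`, or `NULL` for an
#'   unscored (unlabeled) edge.
#' @param source free-text provenance (e.g. database of origin).
#' @export
ppi_interaction <- function(partner_id, score = NULL, source = "") {
  out <- list(partner_id = partner_id, source = source)
  if (!is.null(score)) out$score <- score
  out
}

#' @rdname protein_record
#' @param compartment compartment name (matched against ROI names
#'   case-insensitively after trimming).
#' @export
localization <- function(compartment, source = "") {
  list(compartment = compartment, source = source)
}

#' Construct a protein database
#'
#' A database is an ordered collection of protein records keyed by accession.
#'
#' @param records list of `protein_record` objects.
#' @return an object of class `protein_db` (a named list, accession -> record).
#' @export
protein_db <- function(records = list()) {
  ids <- vapply(records, function(r) as.character(r$uniprot_id %||% ""), "")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate accession(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  names(records) <- ids
  structure(records, class = "protein_db")
}

#' @export
print.protein_db <- function(x, ...) {
  cat(sprintf("<protein_db: %d records>\n", length(x)))
  invisible(x)
}

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

iso8601_ok <- function(x) {
  is_scalar_string(x) &&
    grepl("^\\d{4}-\\d{2}-\\d{2}([T ]\\d{2}:\\d{2}(:\\d{2}(\\.\\d+)?)?(Z|[+-]\\d{2}:?\\d{2})?)?$", x)
}

#' Validate a protein record
#'
#' Checks every type invariant of the document model and returns diagnostics
#' instead of raising: non-empty accession, interaction scores inside
#' `[0,1]`, non-empty partner accessions, non-empty compartment names after
#' trimming, parseable ISO-8601 timestamps.
#'
#' @param record a `protein_record` (or an equivalent plain list, e.g. one
#'   document freshly parsed from JSON).
#' @return a data frame with columns `field` and `message`; zero rows iff the
#'   record is valid.
#' @export
validate_protein <- function(record) {
  bad <- list()
  note <- function(field, message) bad[[length(bad) + 1L]] <<- list(field = field, message = message)

  if (!is_scalar_string(record$uniprot_id) || !nzchar(trimws(record$uniprot_id))) {
    note("uniprot_id", "accession must be a non-empty string")
  }
  for (nm in c("gene_name", "protein_name")) {
    if (!is.null(record[[nm]]) && !is_scalar_string(record[[nm]])) {
      note(nm, "must be a string")
    }
  }
  ints <- record$interactions %||% list()
  if (!is.list(ints)) {
    note("interactions", "must be an array")
  } else {
    for (i in seq_along(ints)) {
      it <- ints[[i]]
      if (!is_scalar_string(it$partner_id) || !nzchar(trimws(it$partner_id))) {
        note(sprintf("interactions[%d].partner_id", i), "partner accession must be non-empty")
      }
      if (!is.null(it$score)) {
        if (!is.numeric(it$score) || length(it$score) != 1L || is.na(it$score) ||
            it$score < 0 || it$score > 1) {
          note(sprintf("interactions[%d].score", i), "score must lie in [0,1] or be absent")
        }
      }
    }
  }
  locs <- record$localizations %||% list()
  if (!is.list(locs)) {
    note("localizations", "must be an array")
  } else {
    for (i in seq_along(locs)) {
      lc <- locs[[i]]
      if (!is_scalar_string(lc$compartment) || !nzchar(trimws(lc$compartment))) {
        note(sprintf("localizations[%d].compartment", i), "compartment name must be non-empty after trimming")
      }
    }
  }
  for (nm in c("created_at", "updated_at")) {
    if (!is.null(record[[nm]]) && !iso8601_ok(record[[nm]])) {
      note(nm, "must be an ISO-8601 timestamp")
    }
  }
  data.frame(
    field = vapply(bad, `[[`, "", "field"),
    message = vapply(bad, `[[`, "", "message"),
    stringsAsFactors = FALSE
  )
}

record_from_document <- function(doc) {
  protein_record(
    uniprot_id = doc$uniprot_id,
    gene_name = doc$gene_name %||% "",
    protein_name = doc$protein_name %||% "",
    interactions = doc$interactions %||% list(),
    localizations = doc$localizations %||% list(),
    created_at = doc$created_at %||% "1970-01-01T00:00:00Z",
    updated_at = doc$updated_at %||% doc$created_at %||% "1970-01-01T00:00:00Z"
  )
}

#' Read / write a protein database
#'
#' The on-disk format is a single JSON array of protein documents (schema in
#' `system.file("extdata", "protein-db.schema.json", package = "cellmapr")`).
#' `load_protein_db()` validates every document; invalid documents are
#' dropped with a warning naming the document index and offending field(s)
#' (or raise an error with `strict = TRUE`). Duplicate accessions are always
#' an error. `write_protein_db()` is the exact inverse: write-then-load is
#' the identity on all fields, including array order, and the output bytes
#' are stable across repeated writes.
#'
#' @param path file path.
#' @param strict error (rather than warn and skip) on invalid documents.
#' @return `load_protein_db()`: a `protein_db`. `write_protein_db()`: the
#'   path, invisibly.
#' @export
load_protein_db <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("cannot read protein database: ", path, call. = FALSE)
  docs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!is.list(docs)) stop("protein database must be a JSON array of documents", call. = FALSE)
  records <- list()
  problems <- character()
  for (i in seq_along(docs)) {
    diag <- validate_protein(docs[[i]])
    if (nrow(diag)) {
      problems <- c(problems, sprintf("document %d: %s (%s)", i, diag$field, diag$message))
    } else {
      records[[length(records) + 1L]] <- record_from_document(docs[[i]])
    }
  }
  if (length(problems)) {
    msg <- paste(problems, collapse = "; ")
    if (strict) stop("invalid protein document(s): ", msg, call. = FALSE)
    warning("skipped invalid protein document(s): ", msg, call. = FALSE)
  }
  protein_db(records)
}

#' @rdname load_protein_db
#' @param db a `protein_db`.
#' @export
write_protein_db <- function(db, path) {
  docs <- lapply(unname(db), function(r) {
    r <- unclass(r)
    # empty arrays must serialize as [], not {}
    if (!length(r$interactions)) r$interactions <- list()
    if (!length(r$localizations)) r$localizations <- list()
    r
  })
  # I(17) significant digits: doubles (reliability scores) survive the
  # round-trip bit-exactly
  json <- jsonlite::toJSON(docs, auto_unbox = TRUE, digits = I(17), pretty = TRUE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}
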