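#' @keywords internal
"_PACKAGE"

# Compartment names are user-authored free text; all comparisons between
# annotation strings and ROI names go through this normalization.
norm_compartment <- function(x) tolower(trimws(x))

#' 32-bit FNV-1a hash
#'
#' Fowler-Noll-Vo 1a hash over the UTF-8 bytes of a string, computed in
#' double-precision arithmetic with a 16-bit split multiply so the full
#' unsigned 32-bit range is exact. Pure integer arithmetic, no locale
#' dependence; used to derive stable compartment hues.
#'
#' @param x a character scalar.
#' @return the hash as a double in `[0, 2^32)`.
#' @export
#' @examples
#' fnv1a32("vacuole")
fnv1a32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  bytes <- as.integer(charToRaw(enc2utf8(x)))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    # (h * 16777619) mod 2^32, split to stay below 2^53
    hi16 <- h %/% 65536
    lo16 <- h %% 65536
    h <- (((hi16 * 16777619) %% 65536) * 65536 + lo16 * 16777619) %% 4294967296
  }
  h
}

# Deterministic per-entity sub-seed so adding a protein to a scene never
# reshuffles the positions of the others.
substream_seed <- function(seed, id) {
  (as.numeric(seed) + fnv1a32(id)) %% 2147483647
}

# Fixed-precision coordinate formatting: all geometry written to SVG goes
# through this, which is what makes renders byte-stable across runs.
fmt_px <- function(x) sprintf("%.2f", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
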