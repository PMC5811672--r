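# Deterministic compartment coloring.
#
# Each compartment gets its hue from a hash of its (trimmed, lower-cased)
# name, so the same compartment is drawn in the same color on every map, in
# every process, on every platform. Saturation and lightness are fixed
# constants; fills are lighter than borders.

PALETTE <- list(saturation = 0.65, lightness_fill = 0.55, lightness_border = 0.35)

hsl_to_hex <- function(h, s, l) {
  c <- (1 - abs(2 * l - 1)) * s
  x <- c * (1 - abs((h / 60) %% 2 - 1))
  m <- l - c / 2
  rgb1 <- if (h < 60) c(c, x, 0) else if (h < 120) c(x, c, 0) else
    if (h < 180) c(0, c, x) else if (h < 240) c(0, x, c) else
    if (h < 300) c(x, 0, c) else c(c, 0, x)
  ch <- as.integer(round(255 * (rgb1 + m)))
  sprintf("#%02x%02x%02x", ch[1], ch[2], ch[3])
}

#' Deterministic color for a compartment name
#'
#' Assigns every compartment a stable color derived from the 32-bit FNV-1a
#' hash of its normalized name: `hue = hash mod 360` degrees, with fixed
#' saturation and lightness. Names differing only in case or surrounding
#' whitespace receive identical colors, so user-authored localization
#' annotations match ROI names robustly. Hues are deterministic per name but
#' not guaranteed collision-free (unbounded name space).
#'
#' @param name compartment name, non-empty after trimming.
#' @param role `"fill"` (protein circles, ROI fills) or `"border"` (a darker
#'   variant of the same hue used for outlines).
#' @return an object of class `cellmap_color`: a list with `hue` (degrees),
#'   `saturation`, `lightness` (fractions) and `hex` (RGB string).
#' @export
#' @examples
#' compartment_color("vacuole")$hex
#' identical(compartment_color("Vacuole"), compartment_color("vacuole"))
compartment_color <- function(name, role = c("fill", "border")) {
  role <- match.arg(role)
  key <- norm_compartment(name)
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(key)) {
    stop("compartment name must be a non-empty string", call. = FALSE)
  }
  hue <- fnv1a32(key) %% 360
  l <- if (role == "fill") PALETTE$lightness_fill else PALETTE$lightness_border
  structure(
    list(hue = hue, saturation = PALETTE$saturation, lightness = l,
         hex = hsl_to_hex(hue, PALETTE$saturation, l)),
    class = "cellmap_color"
  )
}

#' @export
print.cellmap_color <- function(x, ...) {
  cat(sprintf("<color hue=%.0f s=%.2f l=%.2f %s>\n",
              x$hue, x$saturation, x$lightness, x$hex))
  invisible(x)
}
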