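#' Signed percent change relative to a reference
#'
#' Computes `100 * (variant - reference) / reference`, the convention used
#' throughout for comparing phene states (e.g. respiration of reduced versus
#' increased cortical cell file number).
#'
#' @param reference Positive reference value(s).
#' @param variant Value(s) to compare against the reference.
#' @return Signed percent change, vectorised over its arguments.
#' @examples
#' percent_change(0.044, 0.014)  # about -68: reduced CCFN respires 68% less
#' @export
percent_change <- function(reference, variant) {
  if (!is.numeric(reference) || !is.numeric(variant)) {
    stop("`reference` and `variant` must be numeric", call. = FALSE)
  }
  if (any(reference <= 0)) {
    stop("`reference` must be strictly positive", call. = FALSE)
  }
  100 * (variant - reference) / reference
}

#' Round half away from zero
#'
#' Commercial rounding used when reporting percent differences as integers;
#' unlike [round()], halves move away from zero (-67.5 -> -68).
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Report a percent change as rounded magnitude plus direction
#'
#' @param reference Positive reference value.
#' @param variant Comparison value.
#' @param what Optional quantity name included in the phrase.
#' @return A list with `percent` (signed, unrounded), `magnitude` (rounded
#'   integer magnitude), `direction` ("less", "larger" or "equal") and
#'   `phrase` (e.g. "68% less respiration").
#' @export
describe_percent_change <- function(reference, variant, what = NULL) {
  pc <- percent_change(reference, variant)
  mag <- round_half_away(abs(pc))
  dir <- if (pc < 0) "less" else if (pc > 0) "larger" else "equal"
  phrase <- if (dir == "equal") {
    paste0("no change", if (!is.null(what)) paste0(" in ", what))
  } else {
    paste0(mag, "% ", dir, if (!is.null(what)) paste0(" ", what))
  }
  list(percent = pc, magnitude = mag, direction = dir, phrase = phrase)
}
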