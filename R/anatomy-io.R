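ANATOMY_COLUMNS <- c("genotype_id", "category", "n_level",
                     "ccfn", "ccs", "respiration", "tissue_n", "diameter")

ANATOMY_CATEGORIES <- c("reduced_ccfn", "increased_ccfn", "small_ccs", "large_ccs")

#' Validate a set of anatomy observations
#'
#' Checks the plant-level anatomy/cost records used to parameterize the
#' phene-cost regressions: one row per plant and nitrogen level, with the
#' measured cortical cell file number (CCFN), cortical cell size (CCS),
#' root respiration, tissue nitrogen and root diameter.
#'
#' @param observations Data frame with columns `genotype_id`, `category`,
#'   `n_level`, `ccfn`, `ccs`, `respiration`, `tissue_n`, `diameter`.
#' @param strict_ranges If `TRUE` (default), CCFN must lie in [6, 18] and
#'   CCS in [170, 445], the observed anatomical ranges in maize.
#' @return The validated data frame, invisibly.
#' @export
validate_anatomy <- function(observations, strict_ranges = TRUE) {
  missing_cols <- setdiff(ANATOMY_COLUMNS, names(observations))
  if (length(missing_cols)) {
    stop("anatomy observations lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(observations$category %in% ANATOMY_CATEGORIES)) {
    stop("category must be one of ", paste(ANATOMY_CATEGORIES, collapse = ", "),
         call. = FALSE)
  }
  if (!all(observations$n_level %in% c("high", "low"))) {
    stop("n_level must be 'high' or 'low'", call. = FALSE)
  }
  num <- observations[c("ccfn", "ccs", "respiration", "tissue_n", "diameter")]
  if (any(!vapply(num, is.numeric, logical(1)))) {
    stop("measurement columns must be numeric", call. = FALSE)
  }
  if (anyNA(num)) stop("measurement columns contain missing values", call. = FALSE)
  if (any(num$respiration <= 0) || any(num$tissue_n <= 0) || any(num$diameter <= 0)) {
    stop("respiration, tissue_n and diameter must be strictly positive",
         call. = FALSE)
  }
  if (strict_ranges) {
    if (any(observations$ccfn < 6 | observations$ccfn > 18)) {
      stop("ccfn outside the observed range [6, 18]", call. = FALSE)
    }
    if (any(observations$ccs < 170 | observations$ccs > 445)) {
      stop("ccs outside the observed range [170, 445]", call. = FALSE)
    }
  }
  invisible(observations)
}

#' Read anatomy observations from CSV
#'
#' @param path Path to a CSV file with the fixed anatomy header
#'   (`genotype_id, category, n_level, ccfn, ccs, respiration, tissue_n,
#'   diameter`).
#' @param strict_ranges Passed to [validate_anatomy()].
#' @return A validated data frame of observations.
#' @export
read_anatomy <- function(path, strict_ranges = TRUE) {
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_anatomy(obs, strict_ranges = strict_ranges)
  obs
}

#' Write anatomy observations to CSV
#'
#' @param observations Data frame of observations (validated before writing).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_anatomy <- function(observations, path) {
  validate_anatomy(observations)
  utils::write.csv(observations[ANATOMY_COLUMNS], path, row.names = FALSE)
  invisible(path)
}
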