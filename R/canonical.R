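#' Canonical phene-state predictions
#'
#' The four canonical phene states of the root cortex -- reduced and
#' increased cortical cell file number (CCFN, 6 vs 18 files at CCS 360
#' micron^2) and large and small cortical cell size (CCS, 450 vs 200
#' micron^2 at CCFN 10) -- together with the regression-predicted root
#' respiration (g CO2 g^-1 DW d^-1), optimum and minimum tissue nitrogen
#' (umol g^-1) and root diameter (mm) for each. These predictions are the
#' currency between the anatomical cost model and the root/soil simulator.
#'
#' @return A data frame with columns `phene_state`, `ccfn`, `ccs`,
#'   `respiration`, `optimum_n`, `minimum_n`, `diameter`; one row per
#'   canonical state, row names equal to `phene_state`.
#' @examples
#' canonical_phene_states()["reduced_ccfn", "respiration"]
#' @export
canonical_phene_states <- function() {
  path <- system.file("extdata", "canonical_phene_states.csv",
                      package = "rootcortex", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(
    nrow(tab) == 4L,
    all(tab$minimum_n < tab$optimum_n),
    all(tab$respiration > 0), all(tab$diameter > 0)
  )
  rownames(tab) <- tab$phene_state
  tab
}

#' Canonical predictions for one phene state
#'
#' @param label One of `"reduced_ccfn"`, `"increased_ccfn"`, `"large_ccs"`,
#'   `"small_ccs"`.
#' @return A list with `ccfn`, `ccs` and the prediction fields
#'   `respiration`, `optimum_n`, `minimum_n`, `diameter`.
#' @export
canonical_prediction <- function(label) {
  tab <- canonical_phene_states()
  if (!label %in% rownames(tab)) {
    stop("unknown phene state '", label, "'; expected one of ",
         paste(rownames(tab), collapse = ", "), call. = FALSE)
  }
  as.list(tab[label, c("ccfn", "ccs", "respiration",
                       "optimum_n", "minimum_n", "diameter")])
}

# Plane coefficients through the canonical predictions, one OLS fit per
# response. The published predictions are numerically planar (within ~1%),
# so this recovers the cost surface used for arbitrary (ccfn, ccs).
canonical_cost_coefficients_impl <- function() {
  tab <- canonical_phene_states()
  responses <- c("respiration", "optimum_n", "minimum_n", "diameter")
  coefs <- sapply(responses, function(r) {
    stats::coef(stats::lm(tab[[r]] ~ ccfn + ccs, data = tab))
  })
  rownames(coefs) <- c("intercept", "ccfn", "ccs")
  coefs
}

.canonical_cache <- new.env(parent = emptyenv())

#' Cost-surface coefficients anchored to the canonical predictions
#'
#' One ordinary-least-squares plane per response, fitted through the four
#' canonical phene states. Used to predict respiration, nitrogen
#' requirements and diameter for arbitrary (CCFN, CCS) combinations in
#' sensitivity grids and factorial experiments.
#'
#' @return A 3 x 4 numeric matrix; rows `intercept`, `ccfn`, `ccs`, columns
#'   `respiration`, `optimum_n`, `minimum_n`, `diameter`.
#' @export
canonical_cost_coefficients <- function() {
  if (is.null(.canonical_cache$coefs)) {
    .canonical_cache$coefs <- canonical_cost_coefficients_impl()
  }
  .canonical_cache$coefs
}

#' Predict phene costs from the canonical cost surface
#'
#' @param ccfn Cortical cell file number (count, 6-18).
#' @param ccs Cortical cell size (micron^2, 170-450).
#' @return A list with `respiration`, `optimum_n`, `minimum_n`, `diameter`.
#' @export
canonical_costs_at <- function(ccfn, ccs) {
  stopifnot(length(ccfn) == 1L, length(ccs) == 1L)
  co <- canonical_cost_coefficients()
  pred <- as.list(drop(c(1, ccfn, ccs) %*% co))
  validate_prediction(pred, ccfn = ccfn, ccs = ccs)
  pred
}

# Shared validation of a (respiration, optimum_n, minimum_n, diameter)
# prediction: positivity and ordering of the nitrogen requirements.
validate_prediction <- function(pred, ccfn = NA, ccs = NA) {
  vals <- unlist(pred[c("respiration", "optimum_n", "minimum_n", "diameter")])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("parameterization error: non-positive prediction at ccfn=", ccfn,
         ", ccs=", ccs, call. = FALSE)
  }
  if (pred$minimum_n >= pred$optimum_n) {
    stop("parameterization error: minimum_n >= optimum_n at ccfn=", ccfn,
         ", ccs=", ccs, call. = FALSE)
  }
  invisible(pred)
}
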