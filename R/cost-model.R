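#' Fit the anatomical phene-cost model
#'
#' Fits four independent multiple linear regressions predicting root
#' respiration, optimum tissue nitrogen, minimum tissue nitrogen and root
#' diameter from cortical cell file number (CCFN) and cortical cell size
#' (CCS). Respiration and diameter are fitted on all observations; the
#' optimum-nitrogen model is fitted on tissue nitrogen measured under high
#' nitrogen and the minimum-nitrogen model on tissue nitrogen under low
#' nitrogen, mirroring the high/low solution design used to collect the
#' parameterization data.
#'
#' @param observations Data frame of plant-level records, see
#'   [validate_anatomy()] for the required columns.
#' @return An object of class `phene_cost_model`: a list with `coefficients`
#'   (3 x 4 matrix, rows `intercept`, `ccfn`, `ccs`), `diagnostics` (R^2,
#'   residual SD and n per response), `fits` (the underlying [stats::lm]
#'   objects) and `nobs`.
#' @seealso [predict.phene_cost_model()], [canonical_phene_states()]
#' @examples
#' spec <- default_anatomy_generator(noise_sd = c(0, 0, 0, 0))
#' obs <- generate_anatomy_dataset(spec)
#' fit <- fit_cost_models(obs)
#' coef(fit)
#' @export
fit_cost_models <- function(observations) {
  validate_anatomy(observations, strict_ranges = FALSE)
  if (nrow(observations) < 4L) {
    stop("need at least 4 observations to fit the cost model", call. = FALSE)
  }
  if (length(unique(observations$ccfn)) == 1L &&
      length(unique(observations$ccs)) == 1L) {
    stop("degenerate design: ccfn and ccs are both constant", call. = FALSE)
  }

  subsets <- list(
    respiration = list(data = observations, response = "respiration"),
    optimum_n   = list(data = observations[observations$n_level == "high", ],
                       response = "tissue_n"),
    minimum_n   = list(data = observations[observations$n_level == "low", ],
                       response = "tissue_n"),
    diameter    = list(data = observations, response = "diameter")
  )

  fits <- lapply(names(subsets), function(nm) {
    s <- subsets[[nm]]
    if (nrow(s$data) < 3L) {
      stop("too few observations to fit the ", nm, " model", call. = FALSE)
    }
    fml <- stats::reformulate(c("ccfn", "ccs"), response = s$response)
    fit <- stats::lm(fml, data = s$data)
    if (fit$rank < 3L || anyNA(stats::coef(fit))) {
      stop("degenerate design for the ", nm,
           " model: ccfn and ccs are collinear", call. = FALSE)
    }
    fit
  })
  names(fits) <- names(subsets)

  coefs <- sapply(fits, stats::coef)
  rownames(coefs) <- c("intercept", "ccfn", "ccs")
  diagnostics <- t(sapply(fits, function(f) {
    s <- suppressWarnings(summary(f))
    c(r_squared = s$r.squared, residual_sd = s$sigma,
      n = length(stats::residuals(f)))
  }))

  structure(
    list(coefficients = coefs, diagnostics = as.data.frame(diagnostics),
         fits = fits, nobs = nrow(observations)),
    class = "phene_cost_model"
  )
}

#' @export
coef.phene_cost_model <- function(object, ...) object$coefficients

#' @export
print.phene_cost_model <- function(x, ...) {
  cat("Phene-cost model: 4 linear regressions on (ccfn, ccs),",
      x$nobs, "observations\n\nCoefficients:\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
summary.phene_cost_model <- function(object, ...) {
  structure(list(coefficients = object$coefficients,
                 diagnostics = object$diagnostics, nobs = object$nobs),
            class = "summary.phene_cost_model")
}

#' @export
print.summary.phene_cost_model <- function(x, ...) {
  cat("Phene-cost model (", x$nobs, " observations)\n\nCoefficients:\n", sep = "")
  print(x$coefficients)
  cat("\nDiagnostics:\n")
  print(x$diagnostics)
  invisible(x)
}

#' Predict phene costs for (CCFN, CCS) combinations
#'
#' Evaluates the four fitted cost regressions. Combinations outside the
#' anatomical domain (CCFN in [6, 18], CCS in [170, 450]) trigger a warning
#' because the model should not be extrapolated toward unrealistic anatomy.
#'
#' @param object A `phene_cost_model` from [fit_cost_models()].
#' @param ccfn,ccs Numeric vectors (recycled to a common length).
#' @param ... Unused.
#' @return A data frame with columns `ccfn`, `ccs`, `respiration`,
#'   `optimum_n`, `minimum_n`, `diameter`.
#' @export
predict.phene_cost_model <- function(object, ccfn, ccs, ...) {
  n <- max(length(ccfn), length(ccs))
  ccfn <- rep_len(ccfn, n)
  ccs <- rep_len(ccs, n)
  if (any(ccfn < 6 | ccfn > 18) || any(ccs < 170 | ccs > 450)) {
    warning("prediction outside the observed anatomical domain ",
            "(ccfn in [6, 18], ccs in [170, 450])", call. = FALSE)
  }
  X <- cbind(1, ccfn, ccs)
  pred <- X %*% object$coefficients
  out <- data.frame(ccfn = ccfn, ccs = ccs, pred)
  for (i in seq_len(n)) {
    validate_prediction(as.list(out[i, ]), ccfn = ccfn[i], ccs = ccs[i])
  }
  out
}

#' Predict costs for a single anatomy
#'
#' Convenience wrapper around [predict.phene_cost_model()] returning a
#' plain list for a single (CCFN, CCS) pair.
#'
#' @inheritParams predict.phene_cost_model
#' @param model A `phene_cost_model`.
#' @return A list with `respiration`, `optimum_n`, `minimum_n`, `diameter`.
#' @export
predict_costs <- function(model, ccfn, ccs) {
  stopifnot(inherits(model, "phene_cost_model"),
            length(ccfn) == 1L, length(ccs) == 1L)
  out <- predict(model, ccfn = ccfn, ccs = ccs)
  as.list(out[1, c("respiration", "optimum_n", "minimum_n", "diameter")])
}
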