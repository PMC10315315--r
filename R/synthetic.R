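#' Specification for the synthetic anatomy-data generator
#'
#' Defines the structure of a synthetic parameterization dataset: 4
#' anatomical categories (reduced/increased CCFN, small/large CCS) times
#' `genotypes_per_category` genotypes times `plants_per_genotype` plants
#' times 2 nitrogen levels, with responses lying on a shared generating
#' plane per response plus independent Gaussian noise. Tissue nitrogen
#' measured under high nitrogen realizes the optimum-N plane and under low
#' nitrogen the minimum-N plane.
#'
#' @param seed Integer seed; the generator is fully deterministic given the
#'   spec (including its seed).
#' @param genotypes_per_category,plants_per_genotype Counts (defaults 3, 3,
#'   giving the 12-genotype, 72-record design of the greenhouse study the
#'   generator emulates).
#' @param coefficients 3 x 4 matrix of generating coefficients (rows
#'   `intercept`, `ccfn`, `ccs`; columns `respiration`, `optimum_n`,
#'   `minimum_n`, `diameter`). Defaults to the canonical cost surface.
#' @param noise_sd Length-4 vector of response noise SDs, in response units,
#'   named or ordered as the coefficient columns.
#' @param ranges Named list of category sampling windows:
#'   `reduced_ccfn`, `increased_ccfn` (CCFN windows), `small_ccs`,
#'   `large_ccs` (CCS windows), plus `mid_ccfn` and `mid_ccs`, the windows
#'   for the non-focal phene in each category.
#' @param n_level_effect Fractional reduction applied to respiration and
#'   tissue N of low-nitrogen records (default 0: both treatments realize
#'   the same planes, so pooled fitting is unbiased).
#' @return An object of class `anatomy_generator_spec`.
#' @export
anatomy_generator_spec <- function(seed = 1L,
                                   genotypes_per_category = 3L,
                                   plants_per_genotype = 3L,
                                   coefficients = canonical_cost_coefficients(),
                                   noise_sd = c(respiration = 0.003,
                                                optimum_n = 35,
                                                minimum_n = 30,
                                                diameter = 0.05),
                                   ranges = list(
                                     reduced_ccfn = c(6, 9),
                                     increased_ccfn = c(14, 18),
                                     small_ccs = c(170, 260),
                                     large_ccs = c(360, 445),
                                     mid_ccfn = c(10, 13),
                                     mid_ccs = c(270, 350)
                                   ),
                                   n_level_effect = 0) {
  responses <- c("respiration", "optimum_n", "minimum_n", "diameter")
  coefficients <- as.matrix(coefficients)
  stopifnot(identical(dim(coefficients), c(3L, 4L)))
  colnames(coefficients) <- responses
  rownames(coefficients) <- c("intercept", "ccfn", "ccs")
  noise_sd <- unname(noise_sd[if (!is.null(names(noise_sd))) responses else TRUE])
  stopifnot(length(noise_sd) == 4L)
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0", call. = FALSE)
  names(noise_sd) <- responses

  needed <- c("reduced_ccfn", "increased_ccfn", "small_ccs", "large_ccs",
              "mid_ccfn", "mid_ccs")
  stopifnot(all(needed %in% names(ranges)))
  ccfn_windows <- ranges[c("reduced_ccfn", "increased_ccfn", "mid_ccfn")]
  ccs_windows <- ranges[c("small_ccs", "large_ccs", "mid_ccs")]
  if (any(unlist(ccfn_windows) < 6) || any(unlist(ccfn_windows) > 18)) {
    stop("CCFN sampling windows must lie within [6, 18]", call. = FALSE)
  }
  if (any(unlist(ccs_windows) < 170) || any(unlist(ccs_windows) > 445)) {
    stop("CCS sampling windows must lie within [170, 445]", call. = FALSE)
  }
  if (n_level_effect < 0 || n_level_effect >= 1) {
    stop("n_level_effect must be in [0, 1)", call. = FALSE)
  }

  # generating predictions must stay positive over the sampled domain
  corners <- expand.grid(ccfn = c(6, 18), ccs = c(170, 445))
  preds <- cbind(1, corners$ccfn, corners$ccs) %*% coefficients
  if (any(preds <= 0)) {
    stop("generating plane is non-positive somewhere on the sampled domain",
         call. = FALSE)
  }

  structure(
    list(seed = as.integer(seed),
         genotypes_per_category = as.integer(genotypes_per_category),
         plants_per_genotype = as.integer(plants_per_genotype),
         coefficients = coefficients, noise_sd = noise_sd,
         ranges = ranges, n_level_effect = n_level_effect),
    class = "anatomy_generator_spec"
  )
}

#' Generator spec anchored to the canonical predictions
#'
#' Returns a generator whose noiseless plane, evaluated at the four
#' canonical (CCFN, CCS) pairs, reproduces the canonical predictions (the
#' planes are fitted through those very predictions, which are numerically
#' planar).
#'
#' @param ... Overrides passed to [anatomy_generator_spec()].
#' @return An `anatomy_generator_spec`.
#' @export
default_anatomy_generator <- function(...) {
  anatomy_generator_spec(coefficients = canonical_cost_coefficients(), ...)
}

#' Generate a synthetic anatomy parameterization dataset
#'
#' Draws genotype-level (CCFN, CCS) values inside each category's sampling
#' window, then one record per plant and nitrogen level with responses on
#' the generating plane plus Gaussian noise (truncated at a small positive
#' floor; a spec whose noise would truncate more than 0.1% of records is
#' rejected).
#'
#' @param spec An [anatomy_generator_spec()].
#' @return A data frame of anatomy observations (see [validate_anatomy()]),
#'   with attribute `generator_spec` carrying the generating truth.
#' @export
generate_anatomy_dataset <- function(spec) {
  stopifnot(inherits(spec, "anatomy_generator_spec"))
  set.seed(spec$seed)

  categories <- ANATOMY_CATEGORIES
  rows <- list()
  for (cat in categories) {
    for (g in seq_len(spec$genotypes_per_category)) {
      if (cat %in% c("reduced_ccfn", "increased_ccfn")) {
        w <- spec$ranges[[cat]]
        ccfn_g <- round(stats::runif(1, w[1], w[2]))
        ccs_g <- stats::runif(1, spec$ranges$mid_ccs[1], spec$ranges$mid_ccs[2])
      } else {
        w <- spec$ranges[[cat]]
        ccs_g <- stats::runif(1, w[1], w[2])
        ccfn_g <- round(stats::runif(1, spec$ranges$mid_ccfn[1],
                                     spec$ranges$mid_ccfn[2]))
      }
      for (p in seq_len(spec$plants_per_genotype)) {
        for (nl in c("high", "low")) {
          rows[[length(rows) + 1L]] <- data.frame(
            genotype_id = sprintf("%s_g%d", cat, g),
            category = cat, n_level = nl,
            ccfn = ccfn_g, ccs = ccs_g, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  obs <- do.call(rbind, rows)

  co <- spec$coefficients
  X <- cbind(1, obs$ccfn, obs$ccs)
  plane <- X %*% co
  low <- obs$n_level == "low"
  shrink <- 1 - spec$n_level_effect * low

  n <- nrow(obs)
  noise <- function(r) stats::rnorm(n, 0, spec$noise_sd[[r]])
  respiration <- plane[, "respiration"] * shrink + noise("respiration")
  tissue_n <- ifelse(low,
                     plane[, "minimum_n"] * shrink + noise("minimum_n"),
                     plane[, "optimum_n"] * shrink + noise("optimum_n"))
  diameter <- plane[, "diameter"] + noise("diameter")

  floor_at <- 1e-9
  truncated <- sum(respiration < floor_at) + sum(tissue_n < floor_at) +
    sum(diameter < floor_at)
  if (truncated / (3 * n) > 0.001) {
    stop("generator spec rejected: noise truncates more than 0.1% of records",
         call. = FALSE)
  }
  obs$respiration <- pmax(respiration, floor_at)
  obs$tissue_n <- pmax(tissue_n, floor_at)
  obs$diameter <- pmax(diameter, floor_at)

  attr(obs, "generator_spec") <- spec
  validate_anatomy(obs)
  obs
}

#' @export
print.anatomy_generator_spec <- function(x, ...) {
  cat("Anatomy generator: 4 categories x", x$genotypes_per_category,
      "genotypes x", x$plants_per_genotype, "plants x 2 N levels, seed",
      x$seed, "\n")
  cat("Noise SD:", paste(names(x$noise_sd), signif(x$noise_sd, 3),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}
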