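#' Run one phenotype/scenario with replicates
#'
#' Simulates a phenotype `n_reps` times with replicate seeds
#' `base_seed + 0 ... base_seed + n_reps - 1` and aggregates the final
#' shoot dry weight and root length.
#'
#' @param phenotype A [plant_phenotype()].
#' @param soil A [soil_profile()].
#' @param config A [sim_config()].
#' @param n_reps Number of stochastic replicates (>= 1; default 4).
#' @param base_seed Base replicate seed.
#' @return A one-row data frame of class `experiment_result` with the
#'   phenotype label, soil texture, nitrogen supply scalar, replicate count,
#'   and mean/SD of shoot dry weight (g) and root length (cm).
#' @export
run_phenotype <- function(phenotype, soil, config = sim_config(),
                          n_reps = 4L, base_seed = 1L) {
  stopifnot(n_reps >= 1)
  seeds <- base_seed + seq_len(n_reps) - 1L
  sdw <- numeric(n_reps)
  rl <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    sim <- tryCatch(
      run_simulation(phenotype, soil, config, seed = seeds[i]),
      error = function(e) {
        stop("replicate with seed ", seeds[i], " failed: ",
             conditionMessage(e), call. = FALSE)
      })
    sdw[i] <- sim$final$shoot_dw
    rl[i] <- sim$final$root_length
  }
  out <- data.frame(
    label = phenotype$label, texture = soil$texture,
    n_supply = config$n_supply, n_reps = n_reps, base_seed = base_seed,
    mean_sdw = mean(sdw), sd_sdw = stats::sd(c(sdw, if (n_reps == 1) sdw)),
    mean_root_length = mean(rl),
    sd_root_length = stats::sd(c(rl, if (n_reps == 1) rl)),
    stringsAsFactors = FALSE
  )
  if (n_reps == 1) out$sd_sdw <- out$sd_root_length <- 0
  attr(out, "replicates") <- data.frame(seed = seeds, shoot_dw = sdw,
                                        root_length = rl)
  class(out) <- c("experiment_result", "data.frame")
  out
}

# Rebuild a config with a different nitrogen supply scalar.
with_n_supply <- function(config, n_supply) {
  config$n_supply <- n_supply
  config
}

#' Calibrate nitrogen-supply scalars to target stress levels
#'
#' Finds, by bisection on the nitrogen supply scalar, the supplies at which
#' the mean shoot dry weight of the reference phenotype is reduced by the
#' target percentages relative to the unstressed run (supply scalar
#' `upper`). The returned scalars define the low/medium/high stress levels
#' used by the sensitivity and decomposition experiments.
#'
#' @param phenotype Reference [plant_phenotype()].
#' @param soil A [soil_profile()].
#' @param config A [sim_config()]; its `n_supply` is overridden.
#' @param targets Shoot-biomass reduction targets in percent, strictly
#'   between 0 and 100 (default 25, 50, 75).
#' @param n_reps,base_seed Replication, as in [run_phenotype()].
#' @param tol Convergence tolerance on the achieved reduction (points).
#' @param upper Supply scalar of the unstressed reference (default 1).
#' @param max_iter Maximum bisection iterations per target.
#' @return A list with `scalars` (named by target), `achieved` reductions
#'   (%), and `unstressed_sdw` (g).
#' @export
calibrate_stress_levels <- function(phenotype, soil, config = sim_config(),
                                    targets = c(25, 50, 75),
                                    n_reps = 4L, base_seed = 1L,
                                    tol = 1.5, upper = 1, max_iter = 14L) {
  stopifnot(all(targets > 0), all(targets < 100))
  ref <- run_phenotype(phenotype, soil, with_n_supply(config, upper),
                       n_reps, base_seed)$mean_sdw
  reduction <- function(scalar) {
    m <- run_phenotype(phenotype, soil, with_n_supply(config, scalar),
                       n_reps, base_seed)$mean_sdw
    100 * (1 - m / ref)
  }
  red0 <- reduction(0)
  if (red0 < max(targets)) {
    stop("calibration infeasible: zero supply reduces shoot dry weight by ",
         round(red0, 1), "%, below the largest target", call. = FALSE)
  }

  scalars <- numeric(length(targets))
  achieved <- numeric(length(targets))
  for (j in seq_along(targets)) {
    lo <- 0; hi <- upper         # reduction(lo) >= target >= reduction(hi)
    red <- NA_real_; mid <- NA_real_
    for (i in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      red <- reduction(mid)
      if (abs(red - targets[j]) <= tol) break
      if (red > targets[j]) lo <- mid else hi <- mid
    }
    scalars[j] <- mid
    achieved[j] <- red
  }
  names(scalars) <- names(achieved) <- paste0("target_", targets)
  list(scalars = scalars, achieved = achieved, unstressed_sdw = ref,
       targets = targets)
}

#' Additive expectation of component benefits
#'
#' The expected combined effect of independent components under additivity:
#' simply the sum of the single-component relative benefits (in percent).
#' Synergy is the difference between the observed combined benefit and this
#' expectation.
#'
#' @param components Numeric vector of single-component relative benefits
#'   (%).
#' @return Their sum (%).
#' @examples
#' additive_expectation(c(97, 14, 60))  # 171
#' @export
additive_expectation <- function(components) {
  stopifnot(is.numeric(components), length(components) >= 1)
  sum(components)
}

#' Transphenic decomposition of a phene state
#'
#' Isolates the contribution of each cost component (respiration, tissue
#' nitrogen requirements, root diameter) to the benefit of a variant phene
#' state over a reference: each component run replaces only that
#' component's value in the reference phenotype with the variant's;
#' `combined` replaces all three; `transphenic` replaces all but root
#' diameter (the variant's metabolism with the reference's diameter).
#' Benefits are percent changes of replicate-mean shoot dry weight and root
#' length relative to the reference runs.
#'
#' @param reference,variant Canonical phene-state labels (see
#'   [canonical_phene_states()]).
#' @param soil A [soil_profile()].
#' @param config A [sim_config()] (set `n_supply` to a calibrated stress
#'   scalar; decomposition is reported at medium stress by default in the
#'   experiments that use it).
#' @param n_reps,base_seed Replication, as in [run_phenotype()].
#' @param max_rca,lrbd Shared non-focal phene states.
#' @return A list of class `decomposition_result` with elements `benefits`
#'   (data frame: component, shoot-DW and root-length benefit in %),
#'   `additive` (named vector, the component sums), `combined`,
#'   `transphenic`, and `synergy` (combined minus additive), each with
#'   `sdw` and `root_length` entries.
#' @export
transphenic_decomposition <- function(reference, variant, soil,
                                      config = sim_config(),
                                      n_reps = 4L, base_seed = 1L,
                                      max_rca = 0, lrbd = 6) {
  ref_pred <- canonical_prediction(reference)
  var_pred <- canonical_prediction(variant)

  component_overrides <- list(
    respiration = list(respiration = var_pred$respiration),
    n_content = list(optimum_n = var_pred$optimum_n,
                     minimum_n = var_pred$minimum_n),
    diameter = list(diameter = var_pred$diameter)
  )
  all_overrides <- c(component_overrides$respiration,
                     component_overrides$n_content,
                     component_overrides$diameter)
  transphenic_overrides <- c(component_overrides$respiration,
                             component_overrides$n_content)

  run_with <- function(overrides) {
    ph <- canonical_phenotype(reference, max_rca = max_rca, lrbd = lrbd,
                              overrides = overrides)
    run_phenotype(ph, soil, config, n_reps, base_seed)
  }

  ref_res <- run_with(list())
  bene <- function(res) c(
    sdw = percent_change(ref_res$mean_sdw, res$mean_sdw),
    root_length = percent_change(ref_res$mean_root_length,
                                 res$mean_root_length)
  )

  comp <- t(sapply(component_overrides, function(ov) bene(run_with(ov))))
  combined <- bene(run_with(all_overrides))
  transphenic <- bene(run_with(transphenic_overrides))
  additive <- colSums(comp)

  structure(
    list(reference = reference, variant = variant,
         benefits = data.frame(component = rownames(comp),
                               sdw = comp[, "sdw"],
                               root_length = comp[, "root_length"],
                               row.names = NULL),
         additive = additive, combined = combined,
         transphenic = transphenic, synergy = combined - additive,
         reference_means = c(sdw = ref_res$mean_sdw,
                             root_length = ref_res$mean_root_length)),
    class = "decomposition_result"
  )
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("Transphenic decomposition: %s components into %s\n",
              x$variant, x$reference))
  print(transform(x$benefits, sdw = round(sdw, 1),
                  root_length = round(root_length, 1)))
  cat(sprintf("additive: sdw %.1f%%, root length %.1f%%\n",
              x$additive["sdw"], x$additive["root_length"]))
  cat(sprintf("combined: sdw %.1f%%, root length %.1f%%\n",
              x$combined["sdw"], x$combined["root_length"]))
  cat(sprintf("transphenic: sdw %.1f%%, root length %.1f%%\n",
              x$transphenic["sdw"], x$transphenic["root_length"]))
  cat(sprintf("synergy: sdw %.1f points, root length %.1f points\n",
              x$synergy["sdw"], x$synergy["root_length"]))
  invisible(x)
}

#' Sensitivity grid over CCFN and CCS
#'
#' Full factorial of CCFN and CCS values at one or more calibrated stress
#' scalars, replicate-aggregated.
#'
#' @param ccfn_values,ccs_values Grid axes (counts; micron^2).
#' @param stress_scalars Named or unnamed vector of nitrogen supply
#'   scalars.
#' @param soil A [soil_profile()].
#' @param config A [sim_config()].
#' @param n_reps,base_seed Replication, as in [run_phenotype()].
#' @param max_rca,lrbd Non-focal phene states shared by all cells.
#' @return Long-format data frame: `ccfn`, `ccs`, `stress` (scalar name or
#'   value), `n_supply`, `mean_sdw`, `sd_sdw`.
#' @export
sensitivity_grid <- function(ccfn_values, ccs_values, stress_scalars,
                             soil, config = sim_config(),
                             n_reps = 4L, base_seed = 1L,
                             max_rca = 0, lrbd = 6) {
  if (is.null(names(stress_scalars))) {
    names(stress_scalars) <- paste0("supply_", signif(stress_scalars, 3))
  }
  grid <- expand.grid(ccfn = ccfn_values, ccs = ccs_values,
                      stress = names(stress_scalars),
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    sc <- stress_scalars[[grid$stress[i]]]
    ph <- plant_phenotype(grid$ccfn[i], grid$ccs[i],
                          max_rca = max_rca, lrbd = lrbd)
    res <- run_phenotype(ph, soil, with_n_supply(config, sc),
                         n_reps, base_seed)
    data.frame(ccfn = grid$ccfn[i], ccs = grid$ccs[i],
               stress = grid$stress[i], n_supply = sc,
               mean_sdw = res$mean_sdw, sd_sdw = res$sd_sdw,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Plot a sensitivity grid as a shoot-dry-weight surface
#'
#' @param grid Output of [sensitivity_grid()].
#' @param stress Which stress level (value of `grid$stress`) to draw.
#' @param ... Passed to [graphics::filled.contour()].
#' @return The subset drawn, invisibly.
#' @export
plot_sensitivity_grid <- function(grid, stress = grid$stress[1], ...) {
  g <- grid[grid$stress == stress, ]
  xs <- sort(unique(g$ccfn)); ys <- sort(unique(g$ccs))
  z <- matrix(NA_real_, length(xs), length(ys))
  z[cbind(match(g$ccfn, xs), match(g$ccs, ys))] <- g$mean_sdw
  graphics::filled.contour(xs, ys, z, xlab = "CCFN (files)",
                           ylab = expression(CCS ~ (mu * m^2)),
                           main = paste("shoot dry weight (g),", stress), ...)
  invisible(g)
}

#' Factorial experiment across phene axes and soils
#'
#' Simulates every combination of the supplied phene axes in each soil and
#' reports the relative increase in mean shoot dry weight over the worst
#' performer within each soil (the worst performer reports 0). Axes default
#' to the extreme CCFN and CCS states crossed with either an aerenchyma or
#' a branching-density contrast.
#'
#' @param soils List of [soil_profile()] objects.
#' @param config A [sim_config()] (set `n_supply` to the stress scalar at
#'   which the factorial is run).
#' @param ccfn,ccs Phene-state axes (named vectors; names build the
#'   phenotype labels).
#' @param rca Named vector of maximum aerenchyma fractions, or `NULL`.
#' @param lrbd Named vector of branching densities, or `NULL`. Exactly one
#'   of `rca`/`lrbd` must be non-`NULL`.
#' @param fixed_rca,fixed_lrbd Values of the non-varied phene.
#' @param n_reps,base_seed Replication, as in [run_phenotype()].
#' @return Data frame: `label`, `texture`, phene columns, `mean_sdw`,
#'   `sd_sdw`, `rel_increase` (%); sorted within soil by decreasing mean.
#' @export
factorial_experiment <- function(soils, config = sim_config(),
                                 ccfn = c(ReducedCCFN = 6, IncreasedCCFN = 18),
                                 ccs = c(LargeCCS = 450, SmallCCS = 200),
                                 rca = c(LowRCA = 0.10, HighRCA = 0.30),
                                 lrbd = NULL,
                                 fixed_rca = 0, fixed_lrbd = 6,
                                 n_reps = 4L, base_seed = 1L) {
  if (inherits(soils, "soil_profile")) soils <- list(soils)
  if (is.null(rca) == is.null(lrbd)) {
    stop("exactly one of `rca` or `lrbd` must be supplied", call. = FALSE)
  }
  third <- if (!is.null(rca)) rca else lrbd
  third_name <- if (!is.null(rca)) "rca" else "lrbd"

  cells <- expand.grid(i_ccfn = seq_along(ccfn), i_ccs = seq_along(ccs),
                       i_third = seq_along(third))
  rows <- list()
  for (soil in soils) {
    res <- lapply(seq_len(nrow(cells)), function(r) {
      i <- cells[r, ]
      label <- paste(names(ccfn)[i$i_ccfn], names(ccs)[i$i_ccs],
                     names(third)[i$i_third], sep = "/")
      ph <- plant_phenotype(
        ccfn[[i$i_ccfn]], ccs[[i$i_ccs]],
        max_rca = if (third_name == "rca") third[[i$i_third]] else fixed_rca,
        lrbd = if (third_name == "lrbd") third[[i$i_third]] else fixed_lrbd,
        label = label)
      out <- run_phenotype(ph, soil, config, n_reps, base_seed)
      data.frame(label = label, texture = soil$texture,
                 ccfn = ccfn[[i$i_ccfn]], ccs = ccs[[i$i_ccs]],
                 third = third[[i$i_third]],
                 mean_sdw = out$mean_sdw, sd_sdw = out$sd_sdw,
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    names(res)[names(res) == "third"] <- third_name
    # worst performer defines the 0 baseline; ties broken by label order
    worst <- min(res$mean_sdw)
    res$rel_increase <- 100 * (res$mean_sdw - worst) / worst
    res <- res[order(-res$mean_sdw, res$label), ]
    rows[[soil$texture]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
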