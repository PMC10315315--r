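#' Construct a plant phenotype for simulation
#'
#' Bundles the four root cortical phenes -- cortical cell file number
#' (CCFN), cortical cell size (CCS), maximum root cortical aerenchyma
#' fraction (RCA) and lateral root branching density (LRBD) -- with the
#' cost predictions (respiration, optimum/minimum tissue N, diameter) that
#' drive the simulator. Costs default to the canonical cost surface
#' evaluated at (`ccfn`, `ccs`); `overrides` supports transphenic analysis,
#' replacing individual cost components with another phene state's values.
#'
#' @param ccfn Cortical cell file number (6-18).
#' @param ccs Cortical cell size (micron^2, 170-450).
#' @param max_rca Maximum aerenchyma fraction of root cross-section reached
#'   at 20 days of segment age, in [0, 0.39].
#' @param lrbd Lateral root branching density (laterals per cm of axial
#'   root), in [4, 8].
#' @param costs Optional list with `respiration`, `optimum_n`, `minimum_n`,
#'   `diameter`; defaults to [canonical_costs_at()] for (`ccfn`, `ccs`).
#' @param overrides Optional named list replacing any of `respiration`,
#'   `diameter`, or the pair `optimum_n`/`minimum_n` (both must be given
#'   together, since they define one stress response curve).
#' @param label Optional phenotype label carried into experiment reports.
#' @return An object of class `plant_phenotype`.
#' @examples
#' ph <- plant_phenotype(6, 360)        # reduced-CCFN anatomy
#' ph$costs$respiration
#' @export
plant_phenotype <- function(ccfn = 10, ccs = 300, max_rca = 0, lrbd = 6,
                            costs = NULL, overrides = list(), label = NULL) {
  if (max_rca < 0 || max_rca > 0.39) {
    stop("max_rca must lie in [0, 0.39]", call. = FALSE)
  }
  if (lrbd < 4 || lrbd > 8) {
    stop("lrbd must lie in [4, 8] laterals per cm", call. = FALSE)
  }
  if (is.null(costs)) costs <- canonical_costs_at(ccfn, ccs)
  costs <- costs[c("respiration", "optimum_n", "minimum_n", "diameter")]

  if (length(overrides)) {
    bad <- setdiff(names(overrides),
                   c("respiration", "optimum_n", "minimum_n", "diameter"))
    if (length(bad)) {
      stop("unknown override(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    has_opt <- "optimum_n" %in% names(overrides)
    has_min <- "minimum_n" %in% names(overrides)
    if (xor(has_opt, has_min)) {
      stop("optimum_n and minimum_n must be overridden together", call. = FALSE)
    }
    costs[names(overrides)] <- overrides
  }
  validate_prediction(costs, ccfn = ccfn, ccs = ccs)

  if (is.null(label)) {
    label <- sprintf("ccfn%g_ccs%g_rca%g_lrbd%g", ccfn, ccs, max_rca, lrbd)
  }
  structure(
    list(ccfn = ccfn, ccs = ccs, max_rca = max_rca, lrbd = lrbd,
         costs = costs, overrides = overrides, label = label),
    class = "plant_phenotype"
  )
}

#' Phenotype for a canonical phene state
#'
#' @param state Canonical state label (see [canonical_phene_states()]).
#' @param max_rca,lrbd Passed to [plant_phenotype()].
#' @param overrides Transphenic cost overrides, see [plant_phenotype()].
#' @return A `plant_phenotype` whose costs are the canonical predictions.
#' @export
canonical_phenotype <- function(state, max_rca = 0, lrbd = 6,
                                overrides = list()) {
  p <- canonical_prediction(state)
  plant_phenotype(ccfn = p$ccfn, ccs = p$ccs, max_rca = max_rca, lrbd = lrbd,
                  costs = p[c("respiration", "optimum_n", "minimum_n",
                              "diameter")],
                  overrides = overrides, label = state)
}

#' @export
print.plant_phenotype <- function(x, ...) {
  cat("Plant phenotype:", x$label, "\n")
  cat(sprintf("  CCFN %g, CCS %g um^2, max RCA %.0f%%, LRBD %g /cm\n",
              x$ccfn, x$ccs, 100 * x$max_rca, x$lrbd))
  cat(sprintf(
    "  respiration %.4g g CO2/g/d, N opt/min %.5g/%.5g umol/g, diameter %.3g mm\n",
    x$costs$respiration, x$costs$optimum_n, x$costs$minimum_n,
    x$costs$diameter))
  if (length(x$overrides)) {
    cat("  transphenic overrides:", paste(names(x$overrides), collapse = ", "),
        "\n")
  }
  invisible(x)
}
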