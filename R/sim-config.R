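#' Simulation configuration
#'
#' Parameters of the daily-step plant/soil simulation: stand geometry,
#' shoot (light interception and utilization) parameters, root construction
#' and elongation parameters, aerenchyma cost coefficients, nitrate uptake
#' kinetics and stochasticity amplitude. Defaults are calibrated so an
#' unstressed 40-day maize plant reaches a realistic seedling magnitude
#' (shoot dry weight around 20 g, total root length of order 100 m).
#'
#' @param duration Simulated days after germination (default 40, maximum 42).
#' @param row_spacing,plant_spacing Stand geometry (cm); one plant occupies
#'   `row_spacing * plant_spacing` of ground.
#' @param irradiance Daily incident radiation (MJ m^-2 d^-1).
#' @param lue Potential light-use efficiency (g biomass MJ^-1 intercepted).
#' @param k_light Canopy extinction coefficient of the shading function.
#' @param sla Specific leaf area (cm^2 g^-1).
#' @param stem_frac Stem-plus-sheath dry weight per unit leaf dry weight.
#' @param leaf_rel_rate Relative potential leaf-area expansion rate (d^-1,
#'   early exponential phase).
#' @param leaf_max_rate Maximum potential leaf-area expansion (cm^2 d^-1).
#' @param la0 Initial leaf area (cm^2).
#' @param seed_reserve Seed carbon reserve (g biomass equivalent).
#' @param seed_n Seed nitrogen content (umol).
#' @param carbon_frac Carbon fraction of dry biomass (g C g^-1 DW).
#' @param tissue_density Root tissue density (g DW cm^-3 of root volume).
#' @param lateral_diameter_frac Lateral diameter as a fraction of the
#'   phenotype's axial root diameter.
#' @param shoot_resp Shoot maintenance respiration (g C g^-1 DW d^-1).
#' @param k_rca_resp,k_rca_n Fractional reduction of segment respiration
#'   and of segment tissue-N requirement at the reference maximum
#'   aerenchyma fraction (`max_rca_ref`).
#' @param max_rca_ref Reference maximum aerenchyma fraction (0.39 of root
#'   cross-section, the largest reported value).
#' @param imax Maximum nitrate uptake per unit root surface
#'   (umol cm^-2 d^-1).
#' @param km Michaelis constant of nitrate uptake (umol cm^-3 soil water).
#' @param extract_frac Maximum fraction of a layer's nitrate stock the root
#'   system can extract per day, however dense the roots in it (a proxy for
#'   diffusion-limited transport to the root surface).
#' @param n_supply Nitrogen supply scalar multiplying the soil profile's
#'   initial nitrate (1 = unstressed reference supply).
#' @param root_share_min Minimum share of post-respiration carbon offered to
#'   root growth before the shoot sink is served.
#' @param branch_delay Days between initiation of a lateral primordium
#'   behind an axial tip and the start of its elongation.
#' @param stochasticity Lognormal jitter SD applied to daily elongation and
#'   lateral initiation (0 switches stochasticity off).
#' @param elongation_rate Named potential elongation rates (cm d^-1) for
#'   `primary`, `seminal`, `crown`, `lateral` roots.
#' @param depth_rate Named vertical descent per cm of axis for each class.
#' @param diameter_frac Named axial diameter multipliers relative to the
#'   phenotype diameter for `primary`, `seminal`, `crown`.
#' @param max_length Named maximum root lengths (cm) per class.
#' @param crown_days Emergence days of crown-root whorls.
#' @param crown_counts Roots per whorl (recycled to `crown_days`).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(duration = 40,
                       row_spacing = 60, plant_spacing = 26,
                       irradiance = 12, lue = 3.0, k_light = 0.6,
                       sla = 250, stem_frac = 0.6,
                       leaf_rel_rate = 0.22, leaf_max_rate = 350, la0 = 2,
                       seed_reserve = 0.3, seed_n = 350,
                       carbon_frac = 0.45, tissue_density = 0.12,
                       lateral_diameter_frac = 0.3,
                       shoot_resp = 0.01,
                       k_rca_resp = 0.5, k_rca_n = 0.5, max_rca_ref = 0.39,
                       imax = 12, km = 0.05, extract_frac = 0.4,
                       n_supply = 1,
                       root_share_min = 0.3, branch_delay = 3,
                       stochasticity = 0.05,
                       elongation_rate = c(primary = 3.0, seminal = 2.0,
                                           crown = 3.5, lateral = 0.6),
                       depth_rate = c(primary = 1.0, seminal = 0.7,
                                      crown = 0.55, lateral = 0.25),
                       diameter_frac = c(primary = 1.0, seminal = 0.8,
                                         crown = 1.1),
                       max_length = c(primary = 150, seminal = 100,
                                      crown = 130, lateral = 4),
                       crown_days = c(8, 11, 14, 17, 20, 23, 26),
                       crown_counts = c(2, 2, 3, 3, 4, 4, 5)) {
  if (duration < 1 || duration > 42) {
    stop("duration must lie in [1, 42] days", call. = FALSE)
  }
  if (row_spacing <= 0 || plant_spacing <= 0) {
    stop("spacings must be positive", call. = FALSE)
  }
  if (n_supply < 0) stop("n_supply must be >= 0", call. = FALSE)
  if (stochasticity < 0) stop("stochasticity must be >= 0", call. = FALSE)
  classes <- c("primary", "seminal", "crown", "lateral")
  stopifnot(all(classes %in% names(elongation_rate)),
            all(classes %in% names(depth_rate)),
            all(c("primary", "seminal", "crown") %in% names(diameter_frac)),
            all(classes %in% names(max_length)))
  crown_counts <- rep_len(crown_counts, length(crown_days))

  structure(
    list(duration = as.integer(duration),
         row_spacing = row_spacing, plant_spacing = plant_spacing,
         ground_area = row_spacing * plant_spacing,
         irradiance = irradiance, lue = lue, k_light = k_light,
         sla = sla, stem_frac = stem_frac,
         leaf_rel_rate = leaf_rel_rate, leaf_max_rate = leaf_max_rate,
         la0 = la0, seed_reserve = seed_reserve, seed_n = seed_n,
         carbon_frac = carbon_frac, tissue_density = tissue_density,
         lateral_diameter_frac = lateral_diameter_frac,
         shoot_resp = shoot_resp,
         k_rca_resp = k_rca_resp, k_rca_n = k_rca_n,
         max_rca_ref = max_rca_ref,
         imax = imax, km = km, extract_frac = extract_frac,
         n_supply = n_supply,
         root_share_min = root_share_min, branch_delay = branch_delay,
         stochasticity = stochasticity,
         elongation_rate = elongation_rate, depth_rate = depth_rate,
         diameter_frac = diameter_frac, max_length = max_length,
         crown_days = crown_days, crown_counts = crown_counts),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: %d days, %g x %g cm stand, N supply scalar %g\n",
    x$duration, x$row_spacing, x$plant_spacing, x$n_supply))
  invisible(x)
}
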