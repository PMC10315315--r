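#' Fraction of incident light intercepted by one plant
#'
#' Shading function of the stand: `1 - exp(-k * LAI)` with leaf area index
#' computed over the plant's ground area. Monotone and saturating in leaf
#' area.
#'
#' @param leaf_area Leaf area (cm^2), >= 0.
#' @param ground_area Ground area per plant (cm^2, default 60 x 26).
#' @param k Canopy extinction coefficient.
#' @return Intercepted fraction in [0, 1).
#' @export
intercepted_fraction <- function(leaf_area, ground_area = 60 * 26, k = 0.6) {
  stopifnot(all(leaf_area >= 0), ground_area > 0)
  1 - exp(-k * leaf_area / ground_area)
}

#' Nitrogen stress factor
#'
#' Dimensionless growth multiplier derived from plant nitrogen status: 1
#' when the plant nitrogen concentration meets its optimum, 0 at or below
#' the minimum, with a linear ramp between. Applied multiplicatively to
#' light-use efficiency and to potential leaf-area expansion.
#'
#' @param concentration Plant nitrogen concentration (umol g^-1 DW).
#' @param optimum_n,minimum_n Optimum and minimum concentrations
#'   (`minimum_n < optimum_n`).
#' @return Stress factor in [0, 1], vectorised over `concentration`.
#' @export
stress_factor <- function(concentration, optimum_n, minimum_n) {
  if (any(minimum_n >= optimum_n)) {
    stop("minimum_n must be strictly below optimum_n", call. = FALSE)
  }
  pmin(1, pmax(0, (concentration - minimum_n) / (optimum_n - minimum_n)))
}

#' Aerenchyma fraction of a root segment by age
#'
#' No aerenchyma forms in the youngest tissue (the elongation zone,
#' represented as the first day of segment age); the fraction then ramps
#' linearly, reaching the phenotype's maximum at 20 days and staying
#' constant after.
#'
#' @param age Segment age (days), >= 0.
#' @param max_rca Maximum aerenchyma fraction for the phenotype.
#' @param onset Age (days) at which formation starts (default 1).
#' @param full_age Age at which the maximum is reached (default 20).
#' @return Aerenchyma fraction, vectorised over `age`.
#' @export
rca_fraction <- function(age, max_rca, onset = 1, full_age = 20) {
  stopifnot(all(age >= 0), max_rca >= 0, full_age > onset)
  max_rca * pmin(1, pmax(0, (age - onset) / (full_age - onset)))
}

#' Maintenance cost of root segments
#'
#' Carbon respired and tissue nitrogen requirement of root segments, both
#' reduced by aerenchyma: respired C = respiration rate (CO2 basis,
#' converted by 12/44) x dry weight x (1 - k_rca_resp * rca / max_rca_ref),
#' and the optimum/minimum nitrogen requirements scale analogously with
#' `k_rca_n`. Multipliers are clamped to [0, 1].
#'
#' @param dry_weight Segment dry weight(s), g.
#' @param rca_frac Segment aerenchyma fraction(s).
#' @param phenotype A [plant_phenotype()].
#' @param k_rca_resp,k_rca_n,max_rca_ref Aerenchyma cost coefficients, see
#'   [sim_config()].
#' @return A list with `respired_c` (g C d^-1), `n_optimum` and `n_minimum`
#'   (umol), vectorised over segments.
#' @export
segment_maintenance_cost <- function(dry_weight, rca_frac, phenotype,
                                     k_rca_resp = 0.5, k_rca_n = 0.5,
                                     max_rca_ref = 0.39) {
  stopifnot(all(dry_weight >= 0), all(rca_frac >= 0))
  m_resp <- pmin(1, pmax(0, 1 - k_rca_resp * rca_frac / max_rca_ref))
  m_n <- pmin(1, pmax(0, 1 - k_rca_n * rca_frac / max_rca_ref))
  list(
    respired_c = phenotype$costs$respiration * (12 / 44) * dry_weight * m_resp,
    n_optimum = phenotype$costs$optimum_n * dry_weight * m_n,
    n_minimum = phenotype$costs$minimum_n * dry_weight * m_n
  )
}

# Cross-section area (cm^2) of a root of given diameter in mm.
root_xsec_area <- function(diameter_mm) pi * (diameter_mm / 20)^2

# Lognormal multiplicative jitter with unit mean.
growth_jitter <- function(n, sd) {
  if (sd <= 0) return(rep(1, n))
  exp(stats::rnorm(n, -sd^2 / 2, sd))
}

#' Initialize a simulation
#'
#' Builds the day-0 state: seed reserves, embryonic root initials (one
#' primary root plus three seminal roots), the soil nitrate stocks scaled
#' by the nitrogen supply scalar, and the carbon/nitrogen ledgers. The
#' random number generator is seeded here, so two initializations with the
#' same seed produce identical simulations.
#'
#' @param phenotype A [plant_phenotype()].
#' @param soil A [soil_profile()].
#' @param config A [sim_config()].
#' @param seed Integer replicate seed.
#' @return A `sim_state` list; advance it with [step_day()] or run
#'   everything with [run_simulation()].
#' @export
initialize_simulation <- function(phenotype, soil, config, seed = 1L) {
  stopifnot(inherits(phenotype, "plant_phenotype"),
            inherits(soil, "soil_profile"),
            inherits(config, "sim_config"))
  validate_prediction(phenotype$costs, phenotype$ccfn, phenotype$ccs)
  set.seed(as.integer(seed))

  stocks <- soil$init_weights * soil$total_nitrate * config$n_supply
  water_vol <- soil$theta * config$ground_area * soil$dz

  d_mm <- phenotype$costs$diameter
  fr <- config$diameter_frac
  roots <- data.frame(
    class = c("primary", rep("seminal", 3)),
    mult = c(1, 1, 1, 1),
    birth_day = c(0, 1, 1, 1),
    length = 0,
    max_length = config$max_length[c("primary", rep("seminal", 3))],
    tip_depth = c(1, 2, 2, 2),
    depth_rate = config$depth_rate[c("primary", rep("seminal", 3))],
    diameter = d_mm * fr[c("primary", rep("seminal", 3))],
    active = TRUE,
    stringsAsFactors = FALSE
  )

  segs <- data.frame(
    class = character(0), mult = numeric(0), birth_day = numeric(0),
    length = numeric(0), depth = numeric(0), diameter = numeric(0),
    layer = integer(0), dw = numeric(0), stringsAsFactors = FALSE
  )

  state <- list(
    day = 0L, phenotype = phenotype, soil = soil, config = config,
    seed = as.integer(seed),
    drainage = drainage_schedule(soil, config$duration),
    leaf_area = config$la0, shoot_dw = 0.02, reserve = config$seed_reserve,
    stress = 1, plant_n = config$seed_n,
    roots = roots, segs = segs,
    stocks = stocks, water_vol = water_vol,
    cum = c(assim_c = 0, resp_c = 0, uptake_n = 0, leached_n = 0,
            supplied_n = 0),
    daily = list()
  )
  state$init_totals <- c(
    c = (state$shoot_dw + state$reserve) * config$carbon_frac,
    n = state$plant_n + sum(stocks)
  )
  class(state) <- "sim_state"
  state
}

# Effective (aerenchyma-discounted) living dry weight against which plant
# nitrogen concentration is assessed.
effective_dw <- function(state) {
  cfg <- state$config
  if (nrow(state$segs)) {
    rca <- rca_fraction(state$day - state$segs$birth_day,
                        state$phenotype$max_rca)
    m_n <- pmin(1, pmax(0, 1 - cfg$k_rca_n * rca / cfg$max_rca_ref))
    root_eff <- sum(state$segs$dw * state$segs$mult * m_n)
  } else root_eff <- 0
  state$shoot_dw + root_eff
}

#' Grow the root system with a carbon allocation
#'
#' Elongates all active root tips at their potential class rates (with
#' multiplicative lognormal jitter), scaled down uniformly if the carbon
#' allocated to roots cannot pay for the potential growth; construction
#' cost per cm is cross-section area x tissue density. Crown-root whorls
#' emerge on their phytomer schedule, and new lateral root cohorts initiate
#' behind each axial tip at the phenotype's branching density. Unspent
#' carbon is returned (the caller banks it as reserve).
#'
#' @param state A `sim_state`.
#' @param biomass_for_roots Biomass-equivalent carbon available for root
#'   construction (g DW), >= 0.
#' @return The updated state, with `state$unspent` holding the unused
#'   allocation.
#' @export
grow_roots <- function(state, biomass_for_roots) {
  stopifnot(biomass_for_roots >= 0)
  cfg <- state$config
  ph <- state$phenotype
  d <- state$day
  roots <- state$roots

  # crown whorls emerging today
  idx <- which(cfg$crown_days == d)
  if (length(idx)) {
    new_crowns <- data.frame(
      class = "crown", mult = cfg$crown_counts[idx], birth_day = d,
      length = 0, max_length = cfg$max_length[["crown"]],
      tip_depth = 2, depth_rate = cfg$depth_rate[["crown"]],
      diameter = ph$costs$diameter * cfg$diameter_frac[["crown"]],
      active = TRUE, stringsAsFactors = FALSE
    )
    roots <- rbind(roots, new_crowns)
  }

  act <- which(roots$active & roots$birth_day <= d)
  if (!length(act)) {
    state$roots <- roots
    state$unspent <- biomass_for_roots
    return(state)
  }

  pot <- cfg$elongation_rate[roots$class[act]] *
    growth_jitter(length(act), cfg$stochasticity)
  pot <- pmin(pot, roots$max_length[act] - roots$length[act])
  dr <- roots$depth_rate[act]
  room <- (state$soil$depth - roots$tip_depth[act]) / pmax(dr, 1e-9)
  pot <- pmax(0, pmin(pot, room))

  # axial tips are stronger sinks than laterals: they are served first, so
  # carbon scarcity curtails branching before it curtails the depth race
  cost_per_cm <- root_xsec_area(roots$diameter[act]) * cfg$tissue_density
  cost <- roots$mult[act] * pot * cost_per_cm
  is_lat <- roots$class[act] == "lateral"
  ax_demand <- sum(cost[!is_lat])
  lat_demand <- sum(cost[is_lat])
  ax_scale <- if (ax_demand > 0) min(1, biomass_for_roots / ax_demand) else 1
  left <- biomass_for_roots - ax_scale * ax_demand
  lat_scale <- if (lat_demand > 0) min(1, left / lat_demand) else 1
  dl <- pot * ifelse(is_lat, lat_scale, ax_scale)

  grew <- which(dl > 1e-12)
  used <- 0
  if (length(grew)) {
    gi <- act[grew]
    dli <- dl[grew]
    mid_depth <- roots$tip_depth[gi] + dli * roots$depth_rate[gi] / 2
    layer <- pmin(state$soil$n_layers,
                  pmax(1L, as.integer(ceiling(mid_depth / state$soil$dz))))
    dw <- dli * root_xsec_area(roots$diameter[gi]) * cfg$tissue_density
    new_segs <- data.frame(
      class = roots$class[gi], mult = roots$mult[gi], birth_day = d,
      length = dli, depth = mid_depth, diameter = roots$diameter[gi],
      layer = layer, dw = dw, stringsAsFactors = FALSE
    )
    state$segs <- rbind(state$segs, new_segs)
    used <- sum(dw * roots$mult[gi])

    roots$length[gi] <- roots$length[gi] + dli
    roots$tip_depth[gi] <- roots$tip_depth[gi] + dli * roots$depth_rate[gi]

    # lateral cohorts behind axial tips, one cohort per axial per day
    ax <- gi[roots$class[gi] != "lateral"]
    if (length(ax)) {
      dlax <- dli[roots$class[gi] != "lateral"]
      n_lat <- roots$mult[ax] * ph$lrbd * dlax *
        growth_jitter(length(ax), cfg$stochasticity)
      keep <- n_lat > 1e-9
      if (any(keep)) {
        new_lats <- data.frame(
          class = "lateral", mult = n_lat[keep],
          birth_day = d + cfg$branch_delay,
          length = 0, max_length = cfg$max_length[["lateral"]],
          tip_depth = roots$tip_depth[ax[keep]] -
            dlax[keep] * roots$depth_rate[ax[keep]] / 2,
          depth_rate = cfg$depth_rate[["lateral"]],
          diameter = ph$costs$diameter * cfg$lateral_diameter_frac,
          active = TRUE, stringsAsFactors = FALSE
        )
        roots <- rbind(roots, new_lats)
      }
    }
  }

  roots$active <- roots$active &
    (roots$length < roots$max_length - 1e-9) &
    (roots$tip_depth < state$soil$depth - 1e-9)

  state$roots <- roots
  state$unspent <- biomass_for_roots - used
  state
}

#' Per-segment nitrate uptake and soil transport
#'
#' Each root segment takes up nitrate from its soil layer with
#' Michaelis-Menten kinetics in the layer's solution concentration, capped
#' by whole-plant demand (the gap between the optimum nitrogen pool and the
#' current pool) and by the layer stock. Afterwards nitrate advects
#' downward at the texture's leaching velocity times the day's drainage;
#' nitrate leaving the bottom layer is lost and accumulates in the leaching
#' ledger.
#'
#' @param state A `sim_state`.
#' @return The updated state.
#' @export
uptake_and_transport <- function(state) {
  cfg <- state$config
  ph <- state$phenotype

  # uptake: Michaelis-Menten per unit root surface, so thicker roots take
  # up more per cm but build less length per unit carbon
  if (nrow(state$segs)) {
    eff <- effective_dw(state)
    demand <- max(0, ph$costs$optimum_n * eff - state$plant_n)
    conc <- state$stocks / state$water_vol
    surface <- state$segs$length * state$segs$mult *
      pi * state$segs$diameter / 10
    seg_conc <- conc[state$segs$layer]
    pot <- cfg$imax * surface * seg_conc / (cfg$km + seg_conc)
    tot_pot <- sum(pot)
    if (tot_pot > 0 && demand > 0) {
      scale <- min(1, demand / tot_pot)
      lay_pot <- rowsum(pot * scale, state$segs$layer)
      uptake <- numeric(state$soil$n_layers)
      lay_idx <- as.integer(rownames(lay_pot))
      # diffusion to the root limits how fast a layer can be mined,
      # whatever the root length density in it
      uptake[lay_idx] <- pmin(lay_pot[, 1],
                              cfg$extract_frac * state$stocks[lay_idx])
      state$stocks <- state$stocks - uptake
      taken <- sum(uptake)
      state$plant_n <- state$plant_n + taken
      state$cum["uptake_n"] <- state$cum["uptake_n"] + taken
    }
  }

  # downward advection and bottom-boundary loss
  drain <- state$drainage[state$day + 1L]
  frac <- min(1, state$soil$leaching_velocity * drain / state$soil$dz)
  if (frac > 0) {
    moving <- state$stocks * frac
    state$stocks <- state$stocks - moving
    nl <- state$soil$n_layers
    if (nl > 1) {
      state$stocks[2:nl] <- state$stocks[2:nl] + moving[1:(nl - 1)]
    }
    state$cum["leached_n"] <- state$cum["leached_n"] + moving[nl]
  }
  state
}

#' Advance the simulation by one day
#'
#' Applies, in fixed order: light interception, gross assimilation
#' (intercepted radiation x light-use efficiency x stress factor),
#' maintenance respiration (shoot and aerenchyma-discounted root), shoot
#' carbon allocation against the potential leaf-area sink, root growth with
#' the remaining carbon, nitrate uptake and soil transport, and the
#' nitrogen stress-factor update. Carbon and nitrogen ledgers are updated
#' and balance exactly.
#'
#' @param state A `sim_state` with `state$day < duration`.
#' @return The state advanced to the next day, with a new row appended to
#'   the daily output table.
#' @export
step_day <- function(state) {
  cfg <- state$config
  ph <- state$phenotype
  if (state$day >= cfg$duration) {
    stop("simulation already ran its configured duration", call. = FALSE)
  }

  # 1. light interception and gross assimilation (biomass equivalents)
  fi <- intercepted_fraction(state$leaf_area, cfg$ground_area, cfg$k_light)
  gross <- cfg$irradiance * (cfg$ground_area / 1e4) * fi * cfg$lue *
    state$stress

  # 2. maintenance respiration, paid from assimilate plus reserve
  if (nrow(state$segs)) {
    rca <- rca_fraction(state$day - state$segs$birth_day, ph$max_rca)
    seg_cost <- segment_maintenance_cost(
      state$segs$dw * state$segs$mult, rca, ph,
      cfg$k_rca_resp, cfg$k_rca_n, cfg$max_rca_ref)
    resp_c <- sum(seg_cost$respired_c)
  } else resp_c <- 0
  resp_c <- resp_c + cfg$shoot_resp * state$shoot_dw
  resp_biomass <- resp_c / cfg$carbon_frac
  pool <- gross + state$reserve
  resp_paid_biomass <- min(resp_biomass, pool)
  resp_paid_c <- resp_paid_biomass * cfg$carbon_frac
  available <- pool - resp_paid_biomass

  # 3. shoot allocation against the potential leaf-area sink; a minimum
  # share of the pool is held back for root growth so the shoot sink
  # cannot starve the root system outright
  dla_pot <- min(cfg$leaf_rel_rate * max(state$leaf_area, cfg$la0),
                 cfg$leaf_max_rate) * state$stress
  cost_cm2 <- (1 + cfg$stem_frac) / cfg$sla
  shoot_alloc <- min(dla_pot * cost_cm2,
                     (1 - cfg$root_share_min) * available)
  state$shoot_dw <- state$shoot_dw + shoot_alloc
  state$leaf_area <- state$leaf_area + shoot_alloc / cost_cm2
  available <- available - shoot_alloc

  # 4. root growth; unspent carbon banks to the reserve
  state <- grow_roots(state, available)
  state$reserve <- state$unspent
  state$unspent <- NULL

  # 5. nitrate uptake and soil transport
  state <- uptake_and_transport(state)

  # 6. stress factor for tomorrow
  eff <- effective_dw(state)
  conc <- if (eff > 0) state$plant_n / eff else ph$costs$optimum_n
  state$stress <- stress_factor(conc, ph$costs$optimum_n, ph$costs$minimum_n)

  state$cum["assim_c"] <- state$cum["assim_c"] + gross * cfg$carbon_frac
  state$cum["resp_c"] <- state$cum["resp_c"] + resp_paid_c
  state$day <- state$day + 1L

  root_dw <- if (nrow(state$segs)) sum(state$segs$dw * state$segs$mult) else 0
  root_len <- if (nrow(state$segs)) {
    sum(state$segs$length * state$segs$mult)
  } else 0
  state$daily[[state$day]] <- data.frame(
    day = state$day, shoot_dw = state$shoot_dw, root_dw = root_dw,
    root_length = root_len, leaf_area = state$leaf_area,
    stress = state$stress, reserve = state$reserve,
    plant_n = state$plant_n, soil_n = sum(state$stocks),
    assim_c = gross * cfg$carbon_frac, resp_c = resp_paid_c,
    cum_uptake_n = unname(state$cum["uptake_n"]),
    cum_leached_n = unname(state$cum["leached_n"])
  )

  if (state$shoot_dw < 0 || state$reserve < -1e-12 || state$plant_n < 0 ||
      any(state$stocks < -1e-9)) {
    stop("internal conservation error: negative pool after update",
         call. = FALSE)
  }
  state
}

#' Run a complete simulation
#'
#' @inheritParams initialize_simulation
#' @return An object of class `root_sim`: a list with `daily` (one row per
#'   day: shoot and root dry weight, root length, leaf area, stress factor,
#'   plant and soil nitrogen, assimilated and respired carbon, cumulative
#'   uptake and leaching), `segments` (final per-segment table), `roots`
#'   (final root/tip table, laterals aggregated into cohorts with
#'   multiplicity `mult`), `final` (final scalar summaries), and the inputs.
#' @examples
#' sim <- run_simulation(canonical_phenotype("reduced_ccfn"),
#'                       soil_profile("silt_loam"),
#'                       sim_config(duration = 20), seed = 1)
#' sim$final$shoot_dw
#' @export
run_simulation <- function(phenotype, soil, config = sim_config(), seed = 1L) {
  state <- initialize_simulation(phenotype, soil, config, seed)
  for (i in seq_len(config$duration)) state <- step_day(state)
  daily <- do.call(rbind, state$daily)

  segs <- state$segs
  if (nrow(segs)) {
    segs$rca_fraction <- rca_fraction(state$day - segs$birth_day,
                                      phenotype$max_rca)
  }
  structure(
    list(daily = daily, segments = segs, roots = state$roots,
         final = list(
           shoot_dw = state$shoot_dw,
           root_dw = daily$root_dw[nrow(daily)],
           root_length = daily$root_length[nrow(daily)],
           plant_n = state$plant_n,
           leached_n = unname(state$cum["leached_n"])),
         phenotype = phenotype, soil = soil, config = config, seed = seed,
         init_totals = state$init_totals),
    class = "root_sim"
  )
}

#' @export
print.root_sim <- function(x, ...) {
  cat(sprintf("root_sim: %s in %s, %d days, seed %d\n",
              x$phenotype$label, x$soil$texture, x$config$duration, x$seed))
  cat(sprintf(
    "  final shoot DW %.3g g, root DW %.3g g, root length %.4g cm\n",
    x$final$shoot_dw, x$final$root_dw, x$final$root_length))
  cat(sprintf("  plant N %.4g umol, N leached %.4g umol\n",
              x$final$plant_n, x$final$leached_n))
  invisible(x)
}

#' @export
plot.root_sim <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$daily$day, x$daily$shoot_dw, type = "l",
                 xlab = "day", ylab = "shoot dry weight (g)",
                 main = x$phenotype$label, ...)
  graphics::plot(x$daily$day, x$daily$stress, type = "l", ylim = c(0, 1),
                 xlab = "day", ylab = "N stress factor", ...)
  invisible(x)
}

#' Write the daily and per-segment output tables as CSV
#'
#' @param sim A `root_sim`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Paths of the two files written, invisibly.
#' @export
write_sim_outputs <- function(sim, dir, prefix = "sim") {
  stopifnot(inherits(sim, "root_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  daily_path <- file.path(dir, paste0(prefix, "_daily.csv"))
  seg_path <- file.path(dir, paste0(prefix, "_segments.csv"))
  utils::write.csv(sim$daily, daily_path, row.names = FALSE)
  seg_cols <- c("class", "mult", "depth", "length", "diameter",
                "rca_fraction")
  utils::write.csv(sim$segments[intersect(seg_cols, names(sim$segments))],
                   seg_path, row.names = FALSE)
  invisible(c(daily = daily_path, segments = seg_path))
}
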