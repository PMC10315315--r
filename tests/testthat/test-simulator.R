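# Daily ledger checks shared by several tests: assimilated carbon equals
# biomass gain (shoot + root + reserve) times carbon fraction plus respired
# carbon; plant nitrogen gain equals uptake; soil nitrogen loss equals
# uptake plus bottom-boundary leaching.
check_ledgers <- function(sim, tol = 1e-8) {
  cfg <- sim$config
  d <- sim$daily
  prev_bio <- c(0.02 + cfg$seed_reserve,
                head(d$shoot_dw + d$root_dw + d$reserve, -1))
  d_c <- (d$shoot_dw + d$root_dw + d$reserve - prev_bio) * cfg$carbon_frac
  c_err <- abs(d$assim_c - (d_c + d$resp_c)) /
    pmax(abs(d$assim_c), abs(d$resp_c), 1e-6)
  up <- diff(c(0, d$cum_uptake_n))
  le <- diff(c(0, d$cum_leached_n))
  pn_err <- abs(diff(c(cfg$seed_n, d$plant_n)) - up)
  soil0 <- sim$soil$total_nitrate * cfg$n_supply
  sn_err <- abs(diff(c(soil0, d$soil_n)) + up + le)
  n_scale <- pmax(d$soil_n, 1)
  list(c = max(c_err), plant_n = max(pn_err / pmax(d$plant_n, 1)),
       soil_n = max(sn_err / n_scale))
}

test_that("simulations are deterministic per seed", {
  ph <- canonical_phenotype("small_ccs", max_rca = 0.2)
  soil <- soil_profile("silt_loam")
  cfg <- quick_config(15)
  a <- run_simulation(ph, soil, cfg, seed = 33)
  b <- run_simulation(ph, soil, cfg, seed = 33)
  expect_identical(a$daily, b$daily)
  expect_identical(a$segments, b$segments)
  c2 <- run_simulation(ph, soil, cfg, seed = 34)
  expect_false(isTRUE(all.equal(a$daily$root_length, c2$daily$root_length)))
})

test_that("carbon and nitrogen ledgers balance daily to 1e-8 relative", {
  for (texture in c("silt_loam", "loamy_sand")) {
    sim <- run_simulation(canonical_phenotype("large_ccs", max_rca = 0.3),
                          soil_profile(texture), quick_config(20), seed = 2)
    errs <- check_ledgers(sim)
    expect_lt(errs$c, 1e-8)
    expect_lt(errs$plant_n, 1e-8)
    expect_lt(errs$soil_n, 1e-8)
  }
})

test_that("ledgers hold even under complete carbon starvation", {
  cfg <- quick_config(10, irradiance = 0)
  sim <- run_simulation(canonical_phenotype("small_ccs"),
                        soil_profile("silt_loam"), cfg, seed = 1)
  errs <- check_ledgers(sim)
  expect_lt(errs$c, 1e-8)
  expect_true(all(sim$daily$reserve >= -1e-12))
  expect_true(all(sim$daily$shoot_dw >= 0.02))
})

test_that("initialization is deterministic, scales soil nitrogen, and records totals", {
  ph <- canonical_phenotype("reduced_ccfn")
  soil <- soil_profile("silt_loam")
  cfg <- quick_config(10)
  s1 <- initialize_simulation(ph, soil, cfg, seed = 7)
  s2 <- initialize_simulation(ph, soil, cfg, seed = 7)
  expect_identical(s1[setdiff(names(s1), "daily")],
                   s2[setdiff(names(s2), "daily")])
  expect_equal(sum(s1$stocks), soil$total_nitrate)
  expect_equal(unname(s1$init_totals["n"]), cfg$seed_n + sum(s1$stocks))
  expect_equal(unname(s1$init_totals["c"]),
               (s1$shoot_dw + s1$reserve) * cfg$carbon_frac)
  cfg0 <- quick_config(10, n_supply = 0)
  s0 <- initialize_simulation(ph, soil, cfg0, seed = 7)
  expect_equal(sum(s0$stocks), 0)
})

test_that("an inconsistent transphenic override is rejected at initialization", {
  expect_error(
    canonical_phenotype("small_ccs",
                        overrides = list(optimum_n = 500, minimum_n = 600)),
    "parameterization")
})

test_that("stepping past the configured duration errors", {
  st <- initialize_simulation(canonical_phenotype("small_ccs"),
                              soil_profile("silt_loam"), quick_config(2), 1)
  st <- step_day(step_day(st))
  expect_error(step_day(st), "duration")
})

test_that("intercepted fraction follows the saturating shading function", {
  expect_equal(intercepted_fraction(0), 0)
  expect_gt(intercepted_fraction(2e4), 0.999)
  expect_lt(intercepted_fraction(2e4), 1)
  set.seed(3)
  la <- runif(20, 0, 5000)
  expect_equal(intercepted_fraction(la, 1560, 0.6),
               1 - exp(-0.6 * la / 1560))
  grid <- seq(0, 4000, by = 50)
  expect_true(all(diff(intercepted_fraction(grid)) > 0))
})

test_that("stress factor is a clamped linear ramp between minimum and optimum", {
  expect_equal(stress_factor(1000, 1000, 500), 1)
  expect_equal(stress_factor(500, 1000, 500), 0)
  expect_equal(stress_factor(750, 1000, 500), 0.5)
  expect_equal(stress_factor(2000, 1000, 500), 1)
  expect_equal(stress_factor(100, 1000, 500), 0)
  expect_error(stress_factor(700, 500, 1000), "below")
})

test_that("aerenchyma develops after the elongation zone and saturates at 20 days", {
  expect_equal(rca_fraction(0, 0.3), 0)
  expect_equal(rca_fraction(1, 0.3), 0)
  expect_equal(rca_fraction(20, 0.3), 0.3)
  expect_equal(rca_fraction(35, 0.3), 0.3)
  expect_equal(rca_fraction(10.5, 0.39), 0.39 * 9.5 / 19)
  ages <- seq(0, 40, by = 0.25)
  expect_true(all(diff(rca_fraction(ages, 0.25)) >= 0))
})

test_that("segment maintenance cost matches the arithmetic and aerenchyma discount", {
  ph <- canonical_phenotype("small_ccs")
  cost0 <- segment_maintenance_cost(2, 0, ph)
  expect_equal(cost0$respired_c, ph$costs$respiration * 12 / 44 * 2)
  expect_equal(cost0$n_optimum, ph$costs$optimum_n * 2)
  # non-increasing in aerenchyma, all else equal
  rcas <- seq(0, 0.39, by = 0.03)
  costs <- segment_maintenance_cost(rep(2, length(rcas)), rcas, ph)
  expect_true(all(diff(costs$respired_c) < 0))
  expect_true(all(diff(costs$n_optimum) < 0))
  # full reference aerenchyma halves both costs at the default coefficients
  expect_equal(segment_maintenance_cost(2, 0.39, ph)$respired_c,
               cost0$respired_c / 2)
})

test_that("reduced-CCFN segments cost strictly less than increased-CCFN segments", {
  red <- canonical_phenotype("reduced_ccfn")
  inc <- canonical_phenotype("increased_ccfn")
  len <- 5
  dens <- sim_config()$tissue_density
  dw_red <- len * pi * (red$costs$diameter / 20)^2 * dens
  dw_inc <- len * pi * (inc$costs$diameter / 20)^2 * dens
  expect_lt(dw_red, dw_inc)
  expect_lt(segment_maintenance_cost(dw_red, 0, red)$respired_c,
            segment_maintenance_cost(dw_inc, 0, inc)$respired_c)
})

test_that("no carbon means no elongation; doubling diameter quarters new length", {
  soil <- soil_profile("silt_loam")
  cfg <- quick_config(5, stochasticity = 0)
  ph1 <- plant_phenotype(10, 300)
  st <- initialize_simulation(ph1, soil, cfg, seed = 1)
  starved <- grow_roots(st, 0)
  expect_equal(nrow(starved$segs), 0)
  expect_equal(starved$roots$length, st$roots$length)
  expect_equal(starved$unspent, 0)

  # same carbon, doubled diameter: cost per cm scales with diameter^2
  costs2 <- ph1$costs
  costs2$diameter <- 2 * ph1$costs$diameter
  ph2 <- plant_phenotype(10, 300, costs = costs2)
  c_small <- 1e-4   # far below potential demand, so growth is carbon-limited
  g1 <- grow_roots(initialize_simulation(ph1, soil, cfg, seed = 1), c_small)
  g2 <- grow_roots(initialize_simulation(ph2, soil, cfg, seed = 1), c_small)
  len1 <- sum(g1$segs$length * g1$segs$mult)
  len2 <- sum(g2$segs$length * g2$segs$mult)
  expect_equal(len1 / len2, 4, tolerance = 1e-6)
})

test_that("lateral density tracks the branching phene", {
  soil <- soil_profile("silt_loam")
  cfg <- quick_config(15, stochasticity = 0)
  for (lrbd in c(4, 8)) {
    sim <- run_simulation(plant_phenotype(6, 360, lrbd = lrbd), soil, cfg, 1)
    lat <- sim$roots$class == "lateral"
    n_laterals <- sum(sim$roots$mult[lat])
    axial_len <- sum(sim$roots$length[!lat] * sim$roots$mult[!lat])
    expect_equal(n_laterals / axial_len, lrbd, tolerance = 1e-9)
  }
  # with jitter on, the density is still close to the phene on average
  cfgj <- quick_config(15, stochasticity = 0.05)
  sim <- run_simulation(plant_phenotype(6, 360, lrbd = 6), soil, cfgj, 2)
  lat <- sim$roots$class == "lateral"
  dens <- sum(sim$roots$mult[lat]) /
    sum(sim$roots$length[!lat] * sim$roots$mult[!lat])
  expect_equal(dens, 6, tolerance = 0.1)
})

test_that("uptake is zero from an empty profile and saturates at high concentration", {
  ph <- canonical_phenotype("small_ccs")
  soil <- soil_profile("silt_loam")
  cfg <- quick_config(12, n_supply = 0, stochasticity = 0)
  sim <- run_simulation(ph, soil, cfg, seed = 1)
  expect_equal(max(sim$daily$cum_uptake_n), 0)
  expect_equal(max(sim$daily$plant_n), cfg$seed_n)

  # engineered state: enormous stocks, hungry plant -> uptake approaches
  # the surface-limited maximum imax * root surface
  cfg2 <- quick_config(12, stochasticity = 0)
  st <- initialize_simulation(ph, soil, cfg2, seed = 1)
  for (i in 1:10) st <- step_day(st)
  st$stocks <- rep(1e9, st$soil$n_layers)
  st$plant_n <- 0
  before <- st$plant_n
  st2 <- uptake_and_transport(st)
  surface <- sum(st$segs$length * st$segs$mult * pi * st$segs$diameter / 10)
  demand <- canonical_phenotype("small_ccs")$costs$optimum_n *
    (st$shoot_dw + sum(st$segs$dw * st$segs$mult *
      (1 - cfg2$k_rca_n * rca_fraction(st$day - st$segs$birth_day, ph$max_rca) /
         cfg2$max_rca_ref)))
  expect_equal(st2$plant_n - before,
               min(demand, cfg2$imax * surface), tolerance = 1e-3)
})

test_that("without a plant, loamy sand leaches more nitrate than silt loam", {
  silt <- simulate_leaching(soil_profile("silt_loam"), 40)
  sand <- simulate_leaching(soil_profile("loamy_sand"), 40)
  expect_gt(sand$loss_fraction, silt$loss_fraction)
  expect_gt(sand$loss_fraction / silt$loss_fraction, 1.5)
  # mass conserved: leached + remaining = initial
  expect_equal(sand$final_n + sand$leached_n, sand$initial_n)
  # supply scalar 0 empties the profile
  expect_equal(simulate_leaching(soil_profile("loamy_sand"), 10, 0)$initial_n, 0)
})

test_that("shoot growth is non-decreasing in nitrogen supply", {
  ph <- canonical_phenotype("small_ccs")
  soil <- soil_profile("silt_loam")
  means <- sapply(c(0, 0.15, 0.5, 1), function(s) {
    run_phenotype(ph, soil, quick_config(25, n_supply = s),
                  n_reps = 2, base_seed = 1)$mean_sdw
  })
  expect_true(all(diff(means) > -0.02 * means[-1]))
})

test_that("a stress-free plant outgrows every nitrogen-limited run", {
  ph <- canonical_phenotype("increased_ccfn")
  soil <- soil_profile("silt_loam")
  full <- run_simulation(ph, soil, quick_config(25, n_supply = 50,
                                                stochasticity = 0,
                                                seed_n = 3000), 1)
  limited <- run_simulation(ph, soil, quick_config(25, n_supply = 0.1,
                                                   stochasticity = 0), 1)
  expect_gt(full$final$shoot_dw, limited$final$shoot_dw)
  expect_equal(min(full$daily$stress), 1)
})

test_that("simulation outputs round-trip to CSV", {
  sim <- run_simulation(canonical_phenotype("reduced_ccfn", max_rca = 0.2),
                        soil_profile("loamy_sand"), quick_config(12), 5)
  dir <- tempfile()
  paths <- write_sim_outputs(sim, dir)
  daily <- read.csv(paths["daily"])
  expect_equal(nrow(daily), 12)
  segs <- read.csv(paths["segments"])
  expect_true(all(c("class", "depth", "length", "diameter", "rca_fraction")
                  %in% names(segs)))
  expect_true(all(segs$rca_fraction <= 0.2 + 1e-12))
  expect_true(all(segs$depth >= 0))
})
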