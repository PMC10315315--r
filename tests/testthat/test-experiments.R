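soil_sl <- soil_profile("silt_loam")

test_that("a single replicate reports its own value with zero SD", {
  ph <- canonical_phenotype("reduced_ccfn")
  cfg <- quick_config(12)
  res <- run_phenotype(ph, soil_sl, cfg, n_reps = 1, base_seed = 9)
  one <- run_simulation(ph, soil_sl, cfg, seed = 9)
  expect_equal(res$mean_sdw, one$final$shoot_dw)
  expect_equal(res$mean_root_length, one$final$root_length)
  expect_equal(res$sd_sdw, 0)
})

test_that("zero stochasticity gives identical replicates and zero SD", {
  res <- run_phenotype(canonical_phenotype("small_ccs"), soil_sl,
                       quick_config(12, stochasticity = 0),
                       n_reps = 4, base_seed = 1)
  expect_equal(res$sd_sdw, 0, tolerance = 1e-12)
  expect_equal(res$sd_root_length, 0, tolerance = 1e-12)
})

test_that("replicate means are consistent across replication depth", {
  ph <- canonical_phenotype("small_ccs")
  cfg <- quick_config(20, n_supply = 0.3)
  small <- run_phenotype(ph, soil_sl, cfg, n_reps = 3, base_seed = 1)
  big <- run_phenotype(ph, soil_sl, cfg, n_reps = 12, base_seed = 101)
  se <- big$sd_sdw / sqrt(12) + small$sd_sdw / sqrt(3)
  expect_lt(abs(small$mean_sdw - big$mean_sdw), 4 * se + 0.02 * big$mean_sdw)
})

test_that("additivity and synergy are exact identities", {
  set.seed(21)
  for (i in 1:25) {
    comps <- runif(3, -50, 150)
    expect_identical(additive_expectation(comps), sum(comps))
  }
  expect_equal(additive_expectation(c(97, 14, 60)), 171)
  expect_equal(additive_expectation(c(13, 3, -4)), 12)
  expect_equal(additive_expectation(c(94, 1, -9)), 86)
})

test_that("decomposing a phene state against itself gives zero everywhere", {
  cfg <- quick_config(12, n_supply = 0.4)
  d <- transphenic_decomposition("small_ccs", "small_ccs", soil_sl, cfg,
                                 n_reps = 2, base_seed = 1)
  expect_equal(d$benefits$sdw, rep(0, 3))
  expect_equal(d$benefits$root_length, rep(0, 3))
  expect_equal(unname(d$combined), c(0, 0))
  expect_equal(unname(d$synergy), c(0, 0))
})

test_that("decomposition bookkeeping: additive is the component sum, synergy the residual", {
  cfg <- quick_config(15, n_supply = 0.25)
  d <- transphenic_decomposition("small_ccs", "large_ccs", soil_sl, cfg,
                                 n_reps = 2, base_seed = 3)
  expect_equal(unname(d$additive["sdw"]), sum(d$benefits$sdw))
  expect_equal(unname(d$additive["root_length"]), sum(d$benefits$root_length))
  expect_equal(unname(d$synergy), unname(d$combined - d$additive))
})

test_that("a 1x1 sensitivity grid equals run_phenotype for that cell", {
  cfg <- quick_config(12)
  g <- sensitivity_grid(10, 300, c(medium = 0.3), soil_sl, cfg,
                        n_reps = 2, base_seed = 5)
  expect_equal(nrow(g), 1)
  cfg$n_supply <- 0.3
  direct <- run_phenotype(plant_phenotype(10, 300), soil_sl, cfg,
                          n_reps = 2, base_seed = 5)
  expect_equal(g$mean_sdw, direct$mean_sdw)
  expect_equal(g$sd_sdw, direct$sd_sdw)
})

test_that("factorial report: worst performer is 0 and input order is immaterial", {
  cfg <- quick_config(18, n_supply = 0.2)
  a <- factorial_experiment(soil_sl, cfg,
                            ccfn = c(ReducedCCFN = 6, IncreasedCCFN = 18),
                            ccs = c(LargeCCS = 450, SmallCCS = 200),
                            rca = c(LowRCA = 0.1, HighRCA = 0.3),
                            n_reps = 1, base_seed = 2)
  expect_equal(min(a$rel_increase), 0)
  expect_equal(sum(a$rel_increase == 0), 1)
  b <- factorial_experiment(soil_sl, cfg,
                            ccfn = c(IncreasedCCFN = 18, ReducedCCFN = 6),
                            ccs = c(SmallCCS = 200, LargeCCS = 450),
                            rca = c(HighRCA = 0.3, LowRCA = 0.1),
                            n_reps = 1, base_seed = 2)
  expect_equal(a[order(a$label), ], b[order(b$label), ],
               ignore_attr = TRUE)
})

test_that("factorial requires exactly one varied third phene", {
  expect_error(factorial_experiment(soil_sl, quick_config(5), rca = NULL,
                                    lrbd = NULL), "exactly one")
  expect_error(factorial_experiment(soil_sl, quick_config(5),
                                    rca = c(LowRCA = 0.1),
                                    lrbd = c(LowLRBD = 4)), "exactly one")
})

test_that("calibration orders scalars by stress level and flags infeasible targets", {
  cal <- calibrate_stress_levels(plant_phenotype(10, 300), soil_sl,
                                 quick_config(25), targets = c(20, 50),
                                 n_reps = 1, base_seed = 1)
  expect_lt(cal$scalars[["target_50"]], cal$scalars[["target_20"]])
  expect_lt(abs(cal$achieved[["target_20"]] - 20), 3)
  expect_lt(abs(cal$achieved[["target_50"]] - 50), 3)
  # a target no nitrogen scarcity can reach in 12 days is infeasible
  expect_error(
    calibrate_stress_levels(plant_phenotype(10, 300), soil_sl,
                            quick_config(12), targets = 99.5,
                            n_reps = 1, base_seed = 1),
    "infeasible")
})

test_that("replicate failures identify the offending seed", {
  bad_soil <- soil_profile("silt_loam")
  bad_soil$n_layers <- 0   # corrupt the profile to force a failure
  expect_error(
    run_phenotype(canonical_phenotype("small_ccs"), bad_soil,
                  quick_config(5), n_reps = 2, base_seed = 77),
    "seed 77")
})
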