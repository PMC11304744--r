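# Monte Carlo exposure simulation and weight-band dose optimization.

# population with negligible underweight effect for analytic checks
flat_population <- function(n_per_kg, range, seed) {
  make_virtual_population(n_per_kg, range, zwfa_mean = 0, zwfa_sd = 1e-6,
                          zwfa_range = c(-0.1, 0.1), seed = seed)
}

test_that("without variability the per-kg median AUC equals the closed form", {
  pop <- flat_population(101, c(10, 15), seed = 3)
  pop$age <- 8  # keep the absorption-age covariate out of the check
  rep0 <- simulate_exposures(pop, dose_rule_mgkg(20, 300, lpvr = 0),
                             pop_spec = rb_population_spec(0, 0, 0, 0, 0),
                             seed = 4)
  for (b in unique(pop$kg_bin)) {
    wmed <- median(pop$weight[pop$kg_bin == b])
    expected <- 20 * wmed * 1000 / (29.8 * (wmed / 10)^0.75)
    got <- rep0$per_kg$auc_parent_med[rep0$per_kg$kg_bin == b]
    expect_equal(got, expected, tolerance = 1e-9)
  }
})

test_that("the 300-mg adult cap binds for proportional dosing", {
  pop <- flat_population(5, c(19, 21), seed = 5)
  rep <- simulate_exposures(pop, dose_rule_mgkg(20, 300, lpvr = 0),
                            pop_spec = rb_population_spec(0, 0, 0, 0, 0), seed = 6)
  ch <- rep$children
  expect_true(all(ch$dose_mg[ch$weight >= 15] == 300))
  expect_true(all(ch$dose_mg[ch$weight < 15] == 20 * ch$weight[ch$weight < 15]))
})

test_that("exposures scale linearly in dose and band medians are monotone", {
  pop <- make_virtual_population(40, c(8, 12), seed = 7)
  r1 <- simulate_exposures(pop, dose_rule_mgkg(2.5, lpvr = 1), seed = 8)
  r2 <- simulate_exposures(pop, dose_rule_mgkg(5, lpvr = 1), seed = 8)
  expect_equal(r2$per_kg$auc_parent_med, 2 * r1$per_kg$auc_parent_med,
               tolerance = 1e-9)
  expect_equal(r2$per_kg$cmax_metabolite_med, 2 * r1$per_kg$cmax_metabolite_med,
               tolerance = 1e-9)
})

test_that("band rules reject out-of-table weights and flag empty bands", {
  tab <- data.frame(lo = c(6, 10), hi = c(10, 15), dose = c(115, 160))
  rule <- dose_rule_bands(tab, lpvr = 0)
  pop <- flat_population(5, c(14, 16), seed = 9)
  expect_error(simulate_exposures(pop, rule, seed = 10), "band table")
  expect_error(dose_rule_bands(data.frame(lo = c(6, 11), hi = c(10, 15),
                                          dose = c(1, 1))), "contiguous")
  pop2 <- flat_population(5, c(6, 8), seed = 11)
  expect_warning(
    opt <- optimize_band_doses(pop2, bands = data.frame(lo = c(6, 10), hi = c(10, 15)),
                               context = "lpvr", seed = 12),
    "empty band")
  expect_true(is.na(opt$dose[2]))
})

test_that("with no floor and an unbounded window the smallest grid dose wins", {
  pop <- make_virtual_population(30, c(10, 12), seed = 13)
  ref <- adult_reference()
  ref$auc_parent_lpvr <- c(0, Inf); ref$auc_floor <- 0; ref$cmax_limit <- Inf
  for (objective in c("floor", "midpoint")) {
    opt <- optimize_band_doses(pop, bands = data.frame(lo = 10, hi = 12),
                               reference = ref, context = "lpvr",
                               objective = objective, seed = 14)
    expect_equal(opt$dose, 5)
  }
})

test_that("rule evaluation scores medians against the adult windows", {
  pop <- flat_population(60, c(10, 15), seed = 15)
  # the study TB-only dose overshoots the adult window in this band
  rep <- simulate_exposures(pop, dose_rule_mgkg(20, 300, lpvr = 0),
                            bands = data.frame(lo = 10, hi = 15), seed = 16)
  ev <- evaluate_rule(rep, context = "tb")
  expect_false(ev$pass)
  expect_gt(ev$auc_excess_pct, 0)
  # the optimized band dose passes
  tab <- data.frame(lo = 10, hi = 15, dose = 160)
  rep2 <- simulate_exposures(pop, dose_rule_bands(tab, lpvr = 0), seed = 17)
  ev2 <- evaluate_rule(rep2, context = "tb")
  expect_true(ev2$auc_in_window)
  expect_true(ev2$cmax_ok)
})

test_that("optimized band doses reproduce the published tables", {
  pop <- make_virtual_population(150, c(6, 45), seed = 18)
  opt_l <- optimize_band_doses(pop, context = "lpvr", seed = 19)
  published_lpvr <- c(25, 35, 45, 55, 65, 70, 85)
  expect_true(all(abs(opt_l$dose - published_lpvr) <= 5))
  opt_t <- optimize_band_doses(pop, context = "tb", seed = 20)
  published_tb <- c(115, 160, 200, 250, 300, 300, 300)
  expect_true(all(abs(opt_t$dose / published_tb - 1) <= 0.10))
  # the adult cap binds for the heaviest TB-only bands
  expect_true(all(opt_t$dose[6:7] == 300))
  # selected doses respect the toxicity constraint
  expect_true(all(opt_l$cmax_parent < 900))
  expect_true(all(opt_t$cmax_parent < 900))
})

test_that("band dose selection is stable across seeds at moderate sample size", {
  pop1 <- make_virtual_population(150, c(6, 45), seed = 21)
  pop2 <- make_virtual_population(150, c(6, 45), seed = 22)
  d1 <- optimize_band_doses(pop1, context = "lpvr", seed = 23)$dose
  d2 <- optimize_band_doses(pop2, context = "lpvr", seed = 24)$dose
  expect_true(all(abs(d1 - d2) <= 5))
})

test_that("simulated medians converge to the no-variability values", {
  pop <- flat_population(500, c(10, 11), seed = 25)
  pop$age <- 8
  r_sto <- simulate_exposures(pop, dose_rule_mgkg(2.5, lpvr = 1), seed = 26)
  r_det <- simulate_exposures(pop, dose_rule_mgkg(2.5, lpvr = 1),
                              pop_spec = rb_population_spec(0, 0, 0, 0, 0),
                              seed = 27)
  expect_lt(abs(r_sto$per_kg$auc_parent_med / r_det$per_kg$auc_parent_med - 1),
            0.07)
})
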