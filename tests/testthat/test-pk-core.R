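# Structural model: allometry, covariate effects, closed-form solution.

test_that("allometric scaling has the reference identity and the published 70-kg extrapolation", {
  p <- rb_structural_params()
  expect_equal(apply_allometry(p, 10)$cl_cyp_ref, 13.6)
  expect_equal(round(apply_allometry(p, 70)$cl_cyp_ref, 1), 58.5)
  expect_equal(apply_allometry(p, 20)$vc_p_ref, 370)  # 185 * (20/10)^1
  # clearance monotone in weight
  w <- seq(2, 60, by = 0.5)
  cl <- apply_allometry(p, w)$cl_conv_ref
  expect_true(all(diff(cl) > 0))
  expect_error(apply_allometry(p, 0), "positive")
  expect_error(apply_allometry(p, -5), "positive")
})

test_that("covariate effects reproduce the final-model multipliers", {
  p <- apply_allometry(rb_structural_params(), 10)
  ef <- rb_covariate_effects()
  on_lpvr <- apply_covariates(p, ef, list(lpvr = 1))
  expect_equal(on_lpvr$f_ref, 2.58)
  expect_equal(on_lpvr$cl_cyp_ref, 0)           # full CYP3A4 inhibition
  expect_equal(on_lpvr$cl_met_ref, 106 * 0.234)
  expect_equal(on_lpvr$cl_conv_ref, 16.2)       # AADAC pathway untouched

  # above the severe-underweight threshold and off LPV/r: no change
  same <- apply_covariates(p, ef, list(zwfa = -2, lpvr = 0, age = 8))
  expect_equal(unclass(same), unclass(p))

  # one unit below -3: 26% bioavailability loss
  expect_equal(apply_covariates(p, ef, list(zwfa = -4))$f_ref, 0.74)
  # power form stays positive even far below the threshold
  expect_gt(apply_covariates(p, ef, list(zwfa = -15))$f_ref, 0)
  # linear variant
  ef_lin <- rb_covariate_effects(zwfa_form = "linear")
  expect_equal(apply_covariates(p, ef_lin, list(zwfa = -4.5))$f_ref,
               1 - 0.26 * 1.5)
  # slower absorption at 3 years or below
  expect_equal(apply_covariates(p, ef, list(age = 2))$ka, 1.27 * 0.277)
  expect_equal(apply_covariates(p, ef, list(age = 3.01))$ka, 1.27)
  expect_error(apply_covariates(p, ef, list(age = -1)), "age")
})

test_that("concentration profile is zero without input mass and before the lag", {
  p <- apply_allometry(rb_structural_params(), 12)
  none <- concentration_profile(p, data.frame(time = numeric(0), amount = numeric(0)),
                                times = c(0, 1, 12))
  expect_equal(none$conc_parent, c(0, 0, 0))
  expect_equal(none$conc_metabolite, c(0, 0, 0))
  one <- concentration_profile(p, data.frame(time = 0, amount = 100),
                               times = c(0, 0.5, p$tlag * 0.99))
  expect_equal(one$conc_parent, c(0, 0, 0))
  expect_equal(one$conc_metabolite, c(0, 0, 0))
  expect_error(concentration_profile(p, data.frame(time = c(24, 0), amount = 1),
                                     times = 1), "sorted")
})

test_that("closed-form solution matches stiff ODE integration on random parameters", {
  skip_if_not_installed("deSolve")
  set.seed(2203)
  for (i in 1:6) {
    p <- random_params()
    times <- seq(0, 72, by = 1.5)
    a <- concentration_profile(p, data.frame(time = 0, amount = 150), times)
    b <- ode_oracle_profile(p, 150, times)
    expect_lt(max(abs(a$conc_parent - b$conc_parent)) / max(b$conc_parent), 1e-6)
    expect_lt(max(abs(a$conc_metabolite - b$conc_metabolite)) / max(b$conc_metabolite), 1e-6)
  }
})

test_that("concentrations are linear in dose and superpose over doses", {
  set.seed(404)
  p <- random_params()
  times <- c(1, 3, 7, 18, 30)
  one <- concentration_profile(p, data.frame(time = 0, amount = 50), times)
  two <- concentration_profile(p, data.frame(time = 0, amount = 100), times)
  expect_equal(two$conc_parent, 2 * one$conc_parent)
  expect_equal(two$conc_metabolite, 2 * one$conc_metabolite)
  both <- concentration_profile(p, data.frame(time = c(0, 12), amount = c(50, 80)), times)
  d2 <- concentration_profile(p, data.frame(time = 12, amount = 80), times)
  expect_equal(both$conc_parent, one$conc_parent + d2$conc_parent)
  expect_equal(both$conc_metabolite, one$conc_metabolite + d2$conc_metabolite)
})

test_that("mass balance holds at infinite time after a single dose", {
  set.seed(99)
  ct <- rb_constants()
  for (i in 1:4) {
    p <- random_params()
    ex <- steady_state_exposures(p, daily_dose = 120)
    dose_ug <- 120 * 1000
    cl_p <- p$cl_cyp_ref + p$cl_conv_ref
    # parent: amount eliminated (both routes) equals the absorbed dose
    expect_equal(ex$auc_parent * cl_p, p$f_ref * dose_ug, tolerance = 1e-6)
    # metabolite: molar fraction converted, then cleared
    conv_ug <- p$f_ref * dose_ug * (ct$mw_metabolite / ct$mw_parent) *
      p$cl_conv_ref / cl_p
    expect_equal(ex$auc_metabolite * p$cl_met_ref, conv_ug, tolerance = 1e-6)
  }
})

test_that("with LPV/r the parent is cleared by the conversion pathway alone", {
  p <- apply_covariates(apply_allometry(rb_structural_params(), 12.5),
                        rb_covariate_effects(), list(lpvr = 1))
  ex <- steady_state_exposures(p, 31.25)
  expect_equal(ex$auc_parent, 2.58 * 31250 / (16.2 * 1.25^0.75), tolerance = 1e-9)
})

test_that("steady-state metrics: analytic AUC vs trapezoid, geometric series vs long simulation", {
  p <- apply_covariates(apply_allometry(rb_structural_params(), 8),
                        rb_covariate_effects(), list(lpvr = 1, age = 2))
  ex <- steady_state_exposures(p, 40)
  # trapezoid on a fine grid of the periodic profile
  tgrid <- seq(0, 24, by = 0.05)
  prof <- concentration_profile(p, data.frame(time = 0, amount = 40, ss = 1, ii = 24), tgrid)
  trap <- function(y) sum(diff(tgrid) * (head(y, -1) + tail(y, -1)) / 2)
  expect_lt(abs(trap(prof$conc_parent) / ex$auc_parent - 1), 0.005)
  expect_lt(abs(trap(prof$conc_metabolite) / ex$auc_metabolite - 1), 0.005)
  # explicit 60-day superposition agrees with the geometric series
  ex_sim <- steady_state_exposures(p, 40, method = "simulate", n_days = 60)
  expect_equal(ex$auc_parent, ex_sim$auc_parent, tolerance = 1e-8)
  expect_equal(ex$cmax_parent, ex_sim$cmax_parent, tolerance = 1e-8)
  expect_equal(ex$cmax_metabolite, ex_sim$cmax_metabolite, tolerance = 1e-8)
  # linearity and input validation
  ex2 <- steady_state_exposures(p, 80)
  expect_equal(ex2$auc_parent, 2 * ex$auc_parent)
  expect_equal(ex2$cmax_metabolite, 2 * ex$cmax_metabolite)
  expect_error(steady_state_exposures(p, 40, tau = 0), "tau")
})

test_that("scalar and vectorized solution paths agree", {
  set.seed(314)
  ps <- replicate(5, random_params(), simplify = FALSE)
  pv <- do.call(rb_structural_params,
                stats::setNames(lapply(names(ps[[1]]),
                                       function(f) sapply(ps, `[[`, f)),
                                names(ps[[1]])))
  exv <- steady_state_exposures(pv, 100)
  for (i in 1:5) {
    exi <- steady_state_exposures(ps[[i]], 100)
    expect_equal(unlist(exv[i, ]), unlist(exi[1, ]), tolerance = 1e-10)
  }
})

test_that("parameter configurations round-trip through YAML and JSON", {
  p <- rb_structural_params(cl_cyp_ref = 11.1, ka = 0.9)
  ef <- rb_covariate_effects(lpvr_f_fold = 2.2)
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_params_config(p, path, effects = ef)
    back <- read_params_config(path)
    expect_equal(unclass(back$params), unclass(p))
    expect_equal(back$effects$lpvr_f_fold, 2.2)
  }
})
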