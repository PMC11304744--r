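# Estimation machinery: BLQ preprocessing, dose-history reset rule,
# likelihood oracles, Laplace accuracy, model comparison, stepwise
# search, empirical Bayes estimates.

# hand-built single-subject dataset: one steady-state occasion with a
# parent/metabolite pair at each sampling time
mini_dataset <- function(times, dv_p, dv_m, dose = 100, wt = 10, lpvr = 0,
                         age = 8, zwfa = -1) {
  ds <- rbind(
    data.frame(ID = 1, TIME = 0, EVID = 1, AMT = dose, CMT = 1, DV = NA,
               MDV = 1, BLQ = 0L, OCC = 1, WT = wt, AGE = age, ZWFA = zwfa,
               LPVR = lpvr, SS = 1, II = 24),
    data.frame(ID = 1, TIME = rep(times, 2), EVID = 0, AMT = NA,
               CMT = rep(c(2, 3), each = length(times)),
               DV = c(dv_p, dv_m), MDV = 0,
               BLQ = c(censor_blq(dv_p, "parent"), censor_blq(dv_m, "metabolite")),
               OCC = 1, WT = wt, AGE = age, ZWFA = zwfa, LPVR = lpvr,
               SS = 0, II = 0))
  class(ds) <- c("pk_dataset", "data.frame")
  ds
}

test_that("the BLQ rule imputes the boundary samples and excludes the rest", {
  # profile without BLQ: roles untouched
  ds <- mini_dataset(c(0, 2, 4, 8, 12, 24), dv_p = c(50, 300, 400, 250, 150, 80),
                     dv_m = c(40, 60, 90, 70, 50, 45))
  pp <- preprocess_blq(ds)
  expect_true(all(pp$ROLE[pp$EVID == 0] == "obs"))
  expect_equal(pp$DV_FIT, pp$DV)

  # a BLQ run on the elimination side: first imputed at LLOQ/2 with
  # inflated additive error, later ones excluded
  ds2 <- mini_dataset(c(0, 2, 4, 8, 12, 24), dv_p = c(50, 300, 400, 250, 2.1, 0.9),
                      dv_m = c(40, 60, 90, 70, 50, 45))
  pp2 <- preprocess_blq(ds2)
  p12 <- pp2$EVID == 0 & pp2$CMT == 2 & pp2$TIME == 12
  p24 <- pp2$EVID == 0 & pp2$CMT == 2 & pp2$TIME == 24
  expect_equal(pp2$ROLE[p12], "imputed")
  expect_equal(pp2$DV_FIT[p12], 3.91 / 2)
  expect_equal(pp2$ADD_INFL[p12], 3.91 / 2)
  expect_equal(pp2$ROLE[p24], "excluded")

  # an all-BLQ profile keeps exactly the absorption-side last and the
  # elimination-side first sample (peak side from the predicted Tmax)
  ds3 <- mini_dataset(c(0, 2, 4, 8, 12, 24), dv_p = rep(1, 6),
                      dv_m = c(40, 60, 90, 70, 50, 45))
  pp3 <- preprocess_blq(ds3)
  roles <- pp3$ROLE[pp3$EVID == 0 & pp3$CMT == 2]
  expect_equal(sum(roles == "imputed"), 2)
  expect_equal(sum(roles == "excluded"), 4)
  tt <- pp3$TIME[pp3$EVID == 0 & pp3$CMT == 2]
  imputed_t <- tt[roles == "imputed"]
  expect_true(imputed_t[1] < imputed_t[2])  # one on each side of the peak
})

test_that("the pre-dose reset rule applies the one-third threshold", {
  flagged <- mini_dataset(c(0, 24), dv_p = c(10, 40), dv_m = c(5, 20))
  rf <- detect_and_reset(flagged)
  expect_true(all(rf$RESET == 1))
  expect_equal(rf$PREDOSE_P[1], 10)
  clean <- mini_dataset(c(0, 24), dv_p = c(20, 40), dv_m = c(5, 20))
  expect_true(all(detect_and_reset(clean)$RESET == 0))
  # profiles lacking the pre-dose or 24-h sample are never flagged
  nopre <- mini_dataset(c(2, 24), dv_p = c(1, 40), dv_m = c(5, 20))
  expect_true(all(detect_and_reset(nopre)$RESET == 0))
})

test_that("reset flags match a brute-force scan on a nonadherent simulation", {
  ds <- make_study_dataset(nonadherence_frac = 0.3, seed = 88)
  rf <- detect_and_reset(ds)
  # independent rule oracle: row-wise scan over profiles
  expected <- integer(0)
  got <- integer(0)
  for (id in unique(ds$ID)) for (occ in unique(ds$OCC[ds$ID == id])) {
    rows <- ds$ID == id & ds$OCC == occ
    if (!any(rows)) next
    t0 <- max(ds$TIME[rows & ds$EVID == 1])
    pre <- ds$DV[rows & ds$EVID == 0 & ds$CMT == 2 & ds$TIME == t0]
    h24 <- ds$DV[rows & ds$EVID == 0 & ds$CMT == 2 & ds$TIME == t0 + 24]
    flag <- length(pre) == 1 && length(h24) == 1 && pre < h24 / 3
    expected <- c(expected, as.integer(flag))
    got <- c(got, max(rf$RESET[rows]))
  }
  expect_equal(got, expected)
  expect_gt(sum(expected), 0)  # the injector must exercise the rule
})

test_that("the joint -2LL matches a hand-computed Gaussian likelihood", {
  # zero-noise truth: predictions known, residuals constructed by hand
  ds <- noise_free_dataset(seed = 7, n_per_cohort = c(u1 = 1, c1_3 = 0, c3_15 = 1))
  truth <- attr(ds, "truth_pred")
  model <- published_model()
  model$pop_spec <- rb_population_spec(0, 0, 0, 0, 0)  # no random effects
  sig_add_p <- 7; sig_add_m <- 4
  model$error_spec <- rb_residual_spec(0, sig_add_p, 0, sig_add_m, 0)
  ds <- detect_and_reset(preprocess_blq(ds))

  # residuals all zero: only the log-variance terms remain
  n_p <- sum(ds$EVID == 0 & ds$CMT == 2 & ds$ID == 1)
  n_m <- sum(ds$EVID == 0 & ds$CMT == 3 & ds$ID == 1)
  expected0 <- n_p * log(2 * pi * sig_add_p^2) + n_m * log(2 * pi * sig_add_m^2)
  expect_equal(neg2ll_individual(ds, 1, model), expected0, tolerance = 1e-8)

  # displacing one observation adds exactly its standardized square
  i <- which(ds$ID == 1 & ds$EVID == 0 & ds$CMT == 2)[3]
  ds2 <- ds; ds2$DV[i] <- ds2$DV[i] + 10; ds2$DV_FIT[i] <- ds2$DV_FIT[i] + 10
  expect_equal(neg2ll_individual(ds2, 1, model), expected0 + 100 / sig_add_p^2,
               tolerance = 1e-6)

  # with zero correlation the paired likelihood is the sum of the
  # single-analyte (block-diagonal) likelihoods
  model_rho <- model; model_rho$error_spec$corr <- 0.4
  ll_rho0 <- neg2ll_individual(ds2, 1, model)
  zp <- 10 / sig_add_p
  manual_rho <- function(rho) {
    # only one pair has nonzero residuals; its bivariate contribution
    # replaces zp^2 with (zp^2)/(1-rho^2), and every pair adds log(1-rho^2)
    n_pairs <- length(intersect(ds$TIME[ds$ID == 1 & ds$EVID == 0 & ds$CMT == 2],
                                ds$TIME[ds$ID == 1 & ds$EVID == 0 & ds$CMT == 3]))
    expected0 + n_pairs * log(1 - rho^2) + zp^2 / (1 - rho^2)
  }
  expect_equal(neg2ll_individual(ds2, 1, model_rho), manual_rho(0.4), tolerance = 1e-6)
  expect_equal(ll_rho0, manual_rho(0), tolerance = 1e-6)

  # excluded BLQ rows contribute nothing: dropping them changes nothing
  ds3 <- ds2
  j <- which(ds3$ID == 1 & ds3$EVID == 0 & ds3$CMT == 3)[1]
  ds3$ROLE[j] <- "excluded"
  ds4 <- ds3[-j, ]
  expect_equal(neg2ll_individual(ds3, 1, model), neg2ll_individual(ds4, 1, model))
})

test_that("noise-free data identify the fixed effects to within 1%", {
  ds <- make_study_dataset(pop_spec = rb_population_spec(0, 0, 0, 0, 0),
                           error_spec = rb_residual_spec(0, 0.5, 0, 0.25, 0),
                           nonadherence_frac = 0, seed = 31,
                           n_per_cohort = c(u1 = 2, c1_3 = 3, c3_15 = 3))
  init <- published_model()
  init$pop_spec <- rb_population_spec(0, 0, 0, 0, 0)
  init$error_spec <- rb_residual_spec(0, 0.5, 0, 0.25, 0)
  init$params$cl_cyp_ref <- 18; init$params$cl_conv_ref <- 12
  init$params$cl_met_ref <- 140; init$effects$lpvr_f_fold <- 1.8
  fit <- fit_model(ds, init = init)
  expect_lt(abs(fit$params$cl_cyp_ref / 13.6 - 1), 0.01)
  expect_lt(abs(fit$params$cl_conv_ref / 16.2 - 1), 0.01)
  expect_lt(abs(fit$params$cl_met_ref / 106 - 1), 0.01)
  expect_lt(abs(fit$effects$lpvr_f_fold / 2.58 - 1), 0.01)
  expect_lt(abs(fit$effects$lpvr_clmet_frac / 0.234 - 1), 0.01)
  # the optimizer never accepts a worse objective than it reports
  tr <- fit$trace$parent
  expect_equal(min(tr), fit$stage_results$parent$ofv, tolerance = 1e-6)
  expect_lte(fit$stage_results$parent$ofv, tr[1])
})

test_that("the Laplace objective matches adaptive quadrature on one random effect", {
  p0 <- rb_population_spec(25, 0, 0, 0, 0)
  e0 <- rb_residual_spec(0.15, 5, 0.1, 5, 0)
  ds <- make_study_dataset(n_per_cohort = c(u1 = 0, c1_3 = 1, c3_15 = 0),
                           pop_spec = p0, error_spec = e0,
                           nonadherence_frac = 0, seed = 11)
  ds <- detect_and_reset(preprocess_blq(ds))
  model <- published_model(); model$pop_spec <- p0; model$error_spec <- e0
  h <- function(e) neg2ll_individual(ds, 1, model, eta = list(cl = e))
  mode <- stats::optimize(h, c(-1.5, 1.5), tol = 1e-10)
  quad <- stats::integrate(function(es)
    vapply(es, function(e) exp(-0.5 * (h(e) - mode$objective)), 1),
    -2, 2, rel.tol = 1e-10)
  exact <- mode$objective - 2 * log(quad$value)

  comp <- rifabutinpk:::.compile_subjects(ds)
  lay <- rifabutinpk:::.eta_layout(comp[[1]], rifabutinpk:::.model_om2(p0), TRUE)
  ctx <- rifabutinpk:::.make_ctx(comp[[1]], model, TRUE, 805 / 847.02)
  lap <- rifabutinpk:::.subject_marginal(comp[[1]], lay, ctx, 0, "fd")$contrib
  expect_lt(abs(lap - exact), 0.1)
  # the Gauss-Newton curvature is a close (but not exact) surrogate
  gn <- rifabutinpk:::.subject_marginal(comp[[1]], lay, ctx, 0, "gn")$contrib
  expect_lt(abs(gn - exact), 0.5)
})

test_that("model comparison applies the chi-squared calibration", {
  mkfit <- function(ofv, n_par) structure(list(ofv = ofv, n_par = n_par,
                                               data_hash = c(n = 10, sum_dv = 1, n_id = 2)),
                                          class = "rb_fit")
  cmp <- compare_models(mkfit(103.84, 5), mkfit(100, 6))
  expect_equal(cmp$delta_ofv, 3.84)
  expect_equal(cmp$df, 1)
  expect_equal(cmp$p_value, 0.05, tolerance = 1e-3)
  expect_equal(compare_models(mkfit(106.63, 5), mkfit(100, 6))$p_value, 0.01,
               tolerance = 0.01)
  same <- compare_models(mkfit(100, 5), mkfit(100, 5), df = 1)
  expect_equal(same$delta_ofv, 0)
  expect_equal(same$p_value, 1)
  expect_equal(cmp$delta_aic, 100 + 12 - (103.84 + 10))
  bad <- mkfit(90, 5); bad$data_hash <- c(n = 11, sum_dv = 1, n_id = 2)
  expect_error(compare_models(bad, mkfit(100, 6)), "same dataset")
})

test_that("stepwise search keeps real effects and drops null candidates", {
  # fast deterministic setting: no random effects, small additive noise
  ds <- make_study_dataset(pop_spec = rb_population_spec(0, 0, 0, 0, 0),
                           error_spec = rb_residual_spec(0, 2, 0, 1, 0),
                           effects = rb_covariate_effects(zwfa_f_per_unit = 0,
                                                          age_ka_frac = 1),
                           nonadherence_frac = 0, seed = 52,
                           n_per_cohort = c(u1 = 1, c1_3 = 3, c3_15 = 2))
  init <- published_model()
  init$pop_spec <- rb_population_spec(0, 0, 0, 0, 0)
  init$error_spec <- rb_residual_spec(0, 2, 0, 1, 0)
  cfg <- rb_model_config(outer_iter = 40)
  # truth carries the LPV/r bioavailability effect but no underweight
  # effect; base model keeps the fixed CYP inhibition
  sw <- stepwise_covariates(ds, candidates = c("lpvr_f", "zwfa_f"),
                            base_active = c("lpvr_cyp"), config = cfg,
                            init = init, stages = "parent")
  expect_true("lpvr_f" %in% sw$selected)
  expect_false("zwfa_f" %in% sw$selected)
  expect_true(all(c("phase", "candidate", "p_value", "decision") %in%
                    names(sw$trace)))
  # a single candidate reduces to one likelihood-ratio test
  sw1 <- stepwise_covariates(ds, candidates = "lpvr_f",
                             base_active = c("lpvr_cyp"), config = cfg,
                             init = init, stages = "parent")
  expect_equal(sum(sw1$trace$phase == "forward"), 1)
  expect_equal(sw1$selected, "lpvr_f")
})

test_that("empirical Bayes estimates vanish without data or variability", {
  ds <- make_study_dataset(seed = 61, n_per_cohort = c(u1 = 1, c1_3 = 1, c3_15 = 1))
  model0 <- published_model()
  model0$pop_spec <- rb_population_spec(0, 0, 0, 0, 0)
  eb0 <- empirical_bayes(ds, model0)
  expect_null(eb0$ebe)  # no random effects: all etas identically zero

  # an occasion with a dose but no observations gets a zero eta and
  # (pooled) shrinkage toward 100%
  ds2 <- ds[!(ds$ID == 1 & ds$OCC == 2 & ds$EVID == 0), ]
  class(ds2) <- c("pk_dataset", "data.frame")
  eb <- empirical_bayes(ds2, published_model())
  e_f <- eb$ebe[eb$ebe$ID == 1 & eb$ebe$OCC == 2 & eb$ebe$effect == "f", "eta"]
  expect_lt(abs(e_f), 1e-4)
  expect_true(all(c("cl", "cl_met", "f", "ka", "tlag") %in% names(eb$shrinkage)))
})
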