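# Stochastic layer: variability conversion, random-effect draws,
# residual error, BLQ censoring.

test_that("%CV / log-variance conversion matches the reporting convention and inverts", {
  expect_equal(cv_to_omega2(0), 0)
  expect_equal(cv_to_omega2(71.9), log(1 + 0.719^2))
  cvs <- c(0.3, 20.7, 71.9, 118, 300)
  expect_equal(omega2_to_cv(cv_to_omega2(cvs)), cvs, tolerance = 1e-12)
  expect_error(cv_to_omega2(-1), "non-negative")
})

test_that("zero variability reproduces the typical parameters exactly", {
  p <- apply_allometry(rb_structural_params(), 15)
  d <- draw_individual(p, rb_population_spec(0, 0, 0, 0, 0), n = 3,
                       n_occasions = 2, seed = 1)
  for (k in 1:2) for (f in names(p))
    expect_equal(rep_len(d$occasions[[k]][[f]], 3), rep_len(p[[f]], 3))
  expect_true(all(unlist(d$eta) == 0))
})

test_that("the clearance pathways share one between-subject random effect", {
  p <- apply_allometry(rb_structural_params(), 10)
  d <- draw_individual(p, rb_population_spec(), n = 500, n_occasions = 1, seed = 2)
  pc <- d$occasions[[1]]
  expect_equal(cor(log(pc$cl_cyp_ref), log(pc$cl_conv_ref)), 1)
  # metabolite clearance varies independently of the shared effect
  expect_lt(abs(cor(log(pc$cl_met_ref), log(pc$cl_cyp_ref))), 0.15)
})

test_that("realized parameters are lognormal with the specified geometric CV", {
  p <- apply_allometry(rb_structural_params(), 10)
  spec <- rb_population_spec()
  d <- draw_individual(p, spec, n = 1e5, n_occasions = 1, seed = 3)
  pc <- d$occasions[[1]]
  # lognormal median property
  expect_lt(abs(median(pc$cl_met_ref) / p$cl_met_ref - 1), 0.02)
  # distribution shape: log draws are normal with omega SD
  ks <- stats::ks.test(log(pc$cl_met_ref / p$cl_met_ref),
                       "pnorm", 0, sqrt(cv_to_omega2(spec$bsv_cl_met)))
  expect_gt(ks$p.value, 0.01)
  # occasion effects independent across occasions
  d2 <- draw_individual(p, spec, n = 2e4, n_occasions = 2, seed = 4)
  expect_lt(abs(cor(d2$eta$f.1, d2$eta$f.2)), 0.02)
})

test_that("residual error model: zero-noise identity, correlation, proportional limit", {
  pred_p <- rep(200, 1e5); pred_m <- rep(150, 1e5)
  clean <- simulate_dv(pred_p[1:5], pred_m[1:5], rb_residual_spec(0, 0, 0, 0, 0))
  expect_equal(clean$obs_parent, pred_p[1:5])
  expect_equal(clean$obs_metabolite, pred_m[1:5])

  spec <- rb_residual_spec()
  set.seed(5)
  obs <- simulate_dv(pred_p, pred_m, spec)
  zp <- (obs$obs_parent - pred_p) /
    sqrt((spec$prop_parent * pred_p)^2 + spec$add_parent^2)
  zm <- (obs$obs_metabolite - pred_m) /
    sqrt((spec$prop_met * pred_m)^2 + spec$add_met^2)
  expect_lt(abs(cor(zp, zm) - 0.282), 0.01)

  # far above the additive floor the CV tends to the proportional term
  big <- rep(1e5, 2e4)
  obs_big <- simulate_dv(big, big, spec, seed = 6)
  expect_lt(abs(sd(obs_big$obs_parent) / 1e5 / spec$prop_parent - 1), 0.05)
  expect_error(simulate_dv(-1, 1, spec), "non-negative")
})

test_that("BLQ censoring uses a strict lower bound at the quantification limit", {
  expect_equal(censor_blq(c(3.90, 3.91, 0, 1000), "parent"), c(1L, 0L, 1L, 0L))
  expect_equal(censor_blq(c(0.779, 0.780), "metabolite"), c(1L, 0L))
  vals <- runif(200, 0, 10)
  expect_equal(sum(censor_blq(vals, "parent")), sum(vals < 3.91))
  expect_error(censor_blq(1, "parent", constants = list(lloq_parent = NULL)), "LLOQ")
})
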