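# Diagnostics: prediction correction, VPC mechanics, geometric mean
# ratios.

test_that("prediction correction is the documented normalization", {
  # constant PRED within a bin: identity
  obs <- c(10, 20, 30); pred <- c(5, 5, 5)
  expect_equal(prediction_correct(obs, pred, rep(1, 3)), obs)
  # obs = pred: corrected values collapse onto the bin median PRED
  pred2 <- c(2, 4, 8, 16)
  expect_equal(prediction_correct(pred2, pred2, rep(1, 4)),
               rep(median(pred2), 4))
  # two-dose-level toy set, correction computed by hand
  obs3 <- c(100, 110, 210, 190)
  pred3 <- c(100, 100, 200, 200)   # one bin; median PRED 150
  expect_equal(prediction_correct(obs3, pred3, rep(1, 4)),
               c(150, 165, 157.5, 142.5))
  # non-positive predictions are excluded with a warning
  expect_warning(out <- prediction_correct(c(1, 2), c(0, 2), c(1, 1)), "excluded")
  expect_true(is.na(out[1]))
})

test_that("VPC mechanics: degenerate replicate count and LPV/r stratification", {
  ds <- make_study_dataset(seed = 77, nonadherence_frac = 0,
                           n_per_cohort = c(u1 = 1, c1_3 = 2, c3_15 = 2))
  v1 <- vpc(ds, published_model(), n_replicates = 1, bins = 3, seed = 5)
  # with a single replicate the confidence bands collapse onto that
  # replicate's percentiles
  expect_equal(v1$lo10, v1$hi10)
  expect_equal(v1$lo50, v1$hi50)
  expect_true(all(v1$lo50 <= v1$hi90 + 1e-12))
  # stratification: separate panels per analyte and LPV/r status
  expect_setequal(unique(paste(v1$analyte, v1$lpvr)),
                  c("rifabutin 0", "rifabutin 1",
                    "des-rifabutin 0", "des-rifabutin 1"))
  # percentile ordering within every bin
  expect_true(all(v1$obs_p10 <= v1$obs_p50 & v1$obs_p50 <= v1$obs_p90))
})

test_that("geometric mean ratio matches its closed form and is scale invariant", {
  expect_equal(gmr(c(2, 3, 4), c(2, 3, 4))$gmr, 1)
  expect_equal(gmr(c(1, 2, 4), 2 * c(1, 2, 4))$gmr, 0.5)
  # hand-computed t-interval on the log scale
  a <- c(120, 250, 310, 95); b <- c(100, 180, 330, 70)
  d <- log(a / b)
  g <- gmr(a, b)
  expect_equal(g$gmr, exp(mean(d)))
  halfw <- qt(0.975, 3) * sd(d) / sqrt(4)
  expect_equal(g$lower, exp(mean(d) - halfw))
  expect_equal(g$upper, exp(mean(d) + halfw))
  # invariance under common rescaling of both groups
  g2 <- gmr(10 * a, 10 * b)
  expect_equal(g2$gmr, g$gmr)
  expect_equal(g2$lower, g$lower)
  expect_error(gmr(c(1, -1), c(1, 1)), "positive")
  expect_error(gmr(1:3, 1:2), "equal length")
})

test_that("model-derived exposure summaries support within-subject GMR comparisons", {
  ds <- make_study_dataset(seed = 19, nonadherence_frac = 0,
                           n_per_cohort = c(u1 = 1, c1_3 = 2, c3_15 = 1))
  model <- published_model()
  eb <- empirical_bayes(ds, model)
  fit_like <- c(model, list(ebe = eb$ebe, shrinkage = eb$shrinkage))
  ex <- exposure_summary(ds, fit_like)
  expect_true(all(c("auc_parent", "cmax_parent", "auc_metabolite") %in% names(ex)))
  expect_true(all(ex$auc_parent > 0))
  # within-subject comparison: occasions with vs without LPV/r
  young <- ex[ex$ID %in% unique(ds$ID[ds$AGE < 3]), ]
  on <- aggregate(auc_metabolite ~ ID, young[young$lpvr == 1, ], mean)
  off <- aggregate(auc_metabolite ~ ID, young[young$lpvr == 0, ], mean)
  m <- merge(on, off, by = "ID")
  g <- gmr(m$auc_metabolite.x, m$auc_metabolite.y)
  expect_gt(g$gmr, 1)  # LPV/r raises metabolite exposure
})
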