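# Virtual populations, study-replicate datasets, dataset IO.

test_that("virtual population has the configured per-kg structure", {
  pop <- make_virtual_population(10, c(6, 10), seed = 1)
  expect_equal(nrow(pop), 40)
  expect_true(all(pop$weight >= 6 & pop$weight < 10))
  expect_equal(as.vector(table(pop$kg_bin)), rep(10, 4))
  # the published in-silico population: 500 children per kg over 45 bins
  pop45 <- make_virtual_population(500, c(6, 51), seed = 2)
  expect_equal(nrow(pop45), 22500)
  # the study-scale configuration used here: 6-45 kg
  expect_equal(nrow(make_virtual_population(500, c(6, 45), seed = 3)), 19500)
  # severe underweight stays rare under the default z-score distribution
  expect_lt(mean(pop45$zwfa < -3), 0.03)
  expect_true(all(pop45$zwfa >= -5 & pop45$zwfa <= 2))
  # determinism
  expect_identical(make_virtual_population(20, c(8, 12), seed = 9),
                   make_virtual_population(20, c(8, 12), seed = 9))
  expect_error(make_virtual_population(0, c(6, 10)), "positive")
  expect_error(make_virtual_population(10, c(6, 6.5)), "bin")
})

test_that("ages increase with weight and cover the pediatric range", {
  w <- c(4, 6, 10, 14.3, 20, 31, 45)
  a <- weight_to_age(w)
  expect_true(all(diff(a) > 0))
  expect_lt(a[2], 1)
  expect_equal(a[4], 3)
  expect_equal(a[7], 15)
})

test_that("study-replicate dataset mirrors the three-cohort design", {
  ds <- make_study_dataset(seed = 42)
  expect_s3_class(ds, "pk_dataset")
  expect_equal(length(unique(ds$ID)), 28)
  # plasma samples (both analytes quantified from each): about 460-490
  n_samples <- sum(ds$EVID == 0 & ds$CMT == 2)
  expect_true(n_samples >= 440 && n_samples <= 500)

  # youngest cohort: intensive visits with 6 samples per analyte at the
  # protocol times
  u1 <- ds[ds$ID == 1, ]
  first_visit <- u1[u1$OCC == 1 & u1$EVID == 0 & u1$CMT == 2, ]
  t0 <- u1$TIME[u1$OCC == 1 & u1$EVID == 1]
  expect_equal(first_visit$TIME - t0, c(0, 2, 4, 8, 12, 24))

  # week-2 visits of the two younger cohorts are before ART: no LPV/r;
  # all later visits carry LPV/r
  young <- ds[ds$AGE < 3, ]
  expect_true(all(young$LPVR[young$OCC == 1] == 0))
  expect_true(all(young$LPVR[young$OCC > 1] == 1))
  # the ART-experienced cohort is on LPV/r from the start
  old <- ds[ds$AGE > 3, ]
  expect_true(all(old$LPVR == 1))

  # cohort age bounds
  ages <- tapply(ds$AGE, ds$ID, function(x) x[1])
  expect_true(all(ages > 0.5 & ages < 15.5))
  # severely underweight children are common in this population
  zw <- tapply(ds$ZWFA, ds$ID, function(x) x[1])
  expect_gt(mean(zw < -3), 0.4)
  # doses follow the mg/kg rules of the occasion
  doses <- ds[ds$EVID == 1, ]
  mgkg <- doses$AMT / doses$WT
  expect_true(all(abs(mgkg[doses$LPVR == 0] - 20) < 1e-9))
  expect_true(all(pmin(abs(mgkg[doses$LPVR == 1] - 2.5),
                       abs(mgkg[doses$LPVR == 1] - 5)) < 1e-9))
  expect_error(make_study_dataset(n_per_cohort = c(bogus = 3), seed = 1),
               "unknown cohort")
})

test_that("a zero-variability dataset equals the deterministic model predictions", {
  ds0 <- noise_free_dataset(seed = 7)
  obs <- ds0[ds0$EVID == 0, ]
  expect_equal(obs$DV, attr(ds0, "truth_pred")$PRED_TRUE)
})

test_that("the validation cohort uses the thrice-weekly explicit-dose design", {
  ds <- make_study_dataset(n_per_cohort = c(u1 = 0, c1_3 = 0, c3_15 = 0,
                                            validation = 2),
                           include_validation = TRUE, seed = 3)
  expect_equal(length(unique(ds$ID)), 2)
  d1 <- ds[ds$ID == 1 & ds$EVID == 1, ]
  expect_equal(diff(d1$TIME), c(48, 48, 72, 48, 48))
  o1 <- ds[ds$ID == 1 & ds$EVID == 0 & ds$CMT == 2, ]
  expect_equal(o1$TIME - max(d1$TIME), c(0, 2, 4, 9, 24, 48))
})

test_that("dataset files round-trip losslessly with schema validation", {
  ds <- make_study_dataset(seed = 12)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(as.data.frame(back), as.data.frame(ds), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(is.integer(back$BLQ))
  # dose rows: positive amount, empty concentration field
  raw <- utils::read.csv(path, na.strings = "")
  expect_true(all(is.na(raw$DV[raw$EVID == 1])))
  expect_true(all(raw$AMT[raw$EVID == 1] > 0))
  # unknown columns preserved
  ds$EXTRA <- seq_len(nrow(ds))
  write_dataset(ds, path)
  expect_equal(read_dataset(path)$EXTRA, ds$EXTRA)
  # schema errors name the missing column
  bad <- ds[, setdiff(names(ds), "ZWFA")]
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_dataset(path), "ZWFA")
  expect_error(read_dataset("no/such/file.csv"), "no such file")
})
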