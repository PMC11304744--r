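# Virtual populations and study-replicate datasets. The generator
# emulates the three-cohort pediatric study design (doses, visit
# schedules, covariate distributions) and the in-silico simulation
# population, so that every downstream stage of the analysis can be
# exercised without the clinical data.

#' Median age at a given body weight (synthetic growth lookup)
#'
#' Piecewise-linear interpolation of an approximate median
#' weight-for-age relationship for children, used to assign an age to
#' each virtual child from its simulated weight. The table is a
#' synthetic approximation of growth-reference medians, adequate for
#' exposure simulations (age only gates the absorption-rate covariate
#' at the 3-year threshold); it is configurable wherever it is used.
#'
#' @param weight Body weight (kg).
#' @return Age in years.
#' @export
weight_to_age <- function(weight) {
  wt <- c(3.3, 6, 7.5, 9.6, 12.2, 14.3, 16.3, 18.3, 20.5, 22.9, 25.3, 28, 31, 35, 40, 45)
  age <- c(0, 0.4, 0.7, 1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 12, 13.5, 15)
  stats::approx(wt, age, xout = weight, rule = 2)$y
}

# draw from a truncated normal by inverse-CDF
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd); phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a virtual pediatric population
#'
#' Builds the in-silico simulation population: `n_per_kg` children per
#' 1-kg weight bin with weights uniform within each bin, ages assigned
#' from weight via a weight-for-age lookup, and weight-for-age z-scores
#' drawn from a truncated normal distribution. The default z-score
#' distribution (Normal(-1, 1) truncated to `[-5, 2]`) puts fewer than
#' 3% of children below the severe-underweight threshold of -3, so
#' band medians are essentially unaffected by the underweight
#' bioavailability effect.
#'
#' @param n_per_kg Children per 1-kg bin (500 for the study-scale
#'   simulations).
#' @param weight_range Two numbers `c(lo, hi)`: bins are
#'   `[lo, lo+1), ..., [hi-1, hi)`.
#' @param zwfa_mean,zwfa_sd,zwfa_range Parameters of the truncated
#'   normal z-score distribution.
#' @param age_fun Function mapping weight (kg) to age (years).
#' @param seed Optional integer seed.
#' @return A data.frame with `id`, `weight`, `age`, `zwfa`, `kg_bin`
#'   (lower edge of the 1-kg bin).
#' @examples
#' nrow(make_virtual_population(10, c(6, 10), seed = 1))  # 40
#' @export
make_virtual_population <- function(n_per_kg = 500, weight_range = c(6, 45),
                                    zwfa_mean = -1, zwfa_sd = 1,
                                    zwfa_range = c(-5, 2),
                                    age_fun = weight_to_age, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_per_kg <= 0) stop("n_per_kg must be positive")
  if (diff(weight_range) < 1) stop("weight_range must span at least one 1-kg bin")
  bins <- seq(weight_range[1], weight_range[2] - 1)
  n <- n_per_kg * length(bins)
  kg_bin <- rep(bins, each = n_per_kg)
  weight <- kg_bin + stats::runif(n)
  zwfa <- .rtruncnorm(n, zwfa_mean, zwfa_sd, zwfa_range[1], zwfa_range[2])
  data.frame(id = seq_len(n), weight = weight, age = age_fun(weight),
             zwfa = zwfa, kg_bin = kg_bin)
}

#' Study cohort designs
#'
#' Returns the description of the three age-cohort designs of the
#' clinical study (and the external-validation design), each a list
#' with the cohort sample size, dosing rules before and during
#' lopinavir/ritonavir (LPV/r) co-treatment, visit schedule, and
#' covariate distributions:
#' * `u1` (<1 year): 20 mg/kg/day rifabutin for 2 weeks (TB-only),
#'   then 5 mg/kg/day with LPV/r; intensive visits at weeks 2, 4 and 6
#'   with samples at 0, 2, 4, 8, 12 and 24 h post-dose (week 2 without
#'   LPV/r).
#' * `c1_3` (1-3 years): 15-20 mg/kg/day for 2 weeks (default 20),
#'   then 2.5 mg/kg/day with LPV/r; intensive visits at weeks 2 and 4,
#'   sparse visits at weeks 6 and 12 (pre-dose plus one sample at 3-5 h
#'   or 24-26 h).
#' * `c3_15` (3-15 years): 2.5 mg/kg/day with LPV/r from day 0;
#'   intensive visits at weeks 2, 4 and 8 (all with LPV/r).
#' * `validation`: 5 mg/kg thrice weekly with LPV/r, samples at 0, 2,
#'   4, 9, 24 and 48 h after the sixth dose (not included in the
#'   replicate study by default).
#'
#' @param tb_dose_c1_3 mg/kg/day during TB-only treatment for the
#'   1-3-year cohort (the protocol allowed 15-20; default 20).
#' @return Named list of cohort design lists.
#' @export
study_designs <- function(tb_dose_c1_3 = 20) {
  intensive <- c(0, 2, 4, 8, 12, 24)
  list(
    u1 = list(n = 3, label = "u1",
              dose_tb = 20, dose_lpvr = 5, art_start_week = 2,
              visits = data.frame(week = c(2, 4, 6), lpvr = c(0, 1, 1),
                                  type = "intensive"),
              times_intensive = intensive,
              weight = list(lo = 4.5, span = 2.0, shape1 = 1, shape2 = 6),
              age_months = c(8, 11),
              zwfa = list(mean = -4.8, sd = 0.7, lo = -5.15, hi = -3.20)),
    c1_3 = list(n = 10, label = "c1_3",
                dose_tb = tb_dose_c1_3, dose_lpvr = 2.5, art_start_week = 2,
                visits = data.frame(week = c(2, 4, 6, 12), lpvr = c(0, 1, 1, 1),
                                    type = c("intensive", "intensive",
                                             "sparse", "sparse")),
                times_intensive = intensive,
                times_sparse = list(c(0, 4), c(0, 25)),
                weight = list(lo = 5.6, span = 5.4, shape1 = 1.3, shape2 = 3),
                age_months = c(14, 28),
                zwfa = list(mean = -2.8, sd = 1.2, lo = -5.06, hi = -1.39)),
    c3_15 = list(n = 15, label = "c3_15",
                 dose_tb = NA, dose_lpvr = 2.5, art_start_week = 0,
                 visits = data.frame(week = c(2, 4, 8), lpvr = c(1, 1, 1),
                                     type = "intensive"),
                 times_intensive = intensive,
                 weight = list(lo = 20, span = 25, shape1 = 1.2, shape2 = 3),
                 age_months = c(123, 185),
                 zwfa = list(mean = -3.3, sd = 1.0, lo = -4.38, hi = -1.32)),
    validation = list(n = 6, label = "validation",
                      dose_lpvr = 5, thrice_weekly = TRUE,
                      times_after_6th = c(0, 2, 4, 9, 24, 48),
                      weight = list(lo = 8.5, span = 3.7, shape1 = 2, shape2 = 2),
                      age_months = c(10, 41),
                      zwfa = list(mean = -1.0, sd = 1.0, lo = -1.85, hi = 0.951))
  )
}

# sample cohort covariates for n subjects
.draw_cohort_covariates <- function(design, n) {
  w <- design$weight
  weight <- w$lo + w$span * stats::rbeta(n, w$shape1, w$shape2)
  age <- stats::runif(n, design$age_months[1], design$age_months[2]) / 12
  z <- design$zwfa
  zwfa <- .rtruncnorm(n, z$mean, z$sd, z$lo, z$hi)
  data.frame(weight = weight, age = age, zwfa = zwfa)
}

#' Simulate a study-replicate pharmacokinetic dataset
#'
#' Generates a full longitudinal dataset with the structure the
#' analysis assumes: per-cohort covariates, dose records, timed
#' rifabutin and des-rifabutin concentrations with between-subject /
#' between-occasion variability, correlated residual error and BLQ
#' flags. Each sampling visit is one occasion; visit-day profiles are
#' simulated at steady state under the occasion's regimen (dose records
#' carry `SS = 1`, `II = 24`). An optional nonadherence injector makes
#' a fraction of intensive profiles miss their last few pre-visit
#' doses, which produces the low pre-dose concentrations the
#' dose-history reset rule (see [detect_and_reset()]) is designed to
#' catch.
#'
#' @param designs Cohort designs from [study_designs()]; the
#'   `validation` design is only used when `include_validation = TRUE`.
#' @param params,effects,pop_spec,error_spec Simulation truth.
#' @param n_per_cohort Optional named integer vector overriding the
#'   design sample sizes.
#' @param nonadherence_frac Fraction of intensive occasions with missed
#'   pre-visit doses (default 0.15, matching the observed prevalence of
#'   implausibly low troughs in this population).
#' @param missed_doses_range Inclusive integer range from which the
#'   number of missed daily doses is drawn for a nonadherent occasion.
#' @param include_validation Include the thrice-weekly validation
#'   cohort (simulated via an explicit dose list, not fitted by
#'   default).
#' @param seed Integer seed (required: the generator is a stochastic
#'   entry point).
#' @param constants See [rb_constants()].
#' @return A `PKDataset` data.frame with NONMEM-convention columns
#'   `ID, TIME, EVID, AMT, CMT, DV, MDV, BLQ, OCC, WT, AGE, ZWFA,
#'   LPVR, SS, II` (CMT 1 = depot dose, 2 = rifabutin observation,
#'   3 = des-rifabutin observation; TIME in hours; AMT in mg; DV in
#'   ug/L). The truth used per row is attached as attributes
#'   `truth_pred` (noise-free predictions) and `truth_eta`.
#' @export
make_study_dataset <- function(designs = study_designs(),
                               params = rb_structural_params(),
                               effects = rb_covariate_effects(),
                               pop_spec = rb_population_spec(),
                               error_spec = rb_residual_spec(),
                               n_per_cohort = NULL,
                               nonadherence_frac = 0.15,
                               missed_doses_range = c(2, 4),
                               include_validation = FALSE,
                               seed = NULL,
                               constants = rb_constants()) {
  if (!is.null(seed)) set.seed(seed)
  cohorts <- setdiff(names(designs), if (include_validation) character(0) else "validation")
  unknown <- setdiff(names(n_per_cohort), names(designs))
  if (length(unknown) > 0) stop("unknown cohort label: ", paste(unknown, collapse = ", "))

  om <- sqrt(cv_to_omega2(c(cl = pop_spec$bsv_cl_shared, cl_met = pop_spec$bsv_cl_met,
                            f = pop_spec$bov_f, ka = pop_spec$bov_ka,
                            tlag = pop_spec$bov_tlag)))
  rows <- list(); preds <- list(); etas <- list()
  id <- 0
  for (ch in cohorts) {
    d <- designs[[ch]]
    n <- if (!is.null(n_per_cohort[[ch]])) n_per_cohort[[ch]] else d$n
    if (n == 0) next
    cov <- .draw_cohort_covariates(d, n)
    for (i in seq_len(n)) {
      id <- id + 1
      wt <- cov$weight[i]; age <- cov$age[i]; zw <- cov$zwfa[i]
      eta_cl <- stats::rnorm(1, 0, om["cl"])
      eta_clm <- stats::rnorm(1, 0, om["cl_met"])
      p_allo <- apply_allometry(params, wt, effects)
      if (isTRUE(d$thrice_weekly)) {
        subj <- .simulate_validation_subject(id, d, p_allo, effects, om,
                                             eta_cl, eta_clm, wt, age, zw,
                                             error_spec, constants)
        rows[[length(rows) + 1]] <- subj$rows
        preds[[length(preds) + 1]] <- subj$pred
        etas[[length(etas) + 1]] <- subj$eta
        next
      }
      sparse_alt <- 0
      for (v in seq_len(nrow(d$visits))) {
        lpvr <- d$visits$lpvr[v]
        week <- d$visits$week[v]
        vtype <- d$visits$type[v]
        dose_mgkg <- if (lpvr > 0) d$dose_lpvr else d$dose_tb
        dose_mg <- dose_mgkg * wt
        t0 <- week * 168
        if (vtype == "intensive") {
          tobs <- d$times_intensive
        } else {
          sparse_alt <- sparse_alt + 1
          tobs <- d$times_sparse[[1 + (sparse_alt + i) %% 2]]
        }
        e_f <- stats::rnorm(1, 0, om["f"])
        e_ka <- stats::rnorm(1, 0, om["ka"])
        e_tl <- stats::rnorm(1, 0, om["tlag"])
        p_ind <- apply_etas(apply_covariates(p_allo, effects,
                                             list(lpvr = lpvr, zwfa = zw, age = age)),
                            list(cl = eta_cl, cl_met = eta_clm,
                                 f = e_f, ka = e_ka, tlag = e_tl))
        nonadh <- vtype == "intensive" &&
          stats::runif(1) < nonadherence_frac
        m <- if (nonadh) sample(seq(missed_doses_range[1], missed_doses_range[2]), 1) else 0
        pr <- .occ_predict(p_ind, dose_mg, tobs, tau = 24,
                           mode = if (nonadh) "missed" else "ss",
                           m = m, constants = constants)
        obs <- simulate_dv(pr$cp, pr$cm, error_spec)
        occ_rows <- rbind(
          data.frame(ID = id, TIME = t0, EVID = 1, AMT = dose_mg, CMT = 1,
                     DV = NA_real_, MDV = 1, BLQ = 0L, OCC = v, WT = wt,
                     AGE = age, ZWFA = zw, LPVR = lpvr, SS = 1, II = 24),
          data.frame(ID = id, TIME = t0 + rep(tobs, 2), EVID = 0, AMT = NA_real_,
                     CMT = rep(c(2, 3), each = length(tobs)),
                     DV = c(obs$obs_parent, obs$obs_metabolite), MDV = 0,
                     BLQ = c(censor_blq(obs$obs_parent, "parent", constants),
                             censor_blq(obs$obs_metabolite, "metabolite", constants)),
                     OCC = v, WT = wt, AGE = age, ZWFA = zw, LPVR = lpvr,
                     SS = 0, II = 0))
        rows[[length(rows) + 1]] <- occ_rows
        preds[[length(preds) + 1]] <-
          data.frame(ID = id, OCC = v, TIME = t0 + rep(tobs, 2),
                     CMT = rep(c(2, 3), each = length(tobs)),
                     PRED_TRUE = c(pr$cp, pr$cm), MISSED = m)
        etas[[length(etas) + 1]] <-
          data.frame(ID = id, OCC = v, cl = eta_cl, cl_met = eta_clm,
                     f = e_f, ka = e_ka, tlag = e_tl)
      }
    }
  }
  ds <- do.call(rbind, rows)
  ds <- ds[order(ds$ID, ds$TIME, ds$EVID, ds$CMT), ]
  rownames(ds) <- NULL
  # truth attributes sorted like the observation rows (ID, TIME, CMT)
  tp <- do.call(rbind, preds)
  tp <- tp[order(tp$ID, tp$TIME, tp$CMT), ]
  rownames(tp) <- NULL
  attr(ds, "truth_pred") <- tp
  attr(ds, "truth_eta") <- do.call(rbind, etas)
  class(ds) <- c("pk_dataset", "data.frame")
  ds
}

# thrice-weekly validation design: explicit 6-dose history
# (intervals 48, 48, 72 h), samples after the 6th dose
.simulate_validation_subject <- function(id, d, p_allo, effects, om,
                                         eta_cl, eta_clm, wt, age, zw,
                                         error_spec, constants) {
  dose_mg <- d$dose_lpvr * wt
  e_f <- stats::rnorm(1, 0, om["f"])
  e_ka <- stats::rnorm(1, 0, om["ka"])
  e_tl <- stats::rnorm(1, 0, om["tlag"])
  p_ind <- apply_etas(apply_covariates(p_allo, effects,
                                       list(lpvr = 1, zwfa = zw, age = age)),
                      list(cl = eta_cl, cl_met = eta_clm,
                           f = e_f, ka = e_ka, tlag = e_tl))
  dose_times <- c(0, 48, 96, 168, 216, 264)  # Mon/Wed/Fri over two weeks
  tobs <- 264 + d$times_after_6th
  prof <- concentration_profile(p_ind,
                                data.frame(time = dose_times,
                                           amount = rep(dose_mg, 6)),
                                tobs, constants)
  obs <- simulate_dv(prof$conc_parent, prof$conc_metabolite, error_spec)
  nobs <- length(tobs)
  rows <- rbind(
    data.frame(ID = id, TIME = dose_times, EVID = 1, AMT = dose_mg, CMT = 1,
               DV = NA_real_, MDV = 1, BLQ = 0L, OCC = 1, WT = wt, AGE = age,
               ZWFA = zw, LPVR = 1, SS = 0, II = 0),
    data.frame(ID = id, TIME = rep(tobs, 2), EVID = 0, AMT = NA_real_,
               CMT = rep(c(2, 3), each = nobs),
               DV = c(obs$obs_parent, obs$obs_metabolite), MDV = 0,
               BLQ = c(censor_blq(obs$obs_parent, "parent", constants),
                       censor_blq(obs$obs_metabolite, "metabolite", constants)),
               OCC = 1, WT = wt, AGE = age, ZWFA = zw, LPVR = 1, SS = 0, II = 0))
  list(rows = rows,
       pred = data.frame(ID = id, OCC = 1, TIME = rep(tobs, 2),
                         CMT = rep(c(2, 3), each = nobs),
                         PRED_TRUE = c(prof$conc_parent, prof$conc_metabolite),
                         MISSED = 0),
       eta = data.frame(ID = id, OCC = 1, cl = eta_cl, cl_met = eta_clm,
                        f = e_f, ka = e_ka, tlag = e_tl))
}

.pk_dataset_columns <- c("ID", "TIME", "EVID", "AMT", "CMT", "DV", "MDV",
                         "BLQ", "OCC", "WT", "AGE", "ZWFA", "LPVR")

#' Read / write a PK dataset
#'
#' Comma-separated, header-row, NONMEM-style semantics: mandatory
#' columns `ID, TIME, EVID, AMT, CMT, DV, MDV, BLQ, OCC, WT, AGE,
#' ZWFA, LPVR`; dose rows (`EVID = 1`) have an empty `DV` field and a
#' positive `AMT`; `BLQ` is 0/1. Steady-state descriptors (`SS`, `II`)
#' and any further columns are preserved losslessly.
#'
#' @param path File path.
#' @param ds A PK dataset data.frame.
#' @return `read_dataset()` returns the dataset (classed
#'   `pk_dataset`); `write_dataset()` returns `path` invisibly.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ds <- utils::read.csv(path, na.strings = c("NA", "", "."))
  missing_cols <- setdiff(.pk_dataset_columns, names(ds))
  if (length(missing_cols) > 0)
    stop("dataset is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  ds$BLQ <- as.integer(ds$BLQ)
  if (any(ds$TIME < 0)) stop("negative TIME in dataset")
  if (any(ds$EVID == 0 & !ds$CMT %in% c(2, 3)))
    stop("observation rows must carry an analyte compartment (CMT 2 or 3)")
  nodose <- setdiff(unique(ds$ID), unique(ds$ID[ds$EVID == 1]))
  if (length(nodose) > 0)
    stop("subject(s) without any dose row: ", paste(nodose, collapse = ", "))
  class(ds) <- c("pk_dataset", "data.frame")
  ds
}

#' @rdname read_dataset
#' @export
write_dataset <- function(ds, path) {
  missing_cols <- setdiff(.pk_dataset_columns, names(ds))
  if (length(missing_cols) > 0)
    stop("dataset is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  utils::write.csv(as.data.frame(ds), path, row.names = FALSE, na = "")
  invisible(path)
}
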