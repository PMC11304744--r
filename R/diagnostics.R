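# Model diagnostics: prediction-corrected visual predictive check,
# model-derived exposure summaries, geometric-mean-ratio comparisons.

# population (eta = 0) and/or simulated predictions for every
# non-excluded observation row, in dataset order
.design_predict <- function(ds, model, simulate = FALSE,
                            constants = rb_constants()) {
  compiled <- .compile_subjects(ds, constants)
  om2 <- .model_om2(model$pop_spec)
  mw_ratio <- attr(compiled, "mw_ratio")
  out <- list()
  for (subj in compiled) {
    p_allo <- apply_allometry(model$params, subj$wt, model$effects)
    if (simulate) {
      e_cl <- stats::rnorm(1, 0, sqrt(om2[["cl"]]))
      e_clm <- stats::rnorm(1, 0, sqrt(om2[["cl_met"]]))
    }
    for (occ in subj$occs) {
      pc <- apply_covariates(p_allo, model$effects,
                             list(lpvr = occ$lpvr, zwfa = subj$zwfa, age = subj$age))
      if (simulate) {
        pc <- apply_etas(pc, list(cl = e_cl, cl_met = e_clm,
                                  f = stats::rnorm(1, 0, sqrt(om2[["f"]])),
                                  ka = stats::rnorm(1, 0, sqrt(om2[["ka"]])),
                                  tlag = stats::rnorm(1, 0, sqrt(om2[["tlag"]]))))
      }
      tm <- .profile_terms(pc, constants)
      if (occ$ss) {
        pr_p <- .occ_predict(pc, occ$dose_mg, occ$t2, occ$tau, "ss",
                             constants = constants, tm = tm)$cp
        pr_m <- .occ_predict(pc, occ$dose_mg, occ$t3, occ$tau, "ss",
                             constants = constants, tm = tm)$cm
      } else {
        doses <- data.frame(time = occ$dose_times - min(occ$dose_times),
                            amount = rep(occ$dose_mg, length(occ$dose_times)))
        shift <- -min(occ$dose_times)
        pr_p <- concentration_profile(pc, doses, occ$t2 + shift, constants)$conc_parent
        pr_m <- concentration_profile(pc, doses, occ$t3 + shift, constants)$conc_metabolite
      }
      out[[length(out) + 1]] <- data.frame(
        ID = subj$id, OCC = occ$occ, LPVR = occ$lpvr,
        TAD = c(occ$t2, occ$t3),
        CMT = c(rep(2, length(occ$t2)), rep(3, length(occ$t3))),
        DV = c(occ$y2, occ$y3), PRED = c(pr_p, pr_m))
    }
  }
  do.call(rbind, out)
}

#' Prediction-correct observed values
#'
#' Normalizes concentrations for dose and covariate differences within
#' a bin: the corrected value is
#' `obs * median(PRED in bin) / PRED(observation)`, where `PRED` is
#' the population (eta = 0) prediction. Rows with `PRED = 0` are
#' dropped with a warning.
#'
#' @param obs Observed (or simulated) concentrations.
#' @param pred Population predictions, same length.
#' @param bin Bin assignment (factor/integer), same length.
#' @return Numeric vector of prediction-corrected values (`NA` for
#'   dropped rows).
#' @export
prediction_correct <- function(obs, pred, bin) {
  stopifnot(length(obs) == length(pred), length(bin) == length(obs))
  out <- rep(NA_real_, length(obs))
  bad <- pred <= 0
  if (any(bad)) warning(sum(bad), " rows with non-positive PRED excluded")
  med <- stats::ave(ifelse(bad, NA, pred), bin,
                    FUN = function(x) stats::median(x, na.rm = TRUE))
  ok <- !bad & !is.na(med)
  out[ok] <- obs[ok] * med[ok] / pred[ok]
  out
}

#' Prediction-corrected visual predictive check
#'
#' Simulates `n_replicates` datasets under the model with the original
#' design (doses, times, covariates), prediction-corrects both the
#' observed and the simulated values, and summarizes the 10th, 50th
#' and 90th percentiles per time-after-dose bin together with the 95%
#' confidence bands of each percentile across replicates, stratified
#' by analyte and (optionally) by LPV/r co-treatment.
#'
#' @param ds A `pk_dataset`.
#' @param model Fitted model (`rb_fit` or list with `params`,
#'   `effects`, `pop_spec`, `error_spec`).
#' @param n_replicates Simulation replicates (>= 200 recommended; 1
#'   degenerately collapses the bands onto that replicate).
#' @param bins Number of quantile-based bins on time after dose.
#' @param stratify_lpvr Produce separate panels with/without LPV/r.
#' @param seed Integer seed.
#' @param constants See [rb_constants()].
#' @return An object of class `rb_vpc`: data.frame with one row per
#'   (analyte, stratum, bin): `t_mid`, `n`, observed percentiles
#'   `obs_p10/p50/p90`, and simulated bands `lo10/hi10/lo50/hi50/
#'   lo90/hi90`.
#' @export
vpc <- function(ds, model, n_replicates = 200, bins = 8,
                stratify_lpvr = TRUE, seed = NULL,
                constants = rb_constants()) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ds$ROLE)) ds <- preprocess_blq(ds, constants = constants)
  if (is.null(ds$RESET)) ds <- detect_and_reset(ds)
  base <- .design_predict(ds, model, simulate = FALSE, constants = constants)
  strat <- if (stratify_lpvr) interaction(base$CMT, base$LPVR) else factor(base$CMT)
  base$bin <- NA
  for (s in levels(strat)) {
    idx <- strat == s
    qs <- unique(stats::quantile(base$TAD[idx], probs = seq(0, 1, length.out = bins + 1)))
    base$bin[idx] <- paste(s, cut(base$TAD[idx], qs, include.lowest = TRUE))
  }
  base$pc_obs <- prediction_correct(base$DV, base$PRED, base$bin)

  qfun <- function(x) stats::quantile(x, c(0.1, 0.5, 0.9), na.rm = TRUE, names = FALSE)
  sim_q <- array(NA_real_, c(length(unique(base$bin)), 3, n_replicates),
                 dimnames = list(unique(base$bin), c("p10", "p50", "p90"), NULL))
  # same-sample rows keep their residual correlation in the replicates
  key <- paste(base$ID, base$OCC, base$TAD)
  i2 <- which(base$CMT == 2); i3 <- which(base$CMT == 3)
  mm <- match(key[i3], key[i2])
  p3 <- which(!is.na(mm)); p2 <- mm[p3]
  lone2 <- setdiff(seq_along(i2), p2); lone3 <- setdiff(seq_along(i3), p3)
  for (r in seq_len(n_replicates)) {
    simdv <- .design_predict(ds, model, simulate = TRUE, constants = constants)
    yv <- numeric(nrow(simdv))
    e <- simulate_dv(simdv$PRED[i2[p2]], simdv$PRED[i3[p3]], model$error_spec)
    yv[i2[p2]] <- e$obs_parent; yv[i3[p3]] <- e$obs_metabolite
    if (length(lone2) > 0)
      yv[i2[lone2]] <- simulate_dv(simdv$PRED[i2[lone2]],
                                   numeric(length(lone2)),
                                   model$error_spec)$obs_parent
    if (length(lone3) > 0)
      yv[i3[lone3]] <- simulate_dv(numeric(length(lone3)),
                                   simdv$PRED[i3[lone3]],
                                   model$error_spec)$obs_metabolite
    pc_sim <- prediction_correct(yv, base$PRED, base$bin)
    for (b in rownames(sim_q))
      sim_q[b, , r] <- qfun(pc_sim[base$bin == b])
  }
  rows <- list()
  for (b in rownames(sim_q)) {
    idx <- base$bin == b
    ob <- qfun(base$pc_obs[idx])
    bd <- apply(sim_q[b, , , drop = FALSE], 2, function(x)
      stats::quantile(x, c(0.025, 0.975), na.rm = TRUE, names = FALSE))
    rows[[b]] <- data.frame(
      analyte = ifelse(base$CMT[idx][1] == 2, "rifabutin", "des-rifabutin"),
      lpvr = base$LPVR[idx][1], bin = b,
      t_mid = stats::median(base$TAD[idx]), n = sum(idx),
      obs_p10 = ob[1], obs_p50 = ob[2], obs_p90 = ob[3],
      lo10 = bd[1, 1], hi10 = bd[2, 1],
      lo50 = bd[1, 2], hi50 = bd[2, 2],
      lo90 = bd[1, 3], hi90 = bd[2, 3])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("rb_vpc", "data.frame"), n_replicates = n_replicates)
}

#' Model-derived steady-state exposures per subject-occasion
#'
#' Computes `AUC(0-24h)` and `Cmax` for both analytes from the
#' individual post hoc (empirical Bayes) parameters of a fit, per
#' subject and occasion, with the occasion's dose and LPV/r status.
#'
#' @param ds A `pk_dataset`.
#' @param fit An `rb_fit` (its `ebe` table is used; see
#'   [empirical_bayes()]).
#' @param constants See [rb_constants()].
#' @return Data.frame: `ID`, `OCC`, `lpvr`, `dose_mg`, `auc_parent`,
#'   `auc_metabolite`, `cmax_parent`, `cmax_metabolite`.
#' @export
exposure_summary <- function(ds, fit, constants = rb_constants()) {
  if (is.null(ds$ROLE)) ds <- preprocess_blq(ds, constants = constants)
  if (is.null(ds$RESET)) ds <- detect_and_reset(ds)
  compiled <- .compile_subjects(ds, constants)
  ebe <- fit$ebe
  geta <- function(id, occ, eff) {
    v <- ebe$eta[ebe$ID == id & ebe$effect == eff &
                   (is.na(ebe$OCC) | ebe$OCC == occ)]
    if (length(v) == 0) 0 else v[1]
  }
  rows <- list()
  for (subj in compiled) {
    p_allo <- apply_allometry(fit$params, subj$wt, fit$effects)
    for (occ in subj$occs) {
      pc <- apply_covariates(p_allo, fit$effects,
                             list(lpvr = occ$lpvr, zwfa = subj$zwfa, age = subj$age))
      pi <- apply_etas(pc, list(cl = geta(subj$id, occ$occ, "cl"),
                                cl_met = geta(subj$id, occ$occ, "cl_met"),
                                f = geta(subj$id, occ$occ, "f"),
                                ka = geta(subj$id, occ$occ, "ka"),
                                tlag = geta(subj$id, occ$occ, "tlag")))
      ex <- steady_state_exposures(pi, occ$dose_mg, tau = 24, constants = constants)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(ID = subj$id, OCC = occ$occ, lpvr = occ$lpvr,
                   dose_mg = occ$dose_mg), ex)
    }
  }
  do.call(rbind, rows)
}

#' Geometric mean ratio of paired exposures
#'
#' `exp(mean(log(a) - log(b)))` with a t-based confidence interval on
#' the log scale; the standard within-subject exposure comparison
#' (e.g. each subject's occasion with LPV/r against the occasion
#' without).
#'
#' @param a,b Paired positive exposure vectors (ratio reported as
#'   `a / b`).
#' @param conf Confidence level (default 0.95).
#' @return List with `gmr`, `lower`, `upper`, `n`.
#' @examples
#' gmr(c(2, 4, 8), c(1, 2, 4))$gmr  # 2
#' @export
gmr <- function(a, b, conf = 0.95) {
  if (length(a) != length(b)) stop("paired vectors must have equal length")
  if (any(a <= 0) || any(b <= 0)) stop("exposures must be strictly positive")
  d <- log(a) - log(b)
  n <- length(d)
  m <- mean(d)
  if (n > 1) {
    se <- stats::sd(d) / sqrt(n)
    tq <- stats::qt(1 - (1 - conf) / 2, n - 1)
    ci <- c(m - tq * se, m + tq * se)
  } else ci <- c(NA_real_, NA_real_)
  list(gmr = exp(m), lower = exp(ci[1]), upper = exp(ci[2]), n = n)
}
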