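# Dataset preprocessing for estimation: likelihood roles for censored
# observations and the dose-history reset rule for implausibly low
# pre-dose concentrations.

#' Assign likelihood roles to below-quantification observations
#'
#' Applies the censoring rule of the analysis (a variant of Beal's M6
#' method) per analyte and per post-dose profile: the last BLQ sample
#' during absorption and the first BLQ sample during elimination are
#' imputed at half the lower limit of quantification with their
#' additive error inflated by LLOQ/2; all other BLQ samples in the
#' profile are excluded from the fit (but retained for diagnostics).
#' The absorption/elimination split is defined by the predicted time of
#' maximum concentration of the analyte's profile for that
#' subject-occasion (typical prediction at the subject's covariates).
#'
#' Adds columns `ROLE` (`"obs"`, `"imputed"`, `"excluded"`), `DV_FIT`
#' (value entering the likelihood) and `ADD_INFL` (additive-error
#' inflation, ug/L).
#'
#' @param ds A `pk_dataset` (see [make_study_dataset()] /
#'   [read_dataset()]).
#' @param params,effects Typical parameters used for the predicted-Tmax
#'   split.
#' @param constants See [rb_constants()]; supplies the LLOQs.
#' @return The dataset with likelihood-role columns added.
#' @export
preprocess_blq <- function(ds, params = rb_structural_params(),
                           effects = rb_covariate_effects(),
                           constants = rb_constants()) {
  if (any(ds$BLQ[ds$EVID == 0] == 1) &&
      (is.null(constants$lloq_parent) || is.null(constants$lloq_metabolite)))
    stop("BLQ rows present but LLOQ not configured")
  ds$ROLE <- ifelse(ds$EVID == 0, "obs", NA_character_)
  ds$DV_FIT <- ds$DV
  ds$ADD_INFL <- 0
  obs_idx <- which(ds$EVID == 0)
  key <- interaction(ds$ID[obs_idx], ds$OCC[obs_idx], ds$CMT[obs_idx], drop = TRUE)
  for (grp in split(obs_idx, key)) {
    if (!any(ds$BLQ[grp] == 1)) next
    cmt <- ds$CMT[grp[1]]
    analyte <- if (cmt == 2) "parent" else "metabolite"
    lloq <- constants[[paste0("lloq_", analyte)]]
    # visit dose row of this occasion (latest dose at/before first sample)
    sid <- ds$ID[grp[1]]; occ <- ds$OCC[grp[1]]
    drows <- which(ds$ID == sid & ds$OCC == occ & ds$EVID == 1)
    t0 <- if (length(drows) > 0) max(ds$TIME[drows]) else min(ds$TIME[grp])
    tmax <- .typical_tmax(ds, sid, occ, analyte, params, effects, constants)
    trel <- ds$TIME[grp] - t0
    o <- grp[order(trel)]
    trel <- sort(trel)
    blq <- ds$BLQ[o] == 1
    role <- rep("obs", length(o))
    pre <- which(blq & trel <= tmax)
    post <- which(blq & trel > tmax)
    keep <- integer(0)
    if (length(pre) > 0) keep <- c(keep, max(pre))    # last BLQ during absorption
    if (length(post) > 0) keep <- c(keep, min(post))  # first BLQ during elimination
    role[blq] <- "excluded"
    role[keep] <- "imputed"
    ds$ROLE[o] <- role
    ds$DV_FIT[o[keep]] <- lloq / 2
    ds$ADD_INFL[o[keep]] <- lloq / 2
  }
  ds
}

# typical (eta = 0) time of maximum concentration for a subject-occasion
.typical_tmax <- function(ds, sid, occ, analyte, params, effects, constants) {
  rows <- which(ds$ID == sid & ds$OCC == occ)
  drow <- rows[ds$EVID[rows] == 1]
  wt <- ds$WT[rows[1]]; age <- ds$AGE[rows[1]]
  zw <- ds$ZWFA[rows[1]]; lpvr <- ds$LPVR[rows[1]]
  p <- apply_covariates(apply_allometry(params, wt, effects), effects,
                        list(lpvr = lpvr, zwfa = zw, age = age))
  if (length(drow) == 0) return(2)  # no dose information: nominal early peak
  dose_mg <- ds$AMT[drow[length(drow)]]
  tau <- if (!is.null(ds$II) && length(drow) > 0 && isTRUE(ds$SS[drow[length(drow)]] > 0))
    ds$II[drow[length(drow)]] else 24
  grid <- seq(0, tau, by = 0.25)
  pr <- .occ_predict(p, dose_mg, grid, tau = tau, mode = "ss", constants = constants)
  y <- if (analyte == "parent") pr$cp else pr$cm
  grid[which.max(y)]
}

#' Flag profiles for dose-history reset (baseline initialization)
#'
#' Whenever a profile's pre-dose rifabutin concentration falls below
#' one-third of the concentration 24 h after the observed dose, the
#' prior dosing history is disregarded for that occasion and the
#' disposition compartments are initialized from the observed pre-dose
#' concentrations of both analytes (baseline method: central
#' compartments at `C * Vc`, peripheral compartments at the equilibrium
#' ratio `C * Vp`). Occasions lacking either the pre-dose or the 24-h
#' sample are never flagged.
#'
#' Adds columns `RESET` (0/1 per occasion) and, on flagged occasions,
#' `PREDOSE_P` / `PREDOSE_M` (ug/L).
#'
#' @param ds A `pk_dataset`.
#' @return The dataset with reset markers.
#' @examples
#' # pre-dose 10 ug/L vs 40 ug/L at 24 h: 10 < 40 / 3, so flagged
#' @export
detect_and_reset <- function(ds) {
  ds$RESET <- 0L
  ds$PREDOSE_P <- NA_real_
  ds$PREDOSE_M <- NA_real_
  for (key in split(seq_len(nrow(ds)), interaction(ds$ID, ds$OCC, drop = TRUE))) {
    drow <- key[ds$EVID[key] == 1]
    if (length(drow) == 0) next
    t0 <- max(ds$TIME[drow])
    obs <- key[ds$EVID[key] == 0]
    pre_p <- obs[ds$TIME[obs] == t0 & ds$CMT[obs] == 2]
    h24_p <- obs[ds$TIME[obs] == t0 + 24 & ds$CMT[obs] == 2]
    if (length(pre_p) == 0 || length(h24_p) == 0) next
    if (ds$DV[pre_p[1]] < ds$DV[h24_p[1]] / 3) {
      ds$RESET[key] <- 1L
      pre_m <- obs[ds$TIME[obs] == t0 & ds$CMT[obs] == 3]
      ds$PREDOSE_P[key] <- ds$DV[pre_p[1]]
      ds$PREDOSE_M[key] <- if (length(pre_m) > 0) ds$DV[pre_m[1]] else 0
    }
  }
  ds
}
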