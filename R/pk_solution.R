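# Closed-form solution of the linear five-compartment system
#   depot -(ka)-> parent central <-> parent peripheral
#   parent central -(cl_conv, molar)-> metabolite central <-> metabolite peripheral
#   parent central -(cl_cyp)-> out;  metabolite central -(cl_met)-> out
# Because the coupling is strictly feed-forward, every concentration is a
# sum of (at most five) exponentials whose rates are ka plus the two
# hybrid rate constants of each disposition block, with partial-fraction
# coefficients. All helpers below are vectorized over subjects.

# Separate near-coincident rates so the partial fractions stay finite.
# Coincidence is a measure-zero configuration; the nudge (1 part in 1e7)
# is far below any quantity of scientific interest.
.separate_rates <- function(rates) {
  n <- nrow(rates)
  for (pass in 1:3) {
    ord <- t(apply(rates, 1, sort))
    gap <- ord[, -1, drop = FALSE] - ord[, -ncol(ord), drop = FALSE]
    tooclose <- gap < 1e-7 * ord[, -1, drop = FALSE]
    if (!any(tooclose)) break
    bad <- which(rowSums(tooclose) > 0)
    for (i in bad) {
      r <- rates[i, ]
      o <- order(r)
      for (j in 2:length(r)) {
        k <- o[j]; kprev <- o[j - 1]
        if (r[k] - r[kprev] < 1e-7 * r[k]) r[k] <- r[kprev] * (1 + 2e-7)
      }
      rates[i, ] <- r
    }
  }
  rates
}

# Rate constants and unit-dose concentration coefficients.
# Returns, per subject (row): rates (ka, a1, a2, b1, b2) and coefficients
# such that, for one administered dose of `amt` ug rifabutin at time 0
# (lag already handled by the caller, u = time since absorption start):
#   Cp(u) = amt * sum_k cp[k] * exp(-rates[k] u)   [ug/L]
#   Cm(u) = amt * sum_k cm[k] * exp(-rates[k] u)   [ug/L, metabolite mass]
# Bioavailability f is folded into the coefficients.
.profile_terms <- function(p, constants = rb_constants()) {
  n <- max(lengths(unclass(p)))
  gv <- function(x) rep_len(x, n)
  cl_cyp <- gv(p$cl_cyp_ref); cl_conv <- gv(p$cl_conv_ref); cl_met <- gv(p$cl_met_ref)
  vc_p <- gv(p$vc_p_ref); vp_p <- gv(p$vp_p_ref); q_p <- gv(p$q_p_ref)
  vc_m <- gv(p$vc_m_ref); vp_m <- gv(p$vp_m_ref); q_m <- gv(p$q_m_ref)
  f <- gv(p$f_ref); ka <- gv(p$ka)

  ke <- (cl_cyp + cl_conv) / vc_p
  k12 <- q_p / vc_p; k21 <- q_p / vp_p
  s <- ke + k12 + k21
  disc <- sqrt(pmax(s^2 - 4 * ke * k21, 0))
  a1 <- (s + disc) / 2; a2 <- (s - disc) / 2

  kem <- cl_met / vc_m
  k34 <- q_m / vc_m; k43 <- q_m / vp_m
  sm <- kem + k34 + k43
  discm <- sqrt(pmax(sm^2 - 4 * kem * k43, 0))
  b1 <- (sm + discm) / 2; b2 <- (sm - discm) / 2

  rates <- .separate_rates(cbind(ka = ka, a1 = a1, a2 = a2, b1 = b1, b2 = b2))
  ka <- rates[, 1]; a1 <- rates[, 2]; a2 <- rates[, 3]
  b1 <- rates[, 4]; b2 <- rates[, 5]

  # parent central amount per ug dose: f*ka * sum R_q exp(-q u), q in {ka,a1,a2}
  R_ka <- (k21 - ka) / ((a1 - ka) * (a2 - ka))
  R_a1 <- (k21 - a1) / ((ka - a1) * (a2 - a1))
  R_a2 <- (k21 - a2) / ((ka - a2) * (a1 - a2))

  cp <- cbind(ka = R_ka, a1 = R_a1, a2 = R_a2, b1 = 0, b2 = 0) * (f * ka / vc_p)

  # metabolite: input rate kc * Ac_p(t), kc converts parent ug -> metabolite ug
  kc <- (constants$mw_metabolite / constants$mw_parent) * cl_conv / vc_p
  bq <- cbind(R_ka, R_a1, R_a2) * (kc * f * ka)   # amount-input coefficients
  qs <- cbind(ka, a1, a2)
  # transfer through metabolite block H(s) = (s + k43)/((s+b1)(s+b2))
  cm_q <- bq * (k43 - qs) / ((b1 - qs) * (b2 - qs))
  cm_b1 <- rowSums(bq * (k43 - b1) / ((qs - b1) * (b2 - b1)))
  cm_b2 <- rowSums(bq * (k43 - b2) / ((qs - b2) * (b1 - b2)))
  cm <- cbind(cm_q, b1 = cm_b1, b2 = cm_b2) / vc_m
  colnames(cm) <- colnames(cp)

  list(rates = rates, cp = cp, cm = cm, n = n,
       k43 = k43, b1 = b1, b2 = b2, kc = kc,
       ke = ke, k12 = k12, k21 = k21, kem = kem, k34 = k34,
       vc_p = vc_p, vp_p = vp_p, vc_m = vc_m, vp_m = vp_m,
       f = f, tlag = gv(p$tlag))
}

# Exponential terms for the unforced decay of an arbitrary initial state
# x0 = (ac_p, ap_p, ac_m, ap_m) in ug. Returns rates (a1, a2, b1, b2) and
# concentration coefficients; used by the pre-dose reset (baseline)
# initialization and the nonadherence machinery.
.transient_terms <- function(tm, x0) {
  ac_p <- x0[[1]]; ap_p <- x0[[2]]; ac_m <- x0[[3]]; ap_m <- x0[[4]]
  a1 <- tm$rates[, "a1"]; a2 <- tm$rates[, "a2"]
  b1 <- tm$rates[, "b1"]; b2 <- tm$rates[, "b2"]

  d0 <- -(tm$ke + tm$k12) * ac_p + tm$k21 * ap_p
  A1 <- (d0 + a2 * ac_p) / (a2 - a1)
  A2 <- ac_p - A1

  dm0 <- -(tm$kem + tm$k34) * ac_m + tm$k43 * ap_m
  M1 <- (dm0 + b2 * ac_m) / (b2 - b1)
  M2 <- ac_m - M1

  cp <- cbind(a1 = A1, a2 = A2, b1 = 0, b2 = 0) / tm$vc_p

  # metabolite driven by the decaying parent amount (rates a1, a2)
  bq <- cbind(A1, A2) * tm$kc
  qs <- cbind(a1, a2)
  cm_q <- bq * (tm$k43 - qs) / ((b1 - qs) * (b2 - qs))
  cm_b1 <- M1 + rowSums(bq * (tm$k43 - b1) / ((qs - b1) * (b2 - b1)))
  cm_b2 <- M2 + rowSums(bq * (tm$k43 - b2) / ((qs - b2) * (b1 - b2)))
  cm <- cbind(a1 = cm_q[, 1], a2 = cm_q[, 2], b1 = cm_b1, b2 = cm_b2) / tm$vc_m

  list(rates = cbind(a1 = a1, a2 = a2, b1 = b1, b2 = b2), cp = cp, cm = cm)
}

# Evaluate sum-of-exponential terms at a vector of times for ONE subject
# (row i of the terms), with optional steady-state folding.
.eval_terms_one <- function(rates, coef, u, tau = NULL) {
  out <- numeric(length(u))
  pos <- if (is.null(tau)) u >= 0 else rep(TRUE, length(u))
  if (!any(pos)) return(out)
  uu <- u[pos]
  if (!is.null(tau)) uu <- uu %% tau
  acc <- 0
  for (k in seq_along(rates)) {
    if (coef[k] == 0) next
    ek <- exp(-rates[k] * uu)
    if (!is.null(tau)) ek <- ek / (1 - exp(-rates[k] * tau))
    acc <- acc + coef[k] * ek
  }
  out[pos] <- acc
  out
}

# Steady-state sum evaluated at an UNWRAPPED time u >= 0 since the last
# dose of a regimen that then stops: S(u) = sum_k r(u + k*tau), k >= 0.
.eval_ss_unwrapped_one <- function(rates, coef, u, tau, tlag) {
  w <- u - tlag
  acc <- numeric(length(u))
  for (k in seq_along(rates)) {
    if (coef[k] == 0) next
    acc <- acc + coef[k] * exp(-rates[k] * w) / (1 - exp(-rates[k] * tau))
  }
  acc[w < 0] <- NA_real_  # not meaningful before the absorption start
  acc
}

# Occasion-level prediction used by the study-data generator and the
# estimation likelihood. One subject-occasion, scalar parameters.
#   mode "ss":      periodic steady state of a once-`tau` regimen
#   mode "missed":  steady state with the `m` most recent pre-visit doses
#                   not taken; the visit-day dose at t = 0 is taken
#   mode "reset":   dosing history replaced by a baseline state derived
#                   from the observed pre-dose concentrations (method B2);
#                   peripheral compartments at equilibrium with central
# `tobs` are hours after the visit-day (observed) dose.
.occ_predict <- function(p, dose_mg, tobs, tau = 24,
                         mode = c("ss", "missed", "reset"),
                         m = 0, predose = c(0, 0),
                         constants = rb_constants(), tm = NULL) {
  mode <- match.arg(mode)
  if (is.null(tm)) tm <- .profile_terms(p, constants)
  amt <- dose_mg * 1000
  r1 <- tm$rates[1, ]; cp1 <- tm$cp[1, ]; cm1 <- tm$cm[1, ]
  tl <- tm$tlag[1]
  if (mode == "ss") {
    u <- tobs - tl
    cp <- amt * .eval_terms_one(r1, cp1, u, tau)
    cm <- amt * .eval_terms_one(r1, cm1, u, tau)
  } else if (mode == "missed") {
    cp <- amt * .eval_terms_one(r1, cp1, tobs - tl) +
      amt * .eval_ss_unwrapped_one(r1, cp1, tobs + (m + 1) * tau, tau, tl)
    cm <- amt * .eval_terms_one(r1, cm1, tobs - tl) +
      amt * .eval_ss_unwrapped_one(r1, cm1, tobs + (m + 1) * tau, tau, tl)
  } else {
    x0 <- c(predose[1] * tm$vc_p[1], predose[1] * tm$vp_p[1],
            predose[2] * tm$vc_m[1], predose[2] * tm$vp_m[1])
    tt <- .transient_terms(tm, as.list(x0))
    cp <- amt * .eval_terms_one(r1, cp1, tobs - tl) +
      .eval_terms_one(tt$rates[1, ], tt$cp[1, ], tobs)
    cm <- amt * .eval_terms_one(r1, cm1, tobs - tl) +
      .eval_terms_one(tt$rates[1, ], tt$cm[1, ], tobs)
  }
  list(cp = cp, cm = cm)
}

#' Predict concentration-time profiles for a dose history
#'
#' Solves the linear depot / parent two-compartment / metabolite
#' two-compartment system in closed form (superposition of exponential
#' modes) for an arbitrary list of oral doses, and returns paired
#' rifabutin and des-rifabutin plasma concentrations. The absorption
#' lag shifts each dose's input; molar conversion of the transformation
#' flux is applied internally, so concentrations are in mass units
#' (ug/L) of the respective analyte.
#'
#' A dose row with `ss = 1` denotes a regimen at steady state: doses of
#' the same amount every `ii` hours up to and including `time`, and
#' continuing thereafter; predictions are the periodic steady-state
#' solution (geometric-series superposition).
#'
#' @param params An `rb_params` object with scalar fields
#'   (individualized for one subject).
#' @param doses A data.frame with columns `time` (h), `amount` (mg) and
#'   optionally `ss` (0/1) and `ii` (h, dosing interval for `ss = 1`
#'   rows). Times must be sorted non-decreasing and non-negative
#'   amounts are required.
#' @param times Numeric vector of prediction times (h), `>= 0`.
#' @param constants See [rb_constants()].
#' @param init_state Optional numeric length-4 vector of initial
#'   amounts (ug) in (parent central, parent peripheral, metabolite
#'   central, metabolite peripheral) at time 0, decayed forward in
#'   time; used for baseline-initialized (reset) profiles.
#' @return A data.frame with columns `time`, `conc_parent`,
#'   `conc_metabolite` (ug/L).
#' @examples
#' p <- apply_allometry(rb_structural_params(), 12)
#' concentration_profile(p, data.frame(time = 0, amount = 150), times = c(1, 6, 24))
#' @export
concentration_profile <- function(params, doses, times,
                                  constants = rb_constants(),
                                  init_state = NULL) {
  if (any(times < 0)) stop("prediction times must be non-negative")
  if (nrow(doses) > 0) {
    if (is.unsorted(doses$time)) stop("dose times must be sorted non-decreasing")
    if (any(doses$amount < 0) || any(doses$time < 0))
      stop("dose amounts and times must be non-negative")
  }
  tm <- .profile_terms(params, constants)
  if (tm$n != 1) stop("concentration_profile() expects scalar parameters")
  cp <- numeric(length(times)); cm <- numeric(length(times))
  if (nrow(doses) > 0) {
    ss <- if (is.null(doses$ss)) rep(0, nrow(doses)) else doses$ss
    ii <- if (is.null(doses$ii)) rep(NA_real_, nrow(doses)) else doses$ii
    for (j in seq_len(nrow(doses))) {
      amt_ug <- doses$amount[j] * 1000
      if (amt_ug == 0) next
      u <- times - doses$time[j] - tm$tlag[1]
      tau <- NULL
      if (ss[j] > 0) {
        if (!is.finite(ii[j]) || ii[j] <= 0) stop("ss dose rows need a positive ii")
        tau <- ii[j]
        u[times < doses$time[j]] <- NA  # ss rows predict from the dose time on
      }
      keep <- !is.na(u)
      if (!any(keep)) next
      cp[keep] <- cp[keep] + amt_ug *
        .eval_terms_one(tm$rates[1, ], tm$cp[1, ], u[keep], tau)
      cm[keep] <- cm[keep] + amt_ug *
        .eval_terms_one(tm$rates[1, ], tm$cm[1, ], u[keep], tau)
    }
  }
  if (!is.null(init_state)) {
    tt <- .transient_terms(tm, as.list(init_state))
    cp <- cp + .eval_terms_one(tt$rates[1, ], tt$cp[1, ], times)
    cm <- cm + .eval_terms_one(tt$rates[1, ], tt$cm[1, ], times)
  }
  data.frame(time = times, conc_parent = cp, conc_metabolite = cm)
}

#' Steady-state exposure metrics for once-daily dosing
#'
#' Computes the steady-state `AUC` over one dosing interval and the
#' within-interval maximum concentration (`Cmax`) for both analytes
#' under a repeated oral regimen, using the analytic periodic solution.
#' `AUC` is the exact sum-of-exponentials integral (identical to the
#' single-dose `AUC` to infinity); `Cmax` is the maximum over a 0.05-h
#' evaluation grid, the package's `Cmax` convention. Vectorized over
#' subjects: any field of `params` and `daily_dose` may be vectors.
#'
#' The analytic identities `auc_parent = f * dose / (cl_cyp + cl_conv)`
#' and `auc_metabolite = f * dose * (mw_m / mw_p) * cl_conv /
#' ((cl_cyp + cl_conv) * cl_met)` hold exactly (doses in ug).
#'
#' @param params An `rb_params` object (individualized; possibly
#'   vectorized over subjects).
#' @param daily_dose Dose per interval (mg).
#' @param tau Dosing interval (h), default 24.
#' @param dt `Cmax` grid spacing (h).
#' @param method `"analytic"` (geometric-series steady state, default)
#'   or `"simulate"` (explicit superposition of `n_days` doses, used to
#'   verify the analytic route).
#' @param n_days Number of simulated days for `method = "simulate"`.
#' @param constants See [rb_constants()].
#' @return A data.frame with one row per subject: `auc_parent`,
#'   `auc_metabolite` (ug.h/L), `cmax_parent`, `cmax_metabolite` (ug/L).
#' @export
steady_state_exposures <- function(params, daily_dose, tau = 24, dt = 0.05,
                                   method = c("analytic", "simulate"),
                                   n_days = 30, constants = rb_constants()) {
  method <- match.arg(method)
  if (any(tau <= 0)) stop("tau must be positive")
  tm <- .profile_terms(params, constants)
  n <- tm$n
  amt_ug <- rep_len(daily_dose, n) * 1000
  grid <- seq(0, tau - dt, by = dt)

  auc_p <- amt_ug * rowSums(tm$cp / tm$rates)
  auc_m <- amt_ug * rowSums(tm$cm / tm$rates)

  cmax_p <- numeric(n); cmax_m <- numeric(n)
  # Cmax at steady state does not depend on the lag (pure phase shift),
  # so the grid is evaluated in absorption time. Chunked to bound memory.
  chunks <- split(seq_len(n), ceiling(seq_len(n) / 2000))
  for (idx in chunks) {
    accp <- matrix(0, length(idx), length(grid))
    accm <- matrix(0, length(idx), length(grid))
    for (k in 1:5) {
      r <- tm$rates[idx, k]
      if (method == "analytic") {
        ek <- exp(-outer(r, grid)) / (1 - exp(-r * tau))
      } else {
        ek <- 0
        for (d in 0:(n_days - 1)) ek <- ek + exp(-outer(r, grid + d * tau))
      }
      accp <- accp + tm$cp[idx, k] * ek
      accm <- accm + tm$cm[idx, k] * ek
    }
    cmax_p[idx] <- apply(accp, 1, max)
    cmax_m[idx] <- apply(accm, 1, max)
  }
  data.frame(auc_parent = auc_p,
             auc_metabolite = auc_m,
             cmax_parent = cmax_p * amt_ug,
             cmax_metabolite = cmax_m * amt_ug)
}
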