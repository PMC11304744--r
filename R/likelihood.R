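# Marginal-likelihood machinery: per-subject joint -2*log-likelihood in
# the random effects, Laplace approximation of the marginal (with a
# Gauss-Newton "FOCE-I"-style Hessian or an exact finite-difference
# Hessian), and the population objective function.

# Lean scalar version of the exponential-mode decomposition (see
# .profile_terms); called once per occasion per inner-loop evaluation.
.terms_fast <- function(cl_cyp, cl_conv, cl_met, vc_p, vp_p, q_p,
                        vc_m, vp_m, q_m, f, ka, mw_ratio, want_met = TRUE) {
  ke <- (cl_cyp + cl_conv) / vc_p
  k12 <- q_p / vc_p; k21 <- q_p / vp_p
  s <- ke + k12 + k21
  disc <- sqrt(max(s * s - 4 * ke * k21, 0))
  a1 <- (s + disc) / 2; a2 <- (s - disc) / 2
  # separate near-coincident rates (measure-zero configurations)
  if (a1 - a2 < 1e-7 * a1) a1 <- a2 * (1 + 2e-7)
  if (abs(ka - a1) < 1e-7 * ka) ka <- ka * (1 + 3e-7)
  if (abs(ka - a2) < 1e-7 * ka) ka <- ka * (1 - 3e-7)

  R_ka <- (k21 - ka) / ((a1 - ka) * (a2 - ka))
  R_a1 <- (k21 - a1) / ((ka - a1) * (a2 - a1))
  R_a2 <- (k21 - a2) / ((ka - a2) * (a1 - a2))
  fka <- f * ka
  if (!want_met) {
    return(list(r = c(ka, a1, a2),
                cp = c(R_ka, R_a1, R_a2) * (fka / vc_p),
                k21 = k21, ke = ke, k12 = k12, vc_p = vc_p, vp_p = vp_p))
  }
  kem <- cl_met / vc_m
  k34 <- q_m / vc_m; k43 <- q_m / vp_m
  sm <- kem + k34 + k43
  discm <- sqrt(max(sm * sm - 4 * kem * k43, 0))
  b1 <- (sm + discm) / 2; b2 <- (sm - discm) / 2
  if (b1 - b2 < 1e-7 * b1) b1 <- b2 * (1 + 2e-7)
  qs <- c(ka, a1, a2)
  for (k in 1:3) {
    if (abs(qs[k] - b1) < 1e-7 * b1) qs[k] <- qs[k] * (1 + 5e-7)
    if (abs(qs[k] - b2) < 1e-7 * max(b2, 1e-12)) qs[k] <- qs[k] * (1 - 5e-7)
  }
  ka <- qs[1]; a1 <- qs[2]; a2 <- qs[3]
  kc <- mw_ratio * cl_conv / vc_p
  bq <- c(R_ka, R_a1, R_a2) * (kc * fka)
  cm_q <- bq * (k43 - qs) / ((b1 - qs) * (b2 - qs))
  cm_b1 <- sum(bq * (k43 - b1) / ((qs - b1) * (b2 - b1)))
  cm_b2 <- sum(bq * (k43 - b2) / ((qs - b2) * (b1 - b2)))
  list(r = c(ka, a1, a2, b1, b2),
       cp = c(R_ka, R_a1, R_a2, 0, 0) * (fka / vc_p),
       cm = c(cm_q, cm_b1, cm_b2) / vc_m,
       k21 = k21, ke = ke, k12 = k12, kem = kem, k34 = k34, k43 = k43,
       kc = kc, vc_p = vc_p, vp_p = vp_p, vc_m = vc_m, vp_m = vp_m)
}

# decay of an initial state (ac_p, ap_p, ac_m, ap_m), scalar fast path
.transient_fast <- function(tm, x0, want_met = TRUE) {
  a1 <- tm$r[2]; a2 <- tm$r[3]
  d0 <- -(tm$ke + tm$k12) * x0[1] + tm$k21 * x0[2]
  A1 <- (d0 + a2 * x0[1]) / (a2 - a1)
  A2 <- x0[1] - A1
  if (!want_met) return(list(r = c(a1, a2), cp = c(A1, A2) / tm$vc_p))
  b1 <- tm$r[4]; b2 <- tm$r[5]
  dm0 <- -(tm$kem + tm$k34) * x0[3] + tm$k43 * x0[4]
  M1 <- (dm0 + b2 * x0[3]) / (b2 - b1)
  M2 <- x0[3] - M1
  bq <- c(A1, A2) * tm$kc
  qs <- c(a1, a2)
  cm_q <- bq * (tm$k43 - qs) / ((b1 - qs) * (b2 - qs))
  cm_b1 <- M1 + sum(bq * (tm$k43 - b1) / ((qs - b1) * (b2 - b1)))
  cm_b2 <- M2 + sum(bq * (tm$k43 - b2) / ((qs - b2) * (b1 - b2)))
  list(r = c(a1, a2, b1, b2),
       cp = c(A1, A2, 0, 0) / tm$vc_p,
       cm = c(cm_q, cm_b1, cm_b2) / tm$vc_m)
}

.sumexp <- function(coef, r, w) as.vector(crossprod(coef, exp(-outer(r, w))))

# Compile a preprocessed dataset into per-subject structures for fast
# likelihood evaluation. Excluded BLQ rows are dropped here.
.compile_subjects <- function(ds, constants = rb_constants()) {
  if (is.null(ds$ROLE) || is.null(ds$RESET))
    stop("dataset must be preprocessed (preprocess_blq, detect_and_reset)")
  subjects <- list()
  for (sid in unique(ds$ID)) {
    rows <- ds[ds$ID == sid, ]
    occs <- list()
    for (occ in unique(rows$OCC)) {
      orows <- rows[rows$OCC == occ, ]
      drows <- orows[orows$EVID == 1, ]
      if (nrow(drows) == 0) next
      ss <- !is.null(drows$SS) && any(drows$SS > 0)
      t0 <- max(drows$TIME)
      obs <- orows[orows$EVID == 0 & orows$ROLE != "excluded", ]
      op <- obs[obs$CMT == 2, ]; om <- obs[obs$CMT == 3, ]
      t2 <- op$TIME - t0; t3 <- om$TIME - t0
      # same-sample pairing for the correlated (L2) residual model
      common <- intersect(t2, t3)
      ip <- match(common, t2); im <- match(common, t3)
      occs[[length(occs) + 1]] <- list(
        occ = occ, lpvr = orows$LPVR[1], ss = ss,
        dose_mg = drows$AMT[nrow(drows)],
        tau = if (ss) drows$II[nrow(drows)] else 24,
        dose_times = drows$TIME - t0,
        reset = orows$RESET[1] == 1,
        predose = c(orows$PREDOSE_P[1], orows$PREDOSE_M[1]),
        t2 = t2, y2 = op$DV_FIT, infl2 = op$ADD_INFL,
        t3 = t3, y3 = om$DV_FIT, infl3 = om$ADD_INFL,
        ip = ip, im = im,
        lone_p = setdiff(seq_along(t2), ip),
        lone_m = setdiff(seq_along(t3), im))
    }
    subjects[[length(subjects) + 1]] <-
      list(id = sid, wt = rows$WT[1], age = rows$AGE[1], zwfa = rows$ZWFA[1],
           occs = occs, xp = compile_subject_cpp(occs))
  }
  attr(subjects, "mw_ratio") <- constants$mw_metabolite / constants$mw_parent
  subjects
}

# eta layout: which random effects exist, given structurally nonzero
# omegas and the stage (parent-only fits carry no metabolite eta)
.eta_layout <- function(subj, om2, use_met) {
  use <- c(cl = om2[["cl"]] > 0,
           cl_met = use_met && om2[["cl_met"]] > 0,
           f = om2[["f"]] > 0, ka = om2[["ka"]] > 0, tlag = om2[["tlag"]] > 0)
  nocc <- length(subj$occs)
  idx <- 0
  icl <- if (use["cl"]) (idx <- idx + 1) else 0
  iclm <- if (use["cl_met"]) (idx <- idx + 1) else 0
  occm <- matrix(0L, 3, nocc)
  for (k in seq_len(nocc)) {
    if (use["f"]) occm[1, k] <- (idx <- idx + 1)
    if (use["ka"]) occm[2, k] <- (idx <- idx + 1)
    if (use["tlag"]) occm[3, k] <- (idx <- idx + 1)
  }
  om2vec <- numeric(idx)
  if (icl > 0) om2vec[icl] <- om2[["cl"]]
  if (iclm > 0) om2vec[iclm] <- om2[["cl_met"]]
  for (k in seq_len(nocc)) {
    if (occm[1, k] > 0) om2vec[occm[1, k]] <- om2[["f"]]
    if (occm[2, k] > 0) om2vec[occm[2, k]] <- om2[["ka"]]
    if (occm[3, k] > 0) om2vec[occm[3, k]] <- om2[["tlag"]]
  }
  list(d = idx, icl = icl, iclm = iclm, occ = occm, om2 = om2vec)
}

# Joint -2 log [p(y | eta) p(eta)] for one subject, plus (optionally)
# the stacked predictions (f) and residual variances (v) needed for the
# Gauss-Newton Hessian. `ctx` carries the occasion-level
# covariate-adjusted typical parameters and the residual-error model
# for the current theta. Dispatches to the compiled (C++) evaluator;
# the R implementation below is the documented reference and the two
# are compared in the tests.
.subject_h <- function(eta, subj, lay, ctx, want_pred = FALSE) {
  if (!is.null(subj$xp) && !isTRUE(ctx$use_r)) {
    res <- subject_h_cpp(subj$xp, eta, ctx$pocc, ctx$errv, lay$om2,
                         as.integer(lay$occ), lay$icl, lay$iclm,
                         ctx$use_met, ctx$mw_ratio, want_pred)
    if (!res$ok) return(if (want_pred) NULL else 1e10)
    if (!want_pred) return(res$h)
    return(res)
  }
  .subject_h_r(eta, subj, lay, ctx, want_pred)
}

.subject_h_r <- function(eta, subj, lay, ctx, want_pred = FALSE) {
  err <- ctx$err
  use_met <- ctx$use_met
  rho <- if (use_met) err$corr else 0
  h <- 0
  if (lay$d > 0) h <- sum(eta^2 / lay$om2) + sum(log(2 * pi * lay$om2))
  fstack <- vector("list", length(subj$occs))
  vstack <- vector("list", length(subj$occs))
  for (k in seq_along(subj$occs)) {
    occ <- subj$occs[[k]]
    pc <- ctx$p_occ[[k]]
    e_cl <- if (lay$icl > 0) exp(eta[lay$icl]) else 1
    e_clm <- if (lay$iclm > 0) exp(eta[lay$iclm]) else 1
    e_f <- if (lay$occ[1, k] > 0) exp(eta[lay$occ[1, k]]) else 1
    e_ka <- if (lay$occ[2, k] > 0) exp(eta[lay$occ[2, k]]) else 1
    e_tl <- if (lay$occ[3, k] > 0) exp(eta[lay$occ[3, k]]) else 1
    pv <- c(pc$cl_cyp * e_cl, pc$cl_conv * e_cl, pc$cl_met * e_clm,
            pc$vc_p, pc$vp_p, pc$q_p, pc$vc_m, pc$vp_m, pc$q_m,
            pc$f * e_f, pc$ka * e_ka, pc$tlag)
    if (any(!is.finite(pv)) || any(pv[4:11] <= 0) || pv[12] < 0 ||
        pv[1] < 0 || pv[2] <= 0 || pv[3] <= 0)
      return(if (want_pred) NULL else 1e10)
    tm <- .terms_fast(pv[1], pv[2], pv[3], pv[4], pv[5], pv[6], pv[7],
                      pv[8], pv[9], pv[10], pv[11], ctx$mw_ratio, use_met)
    tl <- pc$tlag * e_tl
    amt <- occ$dose_mg * 1000
    if (occ$reset) {
      x0 <- c(occ$predose[1] * tm$vc_p, occ$predose[1] * tm$vp_p,
              if (use_met) c(occ$predose[2] * tm$vc_m, occ$predose[2] * tm$vp_m)
              else c(0, 0))
      tt <- .transient_fast(tm, x0, use_met)
      w2 <- occ$t2 - tl
      fp <- amt * ifelse(w2 >= 0, .sumexp(tm$cp, tm$r, pmax(w2, 0)), 0) +
        .sumexp(tt$cp, tt$r, occ$t2)
      if (use_met) {
        w3 <- occ$t3 - tl
        fm <- amt * ifelse(w3 >= 0, .sumexp(tm$cm, tm$r, pmax(w3, 0)), 0) +
          .sumexp(tt$cm, tt$r, occ$t3)
      }
    } else if (occ$ss) {
      tau <- occ$tau
      gs <- 1 / (1 - exp(-tm$r * tau))
      fp <- amt * .sumexp(tm$cp * gs, tm$r, (occ$t2 - tl) %% tau)
      if (use_met) fm <- amt * .sumexp(tm$cm * gs, tm$r, (occ$t3 - tl) %% tau)
    } else {
      # explicit dose list (e.g. thrice-weekly regimens)
      fp <- numeric(length(occ$t2))
      fm <- numeric(length(occ$t3))
      for (td in occ$dose_times) {
        w2 <- occ$t2 - td - tl
        fp <- fp + amt * ifelse(w2 >= 0, .sumexp(tm$cp, tm$r, pmax(w2, 0)), 0)
        if (use_met) {
          w3 <- occ$t3 - td - tl
          fm <- fm + amt * ifelse(w3 >= 0, .sumexp(tm$cm, tm$r, pmax(w3, 0)), 0)
        }
      }
    }
    if (any(!is.finite(fp)) || (use_met && any(!is.finite(fm))))
      return(if (want_pred) NULL else 1e10)
    v2 <- (err$prop_parent * fp)^2 + (err$add_parent + occ$infl2)^2
    r2 <- occ$y2 - fp
    if (use_met) {
      v3 <- (err$prop_met * fm)^2 + (err$add_met + occ$infl3)^2
      r3 <- occ$y3 - fm
      if (length(occ$ip) > 0) {
        zp <- r2[occ$ip] / sqrt(v2[occ$ip]); zm <- r3[occ$im] / sqrt(v3[occ$im])
        h <- h + sum(log(2 * pi * v2[occ$ip]) + log(2 * pi * v3[occ$im]) +
                       log(1 - rho^2) +
                       (zp^2 - 2 * rho * zp * zm + zm^2) / (1 - rho^2))
      }
      if (length(occ$lone_p) > 0)
        h <- h + sum(log(2 * pi * v2[occ$lone_p]) + r2[occ$lone_p]^2 / v2[occ$lone_p])
      if (length(occ$lone_m) > 0)
        h <- h + sum(log(2 * pi * v3[occ$lone_m]) + r3[occ$lone_m]^2 / v3[occ$lone_m])
      if (want_pred) { fstack[[k]] <- c(fp, fm); vstack[[k]] <- c(v2, v3) }
    } else {
      h <- h + sum(log(2 * pi * v2) + r2^2 / v2)
      if (want_pred) { fstack[[k]] <- fp; vstack[[k]] <- v2 }
    }
  }
  if (want_pred) list(h = h, f = unlist(fstack), v = unlist(vstack)) else h
}

# Damped Newton minimization of the joint -2LL in eta, using an exact
# forward-difference gradient of h and a Gauss-Newton Hessian built
# from the prediction Jacobian (residual variances evaluated at the
# individual prediction: eta-epsilon interaction).
.inner_optimize <- function(subj, lay, ctx, start, tol = 1e-6, max_iter = 50,
                            cold = FALSE) {
  d <- lay$d
  eta <- start
  J_last <- NULL; stack_last <- NULL; J_at <- NULL
  # the joint -2LL can be multimodal in the absorption-rate and lag
  # effects (periodic steady-state wrap), so cold starts run a
  # conservative multi-start descent before Newton polishing
  if (cold && d > 0) {
    starts <- list(eta)
    for (shift in c(-0.7, 0.7)) {
      e_ka <- eta; e_tl <- eta
      for (k in seq_len(ncol(lay$occ))) {
        if (lay$occ[2, k] > 0) e_ka[lay$occ[2, k]] <- shift
        if (lay$occ[3, k] > 0) e_tl[lay$occ[3, k]] <- shift
      }
      starts <- c(starts, list(e_ka, e_tl))
    }
    best <- NULL
    for (st in starts) {
      nb <- stats::nlminb(st, function(e) .subject_h(e, subj, lay, ctx),
                          control = list(rel.tol = tol))
      if (is.finite(nb$objective) &&
          (is.null(best) || nb$objective < best$objective)) best <- nb
    }
    if (!is.null(best)) eta <- best$par
  }
  ev <- .subject_h(eta, subj, lay, ctx, want_pred = TRUE)
  if (is.null(ev)) { eta <- numeric(d); ev <- .subject_h(eta, subj, lay, ctx, TRUE) }
  if (is.null(ev)) return(NULL)
  hval <- ev$h
  converged <- FALSE
  step_fd <- 1e-5
  for (iter in seq_len(max_iter)) {
    # one FD sweep gives both the gradient of h and the Jacobian of f
    grad <- numeric(d)
    stack0 <- ev
    J <- matrix(0, length(stack0$f), d)
    ok <- TRUE
    for (j in seq_len(d)) {
      ej <- eta; ej[j] <- ej[j] + step_fd
      evj <- .subject_h(ej, subj, lay, ctx, want_pred = TRUE)
      if (is.null(evj)) { ok <- FALSE; break }
      grad[j] <- (evj$h - hval) / step_fd
      J[, j] <- (evj$f - stack0$f) / step_fd
    }
    if (!ok) break
    J_last <- J; stack_last <- stack0; J_at <- eta
    if (max(abs(grad)) < 1e-5) { converged <- TRUE; break }
    H2 <- .gn_half_hessian(J, stack0, ctx, lay)  # = H/2
    # damped (Levenberg-Marquardt) Newton step on h
    improved <- FALSE
    ridge <- 0
    for (esc in 1:5) {
      ch <- tryCatch(chol(H2 + diag(ridge, d)), error = function(e) NULL)
      if (!is.null(ch)) {
        dir <- -backsolve(ch, forwardsolve(t(ch), grad / 2))
        lam <- 1
        for (ls in 1:6) {
          cand <- eta + lam * dir
          evc <- .subject_h(cand, subj, lay, ctx, want_pred = TRUE)
          if (!is.null(evc) && is.finite(evc$h) && evc$h < hval - 1e-12) {
            ev <- evc; eta <- cand; hval <- evc$h; improved <- TRUE
            break
          }
          lam <- lam / 4
        }
      }
      if (improved) break
      ridge <- max(ridge * 10, 0.1 * mean(abs(diag(H2))))
    }
    if (!improved || (improved && abs(lam * max(abs(dir))) < tol)) break
  }
  # robustness: if the gradient has not vanished, refine with a
  # general-purpose quasi-Newton pass from the best point found
  if (!converged) {
    gchk <- numeric(d)
    for (j in seq_len(d)) {
      ej <- eta; ej[j] <- ej[j] + step_fd
      gchk[j] <- (.subject_h(ej, subj, lay, ctx) - hval) / step_fd
    }
    converged <- max(abs(gchk)) <= 0.05
  }
  if (!converged) {
    nb <- stats::nlminb(eta, function(e) .subject_h(e, subj, lay, ctx),
                        control = list(rel.tol = tol))
    if (is.finite(nb$objective) && nb$objective < hval) {
      eta <- nb$par; hval <- nb$objective
      ev <- .subject_h(eta, subj, lay, ctx, want_pred = TRUE)
    }
  }
  J_valid <- !is.null(J_at) && isTRUE(all.equal(J_at, eta, tolerance = 1e-4))
  list(eta = eta, h = hval, ev = ev,
       J = if (J_valid) J_last, stack = if (J_valid) stack_last)
}

# H/2 = J' V^-1 J + Omega^-1 with the paired 2x2 correlation blocks
.gn_half_hessian <- function(J, stack, ctx, lay) {
  U <- J / stack$v
  if (ctx$use_met && ctx$err$corr != 0) {
    rho <- ctx$err$corr
    off <- 0
    for (k in seq_along(ctx$np_occ)) {
      np <- ctx$np_occ[k]; nm <- ctx$nm_occ[k]
      ip <- ctx$ip_occ[[k]] + off
      im <- ctx$im_occ[[k]] + off + np
      if (length(ip) > 0) {
        vp <- stack$v[ip]; vm <- stack$v[im]
        a <- 1 / ((1 - rho^2) * vp)
        b <- -rho / ((1 - rho^2) * sqrt(vp * vm))
        cc <- 1 / ((1 - rho^2) * vm)
        U[ip, ] <- a * J[ip, , drop = FALSE] + b * J[im, , drop = FALSE]
        U[im, ] <- b * J[ip, , drop = FALSE] + cc * J[im, , drop = FALSE]
      }
      off <- off + np + nm
    }
  }
  crossprod(J, U) + diag(1 / lay$om2, lay$d)
}

# central-difference Hessian of h (exact Laplace variant)
.fd_hessian <- function(fn, x, step = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- fn(x)
  fp <- numeric(d); fmn <- numeric(d)
  for (i in seq_len(d)) {
    xi <- x; xi[i] <- xi[i] + step; fp[i] <- fn(xi)
    xi <- x; xi[i] <- xi[i] - step; fmn[i] <- fn(xi)
    H[i, i] <- (fp[i] - 2 * f0 + fmn[i]) / step^2
  }
  if (d > 1) {
    for (i in 1:(d - 1)) for (j in (i + 1):d) {
      xij <- x; xij[c(i, j)] <- xij[c(i, j)] + step
      fij <- fn(xij)
      H[i, j] <- H[j, i] <-
        (fij - fp[i] - fp[j] + f0) / step^2
    }
  }
  H
}

# Laplace-approximate -2 log marginal likelihood for one subject
.subject_marginal <- function(subj, lay, ctx, start, hessian = "gn",
                              inner_tol = 1e-6, cold = FALSE) {
  if (lay$d == 0) {
    h <- .subject_h(numeric(0), subj, lay, ctx)
    return(list(contrib = h, eta = numeric(0)))
  }
  opt <- .inner_optimize(subj, lay, ctx, start, tol = inner_tol, cold = cold)
  if (is.null(opt)) return(list(contrib = 1e10, eta = start))
  if (hessian == "fd") {
    H <- .fd_hessian(function(e) .subject_h(e, subj, lay, ctx), opt$eta)
    H2 <- H / 2
  } else if (!is.null(opt$J)) {
    H2 <- .gn_half_hessian(opt$J, opt$stack, ctx, lay)
  } else {
    stack0 <- opt$ev
    d <- lay$d
    J <- matrix(0, length(stack0$f), d)
    for (j in seq_len(d)) {
      ej <- opt$eta; ej[j] <- ej[j] + 1e-5
      evj <- .subject_h(ej, subj, lay, ctx, want_pred = TRUE)
      if (is.null(evj)) return(list(contrib = 1e10, eta = opt$eta))
      J[, j] <- (evj$f - stack0$f) / 1e-5
    }
    H2 <- .gn_half_hessian(J, stack0, ctx, lay)
  }
  ch <- tryCatch(chol(H2), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- tryCatch(chol(H2 + diag(1e-6 + abs(diag(H2)) * 1e-4, lay$d)),
                   error = function(e) NULL)
    if (is.null(ch)) return(list(contrib = 1e10, eta = opt$eta))
  }
  logdet_half <- 2 * sum(log(diag(ch)))
  list(contrib = opt$h - lay$d * log(2 * pi) + logdet_half, eta = opt$eta)
}

# context for one theta evaluation: covariate-adjusted typical
# parameters per subject-occasion plus cached pairing offsets
.make_ctx <- function(subj, model, use_met, mw_ratio) {
  p_allo <- apply_allometry(model$params, subj$wt, model$effects)
  p_occ <- vector("list", length(subj$occs))
  for (k in seq_along(subj$occs)) {
    occ <- subj$occs[[k]]
    pc <- apply_covariates(p_allo, model$effects,
                           list(lpvr = occ$lpvr, zwfa = subj$zwfa, age = subj$age))
    p_occ[[k]] <- list(cl_cyp = pc$cl_cyp_ref, cl_conv = pc$cl_conv_ref,
                       cl_met = pc$cl_met_ref, vc_p = pc$vc_p_ref,
                       vp_p = pc$vp_p_ref, q_p = pc$q_p_ref,
                       vc_m = pc$vc_m_ref, vp_m = pc$vp_m_ref,
                       q_m = pc$q_m_ref, f = pc$f_ref, ka = pc$ka,
                       tlag = pc$tlag)
  }
  err <- model$error_spec
  pocc <- vapply(p_occ, function(x) unlist(x, use.names = FALSE), numeric(12))
  if (is.null(dim(pocc))) pocc <- matrix(pocc, nrow = 12)
  list(p_occ = p_occ, err = err, use_met = use_met,
       pocc = pocc,
       errv = c(err$prop_parent, err$add_parent, err$prop_met, err$add_met,
                err$corr),
       mw_ratio = mw_ratio,
       np_occ = vapply(subj$occs, function(o) length(o$t2), integer(1)),
       nm_occ = vapply(subj$occs, function(o) length(o$t3), integer(1)),
       ip_occ = lapply(subj$occs, function(o) o$ip),
       im_occ = lapply(subj$occs, function(o) o$im))
}

#' Joint -2 log-likelihood contribution of one subject
#'
#' Evaluates the joint (conditional on the random effects) -2
#' log-likelihood of one subject's data: Gaussian residuals with the
#' combined error model, cross-analyte correlation at shared sampling
#' times, residual variances evaluated at the individual prediction
#' (eta-epsilon interaction), additive-error inflation for imputed BLQ
#' rows, excluded rows contributing zero, plus the log-normal prior of
#' the random effects (including normalizing constants).
#'
#' Mainly a building block of [fit_model()], exported for testing and
#' for diagnostic use.
#'
#' @param ds A preprocessed `pk_dataset` restricted to (at least) the
#'   subject of interest.
#' @param id Subject identifier.
#' @param model List with `params` (`rb_params`), `effects`
#'   (`rb_effects`), `pop_spec` (`rb_popspec`), `error_spec`
#'   (`rb_errspec`).
#' @param eta Named list with `cl`, `cl_met` and per-occasion vectors
#'   `f`, `ka`, `tlag` (recycled; defaults 0). Only effects with
#'   nonzero variance enter.
#' @param use_met Include metabolite observations (FALSE for
#'   parent-only stages).
#' @param constants See [rb_constants()].
#' @return The scalar -2 log-likelihood value.
#' @export
neg2ll_individual <- function(ds, id, model, eta = list(), use_met = TRUE,
                              constants = rb_constants()) {
  comp <- .compile_subjects(ds[ds$ID == id, ], constants)
  subj <- comp[[1]]
  om2 <- .model_om2(model$pop_spec)
  lay <- .eta_layout(subj, om2, use_met)
  ctx <- .make_ctx(subj, model, use_met, attr(comp, "mw_ratio"))
  ev <- numeric(lay$d)
  g <- function(nm, k = NULL) {
    x <- eta[[nm]]
    if (is.null(x)) 0 else if (is.null(k)) x[1] else rep_len(x, length(subj$occs))[k]
  }
  if (lay$icl > 0) ev[lay$icl] <- g("cl")
  if (lay$iclm > 0) ev[lay$iclm] <- g("cl_met")
  for (k in seq_along(subj$occs)) {
    if (lay$occ[1, k] > 0) ev[lay$occ[1, k]] <- g("f", k)
    if (lay$occ[2, k] > 0) ev[lay$occ[2, k]] <- g("ka", k)
    if (lay$occ[3, k] > 0) ev[lay$occ[3, k]] <- g("tlag", k)
  }
  .subject_h(ev, subj, lay, ctx)
}

.model_om2 <- function(pop_spec) {
  c(cl = cv_to_omega2(pop_spec$bsv_cl_shared),
    cl_met = cv_to_omega2(pop_spec$bsv_cl_met),
    f = cv_to_omega2(pop_spec$bov_f),
    ka = cv_to_omega2(pop_spec$bov_ka),
    tlag = cv_to_omega2(pop_spec$bov_tlag))
}

# Population objective: sum of Laplace-approximate subject marginals.
# `cache` (an environment) carries warm-start etas across evaluations.
.population_nll <- function(model, compiled, use_met, hessian = "gn",
                            cache = NULL, inner_tol = 1e-6) {
  om2 <- .model_om2(model$pop_spec)
  mw_ratio <- attr(compiled, "mw_ratio")
  total <- 0
  etas <- vector("list", length(compiled))
  for (i in seq_along(compiled)) {
    subj <- compiled[[i]]
    lay <- .eta_layout(subj, om2, use_met)
    start <- numeric(lay$d)
    cold <- TRUE
    if (!is.null(cache) && length(cache$eta) >= i &&
        length(cache$eta[[i]]) == lay$d) {
      start <- cache$eta[[i]]
      cold <- FALSE
    }
    ctx <- .make_ctx(subj, model, use_met, mw_ratio)
    res <- .subject_marginal(subj, lay, ctx, start, hessian, inner_tol, cold)
    total <- total + res$contrib
    etas[[i]] <- res$eta
  }
  if (!is.null(cache)) cache$eta <- etas
  total
}
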