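# Population fitting: staged (parent -> metabolite -> optional joint)
# maximization of the Laplace/FOCE-approximate marginal likelihood over
# fixed effects, random-effect variances and residual-error parameters.

#' Estimation options
#'
#' @param active Covariate effects present in the fitted model, any of
#'   `"lpvr_f"` (LPV/r on bioavailability), `"lpvr_cyp"` (LPV/r
#'   inhibition of the CYP3A4 clearance pathway), `"lpvr_clmet"`
#'   (LPV/r on metabolite clearance), `"zwfa_f"` (underweight effect
#'   on bioavailability), `"age_ka"` (age effect on absorption rate).
#'   Inactive effects are fixed at their null value and not estimated.
#' @param zwfa_form Functional form of the underweight effect (see
#'   [rb_covariate_effects()]).
#' @param hessian Laplace curvature: `"fd"` (exact finite-difference
#'   Hessian of the joint -2LL; the default) or `"gn"` (Gauss-Newton
#'   from the prediction Jacobian, the cheaper FOCE-style
#'   approximation, which mildly biases the variance terms).
#' @param estimate_inhibition Estimate the CYP3A4 inhibition fraction
#'   instead of fixing it at 1 (the final-model convention).
#' @param inner_tol,outer_tol Convergence tolerances: inner, the
#'   per-subject random-effect optimization; outer, the relative
#'   objective tolerance of the population quasi-Newton optimizer.
#' @param outer_iter,outer_eval Iteration / evaluation caps of the
#'   outer quasi-Newton optimizer, per restart round.
#' @param outer_rounds Maximum optimizer restarts per stage (a restart
#'   continues from the incumbent estimates until the objective
#'   improves by less than 0.1).
#' @param b2 Baseline handling for reset profiles: `"observation"`
#'   keeps the pre-dose observation in the likelihood (the baseline is
#'   initialized from it either way); `"exclude_predose"` drops it
#'   from the fit to avoid using it twice.
#' @return A list of class `rb_config`.
#' @export
rb_model_config <- function(active = c("lpvr_f", "lpvr_cyp", "lpvr_clmet",
                                       "zwfa_f", "age_ka"),
                            zwfa_form = c("power", "linear"),
                            hessian = c("fd", "gn"),
                            estimate_inhibition = FALSE,
                            inner_tol = 1e-6, outer_tol = 1e-8,
                            outer_iter = 150, outer_eval = 2000,
                            outer_rounds = 6,
                            b2 = c("observation", "exclude_predose")) {
  structure(list(active = active, zwfa_form = match.arg(zwfa_form),
                 hessian = match.arg(hessian),
                 estimate_inhibition = estimate_inhibition,
                 inner_tol = inner_tol, outer_tol = outer_tol,
                 outer_iter = outer_iter, outer_eval = outer_eval,
                 outer_rounds = outer_rounds,
                 b2 = match.arg(b2)),
            class = "rb_config")
}

.tr <- list(
  log = list(f = log, inv = exp),
  logit = list(f = stats::qlogis, inv = stats::plogis),
  atanh = list(f = atanh, inv = tanh),
  identity = list(f = identity, inv = identity))

# parameter table of one estimation stage
.stage_par_table <- function(stage, config) {
  rows <- list()
  add <- function(name, block, field, transform)
    rows[[length(rows) + 1]] <<- list(name = name, block = block,
                                      field = field, transform = transform)
  if (stage %in% c("parent", "joint")) {
    for (f in c("cl_cyp_ref", "cl_conv_ref", "vc_p_ref", "vp_p_ref",
                "q_p_ref", "ka", "tlag"))
      add(f, "params", f, "log")
    if ("lpvr_f" %in% config$active) add("lpvr_f_fold", "effects", "lpvr_f_fold", "log")
    if ("zwfa_f" %in% config$active) add("zwfa_f_per_unit", "effects", "zwfa_f_per_unit", "logit")
    if ("age_ka" %in% config$active) add("age_ka_frac", "effects", "age_ka_frac", "logit")
    if ("lpvr_cyp" %in% config$active && config$estimate_inhibition)
      add("lpvr_cyp_inhibition", "effects", "lpvr_cyp_inhibition", "logit")
    for (f in c("bsv_cl_shared", "bov_f", "bov_ka", "bov_tlag"))
      add(f, "om", f, "log")
    add("prop_parent", "err", "prop_parent", "log")
    add("add_parent", "err", "add_parent", "log")
  }
  if (stage %in% c("metabolite", "joint")) {
    for (f in c("cl_met_ref", "vc_m_ref", "vp_m_ref", "q_m_ref"))
      add(f, "params", f, "log")
    if ("lpvr_clmet" %in% config$active)
      add("lpvr_clmet_frac", "effects", "lpvr_clmet_frac", "logit")
    add("bsv_cl_met", "om", "bsv_cl_met", "log")
    add("prop_met", "err", "prop_met", "log")
    add("add_met", "err", "add_met", "log")
    add("corr", "err", "corr", "atanh")
  }
  rows
}

.model_get <- function(model, block, field) {
  switch(block,
         params = model$params[[field]],
         effects = model$effects[[field]],
         om = model$pop_spec[[field]],
         err = model$error_spec[[field]])
}

.model_set <- function(model, block, field, value) {
  switch(block,
         params = model$params[[field]] <- value,
         effects = model$effects[[field]] <- value,
         om = model$pop_spec[[field]] <- value,
         err = model$error_spec[[field]] <- value)
  model
}

# theta (transformed, estimable subset) <-> model
.make_stage <- function(stage, config, model0) {
  tab <- .stage_par_table(stage, config)
  par0 <- c(); keep <- list()
  for (row in tab) {
    v <- .model_get(model0, row$block, row$field)
    x <- .tr[[row$transform]]$f(if (row$block == "om") sqrt(cv_to_omega2(v)) else v)
    if (is.finite(x)) {
      par0 <- c(par0, stats::setNames(x, row$name))
      keep[[length(keep) + 1]] <- row
    }
  }
  build <- function(theta) {
    m <- model0
    for (i in seq_along(keep)) {
      row <- keep[[i]]
      v <- unname(.tr[[row$transform]]$inv(theta[i]))
      if (row$block == "om") v <- omega2_to_cv(v^2)
      m <- .model_set(m, row$block, row$field, v)
    }
    m
  }
  list(par0 = par0, build = build, table = keep)
}

# null values for covariate effects not in the fitted model
.apply_active <- function(effects, active) {
  if (!"lpvr_f" %in% active) effects$lpvr_f_fold <- 1
  if (!"lpvr_cyp" %in% active) effects$lpvr_cyp_inhibition <- 0
  if (!"lpvr_clmet" %in% active) effects$lpvr_clmet_frac <- 1
  if (!"zwfa_f" %in% active) effects$zwfa_f_per_unit <- 0
  if (!"age_ka" %in% active) effects$age_ka_frac <- 1
  effects
}

#' Randomly perturb initial estimates
#'
#' Multiplies every structural parameter (and the fold-change covariate
#' effect) by an independent factor drawn uniformly on `range`, so fits
#' do not start from the values used to simulate the data.
#'
#' @param init Model list with `params`, `effects`, `pop_spec`,
#'   `error_spec` (see [fit_model()]).
#' @param seed Integer seed.
#' @param range Multiplicative perturbation range (default `[0.5, 2]`,
#'   log-uniform).
#' @return The perturbed model list.
#' @export
perturb_init <- function(init, seed = NULL, range = c(0.5, 2)) {
  if (!is.null(seed)) set.seed(seed)
  lr <- log(range)
  mult <- function(x) x * exp(stats::runif(1, lr[1], lr[2]))
  for (f in c("cl_cyp_ref", "cl_conv_ref", "cl_met_ref", "vc_p_ref", "vp_p_ref",
              "q_p_ref", "vc_m_ref", "vp_m_ref", "q_m_ref", "ka", "tlag"))
    init$params[[f]] <- mult(init$params[[f]])
  init$effects$lpvr_f_fold <- mult(init$effects$lpvr_f_fold)
  init
}

#' Fit the joint parent-metabolite population model
#'
#' Maximizes the Laplace/FOCE-approximate marginal likelihood over the
#' fixed effects, random-effect variances and residual-error
#' parameters (all log/logit-transformed internally). The default
#' strategy is sequential, mirroring the development of the model:
#' first the rifabutin submodel on the parent observations, then the
#' des-rifabutin side (parent parameters fixed) on both analytes; an
#' optional final `"joint"` stage re-estimates everything together.
#'
#' @param ds A `pk_dataset`; preprocessed automatically (BLQ roles,
#'   reset markers) if the preprocessing columns are absent.
#' @param config An [rb_model_config()].
#' @param init Initial model: list with `params`, `effects`,
#'   `pop_spec`, `error_spec`; defaults to the package's published
#'   typical values (see [perturb_init()] to displace them).
#' @param stages Character vector, subset of
#'   `c("parent", "metabolite", "joint")`, executed in order.
#' @param constants See [rb_constants()].
#' @param verbose Print stage progress.
#' @return An object of class `rb_fit`: estimated `params`, `effects`,
#'   `pop_spec` (%CV), `error_spec`, `ofv` (by stage and final),
#'   `convergence` codes, `n_par`, empirical Bayes estimates (`ebe`)
#'   with `shrinkage` (%), the evaluation `trace`, and bookkeeping
#'   needed by [compare_models()]. Non-convergence is reported in
#'   `convergence`, never silently.
#' @export
fit_model <- function(ds, config = rb_model_config(), init = NULL,
                      stages = c("parent", "metabolite"),
                      constants = rb_constants(), verbose = FALSE) {
  stages <- match.arg(stages, c("parent", "metabolite", "joint"), several.ok = TRUE)
  if (is.null(ds$ROLE)) ds <- preprocess_blq(ds, constants = constants)
  if (is.null(ds$RESET)) ds <- detect_and_reset(ds)
  if (config$b2 == "exclude_predose") {
    for (key in split(seq_len(nrow(ds)), interaction(ds$ID, ds$OCC, drop = TRUE))) {
      if (!any(ds$RESET[key] == 1)) next
      t0 <- max(ds$TIME[key][ds$EVID[key] == 1])
      ds$ROLE[key][ds$EVID[key] == 0 & ds$TIME[key] == t0] <- "excluded"
    }
  }
  compiled <- .compile_subjects(ds, constants)

  model <- list(params = rb_structural_params(), effects = rb_covariate_effects(),
                pop_spec = rb_population_spec(), error_spec = rb_residual_spec())
  if (!is.null(init)) for (nm in names(init)) model[[nm]] <- init[[nm]]
  model$effects$zwfa_form <- config$zwfa_form
  model$effects <- .apply_active(model$effects, config$active)
  if ("lpvr_cyp" %in% config$active && model$effects$lpvr_cyp_inhibition == 0)
    model$effects$lpvr_cyp_inhibition <- 1

  cache <- new.env(parent = emptyenv()); cache$eta <- list()
  trace <- list(); stage_res <- list()
  for (stage in stages) {
    use_met <- stage != "parent"
    sp <- .make_stage(stage, config, model)
    tr_env <- new.env(parent = emptyenv()); tr_env$vals <- numeric(0)
    obj <- function(theta) {
      m <- tryCatch(sp$build(theta), error = function(e) NULL)
      if (is.null(m)) return(1e10)
      val <- .population_nll(m, compiled, use_met, config$hessian, cache,
                             config$inner_tol)
      tr_env$vals <- c(tr_env$vals, val)
      val
    }
    # central-difference gradient with a step sized for the log/logit
    # scale: the Laplace objective carries O(1e-4) warm-start noise, so
    # the optimizer must not difference it at machine-epsilon steps
    grd <- function(theta) {
      g <- numeric(length(theta))
      for (j in seq_along(theta)) {
        tp <- theta; tp[j] <- tp[j] + 1e-3
        tn <- theta; tn[j] <- tn[j] - 1e-3
        g[j] <- (obj(tp) - obj(tn)) / 2e-3
      }
      g
    }
    # quasi-Newton with restarts: the trust-region pass occasionally
    # declares (false) convergence at the objective's noise floor, and
    # a restart rebuilds its model and recovers further progress
    par <- sp$par0
    best_obj <- Inf
    opt <- NULL
    for (round in seq_len(config$outer_rounds)) {
      opt <- stats::nlminb(par, obj, gradient = grd,
                           control = list(iter.max = config$outer_iter,
                                          eval.max = config$outer_eval,
                                          rel.tol = config$outer_tol))
      par <- opt$par
      if (best_obj - opt$objective < 0.1) break
      best_obj <- opt$objective
    }
    model <- sp$build(opt$par)
    stage_res[[stage]] <- list(ofv = opt$objective, convergence = opt$convergence,
                               message = opt$message,
                               iterations = opt$iterations,
                               n_par = length(sp$par0),
                               estimates = stats::setNames(opt$par, names(sp$par0)))
    trace[[stage]] <- tr_env$vals
    if (verbose)
      message(sprintf("stage %-10s OFV %.3f  (%d parameters, %d iterations, code %d)",
                      stage, opt$objective, length(sp$par0), opt$iterations,
                      opt$convergence))
  }

  n_par_total <- sum(vapply(stage_res, function(s) s$n_par, numeric(1)))
  fit <- structure(list(
    params = model$params, effects = model$effects, pop_spec = model$pop_spec,
    error_spec = model$error_spec,
    ofv = stage_res[[length(stage_res)]]$ofv,
    stage_results = stage_res, n_par = n_par_total,
    convergence = vapply(stage_res, function(s) s$convergence, numeric(1)),
    config = config, stages = stages, trace = trace,
    data_hash = .data_hash(ds, constants)), class = "rb_fit")
  eb <- empirical_bayes(ds, fit, constants = constants)
  fit$ebe <- eb$ebe
  fit$shrinkage <- eb$shrinkage
  fit
}

.data_hash <- function(ds, constants) {
  obs <- ds[ds$EVID == 0 & ds$ROLE != "excluded", ]
  c(n = nrow(obs), sum_dv = sum(obs$DV_FIT), n_id = length(unique(ds$ID)))
}

#' @export
print.rb_fit <- function(x, ...) {
  cat("Population PK fit (rifabutin / des-rifabutin)\n")
  cat(sprintf("  OFV: %.3f   parameters: %d   stages: %s\n", x$ofv, x$n_par,
              paste(x$stages, collapse = " -> ")))
  conv <- all(x$convergence == 0)
  cat("  convergence:", if (conv) "clean" else
    paste("check stage codes:", paste(x$convergence, collapse = ", ")), "\n")
  cat(sprintf("  CL_cyp3a4 %.3g  CL_conv %.3g  CL_met %.3g L/h (10 kg)\n",
              x$params$cl_cyp_ref, x$params$cl_conv_ref, x$params$cl_met_ref))
  cat(sprintf("  LPV/r F x%.3g   LPV/r CL_met %+.1f%%   ZWFA %.1f%%/unit   Ka(<=3y) %+.1f%%\n",
              x$effects$lpvr_f_fold, -100 * (1 - x$effects$lpvr_clmet_frac),
              -100 * x$effects$zwfa_f_per_unit, -100 * (1 - x$effects$age_ka_frac)))
  invisible(x)
}

#' Likelihood-ratio / information-criterion model comparison
#'
#' For two fits of the same dataset and observation set, returns the
#' objective-function difference with a chi-squared likelihood-ratio
#' test (nested models; degrees of freedom = difference in estimated
#' parameter count, overridable) and the Akaike information criterion
#' difference for non-nested comparisons.
#'
#' @param fit_reduced,fit_full `rb_fit` objects, reduced model first.
#' @param df Degrees of freedom for the LRT (default: parameter-count
#'   difference).
#' @return List with `delta_ofv` (reduced minus full; positive favours
#'   the full model), `df`, `p_value`, `aic_reduced`, `aic_full`,
#'   `delta_aic`.
#' @examples
#' # a 3.84-point OFV improvement for one extra parameter: p = 0.05
#' stats::pchisq(3.84, 1, lower.tail = FALSE)
#' @export
compare_models <- function(fit_reduced, fit_full, df = NULL) {
  if (!isTRUE(all.equal(fit_reduced$data_hash, fit_full$data_hash)))
    stop("fits are not based on the same dataset/observation set")
  delta <- fit_reduced$ofv - fit_full$ofv
  if (is.null(df)) df <- abs(fit_full$n_par - fit_reduced$n_par)
  p <- if (df > 0) stats::pchisq(max(delta, 0), df, lower.tail = FALSE) else NA_real_
  aic_r <- fit_reduced$ofv + 2 * fit_reduced$n_par
  aic_f <- fit_full$ofv + 2 * fit_full$n_par
  list(delta_ofv = delta, df = df, p_value = p,
       aic_reduced = aic_r, aic_full = aic_f, delta_aic = aic_f - aic_r)
}

#' Stepwise covariate selection
#'
#' Forward addition (likelihood-ratio P < `forward_p`) followed by
#' backward elimination (retained only if removal worsens the fit at
#' P < `backward_p`), over a set of candidate covariate effects (see
#' [rb_model_config()] for the names). Every decision is logged.
#'
#' @param ds A `pk_dataset`.
#' @param candidates Character vector of candidate effect names.
#' @param base_active Effects always present (not subject to search).
#' @param config,init,stages,constants Passed to [fit_model()].
#' @param forward_p,backward_p Inclusion / retention thresholds.
#' @return List with `selected` (character vector), `trace`
#'   (data.frame of every tested step) and `final_fit`.
#' @export
stepwise_covariates <- function(ds, candidates, base_active = character(0),
                                config = rb_model_config(),
                                init = NULL, stages = "parent",
                                constants = rb_constants(),
                                forward_p = 0.05, backward_p = 0.01) {
  if (is.null(ds$ROLE)) ds <- preprocess_blq(ds, constants = constants)
  if (is.null(ds$RESET)) ds <- detect_and_reset(ds)
  fit_with <- function(active) {
    cfg <- config; cfg$active <- active
    fit_model(ds, cfg, init, stages, constants)
  }
  current <- base_active
  cur_fit <- fit_with(current)
  trace <- list()
  note <- function(phase, cand, cmp, decision)
    trace[[length(trace) + 1]] <<- data.frame(
      phase = phase, candidate = cand, delta_ofv = cmp$delta_ofv,
      df = cmp$df, p_value = cmp$p_value, decision = decision)
  repeat {
    pool <- setdiff(candidates, current)
    if (length(pool) == 0) break
    best <- NULL
    for (cand in pool) {
      f <- fit_with(c(current, cand))
      cmp <- compare_models(cur_fit, f, df = 1)
      sig <- !is.na(cmp$p_value) && cmp$p_value < forward_p
      note("forward", cand, cmp, if (sig) "candidate" else "not significant")
      if (sig && (is.null(best) || f$ofv < best$fit$ofv))
        best <- list(cand = cand, fit = f)
    }
    if (is.null(best)) break
    current <- c(current, best$cand)
    cur_fit <- best$fit
  }
  repeat {
    removable <- setdiff(current, base_active)
    if (length(removable) == 0) break
    worst <- NULL
    for (cand in removable) {
      f <- fit_with(setdiff(current, cand))
      cmp <- compare_models(f, cur_fit, df = 1)
      keep <- !is.na(cmp$p_value) && cmp$p_value < backward_p
      note("backward", cand, cmp, if (keep) "retained" else "removable")
      if (!keep && (is.null(worst) || f$ofv < worst$fit$ofv))
        worst <- list(cand = cand, fit = f)
    }
    if (is.null(worst)) break
    current <- setdiff(current, worst$cand)
    cur_fit <- worst$fit
  }
  list(selected = setdiff(current, base_active),
       trace = do.call(rbind, trace), final_fit = cur_fit)
}

#' Empirical Bayes estimates and shrinkage
#'
#' Computes the posterior modes of every subject's random effects under
#' a fitted (or supplied) model, and the shrinkage of each
#' random-effect distribution, `100 * (1 - SD(eta) / omega)`
#' (between-occasion effects pooled over occasions).
#'
#' @param ds A `pk_dataset`.
#' @param fit An `rb_fit`, or a model list with `params`, `effects`,
#'   `pop_spec`, `error_spec`.
#' @param use_met Include metabolite observations when conditioning.
#' @param constants See [rb_constants()].
#' @return List with `ebe` (long data.frame: `ID`, `OCC` (`NA` for
#'   between-subject effects), `effect`, `eta`) and `shrinkage`
#'   (named vector, %).
#' @export
empirical_bayes <- function(ds, fit, use_met = TRUE,
                            constants = rb_constants()) {
  if (is.null(ds$ROLE)) ds <- preprocess_blq(ds, constants = constants)
  if (is.null(ds$RESET)) ds <- detect_and_reset(ds)
  model <- list(params = fit$params, effects = fit$effects,
                pop_spec = fit$pop_spec, error_spec = fit$error_spec)
  inner_tol <- if (!is.null(fit$config)) fit$config$inner_tol else 1e-6
  compiled <- .compile_subjects(ds, constants)
  om2 <- .model_om2(model$pop_spec)
  mw_ratio <- attr(compiled, "mw_ratio")
  rows <- list()
  for (subj in compiled) {
    lay <- .eta_layout(subj, om2, use_met)
    ctx <- .make_ctx(subj, model, use_met, mw_ratio)
    eta <- if (lay$d > 0)
      .inner_optimize(subj, lay, ctx, numeric(lay$d), tol = inner_tol)$eta
    else numeric(0)
    grab <- function(idx, effect, occ)
      if (idx > 0) rows[[length(rows) + 1]] <<-
        data.frame(ID = subj$id, OCC = occ, effect = effect, eta = eta[idx])
    grab(lay$icl, "cl", NA)
    grab(lay$iclm, "cl_met", NA)
    for (k in seq_along(subj$occs)) {
      grab(lay$occ[1, k], "f", subj$occs[[k]]$occ)
      grab(lay$occ[2, k], "ka", subj$occs[[k]]$occ)
      grab(lay$occ[3, k], "tlag", subj$occs[[k]]$occ)
    }
  }
  ebe <- do.call(rbind, rows)
  shr <- c()
  if (!is.null(ebe)) {
    for (eff in unique(ebe$effect)) {
      omega <- sqrt(om2[[eff]])
      sdv <- stats::sd(ebe$eta[ebe$effect == eff])
      shr[eff] <- 100 * (1 - sdv / omega)
    }
  }
  list(ebe = ebe, shrinkage = shr)
}

#' Serialize / restore a fit
#'
#' Writes the estimated parameters, covariate effects (as percent
#' changes where they are reported that way), variability terms (%CV),
#' residual-error terms, objective function value and convergence
#' status to JSON, and reads them back into a model list usable as
#' `init` for [fit_model()] or for simulation.
#'
#' @param fit An `rb_fit`.
#' @param path JSON file path.
#' @return `read_fit()` returns a list with `params`, `effects`,
#'   `pop_spec`, `error_spec`, `ofv`, `convergence`.
#' @export
write_fit <- function(fit, path) {
  obj <- list(params = lapply(unclass(fit$params), unname),
              effects = unclass(fit$effects)[c("lpvr_f_fold", "lpvr_cyp_inhibition",
                                               "lpvr_clmet_frac", "zwfa_f_per_unit",
                                               "age_ka_frac", "zwfa_form",
                                               "allo_cl", "allo_v", "wt_ref")],
              derived = list(
                lpvr_f_percent = 100 * (fit$effects$lpvr_f_fold - 1),
                lpvr_clmet_percent = -100 * (1 - fit$effects$lpvr_clmet_frac),
                zwfa_f_percent_per_unit = -100 * fit$effects$zwfa_f_per_unit,
                age_ka_percent = -100 * (1 - fit$effects$age_ka_frac)),
              pop_spec = unclass(fit$pop_spec),
              error_spec = unclass(fit$error_spec),
              ofv = fit$ofv, convergence = fit$convergence,
              n_par = fit$n_par, shrinkage = as.list(fit$shrinkage))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ef <- obj$effects
  list(params = do.call(rb_structural_params, obj$params),
       effects = rb_covariate_effects(
         lpvr_f_fold = ef$lpvr_f_fold,
         lpvr_cyp_inhibition = ef$lpvr_cyp_inhibition,
         lpvr_clmet_frac = ef$lpvr_clmet_frac,
         zwfa_f_per_unit = ef$zwfa_f_per_unit,
         age_ka_frac = ef$age_ka_frac, zwfa_form = ef$zwfa_form,
         allo_cl = ef$allo_cl, allo_v = ef$allo_v, wt_ref = ef$wt_ref),
       pop_spec = do.call(rb_population_spec, obj$pop_spec[names(formals(rb_population_spec))]),
       error_spec = do.call(rb_residual_spec, obj$error_spec[names(formals(rb_residual_spec))]),
       ofv = obj$ofv, convergence = obj$convergence)
}
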