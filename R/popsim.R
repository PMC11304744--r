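#' Between-subject and between-occasion variability specification
#'
#' Magnitudes of the lognormal random effects of the final model,
#' expressed as approximate percent coefficients of variation
#' (`100 * sqrt(exp(omega^2) - 1)`). One shared between-subject effect
#' acts on both rifabutin clearance pathways, a separate one on the
#' metabolite clearance, and between-occasion effects act on
#' bioavailability, absorption rate constant and lag time.
#'
#' @param bsv_cl_shared %CV of the shared clearance effect (default 20.7).
#' @param bsv_cl_met %CV on des-rifabutin clearance (default 30.8).
#' @param bov_f %CV per occasion on bioavailability (default 71.9).
#' @param bov_ka %CV per occasion on the absorption rate (default 118).
#' @param bov_tlag %CV per occasion on the lag time (default 74.8).
#' @return An object of class `rb_popspec`.
#' @export
rb_population_spec <- function(bsv_cl_shared = 20.7, bsv_cl_met = 30.8,
                               bov_f = 71.9, bov_ka = 118, bov_tlag = 74.8) {
  x <- list(bsv_cl_shared = bsv_cl_shared, bsv_cl_met = bsv_cl_met,
            bov_f = bov_f, bov_ka = bov_ka, bov_tlag = bov_tlag)
  if (any(unlist(x) < 0)) stop("variability magnitudes must be non-negative")
  structure(x, class = "rb_popspec")
}

#' Residual unexplained variability specification
#'
#' Combined (additive + proportional) residual error per analyte, with
#' a correlation between the rifabutin and des-rifabutin errors of the
#' same plasma sample (the two analytes are quantified from one
#' sample).
#'
#' @param prop_parent Proportional error for rifabutin (fraction,
#'   default 0.188).
#' @param add_parent Additive error for rifabutin (ug/L, default 10.1).
#' @param prop_met Proportional error for des-rifabutin (default 0.108).
#' @param add_met Additive error for des-rifabutin (ug/L, default 11.6).
#' @param corr Correlation between same-sample errors (default 0.282).
#' @return An object of class `rb_errspec`.
#' @export
rb_residual_spec <- function(prop_parent = 0.188, add_parent = 10.1,
                             prop_met = 0.108, add_met = 11.6,
                             corr = 0.282) {
  stopifnot(prop_parent >= 0, add_parent >= 0, prop_met >= 0, add_met >= 0,
            abs(corr) < 1)
  structure(list(prop_parent = prop_parent, add_parent = add_parent,
                 prop_met = prop_met, add_met = add_met, corr = corr),
            class = "rb_errspec")
}

#' Convert between %CV and lognormal variance
#'
#' For a lognormal random effect with variance `omega2` on the log
#' scale, the approximate percent coefficient of variation is
#' `100 * sqrt(exp(omega2) - 1)`; these two functions invert each
#' other exactly.
#'
#' @param cv_percent %CV (non-negative).
#' @param omega2 Variance of the log-scale random effect.
#' @return `cv_to_omega2()` returns the log-scale variance;
#'   `omega2_to_cv()` returns the %CV.
#' @examples
#' omega2_to_cv(cv_to_omega2(71.9))  # 71.9
#' @export
cv_to_omega2 <- function(cv_percent) {
  if (any(cv_percent < 0)) stop("cv_percent must be non-negative")
  log(1 + (cv_percent / 100)^2)
}

#' @rdname cv_to_omega2
#' @export
omega2_to_cv <- function(omega2) {
  if (any(omega2 < 0)) stop("omega2 must be non-negative")
  100 * sqrt(exp(omega2) - 1)
}

#' Draw individual random effects and realized parameters
#'
#' Samples the log-normal random-effect vector for one subject (or a
#' population of subjects) and applies it to the typical parameters:
#' a single shared between-subject effect multiplies both rifabutin
#' clearance pathways, an independent effect multiplies the metabolite
#' clearance, and each occasion receives independent effects on
#' bioavailability, absorption rate constant and lag time.
#'
#' @param params Typical-value `rb_params` (allometry and covariates
#'   applied); fields may be vectors of length `n`.
#' @param pop_spec An [rb_population_spec()] object.
#' @param n Number of subjects to draw (defaults to the parameter
#'   vector length).
#' @param n_occasions Number of occasions per subject.
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `eta` (data.frame of draws: `cl`, `cl_met` and
#'   per-occasion `f.k`, `ka.k`, `tlag.k`) and `occasions`, a list of
#'   `rb_params` objects (one per occasion, vectorized over subjects).
#' @export
draw_individual <- function(params, pop_spec = rb_population_spec(),
                            n = NULL, n_occasions = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n)) n <- max(lengths(unclass(params)))
  om <- sqrt(cv_to_omega2(c(cl = pop_spec$bsv_cl_shared,
                            cl_met = pop_spec$bsv_cl_met,
                            f = pop_spec$bov_f,
                            ka = pop_spec$bov_ka,
                            tlag = pop_spec$bov_tlag)))
  eta <- data.frame(cl = stats::rnorm(n, 0, om["cl"]),
                    cl_met = stats::rnorm(n, 0, om["cl_met"]))
  occasions <- vector("list", n_occasions)
  for (k in seq_len(n_occasions)) {
    ef <- stats::rnorm(n, 0, om["f"])
    eka <- stats::rnorm(n, 0, om["ka"])
    etl <- stats::rnorm(n, 0, om["tlag"])
    eta[[paste0("f.", k)]] <- ef
    eta[[paste0("ka.", k)]] <- eka
    eta[[paste0("tlag.", k)]] <- etl
    occasions[[k]] <- apply_etas(params, list(cl = eta$cl, cl_met = eta$cl_met,
                                              f = ef, ka = eka, tlag = etl))
  }
  list(eta = eta, occasions = occasions)
}

#' Simulate observed concentrations with residual error
#'
#' Adds combined (additive + proportional) residual error to paired
#' model predictions, drawing the rifabutin and des-rifabutin errors of
#' each sample from a correlated bivariate normal. Negative simulated
#' values are floored at 0 before any censoring.
#'
#' @param pred_parent,pred_metabolite Non-negative predicted
#'   concentrations (ug/L), equal length.
#' @param error_spec An [rb_residual_spec()] object.
#' @param seed Optional integer seed.
#' @return A data.frame with `obs_parent` and `obs_metabolite`.
#' @export
simulate_dv <- function(pred_parent, pred_metabolite,
                        error_spec = rb_residual_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(pred_parent) != length(pred_metabolite))
    stop("prediction vectors must have equal length")
  if (any(pred_parent < 0) || any(pred_metabolite < 0))
    stop("predictions must be non-negative")
  n <- length(pred_parent)
  rho <- error_spec$corr
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  sd_p <- sqrt((error_spec$prop_parent * pred_parent)^2 + error_spec$add_parent^2)
  sd_m <- sqrt((error_spec$prop_met * pred_metabolite)^2 + error_spec$add_met^2)
  data.frame(obs_parent = pmax(pred_parent + sd_p * z1, 0),
             obs_metabolite = pmax(pred_metabolite + sd_m * z2, 0))
}

#' Flag observations below the limit of quantification
#'
#' Marks values strictly below the analyte's lower limit of
#' quantification as censored (BLQ); the numeric value is retained for
#' diagnostics. A value exactly at the limit is quantifiable.
#'
#' @param values Numeric concentrations (ug/L).
#' @param analyte `"parent"` or `"metabolite"`.
#' @param constants See [rb_constants()]; must carry the LLOQ for the
#'   analyte.
#' @return Integer vector of 0/1 BLQ flags.
#' @export
censor_blq <- function(values, analyte = c("parent", "metabolite"),
                       constants = rb_constants()) {
  analyte <- match.arg(analyte)
  lloq <- constants[[paste0("lloq_", analyte)]]
  if (is.null(lloq) || !is.finite(lloq) || lloq <= 0)
    stop("missing or invalid LLOQ for analyte ", analyte)
  as.integer(values < lloq)
}
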