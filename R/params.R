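#' Structural pharmacokinetic parameters at the 10-kg reference
#'
#' Container for the typical-value parameters of the joint
#' rifabutin / 25-O-desacetyl rifabutin (des-rifabutin) model. The
#' disposition of both analytes is two-compartmental with first-order
#' absorption (through a depot with lag time) and first-order
#' elimination. Rifabutin is cleared by two parallel pathways: an
#' inhibitable CYP3A4 route (`cl_cyp_ref`) and conversion to
#' des-rifabutin by arylacetamide deacetylase (`cl_conv_ref`); the
#' metabolite is eliminated with clearance `cl_met_ref`. All clearances
#' and volumes refer to a 10-kg child (see [apply_allometry()]).
#'
#' Defaults are the published typical values of the final model for
#' this population (reference weight 10 kg, relative bioavailability
#' fixed at 1 without lopinavir/ritonavir).
#'
#' Every field may be a vector (one element per subject); all functions
#' in the package recycle fields against each other.
#'
#' @param cl_cyp_ref Inhibitable CYP3A4-pathway clearance of rifabutin
#'   at 10 kg (L/h).
#' @param cl_conv_ref Conversion (AADAC) clearance of rifabutin to
#'   des-rifabutin at 10 kg (L/h).
#' @param cl_met_ref Elimination clearance of des-rifabutin at 10 kg (L/h).
#' @param vc_p_ref,vp_p_ref Central / peripheral volume of distribution
#'   of rifabutin at 10 kg (L).
#' @param q_p_ref Intercompartmental clearance of rifabutin at 10 kg (L/h).
#' @param vc_m_ref,vp_m_ref Central / peripheral volume of distribution
#'   of des-rifabutin at 10 kg (L).
#' @param q_m_ref Intercompartmental clearance of des-rifabutin at 10 kg (L/h).
#' @param f_ref Relative oral bioavailability (1 fixed for the
#'   reference configuration).
#' @param ka First-order absorption rate constant (1/h).
#' @param tlag Absorption lag time (h).
#' @return An object of class `rb_params` (named list).
#' @examples
#' p <- rb_structural_params()
#' apply_allometry(p, weight = 70)$cl_cyp_ref  # 58.5 L/h
#' @export
rb_structural_params <- function(cl_cyp_ref = 13.6,
                                 cl_conv_ref = 16.2,
                                 cl_met_ref = 106,
                                 vc_p_ref = 185,
                                 vp_p_ref = 232,
                                 q_p_ref = 25.1,
                                 vc_m_ref = 43.0,
                                 vp_m_ref = 241,
                                 q_m_ref = 44.4,
                                 f_ref = 1,
                                 ka = 1.27,
                                 tlag = 0.544) {
  p <- list(cl_cyp_ref = cl_cyp_ref, cl_conv_ref = cl_conv_ref,
            cl_met_ref = cl_met_ref,
            vc_p_ref = vc_p_ref, vp_p_ref = vp_p_ref, q_p_ref = q_p_ref,
            vc_m_ref = vc_m_ref, vp_m_ref = vp_m_ref, q_m_ref = q_m_ref,
            f_ref = f_ref, ka = ka, tlag = tlag)
  # tlag may be 0; every other field must be strictly positive
  strict <- setdiff(names(p), "tlag")
  bad <- strict[vapply(p[strict], function(x) any(!is.finite(x) | x <= 0), logical(1))]
  if (length(bad) > 0)
    stop("structural parameters must be strictly positive: ", paste(bad, collapse = ", "))
  if (any(p$tlag < 0)) stop("tlag must be non-negative")
  structure(p, class = "rb_params")
}

#' Covariate effect sizes of the final model
#'
#' Multiplicative covariate effects applied on top of the allometrically
#' scaled structural parameters:
#' * lopinavir/ritonavir (LPV/r) co-treatment multiplies bioavailability
#'   by `lpvr_f_fold` (2.58, i.e. +158%), removes the fraction
#'   `lpvr_cyp_inhibition` of the CYP3A4-pathway clearance (1 = full
#'   inhibition), and leaves the fraction `lpvr_clmet_frac` (0.234,
#'   i.e. -76.6%) of the metabolite clearance;
#' * each weight-for-age z-score (ZWFA) unit below -3 (severe
#'   underweight) lowers bioavailability by `zwfa_f_per_unit` (26% per
#'   unit), applied as the power form `(1 - 0.26)^(-3 - zwfa)` by
#'   default (a linear form is available via `zwfa_form`);
#' * children aged 3 years or younger retain the fraction `age_ka_frac`
#'   (0.277, i.e. 72.3% slower) of the absorption rate constant.
#'
#' @param lpvr_f_fold Fold-change of bioavailability under LPV/r.
#' @param lpvr_cyp_inhibition Fraction of the CYP3A4-pathway clearance
#'   removed under LPV/r (in `[0, 1]`; 1 = complete inhibition, fixed
#'   in the final model).
#' @param lpvr_clmet_frac Fraction of des-rifabutin clearance remaining
#'   under LPV/r (in `[0, 1]`).
#' @param zwfa_f_per_unit Fractional decrease of bioavailability per
#'   ZWFA unit below -3 (in `[0, 1]`).
#' @param age_ka_frac Fraction of the absorption rate constant
#'   remaining at age <= 3 years (in `[0, 1]`).
#' @param zwfa_form `"power"` (default) applies
#'   `(1 - zwfa_f_per_unit)^(-3 - zwfa)`, guaranteeing positivity;
#'   `"linear"` applies `1 - zwfa_f_per_unit * (-3 - zwfa)` truncated
#'   below at 0.01.
#' @param allo_cl,allo_v Allometric exponents for clearances (0.75
#'   fixed) and volumes (1.0 fixed).
#' @param wt_ref Reference body weight (kg).
#' @return An object of class `rb_effects`.
#' @export
rb_covariate_effects <- function(lpvr_f_fold = 2.58,
                                 lpvr_cyp_inhibition = 1.0,
                                 lpvr_clmet_frac = 0.234,
                                 zwfa_f_per_unit = 0.260,
                                 age_ka_frac = 0.277,
                                 zwfa_form = c("power", "linear"),
                                 allo_cl = 0.75,
                                 allo_v = 1.0,
                                 wt_ref = 10) {
  zwfa_form <- match.arg(zwfa_form)
  stopifnot(lpvr_f_fold > 0,
            lpvr_cyp_inhibition >= 0, lpvr_cyp_inhibition <= 1,
            lpvr_clmet_frac >= 0, lpvr_clmet_frac <= 1,
            zwfa_f_per_unit >= 0, zwfa_f_per_unit <= 1,
            age_ka_frac >= 0, age_ka_frac <= 1,
            wt_ref > 0)
  structure(list(lpvr_f_fold = lpvr_f_fold,
                 lpvr_cyp_inhibition = lpvr_cyp_inhibition,
                 lpvr_clmet_frac = lpvr_clmet_frac,
                 zwfa_f_per_unit = zwfa_f_per_unit,
                 age_ka_frac = age_ka_frac,
                 zwfa_form = zwfa_form,
                 allo_cl = allo_cl, allo_v = allo_v, wt_ref = wt_ref),
            class = "rb_effects")
}

#' Physical constants and quantification limits
#'
#' Molar masses of the two analytes and the lower limits of
#' quantification (LLOQ) of the assay used to measure them.
#'
#' @return A list with `mw_parent` (847.02 g/mol), `mw_metabolite`
#'   (805 g/mol), `lloq_parent` (3.91 ug/L), `lloq_metabolite`
#'   (0.780 ug/L).
#' @export
rb_constants <- function() {
  list(mw_parent = 847.02, mw_metabolite = 805,
       lloq_parent = 3.91, lloq_metabolite = 0.780)
}

#' Apply allometric scaling by body weight
#'
#' Scales all clearances by `(weight / wt_ref)^0.75` and all volumes by
#' `(weight / wt_ref)^1.0`; absorption parameters and bioavailability
#' are unchanged. Vectorized over `weight`.
#'
#' @param params An [rb_structural_params()] object.
#' @param weight Body weight (kg), strictly positive.
#' @param effects An [rb_covariate_effects()] object supplying the
#'   exponents and the reference weight.
#' @return An `rb_params` object with scaled clearances and volumes.
#' @export
apply_allometry <- function(params, weight, effects = rb_covariate_effects()) {
  if (any(!is.finite(weight) | weight <= 0)) stop("weight must be strictly positive")
  fcl <- (weight / effects$wt_ref)^effects$allo_cl
  fv <- (weight / effects$wt_ref)^effects$allo_v
  p <- unclass(params)
  for (nm in c("cl_cyp_ref", "cl_conv_ref", "cl_met_ref", "q_p_ref", "q_m_ref"))
    p[[nm]] <- p[[nm]] * fcl
  for (nm in c("vc_p_ref", "vp_p_ref", "vc_m_ref", "vp_m_ref"))
    p[[nm]] <- p[[nm]] * fv
  structure(p, class = "rb_params")
}

#' Apply covariate effects to structural parameters
#'
#' Multiplies the (already allometrically scaled) parameters by the
#' covariate factors of the final model. The order
#' allometry-then-covariates is the package convention; because all
#' effects are multiplicative the order does not change the result.
#' Vectorized over the covariates.
#'
#' @param params An [rb_structural_params()] object (typically after
#'   [apply_allometry()]).
#' @param effects An [rb_covariate_effects()] object.
#' @param cov A list or data.frame with elements `lpvr` (0/1 per
#'   occasion), `zwfa` (weight-for-age z-score) and `age` (years).
#'   Missing elements are treated as no effect.
#' @return An `rb_params` object with individualized typical values.
#' @examples
#' p <- apply_allometry(rb_structural_params(), 10)
#' apply_covariates(p, rb_covariate_effects(), list(lpvr = 1))$cl_cyp_ref  # 0
#' @export
apply_covariates <- function(params, effects = rb_covariate_effects(), cov = list()) {
  p <- unclass(params)
  lpvr <- if (is.null(cov$lpvr)) 0 else cov$lpvr
  zwfa <- if (is.null(cov$zwfa)) 0 else cov$zwfa
  age <- if (is.null(cov$age)) Inf else cov$age
  if (any(age < 0, na.rm = TRUE)) stop("age must be non-negative")

  p$f_ref <- p$f_ref * ifelse(lpvr > 0, effects$lpvr_f_fold, 1)
  p$cl_cyp_ref <- p$cl_cyp_ref * ifelse(lpvr > 0, 1 - effects$lpvr_cyp_inhibition, 1)
  p$cl_met_ref <- p$cl_met_ref * ifelse(lpvr > 0, effects$lpvr_clmet_frac, 1)

  units_below <- pmax(-3 - zwfa, 0)
  fz <- if (effects$zwfa_form == "power") {
    (1 - effects$zwfa_f_per_unit)^units_below
  } else {
    pmax(1 - effects$zwfa_f_per_unit * units_below, 0.01)
  }
  p$f_ref <- p$f_ref * fz

  p$ka <- p$ka * ifelse(age <= 3, effects$age_ka_frac, 1)
  structure(p, class = "rb_params")
}

#' Individualize typical parameters with random-effect values
#'
#' Applies lognormal random effects (on the natural-log scale) to the
#' structural parameters: one shared between-subject effect on the two
#' rifabutin clearance pathways, one on the metabolite clearance, and
#' per-occasion effects on bioavailability, absorption rate and lag
#' time.
#'
#' @param params An `rb_params` object (allometry and covariates applied).
#' @param eta Named list/vector with any of `cl` (shared on
#'   `cl_cyp_ref` and `cl_conv_ref`), `cl_met`, `f`, `ka`, `tlag`;
#'   missing entries default to 0.
#' @return An `rb_params` object with realized individual parameters.
#' @export
apply_etas <- function(params, eta = list()) {
  g <- function(nm) if (is.null(eta[[nm]])) 0 else eta[[nm]]
  p <- unclass(params)
  p$cl_cyp_ref <- p$cl_cyp_ref * exp(g("cl"))
  p$cl_conv_ref <- p$cl_conv_ref * exp(g("cl"))
  p$cl_met_ref <- p$cl_met_ref * exp(g("cl_met"))
  p$f_ref <- p$f_ref * exp(g("f"))
  p$ka <- p$ka * exp(g("ka"))
  p$tlag <- p$tlag * exp(g("tlag"))
  structure(p, class = "rb_params")
}

#' @export
print.rb_params <- function(x, ...) {
  cat("Structural PK parameters (rifabutin / des-rifabutin)\n")
  n <- max(lengths(x))
  if (n == 1) {
    for (nm in names(x)) cat(sprintf("  %-12s %.4g\n", nm, x[[nm]]))
  } else {
    cat("  vectorized over", n, "subjects\n")
  }
  invisible(x)
}

#' Serialize / restore a parameter configuration
#'
#' Writes the structural parameters (and optionally covariate effects
#' and variability specification) to a flat key-value YAML or JSON
#' file, keyed by the field names of the respective constructors, and
#' reads such a file back.
#'
#' @param params An `rb_params` object.
#' @param path File path; the extension selects the dialect (`.yaml`/
#'   `.yml` or `.json`).
#' @param effects Optional `rb_effects` object stored under `effects`.
#' @return `read_params_config()` returns a list with `params` and
#'   (if present) `effects`.
#' @export
write_params_config <- function(params, path, effects = NULL) {
  obj <- list(params = lapply(unclass(params), function(x) unname(x)))
  if (!is.null(effects)) obj$effects <- unclass(effects)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_params_config
#' @export
read_params_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  out <- list(params = do.call(rb_structural_params, obj$params))
  if (!is.null(obj$effects)) {
    ef <- obj$effects
    out$effects <- rb_covariate_effects(
      lpvr_f_fold = ef$lpvr_f_fold,
      lpvr_cyp_inhibition = ef$lpvr_cyp_inhibition,
      lpvr_clmet_frac = ef$lpvr_clmet_frac,
      zwfa_f_per_unit = ef$zwfa_f_per_unit,
      age_ka_frac = ef$age_ka_frac,
      zwfa_form = ef$zwfa_form,
      allo_cl = ef$allo_cl, allo_v = ef$allo_v, wt_ref = ef$wt_ref)
  }
  out
}
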