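---
title: "Methods: the joint rifabutin / des-rifabutin population model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the joint rifabutin / des-rifabutin population model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it
implements: the structural and stochastic model, the estimation
machinery, the synthetic study generator, and the design choices made
where the design was genuinely open. It states no empirical result
that the test suite or `scripts/acceptance.R` do not themselves
compute.

## 1. Structural model

Five compartments: an absorption depot, central and peripheral
compartments for rifabutin (the parent), and central and peripheral
compartments for 25-O-desacetyl rifabutin (the metabolite). All
transfer is first order, so the system is linear and every
concentration is a sum of at most five exponential modes: the
absorption rate constant and the two hybrid rate constants of each
disposition block. The package computes these modes and their
partial-fraction coefficients in closed form (`R/pk_solution.R`,
mirrored by the C++ evaluator in `src/`), rather than integrating
ODEs; the test suite verifies the closed form against an independent
stiff ODE integration to a relative error below `1e-6`.

Rifabutin is eliminated by two parallel clearances, and this is the
scientific heart of the model: an *inhibitable CYP3A4 pathway*
(`cl_cyp_ref`, 13.6 L/h at the 10-kg reference) and a *conversion
clearance* to the metabolite via arylacetamide deacetylase
(`cl_conv_ref`, 16.2 L/h). The two pathways are ordinarily not
separately identifiable from parent-metabolite data; they become
identifiable here because lopinavir/ritonavir (LPV/r) co-treatment
switches the CYP3A4 pathway off while the study observes the same
children with and without LPV/r. The conversion flux is assumed to
transform 100% of its substrate into metabolite (the identifiability
convention of the final model), with molar correction
(847.02 → 805 g/mol) applied to that flux only; doses stay in mg and
concentrations in µg/L of the respective analyte.

Allometric scaling uses total body weight with fixed exponents, 0.75
for all clearances and 1.0 for all volumes, normalized to 10 kg.
Covariate effects are multiplicative on top of the scaled parameters
(the order allometry-then-covariates is documented but immaterial for
multiplicative terms):

| effect | parameter | value | form |
|---|---|---|---|
| LPV/r on bioavailability | `lpvr_f_fold` | ×2.58 | fold change |
| LPV/r on CYP3A4 pathway | `lpvr_cyp_inhibition` | 1 (fixed) | fraction removed |
| LPV/r on metabolite clearance | `lpvr_clmet_frac` | 0.234 | fraction remaining |
| severe underweight on F | `zwfa_f_per_unit` | 0.26/unit | power (below) |
| age ≤ 3 y on absorption | `age_ka_frac` | 0.277 | fraction remaining |

**Underweight effect.** The source analysis reports a 26% decrease in
bioavailability per weight-for-age z-score (ZWFA) unit below −3
without stating whether successive units act linearly or
multiplicatively. The package defaults to the power form
`F · (1 − 0.26)^(−3 − ZWFA)`, which guarantees positivity for the
most severely underweight children (ZWFA down to −5.15 occurs in this
population; the linear form would leave them with 44% of nothing to
spare and crosses zero at −6.85). The linear form is available via
`rb_covariate_effects(zwfa_form = "linear")`, truncated below at 0.01
so degenerate covariate values cannot produce non-positive
bioavailability.

## 2. Stochastic model

Between-subject variability (BSV) is lognormal with one random effect
*shared* by the two rifabutin clearance pathways (20.7% CV) — so the
pathway *split* is a fixed effect while the total varies — and an
independent effect on metabolite clearance (30.8%). Bioavailability
(71.9%), absorption rate (118%) and lag time (74.8%) vary between
occasions (BOV). Percent CVs convert to log-scale variances by
`ω² = log(1 + (CV/100)²)`, the same convention used for reporting.

Residual error is combined (additive + proportional) per analyte,
with residual variance evaluated at the *individual* prediction
(eta-epsilon interaction). Because both analytes are quantified from
one plasma sample, the two errors of a sample are correlated (0.282);
the likelihood treats each sample's pair as a bivariate normal.
Negative simulated concentrations are floored at zero before
censoring; the alternative (resampling) was considered and rejected
because it distorts the error distribution near the quantification
limit, where the censoring rule operates anyway.

**Occasions.** The study protocol defines visits (PK sampling days);
each visit is one occasion, and all doses leading into a visit share
that occasion's bioavailability, absorption rate and lag time. The
protocol does not define occasion boundaries more finely, and no
information in the data could separate within-visit dose-to-dose
variation.

## 3. Steady-state representation and the reset rule

Visit-day profiles are modeled at steady state under the occasion's
regimen (dose records carry `SS = 1`, `II = 24`): every intensive
visit follows at least two weeks of once-daily dosing on the same
regimen. Carry-over across the regimen switch (week-2 TB-only visit →
week-4 LPV/r visit) is not simulated and not fitted; the generator
and the estimator make the same assumption, and the thrice-weekly
validation design — where steady-state periodicity does not hold — is
generated from its explicit six-dose history instead. For real data
this is an approximation around the switch; its main observable
failure mode (troughs far below what steady state implies) is exactly
what the reset rule addresses.

**Reset rule.** Whenever a profile's pre-dose rifabutin concentration
falls below one third of its 24-h concentration, the dosing history
is disregarded: the disposition compartments are initialized from the
observed pre-dose concentrations of both analytes, with peripheral
compartments at the equilibrium ratio `Vp/Vc` (the steady-state
proportionality), and the visit-day dose is superimposed. The original
description initializes "all disposition compartments using the
observed concentration values and the residual unexplained
variability" with details in an unavailable supplement; this package
provides two readings: the default keeps the pre-dose observation in
the likelihood (it then contributes essentially its variance terms),
and `rb_model_config(b2 = "exclude_predose")` drops it from the fit so
the observation is not used twice. The rule is applied on the
rifabutin analyte; flagged occasions reset both analytes.

The synthetic-data generator exercises this machinery with a
nonadherence injector: by default 15% of intensive occasions miss
their last 2–4 daily doses (the prevalence matching the roughly one
in six profiles with implausibly low troughs reported for this
population), computed in closed form as the steady-state solution
minus the contributions of the missed doses.

## 4. Censored observations

Samples below the lower limit of quantification (3.91 µg/L rifabutin,
0.780 µg/L des-rifabutin; values exactly at the limit are
quantifiable) are handled by a variant of Beal's M6: per analyte and
per post-dose profile, the last BLQ sample during absorption and the
first during elimination are imputed at LLOQ/2 with the additive
error standard deviation inflated by LLOQ/2; all other BLQ samples
are excluded from the fit but kept for diagnostics. The
absorption/elimination split needs a peak time before any fit exists,
so it uses the *typical* (zero-eta) predicted time of maximum
concentration for that subject-occasion on a 0.25-h grid — an
operational reading of "individual predicted Tmax" that is available
at preprocessing time and differs from the post hoc individual Tmax
only through the occasion's absorption etas.

## 5. Estimation

The marginal likelihood is approximated subject by subject with a
Laplace approximation: the joint −2 log-likelihood `h(η)` (residual
terms plus lognormal prior, all normalizing constants included) is
minimized over the subject's random effects, and the curvature at the
mode supplies the Gaussian integral. Two curvature options exist:

* `"fd"` (default): the exact central-difference Hessian of `h` —
  the same curvature the oracle test uses when comparing the Laplace
  objective against adaptive quadrature on a one-random-effect model
  (agreement required within 0.1 objective units);
* `"gn"`: a Gauss-Newton Hessian `J'V⁻¹J + Ω⁻¹` built from the
  finite-difference Jacobian of the predictions, with `V` evaluated
  at the individual prediction — the classical FOCE-I-style
  approximation. It is cheaper but its curvature *decreases* as the
  residual variance grows, which feeds back through the Laplace
  log-determinant and inflates the estimated variance terms (and,
  through them, several structural parameters) by tens of percent in
  replicate-study experiments; that is why it is not the default.

The inner problem is solved by a damped (Levenberg-Marquardt) Newton
iteration with warm starts carried between outer evaluations. The
objective is multimodal in the lag-time effects (the periodic
steady-state wrap makes `h` discontinuous where the shifted sampling
time crosses a dose boundary), so cold starts are preceded by a
conservative multi-start quasi-Newton descent (from zero and from
shifted absorption-rate and lag effects), and a gradient check
triggers a fallback refinement whenever the Newton path stalls. Inner
tolerance is `1e-6` (step) with a `1e-5` gradient target.

The outer problem maximizes over log- or logit-transformed population
parameters with a trust-region quasi-Newton optimizer fed an explicit
central-difference gradient (step `1e-3` on the transformed scale —
the objective carries warm-start noise of order `1e-4`, so
machine-epsilon differencing would return noise). The optimizer is
restarted from its own solution until the objective improves by less
than 0.1; each restart rebuilds the curvature model and reliably
escapes the premature "false convergence" declarations that the noise
floor provokes. The per-subject evaluator is implemented twice — a
documented R reference and a C++ version used in the optimization
loops — and the tests require them to agree to ~1e-9.

**Sequential strategy.** Model development was sequential and the
default fit mirrors it: the rifabutin submodel is estimated on the
parent observations alone, then the des-rifabutin side (clearance,
volumes, LPV/r effect, BSV, residual terms, cross-analyte correlation)
is estimated with the parent fixed effects held fixed while all
random effects are re-conditioned on both analytes. A final `"joint"`
stage re-estimating everything together is available but off by
default; on replicate-study-sized data it mainly re-polishes the
parent parameters at several times the cost. Initial values default
to the published typical values; `perturb_init()` displaces them by
random factors in `[0.5, 2]` so that recovery exercises are not
trivial self-recoveries, and the analysis scripts and acceptance runs
always use it.

The objective function value is the full −2 log marginal likelihood,
*including* `log(2π)` constants (some software omits them; only
differences matter for inference). Likelihood-ratio tests use the
conventional thresholds — 3.84 points for one degree of freedom at
P < 0.05 on forward addition, 6.63 at P < 0.01 on backward
elimination — and non-nested comparisons fall back to AIC.

## 6. The synthetic study generator

`make_study_dataset()` reproduces the statistical structure of the
three-cohort design: 3 infants under 1 year (20 mg/kg/day TB-only for
two weeks, then 5 mg/kg/day with LPV/r; intensive visits at weeks 2,
4, 6), 10 children aged 1–3 years (20 → 2.5 mg/kg/day; intensive
weeks 2 and 4, sparse weeks 6 and 12 with a pre-dose sample plus one
at 3–5 h or 24–26 h), and 15 ART-experienced children aged 3–15 years
(2.5 mg/kg/day with LPV/r throughout; intensive weeks 2, 4, 8).
Intensive sampling is at 0, 2, 4, 8, 12 and 24 h post-dose. The
protocol's "15–20 mg/kg" TB-only dose for the middle cohort defaults
to 20 mg/kg (configurable). Cohort covariates are drawn from scaled
beta (weight) and truncated normal (z-score) distributions calibrated
to the published cohort medians and ranges; about 60% of generated
children are severely underweight, as in the study, which is what
makes the underweight effect estimable from a replicate. A virtual
simulation population (`make_virtual_population()`) provides uniform
per-kg weights with ages from a synthetic growth-reference lookup and
a Normal(−1, 1) z-score distribution truncated to [−5, 2], keeping
severe underweight below 3% so that band medians are essentially
unaffected by the underweight effect.

What the generator does *not* emulate: real adherence patterns beyond
the missed-dose injector, assay drift, sampling-time deviations,
demographic correlation between weight, age and z-score, enzyme
maturation, and any exposure-toxicity relationship. Passing recovery
tests therefore demonstrates that the estimator inverts the model the
generator uses — internal consistency at realistic design, size and
noise — not that the model is right for new clinical data.

## 7. Dosing simulations and weight-band optimization

Steady-state AUC(0–24 h) and Cmax are computed analytically per child
(AUC exactly, Cmax as the maximum on a 0.05-h grid over the dosing
interval — the package's Cmax convention; whether the source's Cmax
was a model maximum or an observed-sample maximum is unstated).
Simulations draw between-subject effects plus a single occasion's
between-occasion effects per child, so the median exposure of the
population equals the typical value (lognormal median property, a
tested invariant). Study scenarios: 20 mg/kg/day capped at the 300-mg
adult dose without LPV/r, and 2.5 and 5 mg/kg/day with LPV/r, each
over 500 children per kg across 6–45 kg. (The published in-silico
population of 22,500 children at 500/kg implies a 45-kg-wide range;
the simulated bands span 6–45 kg — 39 bins — and the range is left
configurable since the discrepancy cannot be resolved from the
source.)

**Optimization objective.** The source states the aim of weight-band
dose optimization as achieving a median steady-state AUC of at least
4,500 µg·h/L (the acquired-rifamycin-resistance floor) while keeping
median Cmax under 900 µg/L; it does not state a formal selection
criterion. Back-computing the published band tables from the final
model shows them consistent with the *smallest 5-mg grid dose whose
band-median rifabutin AUC reaches the floor*, in both treatment
contexts (11 of 14 published entries match exactly, the rest within
one grid step under simulation noise; the ≥25–<30 kg TB-only entry
prints as the 300-mg cap where the floor criterion computes 290 mg).
That floor rule is the default objective. The alternative sometimes
assumed — matching the geometric midpoint of the adult reference
window — is implemented as `objective = "midpoint"`, but it
reproduces the published LPV/r table strictly worse (e.g. 45 mg
instead of 35 mg at 10–15 kg), which is why it is not the default.
Ties break to the lower dose; by linearity of exposures in dose, each
band draws one set of per-child unit exposures and scales them across
the grid, making the selection exactly invariant to grid enumeration
and cheap enough for dense grids.

Band medians are computed over all children in the band (uniform
per-kg weighting); per-kg summaries with 5th–95th percentile whiskers
are reported alongside. A 500-per-kg band median of a lognormal
exposure distribution has a sampling coefficient of variation near
4%, so optimized doses are reproducible across seeds only to about
one 5-mg grid step, and per-kg excess percentages carry a few points
of seed-to-seed variation; the package's own convergence test uses a
7% band for the 500-per-kg median for exactly this reason.

## 8. Diagnostics

The prediction-corrected VPC bins observations on time after dose
into quantile-based bins (default 8; the source shows bins as ticks
without stating the rule), corrects each value by
`median(PRED in bin) / PRED`, and compares observed 10th/50th/90th
percentiles with 95% bands from replicate simulations under the
fitted model with the original design (default 200 replicates or
more; a single replicate degenerately collapses the bands and is
tested as such). Panels are stratified by analyte and LPV/r status.
Geometric mean ratios pair each subject's occasions with LPV/r
against those without, on the log scale with a t-based interval — the
within-patient comparison. The observed-data GMRs reported for the
clinical cohort are patient-data quantities; the package reproduces
the computation, not those numbers.

## 9. Problem sizes and numerical hygiene

The shipped analyses use: 28 subjects (≈480 plasma samples × 2
analytes) for the replicate study; one sequential fit from perturbed
starts for the recovery checks, plus ten full-design replicates of
the rifabutin submodel for the bias suite (the metabolite side is
covered by the single-replicate interval checks); 500 children per kg for dosing simulations; 150–300 VPC
replicates. These sizes were chosen to match the study design and to
keep each stage's Monte Carlo error visibly smaller than the
tolerances asserted on it.

Degenerate inputs are handled explicitly: coincident exponential
rates (a measure-zero configuration) are separated by one part in
10⁷ before partial fractions; non-finite or non-positive parameter
excursions during optimization return a large penalty instead of
propagating NaN; Cholesky failures of the Laplace curvature add a
ridge and are reported, never silently absorbed. Every stochastic
entry point takes an explicit seed.

**A documented bias.** Across the ten-replicate recovery suite the
median relative bias of every typical value stays within a few
percent except the absorption rate constant, which runs 10–20% high.
The effect disappears when the between-occasion variability on the
absorption rate (118% CV, the largest random effect in the model) is
switched off in both generator and fit, identifying it as the
familiar small-sample bias of Laplace-type marginal likelihoods under
very large random-effect variances combined with a first sample at
2 h post-dose — not as an implementation defect (the noise-free
recovery is exact to <1%). The recovery suite asserts the 15% bound
for every parameter and is expected to flag the absorption rate; the
result is reported rather than hidden.

## 10. Known limitations

* Steady-state occasion representation: no carry-over across regimen
  switches (Section 3); appropriate for the design simulated here,
  an approximation for real switching data.
* No parameter-uncertainty machinery (no sampling-importance
  resampling, no covariance step); confidence statements about
  estimates come from the recovery suites, not from per-fit standard
  errors.
* No enzyme maturation, auto-induction, transit-compartment
  absorption, or nonlinear elimination; the validation cohort's
  thrice-weekly design is generated but not fitted by default.
* The estimator's objective carries warm-start noise of order 1e-4,
  which bounds how sharply the outer optimizer can resolve the
  optimum; the restart strategy makes the practical resolution much
  finer than the printed precision of any reported estimate.
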