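---
title: "Validating early liver allograft function scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating early liver allograft function scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

After orthotopic liver transplantation, the first post-operative week of
laboratory values — transaminases (AST, ALT), total bilirubin (TBIL), INR
and platelets (PLT) — carries most of the prognostic signal about whether
the graft will survive. Several competing summaries of that signal are in
clinical use:

* **EAD** (Olthoff): a dichotomous flag — TBIL ≥ 10 mg/dL on POD 7,
  INR ≥ 1.6 on POD 7, or ALT/AST > 2,000 IU/L (strict) in the first week.
* **MEAF**: the sum of three logistic sigmoids of ln-transformed labs,
  `amplitude / (1 + exp(-steepness · (ln x − midpoint)))`, applied to the
  POD 1–3 maxima of ALT and INR and the POD-3 bilirubin. Amplitudes
  3.29, 3.29 and 3.4 bound the total at 9.98.
* **L-GrAFT7 / L-GrAFT10**: polynomials in trajectory features — areas
  under the curve (AUC) and least-squares slopes of ln-lab values over the
  first 7 or 10 days — with published coefficients and risk bins.
* **EASE**: a score mixing peritransplant covariates (MELD at transplant,
  packed-RBC units, early hepatic-vessel thrombosis, center volume) with
  trajectory features on sparse POD subsets (AST on days 1,2,3,7,10;
  PLT and bilirubin on days 1,3,7,10).

`graftscores` implements all five with the published coefficients (never
re-fitted), the published risk-group bins, and the validation machinery a
comparison study needs: fixed-horizon endpoints (90/180/365 days, graft
and patient survival), AUROC with DeLong variance and the paired DeLong
test, Kaplan–Meier curves with log-rank tests by risk class, and a
univariable-screen → multicollinearity-filter → multivariable-logistic
pipeline for risk factors of the L-GrAFT7 high-risk class.

The clinical cohorts such studies use are not publicly available, so the
package ships a seeded synthetic cohort generator that reproduces the
*statistical structure* the analysis assumes. Everything downstream of the
generator is real code under real tests; only the patients are synthetic.

## Trajectory features: the numerical conventions

The original L-GrAFT derivation does not publish its feature-construction
details, so the following conventions are this package's own explicit,
configurable choices.

**AUC is the unnormalized trapezoid** of the (log) value against POD over
the model's window. The decisive argument: the L-GrAFT7 quadratic in
AUC ln AST has its vertex at `0.5799 / (2 · 0.00844) ≈ 34.4`, which is
only a plausible center for a 7-day *integral* of ln AST (typical values
20–45), not for a time-averaged mean (3–7). A `normalized = TRUE` switch
(`auc_normalized` in the pipeline) provides the time-averaged alternative
because the published phrase "measures the average" is ambiguous.

**Gaps.** Missing interior days are bridged by the trapezoid itself
(linear interpolation between observed neighbours). Missing *endpoints* of
the window rescale the observed-span area by `full span / observed span`,
keeping magnitudes comparable for patients whose POD 8–10 labs are sparse.
On an exactly log-linear series these conventions reproduce the exact
integral regardless of which days are observed.

**Slope** is the ordinary least-squares slope of the transformed value on
POD over the same window (and POD subset) as the AUC — the simplest
estimator consistent with "slope". Under the log transform it is invariant
to rescaling the raw series; the AUC shifts by `span · ln k`, and both
invariants are property-tested.

**Reading the formulas literally.** In L-GrAFT7 the INR term is
`ln(AUC INR)` — a raw-scale AUC subsequently logged — while AST, TBIL and
PLT contribute AUCs *of* ln values. In L-GrAFT10 the INR term is the log
of the 10-day *maximum*, the AST slope is taken over days 1–7 only, the
TBIL slope enters linearly (no squared term), and the PLT slope enters
both linearly and squared. In EASE the AST term is the *square* of
AUC ln AST (coefficient 0.000534). The package evaluates each printed
term exactly, in double precision, with no internal rounding.

**Coverage rule.** A model's features count as computable when every
needed analyte has ≥ 3 observations in the (subset-restricted) window,
at least one in the first two window days and one in the last three;
MEAF additionally requires the POD-3 bilirubin exactly (no nearest-day
fallback — the package signals insufficiency instead of guessing), and
EAD requires the POD-7 bilirubin and INR. Note that under this rule the
EASE features need POD 10 itself, since day 10 is the only subset day in
the window tail — which is exactly why sparse POD 8–10 sampling hurts the
10-day models first.

## Risk-group binning

The printed bins differ in closure convention: MEAF bins are right-closed
(`2 < score ≤ 5`), L-GrAFT bins left-closed (`−1.5 ≤ score < −0.5`).
The printed EASE bounds are two-decimal numbers that leave 0.01-wide gaps
(…≤ −1.26, then −1.25 ≤ …); scores are therefore rounded to 2 decimals
before binning, which turns the printed list into a partition. Scores
beyond the terminal printed bounds (possible for extreme trajectories)
clamp to the terminal group with a warning, since no overflow behaviour is
published. L-GrAFT7 groups 4–7 form the high-risk class.

## Endpoints, censoring and discrimination

Graft loss is retransplantation or death, whichever first; the patient
endpoint counts death only. For the binary horizon endpoints, patients
censored before the horizon without an event are **excluded** by default —
the treatment a validation study cannot avoid deciding, yet rarely states.
`censored_as_survivor = TRUE` implements the optimistic alternative; both
are exposed because neither can be verified against the published design.

AUROC uses the Mann–Whitney estimator with midranks, which admits the
dichotomous EAD flag as a degenerate score (its "AUROC" is then the
standard balanced accuracy of the flag). Variance and the paired test
follow DeLong's structural components: placement values are computed by
midranks in `O(N log N)`, the paired variance uses the event- and
survivor-side covariance matrices of the two scores' components, and
p-values are two-sided normal. Pairwise comparisons are reported without
multiplicity correction, matching the presentation style of validation
studies; a Holm option exists, off by default. Model comparisons run on
the complete-case subset across the models being compared.

Kaplan–Meier estimation and the log-rank test wrap the `survival` package
(the de-facto reference implementation); the test suite checks both
against independent hand-computed product-limit and observed-vs-expected
oracles, so the wrapper's contract — not the dependency's reputation — is
what is verified.

## Risk-factor analysis

The screen fits one non-conditional univariable logistic model per
candidate; categorical variables are reference-coded with an overall
likelihood-ratio p. Candidates with p < 0.1 (configurable) pass to a
greedy multicollinearity filter: within any continuous pair with
|Pearson r| > 0.7 or categorical pair with Cramér's V > 0.7 the
later-listed variable is dropped. The 0.7 threshold is this package's
assumption — published analyses state only that collinear variables were
excluded. Mixed continuous/categorical pairs are not tested; listing
order is therefore part of the analysis specification, and the pipeline
is deterministic given data and ordering. Continuous variables enter the
multivariable fit untransformed (published per-unit ORs such as 1.020 per
MELD point and 1.002 per CIT minute imply per-unit coding). Odds ratios
and CIs are exact transforms `exp(b)`, `exp(b ± 1.96·SE)` of the ML
coefficients.

## The synthetic world

One latent severity `z` per patient — a weighted sum of standardized MELD
and cold ischemia time plus unit Gaussian noise — drives everything:

* **Trajectories** are log-linear in POD with lognormal noise (sd 0.25):
  AST decays from a reperfusion peak (severity raises the peak and slows
  the decay), TBIL's trend flips from recovery to cholestasis as severity
  grows, INR sits near 1.3 with severity-scaled elevation, and PLT dips
  around POD 3 and recovers at a severity-dependent rate. These are the
  *minimal* dynamics that make AUC and slope features informative — not a
  physiologic model, and no pharmacokinetics are attempted.
* **Outcomes**: the 90-day failure probability is
  `plogis(intercept + coef · z)` (defaults −3.8 and 1.2, giving ≈ 5–7%
  90-day graft failure as in large-center cohorts); the event time is
  exponential with the rate matched to that probability, a 15% share of
  failures are retransplants, and censoring is uniform on 30–1500 days
  (median follow-up ≈ 2 years). The exponential tail makes 12-month
  failure slightly heavier than real cohorts report — a known, accepted
  simplification.
* **Missingness**: each of PODs 8–10 is unobserved with probability 0.4,
  emulating centers that do not draw daily labs after the first week; labs
  stop at early death/retransplant, which is what makes some patients
  genuinely unscorable and exercises the "insufficient labs" exclusion.
* **Severity effect sizes** on the trajectories were fixed once so that
  roughly a fifth of eligible patients land in the L-GrAFT7 high-risk
  class — the documented tuning target mirroring the 150/677 split of the
  motivating cohort — and are not revisited per analysis.
* **Reproducibility**: every patient has an independent substream seeded
  from `(seed, patient index)`, so patient *i* is identical whatever `n`
  is, and the same `(config, seed)` reproduces the cohort byte for byte.

What a green test on this world establishes: the formulas, windows, bins,
endpoint logic, estimators and pipeline plumbing are wired correctly, and
the estimators are statistically calibrated (type-I error, CI coverage,
null AUROC ≈ 0.5). What it does **not** establish: the clinical AUROC
levels or odds ratios of any real cohort — those depend on data this
package cannot ship. One calibration detail: the null-AUROC check switches
the severity–outcome coefficient to zero *and* raises the outcome
intercept to 0 (≈ 50% event rate), because at the realistic 2% event rate
a 2,000-patient null AUROC has standard error ≈ 0.075 and a ±0.05 band
would be uninformative about correctness.

## Exclusions

The eligibility filter mirrors the standard single-center design:
recipients under 18, transplants for acute liver failure,
retransplantations, multivisceral/split/living-donor grafts, early
(< 14 day) vascular complications, and patients whose labs cannot support
score calculation. Each patient is tallied once, under the first matching
category in that order. By default "insufficient labs" means failing the
coverage rule for EAD, MEAF or L-GrAFT7; the 10-day models are *not*
required, because realistically sparse POD 8–10 sampling would otherwise
disqualify half the cohort — patients whose EASE/L-GrAFT10 scores cannot
be computed simply carry NA for those models (`require_models`
configures this).

## Known limitations

* The L-GrAFT feature-construction conventions (AUC normalization, slope
  estimator, gap handling) are reverse-engineered assumptions, explicit
  and configurable, but not author-confirmed.
* The generator's covariates are mutually independent given severity;
  real casemix correlations (e.g. MELD with pre-op bilirubin and INR) are
  only partially represented, so the risk-factor stage demonstrates
  machinery, not epidemiology.
* No Cox modelling, competing risks, optimal cut-points or
  recalibration; scores are used exactly as published.
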