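# graftscores

Early liver allograft function scores and the machinery to validate them.

After an orthotopic liver transplant, the first week of laboratory values
(AST, ALT, total bilirubin, INR, platelets) predicts graft and patient
survival. Five competing summaries of that signal are in clinical use, and
`graftscores` implements all of them with their published coefficients:

* **EAD** (Olthoff) — dichotomous: TBIL ≥ 10 mg/dL on POD 7, INR ≥ 1.6 on
  POD 7, or ALT/AST > 2,000 IU/L within the first 7 days;
* **MEAF** — sum of three sigmoids of ln-labs,
  `A / (1 + e^{−k(ln x − m)})`, bounded by the amplitude sum 9.98;
* **L-GrAFT7 / L-GrAFT10** — polynomials in AUC and slope features of
  ln-lab trajectories over PODs 1–7 / 1–10 (e.g. L-GrAFT7 =
  6.9647 − 0.5799·AUClnAST + 0.00844·AUClnAST² + … − 0.05115·AUClnPLT),
  with 7 and 5 published risk groups;
* **EASE** — −0.602 + 0.044·MELD + 0.065·RBC units + 2.567·thrombosis +
  0.000534·(AUC lnAST)² − 0.093·AUC lnPLT − 7.766·slope lnPLT +
  0.795·slope lnTBIL − 0.402·high-volume-center, on sparse POD subsets.

Around the scores sits the full validation workflow of a comparison study:
eligibility exclusions, trajectory feature extraction (trapezoid AUC with
gap handling, OLS slopes), risk-group binning, 90/180/365-day graft and
patient endpoints, AUROC with DeLong variance, the paired DeLong test for
correlated AUROCs, Kaplan–Meier / log-rank by risk class, and a
univariable screen → collinearity filter → multivariable logistic
risk-factor analysis. Because the clinical cohorts behind such studies are
not public, a seeded synthetic cohort generator reproduces the statistical
structure the analysis assumes (severity-linked trajectories and outcomes,
POD 8–10 missingness, early-death lab truncation), making every stage
testable end to end.

Intended users: transplant outcomes researchers validating or comparing
early-graft-function definitions, and biostatisticians who need the
scores' exact printed conventions (windows, POD subsets, bin closures)
without re-deriving them from four different original papers.

## Worked example

```r
library(graftscores)

cfg    <- synthetic_config(n = 800, seed = 7)
cohort <- generate_cohort(cfg)

ex <- apply_exclusions(cohort)
ex$tally
#>                    age_lt18         acute_liver_failure
#>                          22                          20
#>           retransplantation               multivisceral
#>                          14                          16
#>                       split                living_donor
#>                           9                           1
#> early_vascular_complication           insufficient_labs
#>                          24                           2

scores <- score_cohort(ex$cohort)
mean(scores$lgraft7_high, na.rm = TRUE)   # fraction in the high-risk class
#> [1] 0.236

labels <- derive_labels(ex$cohort$outcomes, horizon = 90, endpoint = "graft")
cmp <- compare_all_models(scores, labels)
cmp$auroc
#>      model auroc ci_low ci_high   n
#> 1 lgraft10 0.685  0.556   0.814 391
#> 2  lgraft7 0.707  0.583   0.830 391
#> 3     ease 0.780  0.693   0.867 391
#> 4     meaf 0.723  0.623   0.822 391
#> 5      ead 0.663  0.548   0.778 391
head(cmp$pairwise, 3)
#>    model_a model_b      p
#> 1 lgraft10 lgraft7 0.0491
#> 2 lgraft10    ease 0.0173
#> 3 lgraft10    meaf 0.2061
```

The AUROC table is the 90-day graft-survival discrimination of each score
on the complete-case subset (n = 391 here: patients with all five scores
computable and not censored before day 90); `pairwise` holds the paired
DeLong p-values for each model pair on the same patients. On this
synthetic draw the scores separate failures from survivors well above
chance but below the ≈ 0.87 reported for real cohorts — the generator is
deliberately a structural stand-in, not a clinical calibration.

Single calls work too: a patient with constant labs at the three MEAF
sigmoid midpoints scores exactly half of each amplitude,

```r
meaf_score(exp(6.1723), exp(0.6658), exp(1.0607))$score
#> [1] 4.99
```

The whole study runs in one call (`run_study(cohort, out_dir = "out")`)
or from the command line:

```sh
Rscript inst/cli/graftscores.R run-all --simulate --n 800 --seed 7 --out out/
```

which writes `exclusions.csv`, `scores.csv`, the AUROC and pairwise
comparison tables, Kaplan–Meier tables per risk class and the risk-factor
tables, plus a JSON echo of the configuration.

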