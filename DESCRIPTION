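Package: graftscores
Title: Early Liver Allograft Function Scores and Survival Validation
Version: 0.1.0
Authors@R:
    person("Graft", "Scores Maintainers", email = "maintainers@graftscores.org",
           role = c("aut", "cre"))
Description: Computes the established early liver allograft function scores
    (Olthoff EAD, MEAF, L-GrAFT7, L-GrAFT10 and EASE) from post-operative
    laboratory trajectories, assigns the published risk groups, and provides
    the validation machinery used to compare them: horizon endpoints for graft
    and patient survival, Kaplan-Meier curves and log-rank tests by risk
    class, AUROC with DeLong variance and paired DeLong tests, and a
    univariable screen plus multivariable logistic regression for risk-factor
    analysis. A seeded synthetic post-transplant cohort generator emulates the
    statistical structure such studies assume, so the whole pipeline is
    testable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
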