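# End-to-end driver: exclusions -> features -> scores -> endpoints ->
# AUROC/DeLong table -> KM by risk class -> risk-factor tables.

#' Run the full validation study
#'
#' Reproduces the analysis shape of an early-allograft-function validation:
#' eligibility filter, the five scores, fixed-horizon graft/patient
#' endpoints with AUROC and pairwise DeLong comparisons, Kaplan-Meier
#' tables by risk class, and the risk-factor screen plus multivariable
#' logistic fit for the L-GrAFT7 high-risk group. All artifacts are written
#' as CSV under `out_dir` together with a JSON echo of the configuration;
#' the run is a pure function of (inputs, config, seed).
#'
#' @param cohort a `graft_cohort` (e.g. from [read_cohort()] or
#'   [generate_cohort()]).
#' @param out_dir output directory, created if missing. `NULL` skips all
#'   file output.
#' @param horizons subset of c(90, 180, 365) days.
#' @param endpoints subset of c("graft", "patient").
#' @param models score models to validate.
#' @param require_models models whose lab coverage defines the
#'   insufficient-labs exclusion (see [apply_exclusions()]).
#' @param censored_as_survivor see [derive_labels()].
#' @param auc_normalized time-averaged AUC features (see [trapezoid_auc()]).
#' @param screen_p univariable screen threshold for the risk-factor step.
#' @param risk_factor_vars clinical columns screened as risk factors.
#' @param seed recorded in the config echo (the analysis itself is
#'   deterministic).
#' @return list: exclusions, scores, validation (auroc + pairwise, long
#'   format), km (per model x endpoint), risk_factors.
#' @export
run_study <- function(cohort, out_dir = NULL,
                      horizons = c(90, 180, 365),
                      endpoints = c("graft", "patient"),
                      models = c("lgraft10", "lgraft7", "ease", "meaf",
                                 "ead"),
                      require_models = c("ead", "meaf", "lgraft7"),
                      censored_as_survivor = FALSE,
                      auc_normalized = FALSE,
                      screen_p = 0.1,
                      risk_factor_vars = c(
                        "recipient_age", "recipient_male", "recipient_bmi",
                        "diagnosis", "meld", "crea_umol_l",
                        "tbil_preop_umol_l", "inr_preop", "child_pugh",
                        "donor_age", "donor_male", "donor_bmi",
                        "donation_category", "dri", "anhepatic_min",
                        "cit_min", "operation_min", "rbc_units",
                        "ffp_units", "hemorrhage_ml"),
                      seed = NULL) {
  stopifnot(all(horizons %in% c(90, 180, 365)),
            all(endpoints %in% c("graft", "patient")))

  ex <- apply_exclusions(cohort, require_models = require_models)
  cohort <- ex$cohort
  scores <- score_cohort(cohort, normalized = auc_normalized)

  auroc_tab <- NULL
  pairwise_tab <- NULL
  for (ep in endpoints) for (h in horizons) {
    labels <- derive_labels(cohort$outcomes, h, ep,
                            censored_as_survivor = censored_as_survivor)
    cmp <- tryCatch(
      compare_all_models(scores, labels, models = models),
      error = function(e) {
        warning(sprintf("%s %d-day comparison skipped: %s", ep, h,
                        conditionMessage(e)))
        NULL
      })
    if (is.null(cmp)) next
    auroc_tab <- rbind(auroc_tab,
                       cbind(endpoint = ep, horizon = h, cmp$auroc))
    pairwise_tab <- rbind(pairwise_tab,
                          cbind(endpoint = ep, horizon = h, cmp$pairwise))
  }

  km <- list()
  for (ep in endpoints)
    for (mod in intersect(models, c("lgraft10", "lgraft7", "ease", "meaf",
                                    "ead")))
      km[[paste(mod, ep, sep = "_")]] <-
        tryCatch(km_by_risk_class(cohort, scores, mod, ep),
                 error = function(e) NULL)

  rf <- NULL
  if ("lgraft7" %in% models) {
    target <- scores$lgraft7_high
    vars <- intersect(risk_factor_vars, names(cohort$clinical))
    ok <- !is.na(target)
    if (length(vars) && sum(ok) > 20 && length(unique(target[ok])) == 2)
      rf <- risk_factor_analysis(cohort$clinical[ok, , drop = FALSE],
                                 target[ok], vars, screen_p = screen_p)
  }

  result <- list(exclusions = ex$tally, scores = scores,
                 validation = list(auroc = auroc_tab,
                                   pairwise = pairwise_tab),
                 km = km, risk_factors = rf)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(df, f) if (!is.null(df))
      utils::write.csv(df, file.path(out_dir, f), row.names = FALSE)
    w(data.frame(category = names(ex$tally), excluded = as.integer(ex$tally)),
      "exclusions.csv")
    w(scores, "scores.csv")
    w(auroc_tab, "auroc.csv")
    w(pairwise_tab, "pairwise.csv")
    for (nm in names(km)) if (!is.null(km[[nm]]))
      w(km[[nm]]$curves, paste0("km_", nm, ".csv"))
    if (!is.null(rf)) {
      w(rf$screen, "risk_factors_univariable.csv")
      if (!is.null(rf$fit)) w(rf$fit$table, "risk_factors_multivariable.csv")
    }
    cfg <- list(horizons = horizons, endpoints = endpoints, models = models,
                censored_as_survivor = censored_as_survivor,
                auc_normalized = auc_normalized, screen_p = screen_p,
                seed = seed, n_input = nrow(scores) + sum(ex$tally),
                n_analyzed = nrow(scores))
    jsonlite::write_json(cfg, file.path(out_dir, "run_config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}
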