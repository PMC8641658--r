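# The five early allograft function scores and their published risk groups.
#
# All coefficients below are the published ones; they are never re-fitted.
# Scores are evaluated in double precision with no internal rounding, except
# the 2-decimal rounding the EASE bin table requires (its printed bounds are
# 2-dp and leave 0.01-wide gaps otherwise).

# ---- EAD (Olthoff) ---------------------------------------------------------

#' Classify early allograft dysfunction (Olthoff criteria)
#'
#' EAD is positive when any of the following holds: total bilirubin
#' >= 10 mg/dL on POD 7, INR >= 1.6 on POD 7, or ALT or AST > 2,000 IU/L
#' (strict) within the first 7 days. Boundary semantics are exactly the
#' printed ones: inclusive for bilirubin and INR, strict for transaminases.
#'
#' @param labs data.frame with columns pod, analyte, value (canonical units).
#' @return list with `ead` (logical, NA when POD-7 bilirubin or INR is
#'   missing), per-criterion flags `criteria`, and `sufficient`.
#' @export
classify_ead <- function(labs) {
  fx <- extract_features(labs, "ead")
  f <- fx$features
  if (is.na(f[["tbil_pod7"]]) || is.na(f[["inr_pod7"]]))
    return(list(ead = NA, criteria = c(bilirubin = NA, inr = NA,
                                       transaminase = NA),
                sufficient = FALSE))
  tmax <- suppressWarnings(max(f[["alt_max_7"]], f[["ast_max_7"]],
                               na.rm = TRUE))
  crit <- c(bilirubin    = f[["tbil_pod7"]] >= 10,
            inr          = f[["inr_pod7"]] >= 1.6,
            transaminase = is.finite(tmax) && tmax > 2000)
  list(ead = any(crit), criteria = crit, sufficient = fx$sufficient)
}

# ---- MEAF ------------------------------------------------------------------

# amplitude / (1 + exp(-steepness * (ln x - midpoint)))
MEAF_PARAMS <- list(
  alt  = c(amplitude = 3.29, steepness = 1.9132, midpoint = 6.1723),
  inr  = c(amplitude = 3.29, steepness = 6.8204, midpoint = 0.6658),
  bili = c(amplitude = 3.40, steepness = 1.8005, midpoint = 1.0607)
)

meaf_component <- function(x, p) {
  p[["amplitude"]] / (1 + exp(-p[["steepness"]] * (log(x) - p[["midpoint"]])))
}

#' Model for Early Allograft Function (MEAF) score
#'
#' Sum of three sigmoid transforms of the maximum ALT and INR over PODs 1-3
#' and the POD-3 total bilirubin (mg/dL). Each component is bounded by its
#' amplitude, so the total lies in (0, 9.98].
#'
#' @param alt_max_3pod maximum ALT over PODs 1-3, IU/L.
#' @param inr_max_3pod maximum INR over PODs 1-3.
#' @param bilirubin_pod3 total bilirubin at POD 3, mg/dL.
#' @return list with `score`, the three `components`, and `group` (1-5).
#' @export
meaf_score <- function(alt_max_3pod, inr_max_3pod, bilirubin_pod3) {
  if (any(c(alt_max_3pod, inr_max_3pod, bilirubin_pod3) <= 0))
    stop("MEAF inputs must be strictly positive")
  comp <- c(alt  = meaf_component(alt_max_3pod,  MEAF_PARAMS$alt),
            inr  = meaf_component(inr_max_3pod,  MEAF_PARAMS$inr),
            bili = meaf_component(bilirubin_pod3, MEAF_PARAMS$bili))
  s <- sum(comp)
  list(score = s, components = comp,
       group = assign_risk_group(s, "meaf")$group)
}

# ---- L-GrAFT ---------------------------------------------------------------

#' L-GrAFT 7-day linear predictor
#'
#' Published 11-term polynomial in six trajectory features over PODs 1-7:
#' AUC and slope of ln AST, raw-scale AUC of INR (entering through its log),
#' AUC and slope of ln TBIL, and AUC of ln platelets.
#'
#' @param features named numeric vector with `auc_ln_ast`, `slope_ln_ast`,
#'   `auc_inr` (> 0), `auc_ln_tbil`, `slope_ln_tbil`, `auc_ln_plt`.
#' @return The score (numeric scalar).
#' @export
lgraft7_score <- function(features) {
  f <- as.list(features)
  if (f$auc_inr <= 0) stop("AUC INR must be positive (its log is taken)")
  6.9647 -
    0.5799  * f$auc_ln_ast + 0.00844 * f$auc_ln_ast^2 +
    5.25347 * f$slope_ln_ast + 4.65046 * f$slope_ln_ast^2 +
    1.14098 * log(f$auc_inr) -
    0.03475 * f$auc_ln_tbil + 0.00562 * f$auc_ln_tbil^2 +
    4.31135 * f$slope_ln_tbil + 5.84724 * f$slope_ln_tbil^2 -
    0.05115 * f$auc_ln_plt
}

#' L-GrAFT 10-day linear predictor
#'
#' Published 12-term polynomial over PODs 1-10. The AST slope is taken over
#' PODs 1-7 only; INR enters as the log of its 10-day maximum; the TBIL
#' slope enters linearly and the platelet slope both linearly and squared.
#'
#' @param features named numeric vector with `auc_ln_ast`, `slope7_ln_ast`,
#'   `max_inr` (> 0), `auc_ln_tbil`, `slope_ln_tbil`, `auc_ln_plt`,
#'   `slope_ln_plt`.
#' @return The score (numeric scalar).
#' @export
lgraft10_score <- function(features) {
  f <- as.list(features)
  if (f$max_inr <= 0) stop("max INR must be positive (its log is taken)")
  9.77 -
    0.42926 * f$auc_ln_ast + 0.00462 * f$auc_ln_ast^2 +
    4.60719 * f$slope7_ln_ast + 4.4129 * f$slope7_ln_ast^2 +
    0.88974 * log(f$max_inr) -
    0.04852 * f$auc_ln_tbil + 0.00363 * f$auc_ln_tbil^2 +
    5.33627 * f$slope_ln_tbil -
    0.04621 * f$auc_ln_plt -
    5.24897 * f$slope_ln_plt + 13.08633 * f$slope_ln_plt^2
}

# ---- EASE ------------------------------------------------------------------

#' Early Allograft failure Simplified Estimation (EASE) score
#'
#' Combines peritransplant covariates with trajectory features on the
#' published POD subsets (AST on days 1,2,3,7,10; platelets and bilirubin on
#' days 1,3,7,10). Note the AST term is the square of AUC ln AST.
#'
#' @param meld laboratory MELD score at transplant.
#' @param rbc_units packed red blood cell units transfused during surgery.
#' @param thrombosis arterial or portal thrombosis during days 1-10 (logical).
#' @param center_volume_ge70 center performs >= 70 cases per year (logical).
#' @param features named vector with `auc_ln_ast`, `auc_ln_plt`,
#'   `slope_ln_plt`, `slope_ln_tbil` on the published POD subsets.
#' @return list with `score` and `group` (1-5).
#' @export
ease_score <- function(meld, rbc_units, thrombosis, center_volume_ge70,
                       features) {
  f <- as.list(features)
  if (anyNA(c(meld, rbc_units, thrombosis, center_volume_ge70,
              unlist(f[c("auc_ln_ast", "auc_ln_plt", "slope_ln_plt",
                          "slope_ln_tbil")]))))
    stop("EASE requires all covariates and trajectory features")
  s <- -0.602 +
    0.044 * meld +
    0.065 * rbc_units +
    2.567 * as.numeric(thrombosis) +
    0.000534 * f$auc_ln_ast^2 -
    0.093 * f$auc_ln_plt -
    7.766 * f$slope_ln_plt +
    0.795 * f$slope_ln_tbil -
    0.402 * as.numeric(center_volume_ge70)
  list(score = s, group = assign_risk_group(s, "ease")$group)
}

# ---- Risk group bins -------------------------------------------------------

# Published bin tables. `breaks` are bin edges; `closure` records which side
# each interior breakpoint belongs to.
RISK_BINS <- list(
  # (0,2], (2,5], (5,6], (6,8], (8,10] — right-closed; 0 itself unattainable
  meaf     = list(breaks = c(0, 2, 5, 6, 8, 10), right = TRUE,
                  hi_closed = TRUE),
  # <-3.5, then half-open left-closed bins; 7.5 belongs to no printed bin
  lgraft7  = list(breaks = c(-Inf, -3.5, -2.5, -1.5, -0.5, 0.5, 1.5, 7.5),
                  right = FALSE, hi_closed = FALSE),
  lgraft10 = list(breaks = c(-Inf, -3.23, -1.18, -0.57, 1.3, Inf),
                  right = FALSE, hi_closed = TRUE),
  # printed bounds are 2-dp with 0.01 gaps; scores are rounded to 2 decimals
  # first, which makes these half-open intervals a partition; 5 is included
  ease     = list(breaks = c(-Inf, -3.43, -1.255, -0.745, -0.005, 5),
                  right = FALSE, hi_closed = TRUE)
)

#' Assign a score to its published risk group
#'
#' Deterministic binning against the printed bin tables. EASE scores are
#' rounded to two decimals first (the printed bounds are 2-dp). Scores
#' beyond the terminal printed bounds clamp to the terminal group with a
#' warning, since no overflow behaviour is published.
#'
#' @param score finite numeric score.
#' @param model `"meaf"`, `"lgraft7"`, `"lgraft10"` or `"ease"`.
#' @return list with `group` (integer) and, for L-GrAFT7, `high` (logical:
#'   groups 4-7 are the high-risk class).
#' @export
assign_risk_group <- function(score,
                              model = c("meaf", "lgraft7", "lgraft10",
                                        "ease")) {
  model <- match.arg(model)
  stopifnot(is.finite(score))
  b <- RISK_BINS[[model]]
  x <- if (model == "ease") round(score, 2) else score
  ngrp <- length(b$breaks) - 1L
  lo <- b$breaks[1L]; hi <- b$breaks[length(b$breaks)]
  if (is.finite(hi) && (x > hi || (!b$hi_closed && x >= hi)))
    warning(sprintf("%s score %.4g beyond terminal bound; clamped to group %d",
                    model, score, ngrp))
  if (is.finite(lo) && (x < lo || (b$right && x <= lo)))
    warning(sprintf("%s score %.4g below lower bound; clamped to group 1",
                    model, score))
  g <- findInterval(x, b$breaks, left.open = b$right,
                    rightmost.closed = TRUE)
  g <- max(1L, min(ngrp, as.integer(g)))
  out <- list(group = g)
  if (model == "lgraft7") out$high <- g >= 4L
  out
}

# ---- Panel -----------------------------------------------------------------

#' Compute every score for one patient
#'
#' Evaluates all five scoring systems on one patient's labs and clinical
#' record; scores whose sufficiency rule fails are flagged absent (NA) and
#' never guessed.
#'
#' @param labs data.frame with columns pod, analyte, value.
#' @param clinical one-row data.frame (or list) with at least `meld`,
#'   `rbc_units`, `thrombosis_days_1_10`, `center_volume_ge70` for EASE.
#' @param normalized use time-averaged AUCs.
#' @return one-row data.frame: the `scores.csv` columns.
#' @export
score_panel <- function(labs, clinical, normalized = FALSE) {
  out <- data.frame(
    ead = NA, ead_criterion_1 = NA, ead_criterion_2 = NA,
    ead_criterion_3 = NA, ead_sufficient = FALSE,
    meaf = NA_real_, meaf_group = NA_integer_, meaf_sufficient = FALSE,
    lgraft7 = NA_real_, lgraft7_group = NA_integer_, lgraft7_high = NA,
    lgraft7_sufficient = FALSE,
    lgraft10 = NA_real_, lgraft10_group = NA_integer_,
    lgraft10_sufficient = FALSE,
    ease = NA_real_, ease_group = NA_integer_, ease_sufficient = FALSE)

  ead <- classify_ead(labs)
  if (ead$sufficient) {
    out$ead <- ead$ead
    out[c("ead_criterion_1", "ead_criterion_2", "ead_criterion_3")] <-
      as.list(ead$criteria)
    out$ead_sufficient <- TRUE
  }

  mf <- extract_features(labs, "meaf")
  if (mf$sufficient) {
    m <- meaf_score(mf$features[["alt_max_3pod"]],
                    mf$features[["inr_max_3pod"]],
                    mf$features[["bilirubin_pod3"]])
    out$meaf <- m$score; out$meaf_group <- m$group
    out$meaf_sufficient <- TRUE
  }

  f7 <- extract_features(labs, "lgraft7", normalized = normalized)
  if (f7$sufficient) {
    s <- lgraft7_score(f7$features)
    rg <- assign_risk_group(s, "lgraft7")
    out$lgraft7 <- s; out$lgraft7_group <- rg$group
    out$lgraft7_high <- rg$high; out$lgraft7_sufficient <- TRUE
  }

  f10 <- extract_features(labs, "lgraft10", normalized = normalized)
  if (f10$sufficient) {
    s <- lgraft10_score(f10$features)
    out$lgraft10 <- s
    out$lgraft10_group <- assign_risk_group(s, "lgraft10")$group
    out$lgraft10_sufficient <- TRUE
  }

  fe <- extract_features(labs, "ease", normalized = normalized)
  cl <- as.list(clinical)
  have_cov <- all(c("meld", "rbc_units", "thrombosis_days_1_10",
                    "center_volume_ge70") %in% names(cl)) &&
    !anyNA(cl[c("meld", "rbc_units", "thrombosis_days_1_10",
                "center_volume_ge70")])
  if (fe$sufficient && have_cov) {
    e <- ease_score(cl$meld, cl$rbc_units, cl$thrombosis_days_1_10,
                    cl$center_volume_ge70, fe$features)
    out$ease <- e$score; out$ease_group <- e$group
    out$ease_sufficient <- TRUE
  }
  out
}

#' Score every patient in a cohort
#'
#' @param cohort a `graft_cohort`.
#' @param normalized use time-averaged AUCs.
#' @return data.frame keyed by patient_id with the [score_panel()] columns.
#' @export
score_cohort <- function(cohort, normalized = FALSE) {
  ids <- cohort$clinical$patient_id
  rows <- lapply(ids, function(id)
    score_panel(lab_series(cohort, id),
                cohort$clinical[cohort$clinical$patient_id == id, ],
                normalized = normalized))
  cbind(data.frame(patient_id = ids), do.call(rbind, rows))
}
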