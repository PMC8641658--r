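# Trajectory features: AUC and slope of (log) lab values over POD windows.
# These are the regressors the L-GrAFT and EASE scores consume.

#' Trapezoidal area under a laboratory trajectory
#'
#' Integrates the (optionally log-transformed) value against post-operative
#' day over a POD window by the trapezoid rule. Missing interior days are
#' bridged implicitly (linear interpolation between observed neighbours);
#' when the first or last window days are unobserved, the observed-span area
#' is rescaled by full span / observed span so magnitudes stay comparable
#' across patients with POD 8-10 gaps. The integral is unnormalized by
#' default; `normalized = TRUE` divides by the window span (time-average).
#'
#' @param pods integer PODs of the observations.
#' @param values lab values, strictly positive when `transform = "ln"`.
#' @param window length-2 POD interval, e.g. `c(1, 7)`.
#' @param transform `"ln"` or `"identity"`.
#' @param pods_subset optional POD subset named by a score formula (e.g. the
#'   EASE AST days 1,2,3,7,10); observations outside it are ignored.
#' @param normalized divide by window span.
#' @return The area, or `NA_real_` when fewer than two distinct PODs remain
#'   (insufficient data).
#' @export
trapezoid_auc <- function(pods, values, window, transform = c("ln", "identity"),
                          pods_subset = NULL, normalized = FALSE) {
  transform <- match.arg(transform)
  keep <- pods >= window[1] & pods <= window[2]
  if (!is.null(pods_subset)) keep <- keep & pods %in% pods_subset
  pods <- pods[keep]; values <- values[keep]
  o <- order(pods)
  pods <- pods[o]; values <- values[o]
  if (length(unique(pods)) < 2L) return(NA_real_)
  if (transform == "ln") {
    if (any(values <= 0)) stop("non-positive value under ln transform")
    values <- log(values)
  }
  area <- sum(diff(pods) * (values[-length(values)] + values[-1]) / 2)
  span <- window[2] - window[1]
  obs_span <- pods[length(pods)] - pods[1]
  area <- area * span / obs_span
  if (normalized) area <- area / span
  area
}

#' Least-squares slope of a laboratory trajectory
#'
#' Ordinary least-squares slope of the (optionally log-transformed) value on
#' POD, restricted to a window and optional POD subset.
#'
#' @inheritParams trapezoid_auc
#' @return Slope per day, or `NA_real_` with fewer than two distinct PODs.
#' @export
ols_slope <- function(pods, values, window, transform = c("ln", "identity"),
                      pods_subset = NULL) {
  transform <- match.arg(transform)
  keep <- pods >= window[1] & pods <= window[2]
  if (!is.null(pods_subset)) keep <- keep & pods %in% pods_subset
  pods <- pods[keep]; values <- values[keep]
  if (length(unique(pods)) < 2L) return(NA_real_)
  if (transform == "ln") {
    if (any(values <= 0)) stop("non-positive value under ln transform")
    values <- log(values)
  }
  sum((pods - mean(pods)) * (values - mean(values))) /
    sum((pods - mean(pods))^2)
}

# maximum raw value in window (NA when unobserved)
pod_max <- function(pods, values, window) {
  v <- values[pods >= window[1] & pods <= window[2]]
  if (!length(v)) NA_real_ else max(v)
}

# value at one exact POD, no interpolation
pod_value <- function(pods, values, at) {
  v <- values[pods == at]
  if (!length(v)) NA_real_ else v[1]
}

# Coverage rule behind "insufficient laboratory values": a model needs, per
# analyte, >=3 observations in its (subset-restricted) window with at least
# one in the first 2 window days and one in the last 3.
covered <- function(pods, window, pods_subset = NULL) {
  p <- pods[pods >= window[1] & pods <= window[2]]
  if (!is.null(pods_subset)) p <- p[p %in% pods_subset]
  length(p) >= 3L && any(p <= window[1] + 1) && any(p >= window[2] - 2)
}

#' Extract the trajectory features a score model needs
#'
#' Computes, from one patient's laboratory series, the feature bundle of the
#' requested model together with a sufficiency flag from the coverage rule
#' (at least three observations per needed analyte, one in the first two and
#' one in the last three window days; MEAF additionally requires the POD-3
#' bilirubin exactly, EAD the POD-7 bilirubin and INR).
#'
#' @param labs data.frame with columns pod, analyte, value (canonical units),
#'   e.g. from [lab_series()].
#' @param model one of `"lgraft7"`, `"lgraft10"`, `"ease"`, `"meaf"`, `"ead"`.
#' @param normalized use time-averaged AUCs (see [trapezoid_auc()]).
#' @return list with `model`, `features` (named numeric vector), `sufficient`
#'   and `missing` (analytes failing coverage).
#' @export
extract_features <- function(labs,
                             model = c("lgraft7", "lgraft10", "ease",
                                       "meaf", "ead"),
                             normalized = FALSE) {
  model <- match.arg(model)
  g <- function(a) labs[labs$analyte == a, , drop = FALSE]
  P <- function(a) g(a)$pod
  V <- function(a) g(a)$value

  switch(model,
    lgraft7 = {
      w <- c(1, 7)
      miss <- c("AST", "INR", "TBIL", "PLT")[!c(
        covered(P("AST"), w), covered(P("INR"), w),
        covered(P("TBIL"), w), covered(P("PLT"), w))]
      f <- c(
        auc_ln_ast    = trapezoid_auc(P("AST"), V("AST"), w, "ln",
                                      normalized = normalized),
        slope_ln_ast  = ols_slope(P("AST"), V("AST"), w, "ln"),
        auc_inr       = trapezoid_auc(P("INR"), V("INR"), w, "identity",
                                      normalized = normalized),
        auc_ln_tbil   = trapezoid_auc(P("TBIL"), V("TBIL"), w, "ln",
                                      normalized = normalized),
        slope_ln_tbil = ols_slope(P("TBIL"), V("TBIL"), w, "ln"),
        auc_ln_plt    = trapezoid_auc(P("PLT"), V("PLT"), w, "ln",
                                      normalized = normalized))
      list(model = model, features = f,
           sufficient = !length(miss) && !anyNA(f), missing = miss)
    },
    lgraft10 = {
      w <- c(1, 10)
      miss <- c("AST", "INR", "TBIL", "PLT")[!c(
        covered(P("AST"), w) && length(unique(P("AST")[P("AST") <= 7])) >= 2,
        covered(P("INR"), w), covered(P("TBIL"), w), covered(P("PLT"), w))]
      f <- c(
        auc_ln_ast    = trapezoid_auc(P("AST"), V("AST"), w, "ln",
                                      normalized = normalized),
        slope7_ln_ast = ols_slope(P("AST"), V("AST"), c(1, 7), "ln"),
        max_inr       = pod_max(P("INR"), V("INR"), w),
        auc_ln_tbil   = trapezoid_auc(P("TBIL"), V("TBIL"), w, "ln",
                                      normalized = normalized),
        slope_ln_tbil = ols_slope(P("TBIL"), V("TBIL"), w, "ln"),
        auc_ln_plt    = trapezoid_auc(P("PLT"), V("PLT"), w, "ln",
                                      normalized = normalized),
        slope_ln_plt  = ols_slope(P("PLT"), V("PLT"), w, "ln"))
      list(model = model, features = f,
           sufficient = !length(miss) && !anyNA(f), missing = miss)
    },
    ease = {
      w <- c(1, 10)
      ast_days <- c(1, 2, 3, 7, 10)
      oth_days <- c(1, 3, 7, 10)
      miss <- c("AST", "PLT", "TBIL")[!c(
        covered(P("AST"), w, ast_days),
        covered(P("PLT"), w, oth_days),
        covered(P("TBIL"), w, oth_days))]
      f <- c(
        auc_ln_ast    = trapezoid_auc(P("AST"), V("AST"), w, "ln", ast_days,
                                      normalized = normalized),
        auc_ln_plt    = trapezoid_auc(P("PLT"), V("PLT"), w, "ln", oth_days,
                                      normalized = normalized),
        slope_ln_plt  = ols_slope(P("PLT"), V("PLT"), w, "ln", oth_days),
        slope_ln_tbil = ols_slope(P("TBIL"), V("TBIL"), w, "ln", oth_days))
      list(model = model, features = f,
           sufficient = !length(miss) && !anyNA(f), missing = miss)
    },
    meaf = {
      f <- c(
        alt_max_3pod  = pod_max(P("ALT"), V("ALT"), c(1, 3)),
        inr_max_3pod  = pod_max(P("INR"), V("INR"), c(1, 3)),
        bilirubin_pod3 = pod_value(P("TBIL"), V("TBIL"), 3))
      miss <- c("ALT", "INR", "TBIL(POD3)")[is.na(f)]
      list(model = model, features = f,
           sufficient = !anyNA(f), missing = miss)
    },
    ead = {
      f <- c(
        tbil_pod7 = pod_value(P("TBIL"), V("TBIL"), 7),
        inr_pod7  = pod_value(P("INR"), V("INR"), 7),
        alt_max_7 = pod_max(P("ALT"), V("ALT"), c(1, 7)),
        ast_max_7 = pod_max(P("AST"), V("AST"), c(1, 7)))
      miss <- c("TBIL(POD7)", "INR(POD7)", "ALT", "AST")[is.na(f)]
      list(model = model, features = f,
           sufficient = !anyNA(f), missing = miss)
    })
}

#' Per-patient feature dump for audit
#'
#' @param cohort a `graft_cohort`.
#' @param model score model, see [extract_features()].
#' @param normalized use time-averaged AUCs.
#' @return data.frame: patient_id, one column per feature, `sufficient`.
#' @export
feature_table <- function(cohort, model, normalized = FALSE) {
  rows <- lapply(cohort$clinical$patient_id, function(id) {
    fx <- extract_features(lab_series(cohort, id), model,
                           normalized = normalized)
    cbind(data.frame(patient_id = id),
          as.data.frame(as.list(fx$features)),
          data.frame(sufficient = fx$sufficient))
  })
  do.call(rbind, rows)
}
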