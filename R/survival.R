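# Horizon endpoints, Kaplan-Meier curves and log-rank tests.
# Product-limit and log-rank computations are delegated to the survival
# package; this module owns the endpoint definitions and table shapes.

#' Event time and status for an endpoint
#'
#' Graft loss is retransplantation or death, whichever comes first; the
#' patient endpoint counts death only. Patients without the event are
#' censored at their follow-up time.
#'
#' @param outcomes outcome table of a `graft_cohort`.
#' @param endpoint `"graft"` or `"patient"`.
#' @return data.frame: patient_id, time (days), event (0/1).
#' @export
event_times <- function(outcomes, endpoint = c("graft", "patient")) {
  endpoint <- match.arg(endpoint)
  death_day <- ifelse(isTRUE_vec(outcomes$death), outcomes$death_day, Inf)
  retx_day <- ifelse(isTRUE_vec(outcomes$retransplant),
                     outcomes$retransplant_day, Inf)
  ev_day <- if (endpoint == "graft") pmin(death_day, retx_day) else death_day
  event <- is.finite(ev_day)
  data.frame(patient_id = outcomes$patient_id,
             time = ifelse(event, ev_day, outcomes$follow_up_days),
             event = as.integer(event))
}

#' Label patients for a fixed-horizon binary endpoint
#'
#' A patient is an `event` when the endpoint event occurs on or before the
#' horizon, a `survivor` when followed at least to the horizon without it,
#' and `excluded` when censored before the horizon event-free (the default;
#' `censored_as_survivor = TRUE` labels those survivors instead).
#'
#' @param outcomes outcome table of a `graft_cohort`.
#' @param horizon days, one of 90, 180, 365.
#' @param endpoint `"graft"` or `"patient"`.
#' @param censored_as_survivor treat early-censored patients as survivors.
#' @return data.frame: patient_id, label (factor event/survivor/excluded).
#' @export
derive_labels <- function(outcomes, horizon,
                          endpoint = c("graft", "patient"),
                          censored_as_survivor = FALSE) {
  et <- event_times(outcomes, endpoint)
  lab <- ifelse(et$event == 1L & et$time <= horizon, "event",
         ifelse(et$time >= horizon, "survivor",
                if (censored_as_survivor) "survivor" else "excluded"))
  data.frame(patient_id = et$patient_id,
             label = factor(lab, levels = c("event", "survivor", "excluded")))
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times positive event/censoring times.
#' @param events event indicators (1 = event, 0 = censored).
#' @return object of class `graft_km`: data.frame time, n_risk, n_event,
#'   n_censor, survival (unique observed times, survival non-increasing
#'   from 1).
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) > 0, length(times) == length(events),
            all(times > 0))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    survival = fit$surv)
  class(out) <- c("graft_km", "data.frame")
  out
}

#' Survival probability at a time point
#' @param km a `graft_km`.
#' @param t time.
#' @export
km_survival_at <- function(km, t) {
  i <- findInterval(t, km$time[km$n_event > 0])
  s <- c(1, km$survival[km$n_event > 0])
  s[i + 1L]
}

#' Log-rank test across two or more groups
#'
#' @param times positive event/censoring times.
#' @param events event indicators (1 = event, 0 = censored).
#' @param group group membership (any vector; >= 2 non-empty groups).
#' @return list: chisq, df, p.
#' @export
logrank_test <- function(times, events, group) {
  group <- as.factor(droplevels(factor(group)))
  if (nlevels(group) < 2L) stop("log-rank needs >= 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- nlevels(group) - 1L
  list(chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Kaplan-Meier tables by risk class of a score model
#'
#' @param cohort a `graft_cohort`.
#' @param scores output of [score_cohort()].
#' @param model `"meaf"`, `"lgraft7"`, `"lgraft10"`, `"ease"` or `"ead"`.
#' @param endpoint `"graft"` or `"patient"`.
#' @return list with `curves` (data.frame: group plus `graft_km` columns)
#'   and `logrank` (see [logrank_test()]; NULL with < 2 groups).
#' @export
km_by_risk_class <- function(cohort, scores, model,
                             endpoint = c("graft", "patient")) {
  endpoint <- match.arg(endpoint)
  grp_col <- if (model == "ead") "ead" else paste0(model, "_group")
  m <- merge(event_times(cohort$outcomes, endpoint),
             scores[, c("patient_id", grp_col)], by = "patient_id")
  m <- m[!is.na(m[[grp_col]]), ]
  groups <- sort(unique(m[[grp_col]]))
  curves <- do.call(rbind, lapply(groups, function(g) {
    sel <- m[[grp_col]] == g
    cbind(group = g, as.data.frame(km_estimate(m$time[sel], m$event[sel])))
  }))
  lr <- if (length(groups) >= 2L)
    logrank_test(m$time, m$event, m[[grp_col]]) else NULL
  list(curves = curves, logrank = lr)
}
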