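# ROC discrimination: AUROC with DeLong variance and the paired DeLong test
# for correlated AUROCs. Ties get midrank (half) credit, which also admits
# the dichotomous EAD flag as a degenerate score.

# Placement (structural) components. For each event score x and survivor
# score y, psi = 1 if x > y, 1/2 if tied, 0 otherwise. V10[i] averages psi
# over survivors for event i; V01[j] over events for survivor j. Computed
# via midranks in O((m+n) log(m+n)).
delong_components <- function(event_scores, survivor_scores) {
  m <- length(event_scores); n <- length(survivor_scores)
  all_r <- rank(c(event_scores, survivor_scores), ties.method = "average")
  r_ev <- rank(event_scores, ties.method = "average")
  r_sv <- rank(survivor_scores, ties.method = "average")
  v10 <- (all_r[seq_len(m)] - r_ev) / n
  v01 <- 1 - (all_r[m + seq_len(n)] - r_sv) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' AUROC with DeLong variance
#'
#' Mann-Whitney estimator of the area under the ROC curve (midranks for
#' ties), oriented so that higher scores indicate the event, with the DeLong
#' structural-component variance and a Wald 95% CI clipped to [0, 1].
#'
#' @param scores numeric scores (a binary 0/1 marker is admitted).
#' @param labels logical or 0/1: TRUE/1 = event.
#' @return list of class `graft_roc`: auroc, var, ci (length 2), n_events,
#'   n_survivors.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels))
    stop("AUROC needs both events and survivors")
  cmp <- delong_components(scores[labels], scores[!labels])
  m <- sum(labels); n <- sum(!labels)
  v <- if (m > 1) stats::var(cmp$v10) / m else 0
  v <- v + if (n > 1) stats::var(cmp$v01) / n else 0
  ci <- cmp$auc + c(-1, 1) * stats::qnorm(0.975) * sqrt(v)
  structure(list(auroc = cmp$auc, var = v,
                 ci = pmin(pmax(ci, 0), 1),
                 n_events = m, n_survivors = n),
            class = "graft_roc")
}

#' @export
print.graft_roc <- function(x, ...) {
  cat(sprintf("AUROC %.3f (95%% CI %.3f-%.3f), %d events / %d survivors\n",
              x$auroc, x$ci[1], x$ci[2], x$n_events, x$n_survivors))
  invisible(x)
}

#' Paired DeLong test for two correlated AUROCs
#'
#' Compares the AUROCs of two scores measured on the same patients with the
#' same labels, using the covariance of their DeLong structural components.
#' Two-sided normal p-value; a zero difference yields p = 1.
#'
#' @param scores_a,scores_b scores for the same patients.
#' @param labels logical or 0/1: TRUE/1 = event.
#' @return list: auroc_a, auroc_b, difference, var, z, p.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    stop("scores_a, scores_b and labels must have equal length")
  labels <- as.logical(labels)
  ok <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
  scores_a <- scores_a[ok]; scores_b <- scores_b[ok]; labels <- labels[ok]
  if (!any(labels) || all(labels))
    stop("paired DeLong test needs both events and survivors")
  ca <- delong_components(scores_a[labels], scores_a[!labels])
  cb <- delong_components(scores_b[labels], scores_b[!labels])
  m <- sum(labels); n <- sum(!labels)
  s10 <- if (m > 1) stats::cov(cbind(ca$v10, cb$v10)) else matrix(0, 2, 2)
  s01 <- if (n > 1) stats::cov(cbind(ca$v01, cb$v01)) else matrix(0, 2, 2)
  vmat <- s10 / m + s01 / n
  vdiff <- vmat[1, 1] + vmat[2, 2] - 2 * vmat[1, 2]
  d <- ca$auc - cb$auc
  if (vdiff <= .Machine$double.eps) {
    z <- if (abs(d) < .Machine$double.eps^0.5) 0 else sign(d) * Inf
  } else z <- d / sqrt(vdiff)
  list(auroc_a = ca$auc, auroc_b = cb$auc, difference = d,
       var = max(vdiff, 0), z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' AUROC table and pairwise DeLong comparisons across score models
#'
#' Restricts to the complete-case subset (patients with every requested
#' score and a non-excluded label), computes each model's AUROC and all
#' pairwise DeLong p-values. Models with fewer than two patients per class
#' are dropped with a warning.
#'
#' @param score_table data.frame keyed by patient_id with one column per
#'   model (e.g. from [score_cohort()]; `ead` may be logical).
#' @param labels data.frame from [derive_labels()] (excluded labels are
#'   dropped) or a named logical vector keyed like score_table.
#' @param models columns of `score_table` to compare.
#' @param holm apply Holm correction to the pairwise p-values.
#' @return list: `auroc` (data.frame model/auroc/ci_low/ci_high/n), and
#'   `pairwise` (data.frame model_a/model_b/p).
#' @export
compare_all_models <- function(score_table, labels,
                               models = c("lgraft10", "lgraft7", "ease",
                                          "meaf", "ead"),
                               holm = FALSE) {
  if (is.data.frame(labels)) {
    labels <- labels[labels$label != "excluded", ]
    m <- merge(score_table, labels, by = "patient_id")
    y <- m$label == "event"
  } else {
    m <- score_table
    y <- as.logical(labels)
  }
  keep <- models[vapply(models, function(mod)
    mod %in% names(m) && sum(!is.na(m[[mod]])) > 0, logical(1))]
  dropped <- setdiff(models, keep)
  if (length(dropped))
    warning("models absent or all-NA, excluded: ",
            paste(dropped, collapse = ", "))
  cc <- stats::complete.cases(m[, keep, drop = FALSE]) & !is.na(y)
  m <- m[cc, , drop = FALSE]; y <- y[cc]
  rocs <- lapply(keep, function(mod) auroc(as.numeric(m[[mod]]), y))
  tab <- data.frame(
    model = keep,
    auroc = vapply(rocs, `[[`, numeric(1), "auroc"),
    ci_low = vapply(rocs, function(r) r$ci[1], numeric(1)),
    ci_high = vapply(rocs, function(r) r$ci[2], numeric(1)),
    n = sum(cc))
  pairs <- if (length(keep) >= 2) utils::combn(keep, 2) else
    matrix(character(0), 2)
  pw <- data.frame(
    model_a = pairs[1, ], model_b = pairs[2, ],
    p = apply(pairs, 2, function(pr)
      delong_paired_test(as.numeric(m[[pr[1]]]),
                         as.numeric(m[[pr[2]]]), y)$p))
  if (holm && nrow(pw)) pw$p_holm <- stats::p.adjust(pw$p, "holm")
  list(auroc = tab, pairwise = pw)
}
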