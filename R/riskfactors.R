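# Risk-factor analysis for the high-risk class: univariable logistic screen,
# multicollinearity filter, multivariable logistic regression.

# single-predictor logistic fit; categorical predictors are reference-coded
# and summarised by a likelihood-ratio p across all their indicators
fit_univariate <- function(y, x, name) {
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  categorical <- is.character(x) || is.factor(x) || is.logical(x)
  if (categorical) x <- droplevels(as.factor(x))
  if ((categorical && nlevels(x) < 2L) ||
      (!categorical && stats::var(x) == 0))
    return(data.frame(variable = name, n = length(y), p = NA_real_,
                      or = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                      separation = FALSE, zero_variance = TRUE))
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  separation <- !fit$converged ||
    any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE) ||
    all(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8)
  if (categorical && nlevels(x) > 2L) {
    null <- stats::glm(y ~ 1, family = stats::binomial())
    p <- stats::pchisq(null$deviance - fit$deviance,
                       fit$df.null - fit$df.residual, lower.tail = FALSE)
    or <- ci <- NA_real_
    data.frame(variable = name, n = length(y), p = p, or = NA_real_,
               ci_low = NA_real_, ci_high = NA_real_,
               separation = separation, zero_variance = FALSE)
  } else {
    sm <- summary(fit)$coefficients
    b <- sm[2, 1]; se <- sm[2, 2]
    data.frame(variable = name, n = length(y), p = sm[2, 4],
               or = exp(b), ci_low = exp(b - 1.96 * se),
               ci_high = exp(b + 1.96 * se),
               separation = separation, zero_variance = FALSE)
  }
}

#' Univariable logistic screen
#'
#' One non-conditional single-predictor logistic regression per candidate
#' variable against a binary target (e.g. membership of the L-GrAFT7
#' high-risk group). Categorical variables are reference-coded and
#' summarised by a likelihood-ratio p-value; zero-variance predictors are
#' flagged, not fitted; perfect separation is flagged.
#'
#' @param data data.frame of candidate variables.
#' @param target logical/0-1 vector aligned with `data` rows.
#' @param variables column names to screen (default: all).
#' @return data.frame: variable, n, p, or, ci_low, ci_high, separation,
#'   zero_variance.
#' @export
univariate_screen <- function(data, target, variables = names(data)) {
  y <- as.numeric(as.logical(target))
  stopifnot(length(y) == nrow(data))
  do.call(rbind, lapply(variables, function(v)
    fit_univariate(y, data[[v]], v)))
}

# Cramer's V for two categorical vectors
cramers_v <- function(a, b) {
  tab <- table(a, b)
  if (min(dim(tab)) < 2L) return(0)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  sqrt(unname(chi) / (sum(tab) * (min(dim(tab)) - 1L)))
}

#' Multicollinearity filter
#'
#' Greedy screen of candidate variables for collinear pairs: continuous
#' pairs with |Pearson r| above the threshold and categorical pairs with
#' Cramer's V above it. Within an offending pair, the later-listed variable
#' is dropped. Mixed continuous/categorical pairs are not tested.
#'
#' @param data data.frame of candidate variables.
#' @param variables candidate names, in priority order.
#' @param threshold correlation threshold (default 0.7).
#' @return list: `retained` (character), `dropped`
#'   (data.frame kept/dropped/measure/value).
#' @export
multicollinearity_filter <- function(data, variables = names(data),
                                     threshold = 0.7) {
  is_cat <- vapply(variables, function(v)
    is.character(data[[v]]) || is.factor(data[[v]]) || is.logical(data[[v]]),
    logical(1))
  retained <- character(0)
  dropped <- data.frame(kept = character(0), dropped = character(0),
                        measure = character(0), value = numeric(0))
  for (v in variables) {
    clash <- FALSE
    for (r in retained) {
      if (is_cat[[v]] != is_cat[[r]]) next
      ok <- stats::complete.cases(data[, c(v, r)])
      val <- if (is_cat[[v]])
        cramers_v(data[[v]][ok], data[[r]][ok])
      else
        abs(stats::cor(data[[v]][ok], data[[r]][ok]))
      if (is.finite(val) && val > threshold) {
        dropped <- rbind(dropped, data.frame(
          kept = r, dropped = v,
          measure = if (is_cat[[v]]) "cramers_v" else "pearson_r",
          value = val))
        clash <- TRUE
        break
      }
    }
    if (!clash) retained <- c(retained, v)
  }
  list(retained = retained, dropped = dropped)
}

#' Multivariable logistic regression
#'
#' Maximum-likelihood logistic fit of the target on the retained variables,
#' reported as odds ratios with Wald 95% CIs and p-values. Emits a warning
#' when n is below ten times the number of predictors.
#'
#' @param data data.frame holding the retained variables.
#' @param target logical/0-1 vector aligned with `data` rows.
#' @param variables retained variable names (non-empty).
#' @return list of class `graft_logit`: `table` (data.frame variable,
#'   coefficient, se, or, ci_low, ci_high, p), `converged`, `n`.
#' @export
multivariable_logistic <- function(data, target, variables) {
  stopifnot(length(variables) >= 1L)
  y <- as.numeric(as.logical(target))
  df <- data[, variables, drop = FALSE]
  ok <- stats::complete.cases(df) & !is.na(y)
  df <- df[ok, , drop = FALSE]; y <- y[ok]
  if (length(y) < 10L * length(variables))
    warning(sprintf(
      "n = %d below 10 x %d predictors; estimates may be unstable",
      length(y), length(variables)))
  fit <- suppressWarnings(
    stats::glm(y ~ ., data = df, family = stats::binomial()))
  sm <- summary(fit)$coefficients
  sm <- sm[rownames(sm) != "(Intercept)", , drop = FALSE]
  tab <- data.frame(
    variable = rownames(sm),
    coefficient = sm[, 1], se = sm[, 2],
    or = exp(sm[, 1]),
    ci_low = exp(sm[, 1] - 1.96 * sm[, 2]),
    ci_high = exp(sm[, 1] + 1.96 * sm[, 2]),
    p = sm[, 4], row.names = NULL)
  structure(list(table = tab, converged = fit$converged, n = length(y)),
            class = "graft_logit")
}

#' @export
print.graft_logit <- function(x, ...) {
  cat(sprintf("Multivariable logistic regression (n = %d, converged: %s)\n",
              x$n, x$converged))
  print(x$table, digits = 3)
  invisible(x)
}

#' Screen, filter and fit in one pass
#'
#' The full risk-factor workflow: univariable screen, retention of
#' variables with p below the screen threshold, multicollinearity filter,
#' multivariable logistic fit.
#'
#' @param data data.frame of candidate variables.
#' @param target logical/0-1 target.
#' @param variables candidate names, in priority order.
#' @param screen_p univariable retention threshold (default 0.1).
#' @param collinearity_threshold see [multicollinearity_filter()].
#' @return list: screen, retained, collinearity, fit (NULL when nothing
#'   survives the screen).
#' @export
risk_factor_analysis <- function(data, target, variables = names(data),
                                 screen_p = 0.1,
                                 collinearity_threshold = 0.7) {
  screen <- univariate_screen(data, target, variables)
  cand <- screen$variable[!is.na(screen$p) & screen$p < screen_p &
                            !screen$zero_variance]
  if (!length(cand))
    return(list(screen = screen, retained = character(0),
                collinearity = NULL, fit = NULL))
  col <- multicollinearity_filter(data, cand, collinearity_threshold)
  fit <- multivariable_logistic(data, target, col$retained)
  list(screen = screen, retained = col$retained, collinearity = col,
       fit = fit)
}
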