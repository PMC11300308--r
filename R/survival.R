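# Overall-survival analysis: product-limit estimation with Greenwood
# variance and log-log confidence bands, the k-group log-rank test, and a
# thin proportional-hazards fitting contract over survival::coxph.

#' Kaplan-Meier product-limit fit
#'
#' Implements the product-limit estimator directly:
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times, with
#' Greenwood's variance and log-log transformed confidence bands. The
#' median is the first time at which `S(t) <= 0.5`; its confidence
#' interval is read off the times at which the confidence bands cross 0.5
#' (Brookmeyer-Crowley style).
#'
#' @param time non-negative follow-up times (months).
#' @param event logical (or 0/1): `TRUE` = death observed, `FALSE` =
#'   censored.
#' @param group optional grouping vector; one curve per non-empty group
#'   (empty groups are dropped with a warning).
#' @param conf_level confidence level for the bands.
#' @return object of class `"km_fit"`: `curves` (data.frame `group`,
#'   `time`, `n_risk`, `n_event`, `surv`, `se`, `lower`, `upper`) and
#'   `medians` (data.frame `group`, `n`, `events`, `median`, `lower`,
#'   `upper`; `NA` median when the curve never reaches 0.5).
#' @export
km_fit <- function(time, event, group = NULL, conf_level = 0.95) {
  stopifnot(all(time >= 0), length(event) == length(time))
  event <- as.logical(event)
  if (is.null(group)) group <- rep("all", length(time))
  group <- as.character(group)
  keep <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[keep]; event <- event[keep]; group <- group[keep]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  curves <- list(); medians <- list()
  for (g in unique(group)) {
    tg <- time[group == g]; eg <- event[group == g]
    if (!length(tg)) {
      warning("empty group omitted: ", g)
      next
    }
    ut <- sort(unique(tg[eg]))
    if (!length(ut)) {
      # no events: the curve is flat at 1 and the median undefined
      medians[[g]] <- data.frame(group = g, n = length(tg), events = 0L,
                                 median = NA_real_, lower = NA_real_,
                                 upper = NA_real_)
      next
    }
    n_risk <- vapply(ut, function(t) sum(tg >= t), integer(1))
    d <- vapply(ut, function(t) sum(tg == t & eg), integer(1))
    s <- cumprod(1 - d / n_risk)
    gw <- cumsum(d / (n_risk * (n_risk - d)))       # Greenwood sum
    se <- s * sqrt(gw)
    # log-log bands: exp(-exp(log(-log S) -+ z * se(log(-log S))))
    se_ll <- sqrt(gw) / abs(log(s))
    lower <- s^exp(z * se_ll)
    upper <- s^exp(-z * se_ll)
    lower[s %in% c(0, 1)] <- NA
    upper[s %in% c(0, 1)] <- NA
    first_below <- function(surv_curve) {
      i <- which(!is.na(surv_curve) & surv_curve <= 0.5)
      if (length(i)) ut[min(i)] else NA_real_
    }
    curves[[g]] <- data.frame(group = g, time = ut, n_risk = n_risk,
                              n_event = d, surv = s, se = se,
                              lower = lower, upper = upper)
    # the median CI is the set of times whose survival CI contains 0.5:
    # it opens where the lower band first reaches 0.5 and closes where the
    # upper band does
    medians[[g]] <- data.frame(group = g, n = length(tg), events = sum(eg),
                               median = first_below(s),
                               lower = first_below(lower),
                               upper = first_below(upper))
  }
  empty_curves <- data.frame(group = character(), time = numeric(),
                             n_risk = integer(), n_event = integer(),
                             surv = numeric(), se = numeric(),
                             lower = numeric(), upper = numeric())
  out <- list(curves = do.call(rbind, c(curves, list(empty_curves))),
              medians = do.call(rbind, medians),
              conf_level = conf_level)
  rownames(out$curves) <- rownames(out$medians) <- NULL
  class(out) <- "km_fit"
  out
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier fit (", round(100 * x$conf_level), "% CI)\n", sep = "")
  print(x$medians, row.names = FALSE)
  invisible(x)
}

#' Survival probability at given times
#'
#' Step-function evaluation of a fitted curve: `S(t)` is the product-limit
#' estimate at the last event time at or before `t` (1 before the first
#' event).
#'
#' @param fit a [km_fit()] object.
#' @param times times at which to evaluate.
#' @param group which curve (defaults to the first).
#' @return numeric vector of survival probabilities.
#' @export
km_surv_at <- function(fit, times, group = NULL) {
  cv <- fit$curves
  g <- group %||% cv$group[1]
  cv <- cv[cv$group == g, ]
  vapply(times, function(t) {
    i <- which(cv$time <= t)
    if (length(i)) cv$surv[max(i)] else 1
  }, numeric(1))
}

#' k-group log-rank test
#'
#' Standard log-rank chi-square: at each distinct event time the observed
#' group-wise death counts are compared with their hypergeometric
#' expectation given the risk sets; the statistic is the quadratic form of
#' the summed differences in their summed covariance (one group dropped),
#' with `k - 1` degrees of freedom.
#'
#' @param time,event,group as in [km_fit()]; at least two non-empty groups.
#' @return list with `statistic`, `df`, `p_value`, and the per-group
#'   `observed` and `expected` death counts.
#' @export
logrank_test <- function(time, event, group) {
  event <- as.logical(event)
  keep <- !is.na(time) & !is.na(event) & !is.na(group)
  time <- time[keep]; event <- event[keep]
  group <- factor(as.character(group)[keep])
  k <- nlevels(group)
  if (k < 2) stop("log-rank test needs at least two non-empty groups")
  ut <- sort(unique(time[event]))
  U <- numeric(k)
  V <- matrix(0, k, k)
  O <- numeric(k); E <- numeric(k)
  for (t in ut) {
    at_risk <- time >= t
    nj <- sum(at_risk)
    dj <- sum(time == t & event)
    n_g <- tabulate(group[at_risk], nbins = k)
    d_g <- tabulate(group[time == t & event], nbins = k)
    e_g <- dj * n_g / nj
    O <- O + d_g; E <- E + e_g
    U <- U + (d_g - e_g)
    if (nj > 1) {
      p <- n_g / nj
      V <- V + dj * (nj - dj) / (nj - 1) * (diag(p, k) - tcrossprod(p))
    }
  }
  idx <- seq_len(k - 1)
  stat <- tryCatch(
    drop(t(U[idx]) %*% solve(V[idx, idx, drop = FALSE], U[idx])),
    error = function(e) 0
  )
  names(O) <- names(E) <- levels(group)
  list(statistic = stat, df = k - 1,
       p_value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Proportional-hazards fit
#'
#' Thin contract over `survival::coxph` with Efron tie handling: fits
#' `Surv(time, event) ~ covariates` on a data.frame and returns hazard
#' ratios with Wald confidence intervals. Non-convergence, a constant
#' covariate, or complete separation (unbounded coefficient) raises a
#' diagnostic error naming the covariate.
#'
#' @param data data.frame holding the model variables.
#' @param time_col,event_col column names of follow-up time and event
#'   indicator (logical, or `"death"`/`"censored"` strings).
#' @param covariates character vector of covariate column names. Factor
#'   reference levels are taken as given; relevel before fitting to choose
#'   references.
#' @param conf_level Wald confidence level.
#' @return list of class `"cox_ph_fit"`: `terms` (data.frame `term`,
#'   `coef`, `hr`, `lower`, `upper`, `se`, `p_value`), `n`, `events`, and
#'   the underlying `fit`.
#' @export
cox_ph_fit <- function(data, time_col = "survival_months",
                       event_col = "event", covariates,
                       conf_level = 0.95) {
  stopifnot(is.data.frame(data), length(covariates) >= 1,
            all(c(time_col, event_col, covariates) %in% names(data)))
  ev <- data[[event_col]]
  if (is.character(ev) || is.factor(ev)) ev <- as.character(ev) == "death"
  ev <- as.logical(ev)
  for (cv in covariates) {
    x <- data[[cv]]
    if (length(unique(x[!is.na(x)])) < 2) {
      stop("no information in covariate ", cv, " (constant)")
    }
  }
  df <- data.frame(.time = data[[time_col]], .event = ev,
                   data[, covariates, drop = FALSE], check.names = FALSE)
  for (cv in covariates) {
    # treatment contrasts against the first level, also for ordered
    # factors (hazard ratios per level, not polynomial contrasts)
    if (is.ordered(df[[cv]])) df[[cv]] <- factor(df[[cv]], ordered = FALSE)
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  co <- summary(fit)$coefficients
  bad <- !is.finite(co[, "coef"]) | !is.finite(co[, "se(coef)"]) |
    abs(co[, "coef"]) > 15
  if (any(bad)) {
    stop("proportional-hazards fit did not converge for: ",
         paste(rownames(co)[bad], collapse = ", "),
         " (possible complete separation)")
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  terms <- data.frame(
    term = rownames(co),
    coef = co[, "coef"],
    hr = exp(co[, "coef"]),
    lower = exp(co[, "coef"] - z * co[, "se(coef)"]),
    upper = exp(co[, "coef"] + z * co[, "se(coef)"]),
    se = co[, "se(coef)"],
    p_value = co[, "Pr(>|z|)"]
  )
  rownames(terms) <- NULL
  out <- list(terms = terms, n = fit$n, events = fit$nevent, fit = fit)
  class(out) <- "cox_ph_fit"
  out
}

#' @export
print.cox_ph_fit <- function(x, ...) {
  cat("Proportional-hazards fit:", x$n, "subjects,", x$events, "events\n")
  print(x$terms, row.names = FALSE, digits = 4)
  invisible(x)
}
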