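#' Median stratification of a marker
#'
#' Splits patients into group 1 (strictly above the within-table median of
#' the marker) and group 0 (at or below the median, including values exactly
#' at it). The median is the conventional mid-point of the order statistics.
#'
#' @param table a `cohort`.
#' @param marker marker name (must be complete in the table).
#' @return Integer vector of group indicators (0/1).
#' @export
stratify_by_median <- function(table, marker) {
  v <- marker_matrix(table, marker)[, 1]
  if (anyNA(v)) stop("stratification error: marker has missing values")
  if (length(unique(v)) < 2) {
    stop("stratification error: all values identical, one group would be empty")
  }
  as.integer(v > stats::median(v))
}

#' Kaplan-Meier estimate for one group
#'
#' Product-limit estimator of the survival function, with censored subjects
#' at risk through their censoring time. The median overall survival is the
#' first time at which the estimate drops to 0.5 or below, `NA` if it never
#' does.
#'
#' @param times non-negative follow-up times (days).
#' @param events binary event indicators (1 = death, 0 = censored).
#' @return A `km_fit`: `time`, `n_risk`, `n_event`, `surv` (step values at
#'   each distinct observed time), `median`, `n`, `n_events`.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) stop("km error: empty input")
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  # median = first time the step function reaches 0.5 or below (not the
  # flat-interval midpoint convention of survfit's summary table)
  drop_idx <- which(fit$surv <= 0.5 + 1e-12)
  med <- if (length(drop_idx)) fit$time[min(drop_idx)] else NA_real_
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, surv = fit$surv,
                 median = med, n = length(times),
                 n_events = sum(events)),
            class = "km_fit")
}

#' Survival probability at given times
#'
#' Right-continuous step-function lookup of a [km_estimate()] fit
#' (`S(0) = 1`).
#'
#' @param fit a `km_fit`.
#' @param t times at which to evaluate the estimate.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(fit, t) {
  vapply(t, function(ti) {
    k <- which(fit$time <= ti)
    if (!length(k)) 1 else fit$surv[max(k)]
  }, numeric(1))
}

#' Weighted log-rank tests (log-rank and Gehan-Breslow-Wilcoxon)
#'
#' At each distinct event time the observed number of events in group 1 is
#' compared with its hypergeometric expectation given the at-risk sets; the
#' standardized weighted sum is referred to a chi-square with 1 df. Weights:
#' `w(t) = 1` for the log-rank (Mantel-Cox) test, `w(t) = n at risk` for the
#' Gehan-Breslow-Wilcoxon test, which emphasizes early events.
#'
#' @param times,events as in [km_estimate()].
#' @param group binary group indicator.
#' @param weights `"logrank"` (default) or `"gehan"`.
#' @return A `surv_test`: `chisq`, `df = 1`, `p`, `weights`, `observed`,
#'   `expected` (group-1 totals).
#' @export
weighted_logrank <- function(times, events, group,
                             weights = c("logrank", "gehan")) {
  weights <- match.arg(weights)
  stopifnot(length(times) == length(events), length(times) == length(group))
  if (length(unique(group)) < 2) stop("logrank error: a group is empty")
  if (sum(events) == 0) stop("logrank error: no events at all")
  ev_times <- sort(unique(times[events == 1]))
  num <- 0
  den <- 0
  obs_total <- 0
  exp_total <- 0
  for (t in ev_times) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(events == 1 & times == t)
    d1 <- sum(events == 1 & times == t & group == 1)
    e1 <- d * n1 / n
    v1 <- if (n > 1) d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1) else 0
    w <- if (weights == "gehan") n else 1
    num <- num + w * (d1 - e1)
    den <- den + w^2 * v1
    obs_total <- obs_total + d1
    exp_total <- exp_total + e1
  }
  chisq <- if (den > 0) num^2 / den else 0
  structure(list(chisq = chisq, df = 1L,
                 p = stats::pchisq(chisq, 1, lower.tail = FALSE),
                 weights = weights, observed = obs_total,
                 expected = exp_total),
            class = "surv_test")
}

#' Cox hazard ratio for a binary covariate
#'
#' Partial-likelihood estimate (Breslow tie handling) of the hazard ratio of
#' group 1 versus group 0, with Wald 95% CI. A monotone likelihood (all
#' events in one group preceding the other's) is flagged as unbounded rather
#' than reported as a finite estimate.
#'
#' @param times,events as in [km_estimate()].
#' @param group binary group indicator; at least one event per group.
#' @return A `cox_result`: `log_hr`, `se`, `hr`, `ci` (length-2),
#'   `iterations`, `converged`, `unbounded`.
#' @export
cox_hr_binary <- function(times, events, group) {
  stopifnot(length(times) == length(events), length(times) == length(group))
  if (length(unique(group)) < 2) stop("cox error: a group is empty")
  if (sum(events[group == 1]) < 1 || sum(events[group == 0]) < 1) {
    stop("cox error: each group needs at least one event")
  }
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, events) ~ group,
                    ties = "breslow"),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  b <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  unbounded <- warned && (abs(b) > 15 || !is.finite(se))
  structure(list(log_hr = b, se = se, hr = exp(b),
                 ci = exp(b + c(-1, 1) * stats::qnorm(0.975) * se),
                 iterations = fit$iter, converged = !unbounded,
                 unbounded = unbounded),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("Cox HR %.3f (95%% CI %.3f-%.3f)%s\n", x$hr, x$ci[1], x$ci[2],
              if (x$unbounded) " [monotone likelihood: unbounded]" else ""))
  invisible(x)
}

#' Median-stratified survival analysis of one marker
#'
#' The exploratory survival stage: within one diagnosis class (or the whole
#' cohort), patients are stratified by the within-subset median of a marker
#' and the two groups are compared by Kaplan-Meier estimation, log-rank and
#' Gehan-Breslow-Wilcoxon tests, and a binary-covariate Cox model. The
#' median-OS ratio between groups carries a stratified bootstrap percentile
#' CI (a method choice; resamples whose median is undefined are dropped).
#'
#' @param table a `cohort` with `os_days` and `event` columns.
#' @param marker marker to stratify by.
#' @param label_class optional diagnosis class (0 or 1) to restrict to.
#' @param boot bootstrap resamples for the median-ratio CI (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return A `survival_strat` object.
#' @export
survival_stratified <- function(table, marker, label_class = NULL,
                                boot = 1000L, seed = 42L) {
  if (!"os_days" %in% names(table)) {
    stop("survival error: cohort has no survival columns")
  }
  if (!is.null(label_class)) {
    table <- subset_cohort(table, table$label == label_class)
  }
  keep <- !is.na(table$os_days) & !is.na(table$event)
  table <- subset_cohort(table, keep)
  group <- stratify_by_median(table, marker)
  times <- table$os_days
  events <- table$event
  km0 <- km_estimate(times[group == 0], events[group == 0])
  km1 <- km_estimate(times[group == 1], events[group == 1])
  ratio <- if (!is.na(km0$median) && !is.na(km1$median) && km1$median > 0) {
    km0$median / km1$median
  } else {
    NA_real_
  }
  ratio_ci <- if (!is.na(ratio)) {
    i0 <- which(group == 0)
    i1 <- which(group == 1)
    rs <- withr::with_seed(seed, {
      vapply(seq_len(boot), function(b) {
        j0 <- i0[sample.int(length(i0), replace = TRUE)]
        j1 <- i1[sample.int(length(i1), replace = TRUE)]
        m0 <- km_estimate(times[j0], events[j0])$median
        m1 <- km_estimate(times[j1], events[j1])$median
        if (is.na(m0) || is.na(m1) || m1 <= 0) NA_real_ else m0 / m1
      }, numeric(1))
    })
    rs <- rs[!is.na(rs)]
    if (length(rs) >= 100) {
      unname(stats::quantile(rs, c(0.025, 0.975)))
    } else {
      c(NA_real_, NA_real_)
    }
  } else {
    c(NA_real_, NA_real_)
  }
  cox <- tryCatch(cox_hr_binary(times, events, group), error = function(e) e)
  # O/E-ratio hazard approximation, exported alongside the Cox estimate
  lr <- weighted_logrank(times, events, group, "logrank")
  oe_hr <- if (lr$expected > 0 && lr$observed < sum(events)) {
    exp_total0 <- sum(events) - lr$expected
    obs_total0 <- sum(events) - lr$observed
    (lr$observed / lr$expected) /
      if (obs_total0 > 0) obs_total0 / exp_total0 else NA_real_
  } else {
    NA_real_
  }
  structure(list(marker = marker, label_class = label_class,
                 n = nrow(table), group = group,
                 n_above = sum(group == 1), n_below = sum(group == 0),
                 km_above = km1, km_below = km0,
                 median_above = km1$median, median_below = km0$median,
                 median_ratio = ratio, median_ratio_ci = ratio_ci,
                 logrank = lr,
                 gehan = weighted_logrank(times, events, group, "gehan"),
                 cox = cox, oe_hr = oe_hr),
            class = "survival_strat")
}

#' @export
print.survival_strat <- function(x, ...) {
  cat(sprintf("Median stratification of %s%s: n = %d (%d above / %d below)\n",
              x$marker,
              if (!is.null(x$label_class))
                sprintf(" in class %d", x$label_class) else "",
              x$n, x$n_above, x$n_below))
  cat(sprintf("median OS %.1f (above) vs %.1f (below) days; ratio %.2f (95%% CI %.2f-%.2f)\n",
              x$median_above, x$median_below, x$median_ratio,
              x$median_ratio_ci[1], x$median_ratio_ci[2]))
  cat(sprintf("log-rank chi2 %.3f (p = %.4g); Gehan chi2 %.3f (p = %.4g)\n",
              x$logrank$chisq, x$logrank$p, x$gehan$chisq, x$gehan$p))
  if (inherits(x$cox, "cox_result")) print(x$cox)
  invisible(x)
}
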