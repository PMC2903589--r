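# Survival machinery: Kaplan-Meier curves, log-rank tests and Cox models
# are computed through the survival package; the optimal cut-point scan
# (maximally selected log-rank statistic with a minimum-p correction) is
# implemented here.

check_records <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("time_months", "event") %in% names(records))) {
    stop_pdacsig("records must be a data frame with columns time_months, event",
                 "invalid_input")
  }
  if (nrow(records) == 0L) stop_pdacsig("empty survival records",
                                        "invalid_input")
  if (any(!is.finite(records$time_months)) || any(records$time_months <= 0)) {
    stop_pdacsig("survival times must be finite and positive",
                 "invalid_input")
  }
  if (!all(records$event %in% c(0, 1))) {
    stop_pdacsig("event must be 0 (censored) or 1 (death observed)",
                 "invalid_input")
  }
  invisible(records)
}

#' Kaplan-Meier product-limit estimate
#'
#' Estimates the overall-survival curve S(t) by the product-limit method.
#' The median is the first time at which S(t) drops to 0.5 or below, `NA`
#' if the curve never reaches 0.5 (e.g. all records censored).
#'
#' @param records data frame with columns `time_months` (> 0) and `event`
#'   (1 = death observed, 0 = censored).
#' @return Object of class `km_curve`: `time`, `surv`, `n_risk`, `n_event`
#'   (stepwise, at the distinct observed times), `median`, `n`.
#' @export
km_estimate <- function(records) {
  check_records(records)
  fit <- survival::survfit(
    survival::Surv(time_months, event) ~ 1,
    data = records, conf.type = "none")
  med <- if (any(fit$surv <= 0.5)) min(fit$time[fit$surv <= 0.5]) else NA_real_
  structure(
    list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
         n_event = fit$n.event, median = med, n = nrow(records)),
    class = "km_curve"
  )
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: n = %d, events = %d, median = %s months\n",
              x$n, sum(x$n_event),
              if (is.na(x$median)) "not reached" else format(x$median)))
  invisible(x)
}

#' Survival probability at given times
#'
#' Evaluates a [km_estimate()] curve at arbitrary times (right-continuous
#' step function), e.g. for 1/2/3-year survival-rate summaries.
#'
#' @param curve a `km_curve`.
#' @param times times (same units as the records).
#' @return numeric vector of S(t).
#' @export
km_survival_at <- function(curve, times) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(times, function(t) {
    i <- findInterval(t, curve$time)
    if (i == 0L) 1 else curve$surv[i]
  }, numeric(1))
}

# two-group log-rank chi-square from raw vectors; used by the cut-point
# scan where many candidate splits are evaluated
logrank_chisq_2g <- function(time, event, in_group1) {
  et <- sort(unique(time[event == 1]))
  if (length(et) == 0L) return(0)
  o1 <- e1 <- v <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in_group1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & in_group1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n - d) / (n - 1) * (n1 / n) * (1 - n1 / n)
  }
  if (v <= 0) return(0)
  (o1 - e1)^2 / v
}

#' Log-rank test between survival groups
#'
#' Standard (unweighted) log-rank chi-square comparing two or more groups,
#' with df = number of groups - 1. If no events occur at all the statistic
#' is 0 and p = 1.
#'
#' @param records data frame with `time_months`, `event`.
#' @param group group membership, length = nrow(records), >= 2 nonempty
#'   groups.
#' @return Object of class `logrank_result`: `chisq`, `df`, `p`.
#' @export
logrank_test <- function(records, group) {
  check_records(records)
  group <- droplevels(as.factor(group))
  if (length(group) != nrow(records)) {
    stop_pdacsig("group must align with records", "invalid_input")
  }
  if (nlevels(group) < 2L) {
    stop_pdacsig("need >= 2 nonempty groups", "invalid_input")
  }
  df <- nlevels(group) - 1L
  if (sum(records$event) == 0L) {
    res <- list(chisq = 0, df = df, p = 1)
  } else {
    dat <- cbind(records, .grp = group)
    sd_fit <- survival::survdiff(
      survival::Surv(time_months, event) ~ .grp, data = dat)
    res <- list(chisq = unname(sd_fit$chisq), df = df,
                p = stats::pchisq(sd_fit$chisq, df, lower.tail = FALSE))
  }
  structure(res, class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank: chi-square = %.3f on %d df, p = %.4g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood (Efron tie handling by default;
#' Breslow available for parity with SPSS-style output) and reports, per
#' covariate, the coefficient, hazard ratio, Wald 95% CI and p-value.
#' Rows with missing covariate values are dropped and counted.
#'
#' @param records data frame with `time_months`, `event`.
#' @param covariates data frame of covariates (numeric or factor), aligned
#'   with `records`.
#' @param ties "efron" (default) or "breslow".
#' @return Object of class `cox_fit`: coefficient `table` (beta, hr,
#'   ci_lower, ci_upper, p), `ties`, `n`, `n_events`, `n_dropped`.
#' @export
cox_fit <- function(records, covariates, ties = c("efron", "breslow")) {
  check_records(records)
  ties <- match.arg(ties)
  if (!is.data.frame(covariates)) covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(records)) {
    stop_pdacsig("covariates must align with records", "invalid_input")
  }
  complete <- stats::complete.cases(covariates)
  n_dropped <- sum(!complete)
  dat <- cbind(records[complete, c("time_months", "event")],
               covariates[complete, , drop = FALSE])
  if (sum(dat$event) == 0L) {
    stop_pdacsig("no events among complete cases; Cox model undefined",
                 "invalid_input")
  }
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time_months, event) ~ ., data = dat,
                    ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge|Loglik converged before",
                conditionMessage(w))) {
        stop_pdacsig(paste0("Cox fit failed (monotone likelihood / separation): ",
                            conditionMessage(w)), "fit_failure")
      }
      invokeRestart("muffleWarning")
    }
  )
  sm <- summary(fit)
  tab <- data.frame(
    beta = sm$coefficients[, "coef"],
    hr = sm$coefficients[, "exp(coef)"],
    ci_lower = sm$conf.int[, "lower .95"],
    ci_upper = sm$conf.int[, "upper .95"],
    p = sm$coefficients[, "Pr(>|z|)"]
  )
  rownames(tab) <- rownames(sm$coefficients)
  structure(
    list(table = tab, ties = ties, n = nrow(dat),
         n_events = sum(dat$event), n_dropped = n_dropped),
    class = "cox_fit"
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox PH fit (%s ties): n = %d, events = %d (%d dropped for missingness)\n",
              x$ties, x$n, x$n_events, x$n_dropped))
  print(round(x$table, 4))
  invisible(x)
}

# Miller-Siegmund correction of the minimum p over a range of candidate
# split proportions [eps1, eps2]
miller_siegmund_p <- function(chisq_max, eps1, eps2) {
  z <- sqrt(chisq_max)
  if (z <= 1) return(1)
  p <- stats::dnorm(z) * (z - 1 / z) *
    log((eps2 * (1 - eps1)) / (eps1 * (1 - eps2))) +
    4 * stats::dnorm(z) / z
  min(1, p)
}

#' Survival-optimal cut-point on a continuous score
#'
#' Scans all candidate thresholds (midpoints between consecutive distinct
#' sorted scores leaving at least `min_group` samples on each side),
#' computes the two-group log-rank statistic for each split
#' (score above threshold vs. at/below), and returns the maximizing
#' cut-point — the maximally-selected log-rank procedure behind
#' X-tile-style threshold selection. Because the maximum over many splits
#' is anti-conservative, the naive p at the optimum is reported together
#' with the Miller-Siegmund minimum-p corrected p-value.
#'
#' @param scores per-sample continuous scores (e.g. SSP distances).
#' @param records aligned survival data frame (`time_months`, `event`).
#' @param min_group minimum group size on each side (default 5).
#' @return Object of class `cutpoint_result`: `cutpoint`, `chisq` at the
#'   optimum, `naive_p`, `corrected_p`, `group_sizes`, and the per-candidate
#'   scan table.
#' @export
xtile_cutpoint <- function(scores, records, min_group = 5L) {
  check_records(records)
  if (length(scores) != nrow(records)) {
    stop_pdacsig("scores must align with records", "invalid_input")
  }
  if (anyNA(scores)) stop_pdacsig("scores must not be missing",
                                  "invalid_input")
  uq <- sort(unique(scores))
  if (length(uq) < 2L) {
    stop_pdacsig("all scores identical: no candidate cut-point",
                 "no_cutpoint")
  }
  mids <- (uq[-1] + uq[-length(uq)]) / 2
  n_low <- vapply(mids, function(c) sum(scores <= c), integer(1))
  keep <- n_low >= min_group & (length(scores) - n_low) >= min_group
  if (!any(keep)) {
    stop_pdacsig("no candidate split leaves min_group samples on both sides",
                 "no_cutpoint")
  }
  mids <- mids[keep]
  n_low <- n_low[keep]
  stat <- vapply(mids, function(c) {
    logrank_chisq_2g(records$time_months, records$event, scores <= c)
  }, numeric(1))
  best <- which.max(stat)
  naive_p <- stats::pchisq(stat[best], 1, lower.tail = FALSE)
  props <- n_low / length(scores)
  corrected_p <- max(naive_p,
                     miller_siegmund_p(stat[best], min(props), max(props)))
  structure(
    list(cutpoint = mids[best],
         chisq = stat[best],
         naive_p = naive_p,
         corrected_p = corrected_p,
         group_sizes = c(low_score = n_low[best],
                         high_score = length(scores) - n_low[best]),
         scan = data.frame(candidate = mids, chisq = stat, n_low = n_low)),
    class = "cutpoint_result"
  )
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf("Optimal cut-point %.4g (chi-square %.3f): naive p = %.4g, corrected p = %.4g\n",
              x$cutpoint, x$chisq, x$naive_p, x$corrected_p))
  cat(sprintf("  group sizes: %d / %d over %d candidates\n",
              x$group_sizes[1], x$group_sizes[2], nrow(x$scan)))
  invisible(x)
}
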