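test_that("product-limit estimate matches hand calculation", {
  rec <- data.frame(time_months = 1:4, event = 1L)
  km <- km_estimate(rec)
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$median, 2)            # first time S(t) <= 0.5

  cens <- data.frame(time_months = c(2, 5, 9), event = 0L)
  km2 <- km_estimate(cens)
  expect_true(all(km2$surv == 1))
  expect_true(is.na(km2$median))

  one <- km_estimate(data.frame(time_months = 5, event = 1L))
  expect_equal(one$surv, 0)
  expect_equal(one$median, 5)

  expect_error(km_estimate(data.frame(time_months = numeric(0),
                                      event = integer(0))),
               class = "invalid_input")
})

test_that("without censoring the KM curve is the empirical survival function", {
  set.seed(51)
  t <- round(rexp(40, 0.1), 1) + 0.1
  km <- km_estimate(data.frame(time_months = t, event = 1L))
  at <- sort(unique(t))
  expect_equal(km_survival_at(km, at),
               vapply(at, function(x) mean(t > x), numeric(1)))
  expect_equal(km_survival_at(km, 0), 1)
})

test_that("log-rank test degenerates correctly and is symmetric", {
  rec <- data.frame(time_months = c(1, 2, 3, 1, 2, 3),
                    event = c(1L, 1L, 0L, 1L, 1L, 0L))
  g <- rep(c("a", "b"), each = 3)
  res <- logrank_test(rec, g)
  expect_equal(res$chisq, 0)
  expect_equal(res$p, 1)

  nodeath <- data.frame(time_months = c(1, 2, 3, 4), event = 0L)
  res0 <- logrank_test(nodeath, c("a", "a", "b", "b"))
  expect_equal(res0$chisq, 0)
  expect_equal(res0$p, 1)

  set.seed(52)
  s <- make_exp_survival(60, hr = 3)
  r1 <- logrank_test(s$records, s$high)
  r2 <- logrank_test(s$records, !s$high)
  expect_equal(r1$chisq, r2$chisq)
  expect_error(logrank_test(s$records, rep("a", 60)),
               class = "invalid_input")
})

test_that("the internal two-group scan statistic equals survdiff's chi-square", {
  set.seed(53)
  for (i in 1:5) {
    s <- make_exp_survival(50, hr = 2, censor_rate = 0.3)
    mine <- pdacsig:::logrank_chisq_2g(s$records$time_months,
                                       s$records$event, s$high)
    ref <- survival::survdiff(
      survival::Surv(time_months, event) ~ g,
      data = cbind(s$records, g = s$high))$chisq
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("strong simulated hazard ratios give decisive log-rank evidence", {
  set.seed(54)
  ps <- vapply(1:10, function(i) {
    s <- make_exp_survival(400, hr = 4)
    logrank_test(s$records, s$high)$p
  }, numeric(1))
  expect_gte(mean(ps < 0.001), 0.9)
})

test_that("Cox fit is null on identical groups and equivariant to rescaling", {
  rec <- data.frame(time_months = rep(c(1.3, 2.7, 4.1, 6.2, 8.8), 2),
                    event = rep(c(1L, 1L, 1L, 0L, 1L), 2))
  fit <- cox_fit(rec, data.frame(group = rep(0:1, each = 5)))
  expect_lt(abs(fit$table$beta), 1e-8)
  expect_equal(fit$table$hr, 1, tolerance = 1e-6)

  set.seed(55)
  n <- 80
  x <- rnorm(n)
  t <- rexp(n, 0.05 * exp(0.5 * x))
  rec2 <- data.frame(time_months = t, event = 1L)
  f1 <- cox_fit(rec2, data.frame(x = x))
  f2 <- cox_fit(rec2, data.frame(x = 10 * x))
  expect_equal(f2$table$beta, f1$table$beta / 10, tolerance = 1e-6)
})

test_that("Cox handles missing covariates, ties flags, and failure modes", {
  set.seed(56)
  s <- make_exp_survival(60, hr = 3)
  cov <- data.frame(high = as.numeric(s$high))
  cov$high[1:5] <- NA
  fit <- cox_fit(s$records, cov)
  expect_equal(fit$n_dropped, 5)
  expect_equal(fit$n, 55)
  expect_gt(fit$table$beta, 0)          # sign matches the early-death group
  expect_true(fit$table$ci_lower < fit$table$hr &
              fit$table$hr < fit$table$ci_upper)

  fb <- cox_fit(s$records, data.frame(high = as.numeric(s$high)),
                ties = "breslow")
  expect_equal(fb$ties, "breslow")

  nodeath <- data.frame(time_months = 1:5, event = 0L)
  expect_error(cox_fit(nodeath, data.frame(x = 1:5)),
               class = "invalid_input")

  # monotone likelihood: all events in one group before any in the other
  sep <- data.frame(time_months = c(1:5, rep(50, 5)),
                    event = c(rep(1L, 5), rep(0L, 5)))
  expect_error(cox_fit(sep, data.frame(x = rep(c(1, 0), each = 5))),
               class = "fit_failure")
})

test_that("cut-point scan reduces to a plain log-rank on two-valued scores", {
  set.seed(57)
  s <- make_exp_survival(40, hr = 4)
  scores <- ifelse(s$high, 1.8, 0.2)
  cp <- xtile_cutpoint(scores, s$records, min_group = 5)
  expect_equal(nrow(cp$scan), 1)
  expect_equal(cp$cutpoint, 1.0)
  ref <- logrank_test(s$records, s$high)
  expect_equal(cp$chisq, ref$chisq, tolerance = 1e-10)
  expect_equal(cp$naive_p, ref$p, tolerance = 1e-10)
  expect_gte(cp$corrected_p, cp$naive_p)
})

test_that("cut-point scan enforces its preconditions", {
  rec <- data.frame(time_months = 1:10, event = 1L)
  expect_error(xtile_cutpoint(rep(1, 10), rec), class = "no_cutpoint")
  expect_error(xtile_cutpoint(c(rep(1, 9), 2), rec, min_group = 5),
               class = "no_cutpoint")
  expect_error(xtile_cutpoint(1:5, rec), class = "invalid_input")
})

test_that("the scan maximum is attained at the reported cut-point", {
  set.seed(58)
  s <- make_exp_survival(60, hr = 3, censor_rate = 0.2)
  scores <- runif(60)
  cp <- xtile_cutpoint(scores, s$records, min_group = 5)
  expect_equal(cp$chisq, max(cp$scan$chisq))
  expect_true(cp$cutpoint %in% cp$scan$candidate)
  expect_gte(min(cp$group_sizes), 5)
})
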