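# Kaplan-Meier, restricted mean survival, and log-rank tests against
# hand-computed worked examples and closed forms.

# 6-subject worked example with interleaved censoring:
# times 1,2,3,4,5,6; deaths at 1,3,4,6; censored at 2 and 5.
# Product-limit by hand: S(1)=5/6, S(3)=5/6*3/4, S(4)=5/8*2/3, S(6)=0.
six_times <- c(1, 2, 3, 4, 5, 6)
six_events <- c(1, 0, 1, 1, 0, 1)

test_that("product-limit estimate matches the hand-computed table", {
  km <- km_estimate(six_times, six_events)
  expect_equal(km$time, c(1, 3, 4, 6))
  expect_equal(km$n_risk, c(6, 4, 3, 1))
  expect_equal(km$n_event, rep(1, 4))
  expect_equal(km$surv, c(5 / 6, 5 / 8, 5 / 12, 0), tolerance = 1e-12)
})

test_that("no events means S identically 1; all events step down to 0", {
  km <- km_estimate(c(3, 7, 11), c(0, 0, 0))
  expect_equal(nrow(km), 0)
  expect_equal(restricted_mean_survival(km, 11), 11)

  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)
})

test_that("KM equals the empirical survival function without censoring", {
  set.seed(30)
  t <- rexp(40, 0.1)
  km <- km_estimate(t, rep(1, 40))
  for (i in seq_len(nrow(km))) {
    expect_equal(km$surv[i], mean(t > km$time[i]), tolerance = 1e-12)
  }
})

test_that("restricted mean is the exact step-function area", {
  km <- km_estimate(six_times, six_events)
  # 1*1 + (5/6)*2 + (5/8)*1 + (5/12)*2 + 0
  expect_equal(restricted_mean_survival(km, 6),
    1 + (5 / 6) * 2 + (5 / 8) + (5 / 12) * 2,
    tolerance = 1e-12
  )
  # default horizon is the largest observed time
  expect_equal(
    restricted_mean_survival(km),
    restricted_mean_survival(km, 6)
  )
  # agrees with the survival package's printed restricted mean
  fit <- survival::survfit(survival::Surv(six_times, six_events) ~ 1)
  tab <- summary(fit, rmean = 6)$table
  expect_equal(restricted_mean_survival(km, 6), unname(tab["rmean"]),
    tolerance = 1e-9
  )
})

test_that("restricted mean is monotone non-decreasing in the horizon", {
  km <- km_estimate(six_times, six_events)
  h <- seq(0.5, 6, by = 0.5)
  rm <- vapply(h, function(x) restricted_mean_survival(km, x), 1)
  expect_true(all(diff(rm) >= -1e-12))
  expect_error(restricted_mean_survival(km, 0), "positive")
  expect_error(restricted_mean_survival(km, 7), "largest observed")
})

test_that("restricted mean approaches the exponential closed form", {
  set.seed(31)
  lambda <- 0.05
  h <- 30
  t <- rexp(4000, lambda)
  km <- km_estimate(t, rep(1, 4000))
  expect_equal(restricted_mean_survival(km, h),
    (1 - exp(-lambda * h)) / lambda,
    tolerance = 0.05
  )
})

test_that("two-group log-rank matches the hand-computed O-E/V example", {
  # group A: 1 death, 3 death, 5 censored; B: 2 censored, 4 death, 6 death.
  # event-time table by hand (n_A, n, E_A contribution, V contribution):
  #   t=1: 3/6 -> E 1/2,  V = (1*5/5)*(3*3/36) = 1/4
  #   t=3: 2/4 -> E 1/2,  V = (1*3/3)*(2*2/16) = 1/4
  #   t=4: 1/3 -> E 1/3,  V = (1*2/2)*(1*2/9)  = 2/9
  #   t=6: 0/1 -> E 0,    V = 0
  # O_A = 2, E_A = 4/3, V = 13/18; chi-square = (2 - 4/3)^2 / (13/18) = 8/13
  g <- c("A", "B", "A", "B", "A", "B")
  res <- log_rank(six_times, six_events, g)
  expect_equal(res$statistic, 8 / 13, tolerance = 1e-10)
  expect_equal(res$df, 1)
  expect_equal(res$p_value, pchisq(8 / 13, 1, lower.tail = FALSE),
    tolerance = 1e-10
  )
})

test_that("identical groups give a statistic near 0 and p near 1", {
  t <- rep(c(2, 4, 6, 8), 2)
  e <- rep(c(1, 1, 0, 1), 2)
  g <- rep(c("A", "B"), each = 4)
  res <- log_rank(t, e, g)
  expect_lt(res$statistic, 1e-10)
  expect_gt(res$p_value, 0.999)
})

test_that("log-rank is invariant under group label permutation", {
  set.seed(32)
  t <- rexp(60, 0.1)
  e <- rbinom(60, 1, 0.7)
  g <- sample(c("a", "b", "c"), 60, TRUE)
  res1 <- log_rank(t, e, g)
  relabel <- c(a = "z", b = "x", c = "y")
  res2 <- log_rank(t, e, relabel[g])
  expect_equal(res2$statistic, res1$statistic, tolerance = 1e-12)
  expect_equal(res2$df, res1$df)
})

test_that("empty groups are dropped with a warning", {
  g <- factor(c("A", "A", "B", "B", "A", "B"), levels = c("A", "B", "C"))
  expect_warning(res <- log_rank(six_times, six_events, g), "empty group")
  expect_equal(res$df, 1)
})

test_that("pairwise log-rank returns a symmetric unadjusted p matrix", {
  set.seed(33)
  t <- rexp(90, 0.08)
  e <- rbinom(90, 1, 0.8)
  g <- rep(c("s0", "s1", "s2"), each = 30)
  p <- pairwise_log_rank(t, e, g)
  expect_equal(dim(p), c(3, 3))
  expect_true(all(is.na(diag(p))))
  expect_equal(p[upper.tri(p)], t(p)[upper.tri(p)])
  keep <- g %in% c("s0", "s2")
  expect_equal(
    p["s0", "s2"],
    log_rank(t[keep], e[keep], g[keep])$p_value
  )
})

test_that("survival_by_score summarizes a scored cohort", {
  cohort <- generate_cohort(synthetic_params(n_patients = 120, seed = 77))
  out <- survival_by_score(cohort)
  expect_equal(nrow(out$restricted_means), length(unique(cohort$score)))
  expect_true(all(out$restricted_means$n == table(cohort$score)))
  expect_s3_class(out$curves[[1]], "km_curve")
  expect_equal(out$risk_log_rank$df, 1)
})
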