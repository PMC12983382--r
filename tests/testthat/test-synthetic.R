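# Synthetic cohort and field-mask generators: determinism, marginal
# recovery, survival-model recovery, mask ground truth.

test_that("parameter validation rejects bad inputs with explanations", {
  expect_error(synthetic_params(n_patients = 0), "positive count")
  expect_error(synthetic_params(p_wpoi5 = 1.2), "p_wpoi5")
  expect_error(synthetic_params(hazard_ratio_per_point = 0), "positive")
  expect_error(synthetic_params(baseline_hazard = -1), "positive")
  expect_error(
    synthetic_params(covariate_marginals = list(gender = c(male = 0.7, female = 0.2))),
    "summing to 1"
  )
})

test_that("identical parameters give a byte-identical cohort export", {
  p <- synthetic_params(seed = 42)
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.csv")
  f2 <- file.path(d, "b.csv")
  write_cohort(generate_cohort(p), f1)
  write_cohort(generate_cohort(p), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed gives a different cohort
  write_cohort(generate_cohort(synthetic_params(seed = 43)), f2)
  expect_false(identical(readLines(f1), readLines(f2)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(1)
  a <- runif(1)
  set.seed(1)
  invisible(generate_cohort(synthetic_params(seed = 9)))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("cohort CSV round-trips through write/read", {
  cohort <- generate_cohort(synthetic_params(seed = 5))
  d <- withr::local_tempdir()
  path <- write_cohort(cohort, file.path(d, "cohort.csv"))
  back <- read_cohort(file.path(d, "cohort.csv"))
  expect_equal(nrow(back), 58)
  expect_equal(back$score, cohort$score)
  expect_equal(levels(back$til_category), c("low", "high"))
})

test_that("covariate marginals are recovered within 3 SE at n = 2000", {
  p <- synthetic_params(n_patients = 2000, seed = 101)
  cohort <- generate_cohort(p)
  for (nm in names(p$covariate_marginals)) {
    pr <- p$covariate_marginals[[nm]]
    emp <- table(cohort[[nm]]) / 2000
    se <- sqrt(pr * (1 - pr) / 2000)
    expect_true(all(abs(as.numeric(emp) - pr) <= 3 * se + 1e-12),
      label = sprintf("marginal recovery for %s", nm)
    )
  }
})

test_that("WPOI-5 and PNI frequencies track 22/58 and 15/58 over 200 seeds", {
  counts <- vapply(1:200, function(s) {
    ch <- generate_cohort(synthetic_params(seed = s))
    c(sum(ch$wpoi5 == "present"), sum(ch$pni == "present"))
  }, numeric(2))
  n_draws <- 200 * 58
  for (i in 1:2) {
    p0 <- c(22 / 58, 15 / 58)[i]
    phat <- sum(counts[i, ]) / n_draws
    se <- sqrt(p0 * (1 - p0) / n_draws)
    expect_lt(abs(phat - p0), 3 * se)
  }
})

test_that("TIL distribution is right-skewed with the target moments", {
  cohort <- generate_cohort(synthetic_params(n_patients = 20000, seed = 55))
  expect_equal(mean(cohort$til_percent), 22.8, tolerance = 0.02)
  expect_equal(sd(cohort$til_percent), 12.7, tolerance = 0.05)
  expect_lt(median(cohort$til_percent), mean(cohort$til_percent))
  expect_true(all(cohort$til_percent >= 0 & cohort$til_percent <= 100))
})

test_that("event times recover the closed-form exponential group means", {
  p <- synthetic_params(
    n_patients = 4000, seed = 66,
    hazard_ratio_per_point = 2, censor_rate = 0
  )
  cohort <- generate_cohort(p)
  expect_true(all(cohort$event == 1))
  for (s in 0:3) {
    expected <- 1 / (p$baseline_hazard * p$hazard_ratio_per_point^s)
    obs <- mean(cohort$survival_months[cohort$score == s])
    n_s <- sum(cohort$score == s)
    expect_lt(abs(obs - expected) / expected, 4 / sqrt(n_s))
  }
})

test_that("with hazard ratio 1 the event times are independent of the score", {
  p_vals <- vapply(1:120, function(s) {
    ch <- generate_cohort(synthetic_params(
      seed = 1000 + s,
      hazard_ratio_per_point = 1, censor_rate = 0
    ))
    suppressWarnings(
      log_rank(ch$survival_months, ch$event, ch$risk)$p_value
    )
  }, numeric(1))
  # roughly uniform: mean near 0.5 and no excess of small p-values
  expect_lt(abs(mean(p_vals) - 0.5), 3 * sqrt(1 / 12 / 120))
  expect_lt(abs(mean(p_vals < 0.2) - 0.2), 0.12)
})

test_that("the node-score association knob induces a positive trend", {
  ch <- generate_cohort(synthetic_params(
    n_patients = 800, seed = 7,
    node_score_assoc = 0.6
  ))
  tab <- table(ch$p_n, ch$score)
  res <- linear_by_linear(unclass(tab))
  expect_lt(res$p_value, 0.001)
  expect_gt(res$r, 0)
})

test_that("mask synthesis hits the requested fraction within tolerance", {
  f <- generate_field_masks(512, 512, 0.5, 0.25, seed = 1)
  expect_equal(field_til_percentage(f), 25, tolerance = 0.04)
  truth <- attr(f, "truth")
  expect_equal(
    field_til_percentage(f),
    100 * truth$achieved_fraction,
    tolerance = 1e-12
  )

  # percentage equals an independent brute-force pixel count
  ev_px <- 0
  til_px <- 0
  for (i in seq_len(nrow(f$stroma_mask))) {
    for (j in seq_len(ncol(f$stroma_mask))) {
      if (f$stroma_mask[i, j] && !f$exclusion_mask[i, j]) {
        ev_px <- ev_px + 1
        if (f$til_mask[i, j]) til_px <- til_px + 1
      }
    }
  }
  expect_equal(field_til_percentage(f), 100 * til_px / ev_px)
})

test_that("zero TIL fraction gives an exactly empty TIL mask", {
  f <- generate_field_masks(128, 128, 0.4, 0, seed = 2)
  expect_equal(sum(f$til_mask), 0)
  expect_equal(field_til_percentage(f), 0)
})

test_that("zero-area stroma with a TIL request is an error", {
  expect_error(generate_field_masks(64, 64, 0, 0.2, seed = 1), "zero-area")
})

test_that("TIL mask lies strictly inside the stroma, net of exclusions", {
  for (s in 1:5) {
    f <- generate_field_masks(96, 96, 0.5, 0.3,
      seed = s,
      exclusion_fraction = 0.1
    )
    expect_true(all(!f$til_mask | (f$stroma_mask & !f$exclusion_mask)))
  }
})
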