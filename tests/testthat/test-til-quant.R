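# %stromal TIL quantification: pixel ratios, exclusions, case means,
# median dichotomization, mask IO.

test_that("field percentage is the direct pixel-area ratio", {
  # stroma 100x100 = 10,000 px; TIL 50x50 = 2,500 px inside it
  f <- rect_field(
    w = 120, h = 120,
    stroma = c(1, 100, 1, 100), til = c(1, 50, 1, 50)
  )
  expect_equal(field_til_percentage(f), 25.0)
})

test_that("an empty TIL mask gives exactly 0", {
  f <- rect_field(til = NULL)
  expect_equal(field_til_percentage(f), 0)
})

test_that("TIL pixels outside the stroma are ignored", {
  # TIL rectangle half inside (40x40) and half outside the stroma
  f <- rect_field(
    w = 200, h = 200,
    stroma = c(1, 100, 1, 100), til = c(61, 140, 1, 40)
  )
  expect_equal(field_til_percentage(f), 100 * (40 * 40) / (100 * 100))
})

test_that("exclusion subtracts from numerator and denominator alike", {
  f <- rect_field(
    w = 100, h = 100,
    stroma = c(1, 80, 1, 80), # 6400 px
    til = c(1, 40, 1, 40), # 1600 px
    excl = c(21, 60, 1, 40) # overlaps half the TIL region
  )
  stroma_px <- 80 * 80
  excl_in_stroma <- 40 * 40
  til_after <- 20 * 40
  expect_equal(
    field_til_percentage(f),
    100 * til_after / (stroma_px - excl_in_stroma)
  )
  # brute-force masked-array oracle
  ev <- f$stroma_mask & !f$exclusion_mask
  expect_equal(
    field_til_percentage(f),
    100 * sum(f$til_mask & ev) / sum(ev)
  )
})

test_that("exclusion monotonicity matches the pixel-counting oracle", {
  base <- rect_field(
    w = 100, h = 100,
    stroma = c(1, 90, 1, 90), til = c(1, 30, 1, 30)
  )
  p0 <- field_til_percentage(base)
  # enlarging exclusion outside the TIL region never decreases the percentage
  f_out <- rect_field(
    w = 100, h = 100,
    stroma = c(1, 90, 1, 90), til = c(1, 30, 1, 30),
    excl = c(50, 90, 50, 90)
  )
  expect_gte(field_til_percentage(f_out), p0)
  # exclusion strictly inside the TIL region removes numerator and
  # denominator equally; direction checked against the oracle
  f_in <- rect_field(
    w = 100, h = 100,
    stroma = c(1, 90, 1, 90), til = c(1, 30, 1, 30),
    excl = c(1, 15, 1, 30)
  )
  ev <- f_in$stroma_mask & !f_in$exclusion_mask
  expect_equal(
    field_til_percentage(f_in),
    100 * sum(f_in$til_mask & ev) / sum(ev)
  )
})

test_that("empty evaluable stroma and mismatched dimensions are errors", {
  f <- rect_field(stroma = c(1, 40, 1, 40), til = NULL, excl = c(1, 40, 1, 40))
  expect_error(field_til_percentage(f), "no evaluable stromal area")
  expect_error(
    field_annotation(matrix(TRUE, 10, 10), matrix(TRUE, 9, 10)),
    "dimensions"
  )
})

test_that("nearest-neighbour upscaling changes the percentage by < 1 point", {
  f <- generate_field_masks(128, 128, 0.5, 0.3, seed = 2)
  p1 <- field_til_percentage(f)
  up <- function(m, k) m[rep(seq_len(nrow(m)), each = k), rep(seq_len(ncol(m)), each = k)]
  f2 <- field_annotation(
    up(f$stroma_mask, 2), up(f$til_mask, 2),
    up(f$exclusion_mask, 2)
  )
  expect_lt(abs(field_til_percentage(f2) - p1), 1)
})

test_that("case percentage is the arithmetic mean of 5 fields", {
  case <- case_til_percentage(c(10, 20, 30, 20, 10))
  expect_equal(case$case_percentage, 18)
  expect_equal(
    case_til_percentage(rep(22.8, 5))$case_percentage, 22.8
  )
  expect_error(case_til_percentage(c(10, 20, 30)), "required")
  expect_equal(
    case_til_percentage(c(10, 20, 30), min_fields = 3)$case_percentage, 20
  )
})

test_that("case mean over synthetic fields tracks the ground truth", {
  fr <- c(0.10, 0.20, 0.30, 0.15, 0.25)
  fields <- lapply(seq_along(fr), function(i) {
    generate_field_masks(128, 128, 0.5, fr[i], seed = i)
  })
  case <- case_til_percentage(fields)
  truth <- mean(vapply(
    fields,
    function(f) 100 * attr(f, "truth")$achieved_fraction, 1
  ))
  expect_equal(case$case_percentage, truth, tolerance = 1e-12)
  expect_lt(abs(case$case_percentage - mean(100 * fr)), 1)
})

test_that("median dichotomization uses a <=-cutoff rule", {
  split <- dichotomize_by_median(c(10, 20))
  expect_equal(split$cutoff, 15)
  expect_equal(as.character(split$category), c("low", "high"))

  # ties at the cutoff go low
  split <- dichotomize_by_median(c(10, 18, 18.1, 30, 18))
  expect_equal(split$cutoff, 18)
  expect_equal(
    as.character(split$category),
    c("low", "low", "high", "high", "low")
  )
})

test_that("58 distinct values split 29 low / 29 high", {
  set.seed(3)
  v <- rlnorm(58, 3, 0.5)
  stopifnot(!anyDuplicated(v))
  split <- dichotomize_by_median(v)
  expect_equal(as.integer(table(split$category)), c(29, 29))
})

test_that("odd cohorts with distinct values split ceiling(n/2) low", {
  set.seed(4)
  for (n in c(3, 7, 57)) {
    v <- sample(seq_len(10 * n), n)
    split <- dichotomize_by_median(v)
    expect_equal(sum(split$category == "low"), ceiling(n / 2))
    expect_equal(sum(split$category == "high"), floor(n / 2))
  }
})

test_that("identical values warn and all go low", {
  expect_warning(split <- dichotomize_by_median(rep(5, 4)), "identical")
  expect_true(all(split$category == "low"))
})

test_that("PNG mask round-trip preserves the field percentage", {
  f <- generate_field_masks(64, 64, 0.4, 0.3, seed = 9)
  d <- withr::local_tempdir()
  write_mask(f$stroma_mask, file.path(d, "s.png"))
  write_mask(f$til_mask, file.path(d, "t.png"))
  f2 <- field_annotation(
    read_mask(file.path(d, "s.png")),
    read_mask(file.path(d, "t.png"))
  )
  expect_equal(field_til_percentage(f2), field_til_percentage(f))
})

test_that("quantify_cases reads a manifest and excludes missing-mask cases", {
  d <- withr::local_tempdir()
  rows <- list()
  for (case in c("A", "B")) {
    for (i in 1:5) {
      f <- generate_field_masks(48, 48, 0.5, 0.2, seed = i + 10 * (case == "B"))
      sp <- file.path(d, sprintf("%s_%d_s.png", case, i))
      tp <- file.path(d, sprintf("%s_%d_t.png", case, i))
      write_mask(f$stroma_mask, sp)
      write_mask(f$til_mask, tp)
      rows[[length(rows) + 1]] <- data.frame(
        case_id = case, field_id = i, stroma = basename(sp), til = basename(tp)
      )
    }
  }
  manifest <- do.call(rbind, rows)
  res <- quantify_cases(manifest, base_dir = d)
  expect_equal(res$case_id, c("A", "B"))
  expect_true(all(res$til_percent > 15 & res$til_percent < 25))

  manifest$stroma[1] <- "missing.png"
  expect_warning(res2 <- quantify_cases(manifest, base_dir = d), "excluded")
  expect_equal(res2$case_id, "B")
})
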