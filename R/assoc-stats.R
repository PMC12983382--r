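# Association statistics: contingency-table tests, one-way ANOVA (raw and
# from printed group summaries), correlation, and rank-based ROC.

#' Construct a labelled contingency table
#'
#' A small container for an R x C count matrix with optional ordinal
#' scores per axis. Scores are only used by [linear_by_linear()]; when
#' absent, integer ranks `0, 1, 2, ...` are assumed there.
#'
#' @param counts non-negative integer matrix (R x C, both >= 2 after
#'   construction; single-row/column tables are rejected by the tests
#'   that need more).
#' @param row_labels,col_labels optional character labels; default to the
#'   dimnames of `counts` or `R1..`/`C1..`.
#' @param row_scores,col_scores optional numeric ordinal scores, one per
#'   level, for trend tests.
#' @return an object of class `contingency_table`.
#' @examples
#' tab <- contingency_table(matrix(c(9, 3, 1, 0, 8, 12, 8, 8, 2, 5, 2, 0),
#'   nrow = 3, byrow = TRUE,
#'   dimnames = list(c("well", "moderate", "poor"), 0:3)
#' ))
#' pearson_chi_square(tab)
#' @export
contingency_table <- function(counts, row_labels = NULL, col_labels = NULL,
                              row_scores = NULL, col_scores = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(!is.finite(counts))) {
    stop("'counts' must be a finite numeric matrix", call. = FALSE)
  }
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8)) {
    stop("'counts' must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) <= 0) stop("grand total must be positive", call. = FALSE)
  counts <- round(counts)
  if (is.null(row_labels)) {
    row_labels <- rownames(counts)
    if (is.null(row_labels)) row_labels <- paste0("R", seq_len(nrow(counts)))
  }
  if (is.null(col_labels)) {
    col_labels <- colnames(counts)
    if (is.null(col_labels)) col_labels <- paste0("C", seq_len(ncol(counts)))
  }
  stopifnot(
    length(row_labels) == nrow(counts),
    length(col_labels) == ncol(counts)
  )
  if (!is.null(row_scores) && length(row_scores) != nrow(counts)) {
    stop("'row_scores' must have one score per row", call. = FALSE)
  }
  if (!is.null(col_scores) && length(col_scores) != ncol(counts)) {
    stop("'col_scores' must have one score per column", call. = FALSE)
  }
  dimnames(counts) <- list(row_labels, col_labels)
  structure(
    list(
      counts = counts,
      row_scores = row_scores,
      col_scores = col_scores
    ),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf(
    "Contingency table: %d x %d, N = %d\n",
    nrow(x$counts), ncol(x$counts), sum(x$counts)
  ))
  print(x$counts)
  invisible(x)
}

# Internal: uniform result container for all tests in the package.
assoc_result <- function(method, statistic, df, p_value, ...) {
  structure(
    list(
      method = method, statistic = statistic,
      df = df, p_value = p_value, ...
    ),
    class = "assoc_result"
  )
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf(
    "%s: statistic = %.4f, df = %s, p = %s\n",
    x$method, x$statistic,
    paste(format(x$df), collapse = ", "),
    format_p(x$p_value)
  ))
  invisible(x)
}

#' Format a p-value for reports
#'
#' Three decimals; values below 0.0005 print as `"0.000"` (so they round
#' to zero at that precision), a common convention in clinical tables.
#'
#' @param p numeric vector of p-values.
#' @param digits decimals to print.
#' @return character vector.
#' @export
format_p <- function(p, digits = 3) {
  formatC(round(p, digits), format = "f", digits = digits)
}

drop_empty_margins <- function(counts) {
  zr <- rowSums(counts) == 0
  zc <- colSums(counts) == 0
  if (any(zr) || any(zc)) {
    warning(
      "dropping empty levels: ",
      paste(c(rownames(counts)[zr], colnames(counts)[zc]), collapse = ", "),
      call. = FALSE
    )
    counts <- counts[!zr, !zc, drop = FALSE]
  }
  counts
}

#' Pearson chi-square test of independence
#'
#' Classical Pearson statistic `sum((O - E)^2 / E)` with
#' `E = row total x column total / N`, no continuity correction, and
#' `df = (R - 1)(C - 1)`. Levels with a zero margin are dropped (with a
#' warning) and the degrees of freedom adjusted. A warning is issued when
#' any expected count falls below 5; no exact test is substituted.
#'
#' @param table a [contingency_table()] or a count matrix.
#' @return an `assoc_result` with fields `statistic`, `df`, `p_value`,
#'   and `expected` (the expected count matrix).
#' @seealso [linear_by_linear()] for the ordinal trend alternative.
#' @export
pearson_chi_square <- function(table) {
  counts <- as_counts(table)
  counts <- drop_empty_margins(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("need at least 2 non-empty rows and columns", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(res$expected < 5)) {
    warning(
      sprintf(
        "%d of %d expected counts are below 5; chi-square approximation may be poor",
        sum(res$expected < 5), length(res$expected)
      ),
      call. = FALSE
    )
  }
  assoc_result(
    "pearson_chi_square",
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = unname(res$p.value),
    expected = res$expected
  )
}

#' Linear-by-linear association (ordinal trend) test
#'
#' The Mantel-Haenszel trend statistic for ordered categories:
#' `M^2 = (N - 1) r^2` on 1 degree of freedom, where `r` is the Pearson
#' correlation between row and column scores over the N cross-classified
#' observations. Default scores are integer ranks `0, 1, 2, ...`; the
#' statistic is invariant under affine rescaling of either axis's scores.
#'
#' @param table a [contingency_table()] (its `row_scores`/`col_scores`
#'   are used when present) or a count matrix.
#' @param row_scores,col_scores optional score overrides.
#' @return an `assoc_result` with `statistic` (M^2), `df = 1`, `p_value`,
#'   and `r` (the score correlation).
#' @export
linear_by_linear <- function(table, row_scores = NULL, col_scores = NULL) {
  counts <- as_counts(table)
  if (inherits(table, "contingency_table")) {
    if (is.null(row_scores)) row_scores <- table$row_scores
    if (is.null(col_scores)) col_scores <- table$col_scores
  }
  if (is.null(row_scores)) row_scores <- seq_len(nrow(counts)) - 1
  if (is.null(col_scores)) col_scores <- seq_len(ncol(counts)) - 1
  if (length(unique(row_scores)) < 2 || length(unique(col_scores)) < 2) {
    stop("scores are degenerate (all equal) on one axis", call. = FALSE)
  }
  n <- sum(counts)
  if (n < 2) stop("need at least 2 observations", call. = FALSE)
  # weighted Pearson correlation of the two score vectors over all cells
  w <- counts / n
  mx <- sum(rowSums(w) * row_scores)
  my <- sum(colSums(w) * col_scores)
  vx <- sum(rowSums(w) * (row_scores - mx)^2)
  vy <- sum(colSums(w) * (col_scores - my)^2)
  if (vx == 0 || vy == 0) {
    stop("scores carry no variation over the observed margins", call. = FALSE)
  }
  cxy <- sum(w * outer(row_scores - mx, col_scores - my))
  r <- cxy / sqrt(vx * vy)
  m2 <- (n - 1) * r^2
  assoc_result(
    "linear_by_linear",
    statistic = m2,
    df = 1L,
    p_value = stats::pchisq(m2, df = 1, lower.tail = FALSE),
    r = r
  )
}

as_counts <- function(table) {
  if (inherits(table, "contingency_table")) {
    return(table$counts)
  }
  contingency_table(table)$counts
}

#' Group summary triple
#'
#' One row per group with the size, mean and sample standard deviation
#' (n - 1 denominator) -- the "N / Mean +/- SD" cells of a clinical
#' summary table. Singleton groups may carry `NA` (or 0) standard
#' deviations; they contribute nothing to within-group variation.
#'
#' @param n integer group sizes.
#' @param mean group means.
#' @param sd sample standard deviations.
#' @param label optional group labels.
#' @return a `data.frame` with columns `label`, `n`, `mean`, `sd`.
#' @export
group_summary <- function(n, mean, sd, label = NULL) {
  stopifnot(length(n) == length(mean), length(n) == length(sd))
  if (any(n < 1)) stop("group sizes must be >= 1", call. = FALSE)
  sd[n == 1 & is.na(sd)] <- 0
  if (any(is.na(sd) & n >= 2)) {
    stop("sd required for groups with n >= 2", call. = FALSE)
  }
  if (any(sd < 0, na.rm = TRUE)) stop("sd must be non-negative", call. = FALSE)
  if (is.null(label)) label <- paste0("group", seq_along(n))
  data.frame(label = label, n = as.integer(n), mean = mean, sd = sd)
}

sum_of_squares <- function(summaries) {
  n <- summaries$n
  m <- summaries$mean
  s <- summaries$sd
  s[n == 1] <- 0
  grand <- sum(n * m) / sum(n)
  list(
    grand_mean = grand,
    ssb = sum(n * (m - grand)^2),
    ssw = sum((n - 1) * s^2),
    n_total = sum(n),
    k = length(n)
  )
}

#' One-way ANOVA from raw data
#'
#' Classical fixed-effects one-way analysis of variance,
#' `F = (SSB / (k - 1)) / (SSW / (n - k))`, fitted with [stats::lm()].
#' When all groups are constant and equal (SSB = 0) the test
#' degenerates to `F = 0, p = 1`; when groups are internally constant
#' but differ (SSW = 0, SSB > 0) the separation is perfect and `p = 0`
#' is reported with a warning.
#'
#' @param groups a list of numeric vectors (>= 2 groups), or a numeric
#'   vector together with `g`.
#' @param g optional grouping factor when `groups` is a single vector.
#' @return an `assoc_result` with `statistic` (F), `df` (numerator,
#'   denominator), and `p_value`.
#' @export
one_way_anova_raw <- function(groups, g = NULL) {
  if (!is.null(g)) {
    groups <- split(as.numeric(groups), g)
  }
  groups <- lapply(groups, function(x) as.numeric(x[!is.na(x)]))
  groups <- groups[vapply(groups, length, 1L) > 0]
  k <- length(groups)
  n <- sum(lengths(groups))
  if (k < 2) stop("need at least 2 non-empty groups", call. = FALSE)
  if (n < 3 || n - k < 1) {
    stop("need a total of at least k + 1 observations", call. = FALSE)
  }
  y <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_len(k), lengths(groups)))
  # degenerate layouts break the lm path (perfect or constant fits)
  within_var <- vapply(groups, function(x) {
    if (length(x) < 2) 0 else stats::var(x)
  }, 1)
  gmeans <- vapply(groups, mean, 1)
  if (all(within_var == 0)) {
    if (max(gmeans) - min(gmeans) == 0) {
      return(anova_result(0, 0, df1 = k - 1, df2 = n - k))
    }
    return(anova_result(1, 0, df1 = k - 1, df2 = n - k))
  }
  a <- stats::anova(stats::lm(y ~ fac))
  ssb <- a[["Sum Sq"]][1]
  ssw <- a[["Sum Sq"]][2]
  anova_result(ssb, ssw, df1 = k - 1, df2 = n - k)
}

anova_result <- function(ssb, ssw, df1, df2) {
  if (ssw <= .Machine$double.eps * (ssb + ssw) && ssb > 0) {
    warning("no within-group variance; groups are perfectly separated",
      call. = FALSE
    )
    return(assoc_result("one_way_anova",
      statistic = Inf, df = c(df1, df2),
      p_value = 0, ssb = ssb, ssw = ssw
    ))
  }
  if (ssb <= 0) {
    return(assoc_result("one_way_anova",
      statistic = 0, df = c(df1, df2),
      p_value = 1, ssb = ssb, ssw = ssw
    ))
  }
  f <- (ssb / df1) / (ssw / df2)
  assoc_result("one_way_anova",
    statistic = f, df = c(df1, df2),
    p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
    ssb = ssb, ssw = ssw
  )
}

#' One-way ANOVA from group summaries
#'
#' Reconstructs the one-way ANOVA table from `(n, mean, sd)` triples, as
#' needed when only a printed summary table is available: the
#' between-group sum of squares is `sum n_i (m_i - grand)^2` with the
#' n-weighted grand mean, and the within-group sum is
#' `sum (n_i - 1) s_i^2`, treating printed SDs as sample SDs (n - 1
#' denominator). Groups of size 1 contribute zero within-group variance.
#' Numerically identical to [one_way_anova_raw()] on any raw data whose
#' per-group summaries match.
#'
#' @param summaries a `data.frame` from [group_summary()] (columns `n`,
#'   `mean`, `sd`).
#' @return an `assoc_result` as in [one_way_anova_raw()].
#' @examples
#' # %stromal TILs by age group in a 58-patient OSCC cohort
#' s <- group_summary(
#'   n = c(3, 10, 14, 13, 18),
#'   mean = c(11.14, 16.39, 24.34, 16.77, 31.18),
#'   sd = c(2.74, 11.69, 14.11, 6.28, 11.82)
#' )
#' one_way_anova_summary(s) # F ~ 5.13 on (4, 53) df, p ~ 0.001
#' @export
one_way_anova_summary <- function(summaries) {
  check_summaries(summaries)
  if (nrow(summaries) < 2) stop("need at least 2 groups", call. = FALSE)
  if (all(summaries$n == 1)) {
    stop("all groups have n = 1: no within-group variance is estimable",
      call. = FALSE
    )
  }
  ss <- sum_of_squares(summaries)
  if (ss$n_total < ss$k + 1) {
    stop("need a total of at least k + 1 observations", call. = FALSE)
  }
  anova_result(ss$ssb, ss$ssw, df1 = ss$k - 1, df2 = ss$n_total - ss$k)
}

check_summaries <- function(summaries) {
  if (!is.data.frame(summaries) ||
    !all(c("n", "mean", "sd") %in% names(summaries))) {
    stop("'summaries' must be a data.frame with columns n, mean, sd",
      call. = FALSE
    )
  }
  if (any(summaries$n < 1)) stop("group sizes must be >= 1", call. = FALSE)
  if (any(is.na(summaries$sd) & summaries$n >= 2)) {
    stop("sd required for groups with n >= 2", call. = FALSE)
  }
  invisible(summaries)
}

#' Pool group summaries into a total row
#'
#' Exact reconstruction of the overall `(n, mean, sd)` from per-group
#' summaries: the pooled variance is `(SSB + SSW) / (n - 1)`, so the
#' result matches a direct summary of the concatenated raw data.
#'
#' @inheritParams one_way_anova_summary
#' @return a one-row `data.frame` with columns `label`, `n`, `mean`, `sd`.
#' @export
pooled_total_summary <- function(summaries) {
  check_summaries(summaries)
  if (nrow(summaries) == 1) {
    out <- summaries[1, c("n", "mean", "sd"), drop = FALSE]
    return(data.frame(label = "total", out, row.names = NULL))
  }
  ss <- sum_of_squares(summaries)
  if (ss$n_total < 2) stop("need a total of at least 2 observations", call. = FALSE)
  data.frame(
    label = "total",
    n = as.integer(ss$n_total),
    mean = ss$grand_mean,
    sd = sqrt((ss$ssb + ss$ssw) / (ss$n_total - 1))
  )
}

#' Pearson correlation with t-based test
#'
#' Pairwise deletion of incomplete pairs, then [stats::cor.test()].
#'
#' @param x,y paired numeric vectors.
#' @return an `assoc_result` with `statistic` (t), `df`, `p_value`, `r`,
#'   and `n` (complete pairs).
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y", call. = FALSE)
  }
  res <- stats::cor.test(x, y, method = "pearson")
  assoc_result(
    "pearson_correlation",
    statistic = unname(res$statistic),
    df = unname(res$parameter),
    p_value = res$p.value,
    r = unname(res$estimate),
    n = length(x)
  )
}

#' ROC area under the curve by the rank (Mann-Whitney) method
#'
#' AUC is the probability that a randomly chosen positive case carries a
#' larger predictor value than a randomly chosen negative case, with
#' ties counted half -- computed from mid-ranks. The standard error is
#' Hanley-McNeil's, and the p-value is a two-sided normal test of
#' AUC = 0.5. The AUC is always reported in the orientation "larger
#' predictor predicts the positive class"; `flipped` flags an observed
#' AUC below 0.5 (the predictor discriminates in the other direction).
#'
#' @param predictor numeric marker values.
#' @param outcome binary outcome: logical, 0/1, or a two-level factor
#'   (the second level is taken as positive).
#' @return a list of class `roc_result`: `auc`, `se`, `p_value`,
#'   `n_pos`, `n_neg`, `flipped`.
#' @export
roc_auc <- function(predictor, outcome) {
  stopifnot(length(predictor) == length(outcome))
  keep <- stats::complete.cases(predictor, outcome)
  predictor <- predictor[keep]
  outcome <- outcome[keep]
  pos <- as_binary_outcome(outcome)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  r <- rank(predictor) # mid-ranks for ties
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
    (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  z <- if (se > 0) (auc - 0.5) / se else Inf * sign(auc - 0.5)
  structure(
    list(
      auc = auc, se = se,
      p_value = 2 * stats::pnorm(-abs(z)),
      n_pos = n1, n_neg = n0,
      flipped = auc < 0.5
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC AUC = %.3f (SE %.3f), p vs 0.5 = %s  [%d pos / %d neg]%s\n",
    x$auc, x$se, format_p(x$p_value), x$n_pos, x$n_neg,
    if (x$flipped) "  (larger predictor favors the negative class)" else ""
  ))
  invisible(x)
}

as_binary_outcome <- function(outcome) {
  if (is.logical(outcome)) {
    return(outcome)
  }
  if (is.factor(outcome)) {
    if (nlevels(droplevels(outcome)) != 2) {
      stop("'outcome' factor must have exactly 2 observed levels", call. = FALSE)
    }
    return(outcome == levels(droplevels(outcome))[2])
  }
  u <- sort(unique(outcome))
  if (!all(u %in% c(0, 1))) {
    stop("'outcome' must be logical, 0/1, or a two-level factor", call. = FALSE)
  }
  outcome == 1
}
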