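# Kaplan-Meier estimation, restricted mean survival, and log-rank tests.
# Fitting goes through the survival package; the restricted mean is the
# area under the product-limit curve by exact step integration, the
# convention behind the "mean survival" printed by standard statistical
# software.

#' Kaplan-Meier product-limit estimate
#'
#' @param times follow-up in months (>= 0).
#' @param events event indicator: 1/`TRUE` = death, 0/`FALSE` = censored.
#'   Censored subjects at a tied time remain at risk for events at that
#'   time (the standard convention).
#' @return an object of class `km_curve`: a `data.frame` of the distinct
#'   event times with columns `time`, `n_risk`, `n_event`, `surv`
#'   (the step estimate just after `time`), plus attributes `n`
#'   (subjects) and `max_time` (largest observed time, the default
#'   restricted-mean horizon).
#' @examples
#' km_estimate(c(1, 2, 3, 4, 5, 6), c(1, 0, 1, 1, 0, 1))
#' @export
km_estimate <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (length(times) == 0) stop("empty input", call. = FALSE)
  if (any(is.na(times)) || any(is.na(events))) {
    stop("missing times or event indicators", call. = FALSE)
  }
  if (any(times < 0)) stop("times must be non-negative", call. = FALSE)
  events <- as.integer(as.logical(events))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  keep <- fit$n.event > 0
  curve <- data.frame(
    time = fit$time[keep],
    n_risk = fit$n.risk[keep],
    n_event = fit$n.event[keep],
    surv = fit$surv[keep]
  )
  structure(curve,
    n = length(times), max_time = max(times),
    class = c("km_curve", "data.frame")
  )
}

#' Restricted mean survival time
#'
#' Area under the Kaplan-Meier curve from 0 to `horizon` by exact step
#' integration. The default horizon is the largest observed time in the
#' group, matching the "mean survival" that standard packages print for
#' a Kaplan-Meier fit.
#'
#' @param curve a [km_estimate()] result.
#' @param horizon months; must be positive and no larger than the
#'   largest observed time.
#' @return months.
#' @export
restricted_mean_survival <- function(curve, horizon = NULL) {
  stopifnot(inherits(curve, "km_curve"))
  max_time <- attr(curve, "max_time")
  if (is.null(horizon)) horizon <- max_time
  if (horizon <= 0) stop("'horizon' must be positive", call. = FALSE)
  if (horizon > max_time + 1e-9) {
    stop("'horizon' exceeds the largest observed time", call. = FALSE)
  }
  t_ev <- curve$time
  s_ev <- curve$surv
  # survival is 1 before the first event and constant between events
  steps_t <- c(0, t_ev[t_ev < horizon])
  steps_s <- c(1, s_ev[t_ev < horizon])
  widths <- diff(c(steps_t, horizon))
  sum(widths * steps_s)
}

#' Log-rank test across groups
#'
#' The standard log-rank chi-square on `k - 1` degrees of freedom,
#' computed with [survival::survdiff()]. Empty groups are dropped with a
#' warning.
#'
#' @param times,events as in [km_estimate()].
#' @param group grouping factor/vector (>= 2 non-empty groups).
#' @return an `assoc_result` with `statistic`, `df`, `p_value`, and
#'   `obs`/`exp` per-group event counts.
#' @export
log_rank <- function(times, events, group) {
  stopifnot(length(times) == length(events), length(times) == length(group))
  if (!is.factor(group)) group <- factor(group)
  empty <- !levels(group) %in% levels(droplevels(group))
  if (any(empty)) {
    warning(
      "dropping empty group(s): ",
      paste(levels(group)[empty], collapse = ", "),
      call. = FALSE
    )
    group <- droplevels(group)
  }
  if (nlevels(group) < 2) {
    stop("need at least 2 non-empty groups", call. = FALSE)
  }
  events <- as.integer(as.logical(events))
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- nlevels(group) - 1L
  assoc_result(
    "log_rank",
    statistic = unname(sd$chisq),
    df = df,
    p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
    obs = sd$obs, exp = sd$exp
  )
}

#' Pairwise log-rank comparisons
#'
#' Two-group log-rank tests for every pair of groups. P-values are
#' unadjusted for multiplicity.
#'
#' @inheritParams log_rank
#' @return a symmetric matrix of unadjusted p-values (`NA` diagonal).
#' @export
pairwise_log_rank <- function(times, events, group) {
  group <- droplevels(factor(group))
  lv <- levels(group)
  if (length(lv) < 2) stop("need at least 2 non-empty groups", call. = FALSE)
  p <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)[-length(lv)]) {
    for (j in (i + 1):length(lv)) {
      keep <- group %in% lv[c(i, j)]
      res <- log_rank(times[keep], events[keep], droplevels(group[keep]))
      p[i, j] <- p[j, i] <- res$p_value
    }
  }
  p
}

#' Survival analysis by modified BG score and risk category
#'
#' Convenience wrapper for a scored cohort: Kaplan-Meier curves and
#' restricted mean survival per score group (and per risk category),
#' the overall log-rank test, and unadjusted pairwise comparisons.
#'
#' @param cohort a `data.frame` with columns `survival_months`, `event`
#'   (1 = death), and `score` (and optionally `risk`).
#' @return a list: `curves` (per score group), `restricted_means`
#'   (`data.frame` of group, n, events, restricted mean and its
#'   horizon), `log_rank` overall test, `pairwise` p matrix, and the
#'   same four for `risk` when present (`risk_*`).
#' @export
survival_by_score <- function(cohort) {
  need <- c("survival_months", "event", "score")
  if (!all(need %in% names(cohort))) {
    stop("cohort must have columns: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  ev <- as.integer(as.logical(cohort$event))
  by_group <- function(g) {
    g <- droplevels(factor(g))
    curves <- lapply(levels(g), function(lv) {
      keep <- g == lv
      km_estimate(cohort$survival_months[keep], ev[keep])
    })
    names(curves) <- levels(g)
    rm_tab <- data.frame(
      group = levels(g),
      n = as.integer(table(g)),
      events = as.integer(tapply(ev, g, sum)),
      restricted_mean = vapply(curves, restricted_mean_survival, numeric(1)),
      horizon = vapply(curves, function(cv) attr(cv, "max_time"), numeric(1))
    )
    rownames(rm_tab) <- NULL
    list(
      curves = curves,
      restricted_means = rm_tab,
      log_rank = if (nlevels(g) >= 2) {
        log_rank(cohort$survival_months, ev, g)
      } else {
        NULL
      },
      pairwise = if (nlevels(g) > 2) {
        pairwise_log_rank(cohort$survival_months, ev, g)
      } else {
        NULL
      }
    )
  }
  out <- by_group(cohort$score)
  if ("risk" %in% names(cohort)) {
    rk <- by_group(cohort$risk)
    out$risk_curves <- rk$curves
    out$risk_restricted_means <- rk$restricted_means
    out$risk_log_rank <- rk$log_rank
  }
  out
}
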