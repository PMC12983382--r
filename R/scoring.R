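# The modified Brandwein-Gensler score: three binary histological
# indicators added into a 0-3 score, with 0-1 low risk and 2-3 high risk.

#' Modified Brandwein-Gensler score
#'
#' One point each for: worst pattern of invasion grade 5 present,
#' perineural invasion present, and %stromal TILs in the low group.
#' Low TIL density counting as adverse follows the original model's
#' treatment of a weak lymphocytic host response as a risk feature;
#' `til_low_is_adverse = FALSE` flips the coding for sensitivity checks.
#'
#' @param wpoi5,pni `"present"`/`"absent"` (or logical, `TRUE` = present);
#'   vectorized.
#' @param til_category `"low"`/`"high"` (factor or character).
#' @param til_low_is_adverse if `TRUE` (default) low TILs score 1.
#' @return a `data.frame` with one row per subject: the three component
#'   points (`wpoi5_point`, `pni_point`, `til_point`), `score` (0-3) and
#'   `risk` (factor `low`/`high`).
#' @examples
#' modified_bg_score("present", "present", "low") # score 3, high risk
#' modified_bg_score("absent", "absent", "high") # score 0, low risk
#' @export
modified_bg_score <- function(wpoi5, pni, til_category,
                              til_low_is_adverse = TRUE) {
  w <- as_present(wpoi5, "wpoi5")
  p <- as_present(pni, "pni")
  tl <- as_low(til_category)
  n <- max(length(w), length(p), length(tl))
  w <- rep_len(w, n)
  p <- rep_len(p, n)
  tl <- rep_len(tl, n)
  til_point <- if (til_low_is_adverse) as.integer(tl) else as.integer(!tl)
  score <- as.integer(w) + as.integer(p) + til_point
  data.frame(
    wpoi5_point = as.integer(w),
    pni_point = as.integer(p),
    til_point = til_point,
    score = score,
    risk = risk_category(score)
  )
}

as_present <- function(x, component) {
  if (any(is.na(x))) {
    stop(sprintf("missing value in component '%s'", component), call. = FALSE)
  }
  if (is.logical(x)) {
    return(x)
  }
  x <- tolower(as.character(x))
  bad <- !x %in% c("present", "absent")
  if (any(bad)) {
    stop(sprintf(
      "component '%s' must be 'present' or 'absent' (got '%s')",
      component, x[bad][1]
    ), call. = FALSE)
  }
  x == "present"
}

as_low <- function(x) {
  if (any(is.na(x))) {
    stop("missing value in component 'til_category'", call. = FALSE)
  }
  x <- tolower(as.character(x))
  bad <- !x %in% c("low", "high")
  if (any(bad)) {
    stop(sprintf(
      "component 'til_category' must be 'low' or 'high' (got '%s')",
      x[bad][1]
    ), call. = FALSE)
  }
  x == "low"
}

#' Risk category from the modified score
#'
#' Scores 0-1 are low risk, 2-3 high risk.
#'
#' @param score integer vector in `0:3`.
#' @param boundary smallest score counted as high risk (default 2).
#' @return factor with levels `low`, `high`.
#' @export
risk_category <- function(score, boundary = 2) {
  if (any(is.na(score)) || any(!score %in% 0:3)) {
    stop("'score' must lie in 0..3", call. = FALSE)
  }
  factor(ifelse(score >= boundary, "high", "low"), levels = c("low", "high"))
}

#' Score a whole cohort table
#'
#' Appends `til_category` (median split of `til_percent`, unless the
#' column already exists), the three component points, `score`, and
#' `risk` to a cohort `data.frame` with columns `wpoi5`, `pni` and
#' either `til_category` or `til_percent`.
#'
#' @param cohort a cohort `data.frame`.
#' @inheritParams modified_bg_score
#' @param boundary passed to [risk_category()].
#' @return the cohort with scoring columns appended; the TIL cutoff used
#'   (if computed here) is attached as attribute `"til_cutoff"`.
#' @export
score_cohort <- function(cohort, til_low_is_adverse = TRUE, boundary = 2) {
  stopifnot(is.data.frame(cohort))
  if (!all(c("wpoi5", "pni") %in% names(cohort))) {
    stop("cohort must have columns 'wpoi5' and 'pni'", call. = FALSE)
  }
  cutoff <- NA_real_
  if (!"til_category" %in% names(cohort)) {
    if (!"til_percent" %in% names(cohort)) {
      stop("cohort needs 'til_category' or 'til_percent'", call. = FALSE)
    }
    split <- dichotomize_by_median(cohort$til_percent)
    cohort$til_category <- split$category
    cutoff <- split$cutoff
  }
  sc <- modified_bg_score(cohort$wpoi5, cohort$pni, cohort$til_category,
    til_low_is_adverse = til_low_is_adverse
  )
  cohort$score <- sc$score
  cohort$risk <- risk_category(sc$score, boundary = boundary)
  attr(cohort, "til_cutoff") <- cutoff
  cohort
}
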