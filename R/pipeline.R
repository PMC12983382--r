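# One-call pipeline: cohort in (CSV or synthetic), TIL quantification,
# scoring, association tables, survival analysis, report tables out.

#' Pipeline configuration
#'
#' Exactly one input mode is active: `"cohort_csv"` reads a per-patient
#' table; `"synthetic"` generates one (a seed is then required, carried
#' by `params`). An optional mask manifest replaces the cohort's
#' `til_percent` column with values quantified from annotation masks.
#'
#' @param mode `"cohort_csv"` or `"synthetic"`.
#' @param cohort_csv path to a cohort CSV (see [read_cohort()] for the
#'   column dictionary) in `cohort_csv` mode.
#' @param params a [synthetic_params()] object in `synthetic` mode.
#' @param mask_manifest optional path to a mask manifest CSV (see
#'   [quantify_cases()]).
#' @param mask_dir base directory for relative mask paths.
#' @param til_low_is_adverse coding direction of the TIL component.
#' @param risk_boundary smallest score counted as high risk.
#' @param out_dir optional directory; when given, every report table is
#'   written there as CSV.
#' @param p_digits decimals for presented p-values (computation keeps
#'   full precision; rounding happens only in the presentation columns).
#' @return a validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("cohort_csv", "synthetic"),
                            cohort_csv = NULL,
                            params = NULL,
                            mask_manifest = NULL,
                            mask_dir = ".",
                            til_low_is_adverse = TRUE,
                            risk_boundary = 2,
                            out_dir = NULL,
                            p_digits = 3) {
  mode <- match.arg(mode)
  if (mode == "cohort_csv") {
    if (is.null(cohort_csv)) stop("'cohort_csv' required", call. = FALSE)
    if (!file.exists(cohort_csv)) {
      stop("cohort file not found: ", cohort_csv, call. = FALSE)
    }
    if (!is.null(params)) {
      stop("'params' only applies to synthetic mode", call. = FALSE)
    }
  } else {
    if (!is.null(cohort_csv)) {
      stop("'cohort_csv' only applies to cohort_csv mode", call. = FALSE)
    }
    if (is.null(params)) params <- synthetic_params()
    if (!inherits(params, "synthetic_params")) {
      stop("'params' must come from synthetic_params()", call. = FALSE)
    }
  }
  if (!is.null(mask_manifest) && !file.exists(mask_manifest)) {
    stop("mask manifest not found: ", mask_manifest, call. = FALSE)
  }
  structure(
    list(
      mode = mode, cohort_csv = cohort_csv, params = params,
      mask_manifest = mask_manifest, mask_dir = mask_dir,
      til_low_is_adverse = isTRUE(til_low_is_adverse),
      risk_boundary = risk_boundary,
      out_dir = out_dir, p_digits = p_digits
    ),
    class = "pipeline_config"
  )
}

categorical_vars <- function(cohort) {
  cand <- c(
    "age_group", "gender", "site", "c_staging", "p_staging",
    "c_stage", "p_stage", "c_n", "p_n", "grade", "grading"
  )
  intersect(cand, names(cohort))
}

#' Run the full modified-BG pipeline
#'
#' Reads or synthesizes a cohort, optionally quantifies %stromal TILs
#' from a mask manifest, dichotomizes TILs at the cohort median, derives
#' the modified BG score and risk category, and computes: (a) a cohort
#' characteristics table; (b) continuous-variable associations (one-way
#' ANOVA of %stromal TILs and DOI across each categorical variable,
#' with per-group summaries); (c) categorical associations of each
#' variable with score and risk, reporting Pearson chi-square and -- for
#' ordinal variables -- the linear-by-linear trend test side by side,
#' each labelled with its method; (d) Kaplan-Meier curves, restricted
#' mean survival, and (pairwise) log-rank tests by score and risk.
#' Deterministic given the configuration (and its seed). Decisions taken
#' along the way (TIL cutoff, cases dropped for missing DOI or masks)
#' are recorded in the returned `log`.
#'
#' @param config a [pipeline_config()].
#' @return a list of class `bg_report`: `cohort` (scored),
#'   `characteristics`, `continuous`, `categorical`, `survival`, `log`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("'config' must come from pipeline_config()", call. = FALSE)
  }
  log <- character()
  note <- function(msg) log <<- c(log, msg)

  cohort <- if (config$mode == "synthetic") {
    note(sprintf(
      "synthetic cohort: n = %d, seed = %d",
      config$params$n_patients, config$params$seed
    ))
    generate_cohort(config$params)
  } else {
    note(sprintf("cohort read from %s", config$cohort_csv))
    read_cohort(config$cohort_csv)
  }

  if (!is.null(config$mask_manifest)) {
    tq <- quantify_cases(config$mask_manifest, base_dir = config$mask_dir)
    missing_cases <- setdiff(cohort$patient_id, tq$case_id)
    if (length(missing_cases)) {
      note(sprintf(
        "no mask-based TIL value for %d case(s): %s",
        length(missing_cases), paste(missing_cases, collapse = ", ")
      ))
    }
    cohort$til_percent <- tq$til_percent[match(cohort$patient_id, tq$case_id)]
    cohort <- cohort[!is.na(cohort$til_percent), , drop = FALSE]
    cohort$til_category <- NULL
    note(sprintf("TILs quantified from masks for %d case(s)", nrow(cohort)))
  }
  validate_cohort(cohort)

  if ("til_percent" %in% names(cohort)) {
    cohort$til_category <- NULL # recompute the split from the data at hand
  }
  cohort <- score_cohort(cohort,
    til_low_is_adverse = config$til_low_is_adverse,
    boundary = config$risk_boundary
  )
  cutoff <- attr(cohort, "til_cutoff")
  note(sprintf("TIL median cutoff: %.4g (<= cutoff -> low)", cutoff))
  if (!is.null(cohort$doi) && anyNA(cohort$doi)) {
    note(sprintf(
      "%d case(s) without DOI excluded pairwise from DOI statistics",
      sum(is.na(cohort$doi))
    ))
  }
  if (!"age_group" %in% names(cohort) && "age" %in% names(cohort)) {
    cohort$age_group <- cut(cohort$age,
      breaks = c(-Inf, 30, 40, 50, 60, Inf),
      labels = c("<=30", "31-40", "41-50", "51-60", ">60")
    )
  }

  vars <- categorical_vars(cohort)
  report <- list(
    cohort = cohort,
    characteristics = characteristics_table(cohort, vars),
    continuous = continuous_association_table(cohort, vars, config$p_digits),
    categorical = categorical_association_table(cohort, vars, config$p_digits),
    survival = survival_by_score(cohort),
    til_cutoff = cutoff,
    log = log
  )
  class(report) <- "bg_report"
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

validate_cohort <- function(cohort) {
  need <- c("patient_id", "wpoi5", "pni", "survival_months", "event")
  missing <- setdiff(need, names(cohort))
  if (length(missing)) {
    stop("cohort is missing column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  probs <- character()
  if (!("til_percent" %in% names(cohort)) &&
    !("til_category" %in% names(cohort))) {
    probs <- c(probs, "need til_percent (or til_category)")
  }
  if ("survival_months" %in% names(cohort) &&
    any(cohort$survival_months < 0, na.rm = TRUE)) {
    probs <- c(probs, "survival_months: negative values")
  }
  bad <- unlist(lapply(c("wpoi5", "pni"), function(col) {
    x <- tolower(as.character(cohort[[col]]))
    if (any(!x %in% c("present", "absent"))) {
      sprintf("%s: values outside present/absent", col)
    }
  }))
  probs <- c(probs, bad)
  if (length(probs)) {
    stop("malformed cohort: ", paste(probs, collapse = "; "), call. = FALSE)
  }
  invisible(cohort)
}

characteristics_table <- function(cohort, vars) {
  rows <- lapply(vars, function(v) {
    tab <- table(cohort[[v]])
    data.frame(
      variable = v, level = names(tab),
      n = as.integer(tab),
      percent = round(100 * as.integer(tab) / nrow(cohort), 1)
    )
  })
  extra <- list(
    data.frame(
      variable = "wpoi5", level = c("absent", "present"),
      n = c(sum(cohort$wpoi5 == "absent"), sum(cohort$wpoi5 == "present")),
      percent = NA
    ),
    data.frame(
      variable = "pni", level = c("absent", "present"),
      n = c(sum(cohort$pni == "absent"), sum(cohort$pni == "present")),
      percent = NA
    ),
    data.frame(
      variable = "score", level = as.character(0:3),
      n = as.integer(table(factor(cohort$score, 0:3))), percent = NA
    ),
    data.frame(
      variable = "risk", level = c("low", "high"),
      n = as.integer(table(cohort$risk)), percent = NA
    ),
    data.frame(
      variable = "event", level = c("censored", "death"),
      n = as.integer(table(factor(cohort$event, 0:1))), percent = NA
    )
  )
  out <- do.call(rbind, c(rows, extra))
  out$percent <- round(100 * out$n / nrow(cohort), 1)
  rownames(out) <- NULL
  out
}

continuous_association_table <- function(cohort, vars, p_digits) {
  outcomes <- c(til_percent = "tils", doi = "doi")
  outcomes <- outcomes[names(outcomes) %in% names(cohort)]
  rows <- list()
  for (oc in names(outcomes)) {
    y <- cohort[[oc]]
    for (v in vars) {
      g <- droplevels(factor(cohort[[v]][!is.na(y)]))
      yy <- y[!is.na(y)]
      if (nlevels(g) < 2) next
      res <- tryCatch(suppressWarnings(one_way_anova_raw(yy, g)),
        error = function(e) NULL
      )
      if (is.null(res)) next
      means <- tapply(yy, g, mean)
      sds <- tapply(yy, g, stats::sd)
      ns <- tapply(yy, g, length)
      rows[[length(rows) + 1]] <- data.frame(
        outcome = outcomes[[oc]], variable = v, level = levels(g),
        n = as.integer(ns),
        mean = round(as.numeric(means), 2),
        sd = round(as.numeric(sds), 2),
        method = "one_way_anova",
        F = round(res$statistic, 4),
        p = format_p(res$p_value, p_digits),
        row.names = NULL
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

categorical_association_table <- function(cohort, vars, p_digits) {
  rows <- list()
  ordinal_vars <- c(
    "age_group", "c_staging", "p_staging", "c_stage", "p_stage",
    "c_n", "p_n", "grade", "grading"
  )
  for (v in vars) {
    g <- droplevels(factor(cohort[[v]]))
    if (nlevels(g) < 2) next
    for (block in c("score", "risk")) {
      counts <- table(g, cohort[[block]])
      tab <- contingency_table(unclass(counts),
        row_labels = rownames(counts), col_labels = colnames(counts),
        row_scores = if (v %in% ordinal_vars) seq_len(nrow(counts)) - 1,
        col_scores = seq_len(ncol(counts)) - 1
      )
      res_list <- list(tryCatch(
        suppressWarnings(pearson_chi_square(tab)),
        error = function(e) NULL
      ))
      if (v %in% ordinal_vars) {
        res_list <- c(res_list, list(tryCatch(linear_by_linear(tab),
          error = function(e) NULL
        )))
      }
      for (res in res_list) {
        if (is.null(res)) next
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, against = block, method = res$method,
          statistic = round(res$statistic, 4),
          df = paste(res$df, collapse = ","),
          p = format_p(res$p_value, p_digits)
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$cohort, file.path(out_dir, "cohort_scored.csv"),
    row.names = FALSE
  )
  utils::write.csv(report$characteristics,
    file.path(out_dir, "characteristics.csv"),
    row.names = FALSE
  )
  utils::write.csv(report$continuous,
    file.path(out_dir, "continuous_associations.csv"),
    row.names = FALSE
  )
  utils::write.csv(report$categorical,
    file.path(out_dir, "categorical_associations.csv"),
    row.names = FALSE
  )
  utils::write.csv(report$survival$restricted_means,
    file.path(out_dir, "restricted_mean_survival.csv"),
    row.names = FALSE
  )
  writeLines(report$log, file.path(out_dir, "pipeline_log.txt"))
  invisible(out_dir)
}

#' @export
print.bg_report <- function(x, ...) {
  cat("Modified BG pipeline report\n")
  cat(sprintf(
    "  cohort: %d patients; TIL cutoff %.4g\n",
    nrow(x$cohort), x$til_cutoff
  ))
  cat(sprintf(
    "  score distribution: %s\n",
    paste(table(factor(x$cohort$score, 0:3)), collapse = "/")
  ))
  cat(sprintf(
    "  risk: %d low / %d high\n",
    sum(x$cohort$risk == "low"), sum(x$cohort$risk == "high")
  ))
  lr <- x$survival$log_rank
  if (!is.null(lr)) {
    cat(sprintf(
      "  log-rank across scores: chi-square %.3f (df %d), p = %s\n",
      lr$statistic, lr$df, format_p(lr$p_value)
    ))
  }
  cat(sprintf(
    "  restricted mean survival by score: %s months\n",
    paste(sprintf("%.1f", x$survival$restricted_means$restricted_mean),
      collapse = ", "
    )
  ))
  invisible(x)
}
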