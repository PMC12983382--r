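# Synthetic cohorts and annotation-mask fields with known ground truth.
#
# The generator's defaults emulate the marginal structure of a
# 58-patient OSCC cohort: 48 male / 10 female; half the tumors on the
# lateral tongue; WPOI-5 in 22/58 and PNI in 15/58; right-skewed
# %stromal TILs with mean ~22.8 and median ~18; and overall survival
# whose group means fall from roughly 37 months at score 0 to 17 months
# at score 3 (an exponential model with a per-point hazard ratio of
# about 1.3 around a 37-month baseline mean reproduces that gradient).

default_marginals <- function() {
  list(
    gender = c(male = 48, female = 10) / 58,
    site = c(
      tongue_lateral = 29, alveolus_upper = 2, alveolus_lower = 7,
      retromolar = 1, buccal_mucosa = 18, hard_palate = 1
    ) / 58,
    c_stage = c(`1` = 1, `2` = 10, `3` = 29, `4` = 18) / 58,
    p_stage = c(`1` = 2, `2` = 10, `3` = 18, `4` = 28) / 58,
    c_n = c(N0 = 26, N1 = 22, N2 = 7, N3 = 3) / 58,
    p_n = c(N0 = 21, N1 = 19, N2 = 8, N3 = 10) / 58,
    grade = c(well = 13, moderate = 36, poor = 9) / 58
  )
}

#' Parameters for the synthetic cohort generator
#'
#' @param n_patients cohort size.
#' @param seed integer RNG seed; the same parameters always yield a
#'   byte-identical cohort.
#' @param p_wpoi5,p_pni Bernoulli probabilities of WPOI-5 and PNI.
#' @param til_mean,til_sd target mean and SD (percent) of the %stromal
#'   TIL distribution; realized as a moment-matched log-normal (the
#'   reference cohort's mean 22.8 exceeding its median 18 implies right
#'   skew) truncated to \[0, 100\].
#' @param hazard_ratio_per_point multiplicative hazard per unit of
#'   modified BG score (> 0; 1 = no score effect).
#' @param baseline_hazard per-month event hazard at score 0 (> 0).
#' @param censor_rate probability that a subject is subject to
#'   administrative censoring drawn uniformly over the study window.
#' @param study_window months of follow-up over which administrative
#'   censoring times are spread.
#' @param node_score_assoc in \[0, 1\]: 0 gives independent pathological
#'   node status; larger values rank-couple pN to the score, for
#'   trend-test power checks.
#' @param covariate_marginals named list of per-covariate category
#'   probability vectors (each summing to 1); defaults emulate the
#'   reference cohort's marginals.
#' @return a validated list of class `synthetic_params`.
#' @export
synthetic_params <- function(n_patients = 58,
                             seed = 1L,
                             p_wpoi5 = 22 / 58,
                             p_pni = 15 / 58,
                             til_mean = 22.8,
                             til_sd = 12.7,
                             hazard_ratio_per_point = 1.3,
                             baseline_hazard = 1 / 37,
                             censor_rate = 1,
                             study_window = 36,
                             node_score_assoc = 0,
                             covariate_marginals = default_marginals()) {
  if (!is.numeric(n_patients) || n_patients < 1) {
    stop("'n_patients' must be a positive count", call. = FALSE)
  }
  probs <- c(p_wpoi5 = p_wpoi5, p_pni = p_pni, censor_rate = censor_rate,
    node_score_assoc = node_score_assoc)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
      paste(names(probs)[probs < 0 | probs > 1], collapse = ", "),
      call. = FALSE
    )
  }
  if (hazard_ratio_per_point <= 0) {
    stop("'hazard_ratio_per_point' must be positive", call. = FALSE)
  }
  if (baseline_hazard <= 0) stop("'baseline_hazard' must be positive", call. = FALSE)
  if (til_mean <= 0 || til_sd <= 0) {
    stop("'til_mean' and 'til_sd' must be positive", call. = FALSE)
  }
  if (study_window <= 0) stop("'study_window' must be positive", call. = FALSE)
  for (nm in names(covariate_marginals)) {
    pr <- covariate_marginals[[nm]]
    if (is.null(names(pr)) || any(pr < 0) || abs(sum(pr) - 1) > 1e-9) {
      stop(sprintf(
        "marginal '%s' must be a named probability vector summing to 1", nm
      ), call. = FALSE)
    }
  }
  structure(
    list(
      n_patients = as.integer(n_patients), seed = as.integer(seed),
      p_wpoi5 = p_wpoi5, p_pni = p_pni,
      til_mean = til_mean, til_sd = til_sd,
      hazard_ratio_per_point = hazard_ratio_per_point,
      baseline_hazard = baseline_hazard,
      censor_rate = censor_rate, study_window = study_window,
      node_score_assoc = node_score_assoc,
      covariate_marginals = covariate_marginals
    ),
    class = "synthetic_params"
  )
}

# Run 'expr' under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic patient cohort
#'
#' Categorical covariates are drawn independently from their marginals;
#' %stromal TILs from a moment-matched log-normal truncated to
#' \[0, 100\]; WPOI-5 and PNI as independent Bernoulli flags. The TIL
#' median split, modified BG score and risk category are computed as in
#' a real analysis. Event times are exponential with hazard
#' `baseline_hazard * hazard_ratio_per_point^score`; administrative
#' censoring is uniform over the study window.
#'
#' @param params a [synthetic_params()] object.
#' @return a `data.frame` with one row per patient: `patient_id`, `age`,
#'   `gender`, `site`, `c_stage`, `p_stage`, `c_n`, `p_n`, `grade`,
#'   `wpoi5`, `pni`, `til_percent`, `til_category`, `doi`, `score`,
#'   `risk`, `survival_months`, `event` (1 = death).
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "synthetic_params")) {
    stop("'params' must come from synthetic_params()", call. = FALSE)
  }
  n <- params$n_patients
  with_seed(params$seed, {
    cm <- params$covariate_marginals
    draw <- function(pr) {
      factor(sample(names(pr), n, replace = TRUE, prob = pr),
        levels = names(pr)
      )
    }
    cohort <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      age = pmin(pmax(round(stats::rnorm(n, 52, 12)), 28), 76),
      gender = draw(cm$gender),
      site = draw(cm$site),
      c_stage = draw(cm$c_stage),
      p_stage = draw(cm$p_stage),
      c_n = draw(cm$c_n),
      p_n = draw(cm$p_n),
      grade = draw(cm$grade),
      wpoi5 = ifelse(stats::rbinom(n, 1, params$p_wpoi5) == 1,
        "present", "absent"
      ),
      pni = ifelse(stats::rbinom(n, 1, params$p_pni) == 1,
        "present", "absent"
      )
    )
    # log-normal moment-matched to the target mean/SD, truncated at 100
    cv2 <- (params$til_sd / params$til_mean)^2
    sdlog <- sqrt(log1p(cv2))
    meanlog <- log(params$til_mean) - sdlog^2 / 2
    cohort$til_percent <- pmin(stats::rlnorm(n, meanlog, sdlog), 100)
    cohort$til_category <- dichotomize_by_median(cohort$til_percent)$category
    sc <- modified_bg_score(cohort$wpoi5, cohort$pni, cohort$til_category)
    cohort$score <- sc$score
    cohort$risk <- sc$risk
    # depth of invasion, weakly increasing in score (log-normal, cm scale)
    cohort$doi <- round(stats::rlnorm(n, log(1.0) + 0.08 * cohort$score, 0.5), 2)
    if (params$node_score_assoc > 0) {
      # rank-couple pN to the score via a mixed latent quantile
      w <- params$node_score_assoc
      u <- (1 - w) * stats::runif(n) +
        w * (cohort$score + stats::runif(n)) / 4
      br <- cumsum(cm$p_n)
      cohort$p_n <- factor(names(cm$p_n)[findInterval(u, c(0, br[-length(br)])
      )], levels = names(cm$p_n))
    }
    lambda <- params$baseline_hazard *
      params$hazard_ratio_per_point^cohort$score
    t_event <- stats::rexp(n, lambda)
    censored_arm <- stats::rbinom(n, 1, params$censor_rate) == 1
    t_censor <- ifelse(censored_arm,
      stats::runif(n, 0, params$study_window), Inf
    )
    cohort$survival_months <- round(pmin(t_event, t_censor), 3)
    cohort$event <- as.integer(t_event <= t_censor)
    cohort
  })
}

#' Write/read a cohort as CSV
#'
#' Plain-text export, one row per patient, full floating precision.
#' Column dictionary: see [generate_cohort()].
#'
#' @param cohort a cohort `data.frame`.
#' @param path CSV path.
#' @return `path` (write) or the cohort `data.frame` (read).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  canonical <- default_marginals()
  for (col in c("gender", "site", "c_stage", "p_stage", "c_n", "p_n", "grade")) {
    if (!col %in% names(cohort)) next
    lv <- names(canonical[[col]])
    # keep the canonical (ordinal) level order where the values allow it
    if (!is.null(lv) && all(cohort[[col]] %in% lv)) {
      cohort[[col]] <- factor(cohort[[col]], levels = lv)
    } else {
      cohort[[col]] <- factor(cohort[[col]])
    }
  }
  if ("til_category" %in% names(cohort)) {
    cohort$til_category <- factor(cohort$til_category, levels = c("low", "high"))
  }
  if ("risk" %in% names(cohort)) {
    cohort$risk <- factor(cohort$risk, levels = c("low", "high"))
  }
  cohort
}

#' Synthesize one field's annotation masks with known ground truth
#'
#' Builds disc-composite stroma, TIL and (optionally) exclusion masks so
#' the true pixel areas are known exactly by construction: the TIL discs
#' are intersected with the stroma region, and disc radii are chosen by
#' binary search on the pixel counts so the achieved TIL fraction of the
#' evaluable stroma matches the request to within a placement tolerance
#' of about one percentage point (pixel discretization of the disc
#' boundary is the only error source).
#'
#' @param width,height field dimensions in pixels.
#' @param stroma_fraction target stroma area as a fraction of the field.
#' @param til_fraction_of_stroma target TIL area as a fraction of the
#'   evaluable stroma.
#' @param seed RNG seed controlling disc placement.
#' @param exclusion_fraction fraction of the field covered by an
#'   exclusion disc (default 0).
#' @return a [field_annotation()] with attribute `truth`: a list with
#'   `stroma_px`, `til_px`, `exclusion_px`, and `achieved_fraction`
#'   (the exact pixel-count TIL fraction of evaluable stroma).
#' @export
generate_field_masks <- function(width = 256, height = 256,
                                 stroma_fraction = 0.5,
                                 til_fraction_of_stroma = 0.2,
                                 seed = 1L,
                                 exclusion_fraction = 0) {
  stopifnot(width >= 16, height >= 16)
  fr <- c(stroma_fraction, til_fraction_of_stroma, exclusion_fraction)
  if (any(fr < 0 | fr > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (stroma_fraction == 0 && til_fraction_of_stroma > 0) {
    stop("cannot place TILs: zero-area stroma requested", call. = FALSE)
  }
  xs <- matrix(seq_len(width), width, height)
  ys <- matrix(rep(seq_len(height), each = width), width, height)
  disc <- function(cx, cy, r) (xs - cx)^2 + (ys - cy)^2 <= r^2
  with_seed(seed, {
    empty <- matrix(FALSE, width, height)
    if (stroma_fraction == 0) {
      field <- field_annotation(empty, empty, empty, field_id = "synthetic")
      attr(field, "truth") <- list(
        stroma_px = 0L, til_px = 0L, exclusion_px = 0L,
        achieved_fraction = NA_real_
      )
      return(field)
    }
    # stroma: main disc + two satellites, radii scaled together by
    # binary search on the union pixel count
    cx <- width * stats::runif(1, 0.45, 0.55)
    cy <- height * stats::runif(1, 0.45, 0.55)
    sat <- cbind(
      cx + width * stats::runif(2, -0.2, 0.2),
      cy + height * stats::runif(2, -0.2, 0.2)
    )
    target_s <- stroma_fraction * width * height
    stroma_at <- function(scale) {
      disc(cx, cy, scale) |
        disc(sat[1, 1], sat[1, 2], 0.4 * scale) |
        disc(sat[2, 1], sat[2, 2], 0.3 * scale)
    }
    scale <- binary_search_px(
      function(s) sum(stroma_at(s)),
      target_s,
      hi = max(width, height)
    )
    stroma <- stroma_at(scale)
    exclusion <- empty
    if (exclusion_fraction > 0) {
      ex_r <- binary_search_px(
        function(r) sum(disc(cx - 0.3 * scale, cy - 0.3 * scale, r)),
        exclusion_fraction * width * height,
        hi = max(width, height)
      )
      exclusion <- disc(cx - 0.3 * scale, cy - 0.3 * scale, ex_r)
    }
    evaluable <- stroma & !exclusion
    til <- empty
    if (til_fraction_of_stroma > 0) {
      if (sum(evaluable) == 0) {
        stop("exclusion removed all stroma; cannot place TILs", call. = FALSE)
      }
      # TIL blobs: three discs near the stroma center, clipped to the
      # evaluable stroma, radii scaled by binary search
      tc <- cbind(
        cx + scale * stats::runif(3, -0.4, 0.4),
        cy + scale * stats::runif(3, -0.4, 0.4)
      )
      til_at <- function(s) {
        (disc(tc[1, 1], tc[1, 2], s) |
          disc(tc[2, 1], tc[2, 2], 0.7 * s) |
          disc(tc[3, 1], tc[3, 2], 0.5 * s)) & evaluable
      }
      til_scale <- binary_search_px(
        function(s) sum(til_at(s)),
        til_fraction_of_stroma * sum(evaluable),
        hi = 2 * max(width, height)
      )
      til <- til_at(til_scale)
    }
    field <- field_annotation(stroma, til, exclusion, field_id = "synthetic")
    attr(field, "truth") <- list(
      stroma_px = sum(stroma),
      til_px = sum(til),
      exclusion_px = sum(exclusion),
      achieved_fraction = sum(til & evaluable) / sum(evaluable)
    )
    field
  })
}

# Smallest scale whose pixel count reaches the target (monotone count).
binary_search_px <- function(count_at, target, hi, iter = 40) {
  lo <- 0
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (count_at(mid) < target) lo <- mid else hi <- mid
  }
  hi
}
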