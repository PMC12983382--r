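# %stromal TIL quantification from annotation masks.
#
# The quantity of interest is the fraction of the tumor's stroma occupied
# by mononuclear inflammatory cells, expressed as a percentage:
#   100 * area(TIL inside evaluable stroma) / area(evaluable stroma),
# where evaluable stroma is the stromal annotation minus an exclusion
# annotation (granulocyte-rich, ulcerated, crushed or necrotic areas are
# not evaluated). A case is scored as the arithmetic mean over 5
# representative fields, and cases are split into low/high TIL groups at
# the cohort median.

#' Bundle one microscopic field's annotation masks
#'
#' @param stroma_mask,til_mask logical (or 0/1) matrices of identical
#'   dimensions; `TRUE`/nonzero marks pixels inside the region.
#' @param exclusion_mask optional mask of areas excluded from evaluation;
#'   defaults to none.
#' @param field_id optional label.
#' @return an object of class `field_annotation`. TIL pixels falling
#'   outside the stromal annotation are retained in the stored mask but
#'   ignored by [field_til_percentage()], which intersects with the
#'   evaluable stroma (manual annotations overlap imperfectly, and the
#'   measurand is defined as a fraction of stroma).
#' @export
field_annotation <- function(stroma_mask, til_mask, exclusion_mask = NULL,
                             field_id = NA_character_) {
  stroma_mask <- as_mask(stroma_mask, "stroma_mask")
  til_mask <- as_mask(til_mask, "til_mask")
  if (is.null(exclusion_mask)) {
    exclusion_mask <- matrix(FALSE, nrow(stroma_mask), ncol(stroma_mask))
  }
  exclusion_mask <- as_mask(exclusion_mask, "exclusion_mask")
  if (!identical(dim(stroma_mask), dim(til_mask)) ||
    !identical(dim(stroma_mask), dim(exclusion_mask))) {
    stop("all masks must share the same dimensions", call. = FALSE)
  }
  structure(
    list(
      field_id = field_id,
      stroma_mask = stroma_mask,
      til_mask = til_mask,
      exclusion_mask = exclusion_mask
    ),
    class = "field_annotation"
  )
}

as_mask <- function(m, what) {
  if (is.logical(m) && is.matrix(m)) {
    m[is.na(m)] <- FALSE
    return(m)
  }
  if (is.numeric(m) && is.matrix(m)) {
    return(!is.na(m) & m != 0)
  }
  stop(sprintf("'%s' must be a logical or numeric matrix", what),
    call. = FALSE
  )
}

#' @export
print.field_annotation <- function(x, ...) {
  cat(sprintf(
    "Field %s: %d x %d px; stroma %d px, TIL %d px, excluded %d px\n",
    x$field_id, nrow(x$stroma_mask), ncol(x$stroma_mask),
    sum(x$stroma_mask), sum(x$til_mask), sum(x$exclusion_mask)
  ))
  invisible(x)
}

#' Percentage of stromal area occupied by TILs in one field
#'
#' Computes `100 * area(TIL & stroma & !exclusion) / area(stroma &
#' !exclusion)` by pixel counting. Always in \[0, 100\].
#'
#' @param field a [field_annotation()].
#' @return numeric percentage.
#' @export
field_til_percentage <- function(field) {
  if (!inherits(field, "field_annotation")) {
    stop("'field' must be a field_annotation", call. = FALSE)
  }
  evaluable <- field$stroma_mask & !field$exclusion_mask
  denom <- sum(evaluable)
  if (denom == 0) stop("no evaluable stromal area", call. = FALSE)
  100 * sum(field$til_mask & evaluable) / denom
}

#' Case-level %stromal TILs from representative fields
#'
#' The case value is the arithmetic mean of the per-field percentages;
#' five representative fields are the default protocol, enforced unless
#' `min_fields` is lowered explicitly.
#'
#' @param fields either a list of [field_annotation()] objects or a
#'   numeric vector of already-computed field percentages.
#' @param case_id optional label.
#' @param min_fields minimum number of fields required (default 5).
#' @return a list of class `case_til` with `case_id`,
#'   `field_percentages`, and `case_percentage`.
#' @examples
#' case_til_percentage(c(10, 20, 30, 20, 10))$case_percentage # 18
#' @export
case_til_percentage <- function(fields, case_id = NA_character_,
                                min_fields = 5) {
  if (is.numeric(fields)) {
    perc <- as.numeric(fields)
    if (any(perc < 0 | perc > 100)) {
      stop("field percentages must lie in [0, 100]", call. = FALSE)
    }
  } else if (is.list(fields)) {
    perc <- vapply(fields, field_til_percentage, numeric(1))
  } else {
    stop("'fields' must be a list of field annotations or a numeric vector",
      call. = FALSE
    )
  }
  if (length(perc) < min_fields) {
    stop(sprintf(
      "%d field(s) supplied but %d required; lower 'min_fields' to override",
      length(perc), min_fields
    ), call. = FALSE)
  }
  structure(
    list(
      case_id = case_id,
      field_percentages = perc,
      case_percentage = mean(perc)
    ),
    class = "case_til"
  )
}

#' @export
print.case_til <- function(x, ...) {
  cat(sprintf(
    "Case %s: %%stromal TILs = %.2f (fields: %s)\n",
    x$case_id, x$case_percentage,
    paste(sprintf("%.2f", x$field_percentages), collapse = ", ")
  ))
  invisible(x)
}

#' Dichotomize case values at the cohort median
#'
#' The cutoff is the sample median of all case values; values at or
#' below the cutoff are labelled `low`, values above it `high`. With an
#' even number of distinct values this yields the usual balanced split
#' (e.g. 29/29 in a cohort of 58 with no ties spanning the median).
#'
#' @param values numeric case percentages (>= 2 cases; `NA` not allowed).
#' @return a list with `cutoff` and `category` (factor `low`/`high`,
#'   same length as `values`).
#' @export
dichotomize_by_median <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 cases", call. = FALSE)
  if (any(is.na(values))) stop("missing case values", call. = FALSE)
  cutoff <- stats::median(values)
  if (all(values == values[1])) {
    warning("all case values identical; every case labelled 'low'",
      call. = FALSE
    )
  }
  category <- factor(ifelse(values <= cutoff, "low", "high"),
    levels = c("low", "high")
  )
  list(cutoff = cutoff, category = category)
}

#' Read a binary region mask from PNG or TIFF
#'
#' Any nonzero pixel (first channel, if multi-channel) is inside the
#' region.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF masks requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop("unsupported mask format: .", ext, call. = FALSE)
  )
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  arr != 0
}

#' Write a binary region mask
#'
#' @param mask logical matrix.
#' @param path destination `.png`, `.tif` or `.tiff` path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- as_mask(mask, "mask")
  img <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("writing TIFF masks requires the 'tiff' package", call. = FALSE)
      }
      tiff::writeTIFF(img, path)
    },
    stop("unsupported mask format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Quantify %stromal TILs for a manifest of cases
#'
#' The manifest is a delimited table with columns `case_id`, `field_id`,
#' `stroma`, `til`, and optionally `exclusion`, each path column naming a
#' mask image (relative paths resolved against `base_dir`). Cases with a
#' missing mask file are flagged and excluded with a warning.
#'
#' @param manifest a `data.frame` or a path to a CSV file.
#' @param base_dir directory against which relative mask paths resolve.
#' @param min_fields minimum fields per case (default 5).
#' @return a `data.frame` with one row per evaluable case: `case_id`,
#'   `field1..fieldK` percentages, `til_percent` (the case mean).
#' @export
quantify_cases <- function(manifest, base_dir = ".", min_fields = 5) {
  if (is.character(manifest)) {
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  }
  need <- c("case_id", "field_id", "stroma", "til")
  if (!all(need %in% names(manifest))) {
    stop(
      "manifest must have columns: ", paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  has_excl <- "exclusion" %in% names(manifest)
  resolve <- function(p) {
    ifelse(file.exists(p), p, file.path(base_dir, p))
  }
  out <- lapply(split(manifest, manifest$case_id), function(rows) {
    paths <- c(
      resolve(rows$stroma), resolve(rows$til),
      if (has_excl) resolve(rows$exclusion[!is.na(rows$exclusion) & nzchar(rows$exclusion)])
    )
    if (!all(file.exists(paths))) {
      warning(sprintf(
        "case %s: missing mask file(s); case excluded",
        rows$case_id[1]
      ), call. = FALSE)
      return(NULL)
    }
    fields <- lapply(seq_len(nrow(rows)), function(i) {
      excl <- NULL
      if (has_excl && !is.na(rows$exclusion[i]) && nzchar(rows$exclusion[i])) {
        excl <- read_mask(resolve(rows$exclusion[i]))
      }
      field_annotation(
        read_mask(resolve(rows$stroma[i])),
        read_mask(resolve(rows$til[i])),
        excl,
        field_id = rows$field_id[i]
      )
    })
    case <- case_til_percentage(fields,
      case_id = rows$case_id[1],
      min_fields = min_fields
    )
    p <- case$field_percentages
    df <- data.frame(case_id = case$case_id, t(p), til_percent = case$case_percentage)
    names(df)[2:(1 + length(p))] <- paste0("field", seq_along(p))
    df
  })
  out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  rownames(out) <- NULL
  out
}
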