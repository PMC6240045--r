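#' Read a cohort manifest
#'
#' Reads a tab-separated cohort manifest describing one scan per row. The
#' mandatory columns are `subject_id`, `dx`, `site`, `scanner`, `sex`,
#' `timepoint` and `age`; any further columns (e.g. ADOS scores) are kept.
#'
#' @param path Path to a TSV file with a header row.
#' @return A validated cohort `data.frame` (see [validate_cohort()]).
#' @details The manifest dialect is fixed: tab-separated, UTF-8, `.` decimal
#'   separator, header mandatory. `timepoint` must be one of `"baseline"`,
#'   `"followup"`, `"single"`; `dx` one of `"ASD"`, `"TD"`.
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_cohort(df)
}

#' Write a cohort manifest
#'
#' @param cohort A cohort `data.frame`.
#' @param path Output path (TSV).
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

.cohort_mandatory <- c("subject_id", "dx", "site", "scanner", "sex",
                       "timepoint", "age")

#' Validate a cohort table
#'
#' Enforces the cohort invariants: all mandatory columns present,
#' `subject_id` x `timepoint` unique, `dx`/`site`/`scanner` non-empty,
#' ages strictly positive, and longitudinal subjects (rows with timepoint
#' `baseline`/`followup`) having exactly two rows with follow-up age greater
#' than baseline age.
#'
#' @param cohort A `data.frame`.
#' @return The validated `data.frame` (invisibly coerced column types).
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(.cohort_mandatory, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort format error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  cohort$subject_id <- as.character(cohort$subject_id)
  cohort$age <- as.numeric(cohort$age)
  key <- paste(cohort$subject_id, cohort$timepoint, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- cohort$subject_id[duplicated(key)][1L]
    stop("cohort integrity error: duplicate subject_id x timepoint: ", dup)
  }
  if (any(!is.finite(cohort$age)) || any(cohort$age <= 0)) {
    stop("cohort value error: ages must be finite and > 0")
  }
  for (col in c("dx", "site", "scanner")) {
    if (any(is.na(cohort[[col]]) | !nzchar(as.character(cohort[[col]])))) {
      stop("cohort integrity error: empty values in column '", col, "'")
    }
  }
  if (!all(cohort$dx %in% c("ASD", "TD"))) {
    stop("cohort value error: dx must be 'ASD' or 'TD'")
  }
  if (!all(cohort$timepoint %in% c("baseline", "followup", "single"))) {
    stop("cohort value error: timepoint must be baseline/followup/single")
  }
  lngt <- cohort[cohort$timepoint != "single", , drop = FALSE]
  if (nrow(lngt) > 0L) {
    for (id in unique(lngt$subject_id)) {
      rows <- lngt[lngt$subject_id == id, , drop = FALSE]
      if (nrow(rows) != 2L ||
          !setequal(rows$timepoint, c("baseline", "followup"))) {
        stop("cohort integrity error: longitudinal subject '", id,
             "' must have exactly one baseline and one followup row")
      }
      if (rows$age[rows$timepoint == "followup"] <=
          rows$age[rows$timepoint == "baseline"]) {
        stop("cohort integrity error: follow-up age must exceed baseline ",
             "age for subject '", id, "'")
      }
    }
  }
  cohort
}

#' Per-site, per-diagnosis cell counts
#'
#' @param cohort A cohort `data.frame`.
#' @return A `data.frame` with columns `site`, `dx`, `n`.
#' @export
cohort_cell_counts <- function(cohort) {
  tab <- table(site = cohort$site, dx = cohort$dx)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("site", "dx", "n")
  out[order(out$site, out$dx), , drop = FALSE]
}

#' Drop site x diagnosis cells below a minimum size
#'
#' Data-preparation filter mirroring the exclusion of acquisition sites
#' contributing fewer than `min_n` subjects to either diagnostic group.
#'
#' @param cohort A cohort `data.frame` (single-timepoint rows).
#' @param min_n Minimum subjects per (site, dx) cell; sites failing the
#'   threshold in either group are removed entirely. Default 4.
#' @return The filtered cohort.
#' @export
filter_cohort_cells <- function(cohort, min_n = 4) {
  counts <- cohort_cell_counts(cohort)
  # a site must reach min_n in *both* groups to be kept
  keep_site <- vapply(unique(cohort$site), function(s) {
    ns <- counts$n[counts$site == s]
    length(ns) == 2L && all(ns >= min_n)
  }, logical(1))
  cohort[cohort$site %in% names(keep_site)[keep_site], , drop = FALSE]
}
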