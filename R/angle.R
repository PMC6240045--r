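#' Longitudinal rate-of-change angle
#'
#' Per-vertex "angle" of contrast change for a longitudinal scan pair:
#' `atan((WGC_flp - WGC_bsl) / (age_flp - age_bsl))`. The contrast
#' difference is the opposite cathetus, the inter-scan interval the adjacent
#' one, so the statistic is bounded in (-pi/2, pi/2) regardless of how fast
#' the contrast changes.
#'
#' @param wgc_bsl,wgc_flp Numeric vectors of per-vertex contrast at the
#'   baseline and follow-up scans (same length).
#' @param age_bsl,age_flp Ages in years at the two scans;
#'   `age_flp > age_bsl` is required (never a silent division).
#' @return Numeric vector of angles in radians.
#' @export
longitudinal_angle <- function(wgc_bsl, wgc_flp, age_bsl, age_flp) {
  stopifnot(length(wgc_bsl) == length(wgc_flp))
  if (!(age_flp > age_bsl)) {
    stop("value error: age_flp must exceed age_bsl")
  }
  atan((wgc_flp - wgc_bsl) / (age_flp - age_bsl))
}

#' Longitudinal angles for a whole cohort
#'
#' Applies [longitudinal_angle()] to every subject of a longitudinal cohort,
#' pairing the baseline and follow-up rows of a scans-by-vertices matrix.
#'
#' @param wgc Matrix of per-scan contrast values whose rows follow the cohort
#'   row order (two rows per subject).
#' @param cohort Longitudinal cohort `data.frame` (timepoints
#'   baseline/followup).
#' @return Matrix, one row per subject (row names = subject ids), of angles.
#' @export
longitudinal_angles <- function(wgc, cohort) {
  stopifnot(nrow(wgc) == nrow(cohort))
  ids <- unique(cohort$subject_id)
  out <- matrix(NA_real_, length(ids), ncol(wgc),
                dimnames = list(ids, colnames(wgc)))
  for (id in ids) {
    b <- which(cohort$subject_id == id & cohort$timepoint == "baseline")
    f <- which(cohort$subject_id == id & cohort$timepoint == "followup")
    if (length(b) != 1L || length(f) != 1L) {
      stop("longitudinal_angles: subject '", id,
           "' lacks a baseline/followup pair")
    }
    out[id, ] <- longitudinal_angle(wgc[b, ], wgc[f, ],
                                    cohort$age[b], cohort$age[f])
  }
  out
}

#' Cross-sectional rate-of-change angle
#'
#' The cross-sectional analogue of the longitudinal angle: for each subject
#' the mean pairwise contrast difference against all other subjects of the
#' same diagnostic group within the same acquisition site, divided by the
#' corresponding mean age difference, passed through the arctangent:
#' `alpha_i = atan( sum_{j != i}(WGC_i - WGC_j) / sum_{j != i}(age_i - age_j) )`,
#' with the sums running over same-site, same-diagnosis peers only. Because
#' within-site differences cancel additive site offsets, the statistic is a
#' per-subject developmental trajectory largely free of site effects.
#'
#' A subject whose age equals — or nearly equals — the mean age of its
#' peers has a (near-)zero denominator: the ratio's variance diverges and
#' the arctangent saturates at +-pi/2 with an arbitrary sign. Such
#' subjects' angle rows are masked (`NA`) with a warning, identically
#' across vertices, since the event is age-structure-driven. `min_age_gap`
#' sets the tolerance (in years) on the subject-to-peer-mean age gap below
#' which the row is masked; 0 masks exact zeros only.
#'
#' @param wgc Subjects-by-vertices contrast matrix in cohort row order.
#' @param cohort Single-timepoint cohort `data.frame`.
#' @param min_cell Minimum subjects per (site, dx) cell; cells below it raise
#'   an error naming the cell. Default 2 (the formula's minimum); cohorts are
#'   normally pre-filtered at 4 with [filter_cohort_cells()].
#' @param warn_below Emit a warning for cells smaller than this. Default 4.
#' @param min_age_gap Minimum |age_i - mean(peer ages)| in years for the
#'   angle to be considered estimable. Default 0.1.
#' @return Subjects-by-vertices matrix of angles (radians), cohort row order.
#' @export
cross_sectional_angle <- function(wgc, cohort, min_cell = 2, warn_below = 4,
                                  min_age_gap = 0.1) {
  stopifnot(nrow(wgc) == nrow(cohort))
  out <- matrix(NA_real_, nrow(wgc), ncol(wgc),
                dimnames = dimnames(wgc))
  cell <- paste(cohort$site, cohort$dx, sep = ":")
  for (cl in unique(cell)) {
    rows <- which(cell == cl)
    n <- length(rows)
    if (n < min_cell) {
      stop("cross_sectional_angle: cell '", cl, "' has ", n,
           " subject(s); at least ", min_cell, " required")
    }
    if (n < warn_below) {
      warning("cell '", cl, "' has only ", n, " subjects")
    }
    sub_w <- wgc[rows, , drop = FALSE]
    ages <- cohort$age[rows]
    col_sums <- colSums(sub_w)
    den <- n * ages - sum(ages)                     # sum_j (age_i - age_j)
    zero_den <- abs(den / (n - 1)) <= min_age_gap   # gap to peer mean age
    if (any(zero_den)) {
      warning(sum(zero_den), " subject(s) in cell '", cl,
              "' within ", min_age_gap, " y of the peer mean age; ",
              "angles masked")
    }
    num <- n * sub_w - matrix(col_sums, n, ncol(wgc), byrow = TRUE)
    # den (length n) recycles down the columns of num: per-subject denominator
    alpha <- atan(num / den)
    alpha[zero_den, ] <- NA_real_
    out[rows, ] <- alpha
  }
  out
}

#' Drop masked (all-NA) angle rows together with their cohort rows
#'
#' Companion to the masking policy of [cross_sectional_angle()]: subjects
#' whose angle could not be estimated are removed from both the matrix and
#' the cohort before group-level analysis.
#'
#' @param angles Subjects-by-vertices matrix.
#' @param cohort Matching cohort `data.frame`.
#' @return List with `angles`, `cohort` (masked rows removed) and
#'   `n_dropped`.
#' @export
drop_masked_rows <- function(angles, cohort) {
  stopifnot(nrow(angles) == nrow(cohort))
  masked <- rowSums(is.na(angles)) == ncol(angles)
  list(angles = angles[!masked, , drop = FALSE],
       cohort = cohort[!masked, , drop = FALSE],
       n_dropped = sum(masked))
}

#' Z-score angle maps
#'
#' Standardises a subjects-by-vertices angle matrix to emphasise the shape of
#' the distribution over its magnitude. By default each vertex column is
#' z-scored across subjects (sample standard deviation, n - 1); the pooled
#' alternative standardises with the grand mean and sd of the whole matrix.
#' Zero-variance columns map to zero.
#'
#' @param angles Subjects-by-vertices matrix with at least 2 rows.
#' @param by `"vertex"` (default) or `"pooled"`.
#' @return The standardised matrix.
#' @export
standardize_angles <- function(angles, by = c("vertex", "pooled")) {
  by <- match.arg(by)
  if (nrow(angles) < 2L) stop("standardize_angles: need at least 2 subjects")
  if (by == "pooled") {
    mu <- mean(angles, na.rm = TRUE)
    s <- stats::sd(as.numeric(angles), na.rm = TRUE)
    if (s == 0) return(angles * 0)
    return((angles - mu) / s)
  }
  mu <- colMeans(angles, na.rm = TRUE)
  s <- apply(angles, 2, stats::sd, na.rm = TRUE)
  z <- sweep(angles, 2, mu, "-")
  z <- sweep(z, 2, ifelse(s == 0, 1, s), "/")
  z[, s == 0] <- 0
  z
}
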