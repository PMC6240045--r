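#' Read an ADOS calibrated-severity lookup table
#'
#' The table maps (ADOS module, age band, social+communication total band)
#' to a calibrated severity score in 1-10. Schema (TSV, header mandatory):
#' columns `ados_module`, `age_min`, `age_max`, `total_min`, `total_max`,
#' `severity`; bands are closed intervals. The package ships only a
#' clearly-labelled synthetic placeholder
#' (`system.file("extdata", "synthetic_severity_table.tsv", package =
#' "wgcdev")`, implementing `severity = clip(total, 1, 10)` for all modules
#' and ages); real calibration tables must be supplied by the user in the
#' same schema.
#'
#' @param path Path to the TSV file.
#' @return A validated `data.frame` of class `severity_table`.
#' @export
read_severity_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  needed <- c("ados_module", "age_min", "age_max", "total_min", "total_max",
              "severity")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0L) {
    stop("severity table format error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(tab$severity < 1 | tab$severity > 10)) {
    stop("severity table value error: severity must be in [1, 10]")
  }
  class(tab) <- c("severity_table", "data.frame")
  tab
}

#' Proxy calibrated severity lookup
#'
#' Deterministic lookup of the calibrated severity score for ADOS
#' social+communication totals, adjusted for age and ADOS module via the
#' lookup table's bands. Totals falling in no covered cell yield `NA` with
#' the reason recorded in the `reason` attribute, never a silent default.
#'
#' @param total Integer vector of social+communication totals.
#' @param module Integer vector of ADOS modules (recycled if length 1).
#' @param age Numeric vector of ages in years (recycled if length 1).
#' @param table A `severity_table`.
#' @return Numeric vector of severity scores (1-10) with attribute `reason`
#'   (character, `NA` where the lookup succeeded).
#' @export
proxy_severity <- function(total, module, age, table) {
  n <- length(total)
  module <- rep_len(module, n)
  age <- rep_len(age, n)
  out <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (is.na(total[i]) || is.na(module[i]) || is.na(age[i])) {
      reason[i] <- "missing input"
      next
    }
    hit <- table$ados_module == module[i] &
      table$age_min <= age[i] & age[i] <= table$age_max &
      table$total_min <= total[i] & total[i] <= table$total_max
    if (!any(hit)) {
      reason[i] <- sprintf("no table cell for module %s, age %.1f, total %d",
                           module[i], age[i], total[i])
    } else {
      out[i] <- table$severity[which(hit)[1L]]
    }
  }
  attr(out, "reason") <- reason
  out
}

#' Correlate scores with log-positive brain scores
#'
#' Pearson correlation between behavioural scores and the natural log of
#' the positive part of the brain scores: subjects with non-positive or
#' missing brain scores, or missing scores, are excluded.
#'
#' @param brsc Numeric vector of brain scores.
#' @param scores Numeric vector of behavioural scores, same length.
#' @return List with `r`, `p` (two-sided), `n_used`.
#' @export
correlate_log_brainscore <- function(brsc, scores) {
  stopifnot(length(brsc) == length(scores))
  keep <- !is.na(brsc) & brsc > 0 & !is.na(scores)
  if (sum(keep) < 3L) {
    stop("correlate_log_brainscore: fewer than 3 usable subjects")
  }
  ct <- stats::cor.test(log(brsc[keep]), scores[keep], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n_used = sum(keep))
}

#' Fit the severity general linear model
#'
#' Ordinary least squares of severity on brain score in the cross-sectional
#' training sample. The fit retains the training residuals with their brain
#' score coordinates and the residual-window half-width
#' `w = 0.05 * max(BrSc)` used by [predict_severity()].
#'
#' @param brsc Numeric vector of training brain scores (non-constant).
#' @param severity Numeric vector of severity scores, same length.
#' @return Object of class `severity_model`: `beta0`, `beta1`,
#'   `training_brsc`, `training_residuals`, `window_w`.
#' @export
fit_severity_model <- function(brsc, severity) {
  keep <- !is.na(brsc) & !is.na(severity)
  brsc <- brsc[keep]; severity <- severity[keep]
  if (length(brsc) < 3L) stop("fit_severity_model: need n >= 3")
  if (stats::sd(brsc) == 0) stop("fit_severity_model: constant brain scores")
  fit <- stats::lm(severity ~ brsc)
  structure(list(beta0 = unname(stats::coef(fit)[1]),
                 beta1 = unname(stats::coef(fit)[2]),
                 training_brsc = brsc,
                 training_residuals = unname(stats::residuals(fit)),
                 window_w = 0.05 * max(brsc)),
            class = "severity_model")
}

#' Predict severity with windowed residual correction
#'
#' `S_i = beta0 + beta1 * BrSc_i + mean{ eps_k : |BrSc_k - BrSc_i| < w }`,
#' i.e. the linear prediction plus the mean training residual within an
#' open window of half-width `w` around the new brain score. An empty
#' window contributes zero (falls back to the plain GLM prediction).
#'
#' @param model A `severity_model`.
#' @param brsc_new Numeric vector of brain scores to predict at.
#' @return Numeric vector of predicted severity scores.
#' @export
predict_severity <- function(model, brsc_new) {
  stopifnot(inherits(model, "severity_model"))
  vapply(brsc_new, function(b) {
    inside <- abs(model$training_brsc - b) < model$window_w
    corr <- if (any(inside)) mean(model$training_residuals[inside]) else 0
    model$beta0 + model$beta1 * b + corr
  }, numeric(1))
}
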