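#' Build a group design from a cohort
#'
#' Task-PLS groups are the crossing of diagnosis with either acquisition
#' site (longitudinal sample: ASD_UCLA, TD_UCLA, ASD_UPSM, TD_UPSM) or
#' scanner manufacturer (cross-sectional sample: ASD_SIEMENS, TD_SIEMENS,
#' ASD_PHILIPS, TD_PHILIPS).
#'
#' @param cohort Cohort `data.frame`, one row per subject in matrix order.
#' @param by `"dx_site"` or `"dx_scanner"`.
#' @return A factor of group labels, one per subject.
#' @export
group_design <- function(cohort, by = c("dx_site", "dx_scanner")) {
  by <- match.arg(by)
  second <- if (by == "dx_site") cohort$site else cohort$scanner
  factor(paste(cohort$dx, toupper(second), sep = "_"))
}

#' Mean-centred task PLS
#'
#' Re-expresses a subjects-by-vertices data matrix as latent variables (LVs)
#' via singular value decomposition of the group-mean matrix: group means
#' are computed, centred by the unweighted grand mean of group means, and
#' decomposed as `U S W'`. Each LV pairs a group contrast (design scores
#' `U S`) with a cortical pattern (vertex saliences `W`); squared singular
#' values give the fraction of between-group covariance each LV explains.
#'
#' @param x Subjects-by-vertices numeric matrix.
#' @param groups Factor of group labels aligned with rows of `x`; every
#'   level must contain at least 2 subjects.
#' @return An object of class `wgc_pls`: list with `singular_values`,
#'   `covariance_explained`, `design_scores` (groups x LVs, `U S`),
#'   `design_u` (unit-norm `U`), `saliences` (vertices x LVs), `grand_mean`
#'   (the centring row), `group_order`, `groups`, and `degenerate` flag.
#' @export
mean_centered_pls <- function(x, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2L) stop("design error: need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes == 0L)) stop("design error: empty group")
  if (any(sizes < 2L)) stop("design error: every group needs >= 2 subjects")
  m <- group_mean_matrix(x, groups)
  grand <- colMeans(m)                       # unweighted grand mean of group means
  mc <- sweep(m, 2, grand, "-")
  sv <- svd(mc)
  k <- length(sv$d)
  total <- sum(sv$d^2)
  degenerate <- total < .Machine$double.eps * max(1, sum(mc^2))
  cov_expl <- if (total > 0) sv$d^2 / total else rep(0, k)
  structure(list(
    singular_values = sv$d,
    covariance_explained = cov_expl,
    design_scores = sv$u %*% diag(sv$d, k, k),
    design_u = sv$u,
    saliences = sv$v,
    grand_mean = grand,
    group_order = levels(groups),
    groups = groups,
    degenerate = degenerate
  ), class = "wgc_pls")
}

group_mean_matrix <- function(x, groups) {
  g <- levels(groups)
  m <- matrix(0, length(g), ncol(x), dimnames = list(g, colnames(x)))
  for (lev in g) m[lev, ] <- colMeans(x[groups == lev, , drop = FALSE])
  m
}

#' Permutation test for PLS latent variables
#'
#' Reassigns group labels by resampling without replacement (group sizes
#' preserved), recomputes the PLS singular values for each permutation, and
#' counts how often each permuted singular value meets or exceeds the
#' observed one: `p_k = (1 + #exceed) / (1 + n_perm)`.
#'
#' @param x Subjects-by-vertices matrix.
#' @param groups Group factor.
#' @param n_perm Number of permutations (>= 1).
#' @param seed RNG seed.
#' @return Numeric vector of per-LV p-values.
#' @export
pls_permutation <- function(x, groups, n_perm = 1000, seed = 1) {
  if (n_perm < 1) stop("value error: n_perm must be >= 1")
  groups <- droplevels(as.factor(groups))
  obs <- mean_centered_pls(x, groups)$singular_values
  set.seed(seed)
  exceed <- numeric(length(obs))
  for (b in seq_len(n_perm)) {
    gp <- sample(groups)
    d <- svd(centered_group_means(x, gp))$d
    exceed <- exceed + (d >= obs)
  }
  (1 + exceed) / (1 + n_perm)
}

centered_group_means <- function(x, groups) {
  m <- group_mean_matrix(x, groups)
  sweep(m, 2, colMeans(m), "-")
}

#' Bootstrap reliability of PLS saliences (bootstrap ratios)
#'
#' Resamples subjects with replacement within each group (group assignment
#' fixed), recomputes the decomposition, aligns each bootstrap's LVs to the
#' original by maximal absolute correlation of saliences (with sign
#' flipping) to prevent axis flips from corrupting the standard errors, and
#' returns bootstrap ratios `BSR = original salience / bootstrap SE`
#' together with percentile confidence intervals of the design scores.
#' Vertices with zero bootstrap SE are masked (`NA`), never infinite.
#'
#' @param x Subjects-by-vertices matrix.
#' @param groups Group factor.
#' @param n_boot Number of bootstrap resamples (>= 2).
#' @param seed RNG seed.
#' @param conf Confidence level of the design-score intervals. Default 0.95.
#' @return List with `bsr` (vertices x LVs), `salience_se`,
#'   `design_ci_lower`/`design_ci_upper` (groups x LVs).
#' @export
pls_bootstrap <- function(x, groups, n_boot = 500, seed = 1, conf = 0.95) {
  if (n_boot < 2) stop("value error: n_boot must be >= 2")
  groups <- droplevels(as.factor(groups))
  orig <- mean_centered_pls(x, groups)
  k <- length(orig$singular_values)
  v <- ncol(x)
  g <- nlevels(groups)
  idx_by_group <- split(seq_len(nrow(x)), groups)
  set.seed(seed)
  sal_boot <- array(NA_real_, c(v, k, n_boot))
  des_boot <- array(NA_real_, c(g, k, n_boot))
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(idx_by_group, function(i) {
      sample(i, length(i), replace = TRUE)
    }), use.names = FALSE)
    gb <- groups[idx]
    sv <- svd(centered_group_means(x[idx, , drop = FALSE], gb))
    aligned <- align_lvs(orig$saliences, sv$v)
    sal_boot[, , b] <- sv$v[, aligned$perm, drop = FALSE] %*%
      diag(aligned$sign, k, k)
    des <- sv$u %*% diag(sv$d, k, k)
    des_boot[, , b] <- des[, aligned$perm, drop = FALSE] %*%
      diag(aligned$sign, k, k)
  }
  se <- apply(sal_boot, c(1, 2), stats::sd)
  bsr <- orig$saliences / se
  bsr[se == 0] <- NA_real_
  alpha <- (1 - conf) / 2
  list(
    bsr = bsr,
    salience_se = se,
    design_ci_lower = apply(des_boot, c(1, 2), stats::quantile, probs = alpha),
    design_ci_upper = apply(des_boot, c(1, 2), stats::quantile,
                            probs = 1 - alpha)
  )
}

# Greedy LV matching: for each original LV pick the unused bootstrap LV with
# maximal |correlation| of saliences; sign follows the correlation. Falls
# back to dot products if a column is constant.
align_lvs <- function(ref, boot) {
  k <- ncol(ref)
  perm <- integer(k)
  sgn <- numeric(k)
  used <- rep(FALSE, k)
  for (i in seq_len(k)) {
    best <- -Inf; best_j <- NA_integer_; best_s <- 1
    for (j in seq_len(k)) {
      if (used[j]) next
      r <- suppressWarnings(stats::cor(ref[, i], boot[, j]))
      if (!is.finite(r)) r <- sum(ref[, i] * boot[, j])
      if (abs(r) > best) {
        best <- abs(r); best_j <- j; best_s <- if (r < 0) -1 else 1
      }
    }
    perm[i] <- best_j; sgn[i] <- best_s; used[best_j] <- TRUE
  }
  list(perm = perm, sign = sgn)
}

#' Subject brain scores
#'
#' Projects each subject's (grand-mean-centred) data onto the per-LV vertex
#' pattern. Following the described procedure, the projection matrix is the
#' bootstrap-ratio map (reliability-weighted pattern); classical saliences
#' are available via `projection = "salience"`. Masked BSR entries
#' contribute zero.
#'
#' @param x Subjects-by-vertices matrix (same space as the PLS input).
#' @param pls A `wgc_pls` object (for the grand-mean row and saliences).
#' @param bsr Vertices-by-LVs BSR matrix from [pls_bootstrap()] (required
#'   when `projection = "bsr"`).
#' @param projection `"bsr"` (default) or `"salience"`.
#' @return Subjects-by-LVs matrix of brain scores.
#' @export
brain_scores <- function(x, pls, bsr = NULL, projection = c("bsr", "salience")) {
  projection <- match.arg(projection)
  proj <- if (projection == "bsr") {
    if (is.null(bsr)) stop("state error: bsr required for projection = 'bsr'")
    bsr
  } else {
    pls$saliences
  }
  proj[!is.finite(proj)] <- 0
  xc <- sweep(x, 2, pls$grand_mean, "-")
  xc %*% proj
}

#' Orient a latent variable along a group contrast
#'
#' The sign of an SVD axis is arbitrary; for cross-sample comparisons the
#' convention used here is that the diagnosis LV has positive design scores
#' for ASD groups (so negative saliences/BSR mean greater contrast decrease
#' in ASD). Flips the requested LV of a `wgc_pls` fit (and an optional BSR
#' matrix) so that the design scores' dot product with `contrast` is
#' non-negative.
#'
#' @param pls A `wgc_pls` object.
#' @param contrast Numeric vector, one value per group in `group_order`
#'   (e.g. +1 for ASD groups, -1 for TD groups).
#' @param lv Which LV to orient. Default 1.
#' @param bsr Optional vertices-by-LVs BSR matrix flipped in step.
#' @return List with `pls` and (if supplied) `bsr`.
#' @export
orient_lv <- function(pls, contrast, lv = 1, bsr = NULL) {
  stopifnot(length(contrast) == length(pls$group_order))
  if (sum(pls$design_scores[, lv] * contrast) < 0) {
    pls$design_scores[, lv] <- -pls$design_scores[, lv]
    pls$design_u[, lv] <- -pls$design_u[, lv]
    pls$saliences[, lv] <- -pls$saliences[, lv]
    if (!is.null(bsr)) bsr[, lv] <- -bsr[, lv]
  }
  list(pls = pls, bsr = bsr)
}

#' Diagnosis contrast vector for a group order
#'
#' @param group_order Character vector of group labels of the form
#'   `DX_SITE`.
#' @return +1 for ASD groups, -1 for TD groups.
#' @export
dx_contrast <- function(group_order) {
  ifelse(startsWith(group_order, "ASD"), 1, -1)
}

#' Conjunction of two BSR maps
#'
#' Classifies every vertex by the signs of two bootstrap-ratio maps (e.g.
#' the longitudinal and cross-sectional LV1 maps) and reports the four
#' category fractions. A zero BSR counts as negative (decrease).
#'
#' @param bsr_a,bsr_b Numeric vectors of per-vertex BSR values, same length.
#'   Conventionally `a` is the cross-sectional and `b` the longitudinal map.
#' @return List with `category` (factor, levels `both_negative`,
#'   `both_positive`, `a_pos_b_neg`, `b_pos_a_neg`) and `fractions`.
#' @export
conjunction <- function(bsr_a, bsr_b) {
  stopifnot(length(bsr_a) == length(bsr_b))
  neg_a <- bsr_a <= 0
  neg_b <- bsr_b <= 0
  lev <- c("both_negative", "both_positive", "a_pos_b_neg", "b_pos_a_neg")
  cat <- ifelse(neg_a & neg_b, "both_negative",
         ifelse(!neg_a & !neg_b, "both_positive",
         ifelse(!neg_a & neg_b, "a_pos_b_neg", "b_pos_a_neg")))
  cat <- factor(cat, levels = lev)
  fr <- table(cat) / length(cat)
  list(category = cat, fractions = as.numeric(fr) |>
         stats::setNames(lev))
}

#' Group comparison within an extreme-BSR band
#'
#' Reporting utility: selects the vertices whose BSR lies within one
#' standard deviation of the minimum (or maximum) BSR, averages each
#' subject's values over that band, and compares the two diagnostic groups
#' with a two-sample t-test.
#'
#' @param x Subjects-by-vertices matrix (angle values).
#' @param dx Character/factor vector of diagnoses (`ASD`/`TD`) per subject.
#' @param bsr Per-vertex BSR values.
#' @param end `"min"` (default) or `"max"`: which extreme anchors the band.
#' @return An `htest` object from [stats::t.test()] with attribute
#'   `n_vertices` (band size).
#' @export
bsr_band_ttest <- function(x, dx, bsr, end = c("min", "max")) {
  end <- match.arg(end)
  s <- stats::sd(bsr, na.rm = TRUE)
  band <- if (end == "min") {
    which(bsr <= min(bsr, na.rm = TRUE) + s)
  } else {
    which(bsr >= max(bsr, na.rm = TRUE) - s)
  }
  means <- rowMeans(x[, band, drop = FALSE])
  res <- stats::t.test(means[dx == "ASD"], means[dx == "TD"])
  attr(res, "n_vertices") <- length(band)
  res
}

#' Permutation p-value of the diagnosis latent variable
#'
#' Identifies the LV whose design scores correlate most strongly (in
#' absolute value) with the ASD-vs-TD contrast and returns its permutation
#' p-value; used e.g. to show that single-timepoint contrast (no age-change
#' information) carries no diagnostic signal.
#'
#' @param pls A `wgc_pls` object.
#' @param perm_p Vector of per-LV permutation p-values.
#' @return List with `lv`, `p` and `covariance_explained` of that LV.
#' @export
diagnostic_lv <- function(pls, perm_p) {
  contrast <- dx_contrast(pls$group_order)
  score <- abs(as.numeric(crossprod(pls$design_u, contrast)))
  lv <- which.max(score)
  list(lv = lv, p = perm_p[lv],
       covariance_explained = pls$covariance_explained[lv])
}
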