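#' Sigmoid diagnosis prior informed by bootstrap ratios
#'
#' `P(dx) = [1 + exp(s * x * BSR / BSR_max)]^-1` with `s = +1` for TD and
#' `s = -1` for ASD, so the two class priors are complementary for every
#' `x`. When the BSR evidence is negative (greater contrast decrease in
#' ASD), `P(TD | x)` increases monotonically in the angle `x`; the opposite
#' holds for positive BSR. `x` is the standardised angle, conventionally on
#' the training (cross-sectional) angle domain.
#'
#' @param x Standardised angle value(s).
#' @param bsr Bootstrap-ratio evidence at the vertex/region.
#' @param bsr_max Maximum absolute BSR over the cortex (> 0).
#' @param dx `"ASD"` or `"TD"`.
#' @return Prior probabilities, same length as `x`.
#' @export
prior_probability <- function(x, bsr, bsr_max, dx = c("TD", "ASD")) {
  dx <- match.arg(dx)
  if (bsr_max <= 0) stop("value error: bsr_max must be > 0")
  s <- if (dx == "TD") 1 else -1
  1 / (1 + exp(s * x * bsr / bsr_max))
}

#' Two-class posterior from extreme-value likelihoods and sigmoid priors
#'
#' `P(dx | alpha) ~ P(alpha | dx) * P(dx)`, normalised over the two classes.
#' Products are computed in log space and normalised with log-sum-exp, so
#' underflow cannot produce a 0/0.
#'
#' @param x Standardised angle value(s) of the test subject(s).
#' @param ev_asd,ev_td `ev_params` likelihood fits for the two classes.
#' @param bsr,bsr_max Prior evidence, as in [prior_probability()].
#' @param domain Optional length-2 numeric: the training angle range; `x`
#'   is clipped into it before evaluating the prior.
#' @return Matrix with columns `p_asd`, `p_td` (rows follow `x`), each pair
#'   summing to 1.
#' @export
posterior_dx <- function(x, ev_asd, ev_td, bsr, bsr_max, domain = NULL) {
  xp <- if (!is.null(domain)) pmin(pmax(x, domain[1]), domain[2]) else x
  ll_asd <- dgumbel_ev(x, ev_asd$mu, ev_asd$sigma, ev_asd$orientation,
                       log = TRUE)
  ll_td <- dgumbel_ev(x, ev_td$mu, ev_td$sigma, ev_td$orientation,
                      log = TRUE)
  lp_asd <- ll_asd + log(prior_probability(xp, bsr, bsr_max, "ASD"))
  lp_td <- ll_td + log(prior_probability(xp, bsr, bsr_max, "TD"))
  m <- pmax(lp_asd, lp_td)
  den <- m + log(exp(lp_asd - m) + exp(lp_td - m))
  cbind(p_asd = exp(lp_asd - den), p_td = exp(lp_td - den))
}

#' Confusion metrics for a two-class diagnosis
#'
#' Sensitivity is the fraction of ASD subjects predicted ASD; specificity
#' the fraction of TD subjects predicted TD; accuracy the overall fraction
#' correct. A metric whose class is absent from `truth` is reported as `NA`
#' (missing), never as 0.
#'
#' @param truth,predicted Character/factor vectors with values in
#'   `{"ASD", "TD"}`, same length.
#' @return Named list: `sensitivity`, `specificity`, `accuracy`.
#' @export
confusion_metrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (!all(c(truth, predicted) %in% c("ASD", "TD"))) {
    stop("value error: labels must be 'ASD' or 'TD'")
  }
  n_asd <- sum(truth == "ASD")
  n_td <- sum(truth == "TD")
  list(
    sensitivity = if (n_asd > 0) sum(truth == "ASD" & predicted == "ASD") / n_asd
                  else NA_real_,
    specificity = if (n_td > 0) sum(truth == "TD" & predicted == "TD") / n_td
                  else NA_real_,
    accuracy = mean(truth == predicted)
  )
}

#' Train on cross-sectional angles, predict longitudinal diagnoses
#'
#' The diagnostic prediction model: each subject is reduced to the mean of
#' its standardised angles over a region (whole cortex by default); the two
#' class likelihoods are extreme-value fits to the cross-sectional training
#' scalars, the prior is the sigmoid of the region-mean LV1 BSR, and each
#' longitudinal test subject is assigned the class with the larger
#' posterior. An exact posterior tie predicts TD (conservative toward the
#' no-disorder label). Alternatively (`reduce = "posterior"`), per-vertex
#' single-vertex posteriors are averaged over the region.
#'
#' @param crsc_z Standardised cross-sectional angle matrix (subjects x V).
#' @param crsc_cohort Cross-sectional cohort (training labels).
#' @param lngt_z Standardised longitudinal angle matrix (subjects x V,
#'   standardised with its own moments).
#' @param lngt_cohort One row per longitudinal subject (true labels).
#' @param bsr Per-vertex LV1 BSR map from the cross-sectional PLS.
#' @param region Optional integer vector of vertex indices; default all.
#' @param bsr_max Maximum |BSR| over the cortex; default from `bsr`.
#' @param reduce `"mean_angle"` (default: one model on region-mean angles)
#'   or `"posterior"` (average per-vertex posteriors).
#' @return Object of class `wgc_prediction`: list with `table`
#'   (per-subject posterior, prediction, truth), `metrics` (confusion
#'   metrics), `ev_asd`, `ev_td`, `prior_bsr`, `domain`.
#' @export
train_predict <- function(crsc_z, crsc_cohort, lngt_z, lngt_cohort, bsr,
                          region = NULL, bsr_max = NULL,
                          reduce = c("mean_angle", "posterior")) {
  reduce <- match.arg(reduce)
  v <- ncol(crsc_z)
  if (is.null(region)) region <- seq_len(v)
  if (length(region) == 0L) stop("value error: empty region")
  if (any(region < 1L | region > v)) stop("value error: region out of range")
  if (!all(c("ASD", "TD") %in% crsc_cohort$dx)) {
    stop("train_predict: both classes required in training cohort")
  }
  if (is.null(bsr_max)) bsr_max <- max(abs(bsr), na.rm = TRUE)
  train_scalar <- rowMeans(crsc_z[, region, drop = FALSE], na.rm = TRUE)
  test_scalar <- rowMeans(lngt_z[, region, drop = FALSE], na.rm = TRUE)
  ev_asd <- fit_ev_likelihood(train_scalar[crsc_cohort$dx == "ASD"])
  ev_td <- fit_ev_likelihood(train_scalar[crsc_cohort$dx == "TD"])
  prior_bsr <- mean(bsr[region], na.rm = TRUE)
  domain <- range(train_scalar)
  if (reduce == "mean_angle") {
    post <- posterior_dx(test_scalar, ev_asd, ev_td, prior_bsr, bsr_max,
                         domain = domain)
  } else {
    acc <- matrix(0, nrow(lngt_z), 2)
    for (vv in region) {
      ta <- crsc_z[, vv]
      eva <- fit_ev_likelihood(ta[crsc_cohort$dx == "ASD"])
      evt <- fit_ev_likelihood(ta[crsc_cohort$dx == "TD"])
      acc <- acc + posterior_dx(lngt_z[, vv], eva, evt, bsr[vv], bsr_max,
                                domain = range(ta))
    }
    post <- acc / length(region)
    colnames(post) <- c("p_asd", "p_td")
  }
  predicted <- ifelse(post[, "p_asd"] > post[, "p_td"], "ASD", "TD")
  tab <- data.frame(subject_id = lngt_cohort$subject_id,
                    posterior_asd = post[, "p_asd"],
                    predicted = predicted,
                    truth = lngt_cohort$dx,
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 metrics = confusion_metrics(tab$truth, tab$predicted),
                 ev_asd = ev_asd, ev_td = ev_td,
                 prior_bsr = prior_bsr, domain = domain),
            class = "wgc_prediction")
}

#' Per-vertex single-vertex prediction maps
#'
#' Fits a single-vertex diagnostic model at every vertex and maps the
#' resulting sensitivity and specificity over the cortex, together with the
#' mask of vertices where both exceed 50% (excluding trivial all-one-class
#' predictors). Vertices whose model cannot be fitted are masked.
#'
#' @inheritParams train_predict
#' @return List with `sensitivity`, `specificity` (per-vertex vectors) and
#'   `mutual_mask` (logical, both > 0.5).
#' @export
vertexwise_maps <- function(crsc_z, crsc_cohort, lngt_z, lngt_cohort, bsr,
                            bsr_max = NULL) {
  v <- ncol(crsc_z)
  if (is.null(bsr_max)) bsr_max <- max(abs(bsr), na.rm = TRUE)
  sens <- spec <- rep(NA_real_, v)
  for (vv in seq_len(v)) {
    res <- tryCatch(
      train_predict(crsc_z, crsc_cohort, lngt_z, lngt_cohort, bsr,
                    region = vv, bsr_max = bsr_max),
      error = function(e) NULL)
    if (!is.null(res)) {
      sens[vv] <- res$metrics$sensitivity
      spec[vv] <- res$metrics$specificity
    }
  }
  list(sensitivity = sens, specificity = spec,
       mutual_mask = !is.na(sens) & !is.na(spec) & sens > 0.5 & spec > 0.5)
}
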