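#' One conjunction-recovery replicate
#'
#' Generates an effect template with the requested mutually-negative
#' fraction, simulates one cross-sectional and one longitudinal sample from
#' it, computes the two angle matrices, runs both mean-centred PLS analyses
#' with bootstrap, orients each LV1 along the diagnosis contrast (ASD
#' positive), and returns the conjunction of the two LV1 BSR maps.
#'
#' @param mesh A `surface_mesh` (shared across replicates).
#' @param spec A `sim_spec` whose `n_vertices` matches the mesh.
#' @param seed Replicate seed (drives template and both samples).
#' @param negative_fraction Planted mutually-negative fraction. Default 0.81.
#' @param n_boot Bootstrap resamples per PLS. Default 100.
#' @return List with `fractions` (conjunction category fractions),
#'   `bsr_crsc`, `bsr_lngt` (LV1 maps) and `template`.
#' @export
conjunction_replicate <- function(mesh, spec, seed,
                                  negative_fraction = 0.81, n_boot = 100) {
  template <- make_effect_template(mesh, negative_fraction, seed = seed)
  crsc <- simulate_cross_sectional(spec, template, seed = seed + 1L)
  ang_c <- cross_sectional_angle(crsc$wgc, crsc$cohort, warn_below = 2)
  kept <- drop_masked_rows(ang_c, crsc$cohort)
  grp_c <- group_design(kept$cohort, "dx_scanner")
  bsr_c <- diagnosis_bsr(kept$angles, grp_c, n_boot = n_boot, seed = seed + 2L)
  lngt <- simulate_longitudinal(spec, template, seed = seed + 3L)
  ang_l <- longitudinal_angles(lngt$wgc, lngt$cohort)
  coh_l <- lngt$cohort[lngt$cohort$timepoint == "baseline", , drop = FALSE]
  grp_l <- group_design(coh_l, "dx_site")
  bsr_l <- diagnosis_bsr(ang_l, grp_l, n_boot = n_boot, seed = seed + 4L)
  conj <- conjunction(bsr_c, bsr_l)
  list(fractions = conj$fractions, bsr_crsc = bsr_c,
       bsr_lngt = bsr_l, template = template)
}

#' Median both-negative conjunction fraction over replicates
#'
#' @param n_replicates Number of seeded replicates (>= 1).
#' @param seed Base seed; replicate r uses `seed + 1000 * r`.
#' @param n_vertices Template mesh size. Default 400.
#' @param negative_fraction Planted fraction. Default 0.81.
#' @param n_boot Bootstrap resamples per PLS. Default 100.
#' @param spec Optional `sim_spec` override (its `n_vertices` must match).
#' @return List with `median_both_negative` (a fraction between 0 and 1) and
#'   `per_replicate` (vector of both-negative fractions).
#' @export
conjunction_recovery <- function(n_replicates = 20, seed = 1,
                                 n_vertices = 400,
                                 negative_fraction = 0.81, n_boot = 100,
                                 spec = NULL) {
  mesh <- make_mesh(n_vertices)
  if (is.null(spec)) spec <- sim_spec(n_vertices = n_vertices)
  fr <- vapply(seq_len(n_replicates), function(r) {
    conjunction_replicate(mesh, spec, seed = seed + 1000L * r,
                          negative_fraction = negative_fraction,
                          n_boot = n_boot)$fractions[["both_negative"]]
  }, numeric(1))
  list(median_both_negative = stats::median(fr), per_replicate = fr)
}

#' Bootstrap-ratio map of the diagnosis latent variable
#'
#' Runs the mean-centred PLS with bootstrap on a subjects-by-vertices
#' matrix, selects the latent variable whose design scores align most
#' strongly with the ASD-vs-TD contrast (LV1 under the study conditions,
#' but site/scanner structure can promote a non-diagnostic LV in noisy
#' samples), orients it so ASD design scores are positive, and returns its
#' BSR map.
#'
#' @param x Subjects-by-vertices angle matrix.
#' @param groups Group factor with `DX_SITE`-style labels.
#' @param n_boot Bootstrap resamples.
#' @param seed RNG seed.
#' @return Per-vertex BSR vector of the oriented diagnosis LV, with
#'   attribute `lv` (the selected LV index).
#' @export
diagnosis_bsr <- function(x, groups, n_boot = 100, seed = 1) {
  pls <- mean_centered_pls(x, groups)
  boot <- pls_bootstrap(x, groups, n_boot = n_boot, seed = seed)
  contrast <- dx_contrast(pls$group_order)
  lv <- which.max(abs(as.numeric(crossprod(pls$design_u, contrast))))
  o <- orient_lv(pls, contrast, lv = lv, bsr = boot$bsr)
  structure(o$bsr[, lv], lv = lv)
}

#' One diagnostic-classification replicate
#'
#' Simulates a cross-sectional training sample and a longitudinal test
#' sample from one template (planted effect or null), derives standardised
#' angles for both, obtains the LV1 BSR prior from the cross-sectional PLS
#' bootstrap, and classifies the longitudinal subjects.
#'
#' @param mesh A `surface_mesh`.
#' @param spec A `sim_spec` matching the mesh.
#' @param seed Replicate seed.
#' @param planted If `FALSE`, the ASD slopes are set equal to the TD slopes
#'   (null template: no diagnosis effect).
#' @param n_boot Bootstrap resamples for the BSR prior. Default 50.
#' @return The `wgc_prediction` object from [train_predict()].
#' @export
classification_replicate <- function(mesh, spec, seed, planted = TRUE,
                                     n_boot = 50) {
  template <- make_effect_template(mesh, seed = seed)
  if (!planted) {
    template$slope_asd <- template$slope_td
    template$negative_fraction <- 0
  }
  crsc <- simulate_cross_sectional(spec, template, seed = seed + 1L)
  ang_c <- cross_sectional_angle(crsc$wgc, crsc$cohort, warn_below = 2)
  kept <- drop_masked_rows(ang_c, crsc$cohort)
  crsc_cohort <- kept$cohort
  z_c <- standardize_angles(kept$angles)
  grp_c <- group_design(crsc_cohort, "dx_scanner")
  bsr_c <- diagnosis_bsr(z_c, grp_c, n_boot = n_boot, seed = seed + 2L)
  lngt <- simulate_longitudinal(spec, template, seed = seed + 3L)
  ang_l <- longitudinal_angles(lngt$wgc, lngt$cohort)
  z_l <- standardize_angles(ang_l)
  coh_l <- lngt$cohort[lngt$cohort$timepoint == "baseline", , drop = FALSE]
  train_predict(z_c, crsc_cohort, z_l, coh_l, as.numeric(bsr_c))
}
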