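#!/usr/bin/env Rscript
# Stage 3: task PLS of both angle samples, and the conjunction analysis.
#
# Four groups per sample (diagnosis x site for the longitudinal angles,
# diagnosis x scanner for the cross-sectional ones): mean-centred PLS,
# permutation significance, bootstrap ratios (BSR), brain scores, and the
# sign conjunction of the two diagnosis-LV BSR maps. Also runs the control
# analysis on single-timepoint contrast (no age-change information), which
# should carry no diagnostic signal.

suppressPackageStartupMessages({
  library(wgcdev)
  library(jsonlite)
})

seed <- 42L
n_perm <- 500L
n_boot <- 200L
out_dir <- "results/pls"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

crsc_cohort <- read_cohort("results/angles/crsc_cohort_kept.tsv")
ang_crsc <- read_subject_matrix("results/angles/crsc_angle.tsv", crsc_cohort)
lngt_cohort <- read_cohort("results/angles/lngt_cohort_base.tsv")
ang_lngt <- read_subject_matrix("results/angles/lngt_angle.tsv", lngt_cohort)

run_pls <- function(x, cohort, by, tag) {
  groups <- group_design(cohort, by)
  fit <- mean_centered_pls(x, groups)
  perm <- pls_permutation(x, groups, n_perm = n_perm, seed = seed)
  boot <- pls_bootstrap(x, groups, n_boot = n_boot, seed = seed + 1L)
  contrast <- dx_contrast(fit$group_order)
  lv <- which.max(abs(as.numeric(crossprod(fit$design_u, contrast))))
  o <- orient_lv(fit, contrast, lv = lv, bsr = boot$bsr)
  br <- brain_scores(x, o$pls, o$bsr)
  message(sprintf(
    "%s PLS: diagnosis LV = LV%d, p = %.4f, %.1f%% of covariance",
    tag, lv, perm[lv], 100 * fit$covariance_explained[lv]))
  message("  design scores (", paste(fit$group_order, collapse = ", "),
          "): ", paste(round(o$pls$design_u[, lv], 2), collapse = ", "))
  write_vertex_map(o$bsr[, lv], file.path(out_dir, paste0(tag, "_bsr.txt")))
  utils::write.table(
    data.frame(subject_id = cohort$subject_id, dx = cohort$dx,
               brain_score = br[, lv]),
    file.path(out_dir, paste0(tag, "_brain_scores.tsv")),
    sep = "\t", quote = FALSE, row.names = FALSE)
  list(fit = fit, perm = perm, lv = lv, bsr = o$bsr[, lv], brsc = br[, lv])
}

crsc <- run_pls(ang_crsc, crsc_cohort, "dx_scanner", "crsc")
lngt <- run_pls(ang_lngt, lngt_cohort, "dx_site", "lngt")

conj <- conjunction(crsc$bsr, lngt$bsr)
message("conjunction fractions: ",
        paste(names(conj$fractions), round(conj$fractions, 3),
              sep = "=", collapse = ", "))

# extreme-BSR band group comparison (longitudinal sample, decrease end)
band <- bsr_band_ttest(ang_lngt, lngt_cohort$dx, lngt$bsr, end = "min")
message(sprintf("min-BSR band t-test: t = %.2f, p = %.4f (%d vertices)",
                band$statistic, band$p.value, attr(band, "n_vertices")))

# control: single-timepoint contrast carries no diagnostic signal
crsc_all <- read_cohort("results/synthetic/crsc_cohort.tsv")
wgc_static <- read_subject_matrix("results/synthetic/crsc_wgc.tsv", crsc_all)
gs <- group_design(crsc_all, "dx_scanner")
static_fit <- mean_centered_pls(wgc_static, gs)
static_perm <- pls_permutation(wgc_static, gs, n_perm = n_perm, seed = seed)
static <- diagnostic_lv(static_fit, static_perm)
message(sprintf(
  "static-contrast control: diagnosis LV%d, p = %.3f, %.2f%% of covariance",
  static$lv, static$p, 100 * static$covariance_explained))

write_json(list(
  crsc = list(diagnosis_lv = crsc$lv, perm_p = crsc$perm[crsc$lv],
              covariance_explained = crsc$fit$covariance_explained[crsc$lv],
              singular_values = crsc$fit$singular_values),
  lngt = list(diagnosis_lv = lngt$lv, perm_p = lngt$perm[lngt$lv],
              covariance_explained = lngt$fit$covariance_explained[lngt$lv],
              singular_values = lngt$fit$singular_values),
  conjunction = as.list(conj$fractions),
  min_bsr_band = list(t = unname(band$statistic), p = band$p.value,
                      n_vertices = attr(band, "n_vertices")),
  static_control = static
), file.path(out_dir, "pls_summary.json"), auto_unbox = TRUE, digits = 6)
message("written to ", out_dir)
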