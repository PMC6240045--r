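#!/usr/bin/env Rscript
# Stage 2: rate-of-change angles.
#
# Longitudinal sample: per-vertex arctangent of the annual contrast change
# within each subject's scan pair. Cross-sectional sample: the per-subject
# analogue against same-site, same-diagnosis peers. Subjects too close to
# their peer mean age (inestimable angles) are masked and dropped; both
# matrices are also z-scored per vertex for the predictive models.

suppressPackageStartupMessages(library(wgcdev))

in_dir <- "results/synthetic"
out_dir <- "results/angles"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

crsc_cohort <- read_cohort(file.path(in_dir, "crsc_cohort.tsv"))
crsc_wgc <- read_subject_matrix(file.path(in_dir, "crsc_wgc.tsv"), crsc_cohort)
lngt_cohort <- read_cohort(file.path(in_dir, "lngt_cohort.tsv"))
lngt_wgc <- read_subject_matrix(file.path(in_dir, "lngt_wgc.tsv"), lngt_cohort)

ang_crsc <- cross_sectional_angle(crsc_wgc, crsc_cohort, warn_below = 2)
kept <- drop_masked_rows(ang_crsc, crsc_cohort)
message("cross-sectional angles: ", nrow(kept$angles), " subjects kept, ",
        kept$n_dropped, " masked (near-zero peer age gap)")

ang_lngt <- longitudinal_angles(lngt_wgc, lngt_cohort)
# one angle map per subject: carry the baseline metadata as a per-subject table
lngt_base <- lngt_cohort[lngt_cohort$timepoint == "baseline", , drop = FALSE]
lngt_base$timepoint <- "single"
message("longitudinal angles: ", nrow(ang_lngt), " subjects")

write_cohort(kept$cohort, file.path(out_dir, "crsc_cohort_kept.tsv"))
write_subject_matrix(kept$angles, kept$cohort,
                     file.path(out_dir, "crsc_angle.tsv"))
write_subject_matrix(standardize_angles(kept$angles), kept$cohort,
                     file.path(out_dir, "crsc_angle_z.tsv"))
write_cohort(lngt_base, file.path(out_dir, "lngt_cohort_base.tsv"))
write_subject_matrix(ang_lngt, lngt_base, file.path(out_dir, "lngt_angle.tsv"))
write_subject_matrix(standardize_angles(ang_lngt), lngt_base,
                     file.path(out_dir, "lngt_angle_z.tsv"))
message("written to ", out_dir)
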