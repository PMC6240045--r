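#!/usr/bin/env Rscript
# Stage 4: Bayesian diagnostic prediction.
#
# Trains the extreme-value likelihoods and BSR-informed sigmoid prior on
# the standardised cross-sectional angles and predicts the diagnosis of
# every longitudinal subject from its standardised angle map; reports the
# confusion metrics for the whole-cortex model and per-vertex single-vertex
# model maps with the mutual >50% sensitivity/specificity mask.

suppressPackageStartupMessages({
  library(wgcdev)
  library(jsonlite)
})

out_dir <- "results/prediction"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

crsc_cohort <- read_cohort("results/angles/crsc_cohort_kept.tsv")
crsc_z <- read_subject_matrix("results/angles/crsc_angle_z.tsv", crsc_cohort)
lngt_cohort <- read_cohort("results/angles/lngt_cohort_base.tsv")
lngt_z <- read_subject_matrix("results/angles/lngt_angle_z.tsv", lngt_cohort)
bsr <- as.numeric(read_vertex_map("results/pls/crsc_bsr.txt"))

pred <- train_predict(crsc_z, crsc_cohort, lngt_z, lngt_cohort, bsr)
m <- pred$metrics
message(sprintf(
  "whole-cortex model: sensitivity %.0f%%, specificity %.0f%%, accuracy %.0f%%",
  100 * m$sensitivity, 100 * m$specificity, 100 * m$accuracy))
message(sprintf(
  "  likelihoods: ASD Gumbel(mu=%.2f, sigma=%.2f, orient %+d), ",
  pred$ev_asd$mu, pred$ev_asd$sigma, pred$ev_asd$orientation),
  sprintf("TD Gumbel(mu=%.2f, sigma=%.2f, orient %+d); prior BSR %.2f",
          pred$ev_td$mu, pred$ev_td$sigma, pred$ev_td$orientation,
          pred$prior_bsr))

utils::write.table(pred$table, file.path(out_dir, "posteriors.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

maps <- vertexwise_maps(crsc_z, crsc_cohort, lngt_z, lngt_cohort, bsr)
message(sprintf(
  "single-vertex models: %d/%d vertices in the mutual >50%% mask",
  sum(maps$mutual_mask), length(maps$mutual_mask)))
write_vertex_map(maps$sensitivity, file.path(out_dir, "sensitivity.txt"))
write_vertex_map(maps$specificity, file.path(out_dir, "specificity.txt"))
write_vertex_map(as.numeric(maps$mutual_mask),
                 file.path(out_dir, "mutual_mask.txt"))

write_json(list(
  whole_cortex = m,
  prior_bsr = pred$prior_bsr,
  ev_asd = unclass(pred$ev_asd), ev_td = unclass(pred$ev_td),
  mutual_mask_fraction = mean(maps$mutual_mask)
), file.path(out_dir, "prediction_summary.json"), auto_unbox = TRUE,
digits = 6)
message("written to ", out_dir)
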