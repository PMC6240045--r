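#!/usr/bin/env Rscript
# Stage 5: behavioural scores and severity prediction.
#
# Attaches simulated ADOS social+communication totals to the ASD subjects
# (coupled to how strongly each expresses the diagnosis pattern, i.e. their
# brain score), converts them to proxy calibrated severity via the bundled
# synthetic lookup table, reports the log-brain-score correlations, and
# fits the severity GLM with windowed residual correction to predict the
# longitudinal subjects' severity from the cross-sectional model.

suppressPackageStartupMessages({
  library(wgcdev)
  library(jsonlite)
})

seed <- 42L
out_dir <- "results/severity"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

crsc_br <- utils::read.delim("results/pls/crsc_brain_scores.tsv")
lngt_br <- utils::read.delim("results/pls/lngt_brain_scores.tsv")
crsc_cohort <- read_cohort("results/angles/crsc_cohort_kept.tsv")
lngt_cohort <- read_cohort("results/angles/lngt_cohort_base.tsv")

# ASD subjects express the pattern positively: use the positive part of the
# brain score as the expression scalar the ADOS generator couples to
crsc_cohort <- simulate_ados(crsc_cohort, pmax(crsc_br$brain_score, 0),
                             target_r = 0.42, seed = seed)
lngt_cohort <- simulate_ados(lngt_cohort, pmax(lngt_br$brain_score, 0),
                             target_r = 0.42, seed = seed + 1L)

table_path <- system.file("extdata", "synthetic_severity_table.tsv",
                          package = "wgcdev")
css <- read_severity_table(table_path)
sev_crsc <- proxy_severity(crsc_cohort$ados_social_comm_total,
                           crsc_cohort$ados_module, crsc_cohort$age, css)
sev_lngt <- proxy_severity(lngt_cohort$ados_social_comm_total,
                           lngt_cohort$ados_module, lngt_cohort$age, css)

asd_c <- crsc_cohort$dx == "ASD"
r_raw <- correlate_log_brainscore(crsc_br$brain_score[asd_c],
                                  crsc_cohort$ados_social_comm_total[asd_c])
r_css <- correlate_log_brainscore(crsc_br$brain_score[asd_c],
                                  sev_crsc[asd_c])
message(sprintf(
  "cross-sectional: r(log BrSc+, raw ADOS) = %.2f (p = %.3g, n = %d)",
  r_raw$r, r_raw$p, r_raw$n_used))
message(sprintf(
  "cross-sectional: r(log BrSc+, proxy severity) = %.2f (p = %.3g, n = %d)",
  r_css$r, r_css$p, r_css$n_used))

# severity GLM on the cross-sectional ASD subjects, windowed-residual
# prediction for the longitudinal ASD subjects
model <- fit_severity_model(crsc_br$brain_score[asd_c], sev_crsc[asd_c])
asd_l <- lngt_cohort$dx == "ASD"
pred_sev <- predict_severity(model, lngt_br$brain_score[asd_l])
r_pred <- stats::cor.test(pred_sev, sev_lngt[asd_l])
message(sprintf(
  "severity GLM: beta0 = %.2f, beta1 = %.3f, w = %.3f",
  model$beta0, model$beta1, model$window_w))
message(sprintf(
  "longitudinal: r(predicted, actual proxy severity) = %.2f (p = %.3g)",
  r_pred$estimate, r_pred$p.value))

utils::write.table(
  data.frame(subject_id = lngt_cohort$subject_id[asd_l],
             brain_score = lngt_br$brain_score[asd_l],
             actual_severity = sev_lngt[asd_l],
             predicted_severity = pred_sev),
  file.path(out_dir, "severity_predictions.tsv"),
  sep = "\t", quote = FALSE, row.names = FALSE)

write_json(list(
  r_log_brsc_raw_ados = r_raw,
  r_log_brsc_proxy_severity = r_css,
  model = list(beta0 = model$beta0, beta1 = model$beta1,
               window_w = model$window_w),
  r_predicted_vs_actual = list(r = unname(r_pred$estimate),
                               p = r_pred$p.value)
), file.path(out_dir, "severity_summary.json"), auto_unbox = TRUE,
digits = 6)
message("written to ", out_dir)
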