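#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study data.
#
# Builds the template mesh, plants the effect-sign template (81% of the
# cortex with a steeper contrast decrease in ASD), and simulates the two
# cohorts: a cross-sectional sample with the 14-site structure (359
# subjects, 146 ASD) and a longitudinal sample (12 ASD + 9 TD, two scans
# each, 2.31 years apart). Writes cohort manifests, contrast matrices,
# template slope maps and a provenance record under results/synthetic/.

suppressPackageStartupMessages({
  library(wgcdev)
  library(jsonlite)
})

seed <- 42L
n_vertices <- 300L
out_dir <- "results/synthetic"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

mesh <- make_mesh(n_vertices)
spec <- sim_spec(n_vertices = n_vertices)
template <- make_effect_template(mesh, negative_fraction = 0.81, seed = seed)
message("planted negative fraction: ", template$negative_fraction)

crsc <- simulate_cross_sectional(spec, template, seed = seed + 1L)
lngt <- simulate_longitudinal(spec, template, seed = seed + 2L)
message("cross-sectional: ", nrow(crsc$cohort), " subjects (",
        sum(crsc$cohort$dx == "ASD"), " ASD)")
message("longitudinal: ", length(unique(lngt$cohort$subject_id)),
        " subjects, ", nrow(lngt$cohort), " scans")

write_cohort(crsc$cohort, file.path(out_dir, "crsc_cohort.tsv"))
write_subject_matrix(crsc$wgc, crsc$cohort, file.path(out_dir, "crsc_wgc.tsv"))
write_cohort(lngt$cohort, file.path(out_dir, "lngt_cohort.tsv"))
write_subject_matrix(lngt$wgc, lngt$cohort, file.path(out_dir, "lngt_wgc.tsv"))
write_vertex_map(template$slope_td, file.path(out_dir, "slope_td.txt"),
                 template_id = "synthetic-sphere-300")
write_vertex_map(template$slope_asd, file.path(out_dir, "slope_asd.txt"),
                 template_id = "synthetic-sphere-300")

write_json(list(seed = seed, n_vertices = n_vertices,
                negative_fraction = template$negative_fraction,
                package_version = as.character(packageVersion("wgcdev"))),
           file.path(out_dir, "provenance.json"), auto_unbox = TRUE)
message("written to ", out_dir)
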