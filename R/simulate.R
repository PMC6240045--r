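#' Default cross-sectional site table
#'
#' Per-site group sizes, age distributions (mean and sd in years, per
#' diagnostic group) and scanner manufacturer for the default cross-sectional
#' simulation: 14 acquisition sites, 146 ASD and 213 TD subjects (359 in
#' total), ages spanning childhood through young adulthood, scanners split
#' between two manufacturers.
#'
#' @return A `data.frame` with columns `site`, `n_asd`, `n_td`,
#'   `age_mean_asd`, `age_sd_asd`, `age_mean_td`, `age_sd_td`, `scanner`.
#' @export
default_site_table <- function() {
  tab <- utils::read.table(text = "
site          n_asd n_td age_mean_asd age_sd_asd age_mean_td age_sd_td scanner
CMU               6    6         22.5        2.6        24.7       4.8 Siemens
KKI              11   17         10.4        1.5        10.2       1.2 Philips
LEUVEN_1          8   10         22.4        3.2        24.0       3.0 Philips
LEUVEN_2          8    8         13.4        1.1        14.9       1.5 Philips
NYU              25   30         14.5        7.0        12.3       3.9 Siemens
TRINITY          13   11         16.6        2.9        17.1       3.7 Philips
UCLA_1            6    9         14.0        3.6        13.4       1.5 Siemens
ETH_1             6   17         21.3        4.4        22.6       4.5 Philips
GU_1              9   15         10.7        1.7        10.7       1.5 Siemens
KKI_2            10   44         11.0        1.3        10.5       1.2 Philips
NYU_2            22   16          8.8        3.0         8.8       1.8 Siemens
OHSU_1            6    7         12.0        2.7         8.9       0.7 Siemens
TCD_1            12   18         14.3        3.3        15.7       3.2 Philips
UCLA_2            4    5         12.0        1.8        10.8       2.9 Siemens
", header = TRUE, stringsAsFactors = FALSE)
  tab
}

#' Simulation specification
#'
#' Bundles every tunable of the synthetic cohort generator. The defaults
#' reproduce the study-like conditions: the cross-sectional site structure of
#' [default_site_table()] (359 subjects, 146 ASD), a longitudinal sample of
#' 12 ASD + 9 TD subjects scanned twice at two sites with a mean baseline age
#' of 12.75 years and a 2.31-year inter-scan interval, additive site and
#' scanner offsets, and i.i.d. vertex measurement noise.
#'
#' Effect magnitudes (contrast-ratio units per year) have no published
#' values; the defaults are synthetic-only choices sized so that the planted
#' diagnosis effect is recoverable by the downstream analyses at desk scale
#' (see the package vignette).
#'
#' @param n_vertices Vertices of the template mesh.
#' @param site_table Cross-sectional site table (see [default_site_table()]).
#' @param lngt_n_asd,lngt_n_td Longitudinal group sizes.
#' @param lngt_sites Two site labels for the longitudinal sample; subjects
#'   are split between them (ASD 6/6, TD 5/4 under the defaults).
#' @param lngt_age_mean,lngt_age_sd Baseline age distribution (years).
#' @param lngt_interval Inter-scan interval (years), fixed across subjects.
#' @param baseline_wgc_mean Grand mean contrast ratio at the reference age.
#' @param site_offset_sd,scanner_offset_sd SDs of the additive per-site and
#'   per-scanner offsets (drawn once per simulation).
#' @param subject_offset_sd SD of the per-subject trajectory intercept.
#' @param slope_subject_sd SD of the per-subject slope deviation
#'   (contrast-ratio units/year, constant across vertices): inter-subject
#'   heterogeneity of the developmental trajectory.
#' @param noise_sd SD of i.i.d. per-vertex, per-scan measurement noise.
#' @param ados_mean,ados_sd,ados_target_r ADOS social+communication total
#'   generation: marginal location/scale and the target correlation with the
#'   log of positive pattern-expression values.
#' @param age_ref Trajectory anchor age; `NULL` (default) uses the cohort
#'   grand mean age, keeping `baseline_wgc_mean` interpretable.
#' @param anchor `"cell"` (default) anchors each cross-sectional
#'   (site, dx) cell's trajectory at that cell's mean age, so single-
#'   timepoint contrast carries no diagnostic signal (contrast levels are
#'   dominated by site/scanner, as observed empirically; both angle metrics
#'   are invariant to this choice since they cancel intercepts).
#'   `"cohort"` anchors every trajectory at the common `age_ref`.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(n_vertices = 1000,
                     site_table = default_site_table(),
                     lngt_n_asd = 12, lngt_n_td = 9,
                     lngt_sites = c("UCLA", "UPSM"),
                     lngt_age_mean = 12.75, lngt_age_sd = 1.8,
                     lngt_interval = 2.31,
                     baseline_wgc_mean = 1.25,
                     site_offset_sd = 0.02,
                     scanner_offset_sd = 0.01,
                     subject_offset_sd = 0.005,
                     slope_subject_sd = 0.001,
                     noise_sd = 0.005,
                     ados_mean = 10, ados_sd = 4, ados_target_r = 0.42,
                     age_ref = NULL, anchor = c("cell", "cohort")) {
  anchor <- match.arg(anchor)
  spec <- as.list(environment())
  spec$anchor <- anchor
  sds <- c(spec$site_offset_sd, spec$scanner_offset_sd,
           spec$subject_offset_sd, spec$noise_sd, spec$lngt_age_sd)
  if (any(sds < 0)) stop("spec error: standard deviations must be >= 0")
  if (any(c(site_table$n_asd, site_table$n_td,
            lngt_n_asd, lngt_n_td) < 1)) {
    stop("spec error: group sizes must be >= 1")
  }
  class(spec) <- "sim_spec"
  spec
}

#' Planted effect template
#'
#' Generates per-vertex age slopes for the two diagnostic groups such that a
#' configurable fraction of the cortex shows a steeper contrast decrease in
#' ASD (`slope_asd < slope_td`), with the remainder showing the reverse
#' (emulating focal increases in primary-sensory-like regions). The sign
#' pattern is spatially smooth; optional patches force connected discs to a
#' given sign and are applied last, counted within the fraction.
#'
#' The slope magnitudes are synthetic-only defaults (no published values
#' exist): typical-development slopes are a smooth field around
#' `slope_td_mean`, and the ASD-TD difference magnitude is bounded away from
#' zero (`delta_min`) so every vertex carries a recoverable sign.
#'
#' @param mesh A `surface_mesh`.
#' @param negative_fraction Fraction of vertices with `slope_asd < slope_td`
#'   (default 0.81).
#' @param patch_spec Optional list of `list(seed_vertex, radius_mm, sign)`
#'   entries; `sign = -1` forces a steeper ASD decrease inside the patch,
#'   `+1` the reverse.
#' @param seed RNG seed.
#' @param slope_td_mean,slope_td_sd Mean and spatial SD of the TD slope
#'   field (contrast-ratio units/year).
#' @param delta_min,delta_scale Minimum and scale of the ASD-TD slope
#'   difference magnitude.
#' @param field_fwhm_mm FWHM of the smoothing applied to the underlying
#'   random fields.
#' @return List of class `effect_template`: `slope_td`, `slope_asd`
#'   (vectors), `negative_fraction` (achieved), `patch_vertices`.
#' @export
make_effect_template <- function(mesh, negative_fraction = 0.81,
                                 patch_spec = NULL, seed = 1,
                                 slope_td_mean = -0.004,
                                 slope_td_sd = 0.0015,
                                 delta_min = 0.007,
                                 delta_scale = 0.006,
                                 field_fwhm_mm = 25) {
  if (negative_fraction < 0 || negative_fraction > 1) {
    stop("spec error: negative_fraction must be in [0, 1]")
  }
  v <- nrow(mesh$coords)
  set.seed(seed)
  smooth_field <- function() {
    f <- smooth_on_mesh(stats::rnorm(v), mesh, field_fwhm_mm)
    s <- stats::sd(f)
    if (s == 0) f else (f - mean(f)) / s
  }
  slope_td <- slope_td_mean + slope_td_sd * smooth_field()
  delta <- delta_min + delta_scale * abs(smooth_field())
  # sign assignment: patches first (forced), then fill to the target count
  sign_v <- rep(NA_integer_, v)
  patch_vertices <- integer(0)
  for (p in patch_spec) {
    verts <- mesh_patch(mesh, p$seed_vertex, p$radius_mm)
    sign_v[verts] <- as.integer(p$sign)
    patch_vertices <- union(patch_vertices, verts)
  }
  target_neg <- round(negative_fraction * v)
  forced_neg <- sum(sign_v == -1L, na.rm = TRUE)
  forced_pos <- sum(sign_v == 1L, na.rm = TRUE)
  if (forced_pos > v - target_neg || forced_neg > target_neg) {
    stop("spec error: patches cover more vertices than the sign budget ",
         "allows for negative_fraction = ", negative_fraction)
  }
  free <- which(is.na(sign_v))
  u <- smooth_field()[free]
  need_neg <- target_neg - forced_neg
  neg_free <- free[order(u)][seq_len(need_neg)]
  sign_v[is.na(sign_v)] <- 1L
  sign_v[neg_free] <- -1L
  slope_asd <- slope_td + sign_v * delta
  structure(list(slope_td = slope_td,
                 slope_asd = slope_asd,
                 negative_fraction = mean(slope_asd < slope_td),
                 patch_vertices = patch_vertices),
            class = "effect_template")
}

# Per-subject vertex-wise contrast under the linear trajectory model;
# slope_dev is a per-row scalar deviation added to the group slope at every
# vertex (inter-subject trajectory heterogeneity)
wgc_rows <- function(ages, dx, slope_td, slope_asd, age_ref, base,
                     offsets, slope_dev, noise_sd) {
  v <- length(slope_td)
  n <- length(ages)
  age_ref <- rep_len(age_ref, n)
  slopes <- rbind(ASD = slope_asd, TD = slope_td)
  out <- matrix(0, n, v)
  for (i in seq_len(n)) {
    out[i, ] <- base +
      (slopes[dx[i], ] + slope_dev[i]) * (ages[i] - age_ref[i]) + offsets[i] +
      stats::rnorm(v, 0, noise_sd)
  }
  out
}

#' Simulate a cross-sectional cohort with planted age slopes
#'
#' Each subject's vertex-wise contrast follows
#' `WGC_v = baseline + slope_dx,v * (age - age_ref) + site_offset +
#' scanner_offset + subject_offset + N(0, noise_sd)`, with per-site group
#' sizes and age distributions from the spec's site table.
#'
#' @param spec A `sim_spec`.
#' @param template An `effect_template` with `n_vertices`-long slope maps.
#' @param seed RNG seed.
#' @return List with `cohort` (data.frame), `wgc` (subjects x vertices
#'   matrix in cohort order) and `provenance` (planted offsets, `age_ref`,
#'   seed) for planted-parameter recovery checks.
#' @export
simulate_cross_sectional <- function(spec, template, seed = 1) {
  stopifnot(inherits(spec, "sim_spec"), inherits(template, "effect_template"))
  set.seed(seed)
  st <- spec$site_table
  rows <- list()
  for (i in seq_len(nrow(st))) {
    for (dx in c("ASD", "TD")) {
      n <- if (dx == "ASD") st$n_asd[i] else st$n_td[i]
      mu <- if (dx == "ASD") st$age_mean_asd[i] else st$age_mean_td[i]
      sd_ <- if (dx == "ASD") st$age_sd_asd[i] else st$age_sd_td[i]
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sprintf("%s_%s_%02d", st$site[i], dx, seq_len(n)),
        dx = dx, site = st$site[i], scanner = st$scanner[i], sex = "M",
        timepoint = "single",
        age = pmax(4, stats::rnorm(n, mu, sd_)),
        stringsAsFactors = FALSE)
    }
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  age_ref <- if (is.null(spec$age_ref)) mean(cohort$age) else spec$age_ref
  if (identical(spec$anchor, "cell")) {
    cell <- paste(cohort$site, cohort$dx)
    age_ref <- stats::ave(cohort$age, cell)   # per-row cell mean age
  }
  sites <- unique(cohort$site)
  scanners <- unique(cohort$scanner)
  site_off <- stats::setNames(stats::rnorm(length(sites), 0,
                                           spec$site_offset_sd), sites)
  scan_off <- stats::setNames(stats::rnorm(length(scanners), 0,
                                           spec$scanner_offset_sd), scanners)
  subj_off <- stats::rnorm(nrow(cohort), 0, spec$subject_offset_sd)
  slope_dev <- stats::rnorm(nrow(cohort), 0, spec$slope_subject_sd)
  offsets <- site_off[cohort$site] + scan_off[cohort$scanner] + subj_off
  wgc <- wgc_rows(cohort$age, cohort$dx, template$slope_td,
                  template$slope_asd, age_ref, spec$baseline_wgc_mean,
                  offsets, slope_dev, spec$noise_sd)
  rownames(wgc) <- cohort$subject_id
  list(cohort = validate_cohort(cohort), wgc = wgc,
       provenance = list(age_ref = age_ref, site_offsets = site_off,
                         scanner_offsets = scan_off,
                         subject_offsets = subj_off,
                         slope_deviations = slope_dev, seed = seed))
}

#' Simulate a longitudinal cohort (two scans per subject)
#'
#' Subjects follow the same linear trajectory model as the cross-sectional
#' generator; the follow-up scan is generated from the same per-subject
#' trajectory (same offsets) plus independent measurement noise, at age
#' `baseline + lngt_interval`.
#'
#' @inheritParams simulate_cross_sectional
#' @return List with `cohort` (two rows per subject: baseline then followup,
#'   grouped by subject), `wgc` (scans x vertices, cohort order) and
#'   `provenance`.
#' @export
simulate_longitudinal <- function(spec, template, seed = 1) {
  stopifnot(inherits(spec, "sim_spec"), inherits(template, "effect_template"))
  set.seed(seed)
  n_asd <- spec$lngt_n_asd
  n_td <- spec$lngt_n_td
  dx <- c(rep("ASD", n_asd), rep("TD", n_td))
  # alternate subjects between the two longitudinal sites
  site <- spec$lngt_sites[(seq_along(dx) - 1L) %% 2L + 1L]
  ids <- sprintf("L%s_%02d", dx, c(seq_len(n_asd), seq_len(n_td)))
  age_bsl <- pmax(4, stats::rnorm(length(dx), spec$lngt_age_mean,
                                  spec$lngt_age_sd))
  age_flp <- age_bsl + spec$lngt_interval
  cohort <- data.frame(
    subject_id = rep(ids, each = 2L),
    dx = rep(dx, each = 2L),
    site = rep(site, each = 2L),
    scanner = "Siemens",
    sex = "M",
    timepoint = rep(c("baseline", "followup"), length(dx)),
    age = as.numeric(rbind(age_bsl, age_flp)),
    stringsAsFactors = FALSE)
  age_ref <- if (is.null(spec$age_ref)) mean(cohort$age) else spec$age_ref
  site_off <- stats::setNames(stats::rnorm(length(spec$lngt_sites), 0,
                                           spec$site_offset_sd),
                              spec$lngt_sites)
  subj_off <- stats::setNames(stats::rnorm(length(ids), 0,
                                           spec$subject_offset_sd), ids)
  slope_dev <- stats::setNames(stats::rnorm(length(ids), 0,
                                            spec$slope_subject_sd), ids)
  offsets <- site_off[cohort$site] + subj_off[cohort$subject_id]
  wgc <- wgc_rows(cohort$age, cohort$dx, template$slope_td,
                  template$slope_asd, age_ref, spec$baseline_wgc_mean,
                  offsets, slope_dev[cohort$subject_id], spec$noise_sd)
  rownames(wgc) <- paste(cohort$subject_id, cohort$timepoint, sep = ":")
  list(cohort = validate_cohort(cohort), wgc = wgc,
       provenance = list(age_ref = age_ref, site_offsets = site_off,
                         subject_offsets = subj_off,
                         slope_deviations = slope_dev, seed = seed))
}

#' Attach simulated ADOS social+communication totals
#'
#' Gives every ASD subject an integer ADOS social+communication total whose
#' correlation with the natural log of the (positive) pattern-expression
#' values approximates `target_r`; subjects with non-positive expression
#' receive scores from the marginal distribution. TD subjects receive no
#' score. Totals are clipped to the 0-22 range.
#'
#' @param cohort Cohort `data.frame` (one row per subject).
#' @param expression Per-subject scalar expression of the planted pattern
#'   (e.g. brain scores), aligned with cohort rows.
#' @param target_r Target Pearson correlation in (0, 1).
#' @param seed RNG seed.
#' @param ados_mean,ados_sd Marginal location/scale of the totals.
#' @return The cohort with `ados_social_comm_total` and `ados_module`
#'   columns (NA for TD).
#' @export
simulate_ados <- function(cohort, expression, target_r = 0.42, seed = 1,
                          ados_mean = 10, ados_sd = 4) {
  stopifnot(nrow(cohort) == length(expression))
  if (target_r <= 0 || target_r >= 1) {
    stop("value error: target_r must be in (0, 1)")
  }
  asd <- which(cohort$dx == "ASD")
  if (length(asd) == 0L) stop("value error: no ASD subjects in cohort")
  set.seed(seed)
  z <- rep(0, length(asd))
  pos <- expression[asd] > 0 & !is.na(expression[asd])
  if (sum(pos) >= 2L) {
    lg <- log(expression[asd][pos])
    z[pos] <- (lg - mean(lg)) / stats::sd(lg)
  }
  latent <- target_r * z +
    sqrt(1 - target_r^2) * stats::rnorm(length(asd))
  total <- as.integer(pmin(22, pmax(0, round(ados_mean + ados_sd * latent))))
  cohort$ados_social_comm_total <- NA_integer_
  cohort$ados_social_comm_total[asd] <- total
  cohort$ados_module <- NA_integer_
  cohort$ados_module[asd] <- ifelse(cohort$age[asd] >= 16, 4L, 3L)
  cohort
}

#' Simulate a motion-contaminated toy volume
#'
#' A smooth base volume (linear ramp plus a broad quadratic bowl) plus a
#' sinusoidal ripple of the given amplitude along the first axis, emulating
#' the ringing artefacts produced by head motion, together with a central
#' white-matter block mask.
#'
#' @param shape Integer triple, each >= 16.
#' @param ringing_amplitude Ripple amplitude (intensity units, >= 0).
#' @param seed RNG seed (adds reproducible voxel noise; set `noise_sd = 0`
#'   for a purely deterministic volume).
#' @param noise_sd SD of additive voxel noise. Default 0.
#' @param ripple_cycles Number of ripple cycles across the volume. Default 6.
#' @return List with `intensities` (3-D array) and `wm_mask` (3-D logical,
#'   central block).
#' @export
simulate_motion_volume <- function(shape, ringing_amplitude, seed = 1,
                                   noise_sd = 0, ripple_cycles = 6) {
  if (length(shape) != 3L || any(shape < 16)) {
    stop("value error: shape must have 3 axes, each >= 16")
  }
  if (ringing_amplitude < 0) stop("value error: amplitude must be >= 0")
  set.seed(seed)
  xs <- seq(0, 1, length.out = shape[1])
  ys <- seq(0, 1, length.out = shape[2])
  zs <- seq(0, 1, length.out = shape[3])
  base <- outer(xs, ys, function(x, y) 100 + 20 * x - 15 * (y - 0.5)^2)
  vol <- array(rep(base, shape[3]), dim = shape)
  zmod <- rep(1 - 0.1 * (zs - 0.5)^2, each = shape[1] * shape[2])
  vol <- vol * array(zmod, dim = shape)
  ripple <- ringing_amplitude * sin(2 * pi * ripple_cycles * xs)
  vol <- vol + array(ripple, dim = shape)
  if (noise_sd > 0) vol <- vol + array(stats::rnorm(prod(shape), 0, noise_sd),
                                       dim = shape)
  mask <- array(FALSE, dim = shape)
  lo <- pmax(1, floor(shape / 4))
  hi <- pmin(shape, ceiling(3 * shape / 4))
  mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  list(intensities = vol, wm_mask = mask)
}
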