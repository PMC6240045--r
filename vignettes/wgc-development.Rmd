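---
title: "Modelling developmental change in cortical white-gray contrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling developmental change in cortical white-gray contrast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measure and the question

White-gray contrast (WGC) is the ratio of T1-weighted MRI intensity sampled
1 mm inside the white-matter surface to the intensity 1 mm outside it,
evaluated at every vertex of a common cortical surface template. It reflects
the sharpness of the tissue transition at the white-gray boundary and is
sensitive to myelination and microstructural change. This package analyses
not the contrast itself but its *rate of change with age*, comparing autism
spectrum disorder (ASD) with typical development (TD) in two complementary
cohort designs, and then asks whether the pattern of change predicts
diagnosis and symptom severity.

`compute_wgc()` takes already-sampled sub-/supra-white intensity pairs; the
geometric machinery that produces those samples (surface extraction,
distance maps, gradient-field displacement) belongs to an upstream surface
pipeline and is out of scope here. Surface smoothing (`smooth_on_mesh()`) is
applied to the sampled intensities before the ratio is formed.

## The angle metrics

For a subject scanned twice, the per-vertex rate of change is summarised as
an angle,

$$\alpha^{lngt}_i = \arctan\!\left(
  \frac{\mathrm{WGC}^{flp}_i - \mathrm{WGC}^{bsl}_i}
       {\mathrm{age}^{flp}_i - \mathrm{age}^{bsl}_i}\right),$$

the arctangent of annual contrast change (`longitudinal_angle()`). The
arctangent bounds the statistic in $(-\pi/2, \pi/2)$, which tames the heavy
tails that raw ratios would have.

The cross-sectional analogue replaces the within-subject difference by mean
pairwise differences against all same-diagnosis peers scanned at the same
acquisition site:

$$\alpha^{crsc}_i = \arctan\!\left(
  \frac{\sum_{j \ne i}(\mathrm{WGC}_i - \mathrm{WGC}_j)}
       {\sum_{j \ne i}(\mathrm{age}_i - \mathrm{age}_j)}\right).$$

Because the differences are formed strictly within a site, additive site
offsets cancel: the metric is a per-subject developmental trajectory largely
free of site effects (`cross_sectional_angle()`).

**Near-zero denominators.** A subject whose age coincides with the mean age
of its peers has a vanishing denominator. The exact-zero event has measure
zero for continuous ages, but the estimator's variance diverges as the
denominator shrinks, and the arctangent then saturates at $\pm\pi/2$ with an
arbitrary sign — an artefact whose size does not shrink with the noise
level. We therefore treat "zero denominator" with a numerical tolerance: a
subject within `min_age_gap` (default 0.1 years) of its peer mean age is
masked across all vertices, with a warning naming the cell, and
`drop_masked_rows()` removes such subjects (typically 2-5% of a cohort)
before group analysis. This is the one place where the implementation
deliberately extends the letter of the estimator's definition; without it,
single near-tie subjects randomly destroyed the group-level analysis in a
third of simulated replicates.

**Standardisation.** For the predictive models both angle samples are
z-scored (`standardize_angles()`), each vertex column across subjects,
within each sample separately, using the sample (n-1) standard deviation;
constant columns map to zero. Per-vertex (rather than pooled)
standardisation is the default because the classifier consumes per-vertex
distributions; the pooled variant is available via `by = "pooled"`.

## Task PLS, bootstrap ratios and the conjunction

Group-level structure is extracted with mean-centred task partial least
squares (`mean_centered_pls()`): subjects are grouped by diagnosis crossed
with site (longitudinal) or scanner manufacturer (cross-sectional), the
group-mean matrix is centred by the unweighted grand mean of group means,
and the SVD $USW'$ yields latent variables (LVs) pairing group contrasts
(design scores $US$) with cortical patterns (saliences $W$). Significance
uses label permutation with group sizes preserved,
$p_k = (1 + \#\{S^{perm}_k \ge S_k\})/(1 + n_{perm})$; reliability uses
within-group bootstrap resampling with LV re-alignment by maximal absolute
salience correlation (sign included), giving bootstrap ratios
$\mathrm{BSR} = W / \mathrm{SE}_{boot}$ and percentile intervals for the
design scores. Defaults are 1000 permutations and 500 bootstrap resamples;
the analysis scripts use 500/200 and the acceptance checks 100 bootstraps,
sizes at which the BSR sign pattern - all that the conjunction consumes -
is stable.

Brain scores project each (grand-mean-centred) subject onto an LV's
pattern. Following the procedure this pipeline implements, the projection
uses the BSR map, i.e. a reliability-weighted pattern, rather than the raw
saliences; `projection = "salience"` provides the classical variant.

The **conjunction analysis** (`conjunction()`) classifies every vertex by
the signs of the cross-sectional and longitudinal BSR maps of the
*diagnosis LV* — the LV whose design scores correlate most with the
ASD-vs-TD contrast, oriented so ASD design scores are positive
(`diagnosis_bsr()`). Under the study conditions this is LV1 in both
samples, but noisy replicates can promote a site- or age-dispersion LV to
first place, so selection by contrast is used rather than a hard-coded
index. A vertex with BSR exactly zero counts as "decrease"; on continuous
data this affects a measure-zero set.

## The diagnostic model

Diagnosis is predicted in a Bayesian setting,
$P(dx \mid \alpha) \propto P(\alpha \mid dx)\, P(dx)$, trained on the
cross-sectional sample and tested on the longitudinal one:

* **Likelihood** (`fit_ev_likelihood()`): a Gumbel (extreme-value) density
  $\sigma^{-1} e^{z} e^{-e^{z}}$ with $z = (\pm\alpha - \mu)/\sigma$, fitted
  by maximum likelihood under both orientations of $\alpha$; the
  orientation whose fitted density correlates best (Pearson) with the
  empirical histogram is kept. Histograms use Freedman-Diaconis bins —
  scale-adaptive and deterministic. Each subject enters as the mean of its
  standardised angles over the analysis region (whole cortex or an ROI);
  averaging per-vertex posteriors instead is available via
  `reduce = "posterior"`.
* **Prior** (`prior_probability()`): a sigmoid informed by the PLS
  evidence, $P(dx) = [1 + \exp(\pm\, x\, \mathrm{BSR}/\mathrm{BSR_{max}})]^{-1}$,
  positive sign for TD and negative for ASD, so the two priors are exactly
  complementary. The region's evidence is the mean LV1 BSR over its
  vertices; $\mathrm{BSR_{max}}$ is the cortex-wide maximum of $|BSR|$. The
  prior is evaluated at the test subject's standardised angle clipped into
  the training angle range (its stated domain).
* **Posterior** (`posterior_dx()`): computed in log space and normalised by
  log-sum-exp, so underflow can never produce 0/0; the pair sums to 1 to
  machine precision. An exact 0.5/0.5 tie predicts TD — conservative
  toward the no-disorder label.

The likelihood orientation and the prior sign are selected independently
(fit quality for the former, diagnosis for the latter), as the two rules
are stated independently. Sensitivity is the fraction of ASD subjects
predicted ASD, specificity the fraction of TD predicted TD; a class absent
from the test set leaves its metric missing rather than zero
(`confusion_metrics()`). `vertexwise_maps()` repeats the model at single
vertices and thresholds both maps at 50% to flag jointly informative
cortex.

## Severity

ADOS social+communication totals are made comparable across modules and
ages by a calibrated-severity lookup. The published calibration tables are
not redistributable, so the package bundles only a clearly-labelled
synthetic placeholder (`inst/extdata/synthetic_severity_table.tsv`,
implementing severity = total clipped to 1-10) and accepts user tables in
the same TSV schema; an uncovered (module, age, total) cell yields an
explicit missing value with a reason, never a silent default.

Brain-score/severity coupling is quantified by the Pearson correlation of
the score with the natural log of the *positive part* of the brain scores
(`correlate_log_brainscore()`). Severity prediction uses an ordinary
least-squares GLM of severity on brain score plus a windowed residual
correction: the prediction at a new brain score adds the mean training
residual within an open window of half-width $w = 0.05 \times \max
\mathrm{BrSc}$ around it; an empty window contributes zero, falling back to
the plain GLM (the windowed form leaves that case undefined). As the window
grows the correction tends to the training-residual mean, zero, recovering
the GLM; as it shrinks, training points recover their own scores exactly.

## Motion proxy

Head motion produces ringing-like artefacts that raise the variance of the
intensity gradient. The proxy (`motion_proxy()`) is the standard deviation
of the central-difference gradient magnitude (scaled by voxel size) within
the white-matter mask core, obtained by 6-connected morphological erosion
(default depth 2 — "core" has no published depth). It is zero for constant
and linear-ramp volumes, invariant to additive intensity shifts, linear in
multiplicative gain, and strictly increasing in the ringing amplitude of
the toy volumes. Group comparisons use Welch's t-test (the unequal-variance
default for "two-sample t-test"). The gradient is pooled as a magnitude;
per-axis pooling is not exposed.

## The synthetic cohort generator

Every downstream stage is testable without imaging data because the
generator (`sim_spec()`, `make_effect_template()`,
`simulate_cross_sectional()`, `simulate_longitudinal()`) emulates the study
conditions:

* **Cohort structure**: a 14-site cross-sectional table (359 male subjects,
  146 ASD, per-site ages as mean ± sd, two scanner manufacturers), and a
  longitudinal sample of 12 ASD + 9 TD subjects, two scans each, baseline
  age 12.75 ± 1.8 years and a fixed 2.31-year interval, split over two
  sites.
* **Trajectories**: per-vertex linear age trajectories,
  $\mathrm{WGC} = b + (s_{dx,v} + \eta_i)(a - a_{ref}) + \text{offsets} +
  \varepsilon$, with additive site and scanner offsets drawn once per
  simulation, a per-subject intercept, a per-subject slope deviation
  $\eta_i$ (inter-subject trajectory heterogeneity), and i.i.d. vertex
  noise.
* **Effect template**: TD slopes are a smooth field around -0.004
  contrast-ratio units/year; the ASD-TD difference has magnitude bounded
  away from zero (0.007-0.02 units/year) and a spatially smooth sign
  pattern with a configurable mutually-negative fraction (default 0.81),
  plus optional connected "primary-sensory-like" reversal patches grown by
  geodesic distance (breadth-first over mesh edges).
* **Anchoring**: each cross-sectional (site, diagnosis) cell's trajectory
  is anchored at the cell's own mean age. Anchoring everything at one
  common age would make differing slopes mechanically induce *static*
  contrast differences between groups, contradicting the empirical control
  that single-timepoint contrast carries no diagnostic signal; both angle
  metrics cancel intercepts, so the choice does not touch the planted
  dynamic truth. `anchor = "cohort"` restores common-age anchoring.
* **Behaviour**: ASD subjects receive integer ADOS social+communication
  totals (clipped to 0-22, a plausible range for these totals) correlated
  at a target level (default r = 0.42) with the log of their positive
  pattern expression; TD subjects receive none.
* **Motion volumes**: smooth base volumes plus a sinusoidal ripple of
  configurable amplitude along one axis and a central white-matter block
  mask.

No effect magnitudes are published for either group, so the defaults are
synthetic-only choices, calibrated once in pilot runs so that the planted
effect is recoverable by the downstream analyses at desk scale (noise sd
0.005, subject intercept sd 0.005, slope heterogeneity sd 0.001, site
offset sd 0.02, scanner offset sd 0.01) and then frozen. What passing tests
show is therefore that the *pipeline* recovers what was planted under
realistic cohort structure — not that real MRI data behave this way. Real
data add surface-registration error, spatially correlated noise, nonlinear
trajectories (the model here is strictly linear in age), pubertal effects,
heteroscedastic sites and QC-driven attrition, none of which the generator
emulates.

## The surface template

The template mesh (`make_mesh()`) is a deterministic triangulated sphere —
latitude rings with counts proportional to ring circumference, stitched by
a zig-zag triangulation — with exactly the requested number of vertices and
near-uniform spacing (mean edge length within a few percent of the
hexagonal-packing estimate), at a default 70 mm radius so that
millimetre-scale smoothing kernels are meaningful. Vertex indices are
1-based throughout, R's native convention. Smoothing approximates a
Gaussian kernel by iterated symmetric edge diffusion:
`ceil(2 (sigma/h)^2)` steps with the per-step weight solved so the
accumulated kernel variance matches `sigma^2` (using that a 2-D isotropic
Gaussian has expected squared radius `2 sigma^2`); the step count doubles
until the per-vertex outflow is stable. The operator is symmetric, so map
totals are preserved exactly; kernels below the mesh resolution return the
input unchanged with a warning.

## Problem sizes and reproducibility

The analysis scripts and acceptance checks run at 300 template vertices,
500 permutations and 100-200 bootstrap resamples, with 20 replicates for
the conjunction-recovery summary and 50 replicates for the classifier
calibration; at these sizes the whole workflow reproduces stably in a few
minutes on one core. Every stochastic step takes an explicit seed, and
identical spec + seed give bit-identical outputs.

```{r example}
library(wgcdev)
mesh <- make_mesh(300)
spec <- sim_spec(n_vertices = 300)
rep1 <- conjunction_replicate(mesh, spec, seed = 1)
rep1$fractions
```

## Known limitations

* The cross-sectional angle remains heavy-tailed for subjects with small
  (but unmasked) peer age gaps; the masking tolerance trades a small,
  reported loss of subjects against estimator stability.
* The Gumbel orientation choice is by histogram fit quality; for nearly
  symmetric samples it is close to arbitrary, and the two class likelihoods
  may be fitted with opposite orientations.
* The severity lookup bundled with the package is synthetic; scientific use
  requires a real calibration table in the documented schema.
* The generator's linear-trajectory, additive-offset world is the model's
  best case; none of the acceptance results should be read as estimates of
  real-data performance.
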