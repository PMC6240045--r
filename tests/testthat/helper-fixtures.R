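# Small fixture builders shared across test files. Everything is generated
# in code; nothing is read from disk except files the tests write themselves.

tiny_cohort <- function(n = 3, site = "S1", dx = "TD", scanner = "Siemens",
                        ages = NULL) {
  if (is.null(ages)) ages <- seq(10, by = 2, length.out = n)
  data.frame(
    subject_id = sprintf("%s_%s_%02d", site, dx, seq_len(n)),
    dx = dx, site = site, scanner = scanner, sex = "M",
    timepoint = "single", age = ages,
    stringsAsFactors = FALSE)
}

# cohort with two (site, dx) cells suitable for cross-sectional angles
two_cell_cohort <- function(n_per_cell = 5, seed = 1) {
  set.seed(seed)
  rbind(
    tiny_cohort(n_per_cell, site = "S1", dx = "ASD",
                ages = 10 + seq_len(n_per_cell) * 1.5),
    tiny_cohort(n_per_cell, site = "S1", dx = "TD",
                ages = 9 + seq_len(n_per_cell) * 1.7))
}

random_matrix <- function(cohort, v = 6, seed = 1, mean = 1.25, sd = 0.05) {
  set.seed(seed)
  m <- matrix(rnorm(nrow(cohort) * v, mean, sd), nrow(cohort), v)
  rownames(m) <- cohort$subject_id
  m
}

# groups-by-design toy with a strong planted group effect on some vertices
planted_group_data <- function(n_per_group = 6, v = 12, effect = 1,
                               effect_vertices = 1:4, noise = 0.05,
                               seed = 1) {
  set.seed(seed)
  g <- factor(rep(c("ASD_A", "TD_A", "ASD_B", "TD_B"), each = n_per_group))
  x <- matrix(rnorm(length(g) * v, 0, noise), length(g), v)
  asd <- startsWith(as.character(g), "ASD")
  x[asd, effect_vertices] <- x[asd, effect_vertices] - effect
  list(x = x, groups = g)
}
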