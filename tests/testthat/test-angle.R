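test_that("longitudinal angle is the arctangent of the annual change", {
  expect_equal(longitudinal_angle(c(1.2, 1.3), c(1.2, 1.3), 10, 12),
               c(0, 0))
  expect_equal(longitudinal_angle(1, 3, 10, 12), pi / 4)
  expect_equal(longitudinal_angle(1.2, 1.22, 10, 12), atan(0.01),
               tolerance = 1e-12)
  expect_error(longitudinal_angle(1, 2, 12, 12), "age_flp")
  expect_error(longitudinal_angle(1, 2, 12, 10), "age_flp")
})

test_that("cross-sectional angle matches the hand-computed 3-subject case", {
  coh <- tiny_cohort(3, ages = c(10, 12, 14))
  wgc <- matrix(c(1.2, 1.3, 1.4), 3, 1)
  a <- suppressWarnings(cross_sectional_angle(wgc, coh))
  # subject 1: num = (1.2-1.3)+(1.2-1.4) = -0.3, den = (10-12)+(10-14) = -6
  expect_equal(a[1, 1], atan(0.05), tolerance = 1e-9)
  # subject 2 sits exactly at the peer mean age: masked
  expect_true(is.na(a[2, 1]))
  expect_equal(a[3, 1], atan(0.3 / 6), tolerance = 1e-9)
})

test_that("identical contrast maps give zero angles for every subject", {
  coh <- two_cell_cohort(5)
  wgc <- matrix(1.3, nrow(coh), 4)
  a <- suppressWarnings(cross_sectional_angle(wgc, coh))
  expect_true(all(a == 0, na.rm = TRUE))
})

test_that("a two-subject cell reduces to the longitudinal formula", {
  coh <- tiny_cohort(2, ages = c(10, 13))
  set.seed(3)
  wgc <- matrix(rnorm(8, 1.25, 0.05), 2, 4)
  a <- suppressWarnings(cross_sectional_angle(wgc, coh, warn_below = 2))
  ref <- longitudinal_angle(wgc[1, ], wgc[2, ], 10, 13)
  # subject 2 is the "follow-up": its angle equals the pair's rate of change
  expect_equal(a[2, ], ref, tolerance = 1e-12)
  # both subjects carry the same pairwise rate
  expect_equal(a[1, ], a[2, ], tolerance = 1e-12)
  # antisymmetry: exchanging the two subjects' contrast maps (ages fixed)
  # flips the sign of each subject's angle
  a_swapped <- suppressWarnings(
    cross_sectional_angle(wgc[c(2, 1), ], coh, warn_below = 2))
  expect_equal(a_swapped, -a, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("peers never cross site or diagnosis boundaries", {
  coh <- two_cell_cohort(5)
  set.seed(8)
  wgc <- random_matrix(coh, v = 3)
  a1 <- suppressWarnings(cross_sectional_angle(wgc, coh))
  # perturbing the other cell leaves this cell's angles untouched
  wgc2 <- wgc
  wgc2[coh$dx == "TD", ] <- wgc2[coh$dx == "TD", ] + 100
  a2 <- suppressWarnings(cross_sectional_angle(wgc2, coh))
  expect_equal(a1[coh$dx == "ASD", ], a2[coh$dx == "ASD", ])
})

test_that("angles are bounded and monotone in own contrast", {
  set.seed(11)
  for (rep in 1:5) {
    coh <- two_cell_cohort(6, seed = rep)
    wgc <- random_matrix(coh, v = 5, seed = rep)
    a <- suppressWarnings(cross_sectional_angle(wgc, coh))
    expect_true(all(abs(a) < pi / 2, na.rm = TRUE))
  }
  # monotonicity at a positive denominator: raising own WGC raises the angle
  coh <- tiny_cohort(3, ages = c(10, 12, 17))
  wgc <- matrix(c(1.2, 1.3, 1.4), 3, 1)
  a_lo <- suppressWarnings(cross_sectional_angle(wgc, coh))[3, 1]
  wgc[3, 1] <- wgc[3, 1] + 0.05
  a_hi <- suppressWarnings(cross_sectional_angle(wgc, coh))[3, 1]
  expect_gt(a_hi, a_lo)
})

test_that("near-zero age denominators are masked, singleton cells error", {
  coh <- tiny_cohort(3, ages = c(10, 12, 14))  # subject 2 at the peer mean
  wgc <- matrix(rnorm(6), 3, 2)
  expect_warning(a <- cross_sectional_angle(wgc, coh, warn_below = 2),
                 "masked")
  expect_true(all(is.na(a[2, ])))
  expect_true(all(!is.na(a[-2, ])))
  dropped <- drop_masked_rows(a, coh)
  expect_equal(dropped$n_dropped, 1L)
  expect_equal(nrow(dropped$angles), 2L)

  single <- rbind(tiny_cohort(4, dx = "TD"), tiny_cohort(1, dx = "ASD"))
  expect_error(
    suppressWarnings(cross_sectional_angle(matrix(0, 5, 2), single)),
    "S1:ASD")
})

test_that("standardisation gives zero-mean unit-variance vertex columns", {
  expect_equal(standardize_angles(matrix(c(1, 2, 3), 3, 1))[, 1],
               c(-1, 0, 1))
  expect_equal(standardize_angles(matrix(5, 4, 2)),
               matrix(0, 4, 2), ignore_attr = TRUE)
  set.seed(5)
  m <- matrix(rnorm(60, 3, 2), 12, 5)
  z <- standardize_angles(m)
  expect_equal(colMeans(z), rep(0, 5), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), rep(1, 5), tolerance = 1e-12)
  zp <- standardize_angles(m, by = "pooled")
  expect_equal(mean(zp), 0, tolerance = 1e-12)
  expect_equal(sd(as.numeric(zp)), 1, tolerance = 1e-12)
  expect_error(standardize_angles(m[1, , drop = FALSE]), "2 subjects")
})
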