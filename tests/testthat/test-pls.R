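test_that("group means with no between-group covariance give a zero LV", {
  set.seed(1)
  base <- matrix(rnorm(4 * 6), 4, 6)
  x <- rbind(base, base)  # two groups with identical rows
  g <- factor(rep(c("A", "B"), each = 4))
  fit <- mean_centered_pls(x, g)
  expect_lt(fit$singular_values[1], 1e-12)
  expect_true(fit$degenerate)
})

test_that("singular values match a brute-force SVD oracle on a 4-group toy", {
  # hand-built group means: 4 groups x 2 vertices
  m <- rbind(c(1.0, 0.0), c(-1.0, 0.5), c(0.5, -0.5), c(0.0, 1.0))
  x <- m[rep(1:4, each = 3), ] + 0  # three identical subjects per group
  g <- factor(rep(c("g1", "g2", "g3", "g4"), each = 3))
  fit <- mean_centered_pls(x, g)
  oracle <- svd(sweep(m, 2, colMeans(m)))   # direct SVD of the centred means
  expect_equal(fit$singular_values, oracle$d, tolerance = 1e-10)
  expect_equal(sum(fit$covariance_explained), 1, tolerance = 1e-9)
  # reconstruction: U S W' reproduces the centred group-mean matrix
  rec <- fit$design_u %*% diag(fit$singular_values) %*% t(fit$saliences)
  expect_equal(rec, unname(sweep(m, 2, colMeans(m))), tolerance = 1e-8)
  expect_no_error(mean_centered_pls(x[g != "g1", ], droplevels(g[g != "g1"])))
  expect_error(mean_centered_pls(x, factor(rep("g1", 12))), "2 groups")
})

test_that("permutation p-values detect a strong planted effect", {
  d <- planted_group_data(effect = 2, noise = 0.01)
  p <- pls_permutation(d$x, d$groups, n_perm = 99, seed = 3)
  expect_equal(p[1], 1 / 100)
  expect_identical(p, pls_permutation(d$x, d$groups, n_perm = 99, seed = 3))
})

test_that("bootstrap ratios are reliable inside the planted vertex set", {
  d <- planted_group_data(n_per_group = 10, v = 30, effect = 1,
                          effect_vertices = 1:10, noise = 0.2, seed = 5)
  boot <- pls_bootstrap(d$x, d$groups, n_boot = 100, seed = 5)
  expect_identical(boot$bsr,
                   pls_bootstrap(d$x, d$groups, n_boot = 100, seed = 5)$bsr)
  inside <- mean(abs(boot$bsr[1:10, 1]))
  outside <- mean(abs(boot$bsr[11:30, 1]))
  expect_gt(inside, outside)
  # BSR sign equals the salience sign wherever the SE is positive
  fit <- mean_centered_pls(d$x, d$groups)
  ok <- boot$salience_se > 0
  expect_true(all(sign(boot$bsr[ok]) == sign(fit$saliences[ok])))
  # design-score intervals bracket the observed scores for the dominant LV
  ds <- fit$design_scores[, 1]
  expect_true(all(boot$design_ci_lower[, 1] <= ds + 1e-9))
  expect_true(all(boot$design_ci_upper[, 1] >= ds - 1e-9))
})

test_that("noise-free duplicated subjects give masked (not infinite) BSR", {
  m <- rbind(c(1, 0), c(-1, 0.5), c(0.5, -0.5), c(0, 1))
  x <- m[rep(1:4, each = 3), ]
  g <- factor(rep(paste0("g", 1:4), each = 3))
  boot <- pls_bootstrap(x, g, n_boot = 20, seed = 1)
  expect_true(all(is.na(boot$bsr)))
  expect_true(all(boot$salience_se == 0))
})

test_that("brain scores are linear projections about the grand mean", {
  d <- planted_group_data(seed = 7)
  fit <- mean_centered_pls(d$x, d$groups)
  boot <- pls_bootstrap(d$x, d$groups, n_boot = 50, seed = 7)
  br <- brain_scores(d$x, fit, boot$bsr)
  # a subject lying exactly at the grand mean scores zero on every LV
  x2 <- rbind(d$x, fit$grand_mean)
  br2 <- brain_scores(x2, fit, boot$bsr)
  expect_equal(unname(br2[nrow(x2), ]), rep(0, ncol(br)), tolerance = 1e-10)
  # doubling the BSR doubles every brain score
  expect_equal(brain_scores(d$x, fit, 2 * boot$bsr), 2 * br,
               tolerance = 1e-12)
  # the ASD-like and TD-like subjects score on opposite sides
  o <- orient_lv(fit, dx_contrast(levels(d$groups)), lv = 1, bsr = boot$bsr)
  br_or <- brain_scores(d$x, o$pls, o$bsr)
  asd <- startsWith(as.character(d$groups), "ASD")
  expect_gt(mean(br_or[asd, 1]), mean(br_or[!asd, 1]))
  expect_error(brain_scores(d$x, fit, NULL, projection = "bsr"), "bsr")
  expect_silent(brain_scores(d$x, fit, projection = "salience"))
})

test_that("conjunction classifies vertex sign pairs with a negative tie rule", {
  neg <- rep(-1, 10)
  cj <- conjunction(neg, neg)
  expect_equal(cj$fractions[["both_negative"]], 1)
  a <- c(-2, -1, 1, 2, 0)
  b <- c(-1, 1, -1, 2, 1)
  cj2 <- conjunction(a, b)
  expect_equal(as.character(cj2$category),
               c("both_negative", "b_pos_a_neg", "a_pos_b_neg",
                 "both_positive", "b_pos_a_neg"))  # zero counts as negative
  expect_equal(sum(cj2$fractions), 1)
  # swapping the arguments swaps the two mixed categories
  cj3 <- conjunction(b, a)
  expect_equal(cj3$fractions[["a_pos_b_neg"]], cj2$fractions[["b_pos_a_neg"]])
  expect_equal(cj3$fractions[["b_pos_a_neg"]], cj2$fractions[["a_pos_b_neg"]])
  expect_equal(cj3$fractions[["both_negative"]],
               cj2$fractions[["both_negative"]])
})

test_that("the extreme-BSR band comparison reports a group difference", {
  d <- planted_group_data(n_per_group = 10, v = 30, effect = 1,
                          effect_vertices = 1:10, noise = 0.2, seed = 9)
  boot <- pls_bootstrap(d$x, d$groups, n_boot = 100, seed = 9)
  fit <- mean_centered_pls(d$x, d$groups)
  o <- orient_lv(fit, dx_contrast(levels(d$groups)), lv = 1, bsr = boot$bsr)
  dx <- ifelse(startsWith(as.character(d$groups), "ASD"), "ASD", "TD")
  res <- bsr_band_ttest(d$x, dx, o$bsr[, 1], end = "min")
  expect_lt(res$p.value, 0.01)
  expect_gt(attr(res, "n_vertices"), 0)
})

test_that("the diagnosis LV is found and oriented ASD-positive", {
  d <- planted_group_data(effect = 1.5, noise = 0.05, seed = 13)
  fit <- mean_centered_pls(d$x, d$groups)
  perm <- pls_permutation(d$x, d$groups, n_perm = 49, seed = 13)
  dl <- diagnostic_lv(fit, perm)
  expect_equal(dl$lv, 1L)
  expect_lt(dl$p, 0.05)
  expect_equal(dx_contrast(c("ASD_X", "TD_X", "ASD_Y", "TD_Y")),
               c(1, -1, 1, -1))
})
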