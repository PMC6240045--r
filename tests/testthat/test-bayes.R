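test_that("the extreme-value density has the stated mode and normalises", {
  for (s in c(1, -1)) {
    mu <- 0.4; sigma <- 0.7
    mode_x <- s * mu           # where (s*x - mu)/sigma = 0
    expect_equal(dgumbel_ev(mode_x, mu, sigma, s), exp(-1) / sigma,
                 tolerance = 1e-12)
    int <- integrate(dgumbel_ev, mode_x - 16 * sigma, mode_x + 16 * sigma,
                     mu = mu, sigma = sigma, orientation = s,
                     rel.tol = 1e-10)$value
    expect_equal(int, 1, tolerance = 1e-6)
  }
  expect_error(dgumbel_ev(0, 0, -1), "sigma")
})

test_that("maximum likelihood recovers the generating parameters", {
  set.seed(42)
  x <- rgumbel_ev(5000, 0.3, 0.8, orientation = 1)
  fit <- fit_ev_likelihood(x)
  expect_equal(fit$orientation, 1)
  expect_lt(abs(fit$mu - 0.3), 0.05)
  expect_lt(abs(fit$sigma - 0.8), 0.05)
  # mirrored data select the mirrored orientation with the same parameters
  fit2 <- fit_ev_likelihood(-x)
  expect_equal(fit2$orientation, -1)
  expect_lt(abs(fit2$mu - 0.3), 0.05)
  expect_error(fit_ev_likelihood(rep(1, 50)), "degenerate")
  expect_error(fit_ev_likelihood(rnorm(5)), "n >= 10")
})

test_that("likelihood bias shrinks as the sample grows", {
  bias <- vapply(c(100, 1000, 10000), function(n) {
    mus <- vapply(1:5, function(r) {
      set.seed(r)
      fit_ev_likelihood(rgumbel_ev(n, 0.3, 0.8))$mu
    }, numeric(1))
    abs(mean(mus) - 0.3)
  }, numeric(1))
  expect_lt(bias[3], bias[1] + 0.02)
  expect_lt(bias[3], 0.03)
})

test_that("sigmoid priors are complementary and follow the BSR sign", {
  expect_equal(prior_probability(0, -2, 4, "TD"), 0.5)
  expect_equal(prior_probability(0, -2, 4, "ASD"), 0.5)
  xs <- seq(-3, 3, length.out = 21)
  expect_equal(prior_probability(xs, -2, 4, "TD") +
                 prior_probability(xs, -2, 4, "ASD"),
               rep(1, 21), tolerance = 1e-14)
  # negative evidence: P(TD|x) increases with x, P(ASD|x) decreases
  ptd <- prior_probability(xs, -2, 4, "TD")
  expect_true(all(diff(ptd) > 0))
  expect_true(all(diff(prior_probability(xs, -2, 4, "ASD")) < 0))
  # positive evidence reverses the monotonicity
  expect_true(all(diff(prior_probability(xs, 2, 4, "TD")) < 0))
  expect_equal(prior_probability(1, 4, 4, "ASD"), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_error(prior_probability(0, 1, 0, "TD"), "bsr_max")
})

test_that("posteriors follow the likelihood-prior product rule", {
  ev1 <- structure(list(mu = 0, sigma = 1, orientation = 1),
                   class = "ev_params")
  # identical likelihoods and flat prior: exactly (0.5, 0.5)
  p <- posterior_dx(0.7, ev1, ev1, bsr = 0, bsr_max = 1)
  expect_equal(unname(p[1, ]), c(0.5, 0.5))
  # flat prior: posterior ratio equals the likelihood ratio
  ev_asd <- structure(list(mu = -1, sigma = 1, orientation = 1),
                      class = "ev_params")
  ev_td <- structure(list(mu = 1, sigma = 1, orientation = 1),
                     class = "ev_params")
  x <- 0.3
  p2 <- posterior_dx(x, ev_asd, ev_td, bsr = 0, bsr_max = 1)
  lr <- dgumbel_ev(x, -1, 1, 1) / dgumbel_ev(x, 1, 1, 1)
  expect_equal(unname(p2[1, "p_asd"] / p2[1, "p_td"]), lr, tolerance = 1e-12)
  # hand-built toy: explicit scalar evaluation of likelihood x prior
  bsr_max <- 3; bsr <- -3; xt <- -1
  lik_asd <- dgumbel_ev(xt, -1, 1, 1)
  lik_td <- dgumbel_ev(xt, 1, 1, 1)
  pr_asd <- 1 / (1 + exp(-1 * xt * bsr / bsr_max))
  pr_td <- 1 / (1 + exp(+1 * xt * bsr / bsr_max))
  expected <- lik_asd * pr_asd / (lik_asd * pr_asd + lik_td * pr_td)
  p3 <- posterior_dx(xt, ev_asd, ev_td, bsr = bsr, bsr_max = bsr_max)
  expect_equal(unname(p3[1, "p_asd"]), expected, tolerance = 1e-12)
  # monotone evidence: with bsr < 0, increasing x never increases p_asd
  xs <- seq(-2, 2, length.out = 41)
  ps <- posterior_dx(xs, ev1, ev1, bsr = -2, bsr_max = 2)
  expect_true(all(diff(ps[, "p_asd"]) <= 1e-12))
})

test_that("confusion metrics match their definitions", {
  truth <- c(rep("ASD", 12), rep("TD", 9))
  pred <- c(rep("ASD", 10), rep("TD", 2), rep("TD", 6), rep("ASD", 3))
  m <- confusion_metrics(truth, pred)
  expect_equal(m$sensitivity, 10 / 12, tolerance = 1e-12)
  expect_equal(m$specificity, 6 / 9, tolerance = 1e-12)
  expect_equal(m$accuracy, 16 / 21, tolerance = 1e-12)
  all_right <- confusion_metrics(truth, truth)
  expect_equal(unlist(all_right), c(sensitivity = 1, specificity = 1,
                                    accuracy = 1))
  flipped <- ifelse(truth == "ASD", "TD", "ASD")
  expect_equal(unlist(confusion_metrics(truth, flipped)),
               c(sensitivity = 0, specificity = 0, accuracy = 0))
  no_td <- confusion_metrics(rep("ASD", 5), rep("ASD", 5))
  expect_true(is.na(no_td$specificity))
  expect_equal(no_td$sensitivity, 1)
})

test_that("a region of identical vertices predicts like any single vertex", {
  set.seed(21)
  n_train <- 60
  crsc_cohort <- data.frame(
    subject_id = sprintf("c%02d", 1:n_train),
    dx = rep(c("ASD", "TD"), each = n_train / 2),
    stringsAsFactors = FALSE)
  col <- c(rnorm(n_train / 2, -0.8, 1), rnorm(n_train / 2, 0.8, 1))
  crsc_z <- matrix(col, n_train, 4)   # four identical vertex columns
  lngt_cohort <- data.frame(
    subject_id = sprintf("l%02d", 1:10),
    dx = rep(c("ASD", "TD"), each = 5), stringsAsFactors = FALSE)
  lngt_z <- matrix(c(rnorm(5, -0.8, 0.5), rnorm(5, 0.8, 0.5)), 10, 4)
  bsr <- rep(-2, 4)
  full <- train_predict(crsc_z, crsc_cohort, lngt_z, lngt_cohort, bsr)
  single <- train_predict(crsc_z, crsc_cohort, lngt_z, lngt_cohort, bsr,
                          region = 2L)
  expect_equal(full$table$posterior_asd, single$table$posterior_asd,
               tolerance = 1e-10)
  expect_identical(full$table$predicted, single$table$predicted)
  expect_error(train_predict(crsc_z, crsc_cohort, lngt_z, lngt_cohort, bsr,
                             region = integer(0)), "empty region")
  expect_error(train_predict(crsc_z, crsc_cohort, lngt_z, lngt_cohort, bsr,
                             region = 99L), "out of range")
})

test_that("single-vertex maps flag informative vertices only", {
  set.seed(31)
  n_train <- 80
  crsc_cohort <- data.frame(
    subject_id = sprintf("c%02d", 1:n_train),
    dx = rep(c("ASD", "TD"), each = n_train / 2), stringsAsFactors = FALSE)
  v <- 6
  crsc_z <- matrix(rnorm(n_train * v), n_train, v)
  # vertices 1-2 carry a clean class separation, the rest are null
  crsc_z[crsc_cohort$dx == "ASD", 1:2] <- crsc_z[crsc_cohort$dx == "ASD", 1:2] - 2
  crsc_z[crsc_cohort$dx == "TD", 1:2] <- crsc_z[crsc_cohort$dx == "TD", 1:2] + 2
  lngt_cohort <- data.frame(
    subject_id = sprintf("l%02d", 1:20),
    dx = rep(c("ASD", "TD"), each = 10), stringsAsFactors = FALSE)
  lngt_z <- matrix(rnorm(20 * v, 0, 0.5), 20, v)
  lngt_z[1:10, 1:2] <- lngt_z[1:10, 1:2] - 2
  lngt_z[11:20, 1:2] <- lngt_z[11:20, 1:2] + 2
  bsr <- c(-3, -3, rep(0.1, v - 2))
  maps <- vertexwise_maps(crsc_z, crsc_cohort, lngt_z, lngt_cohort, bsr)
  expect_true(all(maps$mutual_mask[1:2]))
  # the mask is exactly the AND of the two thresholded maps
  expect_equal(maps$mutual_mask,
               !is.na(maps$sensitivity) & !is.na(maps$specificity) &
                 maps$sensitivity > 0.5 & maps$specificity > 0.5)
  # null vertices sit near chance: sensitivity + specificity ~ 1
  null_sum <- maps$sensitivity[3:v] + maps$specificity[3:v]
  expect_lt(mean(abs(null_sum - 1)), 0.6)
})
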