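# Median binning, the count GLM against independent numeric maximizers,
# the overdispersion diagnostic, and the Wilcoxon wrapper.

test_that("median binning groups by level and takes even-group means", {
  b <- median_bin(c(0, 0, 1, 1), c(2, 4, 10, 20), min_bin_size = 1L)
  expect_equal(b$x_level, c(0, 1))
  expect_equal(b$median_count, c(3, 15))
  expect_equal(b$n_drugs, c(2L, 2L))
})

test_that("sparse margin levels merge downward with weighted x", {
  # level 5 (n = 1 < 2) merges into level 0; combined level:
  # x = (0*3 + 5*1)/4, median of {1,2,3,40}
  b <- median_bin(c(0, 0, 0, 5), c(1, 2, 3, 40), min_bin_size = 2L)
  expect_equal(nrow(b), 1L)
  expect_equal(b$x_level, 1.25)
  expect_equal(b$median_count, 2.5)
  expect_equal(b$n_drugs, 4L)
})

test_that("degenerate binning inputs are handled", {
  b <- median_bin(rep(2, 5), c(1, 2, 3, 4, 100), min_bin_size = 5L)
  expect_equal(nrow(b), 1L)
  expect_equal(b$median_count, 3)
  expect_error(median_bin(1:3, 1:2), "equal length")
  # singleton cascade: 10 distinct values, min 5 -> two bins of 5
  b2 <- median_bin(1:10, rep(1, 10), min_bin_size = 5L)
  expect_equal(b2$n_drugs, c(5L, 5L))
})

test_that("Poisson fit recovers the generating slope and matches the
           numeric maximizer", {
  set.seed(201)
  x <- stats::runif(500, 0, 3)
  y <- stats::rpois(500, exp(1 + 0.5 * x))
  fit <- fit_count_glm(x, y, family = "poisson", binning = FALSE)
  expect_lt(abs(fit$beta - 0.5), 0.05)
  oracle <- oracle_poisson_ml(x, y)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-8)
  expect_lt(abs(fit$beta - oracle$par[2L]), 1e-5)
})

test_that("NB fit matches glm.nb as an independent cross-check", {
  skip_if_not_installed("MASS")
  set.seed(202)
  x <- stats::runif(400, 0, 2)
  y <- stats::rnbinom(400, size = 1.5, mu = exp(2 + 0.4 * x))
  fit <- fit_count_glm(x, y, family = "negative_binomial", binning = FALSE)
  ref <- MASS::glm.nb(y ~ x)
  expect_lt(abs(fit$beta - unname(stats::coef(ref)[2L])), 1e-4)
  expect_lt(abs(fit$theta - ref$theta) / ref$theta, 1e-3)
  expect_lt(abs(fit$se_beta - summary(ref)$coefficients[2L, 2L]), 1e-3)
})

test_that("NB with huge fixed theta reproduces the Poisson fit", {
  set.seed(203)
  x <- stats::runif(300, 0, 2)
  y <- stats::rpois(300, exp(1.5 + 0.3 * x))
  nb <- fit_count_glm(x, y, family = "negative_binomial",
                      binning = FALSE, theta_fixed = 1e6)
  po <- fit_count_glm(x, y, family = "poisson", binning = FALSE)
  expect_lt(abs(nb$beta - po$beta), 1e-4)
  expect_lt(abs(nb$intercept - po$intercept), 1e-4)
})

test_that("null data yield null slopes in most seeded runs", {
  ps <- vapply(1:20, function(s) {
    set.seed(300 + s)
    x <- rep(0:4, each = 30)
    y <- stats::rnbinom(150, size = 2, mu = 20)
    fit_count_glm(x, y, family = "negative_binomial",
                  binning = FALSE)$wald_p
  }, numeric(1))
  expect_gte(mean(ps > 0.05), 0.9)
})

test_that("scaling counts shifts the intercept but not the slope", {
  set.seed(204)
  x <- stats::runif(200, 0, 2)
  y <- stats::rpois(200, exp(1 + 0.4 * x))
  f1 <- fit_count_glm(x, y, family = "poisson", binning = FALSE)
  f3 <- fit_count_glm(x, 3L * y, family = "poisson", binning = FALSE)
  expect_lt(abs(f1$beta - f3$beta), 1e-6)
  expect_lt(abs(f3$intercept - f1$intercept - log(3)), 1e-6)
  # NB analogue: scaling y by k with theta scaled by k preserves the score
  y2 <- stats::rnbinom(200, size = 2, mu = exp(1 + 0.4 * x))
  n1 <- fit_count_glm(x, y2, family = "negative_binomial",
                      binning = FALSE, theta_fixed = 2)
  n3 <- fit_count_glm(x, 3L * y2, family = "negative_binomial",
                      binning = FALSE, theta_fixed = 6)
  expect_lt(abs(n1$beta - n3$beta), 1e-6)
})

test_that("fitting contracts are enforced", {
  expect_error(fit_count_glm(c(0, 0, 1, 1), c(1, 2, 3, 4),
                             binning = FALSE), "3 distinct")
  expect_error(fit_count_glm(1:4, c(-1, 2, 3, 4), binning = FALSE),
               "non-negative")
  expect_error(fit_count_glm(1:3, 1:2, binning = FALSE), "equal length")
})

test_that("overdispersion diagnostic separates Poisson from NB data", {
  set.seed(205)
  x <- stats::runif(400, 0, 2)
  eq <- overdispersion_check(x, stats::rpois(400, exp(2 + 0.3 * x)))
  expect_lt(abs(eq$dispersion_stat - 1), 0.3)
  expect_true(eq$poisson_ok)
  # theta = 0.5, mu ~ 10: expected Pearson ratio ~ 1 + mu/theta >> 1.5
  od <- overdispersion_check(x, stats::rnbinom(400, size = 0.5,
                                               mu = exp(2 + 0.3 * x)))
  expect_gt(od$dispersion_stat, 1.5)
  expect_false(od$poisson_ok)
})

test_that("Wilcoxon wrapper uses exact enumeration for small samples", {
  # complete separation of n = 3 vs 3: P(U <= 0) = 1/20, two-sided 0.1
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12)), 0.1)
  a <- c(5, 7, 9, 11, 2, 4, 6, 8, 10, 12)
  expect_equal(wilcoxon_rank_sum(a, a), 1)
  set.seed(206)
  big_a <- stats::rnorm(50)
  expect_lt(wilcoxon_rank_sum(big_a, big_a + 10), 1e-6)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})
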