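make_data <- function(dose, tox, eff, type = "continuous", bounds = NULL,
                      J = max(dose)) {
  bqd_data(tibble::tibble(dose_index = dose, toxicity = tox, efficacy = eff),
           type, bounds = bounds, J = J)
}

test_that("toxicity posterior is exact conjugate arithmetic", {
  empty <- make_data(integer(), integer(), numeric(), "binary", J = 2)
  p <- toxicity_posterior(empty, dose = 1)
  expect_equal(c(p$alpha, p$beta), c(1, 1))  # no data returns the prior

  d <- make_data(rep(1, 6), c(1, 0, 0, 0, 0, 0), rep(0, 6), "binary")
  p <- toxicity_posterior(d, dose = 1)
  expect_equal(c(p$alpha, p$beta, p$mean), c(2, 6, 0.25))

  d <- make_data(rep(1, 10), c(rep(1, 3), rep(0, 7)), rep(0, 10), "binary")
  p <- toxicity_posterior(d, dose = 1, prior = c(0.5, 0.5))
  expect_equal(c(p$alpha, p$beta), c(3.5, 7.5))
})

test_that("standardization maps to [0,1], inverts, and rejects degenerate bounds", {
  expect_equal(standardize_efficacy(3, c(0, 4)), 0.75)
  expect_equal(standardize_efficacy(1, c(0, 1)), 1)
  y <- runif(20, -2, 5)
  b <- c(-2, 5)
  expect_equal(inv_standardize_efficacy(standardize_efficacy(y, b), b), y)
  expect_error(standardize_efficacy(1, c(2, 2)), "degenerate")
})

test_that("quasi-Bernoulli posterior accepts fractional pseudo-events", {
  # five no-toxicity patients at one dose with standardized outcomes
  # summing to 2.5 pseudo-events
  d <- make_data(rep(1, 5), rep(0, 5), c(1, 0.5, 0.5, 0.5, 0),
                 "continuous", bounds = c(0, 1))
  p <- efficacy_posterior(d, dose = 1, tox_level = 0)
  expect_equal(c(p$alpha, p$beta, p$mean), c(3.5, 3.5, 0.5))
  # empty stratum returns the prior
  p1 <- efficacy_posterior(d, dose = 1, tox_level = 1)
  expect_equal(c(p1$alpha, p1$beta), c(1, 1))
})

test_that("binary endpoint reduces to the ordinary beta-binomial posterior", {
  d <- make_data(rep(1, 8), rep(0, 8), c(1, 1, 1, 0, 0, 0, 0, 0), "binary")
  p <- efficacy_posterior(d, dose = 1, tox_level = 0)
  expect_equal(c(p$alpha, p$beta), c(3 + 1, 5 + 1))
})

test_that("marginal efficacy draws match the analytic mixture of posterior means", {
  set.seed(11)
  d <- scenario_data(get_scenario("continuous/s1"), n_per_arm = 40)
  cfg <- bqd_config()
  dr <- sample_posterior(d, cfg, n_draws = 100000, seed = 5, isotonic = FALSE)
  # closed-form oracle: independence makes E[mu] the mixture of Beta means
  # mapped through the linear inverse standardization
  for (j in 1:5) {
    pt <- toxicity_posterior(d, j)
    b <- dr$bounds[j, ]
    e0 <- inv_standardize_efficacy(efficacy_posterior(d, j, 0)$mean, b)
    e1 <- inv_standardize_efficacy(efficacy_posterior(d, j, 1)$mean, b)
    analytic <- pt$mean * e1 + (1 - pt$mean) * e0
    mc_se <- stats::sd(dr$mu[, j]) / sqrt(dr$n_draws)
    expect_lt(abs(mean(dr$mu[, j]) - analytic), 3 * mc_se + 1e-9)
  }
})

test_that("degenerate mixtures collapse as expected", {
  T_ <- 200
  pi <- rep(0, T_)
  theta0 <- runif(T_)
  b <- c(-1, 3)
  mu <- pi * inv_standardize_efficacy(0.9, b) +
    (1 - pi) * inv_standardize_efficacy(theta0, b)
  expect_equal(mu, inv_standardize_efficacy(theta0, b))
  # equal strata make the mixture independent of pi
  pi2 <- runif(T_)
  th <- runif(T_)
  mu2 <- pi2 * inv_standardize_efficacy(th, b) +
    (1 - pi2) * inv_standardize_efficacy(th, b)
  expect_equal(mu2, inv_standardize_efficacy(th, b))
})

test_that("draws are reproducible under a seed", {
  set.seed(3)
  d <- scenario_data(get_scenario("continuous/s2"), n_per_arm = 20)
  cfg <- bqd_config(n_draws = 400)
  d1 <- sample_posterior(d, cfg, seed = 7)
  d2 <- sample_posterior(d, cfg, seed = 7)
  expect_identical(d1$mu, d2$mu)
  expect_identical(d1$pi, d2$pi)
  d3 <- sample_posterior(d, cfg, seed = 8)
  expect_false(identical(d1$mu, d3$mu))
})

test_that("continuous draws are equivariant under affine outcome transforms", {
  set.seed(9)
  d <- scenario_data(get_scenario("continuous/s3"), n_per_arm = 25)
  a <- 3.7; b <- -1.2
  d2 <- bqd_data(dplyr::mutate(tibble::as_tibble(d), efficacy = a * efficacy + b),
                 "continuous", J = 5)
  cfg <- bqd_config(n_draws = 300)
  dr1 <- sample_posterior(d, cfg, seed = 21)
  dr2 <- sample_posterior(d2, cfg, seed = 21)
  expect_equal(dr2$theta0, dr1$theta0)
  expect_equal(dr2$theta1, dr1$theta1)
  expect_equal(dr2$mu, a * dr1$mu + b, tolerance = 1e-10)
})

test_that("tidy and glance on draws return well-formed tibbles", {
  set.seed(2)
  d <- scenario_data(get_scenario("continuous/s1"), n_per_arm = 15)
  dr <- sample_posterior(d, bqd_config(n_draws = 200), seed = 1)
  td <- tidy(dr)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$quantity), c("pi", "mu", "theta0", "theta1"))
  expect_equal(nrow(td), 4 * 5)
  expect_true(all(td$conf.low <= td$conf.high))
  gl <- glance(dr)
  expect_equal(gl$n_draws, 200L)
})
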