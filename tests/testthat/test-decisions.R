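test_that("utility functions evaluate the stated tradeoffs", {
  expect_equal(utility_simple(0.70, 0.11, w = 2), 0.48)
  expect_equal(utility_simple(0.44, 0.07, w = 2), 0.30)
  expect_equal(utility_simple(0.9, 0, w = 17), 0.9)  # no toxicity, no penalty
  expect_equal(utility_extended(0.5, 0.2, w1 = 1, w2 = 5, rho = 0.3), 0.3)
  expect_equal(utility_extended(0.5, 0.4, w1 = 1, w2 = 5, rho = 0.3), -1.9)
  # w2 = 0 reduces the extended form to the simple one
  mu <- runif(50); pi <- runif(50); w <- runif(1, 0, 4)
  expect_equal(utility_extended(mu, pi, w1 = w, w2 = 0, rho = 0.3),
               utility_simple(mu, pi, w))
})

test_that("admissibility criteria are vacuous or impossible at the extremes", {
  set.seed(4)
  T_ <- 2000
  mu <- matrix(runif(T_ * 4), T_, 4)
  pi <- matrix(runif(T_ * 4), T_, 4)
  dr <- fake_draws(mu, pi)
  all_in <- admissible_set(dr, bqd_config(J = 4, pi_bar = 1, CE = 0.999,
                                          CT = 0.999))
  expect_setequal(as.integer(all_in), 2:4)
  none <- admissible_set(dr, bqd_config(J = 4, CT = 1e-12, CE = 0.7))
  expect_length(none, 0)
})

test_that("admissibility draw proportions match 2-D Beta quadrature", {
  set.seed(12)
  T_ <- 200000
  ab <- list(c(2, 18), c(6, 14))     # toxicity posteriors, doses 1-2
  mb <- list(c(8, 12), c(11, 9))     # efficacy posteriors on [0,1]
  pi <- cbind(rbeta(T_, ab[[1]][1], ab[[1]][2]),
              rbeta(T_, ab[[2]][1], ab[[2]][2]))
  mu <- cbind(rbeta(T_, mb[[1]][1], mb[[1]][2]),
              rbeta(T_, mb[[2]][1], mb[[2]][2]))
  cfg <- bqd_config(J = 2, pi_bar = 0.1, CT = 0.9, CE = 0.7)
  A <- admissible_set(fake_draws(mu, pi), cfg)
  p_tox_quad <- stats::integrate(function(x)
    dbeta(x, ab[[1]][1], ab[[1]][2]) *
      (1 - pbeta(x + cfg$pi_bar, ab[[2]][1], ab[[2]][2])),
    0, 1, rel.tol = 1e-10)$value
  p_fut_quad <- stats::integrate(function(x)
    dbeta(x, mb[[1]][1], mb[[1]][2]) * pbeta(x, mb[[2]][1], mb[[2]][2]),
    0, 1, rel.tol = 1e-10)$value
  se_tox <- sqrt(p_tox_quad * (1 - p_tox_quad) / T_)
  se_fut <- sqrt(p_fut_quad * (1 - p_fut_quad) / T_)
  expect_lt(abs(attr(A, "prob_toxic")[2] - p_tox_quad), 4 * se_tox)
  expect_lt(abs(attr(A, "prob_futile")[2] - p_fut_quad), 4 * se_fut)
})

test_that("admissibility is monotone in the cutoffs", {
  set.seed(30)
  T_ <- 1000
  for (i in 1:20) {
    mu <- matrix(runif(T_ * 5), T_, 5)
    pi <- matrix(runif(T_ * 5, 0, 0.6), T_, 5)
    dr <- fake_draws(mu, pi)
    loose <- admissible_set(dr, bqd_config(CT = 0.95, CE = 0.9))
    tight <- admissible_set(dr, bqd_config(CT = 0.6, CE = 0.4))
    expect_true(all(as.integer(tight) %in% as.integer(loose)))
  }
})

test_that("PoC test responds to dominance and ties as specified", {
  T_ <- 500
  base <- matrix(rep(runif(T_), 3), T_, 3)
  same <- fake_draws(base)
  cfg <- bqd_config(J = 3, CPoC = 0.5)
  expect_false(poc_test(same, cfg)[1])  # identical arms: strict inequality fails
  up <- base; up[, 3] <- up[, 3] + 1
  expect_true(poc_test(fake_draws(up), cfg)[1])
  expect_equal(attr(poc_test(fake_draws(up), cfg), "statistic"), 1)
  expect_false(poc_test(fake_draws(up), bqd_config(J = 3, CPoC = 1))[1])
})

test_that("MED/MUD selection agrees with exhaustive scans and breaks ties low", {
  set.seed(77)
  cfg <- bqd_config(J = 5, delta = 0.4, w = 2)
  for (i in 1:500) {
    mu_hat <- runif(5, 0, 1)
    pi_hat <- runif(5, 0, 0.5)
    A <- sort(sample(2:5, sample(1:4, 1)))
    dr <- fake_draws(matrix(mu_hat, 1), matrix(pi_hat, 1))
    expect_identical(select_med(dr, A, cfg),
                     scan_med(mu_hat, A, cfg$delta))
    expect_identical(select_mud(dr, A, cfg),
                     scan_mud(utility_simple(mu_hat, pi_hat, 2), A))
  }
  # exact ties go to the lower dose index (binary-exact values)
  tie_mu <- matrix(c(0, 0.25, 0.75), 1)    # target 0.5; both off by 0.25
  dr <- fake_draws(tie_mu, matrix(0, 1, 3))
  expect_identical(select_med(dr, 2:3, bqd_config(J = 3, delta = 0.5)), 2L)
  tie_u <- fake_draws(matrix(c(0.2, 0.6, 0.6), 1), matrix(0, 1, 3))
  expect_identical(select_mud(tie_u, 2:3, bqd_config(J = 3)), 2L)
  expect_identical(select_med(dr, integer(), bqd_config(J = 3)), NA_integer_)
})

test_that("selection at the true curve of Table-like scenarios is correct", {
  sc <- get_scenario("continuous/s1")
  dr <- fake_draws(matrix(sc$eff, 1), matrix(sc$tox, 1))
  cfg <- bqd_config()
  expect_identical(select_med(dr, 2:5, cfg), 2L)  # mean eff 0.57, target 0.60
  expect_identical(select_mud(dr, 2:5, cfg), 3L)  # utility peaks at 0.48
})

test_that("per-draw MED/MUD probabilities match a draw-by-draw scan", {
  set.seed(13)
  cfg <- bqd_config(J = 4)
  for (i in 1:30) {
    T_ <- 40
    mu <- matrix(runif(T_ * 4), T_, 4)
    pi <- matrix(runif(T_ * 4, 0, 0.4), T_, 4)
    A <- sort(sample(2:4, sample(1:3, 1)))
    tp <- target_dose_probabilities(fake_draws(mu, pi), A, cfg)
    p1 <- p2 <- numeric(4)
    for (t in seq_len(T_)) {
      p1[scan_med(mu[t, ], A, cfg$delta)] <-
        p1[scan_med(mu[t, ], A, cfg$delta)] + 1 / T_
      u <- utility_simple(mu[t, ], pi[t, ], cfg$w)
      p2[scan_mud(u, A)] <- p2[scan_mud(u, A)] + 1 / T_
    }
    expect_equal(tp$p1, p1)
    expect_equal(tp$p2, p2)
    expect_equal(sum(tp$p1), 1)
    expect_equal(sum(tp$p2), 1)
    expect_true(all(tp$p1[setdiff(1:4, A)] == 0))
    expect_true(all(tp$p2[setdiff(1:4, A)] == 0))
  }
})

test_that("degenerate and symmetric posteriors give the expected MED probabilities", {
  # identical rows -> indicator vectors
  cfg <- bqd_config(J = 3)
  mu <- matrix(rep(c(0.2, 0.5, 0.9), each = 100), 100, 3)
  tp <- target_dose_probabilities(fake_draws(mu), 2:3, cfg)
  expect_equal(tp$p1, c(0, 1, 0))
  # two symmetric arms straddling the target split 50/50
  set.seed(88)
  T_ <- 200000
  mu <- cbind(rep(0.2, T_), rnorm(T_, 0.55, 0.1), rnorm(T_, 0.65, 0.1))
  tp <- target_dose_probabilities(fake_draws(mu), 2:3, cfg)
  expect_lt(abs(tp$p1[2] - 0.5), 4 * sqrt(0.25 / T_))
  # empty admissible set -> all-zero vectors
  tp0 <- target_dose_probabilities(fake_draws(mu), integer(), cfg)
  expect_equal(tp0$p1, numeric(3))
  expect_equal(tp0$p2, numeric(3))
})

test_that("randomization probabilities implement the boost and control rules", {
  cfg <- bqd_config(J = 5, tau = 0.5, nu = 1)
  # concentrated probabilities: control gets min(pmax, 1/(J-1))
  p1 <- c(0, 0.9, 0.05, 0.03, 0.02)
  p2 <- p1
  pr <- randomization_probabilities(p1, p2, 2:5, cfg)
  score <- c(min(0.9, 0.25), 0.9, 0.05, 0.03, 0.02)
  expect_equal(pr, score / sum(score))
  expect_equal(sum(pr), 1)
  expect_true(all(pr >= 0))

  # nu = 0: equal scores across treatment arms before the pmax boost
  cfg0 <- bqd_config(J = 5, tau = 0.5, nu = 0)
  p1b <- c(0, 0.1, 0.2, 0.3, 0.4); p2b <- c(0, 0.4, 0.3, 0.2, 0.1)
  pr0 <- randomization_probabilities(p1b, p2b, 2:5, cfg0)
  sc0 <- c(min(0.4, 0.25), 0.4, 1, 1, 0.4)  # argmax p1 is dose 5, argmax p2 dose 2
  expect_equal(pr0, sc0 / sum(sc0))

  # tau = 1 reduces scores to p1^nu with a no-op boost
  cfg1 <- bqd_config(J = 5, tau = 1, nu = 1)
  pr1 <- randomization_probabilities(p1b, p2b, 2:5, cfg1)
  sc1 <- c(min(0.4, 0.25), p1b[2:5])
  expect_equal(pr1, sc1 / sum(sc1))

  # inadmissible doses receive zero
  prA <- randomization_probabilities(p1b, p2b, c(2, 4), cfg)
  expect_equal(prA[c(3, 5)], c(0, 0))
  expect_error(randomization_probabilities(p1b, p2b, integer(), cfg),
               "empty admissible")
})

test_that("analyze wires the pipeline together and serializes", {
  set.seed(6)
  d <- scenario_data(get_scenario("continuous/s1"), n_per_arm = 60)
  a <- analyze(d, bqd_config(CPoC = 0.9, n_draws = 800), seed = 2)
  td <- tidy(a)
  expect_equal(nrow(td), 5)
  expect_equal(sum(td$randomization), 1)
  gl <- glance(a)
  expect_true(is.logical(gl$poc_established))
  rec <- as_decision_record(a)
  expect_named(rec, c("admissible", "p1", "p2", "randomization",
                      "poc_established", "poc_statistic", "med", "mud",
                      "utility"), ignore.order = TRUE)
  path <- tempfile(fileext = ".json")
  as_decision_record(a, path)
  back <- jsonlite::read_json(path)
  expect_equal(unlist(back$randomization), a$randomization, tolerance = 1e-12)
})
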