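# Independent oracles and small fixture builders used across the suite.

# Exact weighted isotonic projection by exhaustive search over all
# contiguous-block partitions (2^(J-1)): pool each block to its weighted
# mean, keep partitions whose pooled means are non-decreasing, and return
# the feasible fit with minimal weighted squared error. Exact for small J.
brute_force_pava <- function(x, w = rep(1, length(x))) {
  J <- length(x)
  if (J == 1) return(x)
  best <- NULL
  best_sse <- Inf
  for (mask in 0:(2^(J - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(seq_len(J - 1) - 1)) > 0)
    starts <- c(1, cuts + 1)
    ends <- c(cuts, J)
    fit <- numeric(J)
    means <- numeric(length(starts))
    for (b in seq_along(starts)) {
      idx <- starts[b]:ends[b]
      means[b] <- sum(x[idx] * w[idx]) / sum(w[idx])
      fit[idx] <- means[b]
    }
    if (any(diff(means) < -1e-12)) next
    sse <- sum(w * (x - fit)^2)
    if (sse < best_sse - 1e-15) {
      best_sse <- sse
      best <- fit
    }
  }
  best
}

# Minimal bqd_draws object built directly from draw matrices, for testing
# the decision rules against posteriors with known closed forms.
fake_draws <- function(mu, pi = matrix(0, nrow(mu), ncol(mu))) {
  stopifnot(is.matrix(mu), all(dim(mu) == dim(pi)))
  structure(list(pi = pi, theta0 = mu, theta1 = mu, mu = mu,
                 pi_raw = pi, mu_raw = mu,
                 n_draws = nrow(mu), J = ncol(mu),
                 bounds = cbind(lower = rep(0, ncol(mu)),
                                upper = rep(1, ncol(mu))),
                 weights_pi = rep(1, ncol(mu)),
                 weights_mu = rep(1, ncol(mu)),
                 isotonic = c(toxicity = FALSE, efficacy = FALSE),
                 endpoint_type = "continuous"),
            class = "bqd_draws")
}

# Patient data simulated directly from a scenario, n per arm.
scenario_data <- function(scenario, n_per_arm) {
  recs <- lapply(seq_len(scenario$J), function(j) {
    out <- draw_outcomes(scenario, j, n_per_arm)
    data.frame(dose_index = j, toxicity = out$toxicity,
               efficacy = out$efficacy)
  })
  bounds <- switch(scenario$endpoint_type,
                   binary = c(0, 1),
                   ordinal = c(0, length(scenario$cutoffs)),
                   continuous = NULL)
  bqd_data(do.call(rbind, recs), scenario$endpoint_type,
           bounds = bounds, J = scenario$J)
}

# Exhaustive scans of the MED / MUD rules over an admissible set.
scan_med <- function(mu_hat, A, delta) A[which.min(abs(mu_hat[A] - (mu_hat[1] + delta)))]
scan_mud <- function(u_hat, A) A[which.max(u_hat[A])]

# Quick config for small fast tests.
small_config <- function(...) {
  bqd_config(stage_sizes = c(40, 10, 10), n_draws = 500, ...)
}
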