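#' Standardize an efficacy outcome to the unit interval
#'
#' The quasi-Bernoulli likelihood treats a bounded outcome as a fractional
#' "pseudo-event"; this is the linear map `g(y) = (y - lower)/(upper - lower)`
#' onto \[0, 1\] and its inverse.
#'
#' @param y numeric outcomes on the original scale.
#' @param bounds `(lower, upper)` with `upper > lower`: the declared endpoint
#'   boundaries for bounded endpoints, or the observed per-dose range for
#'   continuous endpoints.
#' @return `standardize_efficacy()` returns values in \[0, 1\];
#'   `inv_standardize_efficacy()` maps standardized values back.
#' @examples
#' standardize_efficacy(3, c(0, 4))
#' inv_standardize_efficacy(0.75, c(0, 4))
#' @export
standardize_efficacy <- function(y, bounds) {
  stopifnot(length(bounds) == 2)
  if (!(bounds[2] > bounds[1]))
    abort("degenerate bounds: `upper` must exceed `lower`")
  (y - bounds[1]) / (bounds[2] - bounds[1])
}

#' @rdname standardize_efficacy
#' @param theta standardized values in \[0, 1\].
#' @export
inv_standardize_efficacy <- function(theta, bounds) {
  stopifnot(length(bounds) == 2)
  theta * (bounds[2] - bounds[1]) + bounds[1]
}

#' Conjugate posterior of the toxicity probability at one dose
#'
#' With `m_j` toxicities among `n_j` patients at dose `j` and a
#' `Beta(alpha, beta)` prior, the posterior is
#' `Beta(m_j + alpha, n_j - m_j + beta)`. With no data the prior is returned.
#'
#' @param data a [bqd_data()] tibble.
#' @param dose dose index in `1..J`.
#' @param prior length-2 positive vector `(alpha, beta)`.
#' @return one-row tibble with the posterior `alpha`, `beta` and `mean`.
#' @examples
#' d <- bqd_data(tibble::tibble(dose_index = rep(1, 6),
#'                              toxicity = c(1, 0, 0, 0, 0, 0),
#'                              efficacy = rep(0, 6)), "binary")
#' toxicity_posterior(d, dose = 1)
#' @export
toxicity_posterior <- function(data, dose, prior = c(1, 1)) {
  stopifnot(inherits(data, "bqd_data"), length(prior) == 2, all(prior > 0))
  J <- attr(data, "J")
  stopifnot(dose >= 1, dose <= J)
  sel <- data$dose_index == dose
  n <- sum(sel)
  m <- sum(data$toxicity[sel])
  beta_tibble(m + prior[1], n - m + prior[2])
}

#' Quasi-Bernoulli posterior of standardized efficacy in one stratum
#'
#' Within the stratum of patients at dose `j` with toxicity outcome `k`, the
#' standardized outcomes act as fractional pseudo-events: with pseudo-event
#' sum `s_jk` over `n_jk` patients and a `Beta(alpha, beta)` prior the
#' posterior is `Beta(s_jk + alpha, n_jk - s_jk + beta)`. `s_jk` need not be
#' an integer. An empty stratum returns the prior.
#'
#' @inheritParams toxicity_posterior
#' @param tox_level toxicity stratum, 0 or 1.
#' @return one-row tibble with the posterior `alpha`, `beta` and `mean`.
#' @export
efficacy_posterior <- function(data, dose, tox_level, prior = c(1, 1)) {
  stopifnot(inherits(data, "bqd_data"), tox_level %in% c(0, 1),
            length(prior) == 2, all(prior > 0))
  st <- dose_statistics(data)
  stopifnot(dose >= 1, dose <= st$J)
  k <- tox_level + 1
  beta_tibble(st$s_k[dose, k] + prior[1],
              st$n_k[dose, k] - st$s_k[dose, k] + prior[2])
}

beta_tibble <- function(alpha, beta) {
  alpha <- unname(alpha); beta <- unname(beta)
  tibble(alpha = alpha, beta = beta, mean = alpha / (alpha + beta))
}

#' Monte-Carlo posterior draws for all doses
#'
#' Draws the toxicity probabilities `pi_j`, the stratum-specific standardized
#' efficacy means `theta_j0`, `theta_j1` independently from their conjugate
#' posteriors, forms the marginal mean-efficacy draws on the original scale,
#' `mu_j = pi_j * g^{-1}(theta_j1) + (1 - pi_j) * g^{-1}(theta_j0)`,
#' and (optionally) imposes monotonicity across doses by weighted isotonic
#' regression applied draw by draw, with weights equal to the reciprocal
#' posterior variances of the unconstrained draws.
#'
#' @param data a [bqd_data()] tibble.
#' @param config a [bqd_config()].
#' @param n_draws number of draws; defaults to `config$n_draws`.
#' @param seed optional integer seed for reproducible draws.
#' @param isotonic `NULL` (use the config flags) or a logical scalar
#'   overriding both flags, e.g. `FALSE` for unconstrained draws.
#' @return an object of class `bqd_draws`: a list with T-by-J matrices
#'   `pi`, `theta0`, `theta1`, `mu` (post-transform), their unconstrained
#'   versions `pi_raw`, `mu_raw`, the per-dose bounds, and the PAVA weights.
#' @examples
#' d <- bqd_data(tibble::tibble(dose_index = rep(1:2, each = 10),
#'                              toxicity = rbinom(20, 1, 0.1),
#'                              efficacy = rnorm(20, 0.3)), "continuous")
#' dr <- sample_posterior(d, bqd_config(J = 2), n_draws = 500, seed = 1)
#' tidy(dr)
#' @export
sample_posterior <- function(data, config, n_draws = config$n_draws,
                             seed = NULL, isotonic = NULL) {
  stopifnot(inherits(data, "bqd_data"), inherits(config, "bqd_config"),
            n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  st <- dose_statistics(data, J = config$J)
  J <- st$J
  T_ <- as.integer(n_draws)
  at <- config$prior_tox; ae <- config$prior_eff
  pi <- theta0 <- theta1 <- matrix(0, T_, J)
  for (j in seq_len(J)) {
    pi[, j] <- rbeta(T_, st$m[j] + at[1], st$n[j] - st$m[j] + at[2])
    if (st$degenerate[j]) {
      theta0[, j] <- 0.5
      theta1[, j] <- 0.5
    } else {
      theta0[, j] <- rbeta(T_, st$s_k[j, 1] + ae[1],
                           st$n_k[j, 1] - st$s_k[j, 1] + ae[2])
      theta1[, j] <- rbeta(T_, st$s_k[j, 2] + ae[1],
                           st$n_k[j, 2] - st$s_k[j, 2] + ae[2])
    }
  }
  width <- st$upper - st$lower
  mu <- pi * sweep(theta1, 2, width, "*") +
    (1 - pi) * sweep(theta0, 2, width, "*")
  mu <- sweep(mu, 2, st$lower, "+")

  iso_tox <- if (is.null(isotonic)) config$isotonic_toxicity else isotonic
  iso_eff <- if (is.null(isotonic)) config$isotonic_efficacy else isotonic
  w_pi <- draw_weights(pi)
  w_mu <- draw_weights(mu)
  out <- list(
    pi = if (iso_tox && J > 1) isotonize_draws(pi, w_pi) else pi,
    theta0 = theta0, theta1 = theta1,
    mu = if (iso_eff && J > 1) isotonize_draws(mu, w_mu) else mu,
    pi_raw = pi, mu_raw = mu,
    n_draws = T_, J = J,
    bounds = cbind(lower = st$lower, upper = st$upper),
    weights_pi = w_pi, weights_mu = w_mu,
    isotonic = c(toxicity = iso_tox, efficacy = iso_eff),
    endpoint_type = st$endpoint_type
  )
  class(out) <- "bqd_draws"
  out
}

# reciprocal empirical variances of the unconstrained draws, guarded
# against degenerate (constant) columns
draw_weights <- function(mat) {
  v <- apply(mat, 2, var)
  1 / pmax(v, 1e-12)
}

#' @export
print.bqd_draws <- function(x, ...) {
  cat("<bqd_draws> ", x$n_draws, " draws x ", x$J, " doses (",
      x$endpoint_type, " endpoint)\n", sep = "")
  cat("  isotonic: toxicity =", x$isotonic["toxicity"],
      ", efficacy =", x$isotonic["efficacy"], "\n")
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy posterior draws into per-dose summaries
#'
#' @param x a `bqd_draws` object.
#' @param ... unused.
#' @return tibble with one row per dose and quantity (`pi`, `mu`, and the
#'   stratum means `theta0`, `theta1`): posterior mean, sd and 95% credible
#'   interval.
#' @export
tidy.bqd_draws <- function(x, ...) {
  one <- function(mat, name) {
    tibble(
      quantity = name, dose = seq_len(ncol(mat)),
      mean = colMeans(mat),
      sd = apply(mat, 2, stats::sd),
      conf.low = apply(mat, 2, quantile, 0.025),
      conf.high = apply(mat, 2, quantile, 0.975)
    )
  }
  bind_rows(one(x$pi, "pi"), one(x$mu, "mu"),
            one(x$theta0, "theta0"), one(x$theta1, "theta1"))
}

#' One-line summary of posterior draws
#'
#' @param x a `bqd_draws` object.
#' @param ... unused.
#' @return one-row tibble with the number of draws, doses and transform flags.
#' @export
glance.bqd_draws <- function(x, ...) {
  tibble(n_draws = x$n_draws, J = x$J,
         endpoint_type = x$endpoint_type,
         isotonic_toxicity = unname(x$isotonic["toxicity"]),
         isotonic_efficacy = unname(x$isotonic["efficacy"]))
}

#' Plot posterior dose–toxicity, dose–efficacy and dose–utility summaries
#'
#' @param object a `bqd_draws` object.
#' @param config optional [bqd_config()]; when supplied the posterior mean
#'   utility curve is added.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.bqd_draws <- function(object, config = NULL, ...) {
  td <- tidy(object) %>% filter(.data$quantity %in% c("pi", "mu"))
  if (!is.null(config)) {
    U <- compute_utility(object$mu, object$pi, config)
    td <- bind_rows(td, tibble(
      quantity = "utility", dose = seq_len(object$J),
      mean = colMeans(U), sd = apply(U, 2, stats::sd),
      conf.low = apply(U, 2, quantile, 0.025),
      conf.high = apply(U, 2, quantile, 0.975)
    ))
  }
  ggplot(td, aes(x = .data$dose, y = .data$mean, colour = .data$quantity)) +
    geom_ribbon(aes(ymin = .data$conf.low, ymax = .data$conf.high,
                    fill = .data$quantity), alpha = 0.15, colour = NA) +
    geom_line() + geom_point() +
    labs(x = "dose index", y = "posterior mean (95% CrI)",
         colour = NULL, fill = NULL) +
    theme_minimal()
}
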