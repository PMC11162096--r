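#' Benefit–risk utility functions
#'
#' The simple tradeoff `U = mu - w * pi` penalizes each unit of toxicity
#' rate by `w` units of mean efficacy. The extended form adds a further
#' penalty `w2 * pi` once the toxicity rate exceeds a threshold `rho`:
#' `U = mu - w1 * pi - w2 * pi * I(pi > rho)`. With `w2 = 0` the extended
#' form reduces to the simple one.
#'
#' @param mu mean efficacy (original scale).
#' @param pi toxicity probability.
#' @param w,w1,w2 penalty weights.
#' @param rho toxicity threshold activating the extra penalty.
#' @return numeric utility, vectorized over the inputs.
#' @examples
#' utility_simple(0.70, 0.11, w = 2)   # 0.48
#' utility_extended(0.5, 0.4, w1 = 1, w2 = 5, rho = 0.3)
#' @export
utility_simple <- function(mu, pi, w) mu - w * pi

#' @rdname utility_simple
#' @export
utility_extended <- function(mu, pi, w1, w2, rho) {
  mu - w1 * pi - w2 * pi * (pi > rho)
}

# Utility matrix for draw matrices under the configured tradeoff.
compute_utility <- function(mu, pi, config) {
  if (is.null(config$w2)) {
    utility_simple(mu, pi, config$w)
  } else {
    utility_extended(mu, pi, config$w1, config$w2, config$rho_utility)
  }
}

#' Admissible dose set: safety and futility screening
#'
#' A treatment dose `j` (2..J) is admissible iff
#' `Pr(pi_j > pi_1 + pi_bar | D) < CT` (not overly toxic) and
#' `Pr(mu_j <= mu_1 | D) < CE` (not futile), with both probabilities
#' estimated as proportions of matched posterior draws. The control (arm 1)
#' is always enrolled and is not a member of the set.
#'
#' @param draws a [sample_posterior()] result.
#' @param config a [bqd_config()].
#' @return integer vector of admissible dose indices (subset of `2:J`,
#'   possibly empty), with the per-dose screening probabilities attached as
#'   attributes `prob_toxic` and `prob_futile`.
#' @export
admissible_set <- function(draws, config) {
  stopifnot(inherits(draws, "bqd_draws"))
  J <- draws$J
  p_tox <- p_fut <- rep(NA_real_, J)
  for (j in seq_len(J)[-1]) {
    p_tox[j] <- mean(draws$pi[, j] > draws$pi[, 1] + config$pi_bar)
    p_fut[j] <- mean(draws$mu[, j] <= draws$mu[, 1])
  }
  A <- which(p_tox < config$CT & p_fut < config$CE)
  structure(as.integer(A), prob_toxic = p_tox, prob_futile = p_fut)
}

#' Proof-of-concept test
#'
#' PoC is established when at least one treatment arm satisfies
#' `Pr(mu_j > mu_1 | D) > CPoC`, with the probability estimated as the
#' proportion of posterior draws (strict inequality; draws pooled with the
#' control by the isotonic transform do not count).
#'
#' @inheritParams admissible_set
#' @return logical flag, with attributes `prob` (per-dose probabilities,
#'   `NA` for the control) and `statistic` (their maximum — the quantity
#'   calibrated by [calibrate_cpoc()]).
#' @export
poc_test <- function(draws, config) {
  stopifnot(inherits(draws, "bqd_draws"))
  J <- draws$J
  prob <- rep(NA_real_, J)
  for (j in seq_len(J)[-1]) prob[j] <- mean(draws$mu[, j] > draws$mu[, 1])
  stat <- max(prob, na.rm = TRUE)
  structure(stat > config$CPoC, prob = prob, statistic = stat)
}

#' Select the minimum effective dose
#'
#' The MED is the admissible dose whose posterior mean efficacy is closest
#' to the control's posterior mean plus the clinically relevant difference:
#' `argmin_{j in A} | mu_hat_j - (mu_hat_1 + delta) |`. Exact ties go to the
#' lower dose.
#'
#' @inheritParams admissible_set
#' @param A admissible dose set from [admissible_set()].
#' @return dose index, or `NA` if `A` is empty.
#' @export
select_med <- function(draws, A, config) {
  if (length(A) == 0) return(NA_integer_)
  muhat <- colMeans(draws$mu)
  A[which.min(abs(muhat[A] - (muhat[1] + config$delta)))]
}

#' Select the maximum utility dose
#'
#' The MUD maximizes the estimated utility over the admissible set, where
#' the estimate is the posterior mean of the per-draw utility
#' `U(mu_j(t), pi_j(t))`. Exact ties go to the lower dose. Optionally the
#' search is restricted to doses at or above a given dose (the
#' `require_mud_ge_med` config flag).
#'
#' @inheritParams select_med
#' @param min_dose optional lower bound on the selected dose index.
#' @return dose index, or `NA` if no admissible dose qualifies.
#' @export
select_mud <- function(draws, A, config, min_dose = NULL) {
  if (!is.null(min_dose) && !is.na(min_dose)) A <- A[A >= min_dose]
  if (length(A) == 0) return(NA_integer_)
  Uhat <- colMeans(compute_utility(draws$mu, draws$pi, config))
  A[which.max(Uhat[A])]
}

#' Posterior probabilities of each dose being the MED and the MUD
#'
#' For every posterior draw the MED and MUD rules are applied to the drawn
#' curves restricted to the admissible set; `p1` and `p2` are the
#' proportions of draws electing each dose. Each vector is zero outside `A`
#' and sums to one over `A` when `A` is nonempty.
#'
#' @inheritParams select_med
#' @return list with numeric length-J vectors `p1` (MED) and `p2` (MUD).
#' @export
target_dose_probabilities <- function(draws, A, config) {
  J <- draws$J
  p1 <- p2 <- numeric(J)
  if (length(A) == 0) return(list(p1 = p1, p2 = p2))
  target <- draws$mu[, 1] + config$delta
  dmat <- abs(draws$mu[, A, drop = FALSE] - target)
  med_draw <- A[max.col(-dmat, ties.method = "first")]
  U <- compute_utility(draws$mu[, A, drop = FALSE],
                       draws$pi[, A, drop = FALSE], config)
  mud_draw <- A[max.col(U, ties.method = "first")]
  p1[A] <- tabulate(med_draw, nbins = J)[A] / draws$n_draws
  p2[A] <- tabulate(mud_draw, nbins = J)[A] / draws$n_draws
  list(p1 = p1, p2 = p2)
}

#' Adaptive randomization probabilities
#'
#' Admissible treatment arms receive unnormalized scores
#' `tau * p1_j^nu + (1 - tau) * p2_j^nu`. The arm with the largest `p1` and
#' the arm with the largest `p2` are each boosted to
#' `pmax = max(p1, p2)` over `A` (to `max p1` when `tau = 1`, `max p2` when
#' `tau = 0`), so the putative MED and MUD both keep high allocation. The
#' control receives `min(pmax, 1/(J - 1))`; inadmissible doses receive 0.
#' Scores are then normalized to a probability vector.
#'
#' @param p1,p2 length-J MED/MUD probabilities from
#'   [target_dose_probabilities()].
#' @inheritParams select_med
#' @return length-J probability vector (sums to 1).
#' @export
randomization_probabilities <- function(p1, p2, A, config) {
  J <- config$J
  stopifnot(length(p1) == J, length(p2) == J)
  if (length(A) == 0)
    abort("empty admissible set: the trial should already have stopped")
  score <- numeric(J)
  score[A] <- config$tau * p1[A]^config$nu +
    (1 - config$tau) * p2[A]^config$nu
  pmax_val <- if (config$tau == 1) max(p1[A])
  else if (config$tau == 0) max(p2[A])
  else max(p1[A], p2[A])
  if (config$tau > 0) score[A[which.max(p1[A])]] <- pmax_val
  if (config$tau < 1) score[A[which.max(p2[A])]] <- pmax_val
  score[1] <- min(pmax_val, 1 / (J - 1))
  if (sum(score) <= 0)
    abort("all randomization scores are zero")
  score / sum(score)
}

#' Full interim or final analysis of accumulated trial data
#'
#' Convenience wrapper running the whole decision pipeline on one data set:
#' posterior sampling, admissibility screening, MED/MUD probabilities,
#' adaptive randomization probabilities, the PoC test and (when PoC holds)
#' MED/MUD selection.
#'
#' @param data a [bqd_data()] tibble.
#' @param config a [bqd_config()].
#' @param n_draws,seed passed to [sample_posterior()].
#' @return an object of class `bqd_analysis`.
#' @examples
#' d <- bqd_data(tibble::tibble(dose_index = rep(1:2, each = 15),
#'                              toxicity = rbinom(30, 1, 0.1),
#'                              efficacy = rnorm(30, rep(c(0, 1), each = 15))),
#'               "continuous")
#' a <- analyze(d, bqd_config(J = 2, CPoC = 0.9), n_draws = 1000, seed = 1)
#' glance(a)
#' @export
analyze <- function(data, config, n_draws = config$n_draws, seed = NULL) {
  draws <- sample_posterior(data, config, n_draws = n_draws, seed = seed)
  A <- admissible_set(draws, config)
  tp <- target_dose_probabilities(draws, A, config)
  rand <- if (length(A)) randomization_probabilities(tp$p1, tp$p2, A, config)
  else numeric(config$J)
  poc <- poc_test(draws, config)
  med <- mud <- NA_integer_
  if (isTRUE(poc[1]) && length(A)) {
    med <- select_med(draws, A, config)
    mud <- select_mud(draws, A, config,
                      min_dose = if (config$require_mud_ge_med) med)
  }
  out <- list(
    draws = draws, A = as.integer(A),
    prob_toxic = attr(A, "prob_toxic"), prob_futile = attr(A, "prob_futile"),
    p1 = tp$p1, p2 = tp$p2, randomization = rand,
    poc_established = isTRUE(poc[1]),
    poc_prob = attr(poc, "prob"), poc_statistic = attr(poc, "statistic"),
    med = med, mud = mud,
    utility = colMeans(compute_utility(draws$mu, draws$pi, config)),
    config = config
  )
  class(out) <- "bqd_analysis"
  out
}

#' @export
print.bqd_analysis <- function(x, ...) {
  cat("<bqd_analysis>\n")
  cat("  admissible doses:",
      if (length(x$A)) paste(x$A, collapse = ", ") else "(none)", "\n")
  cat("  PoC:", if (x$poc_established) "established" else "not established",
      sprintf("(max posterior prob %.3f, cutoff %.3f)\n",
              x$poc_statistic, x$config$CPoC))
  if (!is.na(x$med)) cat("  MED: dose", x$med, "  MUD: dose", x$mud, "\n")
  invisible(x)
}

#' Tidy per-dose decision quantities
#'
#' @param x a `bqd_analysis` object.
#' @param ... unused.
#' @return tibble with one row per dose: posterior means, screening
#'   probabilities, MED/MUD probabilities and randomization probabilities.
#' @export
tidy.bqd_analysis <- function(x, ...) {
  tibble(
    dose = seq_len(x$config$J),
    pi_hat = colMeans(x$draws$pi),
    mu_hat = colMeans(x$draws$mu),
    utility = x$utility,
    admissible = seq_len(x$config$J) %in% c(1L, x$A),
    prob_toxic = x$prob_toxic, prob_futile = x$prob_futile,
    poc_prob = x$poc_prob,
    p_med = x$p1, p_mud = x$p2,
    randomization = x$randomization
  )
}

#' One-row summary of an analysis
#'
#' @param x a `bqd_analysis` object.
#' @param ... unused.
#' @return one-row tibble with the PoC flag and statistic, the selected
#'   MED/MUD and the admissible-set size.
#' @export
glance.bqd_analysis <- function(x, ...) {
  tibble(poc_established = x$poc_established,
         poc_statistic = x$poc_statistic,
         med = x$med, mud = x$mud, n_admissible = length(x$A))
}

#' Serialize an analysis as a structured decision record
#'
#' @param x a `bqd_analysis` object.
#' @param path optional file path; when given, the record is written as JSON.
#' @return the record as a named list (invisibly when writing).
#' @export
as_decision_record <- function(x, path = NULL) {
  stopifnot(inherits(x, "bqd_analysis"))
  rec <- list(
    admissible = x$A, p1 = x$p1, p2 = x$p2,
    randomization = x$randomization,
    poc_established = x$poc_established,
    poc_statistic = x$poc_statistic,
    med = if (is.na(x$med)) NULL else x$med,
    mud = if (is.na(x$mud)) NULL else x$mud,
    utility = x$utility
  )
  if (!is.null(path)) {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(rec))
  }
  rec
}
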