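#' Define a simulation scenario
#'
#' A scenario fixes the true per-dose toxicity rates and efficacy profile
#' and the latent-model parameters used by the correlated outcome generator:
#' toxicity and (latent) efficacy arise from a bivariate normal with
#' correlation `rho`, the toxicity indicator is the latent variable
#' thresholded to give marginal rate `pi_j`, and the efficacy outcome is the
#' latent variable itself (continuous), binned at cutoffs (ordinal), or
#' thresholded on the standardized latent to give rate `pi_E_j` (binary).
#'
#' @param endpoint_type `"continuous"`, `"ordinal"` or `"binary"`.
#' @param tox length-J true toxicity rates in \[0, 1\].
#' @param eff length-J efficacy profile: latent means (continuous), target
#'   ordinal means (ordinal; informational), or response rates (binary).
#' @param rho latent toxicity–efficacy correlation, `|rho| < 1`.
#' @param sigma latent efficacy standard deviation, `> 0`.
#' @param cutoffs strictly increasing ordinal bin cutoffs `gamma_1 <
#'   ... < gamma_{K-1}` (ordinal endpoints only); see
#'   [calibrate_ordinal_cutoffs()].
#' @param latent_mu latent efficacy means for ordinal/binary endpoints
#'   (defaults to `eff` for continuous; required for ordinal).
#' @param true_med,true_mud optional dose-index labels used by the
#'   operating-characteristics metrics.
#' @param name optional scenario name.
#' @param meta optional named list of free-form metadata.
#' @return an object of class `bqd_scenario`.
#' @examples
#' sc <- bqd_scenario("continuous", tox = c(0.05, 0.1), eff = c(0.2, 0.6))
#' draw_outcomes(sc, dose = 2, n = 5)
#' @export
bqd_scenario <- function(endpoint_type = c("continuous", "ordinal", "binary"),
                         tox, eff, rho = 0.3, sigma = 1,
                         cutoffs = NULL, latent_mu = NULL,
                         true_med = NULL, true_mud = NULL,
                         name = NULL, meta = list()) {
  endpoint_type <- match.arg(endpoint_type)
  stopifnot(length(tox) == length(eff),
            all(tox >= 0), all(tox <= 1),
            abs(rho) < 1, sigma > 0)
  if (endpoint_type == "binary") stopifnot(all(eff >= 0), all(eff <= 1))
  if (!is.null(cutoffs)) stopifnot(all(diff(cutoffs) > 0))
  if (is.null(latent_mu))
    latent_mu <- if (endpoint_type == "continuous") eff else rep(0, length(eff))
  sc <- list(endpoint_type = endpoint_type,
             tox = as.numeric(tox), eff = as.numeric(eff),
             rho = rho, sigma = sigma,
             cutoffs = cutoffs, latent_mu = as.numeric(latent_mu),
             true_med = true_med, true_mud = true_mud,
             J = length(tox), name = name, meta = meta)
  class(sc) <- "bqd_scenario"
  sc
}

#' @export
print.bqd_scenario <- function(x, ...) {
  cat("<bqd_scenario>", x$name %||% "", " (", x$endpoint_type, ", J = ",
      x$J, ")\n", sep = "")
  cat("  tox:", paste(format(x$tox), collapse = " "), "\n")
  cat("  eff:", paste(format(x$eff), collapse = " "), "\n")
  cat("  rho:", x$rho, " sigma:", x$sigma, "\n")
  if (!is.null(x$true_med))
    cat("  true MED: dose", x$true_med, " true MUD: dose", x$true_mud, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw correlated toxicity/efficacy outcomes at a dose
#'
#' Samples `(x_tilde, y_tilde)` from the scenario's bivariate normal with
#' means `(0, mu_j)`, variances `(1, sigma^2)` and covariance `rho * sigma`.
#' Toxicity is 1 iff `x_tilde > qnorm(1 - pi_j)`. Efficacy is `y_tilde`
#' (continuous), the bin index of `y_tilde` in the cutoffs (ordinal, values
#' `0..K-1`), or 1 iff `(y_tilde - mu_j)/sigma > qnorm(1 - pi_E_j)`
#' (binary). Uses the ambient RNG.
#'
#' @param scenario a [bqd_scenario()].
#' @param dose dose index.
#' @param n number of patients to draw.
#' @return tibble with columns `toxicity` (0/1) and `efficacy`.
#' @export
draw_outcomes <- function(scenario, dose, n = 1) {
  stopifnot(inherits(scenario, "bqd_scenario"),
            dose >= 1, dose <= scenario$J, n >= 0)
  if (n == 0) return(tibble(toxicity = integer(), efficacy = numeric()))
  rho <- scenario$rho; sigma <- scenario$sigma
  x_lat <- rnorm(n)
  u <- rho * x_lat + sqrt(1 - rho^2) * rnorm(n)  # standardized efficacy latent
  tox <- as.integer(x_lat > qnorm(1 - scenario$tox[dose]))
  eff <- switch(scenario$endpoint_type,
    continuous = scenario$latent_mu[dose] + sigma * u,
    ordinal = {
      if (is.null(scenario$cutoffs))
        abort("ordinal scenario has no cutoffs; see calibrate_ordinal_cutoffs()")
      y_lat <- scenario$latent_mu[dose] + sigma * u
      as.numeric(findInterval(y_lat, scenario$cutoffs, left.open = TRUE))
    },
    binary = as.numeric(u > qnorm(1 - scenario$eff[dose]))
  )
  tibble(toxicity = tox, efficacy = eff)
}

#' Built-in scenario library
#'
#' The library holds 10 continuous, 6 ordinal and 6 binary five-arm
#' scenarios spanning dose–efficacy and dose–toxicity curves with different
#' MED/MUD locations, plus a flat null scenario (all means 0.2, all toxicity
#' rates 0.05) used to calibrate the proof-of-concept cutoff. Ordinal and
#' binary scenarios share the latent efficacy curves of the continuous ones
#' they were built from (`meta$source`); ordinal scenarios need user-supplied
#' bin cutoffs before outcomes can be generated. All scenarios use
#' `rho = 0.3`, `sigma = 1`. Metadata records the utility weight and the
#' MED target difference implied by each table (`meta$w_implied`,
#' `meta$delta_implied`), which differ across endpoint types.
#'
#' @return named list of [bqd_scenario()] objects with names
#'   `continuous/s1` ... `continuous/s10`, `ordinal/s1` ... `ordinal/s6`,
#'   `binary/s1` ... `binary/s6`, and `null/continuous`.
#' @examples
#' names(builtin_scenarios())
#' get_scenario("continuous/s1")
#' @export
builtin_scenarios <- function() {
  cont_eff <- list(
    s1 = c(0.20, 0.57, 0.70, 0.76, 0.80),
    s2 = c(0.20, 0.44, 0.57, 0.67, 0.75),
    s3 = c(0.20, 0.21, 0.58, 0.77, 0.77),
    s4 = c(0.20, 0.20, 0.20, 0.22, 0.60),
    s5 = c(0.20, 0.34, 0.68, 0.76, 0.78),
    s6 = c(0.20, 0.21, 0.72, 0.75, 0.80),
    s7 = c(0.20, 0.24, 0.41, 0.68, 0.78),
    s8 = c(0.20, 0.23, 0.32, 0.65, 0.79),
    s9 = c(0.20, 0.23, 0.25, 0.72, 0.80),
    s10 = c(0.20, 0.20, 0.22, 0.54, 0.80)
  )
  cont_tox <- list(
    s1 = c(0.05, 0.10, 0.11, 0.30, 0.34),
    s2 = c(0.05, 0.07, 0.22, 0.34, 0.45),
    s3 = c(0.05, 0.10, 0.18, 0.20, 0.45),
    s4 = c(0.05, 0.06, 0.08, 0.10, 0.24),
    s5 = c(0.05, 0.12, 0.14, 0.35, 0.45),
    s6 = c(0.05, 0.06, 0.15, 0.24, 0.28),
    s7 = c(0.05, 0.06, 0.10, 0.12, 0.32),
    s8 = c(0.05, 0.08, 0.10, 0.32, 0.45),
    s9 = c(0.05, 0.06, 0.08, 0.15, 0.34),
    s10 = c(0.05, 0.06, 0.08, 0.18, 0.20)
  )
  ord_eff <- list(
    s1 = c(0.80, 1.55, 1.80, 1.92, 2.00),
    s2 = c(0.80, 0.83, 1.56, 1.93, 1.94),
    s3 = c(0.80, 0.80, 0.80, 0.83, 1.60),
    s4 = c(0.80, 1.08, 1.76, 1.92, 1.96),
    s5 = c(0.80, 0.87, 1.22, 1.75, 1.95),
    s6 = c(0.80, 0.86, 1.04, 1.70, 1.98)
  )
  bin_eff <- list(
    s1 = c(0.20, 0.39, 0.45, 0.48, 0.50),
    s2 = c(0.20, 0.21, 0.39, 0.48, 0.48),
    s3 = c(0.20, 0.20, 0.20, 0.21, 0.40),
    s4 = c(0.20, 0.27, 0.44, 0.48, 0.49),
    s5 = c(0.20, 0.22, 0.30, 0.44, 0.49),
    s6 = c(0.20, 0.22, 0.26, 0.43, 0.50)
  )
  # ordinal/binary scenarios reuse the toxicity and latent efficacy curves
  # of these continuous scenarios, in order
  source_cont <- c("s1", "s3", "s4", "s5", "s7", "s8")

  label <- function(eff, tox, w, delta) {
    trt <- seq_along(eff)[-1]
    u <- eff - w * tox
    list(med = trt[which.min(abs(eff[trt] - (eff[1] + delta)))],
         mud = trt[which.max(u[trt])])
  }

  lib <- list()
  for (s in names(cont_eff)) {
    lab <- label(cont_eff[[s]], cont_tox[[s]], w = 2, delta = 0.4)
    lib[[paste0("continuous/", s)]] <- bqd_scenario(
      "continuous", tox = cont_tox[[s]], eff = cont_eff[[s]],
      true_med = lab$med, true_mud = lab$mud,
      name = paste0("continuous/", s),
      meta = list(w_implied = 2, delta_implied = 0.4))
  }
  for (i in seq_along(ord_eff)) {
    s <- names(ord_eff)[i]; src <- source_cont[i]
    lab <- label(ord_eff[[s]], cont_tox[[src]], w = 4, delta = 0.75)
    lib[[paste0("ordinal/", s)]] <- bqd_scenario(
      "ordinal", tox = cont_tox[[src]], eff = ord_eff[[s]],
      latent_mu = cont_eff[[src]],
      true_med = lab$med, true_mud = lab$mud,
      name = paste0("ordinal/", s),
      meta = list(w_implied = 4, delta_implied = 0.75, source = src))
  }
  for (i in seq_along(bin_eff)) {
    s <- names(bin_eff)[i]; src <- source_cont[i]
    lab <- label(bin_eff[[s]], cont_tox[[src]], w = 1, delta = 0.2)
    lib[[paste0("binary/", s)]] <- bqd_scenario(
      "binary", tox = cont_tox[[src]], eff = bin_eff[[s]],
      latent_mu = cont_eff[[src]],
      true_med = lab$med, true_mud = lab$mud,
      name = paste0("binary/", s),
      meta = list(w_implied = 1, delta_implied = 0.2, source = src))
  }
  lib[["null/continuous"]] <- bqd_scenario(
    "continuous", tox = rep(0.05, 5), eff = rep(0.20, 5),
    name = "null/continuous", meta = list(null = TRUE))
  lib
}

#' @rdname builtin_scenarios
#' @param name scenario name, e.g. `"continuous/s1"` or `"null/continuous"`.
#' @export
get_scenario <- function(name) {
  lib <- builtin_scenarios()
  if (!name %in% names(lib))
    abort(paste0("unknown scenario '", name, "'; see names(builtin_scenarios())"))
  lib[[name]]
}

#' Read or write a scenario as YAML
#'
#' @param path file path.
#' @return `read_scenario()` returns a [bqd_scenario()]; `write_scenario()`
#'   returns `path` invisibly.
#' @export
read_scenario <- function(path) {
  v <- yaml::read_yaml(path)
  bqd_scenario(endpoint_type = v$endpoint_type, tox = v$tox, eff = v$eff,
               rho = v$rho %||% 0.3, sigma = v$sigma %||% 1,
               cutoffs = v$cutoffs, latent_mu = v$latent_mu,
               true_med = v$true_med, true_mud = v$true_mud,
               name = v$name, meta = v$meta %||% list())
}

#' @rdname read_scenario
#' @param scenario a [bqd_scenario()].
#' @export
write_scenario <- function(scenario, path) {
  stopifnot(inherits(scenario, "bqd_scenario"))
  yaml::write_yaml(unclass(scenario), path)
  invisible(path)
}

#' Search ordinal bin cutoffs matching target per-dose means
#'
#' Finds a single shared, strictly increasing cutoff vector
#' `gamma_1 < ... < gamma_{K-1}` such that binning the latent normal
#' efficacy variable at each dose approximates the target ordinal means:
#' the mean of the binned outcome at dose `j` is
#' `sum_k (1 - pnorm((gamma_k - mu_j)/sigma))`, and the squared error to the
#' targets is minimized by Nelder–Mead over an increasing parametrization.
#' The fit is approximate — one shared cutoff vector generally cannot hit
#' every target mean exactly.
#'
#' @param target_means length-J target ordinal means (on the `0..K-1` scale).
#' @param latent_mu length-J latent efficacy means.
#' @param sigma latent efficacy standard deviation.
#' @param K number of ordinal categories (values `0..K-1`).
#' @return numeric vector of `K - 1` increasing cutoffs, with the achieved
#'   means in attribute `achieved`.
#' @examples
#' calibrate_ordinal_cutoffs(c(0.8, 1.55, 1.8), c(0.2, 0.57, 0.7), 1, K = 5)
#' @export
calibrate_ordinal_cutoffs <- function(target_means, latent_mu, sigma = 1,
                                      K = 5) {
  stopifnot(length(target_means) == length(latent_mu), K >= 2,
            all(target_means >= 0), all(target_means <= K - 1))
  means_for <- function(g)
    vapply(latent_mu,
           function(m) sum(1 - pnorm((g - m) / sigma)), numeric(1))
  # increasing parametrization: gamma_1 = p[1], increments exp(p[-1]) with a
  # floor keeping the cutoffs strictly increasing even when the optimizer
  # pushes an increment to zero
  to_gamma <- function(p) cumsum(c(p[1], 1e-6 + exp(p[-1])))
  obj <- function(p) sum((means_for(to_gamma(p)) - target_means)^2)
  p0 <- c(min(latent_mu), rep(log(diff(range(c(latent_mu - 2 * sigma,
                                               latent_mu + 2 * sigma))) /
                                   (K - 1)), K - 2))
  fit <- optim(p0, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-10))
  g <- to_gamma(fit$par)
  structure(g, achieved = means_for(g))
}

#' Plot a scenario's true dose–toxicity, dose–efficacy and utility curves
#'
#' @param object a [bqd_scenario()].
#' @param w utility weight; defaults to the scenario's implied weight or 2.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.bqd_scenario <- function(object, w = NULL, ...) {
  w <- w %||% object$meta$w_implied %||% 2
  df <- tibble(
    dose = rep(seq_len(object$J), 3),
    curve = rep(c("toxicity", "efficacy", "utility"), each = object$J),
    value = c(object$tox, object$eff, object$eff - w * object$tox)
  )
  ggplot(df, aes(x = .data$dose, y = .data$value, colour = .data$curve)) +
    geom_line() + geom_point() +
    labs(title = object$name, x = "dose index", y = NULL, colour = NULL) +
    theme_minimal()
}
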