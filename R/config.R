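#' Design configuration for a BQD trial
#'
#' Collects every decision parameter of the Bayesian quasi-likelihood
#' dose-ranging design: the number of arms, the safety/futility/PoC cutoffs,
#' the utility weights, the adaptive-randomization weights, the stage sizes,
#' the conjugate priors and the Monte-Carlo settings.
#'
#' @param J number of arms including the placebo/control (arm 1). Must be
#'   at least 2.
#' @param delta clinically relevant efficacy difference over placebo used to
#'   define the minimum effective dose (MED): the MED targets mean efficacy
#'   `mu_1 + delta`.
#' @param pi_bar highest acceptable increase of the toxicity rate over
#'   placebo; doses with posterior probability at least `CT` of exceeding
#'   `pi_1 + pi_bar` are dropped.
#' @param CT,CE,CPoC probability cutoffs in (0, 1) for the safety rule, the
#'   futility rule and the proof-of-concept test. `CPoC` should be calibrated
#'   with [calibrate_cpoc()] to control the familywise type I error; the
#'   default is a placeholder.
#' @param w toxicity penalty of the simple utility `U = mu - w * pi`.
#' @param w1,w2,rho_utility parameters of the extended utility
#'   `U = mu - w1*pi - w2*pi*I(pi > rho_utility)`. Supplying `w2` switches
#'   the design to the extended form (`w` is then ignored).
#' @param tau weight in \[0, 1\] balancing MED-targeting (`tau = 1`) against
#'   MUD-targeting (`tau = 0`) adaptive randomization.
#' @param nu adaptiveness exponent (`nu = 0` gives equal randomization among
#'   admissible arms).
#' @param stage_sizes integer vector `c(c_1, ..., c_S)` of per-stage cohort
#'   sizes; stage 1 is equally randomized, later stages adaptively.
#' @param prior_tox,prior_eff length-2 positive vectors `(alpha, beta)` of
#'   the Beta priors for toxicity and (per toxicity stratum) standardized
#'   efficacy. Vague `Beta(1, 1)` by default.
#' @param n_draws number of Monte-Carlo posterior draws per analysis.
#' @param isotonic_toxicity,isotonic_efficacy apply the weighted isotonic
#'   transform to toxicity draws / marginal efficacy draws.
#' @param require_mud_ge_med restrict the maximum utility dose to be at or
#'   above the selected MED.
#'
#' @return an object of class `bqd_config` (a named list).
#' @examples
#' cfg <- bqd_config()
#' cfg$stage_sizes
#' @export
bqd_config <- function(J = 5,
                       delta = 0.4,
                       pi_bar = 0.3,
                       CT = 0.9,
                       CE = 0.7,
                       CPoC = 0.95,
                       w = 2,
                       w1 = NULL,
                       w2 = NULL,
                       rho_utility = NULL,
                       tau = 0.5,
                       nu = 1,
                       stage_sizes = c(100, 25, 25, 25, 25),
                       prior_tox = c(1, 1),
                       prior_eff = c(1, 1),
                       n_draws = 4000,
                       isotonic_toxicity = TRUE,
                       isotonic_efficacy = TRUE,
                       require_mud_ge_med = FALSE) {
  cfg <- list(
    J = as.integer(J), delta = delta, pi_bar = pi_bar,
    CT = CT, CE = CE, CPoC = CPoC,
    w = w, w1 = w1, w2 = w2, rho_utility = rho_utility,
    tau = tau, nu = nu,
    stage_sizes = as.integer(stage_sizes),
    prior_tox = as.numeric(prior_tox), prior_eff = as.numeric(prior_eff),
    n_draws = as.integer(n_draws),
    isotonic_toxicity = isTRUE(isotonic_toxicity),
    isotonic_efficacy = isTRUE(isotonic_efficacy),
    require_mud_ge_med = isTRUE(require_mud_ge_med)
  )
  class(cfg) <- "bqd_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$J >= 2,
    length(cfg$stage_sizes) >= 1, all(cfg$stage_sizes > 0),
    cfg$CT > 0, cfg$CT < 1, cfg$CE > 0, cfg$CE < 1,
    cfg$CPoC > 0, cfg$CPoC <= 1,
    cfg$tau >= 0, cfg$tau <= 1, cfg$nu >= 0,
    length(cfg$prior_tox) == 2, all(cfg$prior_tox > 0),
    length(cfg$prior_eff) == 2, all(cfg$prior_eff > 0),
    cfg$n_draws >= 1
  )
  if (!is.null(cfg$w2) && is.null(cfg$rho_utility))
    abort("`rho_utility` must be supplied with the extended utility (`w2`)")
  invisible(cfg)
}

#' @export
print.bqd_config <- function(x, ...) {
  cat("<bqd_config>\n")
  cat("  arms:", x$J, " stages:", paste(x$stage_sizes, collapse = "/"), "\n")
  cat("  delta:", x$delta, " pi_bar:", x$pi_bar, "\n")
  cat("  cutoffs: CT =", x$CT, " CE =", x$CE, " CPoC =", x$CPoC, "\n")
  if (is.null(x$w2)) {
    cat("  utility: U = mu -", x$w, "* pi\n")
  } else {
    cat("  utility: U = mu -", x$w1, "* pi -", x$w2,
        "* pi * I(pi >", x$rho_utility, ")\n")
  }
  cat("  randomization: tau =", x$tau, " nu =", x$nu, "\n")
  cat("  posterior draws:", x$n_draws, "\n")
  invisible(x)
}

#' Read or write a design configuration as YAML
#'
#' Keys mirror the arguments of [bqd_config()]; unknown keys are rejected.
#'
#' @param path file path.
#' @return `read_config()` returns a [bqd_config()]; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(bqd_config))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    abort(paste("unknown config keys:", paste(extra, collapse = ", ")))
  vals[vapply(vals, is.null, logical(1))] <- NULL
  do.call(bqd_config, vals)
}

#' @rdname read_config
#' @param config a [bqd_config()].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "bqd_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
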