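#' Equal randomization of a cohort across arms
#'
#' Splits `c` patients across `J` arms as evenly as possible: every arm
#' receives `floor(c/J)` patients and the remainder is assigned to arms
#' chosen uniformly at random, so counts differ by at most one and sum to
#' `c`. Uses the ambient RNG.
#'
#' @param c cohort size.
#' @param J number of arms.
#' @return integer vector of per-arm counts.
#' @examples
#' set.seed(1); allocate_equally(102, 5)
#' @export
allocate_equally <- function(c, J) {
  stopifnot(c >= 1, J >= 1)
  counts <- rep(c %/% J, J)
  r <- c %% J
  if (r > 0) {
    extra <- sample.int(J, r)
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

#' Conduct one group-sequential BQD trial
#'
#' Runs the full adaptive design against a scenario (simulated outcomes) or
#' a user-supplied outcome source. Stage 1 equally randomizes `c_1` patients
#' across all arms. At each later stage the posteriors are updated from all
#' accumulated data, the admissible set is refreshed, and the next cohort is
#' assigned by independent multinomial draws from the adaptive
#' randomization probabilities; if no dose is admissible the trial stops
#' early and no MED or MUD is selected. At the final analysis the
#' proof-of-concept test is run and, when it succeeds, the MED and MUD are
#' selected among the admissible doses.
#'
#' Randomness is split into two reproducible substreams derived from `seed`
#' — one for patient outcomes, one for posterior sampling — so results are
#' identical for identical inputs.
#'
#' @param scenario a [bqd_scenario()] with `J == config$J`, or `NULL` when
#'   `outcome_fn` is given.
#' @param config a [bqd_config()].
#' @param seed optional integer seed.
#' @param outcome_fn optional function `(dose, n)` returning a data frame
#'   with columns `toxicity` and `efficacy` for `n` patients at `dose`;
#'   used in place of a scenario. `endpoint_type` and `bounds` then describe
#'   the endpoint.
#' @param endpoint_type,bounds endpoint metadata when `outcome_fn` is used;
#'   taken from the scenario otherwise.
#' @return an object of class `bqd_trial`: patient-level data, per-stage
#'   enrollment and interim summaries, the final analysis, and the headline
#'   decisions (`poc_established`, `med`, `mud`, `stopped_early`,
#'   `stop_stage`, `poc_statistic`).
#' @examples
#' tr <- run_trial(get_scenario("continuous/s1"),
#'                 bqd_config(n_draws = 500), seed = 1)
#' glance(tr)
#' @export
run_trial <- function(scenario, config, seed = NULL, outcome_fn = NULL,
                      endpoint_type = NULL, bounds = NULL) {
  stopifnot(inherits(config, "bqd_config"))
  if (is.null(outcome_fn)) {
    stopifnot(inherits(scenario, "bqd_scenario"), scenario$J == config$J)
    endpoint_type <- scenario$endpoint_type
    bounds <- switch(endpoint_type,
                     binary = c(0, 1),
                     ordinal = c(0, length(scenario$cutoffs)),
                     continuous = NULL)
    outcome_fn <- function(dose, n) draw_outcomes(scenario, dose, n)
  } else {
    endpoint_type <- match.arg(endpoint_type,
                               c("continuous", "ordinal", "binary"))
  }
  J <- config$J
  S <- length(config$stage_sizes)
  s_out <- new_rng_stream(seed, stream = 1L)
  s_post <- new_rng_stream(seed, stream = 2L)

# plain vectors in the hot loop; tibbles are built once at the end
  enroll_stage <- function(counts, stage) {
    arms <- which(counts > 0)
    outs <- lapply(arms, function(j) with_stream(s_out, outcome_fn(j, counts[j])))
    list(stage = rep(stage, sum(counts[arms])),
         dose_index = rep(arms, counts[arms]),
         toxicity = unlist(lapply(outs, `[[`, "toxicity"), use.names = FALSE),
         efficacy = unlist(lapply(outs, `[[`, "efficacy"), use.names = FALSE))
  }
  append_records <- function(records, new) {
    list(stage = c(records$stage, new$stage),
         dose_index = c(records$dose_index, new$dose_index),
         toxicity = c(records$toxicity, new$toxicity),
         efficacy = c(records$efficacy, new$efficacy))
  }

  as_data <- function(records)
    bqd_data(tibble(dose_index = records$dose_index,
                    toxicity = records$toxicity,
                    efficacy = records$efficacy),
             endpoint_type, bounds = bounds, J = J)

  counts1 <- with_stream(s_out, allocate_equally(config$stage_sizes[1], J))
  records <- enroll_stage(counts1, 1L)
  stage_counts <- matrix(0L, S, J)
  stage_counts[1, ] <- counts1
  interims <- list()
  stopped_early <- FALSE
  stop_stage <- NA_integer_

  k <- 2L
  while (k <= S) {
    draws <- with_stream(s_post, sample_posterior(as_data(records), config))
    A <- admissible_set(draws, config)
    interims[[length(interims) + 1L]] <-
      list(stage = k, n_admissible = length(A), admissible = as.integer(A))
    if (length(A) == 0) {
      stopped_early <- TRUE
      stop_stage <- k
      break
    }
    tp <- target_dose_probabilities(draws, A, config)
    pr <- randomization_probabilities(tp$p1, tp$p2, A, config)
    ck <- with_stream(s_out,
                      as.integer(rmultinom(1, config$stage_sizes[k], pr)))
    stage_counts[k, ] <- ck
    records <- append_records(records, enroll_stage(ck, k))
    k <- k + 1L
  }

  data <- as_data(records)
  final <- NULL
  poc_established <- FALSE
  poc_statistic <- NA_real_
  med <- mud <- NA_integer_
  if (!stopped_early) {
    draws <- with_stream(s_post, sample_posterior(data, config))
    A <- admissible_set(draws, config)
    poc <- poc_test(draws, config)
    poc_established <- poc[1]
    poc_statistic <- attr(poc, "statistic")
    if (poc_established && length(A)) {
      med <- select_med(draws, A, config)
      mud <- select_mud(draws, A, config,
                        min_dose = if (config$require_mud_ge_med) med)
    }
    final <- list(A = as.integer(A), poc_prob = attr(poc, "prob"),
                  pi_hat = colMeans(draws$pi), mu_hat = colMeans(draws$mu),
                  utility = colMeans(compute_utility(draws$mu, draws$pi,
                                                     config)))
  }
  n_total <- length(records$dose_index)
  out <- list(
    data = tibble(patient_id = seq_len(n_total),
                  stage = records$stage,
                  dose_index = records$dose_index,
                  toxicity = records$toxicity,
                  efficacy = records$efficacy),
    arm_counts = colSums(stage_counts),
    stage_counts = stage_counts,
    interims = if (length(interims))
      tibble(stage = vapply(interims, `[[`, integer(1), "stage"),
             n_admissible = vapply(interims, `[[`, integer(1), "n_admissible"),
             admissible = lapply(interims, `[[`, "admissible"))
      else tibble(),
    final = final,
    poc_established = poc_established,
    poc_statistic = poc_statistic,
    med = med, mud = mud,
    stopped_early = stopped_early, stop_stage = stop_stage,
    n_enrolled = n_total,
    config = config, seed = seed,
    scenario_name = if (!is.null(scenario)) scenario$name else NULL
  )
  class(out) <- "bqd_trial"
  out
}

#' @export
print.bqd_trial <- function(x, ...) {
  cat("<bqd_trial>", x$scenario_name %||% "", "\n")
  cat("  enrolled:", x$n_enrolled, "patients, per arm:",
      paste(x$arm_counts, collapse = "/"), "\n")
  if (x$stopped_early) {
    cat("  stopped early at stage", x$stop_stage,
        "(no admissible dose)\n")
  } else {
    cat("  PoC:", if (x$poc_established) "established" else "not established",
        sprintf("(statistic %.3f)\n", x$poc_statistic))
    if (!is.na(x$med)) cat("  MED: dose", x$med, "  MUD: dose", x$mud, "\n")
  }
  invisible(x)
}

#' Patient-level records of a trial
#'
#' @param x a `bqd_trial`.
#' @param ... unused.
#' @return tibble with one row per enrolled patient: `patient_id`, `stage`,
#'   `dose_index`, `toxicity`, `efficacy`.
#' @export
tidy.bqd_trial <- function(x, ...) x$data

#' One-row summary of a trial
#'
#' @param x a `bqd_trial`.
#' @param ... unused.
#' @return one-row tibble with the decisions and enrollment totals.
#' @export
glance.bqd_trial <- function(x, ...) {
  tibble(poc_established = x$poc_established,
         poc_statistic = x$poc_statistic,
         med = x$med, mud = x$mud,
         stopped_early = x$stopped_early, stop_stage = x$stop_stage,
         n_enrolled = x$n_enrolled)
}

#' Plot per-arm enrollment by stage
#'
#' @param object a `bqd_trial`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.bqd_trial <- function(object, ...) {
  df <- object$data %>% count(.data$stage, .data$dose_index)
  ggplot(df, aes(x = factor(.data$dose_index), y = .data$n,
                 fill = factor(.data$stage))) +
    geom_col() +
    labs(x = "dose index", y = "patients enrolled", fill = "stage") +
    theme_minimal()
}

#' Write a trial result to disk
#'
#' Writes `trial.json` (decisions, per-arm counts, interim admissible sets)
#' and `patients.csv` (patient-level records) into `dir`.
#'
#' @param trial a `bqd_trial`.
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "bqd_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- list(
    poc_established = trial$poc_established,
    poc_statistic = trial$poc_statistic,
    med = if (is.na(trial$med)) NULL else trial$med,
    mud = if (is.na(trial$mud)) NULL else trial$mud,
    stopped_early = trial$stopped_early,
    stop_stage = if (is.na(trial$stop_stage)) NULL else trial$stop_stage,
    n_enrolled = trial$n_enrolled,
    arm_counts = as.integer(trial$arm_counts),
    scenario = trial$scenario_name
  )
  jsonlite::write_json(rec, file.path(dir, "trial.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(trial$data, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  invisible(dir)
}
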