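#' Monte-Carlo operating characteristics of the BQD design
#'
#' Simulates `n_sim` independent trials under a scenario and aggregates the
#' design's operating characteristics: the proof-of-concept rate (the power,
#' or the familywise type I error under a null scenario), the probabilities
#' of correctly selecting the true MED and MUD, the early-stop rate, and the
#' mean fraction of the planned sample size allocated to each arm.
#'
#' Correct-selection rates use all simulated trials as the denominator:
#' trials that stop early or fail to establish PoC count as incorrect.
#' Per-trial seeds are derived from `seed` independently of execution order.
#'
#' @param scenario a [bqd_scenario()]; supply `true_med`/`true_mud` labels
#'   for the correct-selection metrics.
#' @param config a [bqd_config()] (with a calibrated `CPoC`).
#' @param n_sim number of simulated trials.
#' @param seed optional master seed.
#' @return an object of class `bqd_oc` with a one-row `summary` tibble, the
#'   per-trial `trials` tibble, and mean `allocation` fractions.
#' @examples
#' oc <- simulate_oc(get_scenario("continuous/s1"),
#'                   bqd_config(n_draws = 500, CPoC = 0.95),
#'                   n_sim = 5, seed = 1)
#' glance(oc)
#' @export
simulate_oc <- function(scenario, config, n_sim, seed = NULL) {
  stopifnot(inherits(scenario, "bqd_scenario"),
            inherits(config, "bqd_config"), n_sim >= 0)
  N <- sum(config$stage_sizes)
  seeds <- derive_seeds(seed, n_sim)
  trials <- purrr::map_dfr(seq_len(n_sim), function(i) {
    tr <- run_trial(scenario, config, seed = seeds[[i]])
    tibble(trial = i,
           poc_established = tr$poc_established,
           poc_statistic = tr$poc_statistic,
           med = tr$med, mud = tr$mud,
           stopped_early = tr$stopped_early,
           n_enrolled = tr$n_enrolled,
           alloc = list(as.numeric(tr$arm_counts) / N))
  })
  if (n_sim == 0) {
    alloc <- rep(0, config$J)
    summary <- tibble(n_sim = 0L, poc_rate = 0, pcs_med = 0, pcs_mud = 0,
                      early_stop_rate = 0, mean_enrolled = 0)
  } else {
    alloc <- colMeans(do.call(rbind, trials$alloc))
    summary <- tibble(
      n_sim = as.integer(n_sim),
      poc_rate = mean(trials$poc_established),
      pcs_med = if (is.null(scenario$true_med)) NA_real_ else
        mean(!is.na(trials$med) & trials$med == scenario$true_med),
      pcs_mud = if (is.null(scenario$true_mud)) NA_real_ else
        mean(!is.na(trials$mud) & trials$mud == scenario$true_mud),
      early_stop_rate = mean(trials$stopped_early),
      mean_enrolled = mean(trials$n_enrolled)
    )
  }
  out <- list(summary = summary, trials = trials, allocation = alloc,
              scenario = scenario, config = config, seed = seed)
  class(out) <- "bqd_oc"
  out
}

#' @export
print.bqd_oc <- function(x, ...) {
  cat("<bqd_oc>", x$scenario$name %||% "", "—", x$summary$n_sim,
      "simulated trials\n")
  print(x$summary, ...)
  cat("  mean allocation fractions:",
      paste(sprintf("%.3f", x$allocation), collapse = " "), "\n")
  invisible(x)
}

#' Per-trial operating-characteristic records
#'
#' @param x a `bqd_oc`.
#' @param ... unused.
#' @return tibble with one row per simulated trial.
#' @export
tidy.bqd_oc <- function(x, ...) x$trials %>% select(-"alloc")

#' One-row operating-characteristics summary
#'
#' @param x a `bqd_oc`.
#' @param ... unused.
#' @return one-row tibble: `n_sim`, `poc_rate`, `pcs_med`, `pcs_mud`,
#'   `early_stop_rate`, `mean_enrolled`.
#' @export
glance.bqd_oc <- function(x, ...) x$summary

#' Write an operating-characteristics summary to disk
#'
#' Writes `oc.json` (summary plus allocation) and a tidy `oc.csv` with one
#' row per scenario-metric pair.
#'
#' @param oc a `bqd_oc`.
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_oc <- function(oc, dir) {
  stopifnot(inherits(oc, "bqd_oc"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- c(as.list(oc$summary), list(allocation = oc$allocation,
                                     scenario = oc$scenario$name))
  jsonlite::write_json(rec, file.path(dir, "oc.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  long <- tidyr::pivot_longer(oc$summary, cols = -"n_sim",
                              names_to = "metric", values_to = "value") %>%
    mutate(scenario = oc$scenario$name %||% NA_character_)
  utils::write.csv(long, file.path(dir, "oc.csv"), row.names = FALSE)
  invisible(dir)
}

#' Plot operating characteristics
#'
#' Bars for the headline rates and the mean per-arm allocation fractions.
#'
#' @param object a `bqd_oc`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.bqd_oc <- function(object, ...) {
  rates <- tidyr::pivot_longer(object$summary,
                               cols = c("poc_rate", "pcs_med", "pcs_mud",
                                        "early_stop_rate"),
                               names_to = "metric", values_to = "value")
  alloc <- tibble(metric = paste0("alloc_arm", seq_along(object$allocation)),
                  value = object$allocation)
  df <- bind_rows(rates %>% select("metric", "value"), alloc)
  ggplot(df, aes(x = .data$metric, y = .data$value)) +
    geom_col(fill = "steelblue") +
    labs(title = object$scenario$name, x = NULL, y = "rate / fraction") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Calibrate the proof-of-concept cutoff on a null scenario
#'
#' Simulates `n_sim` trials under a no-effect (flat efficacy) scenario,
#' records each trial's final test statistic — the maximum over treatment
#' arms of the posterior probability `Pr(mu_j > mu_1 | D)` (zero for trials
#' stopped early, which can never reject) — and returns the empirical
#' `1 - target_error` quantile of that statistic. Rejecting whenever any
#' arm's posterior probability exceeds the returned cutoff then has
#' familywise type I error close to `target_error` under the null. A single
#' simulation pass suffices because the rejection rule is monotone in the
#' cutoff.
#'
#' @param null_scenario a flat-curve [bqd_scenario()], e.g.
#'   `get_scenario("null/continuous")`.
#' @param config a [bqd_config()] (its `CPoC` is ignored during
#'   calibration).
#' @param target_error target familywise type I error rate in (0, 1).
#' @param n_sim number of calibration trials.
#' @param seed optional master seed.
#' @return an object of class `bqd_calibration`: the calibrated `cpoc`, the
#'   per-trial `statistics`, `target_error` and `n_sim`.
#' @examples
#' cal <- calibrate_cpoc(get_scenario("null/continuous"),
#'                       bqd_config(n_draws = 500, stage_sizes = c(40, 10)),
#'                       n_sim = 20, seed = 1)
#' cal$cpoc
#' @export
calibrate_cpoc <- function(null_scenario, config, target_error = 0.05,
                           n_sim = 2000, seed = NULL) {
  stopifnot(target_error > 0, target_error < 1, n_sim >= 1)
  seeds <- derive_seeds(seed, n_sim)
  stats <- vapply(seq_len(n_sim), function(i) {
    tr <- run_trial(null_scenario, config, seed = seeds[[i]])
    if (tr$stopped_early) 0 else tr$poc_statistic
  }, numeric(1))
  if (length(unique(stats)) == 1L)
    warn("degenerate calibration: all per-trial statistics are identical")
  cpoc <- unname(quantile(stats, probs = 1 - target_error, type = 1))
  out <- list(cpoc = cpoc, statistics = stats,
              target_error = target_error, n_sim = as.integer(n_sim),
              seed = seed)
  class(out) <- "bqd_calibration"
  out
}

#' @export
print.bqd_calibration <- function(x, ...) {
  cat("<bqd_calibration> CPoC =", format(x$cpoc),
      sprintf("(target familywise error %.3f, %d null trials)\n",
              x$target_error, x$n_sim))
  cat("  null rejection rate at this cutoff:",
      format(mean(x$statistics > x$cpoc)), "\n")
  invisible(x)
}
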