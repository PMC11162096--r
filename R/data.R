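#' Assemble patient-level trial data
#'
#' Validates a data frame of accumulated patient records — one row per
#' patient with the assigned dose, the binary toxicity outcome and the
#' efficacy outcome on its original scale — and attaches the endpoint
#' metadata the quasi-likelihood model needs.
#'
#' @param records data frame with columns `dose_index` (integer, 1-based;
#'   arm 1 is placebo/control), `toxicity` (0/1) and `efficacy` (numeric).
#'   Extra columns (e.g. `patient_id`, `stage`) are kept.
#' @param endpoint_type `"continuous"`, `"ordinal"` or `"binary"`.
#' @param bounds declared `(lower, upper)` endpoint boundaries. Required for
#'   bounded endpoints; defaults to `c(0, 1)` for binary and `c(0, 4)` for
#'   ordinal. Ignored (left `NULL`) for continuous endpoints, whose bounds
#'   are the per-dose observed minima/maxima at analysis time.
#' @param J number of arms; defaults to the largest dose index present.
#'
#' @return a tibble of class `bqd_data` with attributes `endpoint_type`,
#'   `bounds` and `J`.
#' @examples
#' df <- tibble::tibble(dose_index = c(1, 1, 2, 2),
#'                      toxicity = c(0, 0, 0, 1),
#'                      efficacy = c(0.1, 0.4, 0.8, 0.5))
#' bqd_data(df, "continuous", J = 2)
#' @export
bqd_data <- function(records,
                     endpoint_type = c("continuous", "ordinal", "binary"),
                     bounds = NULL,
                     J = NULL) {
  endpoint_type <- match.arg(endpoint_type)
  records <- as_tibble(records)
  need <- c("dose_index", "toxicity", "efficacy")
  miss <- setdiff(need, names(records))
  if (length(miss))
    abort(paste("missing columns:", paste(miss, collapse = ", ")))
  if (is.null(J)) J <- max(records$dose_index, 1L)
  J <- as.integer(J)
  if (nrow(records)) {
    stopifnot(
      all(records$dose_index >= 1), all(records$dose_index <= J),
      all(records$toxicity %in% c(0, 1)),
      all(is.finite(records$efficacy))
    )
  }
  if (is.null(bounds)) {
    bounds <- switch(endpoint_type,
                     binary = c(0, 1), ordinal = c(0, 4), continuous = NULL)
  }
  if (!is.null(bounds)) {
    stopifnot(length(bounds) == 2, bounds[2] > bounds[1])
    if (endpoint_type != "continuous" && nrow(records) &&
        (any(records$efficacy < bounds[1]) || any(records$efficacy > bounds[2])))
      abort("efficacy values outside the declared endpoint bounds")
  }
  structure(records,
            endpoint_type = endpoint_type, bounds = bounds, J = J,
            class = c("bqd_data", class(records)))
}

#' Read patient-level data from a delimited text file
#'
#' Expects columns `patient_id`, `dose_index`, `toxicity`, `efficacy`
#' (1-based dose indices, UTF-8); delegates parsing to [utils::read.csv()]
#' and validation to [bqd_data()].
#'
#' @inheritParams bqd_data
#' @param path file path.
#' @param sep field separator, default comma.
#' @return a `bqd_data` tibble.
#' @export
read_patient_data <- function(path,
                              endpoint_type = c("continuous", "ordinal", "binary"),
                              bounds = NULL, J = NULL, sep = ",") {
  df <- utils::read.csv(path, sep = sep, fileEncoding = "UTF-8")
  bqd_data(df, endpoint_type = endpoint_type, bounds = bounds, J = J)
}

# Sufficient statistics per dose: n_j, m_j and, per toxicity stratum k,
# the patient count n_jk and pseudo-event sum s_jk of standardized efficacy.
# Bounds per dose: declared for bounded endpoints; observed per-dose min/max
# for continuous, falling back to the pooled range when a dose has fewer
# than two distinct values, and flagged degenerate when even the pooled
# range is a point.
dose_statistics <- function(data, J = attr(data, "J")) {
  endpoint <- attr(data, "endpoint_type")
  declared <- attr(data, "bounds")
  dose <- data$dose_index
  y <- data$efficacy
  x <- data$toxicity
  lower <- upper <- numeric(J)
  degenerate <- logical(J)
  if (!is.null(declared)) {
    lower[] <- declared[1]; upper[] <- declared[2]
  } else {
    pooled <- if (length(y)) range(y) else c(0, 0)
    for (j in seq_len(J)) {
      yj <- y[dose == j]
      if (length(unique(yj)) >= 2) {
        r <- range(yj)
      } else r <- pooled
      lower[j] <- r[1]; upper[j] <- r[2]
      degenerate[j] <- upper[j] <= lower[j]
    }
  }
  n <- tabulate(dose, nbins = J)
  m <- vapply(seq_len(J), function(j) sum(x[dose == j]), numeric(1))
  n_k <- s_k <- matrix(0, nrow = J, ncol = 2,
                       dimnames = list(NULL, c("k0", "k1")))
  for (j in seq_len(J)) {
    sel <- dose == j
    ystar <- if (degenerate[j]) rep(0.5, sum(sel)) else
      standardize_efficacy(y[sel], c(lower[j], upper[j]))
    for (k in 0:1) {
      sk <- sel & x == k
      n_k[j, k + 1] <- sum(sk)
      s_k[j, k + 1] <- sum(ystar[x[sel] == k])
    }
  }
  list(J = J, n = n, m = m, n_k = n_k, s_k = s_k,
       lower = lower, upper = upper, degenerate = degenerate,
       endpoint_type = endpoint)
}

#' Exact (Clopper–Pearson) binomial confidence interval
#'
#' The equal-tailed exact interval based on Beta quantiles, used when
#' appraising how little a handful of early-phase patients says about a
#' dose's toxicity rate: with 1 event in 6 patients the 95% interval spans
#' roughly 0.004 to 0.64.
#'
#' @param x number of events.
#' @param n number of trials.
#' @param conf_level confidence level, default 0.95.
#' @return one-row tibble with `estimate`, `lower`, `upper`, `conf_level`.
#' @examples
#' clopper_pearson(1, 6)
#' @export
clopper_pearson <- function(x, n, conf_level = 0.95) {
  stopifnot(n >= 1, x >= 0, x <= n, conf_level > 0, conf_level < 1)
  a <- (1 - conf_level) / 2
  lower <- if (x == 0) 0 else qbeta(a, x, n - x + 1)
  upper <- if (x == n) 1 else qbeta(1 - a, x + 1, n - x)
  tibble(estimate = x / n, lower = lower, upper = upper,
         conf_level = conf_level)
}
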