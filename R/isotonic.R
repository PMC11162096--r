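#' Weighted isotonic regression by pool-adjacent-violators
#'
#' Returns the non-decreasing vector minimizing the weighted squared error
#' to `values`. Adjacent violating blocks are pooled to their weighted
#' means, so the weighted mean is preserved within every pooled block.
#'
#' @param values finite numeric vector.
#' @param weights strictly positive weights of the same length; equal by
#'   default.
#' @return numeric vector of the same length, non-decreasing.
#' @examples
#' pava(c(0.3, 0.1))            # pools to (0.2, 0.2)
#' pava(c(0.3, 0.1), c(3, 1))   # weighted pooling
#' @export
pava <- function(values, weights = rep(1, length(values))) {
  if (length(weights) != length(values))
    abort("`values` and `weights` must have the same length")
  stopifnot(all(is.finite(values)), all(is.finite(weights)),
            all(weights > 0))
  if (length(values) <= 1) return(as.numeric(values))
  pava_fit(as.numeric(values), as.numeric(weights))
}

#' Isotonize a matrix of posterior draws row by row
#'
#' Applies weighted PAVA to every row (one posterior draw across doses)
#' using a single weight vector fixed across rows — by convention the
#' reciprocal posterior variances of the unconstrained draws. Every output
#' row is non-decreasing in the dose index, so monotonicity of the dose
#' response is imposed on the whole posterior, not just its mean.
#'
#' @param draws T-by-J numeric matrix of posterior draws.
#' @param weights strictly positive length-J weights; defaults to the
#'   reciprocal empirical column variances of `draws`.
#' @return T-by-J matrix with non-decreasing rows.
#' @examples
#' m <- matrix(rnorm(20), 5, 4)
#' all(diff(t(isotonize_draws(m))) >= 0)
#' @export
isotonize_draws <- function(draws, weights = draw_weights(draws)) {
  stopifnot(is.matrix(draws), all(is.finite(draws)),
            length(weights) == ncol(draws), all(weights > 0))
  if (ncol(draws) <= 1) return(draws)
  pava_rows_fit(draws, as.numeric(weights))
}
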