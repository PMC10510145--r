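# Evaluation statistics: mean squared error and the concordance index.

#' Mean squared error
#'
#' @param predictions,labels Equal-length numeric vectors.
#' @return Scalar mean of squared differences.
#' @export
mse <- function(predictions, labels) {
  if (length(predictions) != length(labels)) {
    rlang::abort("`predictions` and `labels` must have equal length",
                 class = "dtakit_error_input")
  }
  if (length(predictions) < 1L) {
    rlang::abort("need at least one observation", class = "dtakit_error_input")
  }
  mean((predictions - labels)^2)
}

#' Step function used by the concordance index
#'
#' Returns 1 for positive arguments, 0.5 at exactly zero, 0 for negative
#' arguments (vectorized).
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length.
#' @export
step_h <- function(x) {
  if (any(!is.finite(x))) {
    rlang::abort("`x` must be finite", class = "dtakit_error_input")
  }
  (x > 0) + 0.5 * (x == 0)
}

#' Concordance index
#'
#' Over every pair with strictly ordered labels, the fraction of pairs whose
#' predictions preserve the order; prediction ties count one half.  Label
#' ties contribute no pair.
#'
#' @param predictions Numeric vector of predicted affinities.
#' @param labels Numeric vector of observed affinities.
#' @return Scalar in [0, 1].
#' @examples
#' concordance_index(c(0.2, 0.1, 0.3), c(1, 2, 3))  # 2/3
#' @export
concordance_index <- function(predictions, labels) {
  if (length(predictions) != length(labels)) {
    rlang::abort("`predictions` and `labels` must have equal length",
                 class = "dtakit_error_input")
  }
  ordered <- outer(labels, labels, ">")       # [i, j]: label_i > label_j
  z <- sum(ordered)
  if (z == 0L) {
    rlang::abort("all labels equal: concordance index undefined",
                 class = "dtakit_error_undefined_ci")
  }
  diffs <- outer(predictions, predictions, "-")
  sum(step_h(diffs[ordered])) / z
}
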