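#' Sample covariance of two vectors
#'
#' Sample covariance with the n-1 denominator,
#' `sum((x - mean(x)) * (y - mean(y))) / (n - 1)`.
#'
#' Implemented directly because it is the first rung of the package's
#' dependency criterion; agreement with `stats::cov` is asserted in the test
#' suite as an independent cross-check.
#'
#' @param x,y numeric vectors of equal length n >= 2, finite values.
#' @return The sample covariance (a single number).
#' @export
covariance <- function(x, y) {
  check_pair(x, y)
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) / (n - 1)
}

#' Pearson correlation coefficient
#'
#' The correlation compensates the constant-scaling sensitivity of the
#' covariance by dividing by both standard deviations. Three algebraically
#' equivalent forms are provided:
#' \describe{
#'   \item{`"covariance"`}{covariance over the product of root variances
#'     (the covariance-matrix form; default).}
#'   \item{`"deviation"`}{ratio of the centered cross-product sum to the
#'     root product of centered squared sums.}
#'   \item{`"moment"`}{raw-moment form using uncentered sums
#'     `sum(x*y) - n*mean(x)*mean(y)`; numerically the weakest, retained for
#'     cross-checking.}
#' }
#'
#' Zero variance in either vector is an error, not a silent 0: a constant
#' prediction vector carries no ranking information, and downstream code
#' must decide explicitly how to treat it (the deviation search maps it to
#' fitness `-Inf`).
#'
#' @param x,y numeric vectors of equal length n >= 2, finite values, each
#'   with nonzero variance.
#' @param method which algebraic form to evaluate; see Details.
#' @return The correlation, a number in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y,
                                method = c("covariance", "deviation",
                                           "moment")) {
  method <- match.arg(method)
  check_pair(x, y)
  if (variance_degenerate(x) || variance_degenerate(y)) {
    stop(degenerate_error(
      "pearson_correlation: zero variance input; correlation undefined"))
  }
  n <- length(x)
  r <- switch(method,
    covariance = covariance(x, y) / sqrt(covariance(x, x) * covariance(y, y)),
    deviation = {
      dx <- x - mean(x); dy <- y - mean(y)
      sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
    },
    moment = {
      num <- sum(x * y) - n * mean(x) * mean(y)
      den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
      num / den
    }
  )
  # |r| <= 1 up to roundoff by Cauchy-Schwarz; clamp the roundoff only
  stopifnot(abs(r) <= 1 + 1e-12)
  min(1, max(-1, r))
}

#' Fitness of estimated ages against diagnostic classes
#'
#' The search criterion lambda: the Pearson correlation between estimated
#' (brain) ages and the ordinal class codes. A high value means the
#' estimated age separates the disease stages in severity order, which is
#' what makes an age variant useful for classification.
#'
#' @param estimated_ages numeric vector of predicted ages.
#' @param class_labels integer class codes (or a factor, coerced in level
#'   order); at least two distinct classes must be present.
#' @return The fitness lambda in `[-1, 1]`.
#' @export
fitness <- function(estimated_ages, class_labels) {
  if (is.factor(class_labels)) class_labels <- as.integer(class_labels) - 1L
  class_labels <- as.numeric(class_labels)
  check_pair(estimated_ages, class_labels)
  if (length(unique(class_labels)) < 2L) {
    stop(degenerate_error(
      "fitness: only one class present; fitness undefined"))
  }
  if (variance_degenerate(estimated_ages)) {
    stop(degenerate_error(
      "fitness: constant estimated ages; fitness undefined"))
  }
  pearson_correlation(estimated_ages, class_labels)
}

#' Check affine invariance of the correlation
#'
#' Verifies numerically that `corr(a*x + b, y)` equals `corr(x, y)` for a
#' positive scale `a` — the property that motivates using correlation
#' rather than covariance as the dependency criterion. With a negative `a`
#' the correlation flips sign and the check reports `FALSE`.
#'
#' @param x,y numeric vectors satisfying [pearson_correlation()]
#'   preconditions.
#' @param a scale factor (nonzero).
#' @param b offset.
#' @param tol comparison tolerance.
#' @return `TRUE` iff the two correlations agree within `tol`.
#' @export
shift_scale_invariance_check <- function(x, y, a, b, tol = 1e-10) {
  if (a == 0) stop("shift_scale_invariance_check: a must be nonzero")
  abs(pearson_correlation(a * x + b, y) - pearson_correlation(x, y)) < tol
}

check_pair <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y)) stop("inputs must be numeric vectors")
  if (length(x) != length(y)) {
    stop("length mismatch: ", length(x), " vs ", length(y))
  }
  if (length(x) < 2L) stop("at least two observations required")
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    stop("inputs must be finite with no missing values")
  }
  invisible(TRUE)
}

# A constant vector has undefined correlation; detected on the centered
# scale so large offsets (ages ~ 70) do not mask genuine variation.
variance_degenerate <- function(x) {
  sum((x - mean(x))^2) == 0
}

degenerate_error <- function(msg) {
  errorCondition(msg, class = c("pathage_degenerate_error", "pathage_error"))
}
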