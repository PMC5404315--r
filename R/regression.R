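#' Age-estimation model configuration
#'
#' Configures the epsilon support vector regression used as the age
#' estimation model by both the deviation search and the traditional
#' baseline. The solver is delegated to \pkg{e1071} (libsvm); this object
#' pins the hyperparameters explicitly so results are reproducible across
#' library versions.
#'
#' Defaults follow the canonical epsilon-SVR conventions: regularization
#' weight (cost) 1, epsilon tube 0.1 years, polynomial degree 3, and a
#' gaussian/polynomial kernel width `gamma` of `1 / (p * mean feature
#' variance)` computed on the (standardized) training features.
#'
#' Features are z-scored on training statistics by default
#' (`standardize = TRUE`): hippocampal volumes are several orders of
#' magnitude larger than ages, and on that raw scale the quadratic-program
#' solver terminates far from its optimum. Targets are never scaled, so
#' `epsilon` stays in years and predictions are exactly equivariant under
#' target translation. Set `standardize = FALSE` to feed raw features.
#'
#' @param kernel one of `"linear"`, `"polynomial"`, `"gaussian"`.
#' @param cost regularization weight C (> 0).
#' @param epsilon epsilon-insensitive tube half-width, in years.
#' @param degree polynomial kernel degree.
#' @param gamma kernel width for polynomial/gaussian kernels; `NULL` uses
#'   the variance-scaled default above.
#' @param coef0 polynomial kernel offset.
#' @param standardize z-score features on training statistics.
#' @param tolerance solver termination tolerance.
#' @return A list of class `"age_estimator_config"`.
#' @export
age_estimator_config <- function(kernel = c("linear", "polynomial", "gaussian"),
                                 cost = 1, epsilon = 0.1, degree = 3,
                                 gamma = NULL, coef0 = 0,
                                 standardize = TRUE, tolerance = 0.001) {
  kernel <- match.arg(kernel)
  stopifnot(cost > 0, epsilon >= 0, degree >= 1, tolerance > 0)
  if (!is.null(gamma)) stopifnot(gamma > 0)
  structure(
    list(kernel = kernel, cost = cost, epsilon = epsilon, degree = degree,
         gamma = gamma, coef0 = coef0, standardize = isTRUE(standardize),
         tolerance = tolerance),
    class = "age_estimator_config"
  )
}

#' Fit the age-estimation model
#'
#' Trains an epsilon-SVR mapping feature rows to (possibly
#' deviation-shifted) age labels. Deterministic for fixed inputs and
#' configuration.
#'
#' @param features numeric matrix, one row per subject.
#' @param targets numeric vector of training labels (years), one per row.
#' @param config an [age_estimator_config()].
#' @return An object of class `"fitted_age_estimator"`.
#' @seealso [predict_age()]
#' @export
fit_age_model <- function(features, targets, config = age_estimator_config()) {
  stopifnot(inherits(config, "age_estimator_config"))
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features) || nrow(features) < 2L) {
    stop("fit_age_model: features must be a matrix with >= 2 rows")
  }
  if (nrow(features) != length(targets)) {
    stop("fit_age_model: ", nrow(features), " feature rows for ",
         length(targets), " targets")
  }
  if (anyNA(features) || anyNA(targets)) {
    stop("fit_age_model: missing values not allowed")
  }
  if (config$standardize) {
    center <- colMeans(features)
    scl <- apply(features, 2L, stats::sd)
    scl[scl == 0] <- 1  # constant feature: centered to 0, left unscaled
    features <- sweep(sweep(features, 2L, center), 2L, scl, "/")
  } else {
    center <- rep(0, ncol(features))
    scl <- rep(1, ncol(features))
  }
  gamma <- config$gamma
  if (is.null(gamma)) {
    mv <- mean(apply(features, 2L, stats::var))
    gamma <- if (mv > 0) 1 / (ncol(features) * mv) else 1 / ncol(features)
  }
  fit <- tryCatch(
    e1071::svm(
      x = features, y = targets, type = "eps-regression",
      kernel = switch(config$kernel, linear = "linear",
                      polynomial = "polynomial", gaussian = "radial"),
      cost = config$cost, epsilon = config$epsilon, degree = config$degree,
      gamma = gamma, coef0 = config$coef0, tolerance = config$tolerance,
      scale = FALSE
    ),
    error = function(e) {
      if (grepl("empty", conditionMessage(e), ignore.case = TRUE)) {
        # zero support vectors: every target sits inside the epsilon tube
        # of a constant, so the optimal regressor is that constant
        return(structure(list(constant = mean(targets)),
                         class = "constant_age_fit"))
      }
      stop("fit_age_model: solver failed for kernel '", config$kernel,
           "' (cost=", config$cost, ", epsilon=", config$epsilon, "): ",
           conditionMessage(e))
    }
  )
  structure(
    list(config = config, fit = fit, feature_count = ncol(features),
         feature_names = colnames(features), center = center, scale = scl,
         gamma = gamma),
    class = "fitted_age_estimator"
  )
}

#' Predict ages from a fitted model
#'
#' @param model a `"fitted_age_estimator"`.
#' @param features numeric matrix with the same number of columns the model
#'   was trained on.
#' @return Numeric vector of estimated ages, one per row.
#' @export
predict_age <- function(model, features) {
  stopifnot(inherits(model, "fitted_age_estimator"))
  if (is.data.frame(features)) features <- as.matrix(features)
  if (!is.matrix(features)) features <- matrix(features, nrow = 1L)
  if (ncol(features) != model$feature_count) {
    stop("predict_age: model expects ", model$feature_count,
         " feature columns, got ", ncol(features))
  }
  features <- sweep(sweep(features, 2L, model$center), 2L, model$scale, "/")
  out <- if (inherits(model$fit, "constant_age_fit")) {
    rep(model$fit$constant, nrow(features))
  } else {
    as.numeric(stats::predict(model$fit, features))
  }
  if (any(!is.finite(out))) stop("predict_age: non-finite prediction")
  out
}

#' @export
print.fitted_age_estimator <- function(x, ...) {
  cat("fitted age estimator: epsilon-SVR, kernel =", x$config$kernel,
      sprintf("(cost=%g, epsilon=%g)", x$config$cost, x$config$epsilon), "\n")
  cat("features:", x$feature_count,
      if (x$config$standardize) "(standardized)" else "(raw)", "\n")
  invisible(x)
}
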