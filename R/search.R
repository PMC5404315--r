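#' Per-class deviation search grid
#'
#' Defines the candidate set for the deviation search: one inclusive
#' `[min, max]` range per class and a common step. Published practice sets
#' the ranges to about a decade — `[-10, 10]` years for two-class problems
#' and `[-8, 8]` for three-class problems (the cost grows as the product of
#' the per-class grid sizes).
#'
#' @param lower numeric vector of per-class lower bounds (years); recycled
#'   to `n_classes` if scalar.
#' @param upper per-class upper bounds, likewise.
#' @param step grid step in years (> 0); default 1.
#' @param n_classes number of classes; defaults to the common length of
#'   `lower`/`upper`.
#' @return A list of class `"deviation_grid"`.
#' @export
deviation_grid <- function(lower, upper, step = 1, n_classes = NULL) {
  if (is.null(n_classes)) n_classes <- max(length(lower), length(upper))
  lower <- rep_len(as.numeric(lower), n_classes)
  upper <- rep_len(as.numeric(upper), n_classes)
  if (any(lower > upper)) stop("deviation_grid: lower bound above upper bound")
  if (step <= 0) stop("deviation_grid: step must be positive")
  n_cand <- prod(floor((upper - lower) / step) + 1)
  if (!is.finite(n_cand) || n_cand < 1) {
    stop("deviation_grid: empty or unbounded candidate set")
  }
  structure(
    list(lower = lower, upper = upper, step = as.numeric(step),
         n_classes = as.integer(n_classes)),
    class = "deviation_grid"
  )
}

#' @export
print.deviation_grid <- function(x, ...) {
  cat("deviation grid:",
      paste(sprintf("[%g, %g]", x$lower, x$upper), collapse = " x "),
      "step", x$step, "->", nrow(enumerate_candidates(x)), "candidates\n")
  invisible(x)
}

#' Enumerate all deviation candidates of a grid
#'
#' Lexicographic enumeration of the Cartesian product, min to max per
#' class, both endpoints included: the first class varies slowest, so the
#' first candidate is all lower bounds and the last all upper bounds.
#'
#' @param grid a [deviation_grid()].
#' @return Numeric matrix, one row per candidate, one column per class.
#' @export
enumerate_candidates <- function(grid) {
  stopifnot(inherits(grid, "deviation_grid"))
  seqs <- lapply(seq_len(grid$n_classes), function(k) {
    seq(grid$lower[k], grid$upper[k], by = grid$step)
  })
  # expand.grid varies the first factor fastest; reverse to get
  # lexicographic order with class 1 slowest
  g <- do.call(expand.grid, c(rev(seqs), KEEP.OUT.ATTRS = FALSE))
  m <- as.matrix(g[, rev(seq_len(ncol(g))), drop = FALSE])
  dimnames(m) <- list(NULL, paste0("class", seq_len(grid$n_classes) - 1L))
  m
}

#' Shift ages by per-class deviations
#'
#' Adds each subject's class deviation to its age:
#' `out[i] = ages[i] + deviations[class_labels[i] + 1]`. During the search
#' these shifted values are the SVR training labels; applied with the
#' optimal deviations they are the brain pathological ages.
#'
#' @param ages numeric vector of real ages (years).
#' @param class_labels integer class codes `0..(K-1)`.
#' @param deviations numeric vector of per-class deviations (years),
#'   indexed by class code.
#' @return Numeric vector of shifted ages.
#' @export
shifted_labels <- function(ages, class_labels, deviations) {
  stopifnot(length(ages) == length(class_labels))
  class_labels <- as.integer(class_labels)
  if (anyNA(class_labels) || any(class_labels < 0L) ||
      any(class_labels >= length(deviations))) {
    stop("shifted_labels: class code outside deviation vector (0..",
         length(deviations) - 1L, ")")
  }
  as.numeric(ages) + as.numeric(deviations)[class_labels + 1L]
}

#' Brain pathological age
#'
#' The real age plus the optimal per-class deviation. Computationally
#' identical to [shifted_labels()]; this alias carries the result
#' semantics: the deviation estimates the extent of accelerated brain
#' aging in each diagnostic class, and the sum is the pathological age.
#'
#' @inheritParams shifted_labels
#' @param optimal_deviations per-class deviations selected by the search.
#' @return Numeric vector of brain pathological ages (years).
#' @export
pathological_age <- function(ages, class_labels, optimal_deviations) {
  shifted_labels(ages, class_labels, optimal_deviations)
}

#' Deviation search for brain pathological age
#'
#' The core algorithm. For every candidate deviation combination in the
#' grid, an epsilon-SVR is trained on the training cohort with
#' deviation-shifted age labels, validation-set ages are predicted, and the
#' candidate is scored by the fitness lambda — the Pearson correlation
#' between predicted ages and validation class codes. The candidate
#' maximizing the fitness is returned together with the full fitness
#' surface, the refitted best model, and the validation subjects' brain
#' pathological ages (real age + optimal deviation of their class).
#'
#' Candidates whose model degenerates to a constant prediction on the
#' validation set score `-Inf` rather than aborting the search. Exact
#' fitness ties are broken by the smallest Euclidean norm of the deviation
#' vector, then by enumeration (lexicographic) order; this matters because
#' for translation-equivariant regressors the fitness is invariant under a
#' common shift of all deviations, so only deviation differences are
#' identified (see the package vignette).
#'
#' @param train a `"cohort"` used to fit the candidate models.
#' @param validation a `"cohort"` scored by the fitness; must share the
#'   feature columns and class set with `train` and contain >= 2 classes.
#' @param grid a [deviation_grid()] with one range per class.
#' @param config an [age_estimator_config()].
#' @return An object of class `"search_result"` with elements
#'   `optimal_deviations`, `max_fitness`, `surface` (data.frame of
#'   candidates and fitness values), `best_model`, `pathological_ages`
#'   (over the validation subjects), `grid`, `config`.
#' @export
run_search <- function(train, validation, grid,
                       config = age_estimator_config()) {
  validate_cohort(train)
  validate_cohort(validation)
  stopifnot(inherits(grid, "deviation_grid"))
  if (!identical(colnames(train$features), colnames(validation$features))) {
    stop("run_search: train and validation feature columns differ")
  }
  if (!identical(train$class_names, validation$class_names)) {
    stop("run_search: train and validation class sets differ")
  }
  if (grid$n_classes != length(train$class_names)) {
    stop("run_search: grid has ", grid$n_classes, " ranges for ",
         length(train$class_names), " classes")
  }
  if (length(unique(validation$class_label)) < 2L) {
    stop(degenerate_error(
      "run_search: validation set contains a single class"))
  }
  candidates <- enumerate_candidates(grid)
  lambda <- vapply(seq_len(nrow(candidates)), function(i) {
    model <- fit_age_model(
      train$features,
      shifted_labels(train$age, train$class_label, candidates[i, ]),
      config
    )
    tryCatch(
      fitness(predict_age(model, validation$features),
              validation$class_label),
      pathage_degenerate_error = function(e) -Inf
    )
  }, numeric(1))
  if (!any(is.finite(lambda))) {
    stop("run_search: every candidate produced a degenerate fit")
  }
  max_fitness <- max(lambda[is.finite(lambda)])
  best <- which(lambda == max_fitness)
  if (length(best) > 1L) {
    norms <- sqrt(rowSums(candidates[best, , drop = FALSE]^2))
    best <- best[norms == min(norms)]  # then first in lexicographic order
  }
  best <- best[1L]
  optimal <- candidates[best, ]
  best_model <- fit_age_model(
    train$features,
    shifted_labels(train$age, train$class_label, optimal),
    config
  )
  surface <- data.frame(candidates, fitness = lambda, check.names = FALSE)
  structure(
    list(
      optimal_deviations = stats::setNames(as.numeric(optimal),
                                           train$class_names),
      max_fitness = max_fitness,
      surface = surface,
      best_model = best_model,
      pathological_ages = pathological_age(validation$age,
                                           validation$class_label, optimal),
      grid = grid,
      config = config
    ),
    class = "search_result"
  )
}

#' @export
print.search_result <- function(x, ...) {
  cat("deviation search over", nrow(x$surface), "candidates\n")
  cat("optimal deviations:",
      paste(sprintf("%s=%+g", names(x$optimal_deviations),
                    x$optimal_deviations), collapse = ", "), "\n")
  cat(sprintf("max validation fitness: %.4f\n", x$max_fitness))
  invisible(x)
}

#' Traditional brain-age baseline
#'
#' The conventional approach: train the age model on real ages (the
#' epsilon-insensitive loss realizes the error-minimization criterion) and
#' predict test-set brain ages. Equivalent to the deviation search
#' restricted to the all-zero candidate in terms of the fitted model.
#'
#' @param train a `"cohort"` used for fitting (targets are its real ages).
#' @param test a `"cohort"` sharing the feature columns.
#' @param config an [age_estimator_config()].
#' @return A list of class `"baseline_result"`: `predictions` (estimated
#'   brain ages over the test subjects), `mae` (mean absolute error to the
#'   real test ages), `model`.
#' @export
run_baseline <- function(train, test, config = age_estimator_config()) {
  validate_cohort(train)
  validate_cohort(test)
  if (!identical(colnames(train$features), colnames(test$features))) {
    stop("run_baseline: train and test feature columns differ")
  }
  model <- fit_age_model(train$features, train$age, config)
  predictions <- predict_age(model, test$features)
  structure(
    list(predictions = predictions,
         mae = mean(abs(predictions - test$age)),
         model = model),
    class = "baseline_result"
  )
}

#' @export
print.baseline_result <- function(x, ...) {
  cat(sprintf("traditional brain-age baseline: %d predictions, MAE %.3f years\n",
              length(x$predictions), x$mae))
  invisible(x)
}
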