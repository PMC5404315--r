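#' Train/validation/test split policy
#'
#' @param fractions numeric length-3 `(train, validation, test)` proportions
#'   summing to 1; each > 0. Default `c(0.6, 0.2, 0.2)`.
#' @param stratified split within each class so every set keeps the cohort's
#'   class balance (default `TRUE`).
#' @param seed integer seed making the partition deterministic.
#' @return A list of class `"split_policy"`.
#' @export
split_policy <- function(fractions = c(train = 0.6, validation = 0.2,
                                       test = 0.2),
                         stratified = TRUE, seed = 1L) {
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(fractions <= 0)) {
    stop("split_policy: three positive fractions required")
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("split_policy: fractions must sum to 1")
  }
  structure(
    list(fractions = stats::setNames(fractions,
                                     c("train", "validation", "test")),
         stratified = isTRUE(stratified), seed = as.integer(seed)),
    class = "split_policy"
  )
}

#' Random train/validation/test partition of a cohort
#'
#' Disjoint exhaustive partition, stratified by class when the policy says
#' so, deterministic for a given policy seed. Set sizes follow the
#' fractions with largest-remainder rounding, so a 100-subject cohort at
#' `(0.6, 0.2, 0.2)` splits 60/20/20 exactly.
#'
#' @param cohort a `"cohort"`; with stratification every class needs >= 3
#'   subjects so each set can be nonempty.
#' @param policy a [split_policy()].
#' @return Named list of three `"cohort"`s: `train`, `validation`, `test`.
#' @export
split_cohort <- function(cohort, policy = split_policy()) {
  validate_cohort(cohort)
  stopifnot(inherits(policy, "split_policy"))
  assign_one <- function(n) {
    sizes <- largest_remainder_sizes(n, policy$fractions)
    if (any(sizes == 0L)) {
      stop("split_cohort: fraction yields an empty set for a group of ",
           n, " subjects")
    }
    rep(c("train", "validation", "test"), times = sizes)
  }
  assignment <- character(length(cohort$age))
  with_local_seed(policy$seed, {
    if (policy$stratified) {
      for (k in seq_along(cohort$class_names) - 1L) {
        idx <- which(cohort$class_label == k)
        if (length(idx) < 3L) {
          stop("split_cohort: class '", cohort$class_names[k + 1L],
               "' has fewer than 3 subjects; cannot stratify")
        }
        assignment[idx] <- sample(assign_one(length(idx)))
      }
    } else {
      assignment <- sample(assign_one(length(assignment)))
    }
  })
  lapply(stats::setNames(nm = c("train", "validation", "test")),
         function(s) subset_cohort(cohort, assignment == s))
}

# integer set sizes matching fractions: floor, then distribute the
# remainder to the largest fractional parts (ties to earlier sets)
largest_remainder_sizes <- function(n, fractions) {
  raw <- n * fractions
  sizes <- floor(raw)
  short <- n - sum(sizes)
  if (short > 0L) {
    order_frac <- order(raw - sizes, decreasing = TRUE)
    sizes[order_frac[seq_len(short)]] <- sizes[order_frac[seq_len(short)]] + 1L
  }
  as.integer(sizes)
}

#' Repeated-split evaluation of the deviation search
#'
#' Runs the full experimental protocol: for each repeat, draw a fresh
#' train/validation/test partition, run the deviation search on
#' train/validation, then score three age variants on the held-out test
#' set by their fitness (correlation with the class code):
#' \describe{
#'   \item{`test_fitness_real_age`}{the raw real ages ("without age
#'     estimation");}
#'   \item{`test_fitness_baseline`}{traditional brain ages predicted by an
#'     SVR trained on real ages;}
#'   \item{`test_fitness`}{brain pathological ages — real test ages plus
#'     the class deviations selected on the validation set.}
#' }
#' Per-repeat rows are aggregated into mean/SD columns, per-class deviation
#' significance is tested against zero, and a correlation table reports
#' each variant's correlation with the class code (CwC), with each feature
#' (CwF), and the across-feature average (ACwF).
#'
#' Repeat r uses seed `policy$seed + r - 1` for its partition, so any
#' single repeat can be reproduced in isolation.
#'
#' @param cohort a `"cohort"`.
#' @param grid a [deviation_grid()].
#' @param config an [age_estimator_config()].
#' @param policy a [split_policy()]; its seed is the master seed.
#' @param n_repeats number of random splits (>= 2); default 10.
#' @param baseline_train `"all"` trains the baseline on all classes
#'   (default); `"nc"` trains it on the first (least severe) class only, as
#'   some traditional pipelines do.
#' @param verbose print a progress line per repeat.
#' @return An object of class `"evaluation_report"`: `per_repeat`
#'   (data.frame), `aggregates` (mean/SD per column),
#'   `deviation_p_values`, `correlation_table`, plus the inputs.
#' @export
repeat_experiment <- function(cohort, grid, config = age_estimator_config(),
                              policy = split_policy(), n_repeats = 10L,
                              baseline_train = c("all", "nc"),
                              verbose = FALSE) {
  validate_cohort(cohort)
  baseline_train <- match.arg(baseline_train)
  if (n_repeats < 2L) stop("repeat_experiment: n_repeats must be >= 2")
  k <- length(cohort$class_names)
  dev_cols <- paste0("dev_", cohort$class_names)
  rows <- vector("list", n_repeats)
  cor_rows <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    seed_r <- policy$seed + r - 1L
    policy_r <- split_policy(policy$fractions, policy$stratified, seed_r)
    res <- tryCatch({
      parts <- split_cohort(cohort, policy_r)
      sr <- run_search(parts$train, parts$validation, grid, config)
      btrain <- if (baseline_train == "nc") {
        subset_cohort(parts$train, parts$train$class_label == 0L)
      } else parts$train
      bl <- run_baseline(btrain, parts$test, config)
      path_age <- pathological_age(parts$test$age, parts$test$class_label,
                                   sr$optimal_deviations)
      list(sr = sr, bl = bl, parts = parts, path_age = path_age)
    }, error = function(e) {
      stop("repeat_experiment: repeat ", r, " failed: ",
           conditionMessage(e))
    })
    test <- res$parts$test
    row <- data.frame(
      repeat_index = r, seed = seed_r,
      t(stats::setNames(as.numeric(res$sr$optimal_deviations), dev_cols)),
      validation_fitness = res$sr$max_fitness,
      test_fitness = fitness(res$path_age, test$class_label),
      test_fitness_baseline = fitness(res$bl$predictions, test$class_label),
      test_fitness_real_age = fitness(test$age, test$class_label),
      baseline_mae = res$bl$mae
    )
    rows[[r]] <- row
    cor_rows[[r]] <- correlation_report(
      test,
      list(real_age = test$age,
           brain_age = res$bl$predictions,
           pathological_age = res$path_age)
    )
    if (verbose) {
      message(sprintf(
        "repeat %d/%d: deviations (%s), validation fitness %.4f", r,
        n_repeats, paste(sprintf("%+g", res$sr$optimal_deviations),
                         collapse = ", "), res$sr$max_fitness))
    }
  }
  per_repeat <- do.call(rbind, rows)
  num_cols <- setdiff(names(per_repeat), c("repeat_index", "seed"))
  aggregates <- data.frame(
    statistic = c("mean", "sd"),
    rbind(vapply(per_repeat[num_cols], mean, numeric(1)),
          vapply(per_repeat[num_cols], stats::sd, numeric(1)))
  )
  cors <- do.call(rbind, cor_rows)
  metric_cols <- setdiff(names(cors), "variant")
  agg_by_variant <- lapply(split(cors[metric_cols], cors$variant), function(d) {
    data.frame(metric = metric_cols,
               mean = vapply(d, mean, numeric(1)),
               sd = vapply(d, stats::sd, numeric(1)),
               row.names = NULL)
  })
  correlation_table <- do.call(rbind, lapply(names(agg_by_variant), function(v) {
    cbind(variant = v, agg_by_variant[[v]])
  }))
  structure(
    list(
      per_repeat = per_repeat,
      aggregates = aggregates,
      deviation_p_values = deviation_significance(
        as.matrix(per_repeat[dev_cols])),
      correlation_table = correlation_table,
      grid = grid, config = config, policy = policy,
      n_repeats = as.integer(n_repeats),
      class_names = cohort$class_names
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation over", x$n_repeats, "random splits\n\n")
  cat("mean optimal deviations:\n")
  dev_cols <- paste0("dev_", x$class_names)
  means <- colMeans(x$per_repeat[dev_cols])
  print(round(stats::setNames(means, x$class_names), 2))
  cat("\ndeviation p-values (one-sample t vs 0):\n")
  print(signif(x$deviation_p_values, 3))
  cat("\ntest-set fitness (correlation with class):\n")
  f <- x$per_repeat[c("test_fitness_real_age", "test_fitness_baseline",
                      "test_fitness")]
  tab <- data.frame(
    method = c("without age estimation", "traditional brain age",
               "brain pathological age"),
    mean = round(vapply(f, mean, numeric(1)), 4),
    sd = round(vapply(f, stats::sd, numeric(1)), 4),
    row.names = NULL
  )
  print(tab)
  invisible(x)
}

#' Significance of recovered deviations
#'
#' Two-sided one-sample t-test per class of the recovered deviations
#' against zero, across repeats: a small p-value means the estimated
#' pathological-age offset for that class is systematically different from
#' the real age.
#'
#' @param per_repeat_deviations numeric matrix, repeats x classes.
#' @return Named numeric vector of p-values in `(0, 1]`. A class whose
#'   deviations have zero variance across repeats is degenerate for the t
#'   statistic: its entry is `NA` with the columns flagged in
#'   `attr(, "degenerate")` (all-zero recovery is reported this way rather
#'   than as an arbitrary p).
#' @export
deviation_significance <- function(per_repeat_deviations) {
  m <- as.matrix(per_repeat_deviations)
  if (nrow(m) < 2L) stop("deviation_significance: >= 2 repeats required")
  degenerate <- apply(m, 2L, function(col) stats::var(col) == 0)
  p <- vapply(seq_len(ncol(m)), function(j) {
    if (degenerate[j]) return(NA_real_)
    stats::t.test(m[, j], mu = 0)$p.value
  }, numeric(1))
  names(p) <- colnames(m)
  names(degenerate) <- colnames(m)
  structure(p, degenerate = degenerate)
}

#' Correlation table for age variants
#'
#' For each candidate age variant (real age, traditional brain age, brain
#' pathological age, ...) reports its correlation with the ordinal class
#' code (CwC), with every individual feature (CwF1, CwF2, ...), and the
#' average over features (ACwF). High CwC supports classification; high
#' CwF/ACwF means the variant is redundant with the imaging features and
#' can replace them, shrinking the feature set.
#'
#' Correlations are reported signed; set `abs = TRUE` for the
#' magnitude-only presentation common in published tables.
#'
#' @param cohort a `"cohort"` supplying class codes and features.
#' @param age_variants named list of numeric vectors, one value per
#'   subject.
#' @param abs report absolute correlations.
#' @return A data.frame with one row per variant: `variant`, `CwC`,
#'   `CwF<j>` per feature, `ACwF`.
#' @export
correlation_report <- function(cohort, age_variants, abs = FALSE) {
  validate_cohort(cohort)
  stopifnot(is.list(age_variants), length(names(age_variants)) ==
              length(age_variants))
  n <- length(cohort$age)
  p <- ncol(cohort$features)
  rows <- lapply(names(age_variants), function(v) {
    x <- age_variants[[v]]
    if (length(x) != n) {
      stop("correlation_report: variant '", v, "' has ", length(x),
           " values for ", n, " subjects")
    }
    cwc <- pearson_correlation(x, as.numeric(cohort$class_label))
    cwf <- vapply(seq_len(p), function(j) {
      pearson_correlation(x, cohort$features[, j])
    }, numeric(1))
    if (abs) {
      cwc <- base::abs(cwc)
      cwf <- base::abs(cwf)
    }
    out <- data.frame(variant = v, CwC = cwc,
                      t(stats::setNames(cwf, paste0("CwF", seq_len(p)))),
                      ACwF = mean(cwf))
    out
  })
  do.call(rbind, rows)
}

#' Kernel comparison under the repeated-split protocol
#'
#' Runs [repeat_experiment()] once per kernel with the same master seed,
#' so every kernel sees identical partitions (a paired comparison), and
#' tabulates mean deviations and mean/SD fitness per kernel.
#'
#' @inheritParams repeat_experiment
#' @param kernels character vector of kernels to compare.
#' @return A list of class `"kernel_comparison"`: `reports` (named list of
#'   `"evaluation_report"`s) and `summary` (data.frame).
#' @export
compare_kernels <- function(cohort, grid, policy = split_policy(),
                            n_repeats = 10L,
                            kernels = c("linear", "polynomial", "gaussian"),
                            verbose = FALSE) {
  reports <- lapply(stats::setNames(nm = kernels), function(kn) {
    repeat_experiment(cohort, grid, age_estimator_config(kernel = kn),
                      policy, n_repeats, verbose = verbose)
  })
  summary <- do.call(rbind, lapply(names(reports), function(kn) {
    rep_ <- reports[[kn]]
    dev_cols <- paste0("dev_", rep_$class_names)
    data.frame(
      kernel = kn,
      t(stats::setNames(colMeans(rep_$per_repeat[dev_cols]),
                        paste0("mean_", dev_cols))),
      mean_validation_fitness = mean(rep_$per_repeat$validation_fitness),
      mean_test_fitness = mean(rep_$per_repeat$test_fitness),
      sd_test_fitness = stats::sd(rep_$per_repeat$test_fitness)
    )
  }))
  structure(list(reports = reports, summary = summary),
            class = "kernel_comparison")
}

#' @export
print.kernel_comparison <- function(x, ...) {
  cat("kernel comparison over", x$reports[[1L]]$n_repeats, "paired splits\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
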