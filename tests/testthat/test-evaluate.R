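test_that("split sizes follow the fractions exactly", {
  coh <- hand_cohort(n_per_class = 50)  # 100 subjects
  parts <- split_cohort(coh, split_policy(stratified = FALSE, seed = 1))
  expect_identical(vapply(parts, function(p) length(p$age), integer(1)),
                   c(train = 60L, validation = 20L, test = 20L))
  # disjoint exhaustive partition
  ids <- unname(unlist(lapply(parts, `[[`, "subject_id")))
  expect_identical(sort(ids), sort(coh$subject_id))
  expect_identical(anyDuplicated(ids), 0L)
})

test_that("stratified splits keep every class balanced within 1", {
  coh <- hand_cohort(n_per_class = 41)
  parts <- split_cohort(coh, split_policy(seed = 3))
  for (p in parts) {
    counts <- class_counts(p)
    expect_lte(max(counts) - min(counts), 1L)
  }
})

test_that("splits are deterministic per seed and vary across seeds", {
  coh <- hand_cohort(n_per_class = 30)
  a <- split_cohort(coh, split_policy(seed = 11))
  b <- split_cohort(coh, split_policy(seed = 11))
  c_ <- split_cohort(coh, split_policy(seed = 12))
  expect_identical(a$train$subject_id, b$train$subject_id)
  expect_false(identical(a$train$subject_id, c_$train$subject_id))
})

test_that("invalid split policies are rejected", {
  expect_error(split_policy(c(0.5, 0.5, 0.2)), "sum to 1")
  expect_error(split_policy(c(0.8, 0.2, 0)), "positive")
  coh <- hand_cohort(n_per_class = 2)
  expect_error(split_cohort(coh, split_policy(seed = 1)), "fewer than 3")
})

test_that("repeat_experiment aggregates are recomputable from the rows", {
  coh <- hand_cohort(n_per_class = 25, seed = 19, noise_sd = 1)
  grid <- deviation_grid(-2, 2, step = 2, n_classes = 2)
  rep_ <- repeat_experiment(coh, grid, policy = split_policy(seed = 5),
                            n_repeats = 3)
  expect_s3_class(rep_, "evaluation_report")
  expect_identical(nrow(rep_$per_repeat), 3L)
  agg <- rep_$aggregates
  for (cn in setdiff(names(rep_$per_repeat), c("repeat_index", "seed"))) {
    expect_equal(agg[agg$statistic == "mean", cn],
                 mean(rep_$per_repeat[[cn]]), tolerance = 1e-12)
    expect_equal(agg[agg$statistic == "sd", cn],
                 sd(rep_$per_repeat[[cn]]), tolerance = 1e-12)
  }
  # per-repeat seeds follow the documented scheme
  expect_identical(rep_$per_repeat$seed, 5:7)
  # all reported correlations are correlations
  fit_cols <- grep("fitness", names(rep_$per_repeat), value = TRUE)
  expect_true(all(abs(as.matrix(rep_$per_repeat[fit_cols])) <= 1))
})

test_that("a zero-only grid makes the pathological row equal the real-age row", {
  coh <- hand_cohort(n_per_class = 20, seed = 29, noise_sd = 1)
  g0 <- deviation_grid(0, 0, n_classes = 2)
  rep_ <- repeat_experiment(coh, g0, policy = split_policy(seed = 2),
                            n_repeats = 2)
  expect_equal(rep_$per_repeat$test_fitness,
               rep_$per_repeat$test_fitness_real_age, tolerance = 1e-12)
  # all repeats recover exactly zero: degenerate for the t statistic
  expect_true(all(is.na(rep_$deviation_p_values)))
  expect_true(all(attr(rep_$deviation_p_values, "degenerate")))
})

test_that("validation fitness dominates the zero candidate on every repeat", {
  coh <- hand_cohort(n_per_class = 20, seed = 31, noise_sd = 1.5)
  grid <- deviation_grid(-2, 2, step = 2, n_classes = 2)
  g0 <- deviation_grid(0, 0, n_classes = 2)
  pol <- split_policy(seed = 8)
  with_grid <- repeat_experiment(coh, grid, policy = pol, n_repeats = 3)
  zero_only <- repeat_experiment(coh, g0, policy = pol, n_repeats = 3)
  expect_true(all(with_grid$per_repeat$validation_fitness >=
                    zero_only$per_repeat$validation_fitness))
})

test_that("deviation significance behaves like a one-sample t-test", {
  set.seed(61)
  strong <- matrix(rnorm(20, mean = 5, sd = 0.1), ncol = 2)
  p <- deviation_significance(strong)
  expect_true(all(p < 0.001))
  expect_equal(unname(p[1]), t.test(strong[, 1], mu = 0)$p.value,
               tolerance = 1e-12)
  expect_error(deviation_significance(matrix(1, 1, 2)), "2 repeats")
})

test_that("correlation report computes CwC, per-feature CwF and their mean", {
  coh <- hand_cohort(n_per_class = 20, seed = 37)
  tab <- correlation_report(coh, list(
    codes = as.numeric(coh$class_label),
    f1 = coh$features[, 1],
    real = coh$age
  ))
  expect_identical(tab$variant, c("codes", "f1", "real"))
  expect_equal(tab$CwC[1], 1, tolerance = 1e-12)
  expect_equal(tab$CwF1[2], 1, tolerance = 1e-12)
  expect_equal(tab$ACwF, (tab$CwF1 + tab$CwF2) / 2, tolerance = 1e-12)
  # signed by default; abs = TRUE takes magnitudes
  tab_abs <- correlation_report(coh, list(neg = -coh$age), abs = TRUE)
  expect_gte(tab_abs$CwF1, 0)
  expect_error(correlation_report(coh, list(bad = 1:3)), "values for")
})

test_that("real age is uncorrelated with class when accelerations are zero", {
  spec <- cohort_spec(
    n_per_class = 400, class_names = c("NC", "AD"), age_range = c(65, 85),
    class_age_means = rep(75, 2), class_age_sds = rep(5, 2),
    class_accel = c(0, 0), atrophy_slope = 3, feature_noise_sd = 5
  )
  coh <- generate_cohort(spec, seed = 41)
  tab <- correlation_report(coh, list(real = coh$age))
  expect_lt(abs(tab$CwC), 3 / sqrt(length(coh$age)))
})

test_that("kernel comparison runs all kernels on identical partitions", {
  coh <- hand_cohort(n_per_class = 18, seed = 43, noise_sd = 1)
  grid <- deviation_grid(-1, 1, step = 1, n_classes = 2)
  cmp <- compare_kernels(coh, grid, policy = split_policy(seed = 4),
                         n_repeats = 2)
  expect_identical(names(cmp$reports),
                   c("linear", "polynomial", "gaussian"))
  expect_identical(nrow(cmp$summary), 3L)
  # same master seed -> identical per-repeat split seeds across kernels
  expect_identical(cmp$reports$linear$per_repeat$seed,
                   cmp$reports$gaussian$per_repeat$seed)
  # the real-age fitness column depends only on the split, so it must be
  # identical across kernels (paired comparison)
  expect_identical(cmp$reports$linear$per_repeat$test_fitness_real_age,
                   cmp$reports$polynomial$per_repeat$test_fitness_real_age)
})

test_that("baseline_train = 'nc' trains the baseline on the first class only", {
  coh <- hand_cohort(n_per_class = 20, seed = 47, noise_sd = 0.5)
  g0 <- deviation_grid(0, 0, n_classes = 2)
  pol <- split_policy(seed = 9)
  all_cls <- repeat_experiment(coh, g0, policy = pol, n_repeats = 2,
                               baseline_train = "all")
  nc_only <- repeat_experiment(coh, g0, policy = pol, n_repeats = 2,
                               baseline_train = "nc")
  # different training sets give different baseline fits
  expect_false(identical(all_cls$per_repeat$test_fitness_baseline,
                         nc_only$per_repeat$test_fitness_baseline))
})
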