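# Small deterministic cohorts built by hand (independent of the package's
# synthetic generator) for unit tests.

tiny_cohort <- function() {
  cohort(
    subject_id = paste0("s", 1:6),
    age = c(70, 72, 74, 76, 78, 80),
    class_label = c(0L, 0L, 1L, 1L, 2L, 2L),
    class_names = c("NC", "MCI", "AD"),
    features = cbind(left = c(3.2, 3.1, 2.9, 2.8, 2.5, 2.4),
                     right = c(3.3, 3.2, 3.0, 2.9, 2.6, 2.5))
  )
}

# hand-rolled two-class cohort with a strong volume-age-class structure;
# base R RNG only, no package code
hand_cohort <- function(n_per_class = 30, seed = 42, accel = c(0, 6),
                        noise_sd = 0.5) {
  set.seed(seed)
  k <- length(accel)
  n <- n_per_class * k
  lab <- rep(seq_len(k) - 1L, each = n_per_class)
  age <- round(runif(n, 65, 85), 1)
  b <- age + accel[lab + 1L]
  cohort(
    subject_id = sprintf("h%03d", 1:n),
    age = age,
    class_label = lab,
    class_names = c("NC", "AD", "MCI")[seq_len(k)],
    features = cbind(left = 40 - 0.3 * b + rnorm(n, 0, noise_sd),
                     right = 41 - 0.3 * b + rnorm(n, 0, noise_sd))
  )
}

expect_cohort_equal <- function(a, b, tol = 1e-9) {
  expect_identical(a$subject_id, b$subject_id)
  expect_identical(a$class_label, b$class_label)
  expect_identical(a$class_names, b$class_names)
  expect_equal(a$age, b$age, tolerance = tol)
  expect_equal(a$features, b$features, tolerance = tol)
}
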