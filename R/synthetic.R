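#' Specification of a synthetic cohort
#'
#' Describes a generative model for cohorts with the structure the
#' deviation-search method assumes: each diagnostic class ages at an
#' accelerated rate, and volumetric features decline linearly with the
#' latent brain age.
#'
#' The model, per subject of class k:
#' \enumerate{
#'   \item chronological age `a ~ Normal(class_age_means[k], class_age_sds[k])`
#'     truncated to `age_range`;
#'   \item latent brain age `b = a + class_accel[k] + eta`,
#'     `eta ~ Normal(0, brain_age_sd)`;
#'   \item feature j: `baseline_volumes[j] - atrophy_slope[j] * b + e_j`,
#'     where the noise vector `e` has per-feature SD `feature_noise_sd` and
#'     equicorrelation `bilateral_corr` across features (paired left/right
#'     structures share most of their residual variation);
#'   \item volumes are clipped at a small positive floor.
#' }
#'
#' @param n_per_class subjects per class (>= 2).
#' @param class_names ordered class names (severity order).
#' @param age_range numeric length-2, `c(min, max)` age in years.
#' @param class_age_means per-class mean age (years).
#' @param class_age_sds per-class age standard deviation (years) of the
#'   untruncated normal; realized SDs are smaller after truncation.
#' @param class_accel per-class true brain-age acceleration in years (the
#'   generative counterpart of the deviations the search estimates).
#' @param baseline_volumes per-feature volume at brain age 0 (arbitrary
#'   volume units, e.g. mm^3/10).
#' @param atrophy_slope volume lost per brain-age year (units/year),
#'   positive magnitude; scalar or per-feature.
#' @param feature_noise_sd residual SD of each feature (units); scalar or
#'   per-feature.
#' @param bilateral_corr correlation of residual noise between features,
#'   in `[0, 1)`.
#' @param brain_age_sd SD of the brain-age jitter `eta` (years); keeps brain
#'   age from being a deterministic function of age.
#' @param feature_names names of the generated feature columns.
#' @param volume_floor positive floor applied to generated volumes.
#' @param seed default seed used by [generate_cohort()] when none is given.
#' @return A list of class `"cohort_spec"`.
#' @seealso [default_adni_like_spec()], [generate_cohort()]
#' @export
cohort_spec <- function(n_per_class,
                        class_names,
                        age_range,
                        class_age_means,
                        class_age_sds,
                        class_accel,
                        baseline_volumes = c(400, 410),
                        atrophy_slope = 3,
                        feature_noise_sd = 5,
                        bilateral_corr = 0.8,
                        brain_age_sd = 1,
                        feature_names = NULL,
                        volume_floor = 1e-3,
                        seed = 1L) {
  k <- length(class_names)
  p <- length(baseline_volumes)
  if (is.null(feature_names)) {
    feature_names <- if (p == 2L) c("left_hippocampus", "right_hippocampus")
                     else paste0("feature_", seq_len(p))
  }
  spec <- structure(
    list(
      n_per_class = as.integer(n_per_class),
      class_names = as.character(class_names),
      age_range = as.numeric(age_range),
      class_age_means = as.numeric(class_age_means),
      class_age_sds = as.numeric(class_age_sds),
      class_accel = as.numeric(class_accel),
      baseline_volumes = as.numeric(baseline_volumes),
      atrophy_slope = rep_len(as.numeric(atrophy_slope), p),
      feature_noise_sd = rep_len(as.numeric(feature_noise_sd), p),
      bilateral_corr = as.numeric(bilateral_corr),
      brain_age_sd = as.numeric(brain_age_sd),
      feature_names = as.character(feature_names),
      volume_floor = as.numeric(volume_floor),
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
}

#' Validate a cohort specification
#'
#' @param spec a `"cohort_spec"`.
#' @return `spec` invisibly, or a configuration error.
#' @export
validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  k <- length(spec$class_names)
  p <- length(spec$baseline_volumes)
  err <- function(...) stop("cohort_spec: ", ...)
  if (k < 2L) err("at least two classes required")
  if (spec$n_per_class < 2L) err("n_per_class must be >= 2")
  if (length(spec$age_range) != 2L || spec$age_range[1L] >= spec$age_range[2L]) {
    err("age_range must be c(min, max) with min < max")
  }
  for (f in c("class_age_means", "class_age_sds", "class_accel")) {
    if (length(spec[[f]]) != k) err(f, " must have one value per class")
  }
  if (any(spec$class_age_sds <= 0)) err("class_age_sds must be positive")
  if (any(spec$atrophy_slope <= 0)) err("atrophy_slope must be positive")
  if (any(spec$feature_noise_sd < 0)) err("feature_noise_sd must be >= 0")
  if (spec$bilateral_corr < 0 || spec$bilateral_corr >= 1) {
    err("bilateral_corr must lie in [0, 1)")
  }
  if (spec$brain_age_sd < 0) err("brain_age_sd must be >= 0")
  if (length(spec$feature_names) != p) {
    err("feature_names must match baseline_volumes in length")
  }
  if (spec$volume_floor <= 0) err("volume_floor must be positive")
  invisible(spec)
}

#' ADNI-like default cohort specification
#'
#' Returns a specification emulating the balanced hippocampus feature table
#' the method was designed for: three classes (NC/MCI/AD) of 411 subjects,
#' ages 65-85 with class mean ages 76.09/75.36/75.50 and age SDs
#' 4.696/7.635/7.245, and two positively correlated hippocampal-volume
#' features declining with brain age.
#'
#' The true accelerations default to `c(0, 4, 8)` years: within the
#' deviation search ranges and of the same order as published estimates,
#' but otherwise an arbitrary documented choice. Remaining defaults
#' (baseline volumes 400/410 units, atrophy slope 3 units/year, residual SD
#' 5 units, bilateral correlation 0.8, brain-age jitter 1 year) are
#' documented package conventions.
#'
#' @param n_per_class subjects per class; default 411.
#' @param class_accel per-class true acceleration in years; default
#'   `c(0, 4, 8)`.
#' @param ... further overrides passed to [cohort_spec()].
#' @return A `"cohort_spec"`.
#' @export
default_adni_like_spec <- function(n_per_class = 411L,
                                   class_accel = c(0, 4, 8), ...) {
  cohort_spec(
    n_per_class = n_per_class,
    class_names = c("NC", "MCI", "AD"),
    age_range = c(65, 85),
    class_age_means = c(76.09, 75.36, 75.50),
    class_age_sds = c(4.696, 7.635, 7.245),
    class_accel = class_accel,
    ...
  )
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from the generative model described in [cohort_spec()].
#' Deterministic given the seed; the caller's RNG state is untouched.
#'
#' @param spec a `"cohort_spec"`.
#' @param seed integer seed; defaults to `spec$seed`.
#' @return A `"cohort"` of `n_per_class * K` subjects.
#' @examples
#' coh <- generate_cohort(default_adni_like_spec(n_per_class = 50), seed = 7)
#' class_counts(coh)
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  validate_cohort_spec(spec)
  k <- length(spec$class_names)
  p <- length(spec$baseline_volumes)
  n <- spec$n_per_class * k
  with_local_seed(seed, {
    class_label <- rep(seq_len(k) - 1L, each = spec$n_per_class)
    age <- numeric(n)
    for (ki in seq_len(k)) {
      rows <- which(class_label == ki - 1L)
      age[rows] <- rtruncnorm(length(rows), spec$class_age_means[ki],
                              spec$class_age_sds[ki], spec$age_range[1L],
                              spec$age_range[2L])
    }
    brain_age <- age + spec$class_accel[class_label + 1L] +
      stats::rnorm(n, 0, spec$brain_age_sd)
    noise <- equicorrelated_noise(n, p, spec$bilateral_corr) *
      rep(spec$feature_noise_sd, each = n)
    features <- rep(spec$baseline_volumes, each = n) -
      outer(brain_age, spec$atrophy_slope) + noise
    features <- pmax(features, spec$volume_floor)
    dim(features) <- c(n, p)
    colnames(features) <- spec$feature_names
    cohort(
      subject_id = sprintf("sub%04d", seq_len(n)),
      age = age,
      class_label = class_label,
      class_names = spec$class_names,
      features = features
    )
  })
}

# Truncated-normal draws by inverse-CDF so all mass stays inside [lo, hi].
rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::runif(n, plo, phi)
  q <- stats::qnorm(u, mean, sd)
  pmin(pmax(q, lo), hi)  # guard against qnorm rounding at the tails
}

# n x p standard-normal noise with equicorrelation rho across columns,
# via its Cholesky factor. Unit marginal variance for any 0 <= rho < 1.
equicorrelated_noise <- function(n, p, rho) {
  z <- matrix(stats::rnorm(n * p), nrow = n, ncol = p)
  if (p == 1L || rho == 0) return(z)
  sigma <- matrix(rho, p, p)
  diag(sigma) <- 1
  z %*% chol(sigma)
}
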