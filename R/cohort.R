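#' Construct a cohort
#'
#' A cohort is the universal input of the package: one row per subject with
#' chronological age (years), an ordinal diagnostic class code, and a matrix
#' of numeric MRI-derived features (e.g. left/right hippocampal volumes).
#'
#' Class codes are ordinal integers `0..(K-1)` in disease-severity order
#' (default NC = 0, MCI = 1, AD = 2) so that a positive correlation between
#' an age variant and the class code reads as "older with more severe
#' disease".
#'
#' @param subject_id character vector of subject identifiers (never used in
#'   computation, only carried through I/O).
#' @param age numeric vector of chronological ages in years; strictly
#'   positive and finite.
#' @param class_label integer vector of ordinal class codes `0..(K-1)`.
#' @param class_names character vector of length K giving the class name for
#'   each code, in code order.
#' @param features numeric matrix, one row per subject, named columns, no
#'   missing values.
#' @return An object of class `"cohort"`.
#' @examples
#' coh <- cohort(
#'   subject_id = c("s1", "s2", "s3"),
#'   age = c(70, 75, 80),
#'   class_label = c(0L, 1L, 2L),
#'   class_names = c("NC", "MCI", "AD"),
#'   features = cbind(left = c(3.1, 2.9, 2.5), right = c(3.2, 3.0, 2.6))
#' )
#' @export
cohort <- function(subject_id, age, class_label, class_names, features) {
  if (is.data.frame(features)) features <- as.matrix(features)
  storage.mode(features) <- "double"
  x <- structure(
    list(
      subject_id = as.character(subject_id),
      age = as.numeric(age),
      class_label = as.integer(class_label),
      class_names = as.character(class_names),
      features = features
    ),
    class = "cohort"
  )
  validate_cohort(x)
}

#' Validate a cohort's invariants
#'
#' Checks positive finite ages, contiguous class codes `0..(K-1)` with
#' K >= 2 classes named, one feature row per subject and no missing values.
#'
#' @param x a `"cohort"` object.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_cohort <- function(x) {
  stopifnot(inherits(x, "cohort"))
  n <- length(x$age)
  if (length(x$subject_id) != n) {
    stop("cohort: subject_id length (", length(x$subject_id),
         ") differs from number of subjects (", n, ")")
  }
  if (n < 1L) stop("cohort: at least one subject required")
  if (anyNA(x$age) || any(!is.finite(x$age)) || any(x$age <= 0)) {
    stop("cohort: ages must be strictly positive and finite")
  }
  k <- length(x$class_names)
  if (k < 2L) stop("cohort: at least two classes must be named")
  if (anyNA(x$class_label)) stop("cohort: missing class labels")
  if (!all(x$class_label %in% 0:(k - 1L))) {
    stop("cohort: class_label values must lie in 0..", k - 1L)
  }
  if (!is.matrix(x$features) || !is.numeric(x$features)) {
    stop("cohort: features must be a numeric matrix")
  }
  if (nrow(x$features) != n) {
    stop("cohort: features has ", nrow(x$features), " rows for ", n, " subjects")
  }
  if (ncol(x$features) < 1L) stop("cohort: at least one feature required")
  if (is.null(colnames(x$features)) || anyNA(colnames(x$features)) ||
      any(colnames(x$features) == "")) {
    stop("cohort: feature columns must be named")
  }
  if (anyNA(x$features) || any(!is.finite(x$features))) {
    stop("cohort: features must be finite with no missing values")
  }
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  counts <- class_counts(x)
  cat("cohort: ", length(x$age), " subjects, ",
      ncol(x$features), " features (",
      paste(colnames(x$features), collapse = ", "), ")\n", sep = "")
  cat("classes:", paste(sprintf("%s=%d (n=%d)", x$class_names,
                                seq_along(x$class_names) - 1L, counts),
                        collapse = ", "), "\n")
  cat(sprintf("age: %.1f-%.1f years (mean %.2f)\n",
              min(x$age), max(x$age), mean(x$age)))
  invisible(x)
}

#' Number of subjects per class
#'
#' @param cohort a `"cohort"` object.
#' @return Integer vector of length K, named by class, counting subjects
#'   with each class code (0 for empty classes).
#' @export
class_counts <- function(cohort) {
  validate_cohort(cohort)
  k <- length(cohort$class_names)
  counts <- tabulate(cohort$class_label + 1L, nbins = k)
  names(counts) <- cohort$class_names
  counts
}

#' Take a subset of a cohort's subjects
#'
#' @param cohort a `"cohort"` object.
#' @param idx integer or logical index over subjects.
#' @return A `"cohort"` with the selected subjects (class set unchanged).
#' @export
subset_cohort <- function(cohort, idx) {
  validate_cohort(cohort)
  cohort(
    subject_id = cohort$subject_id[idx],
    age = cohort$age[idx],
    class_label = cohort$class_label[idx],
    class_names = cohort$class_names,
    features = cohort$features[idx, , drop = FALSE]
  )
}

#' Restrict a cohort to a subset of classes
#'
#' Keeps only subjects of the named classes and recodes the class labels to
#' a contiguous `0..(K'-1)` range in the order given, so that e.g. an
#' NC/MCI/AD cohort can be reduced to a two-class NC-AD problem.
#'
#' @param cohort a `"cohort"` object.
#' @param classes character vector of class names to keep (>= 2), in the
#'   desired severity order.
#' @return A `"cohort"` over the selected classes.
#' @export
filter_classes <- function(cohort, classes) {
  validate_cohort(cohort)
  if (!all(classes %in% cohort$class_names)) {
    stop("filter_classes: unknown class name(s): ",
         paste(setdiff(classes, cohort$class_names), collapse = ", "))
  }
  if (length(classes) < 2L) stop("filter_classes: keep at least two classes")
  old_codes <- match(classes, cohort$class_names) - 1L
  keep <- cohort$class_label %in% old_codes
  new_label <- match(cohort$class_label[keep], old_codes) - 1L
  cohort(
    subject_id = cohort$subject_id[keep],
    age = cohort$age[keep],
    class_label = new_label,
    class_names = classes,
    features = cohort$features[keep, , drop = FALSE]
  )
}

#' Column mapping for cohort CSV files
#'
#' Declares which CSV columns hold the subject identifier, age and class,
#' how class name strings map to ordinal codes, and (optionally) which
#' columns are features.
#'
#' @param subject_id name of the subject identifier column.
#' @param age name of the age column (years).
#' @param class name of the diagnostic class column (name strings).
#' @param class_names class names in ordinal (severity) order; the first
#'   maps to code 0. Default `c("NC", "MCI", "AD")`.
#' @param features optional character vector naming the feature columns;
#'   `NULL` (default) takes every remaining column.
#' @return A list of class `"cohort_column_map"`.
#' @export
cohort_column_map <- function(subject_id = "subject_id", age = "age",
                              class = "class",
                              class_names = c("NC", "MCI", "AD"),
                              features = NULL) {
  structure(
    list(subject_id = subject_id, age = age, class = class,
         class_names = as.character(class_names), features = features),
    class = "cohort_column_map"
  )
}

#' Read a cohort from a CSV file
#'
#' Expects a UTF-8 comma-separated file with a header row; the canonical
#' layout is `subject_id,age,class,<feature1>,<feature2>,...` with the class
#' written as a name string (e.g. NC/MCI/AD). Decimal point, no thousands
#' separators.
#'
#' @param path path to the CSV file.
#' @param column_map a [cohort_column_map()] describing the columns.
#' @return A `"cohort"`.
#' @seealso [write_cohort_csv()]
#' @export
read_cohort_csv <- function(path, column_map = cohort_column_map()) {
  if (!file.exists(path)) stop("read_cohort_csv: no such file: ", path)
  stopifnot(inherits(column_map, "cohort_column_map"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  for (role in c("subject_id", "age", "class")) {
    if (!column_map[[role]] %in% names(df)) {
      stop("read_cohort_csv: missing required column '", column_map[[role]],
           "' (role: ", role, ")")
    }
  }
  feat_cols <- column_map$features
  if (is.null(feat_cols)) {
    feat_cols <- setdiff(names(df), c(column_map$subject_id, column_map$age,
                                      column_map$class))
  } else if (!all(feat_cols %in% names(df))) {
    stop("read_cohort_csv: missing feature column(s): ",
         paste(setdiff(feat_cols, names(df)), collapse = ", "))
  }
  if (length(feat_cols) < 1L) {
    stop("read_cohort_csv: no feature columns found")
  }
  age <- parse_numeric_column(df[[column_map$age]], column_map$age)
  cls <- as.character(df[[column_map$class]])
  unknown <- !cls %in% column_map$class_names
  if (any(unknown)) {
    stop("read_cohort_csv: unknown class string '", cls[which(unknown)[1L]],
         "' in row ", which(unknown)[1L])
  }
  features <- do.call(cbind, lapply(feat_cols, function(cn) {
    parse_numeric_column(df[[cn]], cn)
  }))
  colnames(features) <- feat_cols
  cohort(
    subject_id = df[[column_map$subject_id]],
    age = age,
    class_label = match(cls, column_map$class_names) - 1L,
    class_names = column_map$class_names,
    features = features
  )
}

# strict numeric parsing: blank or non-numeric cells name the offending row
parse_numeric_column <- function(x, col) {
  raw <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(raw))
  bad <- which(is.na(out) | raw == "")
  if (length(bad) > 0L) {
    stop("read_cohort_csv: non-numeric or missing value in column '", col,
         "', row ", bad[1L])
  }
  out
}

#' Write a cohort to a CSV file
#'
#' Inverse of [read_cohort_csv()]: writes header
#' `subject_id,age,class,<features...>` with the class as its name string.
#'
#' @param cohort a `"cohort"`.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  validate_cohort(cohort)
  df <- data.frame(
    subject_id = cohort$subject_id,
    age = cohort$age,
    class = cohort$class_names[cohort$class_label + 1L],
    cohort$features,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("write_cohort_csv: cannot write to '", path, "': ",
                        conditionMessage(ok))
  invisible(path)
}

#' Balance class sizes by subsampling
#'
#' Subsamples every class without replacement down to the smallest class
#' size, eliminating the effect of unbalanced samples (e.g. 540/534/411
#' NC/MCI/AD subjects reduce to 411 per class). Deterministic given `seed`.
#'
#' @param cohort a `"cohort"`; every class must have at least one subject.
#' @param seed integer seed controlling which subjects are kept.
#' @return A `"cohort"` with equal class counts, subjects in original order.
#' @export
balance_classes <- function(cohort, seed) {
  validate_cohort(cohort)
  counts <- class_counts(cohort)
  if (any(counts == 0L)) {
    stop("balance_classes: class(es) with no subjects: ",
         paste(names(counts)[counts == 0L], collapse = ", "))
  }
  m <- min(counts)
  keep <- with_local_seed(seed, {
    unlist(lapply(seq_along(counts) - 1L, function(k) {
      idx <- which(cohort$class_label == k)
      if (length(idx) == m) idx else sort(sample(idx, m))
    }))
  })
  subset_cohort(cohort, sort(keep))
}

# Run code under a temporary RNG state so package functions that take an
# explicit seed never disturb the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
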