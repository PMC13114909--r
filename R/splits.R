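#' Specification of a dataset split
#'
#' Records which acquisition days form the training and test portions, the
#' stratified validation fraction, a label-subsampling ratio for
#' label-efficiency runs, and the seed that makes all of it reproducible.
#'
#' @param train_days integer vector of training days.
#' @param test_days integer vector of held-out test days (disjoint from
#'   `train_days`; may be empty).
#' @param val_fraction fraction of the training portion split off as a
#'   stratified validation subset, in `[0, 1)`.
#' @param subsample_ratio stratified label-subsampling ratio in `(0, 1]`.
#' @param seed integer seed.
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(train_days = 1:8, test_days = 9:10, val_fraction = 0.2,
                       subsample_ratio = 1, seed = 1L) {
  train_days <- as.integer(train_days)
  test_days <- as.integer(test_days)
  if (length(intersect(train_days, test_days)) > 0L) {
    stop("train_days and test_days must be disjoint")
  }
  if (val_fraction < 0 || val_fraction >= 1) stop("val_fraction must be in [0, 1)")
  if (subsample_ratio <= 0 || subsample_ratio > 1) {
    stop("subsample_ratio must be in (0, 1]")
  }
  structure(
    list(train_days = train_days, test_days = test_days,
         val_fraction = val_fraction, subsample_ratio = subsample_ratio,
         seed = as.integer(seed)),
    class = "split_spec"
  )
}

#' Day-wise train/test split
#'
#' Partitions a dataset by acquisition session so that test measurements come
#' from days never seen in training — the deployment-realistic alternative to
#' random splitting for multi-day E-nose campaigns.
#'
#' @param ds an [enose_dataset()].
#' @param spec a [split_spec()] (only its day sets are used here).
#' @return a list with elements `train`, `test` (an `enose_dataset` or `NULL`
#'   when `test_days` is empty), and `report` (per-class counts per partition).
#' @export
day_wise_split <- function(ds, spec) {
  all_days <- c(spec$train_days, spec$test_days)
  bad <- setdiff(unique(ds$day), all_days)
  if (length(bad) > 0L) {
    stop("measurement day(s) outside train_days + test_days: ",
         paste(sort(bad), collapse = ", "))
  }
  in_train <- ds$day %in% spec$train_days
  train <- ds[in_train]
  test <- if (any(!in_train)) ds[!in_train] else NULL
  report <- list(
    train_counts = class_counts(train),
    test_counts = if (is.null(test)) {
      stats::setNames(integer(ds$n_classes), ds$class_names)
    } else {
      class_counts(test)
    },
    empty_test = is.null(test)
  )
  list(train = train, test = test, report = report)
}

# Largest-remainder allocation of `total` units over classes proportionally to
# `sizes`, each allocation capped at its class size and within +-1 of the
# proportional share. Remainder ties are broken in seed-shuffled class order.
largest_remainder_alloc <- function(sizes, total, seed) {
  k <- length(sizes)
  share <- sizes / sum(sizes) * total
  base <- floor(share)
  rem <- share - base
  left <- total - sum(base)
  if (left > 0L) {
    order_tiebreak <- with_seed(derive_seed(seed, "alloc"), sample.int(k))
    o <- order(-rem, order_tiebreak)
    take <- o[seq_len(left)]
    base[take] <- base[take] + 1
  }
  pmin(as.integer(base), as.integer(sizes))
}

#' Stratified validation split
#'
#' Splits `round(frac * n)` samples off as a validation subset, allocated over
#' classes by largest remainder so per-class validation counts differ by at
#' most one from the proportional share. Deterministic given the seed.
#'
#' @param train an [enose_dataset()].
#' @param frac validation fraction in `(0, 1)`.
#' @param seed integer seed.
#' @return list with `fit` and `val` datasets (disjoint, union = `train`).
#' @export
stratified_validation_split <- function(train, frac, seed) {
  if (frac <= 0 || frac >= 1) stop("frac must be strictly inside (0, 1)")
  counts <- class_counts(train)
  if (any(counts < 2L)) {
    stop("every class needs >= 2 samples to split off validation; got min ",
         min(counts))
  }
  total_val <- round_half_up(frac * length(train))
  total_val <- max(1L, min(total_val, length(train) - train$n_classes))
  per_class <- largest_remainder_alloc(counts, total_val, seed)
  # never let validation empty a class on the fit side
  per_class <- pmin(per_class, counts - 1L)
  val_idx <- integer(0)
  for (k in seq_len(train$n_classes)) {
    members <- which(train$class_label == k - 1L)
    if (per_class[k] > 0L) {
      pick <- with_seed(
        derive_seed(seed, paste0("val_class_", k)),
        sample(members, per_class[k])
      )
      val_idx <- c(val_idx, pick)
    }
  }
  val_idx <- sort(val_idx)
  fit_idx <- setdiff(seq_len(length(train)), val_idx)
  list(fit = train[fit_idx], val = train[val_idx])
}

#' Stratified label subsampling
#'
#' Retains `round_half_up(ratio * n)` samples, allocated across classes by
#' largest remainder (per-class counts within one of the proportional share),
#' emulating progressively reduced target-domain annotation budgets.
#'
#' @param train an [enose_dataset()].
#' @param ratio retention ratio in `(0, 1]`.
#' @param seed integer seed.
#' @return the subsampled `enose_dataset` (identity when `ratio = 1`).
#' @export
stratified_subsample <- function(train, ratio, seed) {
  if (ratio <= 0 || ratio > 1) stop("ratio must be in (0, 1]")
  if (ratio == 1) return(train)
  n <- length(train)
  total <- subsample_total(n, ratio)
  counts <- class_counts(train)
  per_class <- largest_remainder_alloc(counts, total, seed)
  if (any(per_class == 0L & counts > 0L)) {
    stop("ratio ", ratio, " would empty at least one class")
  }
  keep <- integer(0)
  for (k in seq_len(train$n_classes)) {
    members <- which(train$class_label == k - 1L)
    if (per_class[k] > 0L) {
      keep <- c(keep, with_seed(
        derive_seed(seed, paste0("sub_class_", k)),
        sample(members, per_class[k])
      ))
    }
  }
  train[sort(keep)]
}

#' Total retained count for a subsampling ratio
#'
#' Nearest integer to `ratio * n` with halves rounded up — e.g. 288 samples at
#' 60% keep 173 (172.8 rounds up) while 40% keep 115 (115.2 rounds down).
#'
#' @param n number of samples.
#' @param ratio retention ratio.
#' @return integer retained count.
#' @export
subsample_total <- function(n, ratio) round_half_up(ratio * n)

round_half_up <- function(x) as.integer(floor(x + 0.5))

#' Fit a feature standardizer
#'
#' Column-wise z-scoring statistics estimated on a training matrix only (never
#' on test data). Constant columns get their standard deviation floored so the
#' transformed column is all zeros.
#'
#' @param features numeric matrix (rows = samples).
#' @param fitted_on `"source_train"` or `"target_train"` bookkeeping tag.
#' @return an object of class `standardizer`.
#' @export
fit_standardizer <- function(features, fitted_on = "source_train") {
  features <- as.matrix(features)
  if (nrow(features) < 1L) stop("cannot fit a standardizer on an empty matrix")
  mu <- colMeans(features)
  s <- sqrt(colMeans(sweep(features, 2L, mu)^2))
  structure(
    list(mean = mu, std = pmax(s, STD_FLOOR),
         fitted_on = match.arg(fitted_on, c("source_train", "target_train")),
         n_features = ncol(features)),
    class = "standardizer"
  )
}

#' Apply a fitted standardizer
#' @param s a [fit_standardizer()] object.
#' @param features numeric matrix with the same number of columns as the
#'   fitting matrix.
#' @return the standardized matrix `(x - mean) / std`.
#' @export
apply_standardizer <- function(s, features) {
  features <- as.matrix(features)
  if (ncol(features) != s$n_features) {
    stop("feature count mismatch: standardizer fitted on ", s$n_features,
         " features, got ", ncol(features))
  }
  sweep(sweep(features, 2L, s$mean), 2L, s$std, "/")
}

# Flatten a dataset to an n x 1200 feature matrix (sensor-major rows).
flatten_dataset <- function(ds) {
  n <- length(ds)
  matrix(ds$x, n, C_SENSORS * T_STEPS)
}

# Replace dataset values from a flat n x 1200 matrix.
unflatten_dataset <- function(ds, mat) {
  ds$x <- array(mat, c(length(ds), C_SENSORS, T_STEPS))
  ds
}

#' Write a split manifest
#'
#' Records the sample ids of every partition plus the generating [split_spec()]
#' as JSON, the leakage-audit trail for the three-stage protocol.
#'
#' @param path output JSON path.
#' @param spec the [split_spec()] used.
#' @param ... named character vectors of sample ids, one per partition.
#' @return `path`, invisibly.
#' @export
write_split_manifest <- function(path, spec, ...) {
  parts <- list(...)
  jsonlite::write_json(
    list(
      spec = list(
        train_days = spec$train_days, test_days = spec$test_days,
        val_fraction = spec$val_fraction,
        subsample_ratio = spec$subsample_ratio, seed = spec$seed
      ),
      partitions = parts
    ),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
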