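#' Steady-state sensor features
#'
#' Averages each channel over the final 20 sampling steps (0-based time
#' indices 100-119), where MOS responses have plateaued, yielding the classic
#' 10-dimensional steady-state feature vector per measurement.
#'
#' @param ds an [enose_dataset()].
#' @return an `n x 10` numeric matrix.
#' @export
steady_state_features <- function(ds) {
  window <- (T_STEPS - 19L):T_STEPS
  feats <- rowMeans(ds$x[, , window, drop = FALSE], dims = 2L)
  dimnames(feats) <- list(ds$sample_id, paste0("sensor_", 0:(C_SENSORS - 1L)))
  feats
}

#' PCA summary of a feature matrix
#'
#' Z-scores the columns (population statistics, variance floored) and
#' eigen-decomposes the covariance, returning the proportion of variance per
#' component and the projected scores.
#'
#' @param features numeric `n x p` matrix, `n >= 3`.
#' @return list with `explained_variance_ratio` (descending, sums to 1) and
#'   `scores` (`n x p` projections).
#' @export
pca_summary <- function(features) {
  features <- as.matrix(features)
  if (nrow(features) < 3L) stop("pca_summary needs at least 3 samples")
  std <- fit_standardizer(features)
  z <- apply_standardizer(std, features)
  p <- prcomp(z, center = FALSE, scale. = FALSE)
  ev <- p$sdev^2
  list(
    explained_variance_ratio = ev / sum(ev),
    scores = p$x,
    rotation = p$rotation
  )
}

#' Multi-kernel maximum mean discrepancy
#'
#' Kernel two-sample discrepancy between source and target feature samples
#' using a bank of Gaussian kernels. The base bandwidth is the median pairwise
#' squared Euclidean distance over the pooled sample; each kernel scales it by
#' one of `bandwidth_factors`. The default estimator is the biased V-statistic
#' `mean(K_ss) + mean(K_tt) - 2 mean(K_st)`, which is non-negative; the
#' unbiased U-statistic (diagonal removed, may be negative) is available via
#' `biased = FALSE`. The combined value is the mean of the per-kernel MMD^2.
#'
#' @param fs `n_s x d` source feature matrix, `n_s >= 2`.
#' @param ft `n_t x d` target feature matrix, `n_t >= 2`.
#' @param bandwidth_factors multiplicative factors on the median-heuristic
#'   bandwidth.
#' @param biased use the biased (V-statistic) estimator (default `TRUE`).
#' @return an object of class `mmd_report`: `bandwidths`, `per_kernel_mmd2`,
#'   `combined`.
#' @export
multikernel_mmd <- function(fs, ft,
                            bandwidth_factors = c(0.25, 0.5, 1, 2, 4),
                            biased = TRUE) {
  fs <- as.matrix(fs)
  ft <- as.matrix(ft)
  if (nrow(fs) < 2L || nrow(ft) < 2L) {
    stop("multikernel_mmd needs at least 2 samples per side")
  }
  if (ncol(fs) != ncol(ft)) stop("feature dimension mismatch")
  pooled <- rbind(fs, ft)
  d2 <- sq_dists(pooled, pooled)
  base_bw <- stats::median(d2[upper.tri(d2)])
  if (base_bw <= 0) base_bw <- 1
  n_s <- nrow(fs)
  n_t <- nrow(ft)
  iss <- seq_len(n_s)
  itt <- n_s + seq_len(n_t)
  bw <- base_bw * bandwidth_factors
  per_kernel <- vapply(bw, function(b) {
    K <- exp(-d2 / (2 * b))
    Kss <- K[iss, iss]
    Ktt <- K[itt, itt]
    Kst <- K[iss, itt]
    if (biased) {
      mean(Kss) + mean(Ktt) - 2 * mean(Kst)
    } else {
      sum(Kss - diag(diag(Kss))) / (n_s * (n_s - 1)) +
        sum(Ktt - diag(diag(Ktt))) / (n_t * (n_t - 1)) -
        2 * mean(Kst)
    }
  }, 0)
  structure(
    list(bandwidths = bw, bandwidth_factors = bandwidth_factors,
         per_kernel_mmd2 = per_kernel, combined = mean(per_kernel),
         biased = biased, n_source = n_s, n_target = n_t),
    class = "mmd_report"
  )
}

#' @export
print.mmd_report <- function(x, ...) {
  cat("<mmd_report> combined MMD^2 =", format(x$combined, digits = 6),
      if (x$biased) "(biased estimator)" else "(unbiased estimator)", "\n")
  cat("  per-kernel:", paste(format(x$per_kernel_mmd2, digits = 4),
                             collapse = " "), "\n")
  invisible(x)
}

# squared Euclidean distance matrix between row sets
sq_dists <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Export features for external 2-D embedding
#'
#' Writes one row per sample with the feature columns plus `class` and
#' `domain`, ready for any external embedding tool (t-SNE, UMAP, ...).
#'
#' @param features numeric matrix, one row per sample.
#' @param labels integer class labels (0-based).
#' @param domains character domain tags.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_embeddings <- function(features, labels, domains, path) {
  features <- as.matrix(features)
  if (nrow(features) != length(labels) || nrow(features) != length(domains)) {
    stop("features, labels and domains must have matching lengths")
  }
  dt <- data.table::as.data.table(features)
  data.table::setnames(dt, paste0("f", seq_len(ncol(features))))
  data.table::set(dt, j = "class", value = as.integer(labels))
  data.table::set(dt, j = "domain", value = as.character(domains))
  data.table::fwrite(dt, path)
  invisible(path)
}
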