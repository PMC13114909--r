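#' Construct a single E-nose measurement
#'
#' A measurement is one exposure of a 10-sensor metal-oxide array to a sample's
#' headspace, recorded at 1-s intervals over the 120-s sampling stage, i.e. a
#' 10 x 120 response matrix plus class/domain/day metadata.
#'
#' @param values numeric 10 x 120 matrix of sensor responses (rows = sensors).
#' @param sample_id character identifier, unique within a dataset.
#' @param class_label integer class index, 0-based.
#' @param domain `"source"` or `"target"`.
#' @param day acquisition day (1-based session index).
#' @return an object of class `enose_measurement`.
#' @export
enose_measurement <- function(values, sample_id, class_label, domain = "source",
                              day = 1L) {
  values <- as.matrix(values)
  m <- structure(
    list(
      values = values,
      sample_id = as.character(sample_id),
      class_label = as.integer(class_label),
      domain = match.arg(domain, c("source", "target")),
      day = as.integer(day)
    ),
    class = "enose_measurement"
  )
  validate_measurement(m)
  m
}

validate_measurement <- function(m) {
  v <- m$values
  if (!is.matrix(v) || nrow(v) != C_SENSORS || ncol(v) != T_STEPS) {
    stop("measurement values must be a ", C_SENSORS, " x ", T_STEPS,
         " matrix, got ", paste(dim(v), collapse = " x "))
  }
  if (!all(is.finite(v))) {
    stop("measurement '", m$sample_id, "' contains non-finite values")
  }
  if (is.na(m$class_label) || m$class_label < 0L) {
    stop("class_label must be a non-negative integer")
  }
  if (is.na(m$day) || m$day < 1L) stop("day must be a positive integer")
  invisible(m)
}

#' @export
print.enose_measurement <- function(x, ...) {
  cat("<enose_measurement>", x$sample_id, "\n")
  cat("  domain:", x$domain, " class:", x$class_label, " day:", x$day, "\n")
  cat("  response range: [", format(min(x$values), digits = 4), ",",
      format(max(x$values), digits = 4), "]\n")
  invisible(x)
}

#' Construct a labeled E-nose dataset
#'
#' The dataset container stores all measurements in one `n x 10 x 120` array
#' with parallel metadata vectors; this is the unit every splitting, training
#' and analysis function operates on.
#'
#' @param x numeric array `n x 10 x 120`.
#' @param sample_id character vector of length n.
#' @param class_label integer vector of 0-based class indices.
#' @param domain `"source"`/`"target"`, scalar or length-n vector.
#' @param day integer vector of acquisition days (1-based).
#' @param n_classes number of classes; defaults to `max(class_label) + 1`.
#' @param class_names optional character vector of length `n_classes`.
#' @return an object of class `enose_dataset`.
#' @export
enose_dataset <- function(x, sample_id, class_label, domain = "source",
                          day = 1L, n_classes = NULL, class_names = NULL) {
  if (length(dim(x)) != 3L) stop("x must be an n x 10 x 120 array")
  n <- dim(x)[1L]
  if (n < 1L) stop("dataset must be non-empty")
  if (dim(x)[2L] != C_SENSORS || dim(x)[3L] != T_STEPS) {
    stop("x must be n x ", C_SENSORS, " x ", T_STEPS)
  }
  if (!all(is.finite(x))) stop("dataset contains non-finite values")
  class_label <- as.integer(class_label)
  if (is.null(n_classes)) n_classes <- max(class_label) + 1L
  n_classes <- as.integer(n_classes)
  if (any(class_label < 0L) || any(class_label >= n_classes)) {
    stop("every class_label must lie in [0, n_classes)")
  }
  if (is.null(class_names)) class_names <- paste0("class_", seq_len(n_classes) - 1L)
  domain <- rep_len(as.character(domain), n)
  if (!all(domain %in% c("source", "target"))) {
    stop("domain must be 'source' or 'target'")
  }
  ds <- structure(
    list(
      x = x,
      sample_id = rep_len(as.character(sample_id), n),
      class_label = rep_len(class_label, n),
      domain = domain,
      day = rep_len(as.integer(day), n),
      n_classes = n_classes,
      class_names = class_names
    ),
    class = "enose_dataset"
  )
  ds
}

#' Bundle individual measurements into a dataset
#'
#' @param measurements list of [enose_measurement()] objects.
#' @param n_classes,class_names see [enose_dataset()].
#' @return an `enose_dataset`.
#' @export
as_enose_dataset <- function(measurements, n_classes = NULL, class_names = NULL) {
  stopifnot(length(measurements) > 0L)
  n <- length(measurements)
  x <- array(0, c(n, C_SENSORS, T_STEPS))
  for (i in seq_len(n)) x[i, , ] <- measurements[[i]]$values
  enose_dataset(
    x,
    sample_id = vapply(measurements, `[[`, "", "sample_id"),
    class_label = vapply(measurements, `[[`, 0L, "class_label"),
    domain = vapply(measurements, `[[`, "", "domain"),
    day = vapply(measurements, `[[`, 0L, "day"),
    n_classes = n_classes, class_names = class_names
  )
}

#' @export
length.enose_dataset <- function(x) dim(x$x)[1L]

#' Subset an E-nose dataset by sample index
#' @param x an `enose_dataset`.
#' @param i integer or logical index over samples.
#' @param ... unused.
#' @return an `enose_dataset` with the selected samples.
#' @export
`[.enose_dataset` <- function(x, i, ...) {
  idx <- seq_len(length(x))[i]
  if (length(idx) == 0L) stop("cannot create an empty enose_dataset subset")
  enose_dataset(
    x$x[idx, , , drop = FALSE],
    sample_id = x$sample_id[idx],
    class_label = x$class_label[idx],
    domain = x$domain[idx],
    day = x$day[idx],
    n_classes = x$n_classes,
    class_names = x$class_names
  )
}

#' @export
print.enose_dataset <- function(x, ...) {
  cat("<enose_dataset> ", length(x), " measurements, ", x$n_classes,
      " classes, domain(s): ", paste(unique(x$domain), collapse = "/"),
      ", days ", min(x$day), "-", max(x$day), "\n", sep = "")
  tab <- class_counts(x)
  cat("  per-class counts: ", paste(tab, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Per-class sample counts
#' @param ds an `enose_dataset`.
#' @return integer vector of length `n_classes`, named by class.
#' @export
class_counts <- function(ds) {
  tab <- tabulate(ds$class_label + 1L, nbins = ds$n_classes)
  names(tab) <- ds$class_names
  tab
}

#' Per-channel instance normalization
#'
#' Z-scores each sensor channel across its 120 time steps using population
#' statistics, removing per-measurement sensor-level offset and scale before
#' the network sees the signal. Channels with (near-)zero variance map to all
#' zeros: the standard deviation is floored at `1e-8` before division. No
#' learnable affine parameters are applied, since re-introducing a per-channel
#' offset/scale would undo exactly the variability this step removes.
#'
#' @param m an [enose_measurement()], an [enose_dataset()], or a bare
#'   10 x 120 matrix.
#' @return the same type of object with every channel row at mean 0, sd 1.
#' @export
instance_normalize <- function(m) {
  if (inherits(m, "enose_dataset")) {
    m$x <- instance_normalize_array(m$x)
    return(m)
  }
  if (inherits(m, "enose_measurement")) {
    validate_measurement(m)
    m$values <- normalize_rows(m$values)
    return(m)
  }
  if (is.matrix(m)) {
    if (!all(is.finite(m))) stop("cannot normalize non-finite input")
    return(normalize_rows(m))
  }
  stop("instance_normalize expects a measurement, dataset, or matrix")
}

normalize_rows <- function(v) {
  mu <- rowMeans(v)
  centered <- v - mu
  # population sd per channel, floored for constant rows
  s <- sqrt(rowMeans(centered^2))
  centered / pmax(s, STD_FLOOR)
}

instance_normalize_array <- function(x) {
  if (!all(is.finite(x))) stop("cannot normalize non-finite input")
  n <- dim(x)[1L]
  mu <- rowMeans(x, dims = 2L)            # n x C
  centered <- x - as.vector(mu)           # recycles over time dim
  s <- sqrt(rowMeans(centered^2, dims = 2L))
  centered / as.vector(pmax(s, STD_FLOOR))
}
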