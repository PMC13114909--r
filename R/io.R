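#' Write an E-nose dataset as long-format CSV
#'
#' One row per (sample, sensor, time) observation with columns `sample_id`,
#' `domain`, `class_label`, `day`, `sensor_index` (0-9), `time_index` (0-119)
#' and `value` — a plain-text interchange format any downstream tool can read.
#'
#' @param ds an [enose_dataset()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_enose_csv <- function(ds, path) {
  n <- length(ds)
  # column-major unrolling of the n x C x T array: sample varies fastest,
  # then sensor, then time
  dt <- data.table::data.table(
    sample_id = rep(ds$sample_id, times = C_SENSORS * T_STEPS),
    domain = rep(ds$domain, times = C_SENSORS * T_STEPS),
    class_label = rep(ds$class_label, times = C_SENSORS * T_STEPS),
    day = rep(ds$day, times = C_SENSORS * T_STEPS),
    sensor_index = rep(rep(0:(C_SENSORS - 1L), each = n), times = T_STEPS),
    time_index = rep(0:(T_STEPS - 1L), each = n * C_SENSORS),
    value = as.vector(ds$x)
  )
  data.table::setorderv(dt, c("sample_id", "sensor_index", "time_index"))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read an E-nose dataset from long-format CSV
#'
#' Inverse of [write_enose_csv()].
#'
#' @param path CSV path.
#' @param n_classes optional class count (defaults to `max(class_label) + 1`).
#' @return an [enose_dataset()].
#' @export
read_enose_csv <- function(path, n_classes = NULL) {
  dt <- data.table::fread(path)
  need <- c("sample_id", "domain", "class_label", "day", "sensor_index",
            "time_index", "value")
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols) > 0L) {
    stop("CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  ids <- unique(dt$sample_id)
  n <- length(ids)
  x <- array(NA_real_, c(n, C_SENSORS, T_STEPS))
  idx <- match(dt$sample_id, ids)
  x[cbind(idx, dt$sensor_index + 1L, dt$time_index + 1L)] <- dt$value
  if (anyNA(x)) stop("CSV does not cover every (sample, sensor, time) cell")
  meta <- dt[!duplicated(dt$sample_id), ]
  meta <- meta[match(ids, meta$sample_id), ]
  enose_dataset(
    x, sample_id = ids, class_label = meta$class_label,
    domain = meta$domain, day = meta$day, n_classes = n_classes
  )
}
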