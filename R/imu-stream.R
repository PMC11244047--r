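#' Construct an IMU stream tibble
#'
#' An IMU stream is a tibble of uniformly sampled six-axis sensor readings:
#' time `t` in seconds, accelerometer channels `ax, ay, az` in g, gyroscope
#' channels `gx, gy, gz` in degrees per second, and an optional per-sample
#' `label` column (a movement class code or `"transition"`). The sampling
#' rate is carried in the `rate_hz` attribute.
#'
#' @param data data frame with columns `t, ax, ay, az, gx, gy, gz` and
#'   optionally `label`.
#' @param rate_hz sampling rate in Hz.
#' @return A tibble of class `imu_stream`.
#' @export
imu_stream <- function(data, rate_hz) {
  stopifnot(is.data.frame(data), is.numeric(rate_hz), rate_hz > 0)
  need <- c("t", IMU_CHANNELS)
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    rlang::abort(paste0("missing IMU column(s): ", paste(missing, collapse = ", ")))
  }
  if ("label" %in% names(data)) {
    assert_known_classes(data$label, allow_transition = TRUE)
  }
  out <- tibble::as_tibble(data)
  attr(out, "rate_hz") <- as.numeric(rate_hz)
  class(out) <- c("imu_stream", class(tibble::tibble()))
  out
}

#' Sampling rate of an IMU stream
#'
#' @param stream an [imu_stream()].
#' @return Sampling rate in Hz.
#' @export
imu_rate <- function(stream) {
  r <- attr(stream, "rate_hz")
  if (is.null(r)) {
    # fall back to the time axis when the attribute was stripped by wrangling
    if (nrow(stream) < 2) rlang::abort("cannot infer sampling rate from < 2 samples")
    r <- (nrow(stream) - 1) / (stream$t[nrow(stream)] - stream$t[1])
  }
  r
}

stream_matrix <- function(stream) {
  as.matrix(stream[, IMU_CHANNELS])
}

replace_channels <- function(stream, mat) {
  for (i in seq_along(IMU_CHANNELS)) stream[[IMU_CHANNELS[i]]] <- mat[, i]
  stream
}

clip_to_range <- function(mat) {
  mat[, 1:3] <- pmin(pmax(mat[, 1:3], -ACCEL_RANGE_G), ACCEL_RANGE_G)
  mat[, 4:6] <- pmin(pmax(mat[, 4:6], -GYRO_RANGE_DPS), GYRO_RANGE_DPS)
  mat
}

#' Write an IMU stream to CSV
#'
#' Writes `t,ax,ay,az,gx,gy,gz[,label]` with numeric values printed at 9
#' significant digits. Reading the file back with [read_imu_csv()] and
#' writing it again reproduces the file byte for byte.
#'
#' @param stream an [imu_stream()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(stream, path) {
  cols <- c("t", IMU_CHANNELS)
  out <- lapply(stream[cols], function(x) sprintf("%.9g", x))
  out <- do.call(cbind, out)
  header <- cols
  if ("label" %in% names(stream)) {
    out <- cbind(out, stream$label)
    header <- c(header, "label")
  }
  lines <- c(
    paste(header, collapse = ","),
    apply(out, 1, paste, collapse = ",")
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read an IMU stream from CSV
#'
#' @param path CSV file written by [write_imu_csv()] (or any file with the
#'   same header).
#' @param rate_hz sampling rate; if `NULL` it is inferred from the time axis.
#' @return An [imu_stream()].
#' @export
read_imu_csv <- function(path, rate_hz = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(rate_hz)) {
    rate_hz <- round((nrow(df) - 1) / (df$t[nrow(df)] - df$t[1]), 6)
  }
  imu_stream(df, rate_hz)
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf(
    "<imu_stream: %d samples @ %g Hz (%.2f s)%s>\n",
    nrow(x), imu_rate(x), nrow(x) / imu_rate(x),
    if ("label" %in% names(x)) ", labeled" else ""
  ))
  NextMethod()
}

#' Plot an IMU stream
#'
#' Facets the six sensor channels over time, colouring by movement label
#' when the stream is labeled.
#'
#' @param object an [imu_stream()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.imu_stream <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = dplyr::all_of(IMU_CHANNELS),
    names_to = "channel", values_to = "value"
  )
  long$channel <- factor(long$channel, levels = IMU_CHANNELS)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$value))
  if ("label" %in% names(long)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(colour = .data$label, group = 1))
  } else {
    p <- p + ggplot2::geom_line()
  }
  p +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}
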