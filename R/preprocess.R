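#' Zero-phase low-pass filter an IMU stream
#'
#' Butterworth low-pass applied forward and backward (zero phase), which
#' removes high-frequency sensor noise while preserving waveform timing --
#' the property windowed classification relies on. The signal is padded by
#' odd reflection at both ends before filtering to suppress edge transients,
#' so a constant input is returned unchanged and DC gain is exactly 1.
#'
#' @param stream an [imu_stream()].
#' @param cutoff_hz cutoff frequency in Hz; default 5, retaining the sub-5 Hz
#'   movement band of tai chi.
#' @param order Butterworth order (default 4). The forward-backward pass
#'   squares the magnitude response, i.e. an effective order of 8.
#' @param zero_phase apply the filter forward and backward (default `TRUE`);
#'   `FALSE` gives a single causal pass.
#' @return A filtered [imu_stream()] of the same length and rate.
#' @export
low_pass <- function(stream, cutoff_hz = 5, order = 4, zero_phase = TRUE) {
  rate <- imu_rate(stream)
  if (cutoff_hz <= 0 || cutoff_hz >= rate / 2) {
    rlang::abort(sprintf(
      "cutoff_hz must lie in (0, %g) for a %g Hz stream", rate / 2, rate
    ))
  }
  bf <- signal::butter(order, cutoff_hz / (rate / 2), type = "low")
  mat <- stream_matrix(stream)
  n <- nrow(mat)
  # reflect enough signal to absorb the filter transient (several time
  # constants of the cutoff period)
  pad <- min(n - 1, max(3 * (order + 1), round(8 * rate / cutoff_hz)))
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    left <- 2 * x[1] - x[seq(pad + 1, 2)]
    right <- 2 * x[n] - x[seq(n - 1, n - pad)]
    xp <- c(left, x, right)
    yp <- if (zero_phase) {
      signal::filtfilt(bf, xp)
    } else {
      signal::filter(bf, xp)
    }
    mat[, j] <- yp[(pad + 1):(pad + n)]
  }
  replace_channels(stream, mat)
}

#' Resample an IMU stream to a target rate
#'
#' Plain decimation when the source rate is an integer multiple of the
#' target; cubic-spline interpolation onto the target time grid otherwise.
#' Both are alias-free under the caller contract that the stream is already
#' low-passed below the target Nyquist (at 5 Hz content on a 25 Hz Nyquist
#' the signal is heavily oversampled, where spline interpolation is
#' spectrally accurate and exactly time-aligned). Per-sample labels are
#' carried over by nearest-sample mapping.
#'
#' @param stream an [imu_stream()], already low-passed below `target_hz / 2`.
#' @param target_hz target sampling rate; default 50 Hz, the rate common to
#'   smartphone deployments.
#' @return An [imu_stream()] at `target_hz`.
#' @export
resample_to <- function(stream, target_hz = 50) {
  rate <- imu_rate(stream)
  if (target_hz > rate) {
    rlang::abort("target_hz must not exceed the source rate")
  }
  if (isTRUE(all.equal(target_hz, rate))) {
    return(stream)
  }
  n <- nrow(stream)
  ratio <- rate / target_hz
  if (isTRUE(all.equal(ratio, round(ratio)))) {
    idx <- seq(1, n, by = round(ratio))
    out <- stream[idx, ]
  } else {
    mat <- stream_matrix(stream)
    m <- floor((n - 1) * target_hz / rate) + 1
    t_old <- (seq_len(n) - 1) / rate
    t_new <- (seq_len(m) - 1) / target_hz
    new <- matrix(0, m, 6)
    for (j in 1:6) {
      new[, j] <- stats::spline(t_old, mat[, j], xout = t_new)$y
    }
    idx <- pmin(n, round((seq_len(m) - 1) * rate / target_hz) + 1)
    out <- stream[idx, ]
    out <- replace_channels(out, new)
  }
  out$t <- stream$t[1] + (seq_len(nrow(out)) - 1) / target_hz
  imu_stream(out, target_hz)
}

#' Segment an IMU stream into fixed-length overlapping windows
#'
#' Sliding-window segmentation: window length `length_s` seconds, hop
#' `length_s * (1 - overlap)`. With the 50 Hz / 2 s / 50% defaults each
#' window holds 100 samples and windows start every second. The number of
#' windows is `floor((n - L) / H) + 1`.
#'
#' @param stream an [imu_stream()] at the analysis rate.
#' @param length_s window length in seconds (default 2).
#' @param overlap fractional overlap between consecutive windows in
#'   `[0, 1)` (default 0.5).
#' @param subject_id optional identifier attached to every window.
#' @return An `imu_windows` object (see [imu_windows()]).
#' @export
segment_windows <- function(stream, length_s = 2, overlap = 0.5,
                            subject_id = NULL) {
  rate <- imu_rate(stream)
  if (overlap < 0 || overlap >= 1) rlang::abort("overlap must lie in [0, 1)")
  L <- length_s * rate
  if (!isTRUE(all.equal(L, round(L)))) {
    rlang::abort("length_s * rate must be an integer number of samples")
  }
  L <- round(L)
  H <- L * (1 - overlap)
  if (!isTRUE(all.equal(H, round(H))) || round(H) < 1) {
    rlang::abort("window hop must be a positive integer number of samples")
  }
  H <- round(H)
  n <- nrow(stream)
  if (n < L) {
    rlang::abort(
      sprintf("stream (%d samples) shorter than one window (%d samples)", n, L),
      class = "bafawubu_insufficient_data"
    )
  }
  m <- floor((n - L) / H) + 1
  mat <- stream_matrix(stream)
  x <- array(0, dim = c(m, L, 6))
  starts <- (seq_len(m) - 1) * H
  for (i in seq_len(m)) {
    x[i, , ] <- mat[starts[i] + seq_len(L), ]
  }
  sample_labels <- NULL
  if ("label" %in% names(stream)) {
    sample_labels <- matrix("", m, L)
    for (i in seq_len(m)) sample_labels[i, ] <- stream$label[starts[i] + seq_len(L)]
  }
  imu_windows(
    x = x,
    start_s = stream$t[1] + starts / rate,
    rate_hz = rate,
    sample_labels = sample_labels,
    subject_id = if (is.null(subject_id)) NULL else rep(subject_id, m)
  )
}

#' Windowed IMU dataset
#'
#' Container for the fixed-length windows the classifier consumes: an
#' `m x L x 6` array (windows x time x channels) plus optional per-window
#' labels, per-sample labels, subject identifiers and channel
#' standardization statistics.
#'
#' @param x numeric array, `m x L x 6`.
#' @param start_s window start times in seconds.
#' @param rate_hz sampling rate of the windows.
#' @param label optional per-window class labels (length m).
#' @param sample_labels optional `m x L` character matrix of per-sample labels.
#' @param subject_id optional per-window subject identifiers.
#' @param channel_stats optional tibble `channel, mean, sd` recording the
#'   standardization applied.
#' @return An object of class `imu_windows`.
#' @export
imu_windows <- function(x, start_s, rate_hz, label = NULL,
                        sample_labels = NULL, subject_id = NULL,
                        channel_stats = NULL) {
  stopifnot(is.array(x), length(dim(x)) == 3, dim(x)[3] == 6)
  m <- dim(x)[1]
  stopifnot(length(start_s) == m)
  if (!is.null(label) && length(label) != m) {
    rlang::abort("label length must equal the number of windows")
  }
  if (!is.null(subject_id) && length(subject_id) != m) {
    rlang::abort("subject_id length must equal the number of windows")
  }
  structure(
    list(
      x = x, start_s = start_s, rate_hz = rate_hz, label = label,
      sample_labels = sample_labels, subject_id = subject_id,
      channel_stats = channel_stats
    ),
    class = "imu_windows"
  )
}

#' @export
print.imu_windows <- function(x, ...) {
  d <- dim(x$x)
  cat(sprintf(
    "<imu_windows: %d windows x %d samples x 6 channels @ %g Hz%s%s>\n",
    d[1], d[2], x$rate_hz,
    if (!is.null(x$label)) ", labeled" else "",
    if (!is.null(x$channel_stats)) ", standardized" else ""
  ))
  invisible(x)
}

#' Number of windows
#' @param windows an [imu_windows()] object.
#' @return Integer window count.
#' @export
n_windows <- function(windows) dim(windows$x)[1]

#' Subset windows by index
#' @param x an [imu_windows()] object.
#' @param i integer or logical index over windows.
#' @param ... unused.
#' @export
`[.imu_windows` <- function(x, i, ...) {
  imu_windows(
    x = x$x[i, , , drop = FALSE],
    start_s = x$start_s[i],
    rate_hz = x$rate_hz,
    label = if (is.null(x$label)) NULL else x$label[i],
    sample_labels = if (is.null(x$sample_labels)) NULL else x$sample_labels[i, , drop = FALSE],
    subject_id = if (is.null(x$subject_id)) NULL else x$subject_id[i],
    channel_stats = x$channel_stats
  )
}

#' Combine windowed datasets (e.g. across subjects)
#' @param ... `imu_windows` objects with identical window geometry.
#' @return A single [imu_windows()] object.
#' @export
bind_windows <- function(...) {
  parts <- list(...)
  if (length(parts) == 1 && is.list(parts[[1]]) && !inherits(parts[[1]], "imu_windows")) {
    parts <- parts[[1]]
  }
  stopifnot(all(vapply(parts, inherits, logical(1), "imu_windows")))
  dims <- vapply(parts, function(p) dim(p$x)[2], numeric(1))
  if (length(unique(dims)) != 1) rlang::abort("window lengths differ")
  any_null <- function(get) any(vapply(parts, function(p) is.null(get(p)), logical(1)))
  x <- do.call(abind3, lapply(parts, function(p) p$x))
  imu_windows(
    x = x,
    start_s = unlist(lapply(parts, function(p) p$start_s)),
    rate_hz = parts[[1]]$rate_hz,
    label = if (any_null(function(p) p$label)) NULL else unlist(lapply(parts, function(p) p$label)),
    sample_labels = if (any_null(function(p) p$sample_labels)) NULL else do.call(rbind, lapply(parts, function(p) p$sample_labels)),
    subject_id = if (any_null(function(p) p$subject_id)) NULL else unlist(lapply(parts, function(p) p$subject_id))
  )
}

abind3 <- function(...) {
  mats <- list(...)
  d2 <- dim(mats[[1]])[2]; d3 <- dim(mats[[1]])[3]
  total <- sum(vapply(mats, function(m) dim(m)[1], numeric(1)))
  out <- array(0, dim = c(total, d2, d3))
  at <- 0
  for (m in mats) {
    out[at + seq_len(dim(m)[1]), , ] <- m
    at <- at + dim(m)[1]
  }
  out
}

#' Per-window summary tibble
#'
#' @param x an [imu_windows()] object.
#' @param ... unused.
#' @return A tibble with one row per window: start time, label, subject and
#'   per-channel means.
#' @export
as_tibble.imu_windows <- function(x, ...) {
  means <- apply(x$x, c(1, 3), mean)
  colnames(means) <- paste0("mean_", IMU_CHANNELS)
  out <- tibble::tibble(
    window = seq_len(n_windows(x)),
    start_s = x$start_s
  )
  if (!is.null(x$label)) out$label <- x$label
  if (!is.null(x$subject_id)) out$subject_id <- x$subject_id
  dplyr::bind_cols(out, tibble::as_tibble(means))
}

#' Assign one class label per window by majority vote
#'
#' Each window receives the most frequent per-sample class among its
#' samples; `"transition"` samples are excluded from the vote. Ties are
#' broken by the label of the window's center sample. Windows containing no
#' class samples at all (pure transition) are dropped.
#'
#' @param windows an [imu_windows()] from [segment_windows()] on a labeled
#'   stream.
#' @param sample_labels optional `m x L` label matrix overriding the one
#'   stored in `windows`.
#' @return A labeled [imu_windows()] (possibly with fewer windows).
#' @export
label_windows <- function(windows, sample_labels = NULL) {
  if (is.null(sample_labels)) sample_labels <- windows$sample_labels
  if (is.null(sample_labels)) {
    rlang::abort("no per-sample labels available; segment a labeled stream")
  }
  m <- n_windows(windows)
  L <- dim(windows$x)[2]
  if (!is.matrix(sample_labels) || nrow(sample_labels) != m || ncol(sample_labels) != L) {
    rlang::abort("sample_labels must be an m x L matrix aligned to the windows")
  }
  label <- character(m)
  keep <- logical(m)
  center <- ceiling((L + 1) / 2)
  for (i in seq_len(m)) {
    lab <- sample_labels[i, ]
    lab <- lab[lab != TRANSITION_LABEL]
    if (length(lab) == 0) next
    counts <- table(lab)
    top <- names(counts)[counts == max(counts)]
    if (length(top) == 1) {
      label[i] <- top
    } else {
      centre_lab <- sample_labels[i, center]
      label[i] <- if (centre_lab %in% top) centre_lab else top[1]
    }
    keep[i] <- TRUE
  }
  out <- windows[keep]
  out$label <- label[keep]
  out
}

#' Standardize windowed data per channel
#'
#' Z-scores every channel (accelerometer in g and gyroscope in deg/s differ
#' by orders of magnitude) using either supplied statistics -- typically the
#' training set's, stored in a fitted model -- or statistics computed from
#' the dataset itself, which are then recorded in `channel_stats`.
#'
#' @param windows an [imu_windows()] object.
#' @param stats optional tibble `channel, mean, sd` to apply; when `NULL`
#'   the statistics are computed from `windows`.
#' @return A standardized [imu_windows()] with `channel_stats` set.
#' @export
standardize_windows <- function(windows, stats = NULL) {
  if (is.null(stats)) {
    mean_c <- apply(windows$x, 3, mean)
    sd_c <- apply(windows$x, 3, stats::sd)
    if (any(sd_c < 1e-8)) {
      rlang::warn("zero-variance channel(s); standard deviation floored at 1e-8")
      sd_c <- pmax(sd_c, 1e-8)
    }
    stats <- tibble::tibble(channel = IMU_CHANNELS, mean = mean_c, sd = sd_c)
  }
  stopifnot(all(c("channel", "mean", "sd") %in% names(stats)), nrow(stats) == 6)
  stats <- stats[match(IMU_CHANNELS, stats$channel), ]
  for (ch in 1:6) {
    windows$x[, , ch] <- (windows$x[, , ch] - stats$mean[ch]) / stats$sd[ch]
  }
  windows$channel_stats <- stats
  windows
}

#' Persist a windowed dataset as plain text
#'
#' Writes `windows.csv` (long format: window, sample, six channel columns)
#' and `labels.csv` (window, start_s, label, subject_id) into `dir`.
#'
#' @param windows an [imu_windows()] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_windows <- function(windows, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(windows$x)
  long <- data.frame(
    window = rep(seq_len(d[1]), each = d[2]),
    sample = rep(seq_len(d[2]), times = d[1])
  )
  for (ch in 1:6) {
    long[[IMU_CHANNELS[ch]]] <- sprintf("%.9g", as.vector(t(windows$x[, , ch])))
  }
  utils::write.csv(long, file.path(dir, "windows.csv"), row.names = FALSE, quote = FALSE)
  meta <- data.frame(
    window = seq_len(d[1]),
    start_s = windows$start_s,
    label = if (is.null(windows$label)) NA_character_ else windows$label,
    subject_id = if (is.null(windows$subject_id)) NA_character_ else as.character(windows$subject_id),
    rate_hz = windows$rate_hz
  )
  utils::write.csv(meta, file.path(dir, "labels.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a windowed dataset written by [write_windows()]
#'
#' @param dir directory containing `windows.csv` and `labels.csv`.
#' @return An [imu_windows()] object.
#' @export
read_windows <- function(dir) {
  long <- utils::read.csv(file.path(dir, "windows.csv"))
  meta <- utils::read.csv(file.path(dir, "labels.csv"))
  m <- max(long$window)
  L <- max(long$sample)
  x <- array(0, dim = c(m, L, 6))
  ord <- order(long$window, long$sample)
  for (ch in 1:6) {
    x[, , ch] <- matrix(long[[IMU_CHANNELS[ch]]][ord], nrow = m, byrow = TRUE)
  }
  imu_windows(
    x = x,
    start_s = meta$start_s,
    rate_hz = meta$rate_hz[1],
    label = if (all(is.na(meta$label))) NULL else meta$label,
    subject_id = if (all(is.na(meta$subject_id))) NULL else meta$subject_id
  )
}
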