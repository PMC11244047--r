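#' Default movement signatures for the seven Bafa Wubu classes
#'
#' Each movement class is emulated by a quasi-periodic six-axis pattern:
#' a static 1 g gravity component along a class-specific orientation of the
#' arm-worn sensor, plus per-axis sinusoids at a class-specific fundamental
#' frequency (tai chi tempo, 0.2-2 Hz) with a weaker second harmonic. The
#' stationary stance (SKR) has a markedly smaller angular-velocity amplitude
#' than every travelling class. All signatures keep the clean signal well
#' inside the sensor ranges (+-16 g, +-2000 deg/s) and all spectral content
#' below the 5 Hz preprocessing cutoff.
#'
#' @return A tibble with one row per class: `class`, `fundamental_hz`, and
#'   list-columns `gravity_axis`, `accel_amp` (g), `gyro_amp` (deg/s) and
#'   `phase` (radians), each holding a length-3 numeric vector (x, y, z).
#' @examples
#' default_signatures()
#' @export
default_signatures <- function() {
  tilt <- function(fwd = 0, lat = 0) {
    v <- c(sin(fwd * pi / 180), sin(lat * pi / 180), 0)
    v[3] <- sqrt(max(0, 1 - sum(v^2)))
    v
  }
  tibble::tibble(
    class = bafa_codes(),
    fundamental_hz = c(0.50, 0.80, 0.40, 0.70, 0.60, 0.90, 0.30),
    gravity_axis = list(
      tilt(fwd = 15), tilt(fwd = 10), tilt(fwd = -15), tilt(fwd = -8),
      tilt(lat = 18), tilt(lat = -12), tilt()
    ),
    accel_amp = list(
      c(0.60, 0.20, 0.35), c(0.45, 0.30, 0.55), c(0.50, 0.35, 0.25),
      c(0.30, 0.55, 0.40), c(0.25, 0.65, 0.30), c(0.35, 0.50, 0.20),
      c(0.08, 0.06, 0.10)
    ),
    gyro_amp = list(
      c(70, 45, 25), c(40, 80, 30), c(55, 35, 60),
      c(30, 60, 75), c(85, 30, 45), c(45, 55, 90),
      c(6, 5, 4)
    ),
    phase = list(
      c(0, pi / 3, pi / 6), c(pi / 4, 0, pi / 2), c(pi / 2, pi / 5, 0),
      c(0, pi / 2, pi / 4), c(pi / 6, 0, pi / 3), c(pi / 3, pi / 6, 0),
      c(0, pi / 4, pi / 2)
    )
  )
}

#' Specify the noise added to synthetic IMU signals
#'
#' White measurement noise plus an optional narrow-band interference tone
#' strictly above the 5 Hz movement band, so that low-pass filtering is
#' consequential.
#'
#' @param accel_sd white-noise standard deviation on accelerometer channels (g).
#' @param gyro_sd white-noise standard deviation on gyroscope channels (deg/s).
#' @param interference_hz interference frequency in Hz; must exceed 10 Hz.
#' @param accel_interference interference amplitude on accelerometer channels (g).
#' @param gyro_interference interference amplitude on gyroscope channels (deg/s).
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(accel_sd = 0, gyro_sd = 0, interference_hz = 25,
                       accel_interference = 0, gyro_interference = 0) {
  vals <- c(accel_sd, gyro_sd, interference_hz, accel_interference, gyro_interference)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    rlang::abort("noise_spec fields must be finite and non-negative")
  }
  if (interference_hz <= 10) {
    rlang::abort("interference_hz must be above 10 Hz (out of the movement band)")
  }
  structure(
    list(
      accel_sd = accel_sd, gyro_sd = gyro_sd, interference_hz = interference_hz,
      accel_interference = accel_interference, gyro_interference = gyro_interference
    ),
    class = "noise_spec"
  )
}

#' Moderate sensor-noise preset
#'
#' Roughly 10-20% of the typical movement amplitude as white noise plus a
#' small 25 Hz interference tone; a realistic consumer-grade IMU condition.
#'
#' @return A [noise_spec()].
#' @export
moderate_noise <- function() {
  noise_spec(
    accel_sd = 0.10, gyro_sd = 20, interference_hz = 25,
    accel_interference = 0.05, gyro_interference = 10
  )
}

signature_row <- function(sig, signatures) {
  if (is.character(sig) && length(sig) == 1) {
    assert_known_classes(sig)
    sig <- signatures[signatures$class == sig, ]
  }
  stopifnot(is.data.frame(sig), nrow(sig) == 1)
  f <- sig$fundamental_hz
  if (f < 0.2 || f > 2.0) {
    rlang::abort("fundamental_hz must lie in [0.2, 2.0] (tai chi tempo)")
  }
  sig
}

# clean six-channel signal of one movement at time points tt (seconds);
# gravity on accel axes + fundamental and 0.3x second harmonic per axis
clean_signal <- function(sig, tt) {
  f <- sig$fundamental_hz
  g_axis <- sig$gravity_axis[[1]]
  a_amp <- sig$accel_amp[[1]]
  g_amp <- sig$gyro_amp[[1]]
  ph <- sig$phase[[1]]
  out <- matrix(0, length(tt), 6)
  for (i in 1:3) {
    osc <- sin(2 * pi * f * tt + ph[i]) + 0.3 * sin(4 * pi * f * tt + 2 * ph[i])
    out[, i] <- g_axis[i] + a_amp[i] * osc
    out[, i + 3] <- g_amp[i] * sin(2 * pi * f * tt + ph[i] + pi / 5) +
      0.3 * g_amp[i] * sin(4 * pi * f * tt + 2 * ph[i])
  }
  out
}

add_noise <- function(mat, tt, noise) {
  n <- nrow(mat)
  if (noise$accel_interference > 0 || noise$gyro_interference > 0) {
    tone <- sin(2 * pi * noise$interference_hz * tt)
    for (i in 1:3) mat[, i] <- mat[, i] + noise$accel_interference * tone
    for (i in 4:6) mat[, i] <- mat[, i] + noise$gyro_interference * tone
  }
  if (noise$accel_sd > 0) {
    mat[, 1:3] <- mat[, 1:3] + stats::rnorm(3L * n, sd = noise$accel_sd)
  }
  if (noise$gyro_sd > 0) {
    mat[, 4:6] <- mat[, 4:6] + stats::rnorm(3L * n, sd = noise$gyro_sd)
  }
  mat
}

#' Synthesize a single-movement IMU stream
#'
#' @param sig a class code (e.g. `"WOF"`) or one row of [default_signatures()].
#' @param duration_s duration in seconds (> 0).
#' @param rate_hz raw sampling rate in Hz (>= 100; filtering and downsampling
#'   to 50 Hz happen later in the pipeline).
#' @param noise a [noise_spec()].
#' @param seed integer seed; the same seed reproduces the stream exactly.
#' @param signatures signature table used to resolve a class code.
#' @return A labeled [imu_stream()].
#' @examples
#' s <- synth_movement("WOF", duration_s = 5, seed = 1)
#' @export
synth_movement <- function(sig, duration_s, rate_hz = 200,
                           noise = noise_spec(), seed = NULL,
                           signatures = default_signatures()) {
  if (!is.numeric(duration_s) || duration_s <= 0) {
    rlang::abort("duration_s must be positive")
  }
  if (!is.numeric(rate_hz) || rate_hz < 100) {
    rlang::abort("rate_hz must be >= 100 (raw rate before downsampling)")
  }
  sig <- signature_row(sig, signatures)
  n <- round(duration_s * rate_hz)
  tt <- (seq_len(n) - 1) / rate_hz
  build <- function() {
    mat <- clip_to_range(add_noise(clean_signal(sig, tt), tt, noise))
    df <- tibble::tibble(t = tt)
    for (i in seq_along(IMU_CHANNELS)) df[[IMU_CHANNELS[i]]] <- mat[, i]
    df$label <- rep(sig$class, n)
    imu_stream(df, rate_hz)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

#' Define a scripted movement session
#'
#' @param class character vector of movement class codes, in performance order.
#' @param duration_s per-event durations in seconds (recycled).
#' @param transition_s seconds of blended "transition" between consecutive
#'   events.
#' @return A `session_script` tibble with columns `class`, `duration_s`.
#' @export
session_script <- function(class, duration_s, transition_s = 1) {
  if (length(class) == 0) rlang::abort("session script must contain at least one event")
  assert_known_classes(class)
  duration_s <- rep_len(duration_s, length(class))
  if (any(duration_s <= 0)) rlang::abort("event durations must be positive")
  if (transition_s < 0) rlang::abort("transition_s must be non-negative")
  out <- tibble::tibble(class = class, duration_s = duration_s)
  attr(out, "transition_s") <- transition_s
  class(out) <- c("session_script", class(tibble::tibble()))
  out
}

#' The designed full Bafa Wubu session script
#'
#' The designed distribution performs the seven-movement sequence as repeated
#' rounds, seven repetitions of each movement, with short transitions --
#' about four minutes in total, matching the dedicated data-collection bout
#' at the end of each precision-intervention session.
#'
#' @param reps repetitions of each movement (default 7).
#' @param movement_s duration of each movement repetition in seconds.
#' @param transition_s blend time between consecutive movements.
#' @return A [session_script()].
#' @examples
#' scr <- bafa_wubu_script()
#' sum(scr$duration_s) # 196 s of movement + 48 s of transitions ~ 4 min
#' @export
bafa_wubu_script <- function(reps = 7, movement_s = 4, transition_s = 1) {
  session_script(
    class = rep(bafa_codes(), times = reps),
    duration_s = movement_s,
    transition_s = transition_s
  )
}

#' Synthesize a scripted multi-movement session
#'
#' Generates each scripted event's clean signature signal and linearly
#' cross-fades between consecutive events over `transition_s` seconds;
#' transition samples are labeled `"transition"`. Noise is added to the whole
#' session and values are clipped to the sensor ranges (saturation).
#'
#' @param script a [session_script()].
#' @param rate_hz raw sampling rate in Hz.
#' @param noise a [noise_spec()].
#' @param seed integer seed for reproducibility.
#' @param signatures signature table, one row per class used by the script.
#' @return A labeled [imu_stream()]; per-class labeled duration equals the
#'   scripted duration exactly.
#' @export
synth_session <- function(script, rate_hz = 200, noise = noise_spec(),
                          seed = NULL, signatures = default_signatures()) {
  if (!inherits(script, "session_script")) {
    script <- session_script(script$class, script$duration_s)
  }
  if (nrow(script) == 0) rlang::abort("session script must contain at least one event")
  trans_s <- attr(script, "transition_s")
  n_ev <- nrow(script)
  n_event <- round(script$duration_s * rate_hz)
  n_trans <- round(trans_s * rate_hz)

  blocks <- vector("list", 2 * n_ev - 1)
  labels <- vector("list", 2 * n_ev - 1)
  for (i in seq_len(n_ev)) {
    sig <- signature_row(script$class[i], signatures)
    tt <- (seq_len(n_event[i]) - 1) / rate_hz
    blocks[[2 * i - 1]] <- clean_signal(sig, tt)
    labels[[2 * i - 1]] <- rep(script$class[i], n_event[i])
    if (i < n_ev && n_trans > 0) {
      # cross-fade: event i keeps playing past its end while event i+1 leads in
      sig_next <- signature_row(script$class[i + 1], signatures)
      tt_out <- script$duration_s[i] + (seq_len(n_trans) - 1) / rate_hz
      tt_in <- (seq_len(n_trans) - 1 - n_trans) / rate_hz
      w <- seq_len(n_trans) / (n_trans + 1)
      blocks[[2 * i]] <- (1 - w) * clean_signal(sig, tt_out) +
        w * clean_signal(sig_next, tt_in)
      labels[[2 * i]] <- rep(TRANSITION_LABEL, n_trans)
    }
  }
  mat <- do.call(rbind, blocks)
  lab <- unlist(labels)
  n <- nrow(mat)
  tt <- (seq_len(n) - 1) / rate_hz
  build <- function() {
    out <- clip_to_range(add_noise(mat, tt, noise))
    df <- tibble::tibble(t = tt)
    for (i in seq_along(IMU_CHANNELS)) df[[IMU_CHANNELS[i]]] <- out[, i]
    df$label <- lab
    imu_stream(df, rate_hz)
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}
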