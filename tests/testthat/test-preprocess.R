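make_sine_stream <- function(freq, rate = 200, dur = 10, amp = 1) {
  tt <- (seq_len(dur * rate) - 1) / rate
  df <- tibble::tibble(t = tt)
  for (ch in c("ax", "ay", "az", "gx", "gy", "gz")) df[[ch]] <- amp * sin(2 * pi * freq * tt)
  imu_stream(df, rate)
}

butterworth_gain <- function(f, cutoff = 5, order = 4, passes = 2) {
  # analytic Butterworth magnitude response; two passes for filtfilt
  (1 / sqrt(1 + (f / cutoff)^(2 * order)))^passes
}

test_that("low-pass filter preserves DC exactly and matches the Butterworth magnitude oracle", {
  const <- make_sine_stream(1)
  const[c("ax", "ay", "az", "gx", "gy", "gz")] <- 1
  out <- low_pass(const)
  expect_lt(max(abs(as.matrix(out[, c("ax", "gz")]) - 1)), 1e-6)

  # passband: 2 Hz tone keeps (almost) full amplitude
  pass <- low_pass(make_sine_stream(2))
  mid <- 500:1500
  amp2 <- max(abs(pass$ax[mid]))
  expect_gte(amp2, 0.99)
  expect_equal(amp2, butterworth_gain(2), tolerance = 0.01)

  # stopband: 25 Hz tone is crushed
  stop <- low_pass(make_sine_stream(25))
  amp25 <- max(abs(stop$ax[mid]))
  expect_lte(amp25, 0.10)
  expect_lt(amp25, butterworth_gain(25) + 1e-3)

  expect_error(low_pass(make_sine_stream(1), cutoff_hz = 120), "cutoff")
})

test_that("zero-phase filtering commutes with time reversal", {
  s <- synth_movement("RBB", 5, noise = noise_spec(accel_sd = 0.2, gyro_sd = 30), seed = 4)
  fwd <- low_pass(s)
  rev_stream <- s
  for (ch in c("ax", "ay", "az", "gx", "gy", "gz")) rev_stream[[ch]] <- rev(s[[ch]])
  bwd <- low_pass(rev_stream)
  expect_equal(rev(bwd$ax), fwd$ax, tolerance = 1e-6)
  expect_equal(rev(bwd$gy), fwd$gy, tolerance = 1e-4)
})

test_that("resampling hits the target rate by decimation, identity, or rational resampling", {
  s200 <- synth_movement("WOF", 10, rate_hz = 200) |> low_pass()
  out <- resample_to(s200, 50)
  expect_equal(nrow(out), 500)
  expect_equal(imu_rate(out), 50)
  # decimation picks every 4th filtered sample
  expect_equal(out$ax, s200$ax[seq(1, 2000, by = 4)])

  s50 <- out
  expect_identical(resample_to(s50, 50), s50)

  s80 <- synth_movement("WOF", 10, rate_hz = 160) |> low_pass()
  attr(s80, "rate_hz") <- 80 # reinterpret as an 80 Hz recording of a slow signal
  s80$t <- (seq_len(nrow(s80)) - 1) / 80
  out80 <- resample_to(s80, 50)
  expect_equal(imu_rate(out80), 50)
  expect_equal(nrow(out80), 1000)

  expect_error(resample_to(s50, 200), "exceed")
})

test_that("rational resampling agrees with an interpolation oracle on slow content", {
  rate <- 80
  tt <- (seq_len(800) - 1) / rate
  df <- tibble::tibble(t = tt)
  for (ch in c("ax", "ay", "az", "gx", "gy", "gz")) df[[ch]] <- sin(2 * pi * 1 * tt)
  s <- imu_stream(df, rate)
  out <- resample_to(s, 50)
  oracle <- sin(2 * pi * 1 * out$t)
  interior <- 20:(nrow(out) - 20)
  expect_equal(out$ax[interior], oracle[interior], tolerance = 5e-3)
  # labels map by nearest sample
  s$label <- rep(c("WOF", "PB"), each = 400)
  out_lab <- resample_to(s, 50)
  expect_equal(sum(out_lab$label == "WOF"), 250)
})

test_that("segmentation yields floor((n - L) / H) + 1 windows and rejects short streams", {
  s <- synth_movement("LF", 60, rate_hz = 200) |> low_pass() |> resample_to(50)
  w <- segment_windows(s)
  expect_equal(n_windows(w), 59)
  expect_equal(dim(w$x)[2], 100)

  exact <- synth_movement("LF", 2, rate_hz = 200) |> low_pass() |> resample_to(50)
  expect_equal(n_windows(segment_windows(exact)), 1)

  short <- synth_movement("LF", 1.5, rate_hz = 200) |> low_pass() |> resample_to(50)
  expect_error(segment_windows(short), class = "bafawubu_insufficient_data")

  # property: count formula over randomized stream lengths and overlaps
  withr::with_seed(99, {
    for (i in 1:20) {
      n_s <- sample(2:30, 1)
      overlap <- sample(c(0, 0.25, 0.5, 0.75), 1)
      st <- synth_movement("PB", n_s, rate_hz = 100) |> resample_to(50)
      L <- 100
      H <- L * (1 - overlap)
      expected <- floor((nrow(st) - L) / H) + 1
      expect_equal(n_windows(segment_windows(st, overlap = overlap)), expected)
    }
  })
})

test_that("windows are contiguous slices: consecutive half-windows reconstruct the stream", {
  s <- synth_movement("ELS", 10, rate_hz = 200, seed = 2) |> low_pass() |> resample_to(50)
  w <- segment_windows(s)
  # at 50% overlap the first half of each window tiles the stream interior
  rebuilt <- do.call(rbind, lapply(seq_len(n_windows(w)), function(i) w$x[i, 1:50, ]))
  orig <- as.matrix(s[, c("ax", "ay", "az", "gx", "gy", "gz")])
  expect_equal(rebuilt, unname(orig[1:(n_windows(w) * 50), ]))
})

test_that("window labeling follows majority vote with centre-sample tie-break", {
  s <- synth_movement("WOF", 6, rate_hz = 200) |> low_pass() |> resample_to(50)
  w <- segment_windows(s)

  pure <- matrix("WOF", n_windows(w), 100)
  expect_true(all(label_windows(w, pure)$label == "WOF"))

  majority <- pure
  majority[, 1:40] <- "LF"
  expect_true(all(label_windows(w, majority)$label == "WOF"))

  tie <- pure
  tie[, 1:50] <- "LF" # 50/50; centre sample (51st) is WOF
  expect_true(all(label_windows(w, tie)$label == "WOF"))
  tie2 <- pure
  tie2[, 51:100] <- "LF" # centre sample now LF
  expect_true(all(label_windows(w, tie2)$label == "LF"))

  # transition samples don't vote; transition-only windows are dropped
  mixed <- pure
  mixed[, 1:60] <- "transition"
  expect_true(all(label_windows(w, mixed)$label == "WOF"))
  all_trans <- matrix("transition", n_windows(w), 100)
  all_trans[1, 1] <- "PB"
  lw <- label_windows(w, all_trans)
  expect_equal(n_windows(lw), 1)
  expect_equal(lw$label, "PB")

  expect_error(label_windows(w, pure[, 1:50]), "aligned")
})

test_that("standardization z-scores per channel and shifted data lands at shift/sd", {
  w <- small_dataset(2)
  z <- standardize_windows(w)
  for (ch in 1:6) {
    expect_lt(abs(mean(z$x[, , ch])), 1e-9)
    expect_equal(stats::sd(z$x[, , ch]), 1, tolerance = 1e-6)
  }
  # training stats applied to a shifted copy: mean becomes shift / sd
  shift <- 2.5
  w2 <- w
  w2$x[, , 1] <- w2$x[, , 1] + shift
  z2 <- standardize_windows(w2, z$channel_stats)
  expect_equal(mean(z2$x[, , 1]), shift / z$channel_stats$sd[1], tolerance = 1e-9)

  const <- w
  const$x[, , 3] <- 4
  expect_warning(zc <- standardize_windows(const), "floored")
  expect_true(all(is.finite(zc$x)))
})

test_that("windowed datasets persist to CSV and back unchanged", {
  w <- standardize_windows(small_dataset(2))
  dir <- withr::local_tempdir()
  write_windows(w, dir)
  w2 <- read_windows(dir)
  expect_equal(w2$x, w$x, tolerance = 1e-8)
  expect_identical(w2$label, w$label)
  expect_identical(as.character(w2$subject_id), as.character(w$subject_id))
  expect_equal(w2$rate_hz, 50)
})
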