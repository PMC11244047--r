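#' Classify a stream at one-second cadence (offline replay)
#'
#' Re-implements the deployed real-time loop offline: the 50 Hz stream is
#' cut into 2 s windows hopping every second (50% overlap) and each window
#' is classified in order, giving one prediction per second after the first
#' two. Equals batch prediction of [segment_windows()] windows by contract.
#'
#' @param stream an [imu_stream()] preprocessed to the analysis rate.
#' @param classifier a trained [fit_tcn()] model, or [oracle_classifier()]
#'   to label windows from the stream's own ground-truth labels.
#' @param length_s,overlap window geometry (defaults 2 s, 50%).
#' @return A tibble, one row per window in time order: `step`, `start_s`,
#'   `class` (a class code or `"transition"`), `prob` (classifier confidence;
#'   1 for the oracle).
#' @export
stream_infer <- function(stream, classifier, length_s = 2, overlap = 0.5) {
  windows <- segment_windows(stream, length_s = length_s, overlap = overlap)
  if (inherits(classifier, "bafawubu_oracle")) {
    if (is.null(windows$sample_labels)) {
      rlang::abort("oracle classification requires a labeled stream")
    }
    lab <- oracle_window_labels(windows$sample_labels)
    out <- tibble::tibble(class = lab, prob = 1)
  } else if (inherits(classifier, "tcn_fit")) {
    pred <- stats::predict(classifier, windows)
    probs <- as.matrix(pred[, paste0(".prob_", classifier$class_map)])
    out <- tibble::tibble(
      class = pred$.pred_class,
      prob = probs[cbind(seq_len(nrow(pred)), max.col(probs))]
    )
  } else {
    rlang::abort("classifier must be a tcn_fit or oracle_classifier()")
  }
  dplyr::bind_cols(
    tibble::tibble(step = seq_len(nrow(out)), start_s = windows$start_s),
    out
  )
}

#' Ground-truth window classifier
#'
#' A stand-in for the trained network in pipeline checks: each window is
#' labeled by the majority of its per-sample ground-truth labels
#' (transition samples excluded from the vote; a window with only
#' transition samples is labeled `"transition"`).
#'
#' @return An object usable as the `classifier` argument of [stream_infer()].
#' @export
oracle_classifier <- function() {
  structure(list(), class = "bafawubu_oracle")
}

oracle_window_labels <- function(sample_labels) {
  apply(sample_labels, 1, function(lab) {
    votes <- lab[lab != TRANSITION_LABEL]
    if (length(votes) == 0) {
      return(TRANSITION_LABEL)
    }
    counts <- table(votes)
    top <- names(counts)[counts == max(counts)]
    if (length(top) == 1) {
      top
    } else {
      centre <- lab[ceiling((length(lab) + 1) / 2)]
      if (centre %in% top) centre else top[1]
    }
  })
}

#' Smooth a window-label sequence with a sliding mode filter
#'
#' Replaces each label by the most frequent label in a centered window of
#' width `k`, suppressing isolated misclassification flickers before event
#' extraction. The filter is applied left to right, so positions to the left
#' of the current one contribute their already-smoothed labels; ties keep
#' the previous smoothed label; at the boundaries the window shrinks to the
#' available labels. Length is preserved.
#'
#' @param labels character vector of per-second window labels, or the
#'   tibble returned by [stream_infer()].
#' @param k odd filter width (default 3).
#' @return The same type as the input, with smoothed labels.
#' @export
smooth_labels <- function(labels, k = 3) {
  if (k %% 2 != 1 || k < 1) rlang::abort("k must be odd and positive")
  seq_in <- labels
  if (is.data.frame(labels)) seq_in <- labels$class
  n <- length(seq_in)
  half <- (k - 1) / 2
  out <- seq_in
  for (i in seq_len(n)) {
    left <- if (i > 1) out[max(1, i - half):(i - 1)] else character()
    win <- c(left, seq_in[i:min(n, i + half)])
    counts <- table(win)
    top <- names(counts)[counts == max(counts)]
    if (length(top) == 1) {
      out[i] <- top
    } else {
      prev <- if (i > 1) out[i - 1] else seq_in[i]
      out[i] <- if (prev %in% top) prev else top[1]
    }
  }
  if (is.data.frame(labels)) {
    labels$class <- out
    labels
  } else {
    out
  }
}

#' Extract movement events from a label sequence
#'
#' Maximal runs of identical class labels lasting at least `min_run`
#' consecutive windows become events; shorter runs and `"transition"` runs
#' are discarded. With the 1 s hop, `min_run = 2` demands at least 2 s of
#' consistent detections, since the 50% overlap double-covers every second.
#'
#' @param labels character vector of per-second labels, or a
#'   [stream_infer()] tibble.
#' @param min_run minimum run length in windows (default 2).
#' @param hop_s seconds between consecutive windows (default 1).
#' @param start_s start time of the first window (default 0; taken from the
#'   tibble when one is given).
#' @return A tibble of non-overlapping, time-ordered events:
#'   `class`, `start_s`, `end_s`.
#' @export
label_events <- function(labels, min_run = 2, hop_s = 1, start_s = 0) {
  seq_in <- labels
  if (is.data.frame(labels)) {
    seq_in <- labels$class
    start_s <- labels$start_s[1]
    if (nrow(labels) > 1) hop_s <- labels$start_s[2] - labels$start_s[1]
  }
  if (length(seq_in) == 0) {
    return(tibble::tibble(class = character(), start_s = numeric(), end_s = numeric()))
  }
  runs <- rle(seq_in)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$lengths >= min_run & runs$values != TRANSITION_LABEL
  event_start <- start_s + (starts[keep] - 1) * hop_s
  event_end <- start_s + ends[keep] * hop_s
  tibble::tibble(class = runs$values[keep], start_s = event_start, end_s = event_end)
}

#' Count repetitions per movement class
#'
#' @param events an event tibble from [label_events()].
#' @return A tibble `class`, `count` covering all seven classes (absent
#'   classes count 0), in canonical order.
#' @export
count_events <- function(events) {
  counts <- table(factor(events$class, levels = bafa_codes()))
  tibble::tibble(class = bafa_codes(), count = as.integer(counts))
}

#' Flag discrepancies against the designed movement distribution
#'
#' The designed session performs each movement seven times; counts that
#' deviate from the expectation by more than `tolerance` are flagged for
#' follow-up (extra coaching or adherence encouragement -- cause attribution
#' is outside this report).
#'
#' @param counts a tibble `class`, `count` (see [count_events()]); classes
#'   absent from it count as 0.
#' @param expected designed repetitions per class (default 7).
#' @param tolerance allowed absolute deviation (default 0).
#' @return A tibble `class`, `count`, `expected`, `deviation`, `flagged`.
#' @export
discrepancy_report <- function(counts, expected = 7, tolerance = 0) {
  stopifnot(all(c("class", "count") %in% names(counts)))
  assert_known_classes(counts$class)
  if (any(counts$count < 0)) rlang::abort("counts must be non-negative")
  if (tolerance < 0) rlang::abort("tolerance must be non-negative")
  full <- tibble::tibble(class = bafa_codes())
  out <- dplyr::left_join(full, tibble::as_tibble(counts), by = "class")
  out$count[is.na(out$count)] <- 0L
  out$expected <- expected
  out$deviation <- out$count - expected
  out$flagged <- abs(out$deviation) > tolerance
  out
}
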