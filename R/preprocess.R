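#' Preprocessing configuration
#'
#' Defaults follow standard resting-EEG practice for a 1-30 Hz analysis:
#' zero-phase Butterworth band-pass, extreme-value rejection in 1 s
#' windows at +/-100 microvolts, bad channels flagged when flat
#' (peak-to-peak below 0.1 microvolts) or when the z-score of their
#' log-variance across channels exceeds 3, and a 250 Hz analysis rate.
#'
#' @param band_low,band_high band-pass edges in Hz.
#' @param target_sfreq analysis sampling rate in Hz.
#' @param amplitude_threshold extreme-value rejection threshold
#'   (microvolts).
#' @param reject_window_s rejection window length (seconds).
#' @param bad_channel_flat_threshold peak-to-peak floor (microvolts).
#' @param bad_channel_z_threshold log-variance z-score cut-off.
#' @param ica hook for an external artifact cleaner: a function
#'   `recording -> recording`, or `NULL` (default) for a no-op. Synthetic
#'   recordings carry no ocular or muscle artifacts, so nothing is
#'   plugged in here by default.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(band_low = 1, band_high = 30,
                              target_sfreq = 250,
                              amplitude_threshold = 100,
                              reject_window_s = 1,
                              bad_channel_flat_threshold = 0.1,
                              bad_channel_z_threshold = 3,
                              ica = NULL) {
  if (!(band_low > 0 && band_low < band_high && band_high < target_sfreq / 2))
    stopf("need 0 < band_low < band_high < target_sfreq/2")
  structure(list(band_low = band_low, band_high = band_high,
                 target_sfreq = target_sfreq,
                 amplitude_threshold = amplitude_threshold,
                 reject_window_s = reject_window_s,
                 bad_channel_flat_threshold = bad_channel_flat_threshold,
                 bad_channel_z_threshold = bad_channel_z_threshold,
                 ica = ica),
            class = "preprocess_config")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Order-4 Butterworth applied forward and backward
#' ([signal::filtfilt()]), so the passband is amplitude-preserving and
#' phase (and hence the topographies) is untouched. DC is removed by the
#' high-pass edge.
#'
#' @param rec an `eeg_recording`.
#' @param low,high band edges in Hz; `high` must be below Nyquist.
#' @param order Butterworth order (each direction).
#' @return the filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, low = 1, high = 30, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sfreq / 2
  if (high >= nyq) stopf("high edge (%g Hz) must be below Nyquist (%g Hz)", high, nyq)
  if (low <= 0 || low >= high) stopf("need 0 < low < high")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  flen <- max(length(bf$b), length(bf$a))
  n <- n_samples(rec)
  if (n < 3 * flen)
    stopf("record too short for the filter (%d samples, need >= %d)",
          n, 3 * flen)
  # odd-reflection padding keeps the slow high-pass transient out of the
  # record (signal::filtfilt starts from zero state)
  pad <- min(n - 1L, as.integer(round(3 * rec$sfreq / low)))
  out <- t(apply(rec$data, 1, function(x) {
    xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
    signal::filtfilt(bf, xp)[(pad + 1):(pad + n)]
  }))
  eeg_recording(out, rec$sfreq, rec$montage, rec$splice_boundaries)
}

#' Re-reference to the whole-head average
#'
#' Subtracts the across-channel mean from every sample, so the per-sample
#' mean is zero afterwards. Idempotent, and immune to channel-constant
#' offsets.
#'
#' @param rec an `eeg_recording` with at least 2 channels.
#' @return the re-referenced `eeg_recording`.
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_channels(rec) < 2) stopf("average reference needs at least 2 channels")
  out <- sweep(rec$data, 2, colMeans(rec$data))
  eeg_recording(out, rec$sfreq, rec$montage, rec$splice_boundaries)
}

#' Flag bad channels
#'
#' A channel is flagged when it is flat (peak-to-peak below the flat
#' threshold) or when the z-score of its log-variance across channels
#' exceeds the z threshold. Report only; removal or interpolation is a
#' separate call.
#'
#' @param rec an `eeg_recording`.
#' @param config a [preprocess_config()].
#' @return character vector of flagged channel names (possibly empty).
#' @export
detect_bad_channels <- function(rec, config = preprocess_config()) {
  ptp <- apply(rec$data, 1, function(x) diff(range(x)))
  flat <- ptp < config$bad_channel_flat_threshold
  bad <- flat
  v <- apply(rec$data, 1, stats::var)
  ok <- !flat & v > 0
  if (sum(ok) >= 3) {
    lv <- log(v[ok])
    if (stats::sd(lv) > 0) {
      z <- (lv - mean(lv)) / stats::sd(lv)
      bad[ok][abs(z) > config$bad_channel_z_threshold] <- TRUE
    }
  }
  rownames(rec$data)[bad]
}

#' Interpolate bad channels by inverse-distance weighting
#'
#' Each bad channel is replaced by the inverse-distance-weighted average
#' of the good channels (distances from the montage positions); good
#' channels are untouched.
#'
#' @param rec an `eeg_recording`.
#' @param bad character vector of channel names to replace.
#' @param montage montage supplying positions (defaults to the
#'   recording's own).
#' @return the repaired `eeg_recording`.
#' @export
interpolate_bad_channels <- function(rec, bad, montage = rec$montage) {
  if (!length(bad)) return(rec)
  names_all <- rec$montage$channel_names
  if (!all(bad %in% names_all))
    stopf("unknown channel(s): %s", paste(setdiff(bad, names_all), collapse = ", "))
  good <- setdiff(names_all, bad)
  if (length(good) < 2) stopf("fewer than 2 good channels remain")
  pos <- montage$positions
  out <- rec$data
  for (b in bad) {
    d <- sqrt(rowSums(sweep(pos[good, , drop = FALSE], 2, pos[b, ])^2))
    if (any(d < 1e-9)) {
      w <- as.numeric(d < 1e-9)
    } else {
      w <- 1 / d
    }
    out[b, ] <- colSums(rec$data[good, , drop = FALSE] * (w / sum(w)))
  }
  eeg_recording(out, rec$sfreq, rec$montage, rec$splice_boundaries)
}

#' Reject extreme-value windows
#'
#' The record is tiled into non-overlapping windows; any window in which
#' any channel exceeds the amplitude threshold is dropped, and the
#' survivors are concatenated. Joins between non-adjacent survivors are
#' recorded as splice boundaries so that microstate segments never span
#' a splice.
#'
#' @param rec an `eeg_recording`.
#' @param threshold amplitude threshold in microvolts (> 0).
#' @param window_s window length in seconds.
#' @return list with `recording` (survivors, with splice boundaries set),
#'   `kept` (logical, one per window) and `n_windows`.
#' @export
reject_extreme_segments <- function(rec, threshold = 100, window_s = 1) {
  if (threshold <= 0) stopf("threshold must be positive")
  n <- n_samples(rec)
  w <- max(1L, round(window_s * rec$sfreq))
  starts <- seq(1L, n, by = w)
  ends <- pmin(starts + w - 1L, n)
  kept <- vapply(seq_along(starts), function(i)
    max(abs(rec$data[, starts[i]:ends[i], drop = FALSE])) <= threshold,
    logical(1))
  if (!any(kept)) {
    return(list(recording = eeg_recording(rec$data[, 0, drop = FALSE],
                                          rec$sfreq, rec$montage),
                kept = kept, n_windows = length(starts)))
  }
  keep_idx <- which(kept)
  cols <- unlist(lapply(keep_idx, function(i) starts[i]:ends[i]))
  # a splice starts where consecutive kept windows were not adjacent
  lens <- ends[keep_idx] - starts[keep_idx] + 1L
  cum <- cumsum(lens)
  gaps <- which(diff(keep_idx) > 1L)
  splice <- if (length(gaps)) cum[gaps] + 1L else integer(0)
  list(recording = eeg_recording(rec$data[, cols, drop = FALSE], rec$sfreq,
                                 rec$montage, splice),
       kept = kept, n_windows = length(starts))
}

#' Resample a recording to a lower rate
#'
#' Polyphase resampling ([signal::resample()]) after reducing
#' `target/native` to lowest terms. Upsampling is refused: the pipeline
#' only ever moves from the acquisition rate down to the analysis rate.
#'
#' @param rec an `eeg_recording`.
#' @param target_sfreq target rate in Hz (<= native rate).
#' @return the resampled `eeg_recording`.
#' @export
resample_recording <- function(rec, target_sfreq) {
  if (target_sfreq > rec$sfreq) stopf("upsampling is not supported")
  if (target_sfreq == rec$sfreq) return(rec)
  to_i <- round(target_sfreq * 1e6); fr_i <- round(rec$sfreq * 1e6)
  g <- gcd_int(to_i, fr_i)
  p <- to_i / g; q <- fr_i / g
  if (p > 1000 || q > 1000) stopf("rate ratio %g/%g is not a small rational",
                                  target_sfreq, rec$sfreq)
  out <- t(apply(rec$data, 1, function(x) signal::resample(x, p, q)))
  splice <- as.integer(pmax(1, round(rec$splice_boundaries * p / q)))
  eeg_recording(out, target_sfreq, rec$montage, splice)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Run the full preprocessing chain
#'
#' Order: band-pass filter, bad-channel detection and interpolation,
#' the ICA hook (no-op by default), extreme-value rejection, resampling,
#' average reference.
#'
#' @param rec an `eeg_recording`.
#' @param config a [preprocess_config()].
#' @return list with `recording` and a `report` (bad channels, dropped
#'   window count, rates).
#' @export
preprocess_recording <- function(rec, config = preprocess_config()) {
  filtered <- bandpass_filter(rec, config$band_low, config$band_high)
  bad <- detect_bad_channels(filtered, config)
  if (length(bad)) filtered <- interpolate_bad_channels(filtered, bad)
  if (is.function(config$ica)) filtered <- config$ica(filtered)
  rej <- reject_extreme_segments(filtered, config$amplitude_threshold,
                                 config$reject_window_s)
  if (n_samples(rej$recording) == 0)
    stopf("no data survived extreme-value rejection")
  res <- resample_recording(rej$recording, min(config$target_sfreq, rec$sfreq))
  out <- average_reference(res)
  list(recording = out,
       report = list(bad_channels = bad,
                     n_windows = rej$n_windows,
                     n_windows_dropped = sum(!rej$kept),
                     native_sfreq = rec$sfreq,
                     analysis_sfreq = out$sfreq))
}
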