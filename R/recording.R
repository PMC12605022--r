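#' EEG recording container
#'
#' The universal currency between pipeline stages: a channels x samples
#' numeric matrix in microvolts, its sampling rate, and the montage.
#' `splice_boundaries` marks output-sample indices that start a new
#' contiguous stretch after extreme-value windows were removed, so that
#' later stages never let a microstate segment span a splice.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param sfreq sampling rate in Hz (> 0).
#' @param montage an `eeg_montage` whose channel count matches `data`.
#' @param splice_boundaries integer vector of sample indices (> 1) where
#'   non-adjacent data was joined; empty for a continuous record.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, sfreq, montage, splice_boundaries = integer()) {
  data <- as.matrix(data)
  if (!inherits(montage, "eeg_montage")) stopf("montage must be an eeg_montage")
  if (nrow(data) != length(montage$channel_names))
    stopf("data has %d channels but montage has %d",
          nrow(data), length(montage$channel_names))
  if (!is.numeric(sfreq) || length(sfreq) != 1 || !is.finite(sfreq) || sfreq <= 0)
    stopf("sfreq must be a single positive number")
  if (ncol(data) > 0 && !all(is.finite(data)))
    stopf("recording data must be finite")
  rownames(data) <- montage$channel_names
  structure(list(data = data, sfreq = sfreq, montage = montage,
                 splice_boundaries = as.integer(sort(splice_boundaries))),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)%s\n",
              nrow(x$data), ncol(x$data), x$sfreq, ncol(x$data) / x$sfreq,
              if (length(x$splice_boundaries))
                sprintf(", %d splices", length(x$splice_boundaries)) else ""))
  invisible(x)
}

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)
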