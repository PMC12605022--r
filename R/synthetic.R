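#' Generate ground-truth microstate template topographies
#'
#' Draws `k` zero-mean, unit-norm scalp maps whose pairwise absolute
#' spatial correlation does not exceed `max_abs_corr`. With
#' `max_abs_corr = 0` the maps are made exactly orthogonal by
#' Gram-Schmidt within the zero-mean subspace; otherwise maps are
#' rejection-sampled.
#'
#' @param k number of templates (< channel count).
#' @param montage an `eeg_montage`; its channel count sets map length.
#' @param max_abs_corr maximum allowed pairwise |spatial correlation|
#'   (0 forces orthogonality; must be < 1).
#' @param seed optional integer seed; the global RNG state is untouched.
#' @param max_tries rejection-sampling budget before failing.
#' @return channels x k numeric matrix; each column zero-mean, unit-norm.
#' @export
generate_templates <- function(k, montage, max_abs_corr = 0.5, seed = NULL,
                               max_tries = 500) {
  C <- length(montage$channel_names)
  if (k >= C) stopf("k (%d) must be smaller than the channel count (%d)", k, C)
  if (max_abs_corr < 0 || max_abs_corr >= 1)
    stopf("max_abs_corr must be in [0, 1)")
  with_seed_if(seed, {
    if (max_abs_corr == 0) {
      # orthonormal zero-mean maps by Gram-Schmidt
      T <- matrix(stats::rnorm(C * k), C, k)
      T <- sweep(T, 2, colMeans(T))
      for (j in seq_len(k)) {
        v <- T[, j]
        if (j > 1) {
          prev <- T[, seq_len(j - 1), drop = FALSE]
          v <- v - prev %*% crossprod(prev, v)
        }
        nv <- sqrt(sum(v^2))
        if (nv < 1e-10) stopf("degenerate draw during orthogonalisation")
        T[, j] <- v / nv
      }
    } else {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        T <- matrix(stats::rnorm(C * k), C, k)
        T <- sweep(T, 2, colMeans(T))
        T <- sweep(T, 2, sqrt(colSums(T^2)), "/")
        G <- crossprod(T)
        if (max(abs(G[upper.tri(G)])) <= max_abs_corr) { ok <- TRUE; break }
      }
      if (!ok)
        stopf("could not draw %d maps with pairwise |corr| <= %g in %d tries",
              k, max_abs_corr, max_tries)
    }
    rownames(T) <- montage$channel_names
    colnames(T) <- paste0("S", seq_len(k))
    T
  })
}

#' Generate a quasi-stable microstate label sequence
#'
#' Piecewise-constant state labels with geometric segment lengths
#' (memoryless Markov switching), a 2-sample minimum, the requested
#' per-state mean duration, and state-to-state transitions drawn from a
#' row-stochastic matrix with zero diagonal (switches happen only at
#' segment ends).
#'
#' @param k number of states.
#' @param n_samples sequence length (0 gives an empty sequence).
#' @param sfreq sampling rate in Hz.
#' @param mean_durations per-state mean segment duration in ms (recycled
#'   to length `k`); each must be at least 2 samples long.
#' @param transition_matrix k x k row-stochastic matrix, zero diagonal;
#'   default uniform over the other states.
#' @param seed optional integer seed.
#' @return integer vector of labels in 1..k.
#' @export
generate_label_sequence <- function(k, n_samples, sfreq, mean_durations = 100,
                                    transition_matrix = NULL, seed = NULL) {
  if (n_samples == 0) return(integer(0))
  mean_durations <- rep_len(mean_durations, k)
  m <- mean_durations / 1000 * sfreq  # mean length in samples
  if (any(m < 2))
    stopf("mean durations must be at least 2 samples at %g Hz", sfreq)
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / max(k - 1, 1), k, k)
    diag(transition_matrix) <- 0
    if (k == 1) transition_matrix <- matrix(0, 1, 1)
  }
  transition_matrix <- as.matrix(transition_matrix)
  if (any(diag(transition_matrix) != 0))
    stopf("transition matrix must have a zero diagonal")
  if (k > 1 && any(abs(rowSums(transition_matrix) - 1) > 1e-8))
    stopf("transition matrix rows must sum to 1")
  with_seed_if(seed, {
    labels <- integer(n_samples)
    pos <- 1L
    state <- sample.int(k, 1)
    while (pos <= n_samples) {
      # geometric with 2-sample floor: E[len] = 2 + (1-p)/p = m
      p <- 1 / (m[state] - 1)
      len <- 2L + stats::rgeom(1, p)
      end <- min(pos + len - 1L, n_samples)
      labels[pos:end] <- state
      pos <- end + 1L
      if (k > 1) state <- sample.int(k, 1, prob = transition_matrix[state, ])
    }
    labels
  })
}

#' Synthesise an EEG recording from templates and a label sequence
#'
#' The noiseless signal is `a(t) * template[label(t)] * amplitude`, with
#' `a(t)` a sinusoidal carrier at `envelope_frequency`: its magnitude
#' waxes and wanes like the GFP of an oscillatory burst, and the map
#' polarity flips each half-cycle exactly as a scalp oscillation does
#' (the microstate analysis ignores polarity throughout). A signed
#' carrier keeps the signal free of DC, so the analysis band-pass passes
#' it undistorted; a rectified carrier would put most of its power at DC
#' and smear template transitions across segment boundaries. Because
#' templates are zero-mean, the noiseless signal is exactly
#' average-referenced at every sample. Zero-mean white sensor noise is
#' added and scaled so that RMS(noiseless) / RMS(noise) over the whole
#' record equals `snr` (use `snr = Inf` for a noise-free recording).
#'
#' @param templates channels x k template matrix (zero-mean columns).
#' @param label_sequence integer labels in 1..k, one per sample.
#' @param sfreq sampling rate in Hz.
#' @param montage the montage the templates live on.
#' @param envelope_frequency rectified-sinusoid frequency in Hz.
#' @param snr amplitude signal-to-noise ratio (> 0, may be `Inf`).
#' @param amplitude peak scalp amplitude scale in microvolts.
#' @param seed optional integer seed.
#' @return list with `recording` (an `eeg_recording`) and `ground_truth`
#'   (templates, label sequence, snr, envelope frequency, amplitude).
#' @export
generate_eeg <- function(templates, label_sequence, sfreq, montage,
                         envelope_frequency = 10, snr = 4, amplitude = 15,
                         seed = NULL) {
  templates <- as.matrix(templates)
  C <- nrow(templates)
  if (C != length(montage$channel_names))
    stopf("templates and montage disagree on channel count")
  if (length(label_sequence) > 0 &&
      (min(label_sequence) < 1 || max(label_sequence) > ncol(templates)))
    stopf("label sequence refers to states outside the template set")
  if (!is.finite(snr) && !is.infinite(snr)) stopf("snr must be numeric")
  if (snr <= 0) stopf("snr must be positive")
  n <- length(label_sequence)
  t_sec <- (seq_len(n) - 1) / sfreq
  a <- sin(2 * pi * envelope_frequency * t_sec)
  clean <- templates[, label_sequence, drop = FALSE] *
    rep(a * amplitude, each = C)
  data <- with_seed_if(seed, {
    if (is.infinite(snr)) {
      clean
    } else {
      rms_clean <- sqrt(mean(clean^2))
      noise_sd <- rms_clean / snr
      clean + matrix(stats::rnorm(C * n, sd = noise_sd), C, n)
    }
  })
  list(recording = eeg_recording(data, sfreq, montage),
       ground_truth = list(templates = templates,
                           label_sequence = label_sequence,
                           snr = snr,
                           envelope_frequency = envelope_frequency,
                           amplitude = amplitude,
                           seed = seed))
}

#' Simulation configuration for two-group synthetic cohorts
#'
#' Bundles the generator settings for [generate_cohort()]. Group B (the
#' patient-like group) applies per-state multipliers to mean durations
#' and to entry (occurrence) probabilities. Per-subject biological
#' variability is modelled as a log-normal multiplier on the per-state
#' mean durations with log-SD `subject_cv`.
#'
#' @param n_states number of planted microstates.
#' @param sfreq sampling rate in Hz.
#' @param record_s record length per subject in seconds.
#' @param envelope_frequency rectified-sinusoid frequency (Hz).
#' @param snr amplitude SNR.
#' @param amplitude scalp amplitude scale (microvolts).
#' @param mean_duration_ms per-state mean segment duration (ms).
#' @param group_sizes length-2 integer vector (group A, group B).
#' @param duration_multipliers per-state duration multipliers for group B.
#' @param occurrence_multipliers per-state occurrence multipliers for
#'   group B (applied to transition-entry probabilities, renormalised).
#' @param subject_cv log-SD of per-subject duration variability.
#' @param montage montage (default 19-channel 10-20).
#' @param max_abs_corr template dissimilarity bound for
#'   [generate_templates()].
#' @param connectivity optional list enabling planted source
#'   connectivity: fields `n_sources`, `n_regions`, `base_correlation`
#'   (off-diagonal level of the planted region correlation, group A),
#'   `group_b_scale` (multiplier on group-B off-diagonals) and
#'   `source_amplitude` (microvolts).
#' @param seed master seed; per-subject seeds are drawn once from it.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_states = 4, sfreq = 250, record_s = 60,
                              envelope_frequency = 10, snr = 4, amplitude = 15,
                              mean_duration_ms = 100, group_sizes = c(17, 23),
                              duration_multipliers = rep(1, n_states),
                              occurrence_multipliers = rep(1, n_states),
                              subject_cv = 0.2,
                              montage = standard_montage_1020(),
                              max_abs_corr = 0.5,
                              connectivity = NULL, seed = 1) {
  stopifnot(n_states >= 1, sfreq > 0, record_s > 0, snr > 0,
            length(group_sizes) == 2, all(group_sizes >= 1))
  if (n_states >= length(montage$channel_names))
    stopf("n_states must be below the channel count")
  structure(list(n_states = n_states, sfreq = sfreq, record_s = record_s,
                 envelope_frequency = envelope_frequency, snr = snr,
                 amplitude = amplitude, mean_duration_ms = mean_duration_ms,
                 group_sizes = as.integer(group_sizes),
                 duration_multipliers = rep_len(duration_multipliers, n_states),
                 occurrence_multipliers = rep_len(occurrence_multipliers, n_states),
                 subject_cv = subject_cv, montage = montage,
                 max_abs_corr = max_abs_corr,
                 connectivity = connectivity, seed = as.integer(seed)),
            class = "simulation_config")
}

# Scale entries into each state by the occurrence multipliers and
# renormalise rows (diagonal stays zero).
apply_occurrence_multipliers <- function(tm, mult) {
  k <- nrow(tm)
  out <- tm * matrix(mult, k, k, byrow = TRUE)
  diag(out) <- 0
  sweep(out, 1, rowSums(out), "/")
}

#' Generate a two-group synthetic cohort
#'
#' Draws one shared set of ground-truth templates, then one recording
#' per subject with independent per-subject seeds derived once from the
#' master seed. Group B applies the configured duration / occurrence
#' multipliers. When `config$connectivity` is set, a toy spherical
#' forward model is generated and each recording additionally carries
#' state-conditioned correlated source activity (group B with scaled-down
#' off-diagonal correlations).
#'
#' @param config a [simulation_config()].
#' @return list with `groups` (list `A`, `B` of per-subject lists holding
#'   `recording`, `ground_truth`, `seed`, `id`), `templates`, `config`,
#'   and (when connectivity is enabled) `leadfield`, `parcellation`,
#'   `state_correlations` per group.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  k <- config$n_states
  n_total <- sum(config$group_sizes)
  seeds <- with_seed_if(config$seed, {
    list(templates = sample.int(2^31 - 2, 1),
         subjects = sample.int(2^31 - 2, n_total))
  })
  templates <- generate_templates(k, config$montage, config$max_abs_corr,
                                  seed = seeds$templates)
  base_tm <- matrix(1 / max(k - 1, 1), k, k); diag(base_tm) <- 0
  n_samples <- round(config$record_s * config$sfreq)
  base_dur <- rep_len(config$mean_duration_ms, k)

  conn <- config$connectivity
  fwd <- NULL
  state_corr <- NULL
  if (!is.null(conn)) {
    fwd <- generate_forward_model(conn$n_sources %||% 64, config$montage,
                                  n_regions = conn$n_regions %||% 6)
    mk_corr <- function(off) {
      R <- length(fwd$parcellation$region_names)
      M <- matrix(off, R, R); diag(M) <- 1
      M
    }
    state_corr <- list(
      A = lapply(seq_len(k), function(i) mk_corr(conn$base_correlation %||% 0.6)),
      B = lapply(seq_len(k), function(i)
        mk_corr((conn$base_correlation %||% 0.6) * (conn$group_b_scale %||% 0.8))))
  }

  make_subject <- function(group, idx, seed) {
    mult_d <- if (group == "B") config$duration_multipliers else rep(1, k)
    tm <- if (group == "B")
      apply_occurrence_multipliers(base_tm, config$occurrence_multipliers)
    else base_tm
    with_seed_if(seed, {
      subj_dur <- base_dur * mult_d *
        exp(stats::rnorm(k, 0, config$subject_cv))
      labels <- generate_label_sequence(k, n_samples, config$sfreq,
                                        subj_dur, tm)
      if (is.null(conn)) {
        sim <- generate_eeg(templates, labels, config$sfreq, config$montage,
                            config$envelope_frequency, config$snr,
                            config$amplitude)
      } else {
        sim <- generate_connected_sources(
          fwd$leadfield, fwd$parcellation, state_corr[[group]], labels,
          config$sfreq, config$montage, snr = config$snr,
          templates = templates,
          envelope_frequency = config$envelope_frequency,
          template_amplitude = config$amplitude,
          # default: source component at half the template's sensor RMS
          source_amplitude = conn$source_amplitude %||%
            (0.5 * config$amplitude * sqrt(0.5 / length(config$montage$channel_names))))
      }
      sim$ground_truth$mean_durations <- subj_dur
      sim$ground_truth$transition_matrix <- tm
      list(recording = sim$recording, ground_truth = sim$ground_truth,
           seed = seed, id = sprintf("%s%02d", group, idx))
    })
  }

  nA <- config$group_sizes[1]
  groups <- list(
    A = lapply(seq_len(nA), function(i)
      make_subject("A", i, seeds$subjects[i])),
    B = lapply(seq_len(config$group_sizes[2]), function(i)
      make_subject("B", i, seeds$subjects[nA + i])))
  out <- list(groups = groups, templates = templates, config = config)
  if (!is.null(conn)) {
    out$leadfield <- fwd$leadfield
    out$parcellation <- fwd$parcellation
    out$state_correlations <- state_corr
  }
  out
}
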