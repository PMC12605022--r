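# Small montages and recordings built in code for the unit tests.

montage4 <- function() {
  montage(c("a", "b", "c", "d"),
          rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 0), c(0, -1, 0)))
}

montage19 <- function() standard_montage_1020()

# Recording holding an arbitrary matrix on a matching ad-hoc montage.
rec_from_matrix <- function(X, sfreq = 100) {
  C <- nrow(X)
  ang <- 2 * pi * seq_len(C) / C
  m <- montage(sprintf("ch%02d", seq_len(C)),
               cbind(cos(ang), sin(ang), 0))
  eeg_recording(X, sfreq, m)
}

# One preprocessed synthetic subject with known ground truth.
quick_subject <- function(seed = 1, snr = 4, n_samples = 7500, sfreq = 250,
                          k = 4, mean_dur = 100, mont = montage19()) {
  templates <- generate_templates(k, mont, 0.5, seed = seed)
  labels <- generate_label_sequence(k, n_samples, sfreq, mean_dur,
                                    seed = seed + 1)
  sim <- generate_eeg(templates, labels, sfreq, mont, snr = snr,
                      seed = seed + 2)
  pp <- preprocess_recording(sim$recording)
  list(templates = templates, labels = labels, raw = sim$recording,
       clean = pp$recording, gfp = compute_gfp(pp$recording))
}
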