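#!/usr/bin/env Rscript
# Shared configuration for the analysis drivers. Sourced by 01-05.
#
# The synthetic cohort mirrors the clinical study design this analysis
# emulates: 17 control-like subjects (group A) and 23 patient-like
# subjects (group B), resting EEG on the 19-channel 10-20 montage,
# analysed at 250 Hz in the 1-30 Hz band. Group B carries a planted
# occurrence deficit on one microstate and globally weakened planted
# source connectivity, the two effects the group statistics should find.

library(eegmicrostates)

analysis_seed <- 20260929L

analysis_config <- function(out_dir = "results") {
  pipeline_config(
    simulation = simulation_config(
      n_states = 4, sfreq = 250, record_s = 60,
      snr = 4, mean_duration_ms = 100,
      group_sizes = c(17, 23),
      occurrence_multipliers = c(1, 1, 1, 0.75),
      subject_cv = 0.15,
      connectivity = list(n_sources = 48, n_regions = 6,
                          base_correlation = 0.6, group_b_scale = 0.7,
                          source_amplitude = 2)),
    k_range = 2:8, n_restarts = 50, forced_k = 4,
    out_dir = out_dir, seed = analysis_seed)
}

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)
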