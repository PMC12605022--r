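# eegmicrostates

Resting-state EEG **microstate** analysis with **microstate-conditioned
source connectivity** and nonparametric group statistics, plus a
ground-truthed synthetic cohort generator so that every stage of the
pipeline is testable by parameter recovery.

The package is aimed at clinical-neurophysiology analyses that compare a
patient group against controls — the motivating application is prolonged
disorders of consciousness, where microstate temporal parameters and
source-space connectivity both degrade — but all components are generic
resting-EEG machinery.

## What it computes

Band-limited (1–30 Hz), average-referenced EEG is modelled as a sequence
of quasi-stable scalp topographies. For average-referenced maps
$x_t \in \mathbb{R}^C$:

* **GFP**: $\mathrm{GFP}_t = \sqrt{\tfrac1C \sum_c x_{tc}^2}$ — the
  spatial RMS; its peaks are the high-SNR moments.
* **Polarity-insensitive modified k-means** on GFP-peak maps: assignment
  $L_t=\arg\max_k (T_k^\top x_t)^2$, template update by the principal
  eigenvector of the assigned maps' scatter, best of 50 random restarts
  by **GEV** $= \sum_t (T_{L_t}^\top x_t)^2 / \sum_t \lVert x_t \rVert^2$.
* **Model selection** over $K = 2..8$ by the cross-validation criterion
  $\mathrm{CV} = \hat\sigma^2\left(\frac{C-1}{C-1-K}\right)^2$, with a
  forced-$K{=}4$ reporting mode.
* **Backfitting** and the temporal parameters per state: Duration (ms),
  Occurrence (s⁻¹), Coverage (fraction; Coverage = Occurrence ×
  Duration exactly when edge segments are included).
* **sLORETA** source imaging ($W = G^\top(GG^\top+\alpha H)^{+}$,
  standardised by the resolution diagonal; zero localization error on
  noiseless single sources), region parcellation, and per-microstate
  Pearson connectivity with thresholded edge lists.
* **Group statistics**: Mann–Whitney U with SPSS-style asymptotic Z
  (tie-corrected, no continuity correction by default; exact
  enumeration available), and a two-sample Z test that also accepts
  printed mean ± SD summaries. Clinical-style descriptive summaries
  with half-up percentage rounding.
* **Synthetic cohorts**: Markov microstate sequences (geometric segment
  lengths), planted templates, sinusoidal carrier, white sensor noise at
  a stated amplitude SNR, a toy single-shell spherical head model, and
  planted inter-regional source correlations — with per-group effect
  multipliers so downstream tests can be scored by recovery.

## Worked example

Simulate one minute of four-state resting EEG at SNR 4, preprocess,
cluster, select K, and recover the planted structure:

```r
library(eegmicrostates)

mont      <- standard_montage_1020()
templates <- generate_templates(4, mont, max_abs_corr = 0.5, seed = 1)
labels    <- generate_label_sequence(4, n_samples = 15000, sfreq = 250,
                                     mean_durations = 100, seed = 2)
sim   <- generate_eeg(templates, labels, sfreq = 250, montage = mont,
                      snr = 4, seed = 3)
clean <- preprocess_recording(sim$recording)$recording
gfp   <- compute_gfp(clean)
models <- fit_microstates(clean$data[, gfp$peaks], k_range = 2:8,
                          n_restarts = 10, seed = 4)
model <- select_k(models)
model
#> <microstate_model> k = 4 on 1302 maps: GEV = 0.987, CV = 0.2433
round(sapply(models, `[[`, "cv"), 3)
#> [1] 5.301 2.490 0.243 0.271 0.309 0.354 0.415   # argmin at K = 4
match_templates(model, templates)$correlations
#> [1] 1 1 1 1                                     # planted maps recovered
compute_parameters(backfit(model, clean, gfp))
#>   state n_segments duration_ms occurrence_hz  coverage
#> 1     1        126    110.3175      2.100000 0.2316667
#> 2     2        128    121.2500      2.133333 0.2586667
#> 3     3        127    116.5669      2.116667 0.2467333
#> 4     4        127    124.2205      2.116667 0.2629333
```

The CV criterion bottoms out at the planted $K = 4$, the fitted
templates match the planted ones to $|r| = 1.000$, and the temporal
parameters sit near the planted 100 ms / 0.25 coverage per state (the
peak-interpolated backfit overestimates duration somewhat; the methods
vignette quantifies why, and shows the all-samples estimator that
recovers durations within a few percent).

## The analysis workflow

The full two-group study lives in `analysis/` as numbered drivers over
the package functions:

```sh
Rscript analysis/01_simulate.R          # 17 + 23 subject cohort + ground truth manifest
Rscript analysis/02_preprocess.R        # filtering, rejection, re-referencing
Rscript analysis/03_microstates.R       # group templates, backfit, parameter table
Rscript analysis/04_connectivity.R      # sLORETA + per-state Pearson connectivity
Rscript analysis/05_group_statistics.R  # Mann-Whitney / Z-test report
```

Small tables land in `results/`, bulky intermediates in `scratch/`.
`run_all(pipeline_config(...))` performs the same chain in one call and
writes a manifest with md5 hashes of every emitted table; reruns with
the same seed are hash-identical.

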