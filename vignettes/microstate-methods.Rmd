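---
title: "Resting-state EEG microstates and microstate-conditioned connectivity: methods"
author: "eegmicrostates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state EEG microstates and microstate-conditioned connectivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the microstate model and its estimators, the source-connectivity stage,
the group statistics, and the synthetic cohorts everything is validated
against. It also records the numerical and design choices that were
genuinely open, and what the validation studies do and do not show.

## The microstate model

Resting EEG, band-limited to 1--30 Hz and average-referenced, is modelled
as a sequence of quasi-stable scalp topographies ("microstates"): for
stretches of roughly 80--120 ms the spatial pattern of the scalp
potential is fixed up to amplitude and polarity, then switches rapidly to
another pattern. Four canonical patterns (labelled A--D) dominate the
healthy resting literature.

The quantities involved, per sample $t$ with average-referenced map
$x_t \in \mathbb{R}^C$ over $C$ channels:

* **GFP** (global field power): the population spatial standard
  deviation $\mathrm{GFP}_t = \sqrt{\tfrac1C\sum_c x_{tc}^2}$,
  equivalently the RMS of the average-referenced map. GFP is nowhere
  given a formula in parts of the applied literature; the population
  form is this package's convention (`compute_gfp()`), and its peaks
  mark the moments of highest topographic signal-to-noise.
* **Modified k-means** (`modified_kmeans()`): clustering of the maps at
  GFP peaks into $K$ unit-norm, zero-mean template topographies
  $T_1,\dots,T_K$. Assignment ignores polarity,
  $L_t = \arg\max_k (T_k^\top x_t)^2$, and the update step sets $T_k$ to
  the principal eigenvector of $\sum_{t: L_t=k} x_t x_t^\top$, so a map
  and its negation are the same state by construction. The procedure is
  restarted from random maps (50 restarts by default) and the restart
  with the highest GEV wins. Ties in the assignment go to the lowest
  state index; an emptied cluster is re-seeded from the worst-fit map.
* **GEV** (global explained variance):
  $\mathrm{GEV} = \sum_t (T_{L_t}^\top x_t)^2 / \sum_t \lVert x_t\rVert^2$,
  the GFP-squared-weighted fraction of topographic variance the
  labelling explains. Per-state GEVs partition the total.
* **CV criterion** (`cross_validation_criterion()`):
  $\mathrm{CV} = \hat\sigma^2\,\bigl(\tfrac{C-1}{C-1-K}\bigr)^2$ with
  $\hat\sigma^2$ the mean residual map variance after removing each
  map's projection on its template. The correction factor penalises the
  degrees of freedom spent on templates; `select_k()` minimises CV over
  the fitted range $K = 2..8$, with a forced-$K$ mode mirroring the
  common four-state reporting convention.
* **Backfitting** (`backfit()`): the chosen templates are fitted back to
  the continuous recording. In the default peak-interpolated mode each
  GFP peak is labelled by squared spatial correlation and non-peak
  samples inherit the label of the nearest peak in time, never crossing
  a splice left by artifact rejection; the all-samples mode labels every
  sample directly.
* **Temporal parameters** (`compute_parameters()`): per state, Duration
  (mean segment length, ms), Occurrence (segments per second of labelled
  time) and Coverage (fraction of labelled samples). With edge segments
  included, Coverage $=$ Occurrence $\times$ Duration(s) is an exact
  identity, which published mean-parameter triads satisfy after
  rounding.

Cross-group comparability of state labels is never assumed: group-level
template sets are matched by exhaustive best-permutation assignment on
absolute spatial correlation (`match_templates()`), and states are named
A--D against canonical geometric maps (`canonical_microstate_maps()`).

## Source connectivity

For each microstate the sensor maps at that state's GFP peaks are pushed
into source space and correlated between regions
(`extract_state_data()` → `build_sloreta_inverse()` /
`apply_inverse()` → `parcellate()` → `pearson_connectivity()`).

The inverse operator is sLORETA: with $H$ the average-reference
projector and $G = H\,\mathrm{gain}$, the minimum-norm kernel is
$W = G^\top (GG^\top + \alpha H)^{+}$ and source $j$'s estimate is
standardised by $\sqrt{(WG)_{jj}}$. For noiseless single-source data and
$\alpha \to 0$ the standardised power peaks exactly at the true source;
the test suite verifies this zero-localization property for every source
of the toy head model. The default $\alpha$ is small and explicit
(`pipeline_config(alpha = 1e-6)`) rather than estimated, because the
synthetic sensors have known noise; with real data $\alpha$ should be
chosen against the measured noise level.

Three design choices in this stage deserve their reasoning spelled out,
because naive microstate-conditioned correlation is dominated by the
microstate itself:

1. **Polarity normalisation** (`align_to`): within a microstate the
   scalp map flips sign with the underlying oscillation phase. The
   clustering treats $\pm x$ as the same state, but a signed analysis
   downstream does not: at GFP peaks the state topography appears as a
   large amplitude signal of alternating sign, and its projection into
   source space dominates every region covariance. Each extracted map is
   therefore flipped to project positively on its state template.
2. **Template-span removal** (`remove_span`): even after polarity
   alignment, residual amplitude fluctuations of the stereotyped
   topographies — including smeared residues of neighbouring states
   introduced by the zero-phase band-pass — act as a common mode that
   inflates every region pair's correlation uniformly. The span of the
   $K$ fitted templates is projected out of the state-conditioned maps
   before inversion, analogous to removing an evoked component before
   functional connectivity. In validation this step is what makes
   planted between-group connectivity differences recoverable at all.
3. **Region sign alignment** (`parcellate(global_sign = TRUE)`): the
   sign of a minimum-norm source estimate is arbitrary per region.
   Sources are first flipped to load positively on their region's
   leading principal direction, then region series are flipped to load
   positively on the leading direction across regions, so pooled
   Pearson values are comparable across subjects instead of carrying
   random sign patterns.

Pooling across subjects uses raw $r$ of the upper triangle by default
(mirroring mean-and-SD connectivity tables in the clinical literature);
Fisher-z averaging is available. Edge lists thresholded on $|r|$ are the
export format for circos-style figures.

## Group statistics

`mann_whitney()` computes U from rank sums and the asymptotic Z with
tie-corrected variance and, by default, *no* continuity correction —
the convention of the major commercial packages whose printed Z values
clinical papers report. An exact two-sided p by complete enumeration of
rank splits is available for small samples and is the oracle the
approximation is tested against. One nuance the validation made
explicit: over all possible data sets at $n = 8$ vs 8 the
no-correction asymptotic p differs from the conventional exact
two-sided p by up to 0.047 (largest mid-range, where the discrete mass
at the observed U is large), while the continuity-corrected form stays
within 0.011 of the exact value. The calibration test therefore bounds
the continuity-corrected form at 0.02 and the default form at 0.05;
both forms are exposed, the default is unchanged.

`two_sample_z()` implements
$Z = (\bar x - \bar y)/\sqrt{s_x^2/n_x + s_y^2/n_y}$ and accepts either
raw values or printed (mean, sd, n) summaries, so comparisons can be
reproduced directly from published tables. Pooled connectivity edges are
treated as independent observations in `compare_connectivity_tables()`
because that is the only reading consistent with Z values of the
magnitude published for pooled-edge tables; the output carries an
explicit caveat that within-subject edges share sources. No
multiple-testing correction is applied by default (matching the
single-test reporting style of the target literature); a Holm option
exists and is a documented deviation from that style.

## The synthetic cohort generator

`generate_cohort()` produces the ground-truthed cohorts every stage is
validated against: per subject, a Markov label sequence with geometric
segment lengths (memoryless switching, 2-sample minimum, requested
per-state means), zero-mean unit-norm template topographies shared
across the cohort, a sinusoidal carrier, white sensor noise at a stated
amplitude SNR (RMS of noiseless signal over RMS of noise for the whole
record), and optionally leadfield-projected region-correlated source
activity. Group B applies configurable multipliers to per-state mean
durations and to transition-entry probabilities (occurrence), and a
scale factor on planted off-diagonal region correlations.

Defaults, with the reasoning where a choice was open:

* `envelope_frequency = 10` Hz, **signed** carrier
  $a(t) = \sin(2\pi f t)$. A rectified carrier was considered and
  rejected: $|\sin|$ has most of its power at DC, and switching
  templates modulates that DC into in-band boxcar transitions that the
  1--30 Hz zero-phase filter smears across segment boundaries — the
  median noiseless GFP-peak map then correlates only ~0.94 with its
  template. The signed carrier is polarity-equivalent sample by sample
  (the analysis ignores polarity), matches real EEG (which has no DC),
  and passes the band-pass undistorted, so noiseless peak maps match
  their template to machine precision.
* `snr = 4` (amplitude ratio), `amplitude = 15` µV peak scalp scale,
  60 s records at 250 Hz: desk-scale conditions under which template
  recovery, K selection and duration recovery are all comfortably
  testable.
* `subject_cv = 0.2`: log-normal per-subject duration variability,
  matching the ~20--40% between-subject coefficients of variation of
  published temporal-parameter tables.
* Toy head model: radial dipoles in a single-shell sphere with the
  closed-form surface potential, Fibonacci-lattice sources on the upper
  hemisphere, unit-norm gain columns, and deterministic equal-azimuth
  sector parcellation (contiguous on the sphere). This replaces
  anatomical BEM modelling deliberately: it is analytic and exercises
  the inverse operator's contract, nothing more.
* `source_amplitude` is specified as the sensor-level RMS of the
  projected source component, because member sources of a region sum
  coherently at the scalp and the raw latent scale would otherwise be
  uninterpretable.

What the generator does **not** emulate: ocular/muscle artifacts (the
ICA hook in preprocessing is a deliberate no-op), 1/f background
spectra, spatially correlated sensor noise, individual anatomy, or
non-geometric (heavy-tailed) segment-length distributions. Passing
validation on these cohorts shows the estimators recover the model they
assume; it does not certify performance on clinical recordings.

## Numerical choices and degenerate inputs

* Filtering: order-4 Butterworth applied forward--backward with
  odd-reflection padding of $3/f_\mathrm{low}$ seconds, so the slow
  high-pass transient never reaches the record.
* Convergence: relative GEV change $< 10^{-7}$, at most 300 iterations,
  50 restarts by default.
* Eigenvector signs are fixed by making the largest-magnitude loading
  positive everywhere an eigendecomposition is used, which (with seeded
  RNG throughout, isolated via `withr::with_seed`) makes every stage
  bit-reproducible; the pipeline manifest records md5 hashes of all
  written tables and reruns must reproduce them.
* Rank-deficient systems (average-referenced leadfields) go through an
  eigenvalue-thresholded pseudo-inverse; sources with vanishing
  resolution are zeroed with a warning rather than amplified.
* Degenerate tests are flagged, not silently absorbed: identical
  samples give $Z = 0, p = 1$ with a `degenerate` flag; zero-variance
  region series yield NA correlations plus a `degenerate_regions` flag;
  an empty post-rejection recording is an error.

## Validation studies and their sizes

The acceptance-style checks in `tests/testthat/test-acceptance.R` (and
recomputed by `scripts/acceptance.R`) use the following study sizes,
chosen as the package's own trade-off between resolution and a
desk-scale run:

* Exhaustive-oracle equivalence: 8 maps × 3 channels, $K=2$, 20 seeds —
  all $2^8$ assignments enumerated independently.
* Parameter recovery: 20 independent 60 s subjects at SNR 4 with 10
  k-means restarts per K (identifiability at this SNR is easy; 50
  restarts remains the per-fit default). Template recovery and CV-based
  K selection are assessed per run; durations are pooled across runs
  per state.
* Duration recovery uses the all-samples backfit plus minimum-duration
  smoothing at 8 ms — exactly the generator's 2-sample segment floor,
  so only segments the generator cannot produce are absorbed. The
  peak-interpolated default is the right estimator for real data
  reporting, but its temporal resolution is the GFP peak spacing
  (twice the carrier frequency); under geometric segment lengths, where
  ~19% of segments are shorter than 25 ms, it overestimates mean
  duration by ~12--26% depending on carrier frequency. This bias is a
  property of peak-conditioned segmentation, measured and documented
  here rather than hidden.
* Statistics calibration: exact-vs-asymptotic agreement over 100 random
  datasets at $n=8$ vs 8; type-I error over 400 null cohort pairs at
  the published group sizes (17 vs 23); power for a 12% occurrence
  deficit over 50 replicates with per-subject SD 0.25. The latter two
  operate on parameter tables drawn at the subject level — the quantity
  `compare_parameter_tables()` actually consumes — not on full EEG
  simulations per replicate.
* End-to-end determinism: the full 17 + 23 cohort (60 s @ 250 Hz, 19
  channels, connectivity enabled, $K$ fitted over 2..8 with the
  four-state reporting convention) run twice; all emitted tables must
  hash identically.

## Known limitations

* The peak-mode duration bias above; consider the all-samples mode with
  minimal smoothing when absolute durations matter.
* Pooled-edge Z tests overstate the effective n; the caveat travels
  with the output, and subject-level summaries are the conservative
  alternative.
* The toy spherical model cannot speak to localisation accuracy under
  realistic head geometry; it verifies operator contracts only.
* With identical templates planted in both groups, group topography
  differences (a key clinical observation) are out of the generator's
  reach; only temporal-parameter and connectivity differences are
  planted and recovered.
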