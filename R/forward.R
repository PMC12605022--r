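#' Toy spherical forward model
#'
#' Radial fixed-orientation dipoles in a single-shell conducting sphere
#' (unit sensor radius), with the closed-form surface potential of a
#' radial dipole. Sources are laid out on the upper hemisphere at
#' `source_radius` by a Fibonacci lattice, so the geometry is fully
#' deterministic. Gain columns are scaled to unit norm. The parcellation
#' assigns each source to exactly one of `n_regions` equal-azimuth
#' sectors, which are contiguous on the sphere.
#'
#' This is a desk-scale stand-in for an anatomical BEM head model: it is
#' analytic and exercises the inverse-operator contract, nothing more.
#'
#' @param n_sources number of sources (>= n_regions >= 2).
#' @param montage sensor montage (positions on the unit sphere).
#' @param n_regions number of parcellation regions.
#' @param source_radius source shell radius (< 1).
#' @param parcellation `"sectors"` (default) or `"singleton"` (one region
#'   per source, the testing configuration).
#' @param identity if `TRUE`, return an identity leadfield over the
#'   sensors themselves (testing hook); `n_sources` is then the channel
#'   count.
#' @param seed unused (the geometry is deterministic); kept so callers
#'   can treat all generators uniformly.
#' @return list with `leadfield` (class `leadfield`: `gain` C x S,
#'   `source_positions` S x 3, `alpha`) and `parcellation` (class
#'   `parcellation`: `region_of_source`, `region_names`).
#' @export
generate_forward_model <- function(n_sources, montage, n_regions = 6,
                                   source_radius = 0.7,
                                   parcellation = c("sectors", "singleton"),
                                   identity = FALSE, seed = NULL) {
  parcellation <- match.arg(parcellation)
  sens <- montage$positions
  C <- nrow(sens)
  if (identity) {
    gain <- diag(C)
    src_pos <- sens
    n_sources <- C
  } else {
    if (n_sources < 2) stopf("need at least 2 sources")
    i <- seq_len(n_sources)
    z <- (i - 0.5) / n_sources            # upper hemisphere
    r_xy <- sqrt(pmax(0, 1 - z^2))
    golden <- pi * (3 - sqrt(5))
    phi <- i * golden
    src_pos <- source_radius * cbind(x = r_xy * cos(phi),
                                     y = r_xy * sin(phi), z = z)
    d2 <- outer(rowSums(sens^2), rowSums(src_pos^2), "+") -
      2 * sens %*% t(src_pos)
    if (min(d2) < 1e-12) stopf("a source is colocated with a sensor")
    # closed-form surface potential of a radial dipole in a single-shell
    # sphere: V = 2(cos(theta) - f)/g^3 + (1/f)(1/g - 1),
    # f = |r_src|/R, g = sqrt(1 - 2 f cos(theta) + f^2)
    sens_u <- sens / sqrt(rowSums(sens^2))
    src_u <- src_pos / sqrt(rowSums(src_pos^2))
    f <- sqrt(rowSums(src_pos^2))          # sensor sphere radius is 1
    cth <- sens_u %*% t(src_u)             # C x S
    fm <- matrix(f, C, n_sources, byrow = TRUE)
    g <- sqrt(pmax(1 - 2 * fm * cth + fm^2, 1e-12))
    gain <- 2 * (cth - fm) / g^3 + (1 / fm) * (1 / g - 1)
    gain <- sweep(gain, 2, sqrt(colSums(gain^2)), "/")
  }
  dimnames(gain) <- list(montage$channel_names, NULL)

  if (parcellation == "singleton") {
    region_of_source <- seq_len(n_sources)
    region_names <- sprintf("R%02d", seq_len(n_sources))
  } else {
    if (n_regions < 2) stopf("need at least 2 regions")
    if (n_sources < n_regions) stopf("need n_sources >= n_regions")
    az <- atan2(src_pos[, 2], src_pos[, 1])          # (-pi, pi]
    region_of_source <- as.integer(cut(az, breaks = seq(-pi, pi,
                                                        length.out = n_regions + 1),
                                       include.lowest = TRUE))
    if (length(unique(region_of_source)) < n_regions)
      stopf("empty region in sector parcellation; increase n_sources")
    region_names <- sprintf("R%02d", seq_len(n_regions))
  }
  list(leadfield = structure(list(gain = gain, source_positions = src_pos,
                                  alpha = 0), class = "leadfield"),
       parcellation = structure(list(region_of_source = region_of_source,
                                     region_names = region_names),
                                class = "parcellation"))
}

#' Synthesise a recording with planted inter-regional source correlations
#'
#' Region-level latent series are drawn state by state from the planted
#' correlation matrix of the state occupying each sample (Cholesky of the
#' target applied to white noise), broadcast to every member source,
#' projected through the leadfield, and mixed with sensor noise at `snr`.
#' Optionally a microstate template component (as in [generate_eeg()]) is
#' added so that one recording carries both the temporal microstate
#' structure and the planted connectivity.
#'
#' @param leadfield a `leadfield`.
#' @param parcellation a `parcellation` over the leadfield's sources.
#' @param state_correlations list (one per state) of symmetric
#'   positive-semidefinite region correlation matrices with unit diagonal.
#' @param label_sequence per-sample state labels.
#' @param sfreq sampling rate (Hz).
#' @param montage sensor montage.
#' @param snr amplitude SNR of total noiseless signal vs sensor noise.
#' @param seed optional integer seed.
#' @param templates optional channels x k template matrix; when given,
#'   `template_amplitude * a(t) * template[label(t)]` is added.
#' @param envelope_frequency rectified-sinusoid frequency for the
#'   template component (Hz).
#' @param template_amplitude microvolt scale of the template component.
#' @param source_amplitude sensor-level RMS (microvolts) of the projected
#'   source component; the projection is rescaled to this value, so the
#'   knob is comparable to `template_amplitude` regardless of how
#'   coherently member sources sum at the scalp.
#' @return list with `recording` and `ground_truth` (latent region
#'   series, planted correlations, labels, leadfield reference).
#' @export
generate_connected_sources <- function(leadfield, parcellation,
                                       state_correlations, label_sequence,
                                       sfreq, montage, snr = Inf, seed = NULL,
                                       templates = NULL,
                                       envelope_frequency = 10,
                                       template_amplitude = 15,
                                       source_amplitude = 2) {
  gain <- leadfield$gain
  C <- nrow(gain); S <- ncol(gain)
  if (length(parcellation$region_of_source) != S)
    stopf("parcellation does not cover the leadfield's sources")
  R <- length(parcellation$region_names)
  k <- length(state_correlations)
  n <- length(label_sequence)
  if (snr <= 0) stopf("snr must be positive")
  chols <- lapply(state_correlations, function(M) {
    M <- as.matrix(M)
    if (nrow(M) != R || ncol(M) != R) stopf("correlation matrix must be R x R")
    if (max(abs(M - t(M))) > 1e-8) stopf("correlation matrix must be symmetric")
    if (max(abs(diag(M) - 1)) > 1e-8) stopf("correlation matrix needs a unit diagonal")
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) {
      # PSD but singular targets are allowed; rank-revealing fallback
      e <- eigen(M, symmetric = TRUE)
      if (min(e$values) < -1e-8) stopf("correlation matrix is not positive semi-definite")
      L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), R)
      return(t(L))  # acts like chol: crossprod(ch, z)
    }
    ch
  })
  with_seed_if(seed, {
    latent <- matrix(0, R, n)
    for (s in seq_len(k)) {
      idx <- which(label_sequence == s)
      if (!length(idx)) next
      Z <- matrix(stats::rnorm(R * length(idx)), R)
      latent[, idx] <- crossprod(chols[[s]], Z)
    }
    src <- latent[parcellation$region_of_source, , drop = FALSE]
    clean <- gain %*% src
    rms <- sqrt(mean(clean^2))
    if (rms > 0) clean <- clean * (source_amplitude / rms)
    if (!is.null(templates)) {
      t_sec <- (seq_len(n) - 1) / sfreq
      a <- abs(sin(2 * pi * envelope_frequency * t_sec))
      clean <- clean + as.matrix(templates)[, label_sequence, drop = FALSE] *
        rep(a * template_amplitude, each = C)
    }
    data <- if (is.infinite(snr)) clean else {
      noise_sd <- sqrt(mean(clean^2)) / snr
      clean + matrix(stats::rnorm(C * n, sd = noise_sd), C, n)
    }
    list(recording = eeg_recording(data, sfreq, montage),
         ground_truth = list(latent = latent,
                             state_correlations = state_correlations,
                             label_sequence = label_sequence,
                             region_of_source = parcellation$region_of_source,
                             leadfield = leadfield, snr = snr, seed = seed))
  })
}
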