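#' Global field power
#'
#' GFP(t) is the spatial standard deviation of the scalp map at sample t
#' in its population form (divide by the channel count), equivalently the
#' RMS of the average-referenced map. Peaks are strict local maxima; an
#' optional minimum separation keeps only the locally largest peak within
#' that distance, suppressing duplicate maxima created by sensor noise.
#'
#' @param rec an average-referenced `eeg_recording` (>= 3 channels).
#' @param min_peak_sep_ms minimum distance between retained peaks (ms);
#'   0 keeps every strict local maximum.
#' @return a `gfp_series`: list with `values`, `peaks` (sample indices),
#'   `sfreq`.
#' @export
compute_gfp <- function(rec, min_peak_sep_ms = 10) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_channels(rec) < 3) stopf("GFP needs at least 3 channels")
  X <- sweep(rec$data, 2, colMeans(rec$data))
  g <- sqrt(colMeans(X^2))
  n <- length(g)
  peaks <- if (n >= 3) {
    which(g[2:(n - 1)] > g[1:(n - 2)] & g[2:(n - 1)] > g[3:n]) + 1L
  } else integer(0)
  if (min_peak_sep_ms > 0 && length(peaks) > 1) {
    sep <- min_peak_sep_ms / 1000 * rec$sfreq
    ord <- peaks[order(g[peaks], decreasing = TRUE)]
    kept <- integer(0)
    for (p in ord) if (!length(kept) || min(abs(kept - p)) >= sep)
      kept <- c(kept, p)
    peaks <- sort(kept)
  }
  structure(list(values = g, peaks = peaks, sfreq = rec$sfreq),
            class = "gfp_series")
}

# Single k-means run on zero-mean map columns X (C x N).
# Assignment: argmax_k (T_k . x)^2 (polarity ignored, ties to the lowest
# state); update: principal eigenvector of the assigned maps' scatter;
# empty clusters re-seeded from the worst-fit map.
ms_kmeans_once <- function(X, K, max_iter, tol) {
  C <- nrow(X); N <- ncol(X)
  norm2 <- colSums(X^2)
  denom <- sum(norm2)
  T <- X[, sample.int(N, K), drop = FALSE]
  T <- sweep(T, 2, pmax(sqrt(colSums(T^2)), 1e-300), "/")
  gev_prev <- -Inf
  converged <- FALSE
  lab <- integer(N)
  for (it in seq_len(max_iter)) {
    A2 <- crossprod(T, X)^2                       # K x N
    lab <- max.col(t(A2), ties.method = "first")
    fit <- A2[cbind(lab, seq_len(N))]
    for (k in seq_len(K)) {
      if (!any(lab == k)) {
        worst <- which.min(fit / pmax(norm2, .Machine$double.eps))
        lab[worst] <- k
        fit[worst] <- Inf
      }
    }
    for (k in seq_len(K)) {
      Xk <- X[, lab == k, drop = FALSE]
      v <- eigen(tcrossprod(Xk), symmetric = TRUE)$vectors[, 1]
      v <- v - mean(v)                            # stay in avg-ref subspace
      nv <- sqrt(sum(v^2))
      if (nv < 1e-12) v <- rep(1 / sqrt(C), C) - 1 / C  # degenerate guard
      v <- v / sqrt(sum(v^2))
      if (v[which.max(abs(v))] < 0) v <- -v       # deterministic sign
      T[, k] <- v
    }
    A2 <- crossprod(T, X)^2
    lab <- max.col(t(A2), ties.method = "first")
    gev <- sum(A2[cbind(lab, seq_len(N))]) / denom
    if (is.finite(gev_prev) &&
        abs(gev - gev_prev) < tol * max(gev, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    gev_prev <- gev
  }
  sigma2 <- sum(norm2 - A2[cbind(lab, seq_len(N))]) / (N * (C - 1))
  list(templates = T, labels = lab, gev = gev, sigma2 = sigma2,
       converged = converged, iterations = it)
}

#' Polarity-insensitive modified k-means clustering of topographies
#'
#' The microstate clustering of Pascual-Marqui and colleagues: maps are
#' assigned to the template maximising the squared (polarity-ignored)
#' projection, templates are re-estimated as the principal eigenvector
#' of the scatter of their assigned maps, and the whole procedure is
#' restarted from random initial maps, keeping the run with the highest
#' global explained variance.
#'
#' @param maps channels x maps numeric matrix of (zero-mean) topographies,
#'   typically GFP-peak maps.
#' @param k number of microstate classes (<= number of distinct maps).
#' @param n_restarts random restarts (default 50).
#' @param max_iter iteration cap per restart.
#' @param tol relative GEV change declaring convergence.
#' @param seed optional integer seed; fixing it makes the fit
#'   bit-reproducible.
#' @return a `microstate_model`: list with `k`, `templates` (channels x k,
#'   zero-mean unit-norm columns), `gev_total`, `gev_per_state`, `sigma2`,
#'   `cv`, `labels` (per input map), `n_restarts`, `converged`, `n_maps`.
#' @export
modified_kmeans <- function(maps, k, n_restarts = 50, max_iter = 300,
                            tol = 1e-7, seed = NULL) {
  X <- as.matrix(maps)
  C <- nrow(X); N <- ncol(X)
  if (N < k) stopf("need at least k = %d maps, got %d", k, N)
  X <- sweep(X, 2, colMeans(X))
  if (nrow(unique(t(X))) < k) stopf("fewer than k distinct maps")
  best <- NULL
  with_seed_if(seed, {
    for (r in seq_len(n_restarts)) {
      run <- ms_kmeans_once(X, k, max_iter, tol)
      if (is.null(best) || run$gev > best$gev) best <- run
    }
  })
  A2 <- crossprod(best$templates, X)^2
  idx <- cbind(best$labels, seq_len(N))
  denom <- sum(colSums(X^2))
  gev_state <- vapply(seq_len(k), function(s)
    sum(A2[idx][best$labels == s]) / denom, numeric(1))
  cv <- if (k < C - 1) best$sigma2 * ((C - 1) / (C - 1 - k))^2 else NA_real_
  structure(list(k = k, templates = best$templates,
                 gev_total = best$gev, gev_per_state = gev_state,
                 sigma2 = best$sigma2, cv = cv, labels = best$labels,
                 n_restarts = n_restarts, converged = best$converged,
                 n_maps = N),
            class = "microstate_model")
}

#' @export
print.microstate_model <- function(x, ...) {
  cat(sprintf("<microstate_model> k = %d on %d maps: GEV = %.3f, CV = %.4g%s\n",
              x$k, x$n_maps, x$gev_total, x$cv,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  invisible(x)
}

#' Global explained variance of a labelling
#'
#' GEV = sum_t (GFP_t * corr(x_t, T_label(t)))^2 / sum_t GFP_t^2, with
#' the spatial correlation taken polarity-free through its square.
#' Unassigned samples (NA labels) contribute zero to the numerator only.
#'
#' @param maps channels x samples matrix of (zero-mean) maps.
#' @param model a `microstate_model` (or channels x k template matrix).
#' @param labels integer labels (NA = unassigned), one per map.
#' @return list with `gev_total` and `gev_per_state`.
#' @export
compute_gev <- function(maps, model, labels) {
  T <- if (inherits(model, "microstate_model")) model$templates else as.matrix(model)
  X <- sweep(as.matrix(maps), 2, colMeans(as.matrix(maps)))
  if (length(labels) != ncol(X)) stopf("labels must align with the maps")
  denom <- sum(colSums(X^2))
  if (denom == 0) stopf("all-zero GFP: nothing to explain")
  k <- ncol(T)
  A2 <- crossprod(T, X)^2
  ok <- !is.na(labels)
  num_per_map <- numeric(ncol(X))
  num_per_map[ok] <- A2[cbind(labels[ok], which(ok))]
  gev_state <- vapply(seq_len(k), function(s)
    sum(num_per_map[ok & labels == s]) / denom, numeric(1))
  list(gev_total = sum(num_per_map) / denom, gev_per_state = gev_state)
}

#' Cross-validation criterion for microstate model selection
#'
#' CV = sigma2_hat * ((C - 1)/(C - 1 - K))^2, where sigma2_hat is the
#' mean residual map variance after removing each map's projection onto
#' its assigned template. Smaller is better; the correction factor
#' penalises the degrees of freedom spent on templates.
#'
#' @param model a `microstate_model`.
#' @param maps optional channels x maps matrix to recompute the residual
#'   variance on (defaults to the stored fit).
#' @param n_channels channel count C (needed only with `maps`).
#' @return the CV value (>= 0).
#' @export
cross_validation_criterion <- function(model, maps = NULL, n_channels = NULL) {
  k <- model$k
  if (is.null(maps)) {
    if (is.na(model$cv)) stopf("K >= C - 1: the CV correction factor is degenerate")
    return(model$cv)
  }
  X <- sweep(as.matrix(maps), 2, colMeans(as.matrix(maps)))
  C <- n_channels %||% nrow(X)
  if (k >= C - 1) stopf("K >= C - 1: the CV correction factor is degenerate")
  A2 <- crossprod(model$templates, X)^2
  lab <- max.col(t(A2), ties.method = "first")
  sigma2 <- sum(colSums(X^2) - A2[cbind(lab, seq_len(ncol(X)))]) /
    (ncol(X) * (C - 1))
  sigma2 * ((C - 1) / (C - 1 - k))^2
}

#' Select the number of microstate classes
#'
#' Default rule: minimise the cross-validation criterion over the fitted
#' models (conventionally fit over K = 2-8). `forced_k` mirrors the common
#' four-state reporting convention and returns that model regardless of
#' CV. The decision rule used is recorded in the returned model's
#' `selection` attribute.
#'
#' @param models list of `microstate_model`s fit on the same maps.
#' @param rule `"cv"` (argmin CV) or `"gev"` (largest GEV increase drop,
#'   i.e. elbow).
#' @param forced_k optional K to force.
#' @return the chosen `microstate_model`.
#' @export
select_k <- function(models, rule = c("cv", "gev"), forced_k = NULL) {
  if (!length(models)) stopf("empty model list")
  rule <- match.arg(rule)
  ks <- vapply(models, `[[`, numeric(1), "k")
  if (!is.null(forced_k)) {
    i <- match(forced_k, ks)
    if (is.na(i)) stopf("no fitted model with k = %d", forced_k)
    chosen <- models[[i]]
    attr(chosen, "selection") <- list(rule = "forced", k = forced_k)
    return(chosen)
  }
  if (rule == "cv") {
    cvs <- vapply(models, `[[`, numeric(1), "cv")
    i <- which.min(cvs)
  } else {
    gevs <- vapply(models, `[[`, numeric(1), "gev_total")
    gains <- diff(c(0, gevs))
    i <- if (length(gains) > 1) which.max(-diff(gains)) else 1L
  }
  chosen <- models[[i]]
  attr(chosen, "selection") <- list(rule = rule, k = ks[i])
  chosen
}

#' Fit microstate models over a range of K
#'
#' Convenience wrapper running [modified_kmeans()] for each K on the same
#' maps, with per-K seeds derived from `seed`.
#'
#' @inheritParams modified_kmeans
#' @param k_range integer vector of K values (conventional range 2:8).
#' @return list of `microstate_model`s, one per K.
#' @export
fit_microstates <- function(maps, k_range = 2:8, n_restarts = 50,
                            max_iter = 300, tol = 1e-7, seed = NULL) {
  seeds <- if (is.null(seed)) vector("list", length(k_range)) else
    as.list(seed + seq_along(k_range) - 1L)
  mapply(function(k, s) modified_kmeans(maps, k, n_restarts, max_iter, tol,
                                        seed = s),
         k_range, seeds, SIMPLIFY = FALSE)
}

#' Backfit microstate templates to a recording
#'
#' Peaks-interpolated mode (default): every GFP peak is labelled by the
#' template with the highest squared spatial correlation, and non-peak
#' samples inherit the label of the nearest peak in time, never crossing
#' a splice boundary; stretches with no peak stay unassigned. All-samples
#' mode labels every sample directly. Ties go to the lowest state index,
#' and polarity is ignored throughout.
#'
#' @param model a `microstate_model`.
#' @param rec an (average-referenced) `eeg_recording`.
#' @param gfp optional precomputed `gfp_series` for `rec`.
#' @param mode `"peaks"` or `"all"`.
#' @return an `ms_segmentation`: list with `labels` (integer or NA per
#'   sample), `k`, `sfreq`, `splice_boundaries`, `peaks`.
#' @export
backfit <- function(model, rec, gfp = NULL, mode = c("peaks", "all")) {
  mode <- match.arg(mode)
  if (nrow(model$templates) != n_channels(rec))
    stopf("model and recording disagree on channel count")
  X <- sweep(rec$data, 2, colMeans(rec$data))
  n <- ncol(X)
  A2 <- crossprod(model$templates, X)^2
  direct <- max.col(t(A2), ties.method = "first")
  bounds <- c(1L, rec$splice_boundaries, n + 1L)
  if (mode == "all") {
    labels <- direct
    peaks <- integer(0)
  } else {
    gfp <- gfp %||% compute_gfp(rec)
    peaks <- gfp$peaks
    if (!length(peaks)) stopf("no GFP peaks found; cannot backfit in peak mode")
    labels <- rep(NA_integer_, n)
    for (b in seq_len(length(bounds) - 1L)) {
      lo <- bounds[b]; hi <- bounds[b + 1L] - 1L
      pk <- peaks[peaks >= lo & peaks <= hi]
      if (!length(pk)) next
      idx <- lo:hi
      # nearest peak in time; equidistant samples go to the earlier peak
      mids <- pk[-length(pk)] + diff(pk) / 2
      nearest <- pk[1L + findInterval(idx - 0.25, mids)]
      labels[idx] <- direct[nearest]
    }
  }
  structure(list(labels = labels, k = model$k, sfreq = rec$sfreq,
                 splice_boundaries = rec$splice_boundaries, peaks = peaks),
            class = "ms_segmentation")
}

#' @export
print.ms_segmentation <- function(x, ...) {
  cat(sprintf("<ms_segmentation> %d samples @ %g Hz, k = %d, %.1f%% unassigned\n",
              length(x$labels), x$sfreq, x$k,
              100 * mean(is.na(x$labels))))
  invisible(x)
}

#' Absorb segments shorter than a minimum duration
#'
#' Segments shorter than `min_duration_ms` are relabelled into a
#' temporally adjacent segment: when `rec` and `model` are supplied the
#' neighbour whose template correlates better with the data at the
#' boundary wins, otherwise the longer neighbour absorbs. The default of
#' 0 disables smoothing (the literal reading of the analysis this
#' package follows, which applies none).
#'
#' @param seg an `ms_segmentation`.
#' @param min_duration_ms minimum segment duration (ms); 0 = identity.
#' @param rec,model optional recording and model for correlation-based
#'   absorption.
#' @return the smoothed `ms_segmentation` (total length unchanged).
#' @export
smooth_labels <- function(seg, min_duration_ms = 0, rec = NULL, model = NULL) {
  if (min_duration_ms <= 0) return(seg)
  min_len <- min_duration_ms / 1000 * seg$sfreq
  labels <- seg$labels
  n <- length(labels)
  bounds <- c(1L, seg$splice_boundaries, n + 1L)
  use_corr <- !is.null(rec) && !is.null(model)
  X <- if (use_corr) sweep(rec$data, 2, colMeans(rec$data)) else NULL
  runs <- segment_runs(labels, bounds)
  if (is.null(runs) || !nrow(runs)) return(seg)
  # doubly-linked run list; repeatedly absorb the shortest short segment
  st <- runs$state; len <- runs$length
  start <- runs$start; end <- runs$end; reg <- runs$region
  m <- length(st)
  prv <- c(0L, seq_len(m - 1L)); nxt <- c(seq_len(m)[-1L], 0L)
  neighbour <- function(i, side) {
    j <- if (side == "L") prv[i] else nxt[i]
    if (j == 0L || reg[j] != reg[i] || is.na(st[j])) 0L else j
  }
  repeat {
    cand <- which(!is.na(st) & len > 0 & len < min_len)
    cand <- cand[vapply(cand, function(i)
      neighbour(i, "L") > 0L || neighbour(i, "R") > 0L, logical(1))]
    if (!length(cand)) break
    for (i in cand[order(len[cand])]) {
      if (is.na(st[i]) || len[i] == 0 || len[i] >= min_len) next
      L <- neighbour(i, "L"); R <- neighbour(i, "R")
      if (L == 0L && R == 0L) next
      take <- if (L > 0L && R > 0L) {
        if (use_corr) {
          xb <- X[, start[i]]
          if (abs(spatial_correlation(xb, model$templates[, st[L]])) >=
              abs(spatial_correlation(xb, model$templates[, st[R]]))) L else R
        } else if (len[L] >= len[R]) L else R
      } else max(L, R)
      labels[start[i]:end[i]] <- st[take]
      # merge run i into `take`, then fuse equal-state neighbours
      if (take == L) end[L] <- end[i] else start[R] <- start[i]
      len[take] <- len[take] + len[i]
      len[i] <- 0L; st[i] <- NA_integer_
      if (prv[i] > 0L) nxt[prv[i]] <- nxt[i]
      if (nxt[i] > 0L) prv[nxt[i]] <- prv[i]
      oth <- neighbour(take, if (take == L) "R" else "L")
      if (oth > 0L && !is.na(st[oth]) && st[oth] == st[take]) {
        a <- min(take, oth); b <- max(take, oth)
        end[a] <- end[b]; len[a] <- len[a] + len[b]
        len[b] <- 0L; st[b] <- NA_integer_
        if (prv[b] > 0L) nxt[prv[b]] <- nxt[b]
        if (nxt[b] > 0L) prv[nxt[b]] <- prv[b]
      }
    }
  }
  seg$labels <- labels
  seg
}

# Run-length segments of a label vector, split at region bounds and NA.
segment_runs <- function(labels, bounds) {
  out <- list()
  for (b in seq_len(length(bounds) - 1L)) {
    lo <- bounds[b]; hi <- bounds[b + 1L] - 1L
    if (hi < lo) next
    r <- rle(labels[lo:hi])
    ends <- lo - 1L + cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    out[[b]] <- data.frame(state = r$values, start = starts, end = ends,
                           length = r$lengths, region = b)
  }
  do.call(rbind, out)
}

#' Microstate temporal parameters
#'
#' Per state: Duration is the mean segment length (ms), Occurrence the
#' number of segments per second of labelled time, Coverage the fraction
#' of labelled samples spent in the state. Segments touching a splice
#' boundary or the record edge are included by default; with
#' `include_edge_segments = FALSE` they still count toward Coverage and
#' Occurrence denominators but are excluded from the Duration mean (they
#' are truncated and would bias it down). By construction Coverage =
#' Occurrence x Duration (in seconds) when edge segments are included.
#'
#' @param seg an `ms_segmentation` with at least one labelled segment.
#' @param include_edge_segments include edge/splice-truncated segments in
#'   the duration mean (default TRUE).
#' @return data.frame with one row per state: `state`, `n_segments`,
#'   `duration_ms`, `occurrence_hz`, `coverage`, plus an `unassigned`
#'   attribute (fraction of unlabelled samples).
#' @export
compute_parameters <- function(seg, include_edge_segments = TRUE) {
  labels <- seg$labels
  n <- length(labels)
  bounds <- c(1L, seg$splice_boundaries, n + 1L)
  runs <- segment_runs(labels, bounds)
  runs <- runs[!is.na(runs$state), , drop = FALSE]
  if (!nrow(runs)) stopf("no labelled segments")
  labelled <- sum(runs$length)
  t_lab_s <- labelled / seg$sfreq
  edge <- runs$start %in% bounds[-length(bounds)] |
    runs$end %in% (bounds[-1] - 1L)
  states <- seq_len(seg$k)
  res <- do.call(rbind, lapply(states, function(s) {
    rs <- runs[runs$state == s, , drop = FALSE]
    dur_rows <- if (include_edge_segments) rs else rs[!edge[runs$state == s], , drop = FALSE]
    data.frame(state = s,
               n_segments = nrow(rs),
               duration_ms = if (nrow(dur_rows))
                 mean(dur_rows$length) / seg$sfreq * 1000 else NA_real_,
               occurrence_hz = nrow(rs) / t_lab_s,
               coverage = sum(rs$length) / labelled)
  }))
  attr(res, "unassigned") <- mean(is.na(labels))
  res
}

#' Tidy per-subject parameter table
#'
#' Reshapes [compute_parameters()] output into the tidy
#' (subject, state, metric, value) layout consumed by the group
#' statistics, with states given as names (letters once matched).
#'
#' @param params data.frame from [compute_parameters()].
#' @param subject subject identifier.
#' @param state_names optional character names per state index.
#' @return data.frame with columns subject, state, metric, value.
#' @export
parameters_tidy <- function(params, subject, state_names = NULL) {
  st <- if (is.null(state_names)) as.character(params$state)
  else state_names[params$state]
  data.frame(
    subject = subject,
    state = rep(st, 3),
    metric = rep(c("duration_ms", "occurrence_hz", "coverage"),
                 each = nrow(params)),
    value = c(params$duration_ms, params$occurrence_hz, params$coverage))
}

#' Match two template sets
#'
#' Finds the one-to-one assignment of states maximising the total
#' absolute spatial correlation (exact search over permutations; the
#' microstate K range keeps this tiny), reporting per-pair |corr| and the
#' relative polarity, so claims that two groups share or differ in a
#' topography are quantifiable.
#'
#' @param model_a,model_b `microstate_model`s (or channels x k template
#'   matrices) with equal K.
#' @return list with `permutation` (index into b for each state of a),
#'   `signs`, `correlations` (per matched pair), `mean_abs_corr`.
#' @export
match_templates <- function(model_a, model_b) {
  Ta <- if (inherits(model_a, "microstate_model")) model_a$templates else as.matrix(model_a)
  Tb <- if (inherits(model_b, "microstate_model")) model_b$templates else as.matrix(model_b)
  if (ncol(Ta) != ncol(Tb)) stopf("template sets must share K")
  k <- ncol(Ta)
  Ca <- sweep(Ta, 2, colMeans(Ta)); Ca <- sweep(Ca, 2, sqrt(colSums(Ca^2)), "/")
  Cb <- sweep(Tb, 2, colMeans(Tb)); Cb <- sweep(Cb, 2, sqrt(colSums(Cb^2)), "/")
  R <- crossprod(Ca, Cb)                 # k x k signed correlations
  perms <- all_permutations(k)
  scores <- vapply(perms, function(p) sum(abs(R[cbind(seq_len(k), p)])),
                   numeric(1))
  best <- perms[[which.max(scores)]]
  r <- R[cbind(seq_len(k), best)]
  list(permutation = best, signs = sign(r), correlations = abs(r),
       mean_abs_corr = mean(abs(r)))
}

#' Canonical four-microstate topographies
#'
#' The classical A-D maps used as a naming convention: A runs from the
#' left-posterior to the right-frontal quadrant, B from right-posterior
#' to left-frontal, C along the anterior-posterior axis, and D has a
#' fronto-central maximum. Built from the montage geometry as linear
#' potential gradients, zero-mean and unit-norm.
#'
#' @param montage an `eeg_montage`.
#' @return channels x 4 matrix with columns A, B, C, D.
#' @export
canonical_microstate_maps <- function(montage) {
  p <- montage$positions
  maps <- cbind(A = p[, "x"] - p[, "y"],
                B = p[, "x"] + p[, "y"],
                C = p[, "x"],
                D = p[, "z"])
  maps <- sweep(maps, 2, colMeans(maps))
  sweep(maps, 2, sqrt(colSums(maps^2)), "/")
}

#' Name fitted states by the canonical convention
#'
#' Matches a model's templates against [canonical_microstate_maps()] and
#' returns the letter of the best-matching canonical map per state (for
#' K = 4 a one-to-one assignment; other K fall back to greedy naming with
#' numeric suffixes for surplus states).
#'
#' @param model a `microstate_model`.
#' @param montage the montage the model lives on.
#' @return character vector of state names, one per state.
#' @export
name_states <- function(model, montage) {
  canon <- canonical_microstate_maps(montage)
  k <- model$k
  if (k == 4) {
    m <- match_templates(model, canon)
    return(colnames(canon)[m$permutation])
  }
  Ct <- sweep(model$templates, 2, colMeans(model$templates))
  Ct <- sweep(Ct, 2, sqrt(colSums(Ct^2)), "/")
  R <- abs(crossprod(Ct, canon))
  names_out <- character(k)
  used <- logical(4)
  for (i in order(apply(R, 1, max), decreasing = TRUE)) {
    j <- order(R[i, ], decreasing = TRUE)
    j <- j[!used[j]][1]
    if (is.na(j)) {
      names_out[i] <- paste0("S", i)
    } else {
      used[j] <- TRUE
      names_out[i] <- colnames(canon)[j]
    }
  }
  names_out
}
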