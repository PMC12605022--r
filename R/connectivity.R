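#' Extract the sensor data belonging to one microstate
#'
#' Peaks mode (default) collects the columns at GFP peaks labelled with
#' `state` -- the samples the connectivity stage reconstructs, following
#' the GFP-peak reading of microstate-conditioned analysis. All mode
#' collects every labelled sample. Column order preserves time.
#'
#' @param rec an `eeg_recording`.
#' @param seg an `ms_segmentation` for `rec`.
#' @param state state index.
#' @param mode `"peaks"` or `"all"`.
#' @param gfp optional precomputed `gfp_series` (recomputed otherwise in
#'   peaks mode; pass the one used for backfitting to stay consistent).
#' @param align_to optional `microstate_model` (or channels x k template
#'   matrix): each extracted column is polarity-normalised, i.e. flipped
#'   so its projection on the state's template is positive. Within a
#'   microstate the scalp maps alternate polarity with the oscillation
#'   phase; the clustering treats both polarities as the same state, and
#'   aligning them keeps the state-defining topography as a common
#'   baseline instead of a dominant sign-flipping signal in downstream
#'   source correlations. `NULL` (default) leaves the raw columns.
#' @param remove_span if `TRUE` (requires `align_to`), the span of all
#'   the model's templates is projected out of the extracted columns.
#'   The stereotyped microstate topographies behave as a global common
#'   mode in source space -- including smeared residues of neighbouring
#'   states introduced by zero-phase filtering -- and inflate every
#'   region pair's correlation uniformly; removing the fitted template
#'   subspace (analogous to removing an evoked component before
#'   functional connectivity) leaves the residual broadband activity
#'   whose inter-regional structure is of interest.
#' @return list with `data` (channels x m), `n` (= m), `indices`.
#' @export
extract_state_data <- function(rec, seg, state, mode = c("peaks", "all"),
                               gfp = NULL, align_to = NULL,
                               remove_span = FALSE) {
  mode <- match.arg(mode)
  if (remove_span && is.null(align_to))
    stopf("remove_span needs align_to templates")
  if (length(seg$labels) != n_samples(rec))
    stopf("segmentation does not match the recording")
  idx <- if (mode == "peaks") {
    pk <- if (length(seg$peaks)) seg$peaks else (gfp %||% compute_gfp(rec))$peaks
    pk[!is.na(seg$labels[pk]) & seg$labels[pk] == state]
  } else {
    which(!is.na(seg$labels) & seg$labels == state)
  }
  out <- rec$data[, idx, drop = FALSE]
  if (!is.null(align_to) && length(idx)) {
    T <- if (inherits(align_to, "microstate_model")) align_to$templates
    else as.matrix(align_to)
    proj <- drop(crossprod(T[, state], sweep(out, 2, colMeans(out))))
    flip <- ifelse(proj < 0, -1, 1)
    out <- sweep(out, 2, flip, "*")
    if (remove_span) {
      Q <- qr.Q(qr(T))
      out <- out - Q %*% crossprod(Q, out)
    }
  }
  list(data = out, n = length(idx), indices = idx)
}

#' Collapse source series to region series
#'
#' Region series are the mean of their member-source series after sign
#' alignment: each source is flipped to load positively on the region's
#' first principal direction (whose own sign is fixed by its largest
#' loading), so that sources carrying the same signal with opposite
#' leadfield polarity reinforce rather than cancel. Because the sign of
#' a minimum-norm source estimate is itself arbitrary, the region series
#' are then (by default) flipped to load positively on the dominant
#' common component across regions, which makes pooled Pearson
#' correlations comparable across subjects.
#'
#' @param source_ts sources x samples matrix.
#' @param parcellation a `parcellation` covering all sources.
#' @param global_sign also align region signs to the first principal
#'   direction across regions (default TRUE).
#' @return regions x samples matrix with region names as row names.
#' @export
parcellate <- function(source_ts, parcellation, global_sign = TRUE) {
  source_ts <- as.matrix(source_ts)
  S <- nrow(source_ts)
  if (length(parcellation$region_of_source) != S)
    stopf("parcellation does not cover all sources")
  R <- length(parcellation$region_names)
  out <- matrix(0, R, ncol(source_ts),
                dimnames = list(parcellation$region_names, NULL))
  for (r in seq_len(R)) {
    members <- which(parcellation$region_of_source == r)
    if (!length(members)) stopf("region %s is empty", parcellation$region_names[r])
    M <- source_ts[members, , drop = FALSE]
    if (length(members) == 1) { out[r, ] <- M; next }
    u <- eigen(tcrossprod(M), symmetric = TRUE)$vectors[, 1]
    if (u[which.max(abs(u))] < 0) u <- -u
    signs <- ifelse(sign(u) == 0, 1, sign(u))
    out[r, ] <- colMeans(M * signs)
  }
  if (global_sign && R > 1) {
    u <- eigen(tcrossprod(out), symmetric = TRUE)$vectors[, 1]
    if (u[which.max(abs(u))] < 0) u <- -u
    out <- out * ifelse(sign(u) == 0, 1, sign(u))
  }
  out
}

#' Per-microstate Pearson connectivity matrix
#'
#' Pairwise Pearson correlations between region series; symmetric with a
#' unit diagonal. Constant series yield NA rows/columns and are flagged,
#' never silently zeroed.
#'
#' @param region_ts regions x samples matrix (>= 3 samples).
#' @param state microstate label the matrix belongs to (metadata).
#' @return a `connectivity_matrix`: list with `values` (R x R), `state`,
#'   `n_samples`, `region_names`, `degenerate_regions`.
#' @export
pearson_connectivity <- function(region_ts, state = NA) {
  region_ts <- as.matrix(region_ts)
  if (ncol(region_ts) < 3) stopf("need at least 3 samples for a correlation")
  sds <- apply(region_ts, 1, stats::sd)
  degenerate <- rownames(region_ts)[sds == 0] %||% character(0)
  vals <- suppressWarnings(stats::cor(t(region_ts)))
  diag(vals) <- 1
  structure(list(values = vals, state = state, n_samples = ncol(region_ts),
                 region_names = rownames(region_ts),
                 degenerate_regions = degenerate),
            class = "connectivity_matrix")
}

#' Threshold a connectivity matrix into an edge list
#'
#' Upper-triangle pairs with |r| at or above the threshold, sorted by
#' |r| descending -- the circos-compatible exchange format.
#'
#' @param cm a `connectivity_matrix`.
#' @param threshold absolute-correlation threshold in [0, 1].
#' @return data.frame with columns `region_a`, `region_b`, `r`.
#' @export
threshold_edges <- function(cm, threshold = 0) {
  if (threshold < 0 || threshold > 1) stopf("threshold must be in [0, 1]")
  V <- cm$values
  ut <- which(upper.tri(V), arr.ind = TRUE)
  rn <- cm$region_names %||% as.character(seq_len(nrow(V)))
  df <- data.frame(region_a = rn[ut[, 1]], region_b = rn[ut[, 2]],
                   r = V[ut])
  df <- df[!is.na(df$r) & abs(df$r) >= threshold, , drop = FALSE]
  df[order(abs(df$r), decreasing = TRUE), , drop = FALSE]
}

#' Pool connectivity across subjects
#'
#' Pools the upper-triangle values of the subjects' matrices for one
#' state and reports mean, SD and n (the pooled edge count). Raw r is
#' pooled by default, mirroring mean-and-SD connectivity tables; Fisher-z
#' mode averages on the z scale and back-transforms the mean.
#'
#' @param cms list of `connectivity_matrix` objects sharing a
#'   parcellation.
#' @param fisher_z average on the Fisher-z scale.
#' @return list with `state`, `mean`, `sd`, `n`, `values`.
#' @export
summarize_connectivity <- function(cms, fisher_z = FALSE) {
  if (!length(cms)) stopf("no matrices to summarise")
  rn <- cms[[1]]$region_names
  for (cm in cms)
    if (!identical(cm$region_names, rn)) stopf("mixed parcellations")
  vals <- unlist(lapply(cms, function(cm) cm$values[upper.tri(cm$values)]))
  vals <- vals[!is.na(vals)]
  if (fisher_z) {
    z <- atanh(pmin(pmax(vals, -1 + 1e-12), 1 - 1e-12))
    list(state = cms[[1]]$state, mean = tanh(mean(z)),
         sd = stats::sd(vals), n = length(vals), values = vals)
  } else {
    list(state = cms[[1]]$state, mean = mean(vals), sd = stats::sd(vals),
         n = length(vals), values = vals)
  }
}
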