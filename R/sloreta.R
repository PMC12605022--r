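#' Build an sLORETA inverse operator
#'
#' With H the average-reference projector and G = H * gain, the
#' minimum-norm kernel is W = G' (G G' + alpha H)^+ (pseudo-inverse,
#' since the average-referenced system is rank deficient by one).
#' sLORETA standardises source j's estimate by the square root of the
#' j-th diagonal of the resolution-like matrix W G; for noiseless
#' single-source data and alpha -> 0 the standardised power then peaks
#' exactly at the true source (zero localization error).
#'
#' @param leadfield a `leadfield` (gain C x S, columns finite).
#' @param alpha Tikhonov regularisation (>= 0); defaults to the value
#'   stored in the leadfield.
#' @return an `sloreta_inverse`: list with `kernel` (S x C, includes the
#'   average-reference projection), `std` (per-source standardisation),
#'   `alpha`, `n_channels`, `n_sources`.
#' @export
build_sloreta_inverse <- function(leadfield, alpha = NULL) {
  gain <- leadfield$gain
  if (!all(is.finite(gain))) stopf("leadfield gain must be finite")
  alpha <- alpha %||% leadfield$alpha %||% 0
  if (alpha < 0) stopf("alpha must be >= 0")
  C <- nrow(gain); S <- ncol(gain)
  H <- diag(C) - matrix(1 / C, C, C)
  G <- H %*% gain
  M <- tcrossprod(G) + alpha * H
  W <- crossprod(G, pinv_sym(M)) %*% H     # S x C, applies avg ref itself
  resol <- rowSums(W * t(G))               # diag(W %*% G)
  bad <- resol <= .Machine$double.eps * max(resol, 1)
  if (any(bad))
    warning(sprintf("%d source(s) with vanishing resolution; their estimates are zeroed",
                    sum(bad)))
  std <- ifelse(bad, 0, 1 / sqrt(pmax(resol, .Machine$double.xmin)))
  structure(list(kernel = W, std = std, alpha = alpha,
                 n_channels = C, n_sources = S),
            class = "sloreta_inverse")
}

#' Apply an inverse operator to sensor data
#'
#' Linear per-sample application of the standardised kernel; linear in
#' the data by construction.
#'
#' @param inverse an `sloreta_inverse`.
#' @param data channels x samples matrix (or an `eeg_recording`).
#' @return sources x samples matrix of standardised source estimates.
#' @export
apply_inverse <- function(inverse, data) {
  if (inherits(data, "eeg_recording")) data <- data$data
  data <- as.matrix(data)
  if (nrow(data) != inverse$n_channels)
    stopf("data has %d channels, inverse expects %d",
          nrow(data), inverse$n_channels)
  inverse$std * (inverse$kernel %*% data)
}
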