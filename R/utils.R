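`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Round half away from zero
#'
#' Plain "half-up" decimal rounding (0.5 always rounds away from zero),
#' matching how clinical tables print percentages, as opposed to the
#' IEC 60559 banker's rounding of [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5 + 1e-12) / p
}

# Moore-Penrose pseudo-inverse of a symmetric matrix via eigendecomposition.
pinv_sym <- function(M, tol = NULL) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  tol <- tol %||% (max(abs(e$values), 0) * nrow(M) * .Machine$double.eps)
  keep <- abs(e$values) > tol
  if (!any(keep)) return(matrix(0, nrow(M), ncol(M)))
  V <- e$vectors[, keep, drop = FALSE]
  V %*% (t(V) / e$values[keep])
}

# All permutations of 1..n as a list (n <= 9; used for template matching).
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- all_permutations(n - 1L)
    for (p in rest) out[[length(out) + 1L]] <- c(i, setdiff(seq_len(n), i)[p])
  }
  out
}

# Spatial (Pearson) correlation between topographic maps, i.e. across
# channels with centring; maps may be vectors or columns of matrices.
spatial_correlation <- function(a, b) {
  a <- a - mean(a)
  b <- b - mean(b)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}

# Run `code` under `seed` if non-NULL without disturbing the caller's RNG.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}
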