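#' Mann-Whitney U test with asymptotic Z
#'
#' U from rank sums; Z from the normal approximation with tie-corrected
#' variance and, by default, no continuity correction -- the asymptotic
#' convention of the major commercial statistics packages, whose printed
#' Z values this mirrors. An exact two-sided p by complete enumeration of
#' rank splits is available for small samples and serves as the test
#' oracle for the approximation.
#'
#' @param x,y numeric samples (non-empty).
#' @param continuity apply the 0.5 continuity correction.
#' @param exact also compute the exact enumeration p (feasible roughly
#'   for min(n) <= 8 at these group sizes).
#' @return list with `u`, `z`, `p` (asymptotic two-sided), `p_exact`
#'   (NULL unless requested), `n` (per group), `degenerate` (TRUE when
#'   all values coincide; then Z = 0, p = 1).
#' @export
mann_whitney <- function(x, y, continuity = FALSE, exact = FALSE) {
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  degenerate <- v <= 0
  z <- if (degenerate) 0 else {
    d <- U - mu
    if (continuity) d <- sign(d) * max(0, abs(d) - 0.5)
    d / sqrt(v)
  }
  p <- if (degenerate) 1 else min(1, 2 * stats::pnorm(-abs(z)))
  p_exact <- NULL
  if (exact) {
    if (degenerate) {
      p_exact <- 1
    } else {
      if (choose(N, n1) > 2e6)
        stopf("exact enumeration infeasible for n = (%d, %d); use the asymptotic p",
              n1, n2)
      splits <- utils::combn(N, n1)
      Ws <- colSums(matrix(r[splits], nrow = n1))
      Us <- Ws - n1 * (n1 + 1) / 2
      p_exact <- min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
    }
  }
  list(u = U, z = z, p = p, p_exact = p_exact, n = c(n1, n2),
       degenerate = degenerate)
}

#' Two-sample Z test on raw values or printed summaries
#'
#' Z = (mean_x - mean_y) / sqrt(sd_x^2/n_x + sd_y^2/n_y), with the
#' two-sided p from the standard normal. Accepts raw numeric vectors or
#' `list(mean =, sd =, n =)` summaries, so comparisons can be run
#' directly from published mean-and-SD tables.
#'
#' @param x,y numeric vectors or summary lists.
#' @return list with `z`, `p`, `mean` (per group), `sd`, `n`,
#'   `degenerate` (both SDs zero with equal means), `infinite_z` (both
#'   SDs zero with unequal means).
#' @export
two_sample_z <- function(x, y) {
  s <- function(v) {
    if (is.numeric(v)) {
      if (length(v) < 2) stopf("need n >= 2 per group")
      list(mean = mean(v), sd = stats::sd(v), n = length(v))
    } else {
      if (!all(c("mean", "sd", "n") %in% names(v)))
        stopf("summary input needs mean, sd and n")
      if (v$n < 2) stopf("need n >= 2 per group")
      if (v$sd < 0) stopf("sd must be >= 0")
      v
    }
  }
  a <- s(x); b <- s(y)
  se <- sqrt(a$sd^2 / a$n + b$sd^2 / b$n)
  diff <- a$mean - b$mean
  if (se == 0) {
    if (diff == 0)
      return(list(z = 0, p = 1, mean = c(a$mean, b$mean), sd = c(a$sd, b$sd),
                  n = c(a$n, b$n), degenerate = TRUE, infinite_z = FALSE))
    return(list(z = sign(diff) * Inf, p = 0, mean = c(a$mean, b$mean),
                sd = c(a$sd, b$sd), n = c(a$n, b$n), degenerate = FALSE,
                infinite_z = TRUE))
  }
  z <- diff / se
  list(z = z, p = min(1, 2 * stats::pnorm(-abs(z))),
       mean = c(a$mean, b$mean), sd = c(a$sd, b$sd), n = c(a$n, b$n),
       degenerate = FALSE, infinite_z = FALSE)
}

#' Compare microstate parameter tables between groups
#'
#' One Mann-Whitney test per (state x metric) cell across Duration,
#' Occurrence and Coverage, on tidy (subject, state, metric, value)
#' tables whose state labels have already been matched across groups.
#' No multiple-testing correction is applied by default, mirroring the
#' single-test-per-cell reporting style of the clinical literature this
#' package targets; `correction = "holm"` is available and documented as
#' a deviation from that style.
#'
#' @param params_a,params_b tidy parameter tables (data.frames with
#'   columns subject, state, metric, value).
#' @param correction `"none"` (default) or `"holm"`.
#' @return data.frame with one row per state x metric: group means and
#'   SDs, `z`, `p` (and `p_adj` under Holm).
#' @export
compare_parameter_tables <- function(params_a, params_b,
                                     correction = c("none", "holm")) {
  correction <- match.arg(correction)
  need <- c("subject", "state", "metric", "value")
  if (!all(need %in% names(params_a)) || !all(need %in% names(params_b)))
    stopf("parameter tables must have columns %s", paste(need, collapse = ", "))
  states <- sort(unique(params_a$state))
  if (!setequal(states, unique(params_b$state)))
    stopf("state labels do not match between groups (run match_templates / name_states first)")
  metrics <- intersect(c("duration_ms", "occurrence_hz", "coverage"),
                       unique(params_a$metric))
  rows <- list()
  for (st in states) for (me in metrics) {
    va <- params_a$value[params_a$state == st & params_a$metric == me]
    vb <- params_b$value[params_b$state == st & params_b$metric == me]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    mw <- mann_whitney(va, vb)
    rows[[length(rows) + 1L]] <- data.frame(
      state = st, metric = me,
      mean_a = mean(va), sd_a = stats::sd(va),
      mean_b = mean(vb), sd_b = stats::sd(vb),
      n_a = length(va), n_b = length(vb),
      z = mw$z, p = mw$p)
  }
  out <- do.call(rbind, rows)
  if (correction == "holm") out$p_adj <- stats::p.adjust(out$p, "holm")
  out
}

#' Compare pooled connectivity between groups
#'
#' A two-sample Z test per microstate on pooled edge summaries (sign
#' convention: first-group mean minus second-group mean). The pooled n
#' must be explicit in the summaries. Treating pooled edges as
#' independent observations overstates the effective n -- edges within a
#' subject share sources -- which is flagged in the output so reports
#' carry the caveat.
#'
#' @param pooled_a,pooled_b lists of per-state summaries as produced by
#'   [summarize_connectivity()] (each with `state`, `mean`, `sd`, `n`).
#' @return data.frame with one row per state: group means/SDs/n, `z`,
#'   `p`, and an `independence_caveat` attribute.
#' @export
compare_connectivity_tables <- function(pooled_a, pooled_b) {
  if (length(pooled_a) != length(pooled_b)) stopf("state sets differ")
  rows <- lapply(seq_along(pooled_a), function(i) {
    a <- pooled_a[[i]]; b <- pooled_b[[i]]
    if (is.null(a$n) || is.null(b$n)) stopf("pooled summaries must carry n")
    zt <- two_sample_z(list(mean = a$mean, sd = a$sd, n = a$n),
                       list(mean = b$mean, sd = b$sd, n = b$n))
    data.frame(state = a$state, mean_a = a$mean, sd_a = a$sd, n_a = a$n,
               mean_b = b$mean, sd_b = b$sd, n_b = b$n,
               z = zt$z, p = zt$p)
  })
  out <- do.call(rbind, rows)
  attr(out, "independence_caveat") <-
    "pooled edges are treated as independent observations; edges within a subject are not"
  out
}

#' Descriptive cohort summary
#'
#' Means and SDs for numeric attributes; counts and percentages for
#' categorical attributes, with half-up rounding to one decimal and an
#' integer display column for tables that print whole percentages.
#'
#' @param records data.frame of subject attributes (one row per subject).
#' @return list with `numeric` (variable, mean, sd, n) and `categorical`
#'   (variable, level, n, percent, percent_integer) data.frames.
#' @export
cohort_summary <- function(records) {
  if (!nrow(records)) stopf("empty attribute table")
  num <- names(records)[vapply(records, is.numeric, logical(1))]
  cat_ <- setdiff(names(records), num)
  numeric_df <- do.call(rbind, lapply(num, function(v) {
    x <- records[[v]][!is.na(records[[v]])]
    data.frame(variable = v, mean = mean(x), sd = stats::sd(x), n = length(x))
  }))
  categorical_df <- do.call(rbind, lapply(cat_, function(v) {
    x <- records[[v]][!is.na(records[[v]])]
    tab <- table(x)
    data.frame(variable = v, level = names(tab), n = as.integer(tab),
               percent = round_half_up(100 * as.integer(tab) / length(x), 1),
               percent_integer = round_half_up(100 * as.integer(tab) / length(x), 0))
  }))
  list(numeric = numeric_df, categorical = categorical_df)
}
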