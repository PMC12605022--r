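test_that("GFP is the population spatial SD with strict local maxima", {
  maps <- cbind(c(1, 1, -1, -1), 2 * c(1, 1, -1, -1), c(3, 3, 3, 3))
  r <- rec_from_matrix(maps)
  g <- compute_gfp(r, min_peak_sep_ms = 0)
  expect_equal(g$values[1], 1)          # zero-mean unit-SD map
  expect_equal(g$values[2], 2)          # homogeneity
  expect_equal(g$values[3], 0)          # constant map after average reference
  expect_equal(g$peaks, 2L)             # strict interior maximum

  expect_error(compute_gfp(rec_from_matrix(matrix(1, 2, 5))), "3 channels")

  # minimum separation keeps the locally largest peak
  v <- c(0, 1, 0, 0.9, 0, 5, 0)
  X <- rbind(v, -v, v, -v)
  g2 <- compute_gfp(rec_from_matrix(X, sfreq = 100), min_peak_sep_ms = 30)
  expect_equal(g2$peaks, c(2L, 6L))
})

test_that("modified k-means recovers planted structure and ignores polarity", {
  T2 <- generate_templates(2, montage4(), max_abs_corr = 0, seed = 1)
  maps <- T2[, rep(c(1, 2), 30)] * rep(runif(60, 0.5, 2), each = 4)
  mod <- modified_kmeans(maps, 2, n_restarts = 5, seed = 2)
  m <- match_templates(mod, T2)
  expect_equal(unname(m$correlations), c(1, 1), tolerance = 1e-9)
  expect_equal(mod$gev_total, 1, tolerance = 1e-9)

  # negating every second map changes nothing
  flipped <- sweep(maps, 2, rep(c(1, -1), 30), "*")
  mod2 <- modified_kmeans(flipped, 2, n_restarts = 5, seed = 2)
  expect_equal(mod2$templates, mod$templates, tolerance = 1e-9)
  expect_equal(mod2$labels, mod$labels)

  # determinism under a fixed seed
  mod3 <- modified_kmeans(maps, 2, n_restarts = 5, seed = 2)
  expect_identical(mod$templates, mod3$templates)

  expect_error(modified_kmeans(maps, 70), "at least k")
})

test_that("best-of-restarts GEV equals the exhaustive-assignment optimum", {
  # 8 maps x 3 channels, K = 2: enumerate all 2^8 assignments with the
  # same eigenvector template update and compare optima
  exhaustive_gev <- function(X) {
    denom <- sum(X^2)
    best <- 0
    for (mask in 0:255) {
      asg <- as.integer(intToBits(mask))[1:8] + 1L
      if (length(unique(asg)) < 2) next
      gev <- 0
      for (k in 1:2)
        gev <- gev + eigen(tcrossprod(X[, asg == k, drop = FALSE]),
                           symmetric = TRUE)$values[1]
      best <- max(best, gev / denom)
    }
    best
  }
  for (s in 1:5) {
    set.seed(800 + s)
    X <- matrix(rnorm(24), 3)
    X <- sweep(X, 2, colMeans(X))
    mod <- modified_kmeans(X, 2, n_restarts = 50, seed = s)
    expect_equal(mod$gev_total, exhaustive_gev(X), tolerance = 1e-9)
  }
})

test_that("GEV follows its definition on constructed labellings", {
  T2 <- generate_templates(2, montage4(), max_abs_corr = 0, seed = 3)
  # data exactly a scaled template
  maps <- T2[, c(1, 1, 1)] * rep(c(1, 2, 3), each = 4)
  expect_equal(compute_gev(maps, T2, c(1, 1, 1))$gev_total, 1, tolerance = 1e-12)
  # data orthogonal to its assigned template
  expect_equal(compute_gev(maps, T2, c(2, 2, 2))$gev_total, 0, tolerance = 1e-12)
  # half fits perfectly, half orthogonally, equal GFP
  half <- cbind(T2[, 1], T2[, 1])
  g <- compute_gev(half, T2, c(1, 2))
  expect_equal(g$gev_total, 0.5, tolerance = 1e-12)
  expect_equal(g$gev_per_state, c(0.5, 0), tolerance = 1e-12)
  # per-state contributions sum to the total; NA contributes nothing
  g2 <- compute_gev(maps, T2, c(1, NA, 2))
  expect_equal(sum(g2$gev_per_state), g2$gev_total, tolerance = 1e-12)
})

test_that("the CV criterion applies the stated correction factor", {
  mod <- list(k = 4, sigma2 = 1, cv = 1 * ((20 - 1) / (20 - 1 - 4))^2)
  class(mod) <- "microstate_model"
  expect_equal(cross_validation_criterion(mod), (19 / 15)^2)
  expect_equal((19 / 15)^2, 1.6044, tolerance = 1e-4)

  # perfect fit has CV = 0
  T2 <- generate_templates(2, montage4(), max_abs_corr = 0, seed = 1)
  maps <- T2[, rep(1:2, 10)]
  m2 <- modified_kmeans(maps, 2, n_restarts = 5, seed = 1)
  expect_equal(m2$cv, 0, tolerance = 1e-12)

  # sigma2 never increases with K (best-of-restarts)
  set.seed(31)
  X <- matrix(rnorm(19 * 80), 19); X <- sweep(X, 2, colMeans(X))
  s2 <- vapply(2:6, function(k)
    modified_kmeans(X, k, n_restarts = 10, seed = k)$sigma2, numeric(1))
  expect_true(all(diff(s2) <= 1e-10))

  mbad <- list(k = 3, sigma2 = 1, cv = NA_real_)
  class(mbad) <- "microstate_model"
  expect_error(cross_validation_criterion(mbad), "degenerate")
})

test_that("K selection minimises CV unless forced", {
  mk <- function(k, cv) structure(list(k = k, cv = cv, gev_total = 0.5),
                                  class = "microstate_model")
  models <- Map(mk, 2:8, c(5, 3, 2, 2.5, 2.6, 2.7, 2.8))
  expect_equal(select_k(models)$k, 4)
  expect_equal(attr(select_k(models), "selection")$rule, "cv")
  expect_equal(select_k(models, forced_k = 4)$k, 4)
  expect_equal(select_k(models, forced_k = 6)$k, 6)
  expect_error(select_k(list()), "empty")
  expect_error(select_k(models, forced_k = 9), "no fitted model")
})

test_that("backfitting labels by polarity-free correlation and interpolates peaks", {
  T2 <- generate_templates(2, montage4(), max_abs_corr = 0, seed = 5)
  mod <- structure(list(k = 2, templates = T2), class = "microstate_model")
  # data = one template scaled everywhere -> all samples labelled to it
  a <- abs(sin(2 * pi * 7 * (0:99) / 100)) + 0.1
  r <- eeg_recording(T2[, 2] %o% a, 100, montage4())
  seg <- backfit(mod, r, mode = "all")
  expect_true(all(seg$labels == 2L))
  # polarity-insensitive
  rneg <- eeg_recording(-r$data, 100, montage4())
  expect_equal(backfit(mod, rneg, mode = "all")$labels, seg$labels)
  # peaks mode on a noiseless planted sequence is exact at peaks
  subj <- quick_subject(seed = 30, snr = Inf, n_samples = 2500)
  mfit <- structure(list(k = 4, templates = subj$templates),
                    class = "microstate_model")
  segp <- backfit(mfit, subj$clean, subj$gfp)
  pk <- subj$gfp$peaks
  expect_equal(mean(segp$labels[pk] == subj$labels[pk]), 1)
  # every sample inside a splice-free record gets some label
  expect_false(anyNA(segp$labels))
})

test_that("splice boundaries confine peak-label interpolation", {
  T2 <- generate_templates(2, montage4(), max_abs_corr = 0, seed = 5)
  mod <- structure(list(k = 2, templates = T2), class = "microstate_model")
  a <- c(0.2, 1, 0.2, 0.2, 1, 0.2)
  X <- cbind(T2[, 1] %o% a[1:3], T2[, 2] %o% a[4:6])
  r <- eeg_recording(X, 100, montage4(), splice_boundaries = 4L)
  seg <- backfit(mod, r)
  expect_equal(seg$labels, c(1L, 1L, 1L, 2L, 2L, 2L))
  # a region with no peak stays unassigned
  r2 <- eeg_recording(cbind(X, T2[, 1] %o% c(0.5)), 100, montage4(),
                      splice_boundaries = c(4L, 7L))
  expect_true(is.na(backfit(mod, r2)$labels[7]))
})

test_that("label smoothing absorbs sub-minimum segments and conserves length", {
  labels <- c(1L, 1L, 1L, 2L, 1L, 1L, 1L)
  seg <- structure(list(labels = labels, k = 2, sfreq = 1000,
                        splice_boundaries = integer(), peaks = integer()),
                   class = "ms_segmentation")
  expect_identical(smooth_labels(seg, 0), seg)
  out <- smooth_labels(seg, 2)  # 2 ms = 2 samples at 1 kHz
  expect_equal(out$labels, rep(1L, 7))
  expect_length(out$labels, length(labels))
})

test_that("temporal parameters follow their definitions and identities", {
  labels <- c(rep(1L, 5), rep(2L, 5))
  seg <- structure(list(labels = labels, k = 2, sfreq = 100,
                        splice_boundaries = integer(), peaks = integer()),
                   class = "ms_segmentation")
  p <- compute_parameters(seg)
  expect_equal(p$duration_ms, c(50, 50))
  expect_equal(p$occurrence_hz, c(10, 10))
  expect_equal(p$coverage, c(0.5, 0.5))

  # single-state record
  seg1 <- structure(list(labels = rep(1L, 200), k = 1, sfreq = 100,
                         splice_boundaries = integer(), peaks = integer()),
                    class = "ms_segmentation")
  p1 <- compute_parameters(seg1)
  expect_equal(p1$coverage, 1)
  expect_equal(p1$occurrence_hz, 1 / 2)

  # coverage = occurrence x duration(s) exactly, and coverages sum to 1
  set.seed(77)
  lab <- generate_label_sequence(3, 5000, 250, c(80, 100, 120), seed = 8)
  seg3 <- structure(list(labels = lab, k = 3, sfreq = 250,
                         splice_boundaries = integer(), peaks = integer()),
                    class = "ms_segmentation")
  p3 <- compute_parameters(seg3)
  expect_equal(sum(p3$coverage) + attr(p3, "unassigned"), 1, tolerance = 1e-12)
  expect_equal(p3$occurrence_hz * p3$duration_ms / 1000, p3$coverage,
               tolerance = 0.02)
})

test_that("template matching recovers shuffles and quantifies dissimilarity", {
  m <- montage19()
  T4 <- generate_templates(4, m, 0.5, seed = 11)
  self <- match_templates(T4, T4)
  expect_equal(self$permutation, 1:4)
  expect_equal(unname(self$correlations), rep(1, 4), tolerance = 1e-12)

  perm <- c(3, 1, 4, 2)
  shuf <- T4[, perm] * rep(c(-1, 1, -1, 1), each = 19)
  m2 <- match_templates(T4, shuf)
  expect_equal(order(perm), m2$permutation)
  expect_equal(unname(m2$correlations), rep(1, 4), tolerance = 1e-12)

  # unrelated orthonormal sets correlate weakly
  set.seed(12)
  vals <- replicate(20, {
    A <- generate_templates(4, m, max_abs_corr = 0)
    B <- generate_templates(4, m, max_abs_corr = 0)
    match_templates(A, B)$mean_abs_corr
  })
  expect_lt(mean(vals), 0.6)

  expect_error(match_templates(T4, T4[, 1:3]), "share K")
})

test_that("canonical naming assigns each letter once for K = 4", {
  m <- montage19()
  canon <- canonical_microstate_maps(m)
  expect_equal(colnames(canon), c("A", "B", "C", "D"))
  expect_equal(colMeans(canon), c(A = 0, B = 0, C = 0, D = 0),
               tolerance = 1e-12)
  mod <- structure(list(k = 4, templates = canon[, c(3, 1, 4, 2)]),
                   class = "microstate_model")
  expect_equal(name_states(mod, m), c("C", "A", "D", "B"))
})
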