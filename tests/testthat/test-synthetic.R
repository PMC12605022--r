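test_that("generated templates are zero-mean, unit-norm and dissimilarity-bounded", {
  m <- montage19()

  T0 <- generate_templates(2, montage4(), max_abs_corr = 0, seed = 1)
  expect_equal(colMeans(T0), c(S1 = 0, S2 = 0), tolerance = 1e-12)
  expect_equal(colSums(T0^2), c(S1 = 1, S2 = 1), tolerance = 1e-12)
  expect_lt(abs(sum(T0[, 1] * T0[, 2])), 1e-12)  # exactly orthogonal

  T1 <- generate_templates(4, m, max_abs_corr = 0.5, seed = 1)
  T2 <- generate_templates(4, m, max_abs_corr = 0.5, seed = 1)
  expect_identical(T1, T2)
  G <- crossprod(T1)
  expect_true(all(abs(G[upper.tri(G)]) <= 0.5))

  expect_error(generate_templates(19, m), "smaller")
  expect_error(generate_templates(4, m, max_abs_corr = 0.001, max_tries = 3),
               "could not draw")
})

test_that("label sequences are piecewise constant with the requested statistics", {
  expect_identical(generate_label_sequence(2, 0, 250), integer(0))

  lab1 <- generate_label_sequence(1, 100, 100, 50, seed = 1)
  expect_equal(lab1, rep(1L, 100))

  # strict alternation under an off-diagonal permutation matrix
  tm <- rbind(c(0, 1), c(1, 0))
  lab <- generate_label_sequence(2, 5000, 250, 60, tm, seed = 3)
  r <- rle(lab)
  expect_true(all(diff(r$values) != 0))
  expect_true(all(abs(diff(r$values)) == 1))

  # empirical mean segment length within 5% of 100 ms at large n
  lab <- generate_label_sequence(2, 250000, 250, 100, seed = 7)
  r <- rle(lab)
  expect_gt(length(r$lengths), 2000)
  expect_equal(mean(r$lengths) / 250 * 1000, 100, tolerance = 0.05)
  expect_true(all(r$lengths >= 2))

  expect_error(generate_label_sequence(2, 100, 250, 4), "at least 2 samples")
})

test_that("synthetic EEG matches its ground truth and SNR definition", {
  m <- montage19()
  T <- generate_templates(4, m, 0.5, seed = 1)
  lab <- generate_label_sequence(4, 2500, 250, 100, seed = 2)

  noiseless <- generate_eeg(T, lab, 250, m, snr = Inf, seed = 3)
  X <- noiseless$recording$data
  # average reference holds exactly at every sample
  expect_lt(max(abs(colMeans(X))), 1e-12)
  # where the carrier is non-zero the map is exactly the template (up to sign)
  a <- sin(2 * pi * 10 * (seq_len(2500) - 1) / 250)
  live <- which(abs(a) > 1e-3)
  cors <- vapply(live[seq(1, length(live), by = 25)], function(t)
    abs(spatial_correlation(X[, t], T[, lab[t]])), numeric(1))
  expect_true(all(cors > 1 - 1e-9))

  # seeded reruns are bit-identical
  again <- generate_eeg(T, lab, 250, m, snr = Inf, seed = 3)
  expect_identical(noiseless$recording$data, again$recording$data)

  # realised SNR matches the requested amplitude ratio
  noisy <- generate_eeg(T, lab, 250, m, snr = 4, seed = 3)
  noise <- noisy$recording$data - X
  expect_equal(sqrt(mean(X^2)) / sqrt(mean(noise^2)), 4, tolerance = 0.05)

  expect_error(generate_eeg(T, lab, 250, m, snr = 0), "positive")
})

test_that("spatial_correlation is a proper centred correlation", {
  x <- c(1, 2, 3, 4)
  expect_equal(spatial_correlation(x, 2 * x + 5), 1)
  expect_equal(spatial_correlation(x, -x), -1)
  expect_equal(spatial_correlation(c(1, -1, 1, -1), c(1, 1, -1, -1)), 0)
})

test_that("toy forward model partitions sources and has full avg-ref rank", {
  m <- montage19()
  fwd <- generate_forward_model(64, m, n_regions = 6)
  lf <- fwd$leadfield; pc <- fwd$parcellation

  expect_equal(dim(lf$gain), c(19, 64))
  expect_equal(colSums(lf$gain^2), rep(1, 64), tolerance = 1e-12)
  # every source in exactly one region; sizes sum to n_sources
  expect_true(all(pc$region_of_source %in% seq_along(pc$region_names)))
  expect_equal(sum(table(pc$region_of_source)), 64)
  expect_equal(length(unique(pc$region_of_source)), 6)
  # deterministic geometry
  fwd2 <- generate_forward_model(64, m, n_regions = 6)
  expect_identical(fwd$leadfield$gain, fwd2$leadfield$gain)
  # rank C-1 after average-reference projection
  H <- diag(19) - matrix(1 / 19, 19, 19)
  expect_equal(qr(H %*% lf$gain)$rank, 18)

  idf <- generate_forward_model(19, m, identity = TRUE)
  expect_equal(unname(idf$leadfield$gain), diag(19))
})

test_that("planted region correlations are present in the latent series", {
  m <- montage19()
  fid <- generate_forward_model(19, m, identity = TRUE,
                                parcellation = "singleton")
  Ck <- diag(19); Ck[1, 2] <- Ck[2, 1] <- 0.8
  lab <- generate_label_sequence(1, 100000, 250, 400, seed = 3)
  sim <- generate_connected_sources(fid$leadfield, fid$parcellation,
                                    list(Ck), lab, 250, m, snr = Inf,
                                    seed = 4)
  lat <- sim$ground_truth$latent
  expect_equal(cor(lat[1, ], lat[2, ]), 0.8, tolerance = 0.05)
  # identity target: off-diagonals shrink toward zero
  off <- cor(t(lat))[upper.tri(diag(19))]
  off <- off[-1]  # drop the planted pair
  expect_lt(max(abs(off)), 0.05)
  # determinism
  sim2 <- generate_connected_sources(fid$leadfield, fid$parcellation,
                                     list(Ck), lab, 250, m, snr = Inf,
                                     seed = 4)
  expect_identical(sim$recording$data, sim2$recording$data)
  # non-PSD target refused
  bad <- diag(19); bad[1, 2] <- bad[2, 1] <- 1.5
  expect_error(generate_connected_sources(fid$leadfield, fid$parcellation,
                                          list(bad), lab, 250, m),
               "positive semi-definite")
})

test_that("cohorts have the requested sizes, distinct seeds and group symmetry", {
  cfg <- simulation_config(group_sizes = c(17, 23), record_s = 2, snr = Inf,
                           subject_cv = 0.2, seed = 5)
  cohort <- generate_cohort(cfg)
  expect_length(cohort$groups$A, 17)
  expect_length(cohort$groups$B, 23)
  seeds <- c(vapply(cohort$groups$A, `[[`, numeric(1), "seed"),
             vapply(cohort$groups$B, `[[`, numeric(1), "seed"))
  expect_equal(anyDuplicated(seeds), 0L)

  # with unit multipliers the groups' generating durations are exchangeable
  dA <- unlist(lapply(cohort$groups$A, function(s) s$ground_truth$mean_durations))
  dB <- unlist(lapply(cohort$groups$B, function(s) s$ground_truth$mean_durations))
  expect_gt(mann_whitney(dA, dB)$p, 0.01)

  # duration multiplier shifts group B's planted durations
  cfg2 <- simulation_config(group_sizes = c(5, 5), record_s = 2, snr = Inf,
                            duration_multipliers = c(2, 1, 1, 1),
                            subject_cv = 0, seed = 5)
  c2 <- generate_cohort(cfg2)
  expect_equal(c2$groups$B[[1]]$ground_truth$mean_durations[1] /
                 c2$groups$A[[1]]$ground_truth$mean_durations[1], 2,
               tolerance = 0.3)

  # occurrence multiplier reduces entries into the targeted state
  tmB <- c2$groups$B[[1]]$ground_truth$transition_matrix
  cfg3 <- simulation_config(group_sizes = c(2, 2), record_s = 2,
                            occurrence_multipliers = c(1, 1, 1, 0.5),
                            subject_cv = 0, seed = 5)
  c3 <- generate_cohort(cfg3)
  tm3 <- c3$groups$B[[1]]$ground_truth$transition_matrix
  expect_true(all(tm3[-4, 4] < 1 / 3))
  expect_equal(rowSums(tm3), rep(1, 4), tolerance = 1e-12)

  # identical config implies a bit-identical cohort
  c4 <- generate_cohort(cfg2)
  expect_identical(c2$groups$A[[3]]$recording$data,
                   c4$groups$A[[3]]$recording$data)
})
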