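test_that("state extraction partitions labelled samples and respects truth", {
  subj <- quick_subject(seed = 40, snr = Inf, n_samples = 2500)
  mod <- structure(list(k = 4, templates = subj$templates),
                   class = "microstate_model")
  seg <- backfit(mod, subj$clean, subj$gfp)

  # peaks mode returns exactly the peak columns of that state
  s1 <- extract_state_data(subj$clean, seg, 1, gfp = subj$gfp)
  pk1 <- subj$gfp$peaks[seg$labels[subj$gfp$peaks] == 1]
  expect_equal(s1$indices, pk1)
  expect_equal(s1$data, subj$clean$data[, pk1, drop = FALSE])

  # all mode unions disjointly over states to every labelled sample
  idx <- lapply(1:4, function(s)
    extract_state_data(subj$clean, seg, s, mode = "all")$indices)
  expect_equal(sort(unlist(idx)), which(!is.na(seg$labels)))
  expect_equal(anyDuplicated(unlist(idx)), 0L)

  # noiseless peak labels never collide with a different true state
  for (s in 1:4) {
    es <- extract_state_data(subj$clean, seg, s, gfp = subj$gfp)
    expect_true(all(subj$labels[es$indices] == s))
  }

  # absent state gives an explicit empty result
  seg0 <- seg; seg0$labels[seg0$labels == 2] <- 1L
  e <- extract_state_data(subj$clean, seg0, 2, gfp = subj$gfp)
  expect_equal(e$n, 0)
  expect_equal(ncol(e$data), 0)
})

test_that("sLORETA has zero localization error on the toy sphere", {
  fwd <- generate_forward_model(40, montage19(), n_regions = 4)
  inv <- build_sloreta_inverse(fwd$leadfield, alpha = 1e-12)
  hits <- vapply(seq_len(40), function(j) {
    est <- apply_inverse(inv, fwd$leadfield$gain[, j, drop = FALSE])
    which.max(abs(est)) == j
  }, logical(1))
  expect_true(all(hits))
})

test_that("the identity-gain hook returns average-referenced data up to scale", {
  fid <- generate_forward_model(19, montage19(), identity = TRUE)
  inv <- build_sloreta_inverse(fid$leadfield, alpha = 0)
  set.seed(3)
  X <- matrix(rnorm(19 * 50), 19)
  est <- apply_inverse(inv, X)
  Xr <- sweep(X, 2, colMeans(X))
  # proportional per source, with a positive common factor here
  ratio <- est / Xr
  expect_lt(max(abs(ratio - ratio[1, 1])), 1e-8)
  expect_gt(ratio[1, 1], 0)
})

test_that("inverse application is linear and shrinks with regularisation", {
  fwd <- generate_forward_model(30, montage19(), n_regions = 3)
  inv <- build_sloreta_inverse(fwd$leadfield, alpha = 1e-4)
  set.seed(4)
  x <- matrix(rnorm(19 * 20), 19); y <- matrix(rnorm(19 * 20), 19)
  expect_equal(apply_inverse(inv, x + y),
               apply_inverse(inv, x) + apply_inverse(inv, y),
               tolerance = 1e-12)
  expect_equal(apply_inverse(inv, 2 * x), 2 * apply_inverse(inv, x),
               tolerance = 1e-12)
  expect_equal(apply_inverse(inv, matrix(0, 19, 5)), matrix(0, 30, 5))
  # unstandardised minimum-norm estimates shrink as alpha grows
  shrink <- vapply(c(1e-4, 1e-3, 1e-2, 1e-1), function(a) {
    iv <- build_sloreta_inverse(fwd$leadfield, alpha = a)
    sum((iv$kernel %*% x)^2)
  }, numeric(1))
  expect_true(all(diff(shrink) < 0))
  expect_error(apply_inverse(inv, matrix(0, 5, 5)), "channels")
})

test_that("parcellation aligns signs so antiphase sources reinforce", {
  x <- sin(seq(0, 10, length.out = 200))
  ts <- rbind(x, -x, x + rnorm(200, sd = 1e-3))
  pc <- structure(list(region_of_source = c(1L, 1L, 2L),
                       region_names = c("R1", "R2")), class = "parcellation")
  out <- parcellate(ts, pc)
  expect_equal(nrow(out), 2)
  # without alignment the R1 mean would vanish; with it, |R1| = |x|
  expect_equal(abs(out["R1", ]), abs(x), tolerance = 1e-9)
  # singleton region series equal the source series up to sign
  expect_equal(abs(out["R2", ]), abs(ts[3, ]), tolerance = 1e-12)
  pc_bad <- structure(list(region_of_source = c(1L, 1L, 1L),
                           region_names = c("R1", "R2")),
                      class = "parcellation")
  expect_error(parcellate(ts, pc_bad), "empty")
})

test_that("Pearson connectivity is symmetric with unit diagonal and flags degeneracy", {
  set.seed(5)
  x <- rnorm(10000)
  ts <- rbind(a = x, b = -x, c = rnorm(10000), d = rnorm(10000))
  cm <- pearson_connectivity(ts, state = "A")
  expect_equal(cm$values["a", "b"], -1, tolerance = 1e-12)
  expect_equal(diag(cm$values), c(a = 1, b = 1, c = 1, d = 1))
  expect_equal(cm$values, t(cm$values))
  expect_lt(abs(cm$values["c", "d"]), 0.05)  # independent white series
  expect_identical(cm$degenerate_regions, character(0))

  ts2 <- rbind(a = x, flat = rep(1, 10000))
  cm2 <- pearson_connectivity(ts2)
  expect_identical(cm2$degenerate_regions, "flat")
  expect_true(is.na(cm2$values["a", "flat"]))
  expect_error(pearson_connectivity(ts[, 1:2]), "3 samples")
})

test_that("edge thresholding is monotone and sorted", {
  V <- matrix(c(1, .9, .2, .9, 1, -.5, .2, -.5, 1), 3,
              dimnames = list(NULL, NULL))
  cm <- structure(list(values = V, region_names = c("x", "y", "z"),
                       state = "A", n_samples = 10),
                  class = "connectivity_matrix")
  all_edges <- threshold_edges(cm, 0)
  expect_equal(nrow(all_edges), 3)
  expect_equal(all_edges$r, c(0.9, -0.5, 0.2))  # sorted by |r|
  expect_equal(nrow(threshold_edges(cm, 1)), 0)
  ns <- vapply(c(0, .3, .6, .95), function(th) nrow(threshold_edges(cm, th)),
               numeric(1))
  expect_true(all(diff(ns) <= 0))
  expect_error(threshold_edges(cm, 1.5), "0, 1")
})

test_that("connectivity pooling matches hand-computed summaries", {
  mk <- function(r) {
    V <- matrix(r, 3, 3); diag(V) <- 1
    structure(list(values = V, region_names = c("x", "y", "z"),
                   state = "A", n_samples = 10),
              class = "connectivity_matrix")
  }
  s1 <- summarize_connectivity(list(mk(0.5)))
  expect_equal(s1$mean, 0.5)
  expect_equal(s1$sd, 0)
  expect_equal(s1$n, 3)
  s2 <- summarize_connectivity(list(mk(0.4), mk(0.6)))
  expect_equal(s2$mean, 0.5)
  # fisher mode agrees on inputs symmetric around zero
  s3 <- summarize_connectivity(list(mk(0.5), mk(-0.5)))
  s3f <- summarize_connectivity(list(mk(0.5), mk(-0.5)), fisher_z = TRUE)
  expect_equal(s3$mean, s3f$mean, tolerance = 1e-12)
  bad <- mk(0.2); bad$region_names <- c("p", "q", "r")
  expect_error(summarize_connectivity(list(mk(0.1), bad)), "mixed")
})

test_that("recovered connectivity weakens monotonically as SNR drops", {
  m <- montage19()
  fid <- generate_forward_model(19, m, identity = TRUE,
                                parcellation = "singleton")
  Ck <- diag(19); Ck[1, 2] <- Ck[2, 1] <- 0.8
  lab <- generate_label_sequence(1, 20000, 250, 400, seed = 3)
  inv <- build_sloreta_inverse(fid$leadfield, alpha = 0)
  rs <- vapply(c(Inf, 2, 0.5), function(snr) {
    sim <- generate_connected_sources(fid$leadfield, fid$parcellation,
                                      list(Ck), lab, 250, m, snr = snr,
                                      seed = 9)
    reg <- parcellate(apply_inverse(inv, sim$recording$data),
                      fid$parcellation)
    pearson_connectivity(reg)$values[1, 2]
  }, numeric(1))
  expect_true(all(diff(rs) < 0))
  expect_gt(rs[1], 0.7)
})
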