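hkl4 <- cbind(h = c(1, 2, 3, 1), k = c(0, 1, 0, 1), l = c(0, 0, 1, 1))

test_that("scaling solves the closed-form least squares per crystal", {
  A <- make_crystal("A", hkl4, c(10, 20, 30, 40))
  # identical datasets scale to (1, 1)
  s <- scale_datasets(list(A, make_crystal("B", hkl4, c(10, 20, 30, 40))),
                      pg1, 2)
  expect_equal(unname(s[c("A", "B")]), c(1, 1))
  # doubled / quadrupled intensities invert to 0.5 / 0.25
  s <- scale_datasets(list(A,
                           make_crystal("B", hkl4, 2 * c(10, 20, 30, 40)),
                           make_crystal("C", hkl4, 4 * c(10, 20, 30, 40))),
                      pg1, 2)
  expect_equal(unname(s[c("A", "B", "C")]), c(1, 0.5, 0.25))
  expect_identical(attr(s, "reference"), "A")
  # disjoint reflection sets: scale stays 1 with a warning
  B <- make_crystal("B", cbind(5, 5, 5), 7)
  expect_warning(s <- scale_datasets(list(A, B), pg1, 2), "no reflection")
  expect_equal(unname(s[["B"]]), 1)
  expect_error(scale_datasets(list(), pg1, 2), "no datasets")
})

test_that("merging is the inverse-variance weighted mean", {
  one <- make_crystal("A", cbind(1, 2, 3), 10, sigma = 2)
  m <- merge_datasets(list(one), pg1, 2)
  expect_equal(m$table$I, 10)
  expect_equal(m$table$sigI, 2)
  expect_identical(m$table$multiplicity, 1L)
  # equal sigmas: symmetric mean
  two <- make_crystal("A", rbind(c(1, 2, 3), c(1, 2, 3)), c(10, 12),
                      frame = c(1, 2))
  expect_equal(merge_datasets(list(two), pg1, 2)$table$I, 11)
  # unequal sigmas: (10/1 + 20/4) / (1/1 + 1/4) = 12
  wtd <- make_crystal("A", rbind(c(1, 2, 3), c(1, 2, 3)), c(10, 20),
                      sigma = c(1, 2), frame = c(1, 2))
  m <- merge_datasets(list(wtd), pg1, 2)
  expect_equal(m$table$I, 12)
  expect_equal(m$table$sigI, 1 / sqrt(1 + 1 / 4))
})

test_that("merging folds symmetry mates and splits Friedel pairs in anomalous mode", {
  ds <- make_crystal("A", rbind(c(1, 2, 3), c(-1, 2, 3), c(1, -2, -3)),
                     c(10, 14, 12), frame = c(1, 2, 3))
  m <- merge_datasets(list(ds), pg222, 2)
  expect_identical(nrow(m$table), 1L)          # one orbit
  expect_identical(m$table$multiplicity, 3L)
  ma <- merge_datasets(list(ds), pg222, 2, anomalous = TRUE)
  expect_identical(nrow(ma$table), 2L)         # I(+) and I(-) kept apart
  expect_setequal(ma$table$sign, c(1L, -1L))
  # (1,2,3) and its 2-fold image (1,-2,-3) are the + mate; (-1,2,3) is -
  expect_equal(ma$table$I[ma$table$sign == 1L], 11)
  expect_equal(ma$table$I[ma$table$sign == -1L], 14)
})

test_that("rmerge and rmeas reproduce hand arithmetic", {
  # identical repeats: exactly zero
  flat <- make_crystal("A", rbind(c(1, 2, 3), c(1, 2, 3), c(2, 0, 0), c(2, 0, 0)),
                       c(10, 10, 4, 4), frame = c(1, 2, 1, 2))
  expect_equal(rmerge(list(flat), pg1, 2), 0)
  # single reflection {10, 12}: (1 + 1) / 22
  pair <- make_crystal("A", rbind(c(1, 2, 3), c(1, 2, 3)), c(10, 12),
                       frame = c(1, 2))
  expect_equal(rmerge(list(pair), pg1, 2), 2 / 22)
  expect_equal(rmeas(list(pair), pg1, 2), sqrt(2) * 2 / 22)
  # no multiply-observed reflection: undefined, not zero
  single <- make_crystal("A", hkl4, c(10, 20, 30, 40))
  expect_true(is.na(rmerge(list(single), pg1, 2)))
})

test_that("cc_half is 1 on noise-free repeats and ~0 on pure noise", {
  ur <- unique_reflections(cell_ortho, pg1, 2.5)
  n <- nrow(ur)
  expect_gt(n, 500)
  truei <- seq(10, 1000, length.out = n)
  hkl <- as.matrix(ur[, c("h", "k", "l")])
  exact <- make_crystal("A", rbind(hkl, hkl), rep(truei, 2),
                        frame = rep(1:2, each = n))
  expect_equal(cc_half(list(exact), pg1, 2.5, seed = 7), 1)
  # bit-for-bit reproducible under a fixed seed
  set.seed(99)
  noisy_i <- rep(truei, 2) + rnorm(2 * n, 0, 50)
  noisy <- make_crystal("A", rbind(hkl, hkl), noisy_i,
                        frame = rep(1:2, each = n))
  expect_identical(cc_half(list(noisy), pg1, 2.5, seed = 3),
                   cc_half(list(noisy), pg1, 2.5, seed = 3))
  # pure noise: |cc| below 3/sqrt(n_refl)
  set.seed(17)
  pure <- make_crystal("A", rbind(hkl, hkl), rnorm(2 * n, 100, 10),
                       frame = rep(1:2, each = n))
  expect_lt(abs(cc_half(list(pure), pg1, 2.5, seed = 5)), 3 / sqrt(n))
  # too few repeated reflections: undefined
  tiny <- make_crystal("A", hkl4, 1:4)
  expect_true(is.na(cc_half(list(tiny), pg1, 2)))
})

test_that("cc_half matches the analytic variance-ratio expectation", {
  cellb <- unit_cell(50, 60, 70)
  ur <- unique_reflections(cellb, pg1, 2.5)
  n <- 2000
  ur <- ur[seq_len(n), ]
  hkl <- as.matrix(ur[, c("h", "k", "l")])
  sig_s <- 10
  for (seed in 1:3) {
    set.seed(seed)
    truei <- rnorm(n, 100, sig_s)
    # two observations per reflection; each half mean is one observation
    # with noise sd sig_e, so E[cc] = sig_s^2 / (sig_s^2 + sig_e^2)
    sig_e <- 10
    obs <- rep(truei, 2) + rnorm(2 * n, 0, sig_e)
    ds <- make_crystal("A", rbind(hkl, hkl), obs, frame = rep(1:2, each = n),
                       cell = cellb)
    cc <- cc_half(list(ds), pg1, 2.5, seed = seed + 10)
    expect_equal(cc, sig_s^2 / (sig_s^2 + sig_e^2), tolerance = 0.1)
  }
})

test_that("delanom sees planted anomalous signal and not its absence", {
  # noise-free planted differences give exactly 1
  ur <- unique_reflections(cell_ortho, pg1, 3)[1:200, ]
  hkl <- as.matrix(ur[, c("h", "k", "l")])
  set.seed(5)
  ip <- runif(200, 50, 150)
  di <- rnorm(200, 0, 20)
  mk <- function(noise) {
    obs_hkl <- rbind(hkl, hkl, -hkl, -hkl)
    ints <- c(ip + di / 2, ip + di / 2, ip - di / 2, ip - di / 2) +
      rnorm(800, 0, noise)
    make_crystal("A", obs_hkl, ints, frame = rep(1:4, each = 200))
  }
  expect_equal(delanom(list(mk(0.0001)), pg1, 3, seed = 2), 1,
               tolerance = 1e-4)
  # no planted signal: correlation near zero
  di <- rep(0, 200)
  expect_lt(abs(delanom(list(mk(10)), pg1, 3, seed = 2)), 3 / sqrt(200))
  # monotone in the planted anomalous signal-to-noise
  vals <- vapply(c(0.5, 1, 2), function(snr) {
    cfg <- sim_config(n_crystals = 8,
      class_specs = list(list(cell = cell_ortho, jitter = 0, fraction = 1)),
      frames_range = c(25L, 30L), dmin = 3, pg = pg222, decay_rate = 0,
      obs_per_frame = 40, noise_gain = 4, sigma0 = 2,
      anomalous_fraction = 0.05 * snr, seed = 31)
    st <- simulate_study(cfg)
    sc <- scale_datasets(st$datasets, pg222, 3)
    delanom(st$datasets, pg222, 3, sc, seed = 8)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("completeness equals the brute-force unique-reflection ratio", {
  ur <- unique_reflections(cell_cubic10, pg1, 2.5)
  n <- nrow(ur)
  full <- make_crystal("A", as.matrix(ur[, c("h", "k", "l")]),
                       rep(100, n), cell = cell_cubic10)
  m <- merge_datasets(list(full), pg1, 2.5)
  expect_equal(completeness(m, cell_cubic10, pg1, 2.5), 100)
  # drop every second canonical index -> 50% (even counts)
  half_idx <- seq(1, n, by = 2)
  half <- make_crystal("A", as.matrix(ur[half_idx, c("h", "k", "l")]),
                       rep(100, length(half_idx)), cell = cell_cubic10)
  mh <- merge_datasets(list(half), pg1, 2.5)
  expect_equal(completeness(mh, cell_cubic10, pg1, 2.5),
               100 * length(half_idx) / n)
  expect_error(completeness(m, cell_cubic10, pg1, 100), "expected")
})

test_that("completeness matches a random-subset oracle over many cells", {
  set.seed(23)
  for (rep in 1:50) {
    cell <- unit_cell(runif(1, 8, 15), runif(1, 8, 15), runif(1, 8, 15))
    dmin <- runif(1, 2.5, 4)
    pg <- list(pg1, pg222)[[sample(2, 1)]]
    ur <- unique_reflections(cell, pg, dmin)
    if (nrow(ur) < 4) next
    k <- sample(nrow(ur) - 1, 1)
    pick <- sample(nrow(ur), k)
    ds <- make_crystal("A", as.matrix(ur[pick, c("h", "k", "l")]),
                       rep(50, k), cell = cell)
    m <- merge_datasets(list(ds), pg, dmin)
    cmp <- completeness(m, cell, pg, dmin)
    expect_equal(cmp, 100 * k / nrow(ur), tolerance = 1e-12)
    expect_lte(cmp, 100)
  }
})

test_that("frame profiles score frames against the merged reference", {
  # reference: three reflections with known means
  hkl3 <- rbind(c(1, 2, 3), c(2, 0, 0), c(0, 3, 1))
  ref_ds <- make_crystal("R", rbind(hkl3, hkl3), rep(c(10, 20, 40), 2),
                         frame = rep(1:2, each = 3))
  ref <- merge_datasets(list(ref_ds), pg1, 2)
  # crystal deviating by +10% on every frame: raw = 0.1 everywhere,
  # and smoothing preserves the constant
  dev <- make_crystal("C", do.call(rbind, replicate(5, hkl3, simplify = FALSE)),
                      rep(c(11, 22, 44), 5), frame = rep(1:5, each = 3))
  p <- frame_profile(dev, ref, kernel_sigma = 2)
  expect_equal(p$raw, rep(0.1, 5))
  expect_equal(p$smr, rep(0.1, 5))
  # zero kernel sigma: smoothed equals raw
  p0 <- frame_profile(dev, ref, kernel_sigma = 0)
  expect_identical(p0$smr, p0$raw)
  # spike frame is pulled down, neighbors pulled up, kernel math exact
  spike_i <- c(rep(c(10, 20, 40), 3), c(20, 40, 80), rep(c(10, 20, 40), 3))
  spike <- make_crystal("C", do.call(rbind, replicate(7, hkl3, simplify = FALSE)),
                        spike_i, frame = rep(1:7, each = 3))
  ps <- frame_profile(spike, ref, kernel_sigma = 1)
  expect_equal(ps$raw, c(0, 0, 0, 1, 0, 0, 0))
  w <- dnorm(-3:3, 0, 1)
  expect_equal(ps$smr[4], w[4] / sum(w))
  # frame 3's window is clipped to frames 1..6, so weights renormalize
  expect_equal(ps$smr[3], w[5] / sum(w[2:7]))
  expect_lt(ps$smr[4], ps$raw[4])
  expect_gt(ps$smr[3], ps$raw[3])
  # frame with no matchable observation stays NA through smoothing
  gap <- make_crystal("C", rbind(hkl3, c(9, 9, 9), hkl3),
                      c(11, 22, 44, 5, 11, 22, 44), frame = c(1, 1, 1, 2, 3, 3, 3),
                      n_frames = 3)
  pg_ <- frame_profile(gap, ref, kernel_sigma = 1)
  expect_true(is.na(pg_$raw[2]) && is.na(pg_$smr[2]))
  expect_false(anyNA(pg_$smr[c(1, 3)]))
})

test_that("merging is invariant to observation order and crystal relabeling", {
  set.seed(8)
  ur <- unique_reflections(cell_ortho, pg222, 3)[1:50, ]
  hkl <- as.matrix(ur[, c("h", "k", "l")])
  ints <- runif(50, 10, 100)
  ds1 <- make_crystal("A", rbind(hkl, hkl), c(ints * 1.02, ints * 0.98),
                      frame = rep(1:2, each = 50))
  perm <- sample(100)
  obs2 <- ds1$observations[perm, ]
  ds2 <- crystal_dataset("A", cell_ortho, obs2, n_frames = 2)
  m1 <- merge_datasets(list(ds1), pg222, 3)
  m2 <- merge_datasets(list(ds2), pg222, 3)
  expect_equal(m1$table, m2$table)
  expect_equal(rmerge(list(ds1), pg222, 3), rmerge(list(ds2), pg222, 3))
})

test_that("gaussian smoothing preserves the mean of defined traces", {
  set.seed(11)
  x <- runif(40, 0, 1)
  sm <- xtalmerge:::gauss_smooth(x, 2)
  # interior (away from edge truncation) is mean-preserving to first order
  expect_equal(mean(sm[7:34]), mean(x[7:34]), tolerance = 0.05)
  # constant trace is exactly preserved including edges
  expect_equal(xtalmerge:::gauss_smooth(rep(0.3, 10), 2), rep(0.3, 10))
})
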