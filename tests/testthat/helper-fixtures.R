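# Shared fixtures built in code. Small cells keep index enumeration fast.

cell_cubic10 <- unit_cell(10, 10, 10)
cell_ortho <- unit_cell(20, 25, 30)
pg1 <- point_group("1")
pg222 <- point_group("222")

# one crystal observing the given reflections on the given frames
make_crystal <- function(id, hkl, intensity, sigma = 1, frame = 1,
                         cell = cell_ortho, n_frames = max(frame)) {
  obs <- data.frame(frame = frame, h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
                    intensity = intensity, sigma = sigma)
  crystal_dataset(id, cell, obs, n_frames = n_frames)
}

# brute-force oracle: count of unique reflections by scanning the index
# cube and reducing orbits by exhaustive matrix application
brute_unique_count <- function(cell, pg, dmin) {
  hmax <- floor(cell$a / dmin); kmax <- floor(cell$b / dmin)
  lmax <- floor(cell$c / dmin)
  seen <- character()
  for (h in -hmax:hmax) for (k in -kmax:kmax) for (l in -lmax:lmax) {
    if (h == 0 && k == 0 && l == 0) next
    if (d_spacing(cell, c(h, k, l)) < dmin) next
    orbit <- unique(do.call(rbind, c(
      lapply(pg$rotations, function(R) as.integer(R %*% c(h, k, l))),
      lapply(pg$rotations, function(R) as.integer(-R %*% c(h, k, l))))))
    keys <- apply(orbit, 1, paste, collapse = ",")
    canonical <- sort(keys, decreasing = TRUE)[1]
    seen <- union(seen, canonical)
  }
  length(seen)
}

# noise-free study: every observation equals its true intensity
noise_free_config <- function(seed = 1L, n_crystals = 4L, anomalous = 0) {
  sim_config(n_crystals = n_crystals,
             class_specs = list(list(cell = cell_ortho, jitter = 0, fraction = 1)),
             frames_range = c(15L, 20L), dmin = 3, pg = pg222,
             decay_rate = 0, b0 = 0, noise_gain = Inf, sigma0 = 0,
             obs_per_frame = 40, anomalous_fraction = anomalous, seed = seed)
}

expect_no_na <- function(x) expect_false(anyNA(x))
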