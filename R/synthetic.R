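# Synthetic microcrystal study generator. Emulates the inputs the
# assembly workflow was designed for: many crystals, each contributing a
# small rotation wedge (10-100 frames, 0.1-0.3 degrees per frame), with
# per-frame B-factor decay from radiation damage, class-structured
# unit-cell variation, optional planted anomalous differences and
# optional planted high-noise ("bad") crystals. Wedge geometry is
# emulated combinatorially: the full list of Miller indices in the
# resolution sphere is laid out in a random sweep order and each frame
# observes a contiguous window of it, consecutive frames overlapping so
# reflections recur on neighboring frames as they would while passing
# through the diffracting condition.

#' Simulation configuration
#'
#' @param n_crystals Number of crystals M.
#' @param class_specs List of class descriptions, each a list with
#'   `cell` (mean `unit_cell`), `jitter` (normal sd applied to the cell
#'   edges a, b, c; a scalar or length-3 vector, angles are kept fixed at
#'   the class mean) and `fraction` (share of M; fractions must sum
#'   to 1).
#' @param frames_range Inclusive range the per-crystal frame count is
#'   drawn from (default 10 to 100).
#' @param frame_width_range Rotation width per frame in degrees (default
#'   0.1 to 0.3); sets how many sweep positions one frame covers.
#' @param dmin Simulation resolution limit in angstroms.
#' @param pg Point group used to lay out the true intensities.
#' @param intensity_scale Mean true intensity at zero scattering angle.
#' @param wilson_b Overall Wilson B factor in square angstroms: mean true
#'   intensity falls off as exp(-wilson_b s^2 / 2), s = 1/d.
#' @param b0 Starting per-crystal damage B offset (square angstroms).
#' @param decay_rate Radiation-damage rate beta in square angstroms per
#'   frame: the effective B on frame f is b0 + beta * max(0, f - onset).
#' @param decay_onset Frame after which damage sets in (0 = immediately).
#' @param noise_gain Counting-statistics gain: noise sd is
#'   sqrt(max(I,0)/noise_gain + sigma0^2).
#' @param sigma0 Additive noise floor.
#' @param anomalous_fraction Relative scale of planted Bijvoet
#'   differences (0 disables them).
#' @param overlap How many consecutive frames each reflection appears on.
#' @param obs_per_frame Observations recorded per frame; `NULL` derives
#'   it from the frame width as sweep_length * width / 180 (at least 3).
#' @param bad_crystals Integer indices of crystals given extra noise.
#' @param bad_noise_multiplier Noise (and sigma) multiplier for them.
#' @param seed Master seed; crystal i consumes the derived seed
#'   `seed + i`, so altering one crystal's spec never perturbs another's
#'   data.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_crystals = 20L,
                       class_specs = list(list(
                         cell = unit_cell(40, 50, 60), jitter = 0.2,
                         fraction = 1)),
                       frames_range = c(10L, 100L),
                       frame_width_range = c(0.1, 0.3),
                       dmin = 2.5,
                       pg = point_group("222"),
                       intensity_scale = 100,
                       wilson_b = 15,
                       b0 = 0,
                       decay_rate = 0.3,
                       decay_onset = 0L,
                       noise_gain = 4,
                       sigma0 = 0.5,
                       anomalous_fraction = 0,
                       overlap = 2L,
                       obs_per_frame = NULL,
                       bad_crystals = integer(),
                       bad_noise_multiplier = 2,
                       seed = 1L) {
  fr <- vapply(class_specs, function(s) s$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-8) stop("class fractions must sum to 1")
  if (intensity_scale <= 0 || noise_gain <= 0 || sigma0 < 0)
    stop("scale parameters must be positive")
  structure(list(n_crystals = as.integer(n_crystals),
                 class_specs = class_specs,
                 frames_range = as.integer(frames_range),
                 frame_width_range = frame_width_range,
                 dmin = dmin, pg = pg,
                 intensity_scale = intensity_scale, wilson_b = wilson_b,
                 b0 = b0, decay_rate = decay_rate,
                 decay_onset = as.integer(decay_onset),
                 noise_gain = noise_gain, sigma0 = sigma0,
                 anomalous_fraction = anomalous_fraction,
                 overlap = as.integer(overlap),
                 obs_per_frame = obs_per_frame,
                 bad_crystals = as.integer(bad_crystals),
                 bad_noise_multiplier = bad_noise_multiplier,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw the ground truth of a simulated study
#'
#' True intensities of all symmetry-unique reflections to `dmin` are
#' drawn from the acentric Wilson (exponential) distribution with mean
#' intensity_scale * exp(-wilson_b s^2 / 2). With a nonzero
#' `anomalous_fraction`, antisymmetric Bijvoet perturbations are added:
#' delta-I is normal with sd anomalous_fraction * local mean intensity,
#' and the mates carry I +/- delta-I/2. The full +/- index sphere is laid
#' out in a seeded random sweep order used by all crystals.
#'
#' @param config A `sim_config`.
#' @return An object of class `truth_record`: `reflections` (canonical
#'   h, k, l, d, I, dI), `sweep` (the ordered index list with canonical
#'   lookup and Friedel sign) and the generating `config`.
#' @export
simulate_truth <- function(config) {
  cell <- config$class_specs[[1L]]$cell
  pg <- config$pg
  local_seed(config$seed, {
    refl <- unique_reflections(cell, pg, config$dmin)
    s2 <- 1 / refl$d^2
    mean_i <- config$intensity_scale * exp(-config$wilson_b * s2 / 2)
    refl$I <- stats::rexp(nrow(refl), rate = 1 / mean_i)
    refl$dI <- if (config$anomalous_fraction > 0)
      stats::rnorm(nrow(refl), 0, config$anomalous_fraction * mean_i)
    else rep(0, nrow(refl))
    # full observable sphere in a random sweep order
    hmax <- floor(cell$a / config$dmin)
    kmax <- floor(cell$b / config$dmin)
    lmax <- floor(cell$c / config$dmin)
    grid <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax))
    grid <- grid[rowSums(grid != 0) > 0, , drop = FALSE]
    storage.mode(grid) <- "double"
    d <- d_spacing_matrix(cell, grid)
    keep <- d >= config$dmin
    grid <- grid[keep, , drop = FALSE]
    d <- d[keep]
    red <- asu_reduce(grid, pg)
    ridx <- match(paste(red$hkl[, 1L], red$hkl[, 2L], red$hkl[, 3L]),
                  paste(refl$h, refl$k, refl$l))
    ord <- sample.int(nrow(grid))
    sweep <- data.frame(h = as.integer(grid[ord, 1L]),
                        k = as.integer(grid[ord, 2L]),
                        l = as.integer(grid[ord, 3L]),
                        d = d[ord], refl = ridx[ord],
                        sign = red$sign[ord])
    structure(list(reflections = refl, sweep = sweep, cell = cell,
                   config = config, crystals = NULL),
              class = "truth_record")
  })
}

#' @export
print.truth_record <- function(x, ...) {
  cat(sprintf("truth record: %d unique reflections, sweep length %d, dmin %.2f A\n",
              nrow(x$reflections), nrow(x$sweep), x$config$dmin))
  invisible(x)
}

# number of sweep positions covered per frame
derive_obs_per_frame <- function(config, sweep_len, frame_width) {
  config$obs_per_frame %||% max(3L, round(sweep_len * frame_width / 180))
}

#' Simulate one crystal's rotation wedge
#'
#' Draws a contiguous slice of the sweep (a random start position; frame
#' f covers `obs_per_frame` positions advanced by `obs_per_frame /
#' overlap` per frame, with wrap-around) and generates observations:
#' observed I = true I * scale * exp(-(b0 + beta * max(0, f - onset)) *
#' s^2 / 2) + Gaussian noise of sd sqrt(max(I,0)/gain + sigma0^2), with
#' the honest sd stored in the sigma column. Bad crystals have both the
#' noise draw and the sigma column multiplied.
#'
#' @param truth A `truth_record`.
#' @param crystal_spec List with `crystal_id`, `cell`, and optionally
#'   `n_frames`, `frame_width`, `scale`, `b0`, `decay_rate`,
#'   `decay_onset`, `noise_multiplier`, `start` (defaults come from the
#'   truth's config or are drawn from the crystal's seed).
#' @param seed Seed for this crystal's draws.
#' @return A `crystal_dataset`.
#' @export
simulate_crystal <- function(truth, crystal_spec, seed) {
  config <- truth$config
  sweep <- truth$sweep
  T_len <- nrow(sweep)
  local_seed(seed, {
    n_frames <- crystal_spec$n_frames %||%
      sample(seq(config$frames_range[1L], config$frames_range[2L]), 1L)
    frame_width <- crystal_spec$frame_width %||%
      stats::runif(1, config$frame_width_range[1L], config$frame_width_range[2L])
    w <- derive_obs_per_frame(config, T_len, frame_width)
    step <- max(1L, round(w / config$overlap))
    start <- crystal_spec$start %||% sample.int(T_len, 1L)
    scale <- crystal_spec$scale %||% 1
    b0 <- crystal_spec$b0 %||% config$b0
    beta <- crystal_spec$decay_rate %||% config$decay_rate
    onset <- crystal_spec$decay_onset %||% config$decay_onset
    noise_mult <- crystal_spec$noise_multiplier %||% 1
    frames <- rep(seq_len(n_frames), each = w)
    pos <- (start - 1L + (frames - 1L) * step +
              rep(seq_len(w) - 1L, times = n_frames)) %% T_len + 1L
    sw <- sweep[pos, , drop = FALSE]
    i_true <- truth$reflections$I[sw$refl] +
      sw$sign * truth$reflections$dI[sw$refl] / 2
    s2 <- 1 / sw$d^2
    b_eff <- b0 + beta * pmax(0, frames - onset)
    i_model <- i_true * scale * exp(-b_eff * s2 / 2)
    sig <- sqrt(pmax(i_model, 0) / config$noise_gain + config$sigma0^2) * noise_mult
    i_obs <- i_model + stats::rnorm(length(i_model), 0, sig)
    # a zero noise model yields exact intensities; report unit sigmas so
    # the dataset stays valid (sigma > 0) without inventing noise
    obs <- data.frame(frame = frames, h = sw$h, k = sw$k, l = sw$l,
                      intensity = i_obs, sigma = ifelse(sig > 0, sig, 1))
    crystal_dataset(crystal_spec$crystal_id, crystal_spec$cell, obs,
                    n_frames = n_frames)
  })
}

#' Simulate a complete multi-crystal study
#'
#' Draws the ground truth, assigns crystals to unit-cell classes in
#' config order (first `fraction_1 * M` crystals to class 1 and so on),
#' jitters each crystal's cell edges around its class mean, and simulates
#' every crystal's wedge from its derived seed.
#'
#' @param config A `sim_config`.
#' @return A list with `datasets` (named list of `crystal_dataset`) and
#'   `truth` (a `truth_record` whose `crystals` field records each
#'   crystal's true class, cell, damage parameters and bad flag).
#' @export
simulate_study <- function(config) {
  truth <- simulate_truth(config)
  M <- config$n_crystals
  fr <- vapply(config$class_specs, function(s) s$fraction, numeric(1))
  bounds <- round(cumsum(fr) * M)
  class_of <- findInterval(seq_len(M) - 1L, c(0L, bounds[-length(bounds)]))
  datasets <- list()
  rows <- list()
  for (i in seq_len(M)) {
    cls <- class_of[i]
    spec_cls <- config$class_specs[[cls]]
    cid <- sprintf("xtal%03d", i)
    crystal_seed <- config$seed + i
    cell <- local_seed(crystal_seed * 2L + 1L, {
      j <- stats::rnorm(3, 0, rep_len(spec_cls$jitter, 3L))
      unit_cell(spec_cls$cell$a + j[1L], spec_cls$cell$b + j[2L],
                spec_cls$cell$c + j[3L], spec_cls$cell$alpha,
                spec_cls$cell$beta, spec_cls$cell$gamma)
    })
    is_bad <- i %in% config$bad_crystals
    spec <- list(crystal_id = cid, cell = cell,
                 noise_multiplier = if (is_bad) config$bad_noise_multiplier else 1)
    datasets[[cid]] <- simulate_crystal(truth, spec, crystal_seed)
    rows[[cid]] <- data.frame(crystal_id = cid, class = cls,
                              a = cell$a, b = cell$b, c = cell$c,
                              n_frames = datasets[[cid]]$n_frames,
                              bad = is_bad)
  }
  truth$crystals <- do.call(rbind, rows)
  rownames(truth$crystals) <- NULL
  list(datasets = datasets, truth = truth)
}
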