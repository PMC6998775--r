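# Step 3 of the workflow: iterative crystal rejection by mean smoothed
# per-frame Rmerge, and grid-search frame rejection driven by the decay
# cutoff formula rjframe = min(SmRmerge) * (1 + decay).

#' Rejection configuration
#'
#' @param xtal_step Crystals removed per rejection iteration (>= 1).
#' @param decay_sequence Ordered decay values for the frame-rejection
#'   grid; the default `c(5, 3, 2, 1)` corresponds to cutoffs at 6, 4, 3
#'   and 2 times the minimum SmRmerge.
#' @param completeness_threshold Classes whose merged completeness does
#'   not exceed this percentage are barred from the rejection loops
#'   (default 90).
#' @param reject_crystals,reject_frames Enable the two rejection loops.
#' @param kernel_sigma Smoothing width (frames) for the SmRmerge profiles.
#' @return An object of class `rejection_config`.
#' @export
rejection_config <- function(xtal_step = 10L,
                             decay_sequence = c(5.0, 3.0, 2.0, 1.0),
                             completeness_threshold = 90,
                             reject_crystals = TRUE,
                             reject_frames = FALSE,
                             kernel_sigma = 2) {
  xtal_step <- as.integer(xtal_step)
  if (xtal_step < 1L) stop("xtal_step must be >= 1")
  if (length(decay_sequence) && any(decay_sequence <= 0))
    stop("decay values must be > 0")
  structure(list(xtal_step = xtal_step, decay_sequence = decay_sequence,
                 completeness_threshold = completeness_threshold,
                 reject_crystals = isTRUE(reject_crystals),
                 reject_frames = isTRUE(reject_frames),
                 kernel_sigma = kernel_sigma),
            class = "rejection_config")
}

#' Per-crystal compatibility scores
#'
#' The mean of each crystal's defined SmRmerge values; undefined frames
#' are skipped. A crystal whose whole profile is undefined scores `Inf`
#' so it is rejected first.
#'
#' @param profiles List of `frame_profile` objects.
#' @return Named numeric vector of scores.
#' @export
crystal_scores <- function(profiles) {
  if (!length(profiles)) stop("no profiles supplied")
  vapply(profiles, function(p) {
    v <- p$smr[!is.na(p$smr)]
    if (!length(v)) Inf else mean(v)
  }, numeric(1))
}

#' Remove the worst crystals in one rejection step
#'
#' Removes exactly `xtal_step` crystals with the largest scores; ties are
#' broken by ascending crystal id. When the current count is already at
#' or below `xtal_step` no crystal is removed (the loop terminator).
#'
#' @param scores Named scores from [crystal_scores()].
#' @param xtal_step Number of crystals to remove.
#' @return Character vector of removed crystal ids (possibly empty).
#' @export
reject_crystals_once <- function(scores, xtal_step) {
  if (length(scores) <= xtal_step) return(character())
  ord <- order(-scores, names(scores))
  names(scores)[ord[seq_len(xtal_step)]]
}

#' Frame-rejection cutoff
#'
#' The cutoff rjframe = min(SmRmerge) * (1 + decay) over a crystal's
#' defined frames; with the default decay sequence 5, 3, 2, 1 this is 6,
#' 4, 3 and 2 times the minimum.
#'
#' @param profile A `frame_profile`.
#' @param decay Decay parameter (> 0 in normal use).
#' @return The cutoff, or `NA` for an all-undefined profile.
#' @export
frame_cutoff <- function(profile, decay) {
  v <- profile$smr[!is.na(profile$smr)]
  if (!length(v)) return(NA_real_)
  min(v) * (1 + decay)
}

#' Reject radiation-damaged frames of one crystal
#'
#' Keeps the frames whose SmRmerge does not exceed the decay cutoff.
#' Frames with undefined SmRmerge are kept (there is no evidence against
#' them), and the kept set is not forced to be contiguous.
#'
#' @param profile A `frame_profile`.
#' @param decay Decay parameter.
#' @return An object of class `frame_rejection_result` with `crystal_id`,
#'   `decay`, `min_smr`, `cutoff` and `kept_frames`.
#' @export
reject_frames <- function(profile, decay) {
  cutoff <- frame_cutoff(profile, decay)
  smr <- profile$smr
  kept <- if (is.na(cutoff)) seq_len(profile$n_frames)
          else which(is.na(smr) | smr <= cutoff)
  v <- smr[!is.na(smr)]
  structure(list(crystal_id = profile$crystal_id, decay = decay,
                 min_smr = if (length(v)) min(v) else NA_real_,
                 cutoff = cutoff, kept_frames = as.integer(kept)),
            class = "frame_rejection_result")
}

new_assembly_result <- function(class_label, iteration, decay, datasets,
                                stats, merged) {
  structure(list(
    class_label = class_label, iteration = iteration, decay = decay,
    crystal_ids = names(datasets),
    kept_frames = lapply(datasets, function(d) sort(unique(d$observations$frame))),
    n_crystals = length(datasets),
    stats = stats, merged = merged),
    class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("assembly result: class %s, iteration %d, decay %s, %d crystals\n",
              x$class_label, x$iteration,
              if (is.na(x$decay)) "none" else fmt_num(x$decay), x$n_crystals))
  print(x$stats)
  invisible(x)
}

#' Assemble one unit-cell class with iterative rejection
#'
#' Runs the full step-3 loop for one class. Iteration 0 merges the whole
#' class; if its completeness exceeds the threshold and crystal rejection
#' is enabled, crystals are repeatedly scored by mean SmRmerge against
#' the current merged reference and the worst `xtal_step` removed, with a
#' merged dataset and statistics emitted at every iteration, until the
#' surviving count is at or below `xtal_step` (the final dataset is
#' emitted before stopping). When frame rejection is enabled, each
#' iteration additionally emits one dataset per decay value, built from
#' the frames passing that decay's cutoff. Classes that fail the
#' completeness gate, or have fewer than two crystals, emit only their
#' iteration-0 result.
#'
#' @param class_data List of `crystal_dataset` objects in one class.
#' @param config A `rejection_config`.
#' @param pg A `point_group`.
#' @param reso Assembly resolution cutoff in angstroms.
#' @param seed Integer seed for the half-split statistics.
#' @param class_label Label carried into the results.
#' @return List of `assembly_result` objects, in emission order.
#' @export
assemble_class <- function(class_data, config, pg, reso, seed = 1L,
                           class_label = 1L) {
  surviving <- as_dataset_list(class_data)
  cell0 <- average_cell(lapply(surviving, `[[`, "cell"))
  results <- list()
  iteration <- 0L
  repeat {
    scales <- scale_datasets(surviving, pg, reso)
    merged <- merge_datasets(surviving, pg, reso, scales)
    stats <- dataset_stats(surviving, pg, reso, scales, seed = seed,
                           cell = cell0, merged = merged)
    results[[length(results) + 1L]] <-
      new_assembly_result(class_label, iteration, NA_real_, surviving,
                          stats, merged)
    gate <- stats$completeness > config$completeness_threshold
    if (iteration == 0L &&
        (!gate || length(surviving) < 2L ||
         !(config$reject_crystals || config$reject_frames))) break
    profiles <- lapply(surviving, function(ds)
      frame_profile(ds, merged, config$kernel_sigma,
                    scale = unname(scales[ds$crystal_id])))
    if (config$reject_frames) {
      for (decay in config$decay_sequence) {
        trimmed <- Map(function(ds, p)
          subset_frames(ds, reject_frames(p, decay)$kept_frames),
          surviving, profiles)
        tr_scales <- scale_datasets(trimmed, pg, reso)
        tr_merged <- merge_datasets(trimmed, pg, reso, tr_scales)
        tr_stats <- dataset_stats(trimmed, pg, reso, tr_scales, seed = seed,
                                  cell = cell0, merged = tr_merged)
        results[[length(results) + 1L]] <-
          new_assembly_result(class_label, iteration, decay, trimmed,
                              tr_stats, tr_merged)
      }
    }
    if (!config$reject_crystals) break
    removed <- reject_crystals_once(crystal_scores(profiles), config$xtal_step)
    if (!length(removed)) break
    surviving <- surviving[setdiff(names(surviving), removed)]
    iteration <- iteration + 1L
  }
  results
}

#' Iterative crystal rejection (no frame grid)
#'
#' Convenience wrapper around [assemble_class()] with frame rejection
#' disabled: emits the sequence of crystal-rejection iterations only.
#'
#' @inheritParams assemble_class
#' @return List of `assembly_result` objects, one per iteration.
#' @export
iterate_crystal_rejection <- function(class_data, config, pg, reso,
                                      seed = 1L, class_label = 1L) {
  config$reject_frames <- FALSE
  config$reject_crystals <- TRUE
  assemble_class(class_data, config, pg, reso, seed, class_label)
}

#' Select the best assembled dataset
#'
#' The result maximizing the chosen criterion: CC1/2 for resolution-
#' oriented work, DelAnom for anomalous phasing. Ties favor fewer
#' rejections: the earlier iteration, then the larger decay (no frame
#' rejection counting as largest), then more crystals.
#'
#' @param results List of `assembly_result` objects.
#' @param criterion `"cc_half"` or `"delanom"`.
#' @return The selected `assembly_result`.
#' @export
select_best <- function(results, criterion = c("cc_half", "delanom")) {
  criterion <- match.arg(criterion)
  vals <- vapply(results, function(r) {
    v <- r$stats[[criterion]]
    if (is.null(v) || is.na(v)) NA_real_ else v
  }, numeric(1))
  if (all(is.na(vals)))
    stop("criterion '", criterion, "' is undefined for every result")
  it <- vapply(results, `[[`, numeric(1), "iteration")
  dec <- vapply(results, function(r) if (is.na(r$decay)) Inf else r$decay,
                numeric(1))
  ncr <- vapply(results, `[[`, numeric(1), "n_crystals")
  ord <- order(-vals, it, -dec, -ncr, na.last = TRUE)
  results[[ord[1L]]]
}
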