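# Step 1 of the workflow: each crystal's rotation series is scored as
# progressive (accumulative) wedges and trimmed to the wedge with the
# best CC1/2 at the statistics resolution.

#' Build progressive wedge boundaries
#'
#' Divides a crystal's frames into `q_total` contiguous base wedges as
#' evenly as possible (remainder frames go to the earliest wedges, which
#' are the least damaged) and returns the cumulative wedges: wedge q
#' covers base wedges 1..q, so frame ranges are nested and wedge
#' `q_total` covers the full series.
#'
#' @param crystal A `crystal_dataset`.
#' @param q_total Number of wedges (1 <= q_total <= n_frames).
#' @return A data.frame with columns `q` and `last_frame`.
#' @examples
#' ds <- crystal_dataset("x", unit_cell(10, 10, 10),
#'   data.frame(frame = 1:10, h = 1, k = 0, l = 0, intensity = 1, sigma = 1))
#' build_progressive_wedges(ds, 3)  # cumulative ends 4, 7, 10
#' @export
build_progressive_wedges <- function(crystal, q_total) {
  n <- crystal$n_frames
  q_total <- as.integer(q_total)
  if (q_total < 1L || q_total > n)
    stop("q_total must lie in [1, n_frames]")
  sizes <- rep(n %/% q_total, q_total)
  r <- n %% q_total
  if (r > 0L) sizes[seq_len(r)] <- sizes[seq_len(r)] + 1L
  data.frame(q = seq_len(q_total), last_frame = cumsum(sizes))
}

#' Score progressive wedges by CC1/2
#'
#' Computes CC1/2 at the statistics resolution `reso_cchalf` for every
#' cumulative wedge of one crystal. Wedges with too few repeated
#' observations carry `NA`, never a sentinel value.
#'
#' @param crystal A `crystal_dataset`.
#' @param wedges Output of [build_progressive_wedges()].
#' @param pg A `point_group`.
#' @param reso_cchalf Statistics resolution cutoff in angstroms.
#' @param seed Integer seed for the half-splits (wedge q uses `seed + q`).
#' @return The `wedges` data.frame with `cc_half` and `n_obs` columns.
#' @export
score_wedges <- function(crystal, wedges, pg, reso_cchalf, seed = 1L) {
  wedges$cc_half <- NA_real_
  wedges$n_obs <- 0L
  for (i in seq_len(nrow(wedges))) {
    sub <- subset_frames(crystal, seq_len(wedges$last_frame[i]))
    wedges$n_obs[i] <- nrow(sub$observations)
    wedges$cc_half[i] <- cc_half(list(sub), pg, reso_cchalf,
                                 seed = seed + wedges$q[i])
  }
  wedges
}

#' Select the best progressive wedge
#'
#' Returns the wedge with the maximum CC1/2; ties are broken in favor of
#' the larger wedge (more frames at equal quality). A crystal whose
#' wedges all have undefined CC1/2 is flagged excluded rather than
#' raising an error.
#'
#' @param stats Scored wedges from [score_wedges()].
#' @return A list with `q`, `last_frame`, `cc_half` and `excluded`.
#' @export
select_best_wedge <- function(stats) {
  ok <- which(!is.na(stats$cc_half))
  if (!length(ok)) {
    return(list(q = NA_integer_, last_frame = NA_integer_,
                cc_half = NA_real_, excluded = TRUE))
  }
  best <- max(stats$cc_half[ok])
  cand <- ok[stats$cc_half[ok] == best]
  pick <- cand[which.max(stats$last_frame[cand])]
  list(q = stats$q[pick], last_frame = stats$last_frame[pick],
       cc_half = stats$cc_half[pick], excluded = FALSE)
}

#' Progressive-wedge selection across a study
#'
#' Runs wedge construction, scoring and selection for every crystal and
#' trims each retained crystal to its best wedge. Crystals with no
#' defined CC1/2 in any wedge are excluded from the returned collection
#' but reported.
#'
#' @param datasets List of `crystal_dataset` objects.
#' @param pg A `point_group`.
#' @param reso_cchalf Statistics resolution cutoff in angstroms.
#' @param q_total Number of progressive wedges per crystal (crystals with
#'   fewer frames than `q_total` use one wedge per frame).
#' @param seed Integer seed.
#' @return A list with `datasets` (trimmed, excluded crystals dropped)
#'   and `report` (one row per crystal: chosen wedge, CC1/2, exclusion).
#' @export
select_wedges <- function(datasets, pg, reso_cchalf, q_total = 10L, seed = 1L) {
  datasets <- as_dataset_list(datasets)
  rows <- list()
  kept <- list()
  for (ds in datasets) {
    qt <- min(as.integer(q_total), ds$n_frames)
    wedges <- build_progressive_wedges(ds, qt)
    scored <- score_wedges(ds, wedges, pg, reso_cchalf, seed)
    best <- select_best_wedge(scored)
    rows[[ds$crystal_id]] <- data.frame(
      crystal_id = ds$crystal_id, n_frames = ds$n_frames,
      q = best$q, last_frame = best$last_frame,
      cc_half = best$cc_half, excluded = best$excluded)
    if (!best$excluded) {
      trimmed <- subset_frames(ds, seq_len(best$last_frame))
      trimmed$n_frames <- as.integer(best$last_frame)
      kept[[ds$crystal_id]] <- trimmed
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  list(datasets = kept, report = report)
}
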