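# Internal statistics engine: scaling, merging, Rmerge/Rmeas, CC1/2,
# anomalous-difference correlation, completeness and per-frame Rmerge
# profiles. All downstream assembly decisions consume these quantities.

# Flatten a dataset collection into one observation table with scaled
# intensities and canonical (ASU-reduced) indices. Observations beyond
# the resolution cutoff (by each crystal's own cell) are dropped.
obs_table <- function(datasets, pg, dmin, scales = NULL) {
  datasets <- as_dataset_list(datasets)
  parts <- lapply(datasets, function(ds) {
    obs <- ds$observations
    if (!nrow(obs)) return(NULL)
    H <- cbind(obs$h, obs$k, obs$l)
    storage.mode(H) <- "double"
    d <- d_spacing_matrix(ds$cell, H)
    keep <- d >= dmin
    if (!any(keep)) return(NULL)
    obs <- obs[keep, , drop = FALSE]
    H <- H[keep, , drop = FALSE]
    k <- if (is.null(scales)) 1 else unname(scales[ds$crystal_id])
    if (is.na(k)) stop("no scale factor for crystal ", ds$crystal_id)
    red <- asu_reduce(H, pg)
    data.frame(crystal_id = ds$crystal_id, frame = obs$frame,
               h = as.integer(red$hkl[, 1L]), k = as.integer(red$hkl[, 2L]),
               l = as.integer(red$hkl[, 3L]), sign = red$sign,
               I = obs$intensity * k, sig = obs$sigma * k,
               d = d[keep])
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) {
    return(data.frame(crystal_id = character(), frame = integer(),
                      h = integer(), k = integer(), l = integer(),
                      sign = integer(), I = numeric(), sig = numeric(),
                      d = numeric(), key = character()))
  }
  tab <- do.call(rbind, parts)
  rownames(tab) <- NULL
  tab$key <- paste(tab$h, tab$k, tab$l)
  tab
}

#' Inter-crystal scale factors
#'
#' Fits one multiplicative scale per crystal against a reference crystal
#' (the first by sorted `crystal_id`, whose scale is fixed at 1). For each
#' other crystal, per-reflection mean intensities over canonical indices
#' are matched against the reference's and the scale k minimizing
#' sum (I_ref - k I_crys)^2 is solved in closed form. Crystals sharing no
#' reflection with the reference keep k = 1 with a warning.
#'
#' @param datasets List of `crystal_dataset` objects.
#' @param pg A `point_group`.
#' @param dmin Resolution cutoff in angstroms.
#' @return A named numeric vector of scales (class `scale_set`) with the
#'   reference id in attribute `reference`.
#' @export
scale_datasets <- function(datasets, pg, dmin) {
  datasets <- as_dataset_list(datasets)
  if (!length(datasets)) stop("no datasets to scale")
  refl_means <- lapply(datasets, function(ds) {
    tab <- obs_table(list(ds), pg, dmin)
    if (!nrow(tab)) return(numeric())
    sums <- rowsum(tab$I, tab$key)
    cnts <- rowsum(rep(1, nrow(tab)), tab$key)
    stats::setNames(as.numeric(sums / cnts), rownames(sums))
  })
  ids <- names(datasets)
  ref <- ids[[1L]]
  scales <- stats::setNames(rep(1, length(ids)), ids)
  ref_means <- refl_means[[ref]]
  for (id in ids[-1L]) {
    m <- refl_means[[id]]
    common <- intersect(names(ref_means), names(m))
    if (!length(common)) {
      warning("crystal ", id, " shares no reflection with the reference; scale kept at 1")
      next
    }
    ir <- ref_means[common]
    ic <- m[common]
    denom <- sum(ic^2)
    if (denom <= 0) {
      warning("degenerate intensities for crystal ", id, "; scale kept at 1")
      next
    }
    scales[[id]] <- sum(ir * ic) / denom
  }
  structure(scales, reference = ref, class = "scale_set")
}

#' Merge scaled observations into a unique reflection list
#'
#' Observations are scaled, mapped to the canonical asymmetric unit and
#' combined per reflection by the inverse-variance weighted mean, with
#' merged sigma 1/sqrt(sum 1/sigma^2). In anomalous mode the Friedel
#' mates I(+) and I(-) are merged separately (distinguished by the
#' `sign` column).
#'
#' @param datasets List of `crystal_dataset` objects.
#' @param pg A `point_group`.
#' @param dmin Resolution cutoff in angstroms.
#' @param scales A `scale_set` (or NULL for unit scales).
#' @param anomalous Keep Friedel mates separate.
#' @return An object of class `merged_dataset`: a reflection table plus
#'   the merge parameters and contributing crystal ids.
#' @export
merge_datasets <- function(datasets, pg, dmin, scales = NULL, anomalous = FALSE) {
  datasets <- as_dataset_list(datasets)
  tab <- obs_table(datasets, pg, dmin, scales)
  cells <- lapply(datasets, `[[`, "cell")
  avg_cell <- average_cell(cells)
  if (!nrow(tab)) {
    table <- data.frame(h = integer(), k = integer(), l = integer(),
                        sign = integer(), I = numeric(), sigI = numeric(),
                        multiplicity = integer())
  } else {
    gkey <- if (anomalous) paste(tab$key, tab$sign) else tab$key
    w <- 1 / tab$sig^2
    sw <- rowsum(w, gkey)
    swi <- rowsum(w * tab$I, gkey)
    n <- rowsum(rep(1L, nrow(tab)), gkey)
    first <- !duplicated(gkey)
    ord <- match(rownames(sw), gkey[first])
    idx <- which(first)[ord]
    table <- data.frame(h = tab$h[idx], k = tab$k[idx], l = tab$l[idx],
                        sign = if (anomalous) tab$sign[idx] else 1L,
                        I = as.numeric(swi / sw),
                        sigI = as.numeric(1 / sqrt(sw)),
                        multiplicity = as.integer(n))
    table <- table[order(table$h, table$k, table$l, table$sign), , drop = FALSE]
    rownames(table) <- NULL
  }
  structure(list(table = table, pg = pg, dmin = dmin, anomalous = anomalous,
                 crystal_ids = names(datasets), cell = avg_cell,
                 n_obs = nrow(tab)),
            class = "merged_dataset")
}

#' @export
print.merged_dataset <- function(x, ...) {
  cat(sprintf("merged dataset: %d unique reflections from %d crystals (dmin %.2f A%s)\n",
              nrow(x$table), length(x$crystal_ids), x$dmin,
              if (x$anomalous) ", anomalous" else ""))
  invisible(x)
}

average_cell <- function(cells) {
  p <- sapply(cells, function(cl) unlist(cl[c("a", "b", "c", "alpha", "beta", "gamma")]))
  m <- rowMeans(matrix(p, nrow = 6L))
  unit_cell(m[1L], m[2L], m[3L], m[4L], m[5L], m[6L])
}

# shared core for rmerge / rmeas: unweighted per-reflection means over
# multiply-observed canonical reflections
rfactor_core <- function(datasets, pg, dmin, scales) {
  tab <- obs_table(datasets, pg, dmin, scales)
  if (!nrow(tab)) return(list(rmerge = NA_real_, rmeas = NA_real_))
  n <- stats::ave(tab$I, tab$key, FUN = length)
  if (all(n < 2)) return(list(rmerge = NA_real_, rmeas = NA_real_))
  m <- stats::ave(tab$I, tab$key, FUN = mean)
  sel <- n >= 2
  dev <- abs(tab$I - m)[sel]
  den <- sum(tab$I[sel])
  if (den <= 0) return(list(rmerge = NA_real_, rmeas = NA_real_))
  corr <- sqrt(n[sel] / (n[sel] - 1))
  list(rmerge = sum(dev) / den, rmeas = sum(corr * dev) / den)
}

#' Merging R factors
#'
#' `rmerge()` is sum |I_i - <I>| / sum I_i over all reflections measured
#' at least twice, with <I> the unweighted mean of each reflection's
#' scaled observations; `rmeas()` is the multiplicity-corrected variant
#' with each deviation weighted by sqrt(n/(n-1)). Returns `NA` when no
#' reflection is multiply observed.
#'
#' @inheritParams merge_datasets
#' @return A single numeric value (or `NA`).
#' @export
rmerge <- function(datasets, pg, dmin, scales = NULL) {
  rfactor_core(datasets, pg, dmin, scales)$rmerge
}

#' @rdname rmerge
#' @export
rmeas <- function(datasets, pg, dmin, scales = NULL) {
  rfactor_core(datasets, pg, dmin, scales)$rmeas
}

# balanced random half-assignment within groups: observations are ranked
# by a seeded uniform draw inside each group and alternate halves
half_split <- function(group) {
  r <- stats::runif(length(group))
  rk <- stats::ave(r, group, FUN = rank)
  ifelse(rk %% 2 == 1, 1L, 2L)
}

#' Half-dataset correlation CC1/2
#'
#' Observations of every multiply-observed reflection are split at random
#' (reproducibly, via `seed`) into two balanced halves; the Pearson
#' correlation of the two half-dataset mean-intensity vectors is
#' returned. Reflections observed once are excluded; fewer than three
#' usable reflections give `NA`.
#'
#' @inheritParams merge_datasets
#' @param seed Integer seed controlling the half-split.
#' @return Numeric in [-1, 1], or `NA` when undefined.
#' @export
cc_half <- function(datasets, pg, dmin, scales = NULL, seed = 1L) {
  tab <- obs_table(datasets, pg, dmin, scales)
  if (!nrow(tab)) return(NA_real_)
  n <- stats::ave(tab$I, tab$key, FUN = length)
  tab <- tab[n >= 2, , drop = FALSE]
  if (length(unique(tab$key)) < 3L) return(NA_real_)
  half <- local_seed(seed, half_split(tab$key))
  m1 <- rowsum(tab$I * (half == 1L), tab$key) / rowsum(as.numeric(half == 1L), tab$key)
  m2 <- rowsum(tab$I * (half == 2L), tab$key) / rowsum(as.numeric(half == 2L), tab$key)
  ok <- is.finite(m1) & is.finite(m2)
  if (sum(ok) < 3L) return(NA_real_)
  v1 <- m1[ok]; v2 <- m2[ok]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) return(NA_real_)
  stats::cor(v1, v2)
}

#' Anomalous-difference correlation (DelAnom)
#'
#' For every reflection with both Friedel mates observed at least twice,
#' the I(+) and I(-) observations are each split at random into two
#' halves and the anomalous difference delta-I = <I(+)> - <I(-)> is
#' formed per half. Returns the Pearson correlation of the two
#' half-dataset delta-I vectors (the CCanom interpretation); fewer than
#' three usable Bijvoet pairs give `NA`.
#'
#' @inheritParams cc_half
#' @return Numeric in [-1, 1], or `NA` when undefined.
#' @export
delanom <- function(datasets, pg, dmin, scales = NULL, seed = 1L) {
  tab <- obs_table(datasets, pg, dmin, scales)
  if (!nrow(tab)) return(NA_real_)
  skey <- paste(tab$key, tab$sign)
  n_sign <- stats::ave(tab$I, skey, FUN = length)
  # usable reflections: both mates present with >= 2 observations each
  ok_grp <- n_sign >= 2
  tab <- tab[ok_grp, , drop = FALSE]
  skey <- skey[ok_grp]
  if (!nrow(tab)) return(NA_real_)
  has_plus <- unique(tab$key[tab$sign == 1L])
  has_minus <- unique(tab$key[tab$sign == -1L])
  pairs <- intersect(has_plus, has_minus)
  if (length(pairs) < 3L) return(NA_real_)
  tab <- tab[tab$key %in% pairs, , drop = FALSE]
  skey <- paste(tab$key, tab$sign)
  half <- local_seed(seed, half_split(skey))
  dvec <- function(h) {
    sel <- half == h
    m <- rowsum(tab$I[sel], paste(tab$key[sel], tab$sign[sel])) /
      rowsum(rep(1, sum(sel)), paste(tab$key[sel], tab$sign[sel]))
    mp <- m[paste(pairs, 1L), ]
    mm <- m[paste(pairs, -1L), ]
    mp - mm
  }
  d1 <- dvec(1L); d2 <- dvec(2L)
  ok <- is.finite(d1) & is.finite(d2)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(d1[ok]) == 0 || stats::sd(d2[ok]) == 0) return(NA_real_)
  stats::cor(d1[ok], d2[ok])
}

#' Completeness of a merged dataset
#'
#' Percentage of symmetry-unique reflections to `dmin` actually present
#' in the merged data, with the denominator enumerated from the (class
#' average) unit cell.
#'
#' @param merged A `merged_dataset`.
#' @param cell Reference `unit_cell` for the enumeration (defaults to the
#'   merged dataset's average cell).
#' @param pg A `point_group` (defaults to the merged dataset's).
#' @param dmin Resolution limit (defaults to the merged dataset's).
#' @return Completeness in percent, in [0, 100].
#' @export
completeness <- function(merged, cell = merged$cell, pg = merged$pg,
                         dmin = merged$dmin) {
  expected <- enumerate_unique(cell, pg, dmin)
  if (expected == 0L) stop("no reflections expected at this resolution")
  tb <- merged$table
  if (!nrow(tb)) return(0)
  key <- paste(tb$h, tb$k, tb$l)
  uniq <- !duplicated(key)
  H <- cbind(tb$h, tb$k, tb$l)[uniq, , drop = FALSE]
  storage.mode(H) <- "double"
  d <- d_spacing_matrix(cell, H)
  100 * sum(d >= dmin) / expected
}

# Gaussian kernel smoothing of a trace with NA gaps; kernel truncated at
# +/- 3 sigma, weights renormalized over the defined frames in window.
# NA positions stay NA (no evidence is invented for empty frames).
gauss_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  n <- length(x)
  hw <- as.integer(ceiling(3 * sigma))
  w0 <- stats::dnorm(-hw:hw, mean = 0, sd = sigma)
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (is.na(x[i])) next
    j <- max(1L, i - hw):min(n, i + hw)
    wj <- w0[j - i + hw + 1L]
    ok <- !is.na(x[j])
    out[i] <- sum(wj[ok] * x[j][ok]) / sum(wj[ok])
  }
  out
}

#' Per-frame smoothed Rmerge profile (SmRmerge)
#'
#' Scores each frame of one crystal against a merged reference: the raw
#' value of frame f is sum |I_obs - I_ref| / sum I_ref over the frame's
#' observations whose canonical reflection exists in the reference. The
#' raw trace is then Gaussian-smoothed over frame number (default kernel
#' sigma 2 frames, truncated at +/- 3 sigma, renormalized at edges and
#' across gaps). Frames with no matchable observation, or a non-positive
#' reference denominator, carry `NA` in both traces.
#'
#' @param crystal A `crystal_dataset`.
#' @param merged_reference A `merged_dataset` built from the crystal's
#'   class (the crystal itself may be included).
#' @param kernel_sigma Smoothing kernel width in frames; 0 disables
#'   smoothing.
#' @param scale Multiplicative scale applied to the crystal's intensities
#'   before comparison.
#' @return An object of class `frame_profile` with per-frame `raw` and
#'   `smr` vectors.
#' @export
frame_profile <- function(crystal, merged_reference, kernel_sigma = 2,
                          scale = 1) {
  stopifnot(inherits(merged_reference, "merged_dataset"))
  pg <- merged_reference$pg
  dmin <- merged_reference$dmin
  ref <- merged_reference$table
  # collapse Friedel mates of an anomalous reference to one mean per hkl
  rkey <- paste(ref$h, ref$k, ref$l)
  rsum <- rowsum(ref$I * ref$multiplicity, rkey)
  rn <- rowsum(as.numeric(ref$multiplicity), rkey)
  ref_mean <- stats::setNames(as.numeric(rsum / rn), rownames(rsum))
  scl <- stats::setNames(scale, crystal$crystal_id)
  tab <- obs_table(list(crystal), pg, dmin, scl)
  n_frames <- crystal$n_frames
  raw <- rep(NA_real_, n_frames)
  if (nrow(tab)) {
    iref <- ref_mean[tab$key]
    ok <- !is.na(iref)
    if (any(ok)) {
      num <- rowsum(abs(tab$I[ok] - iref[ok]), tab$frame[ok])
      den <- rowsum(iref[ok], tab$frame[ok])
      f <- as.integer(rownames(num))
      val <- as.numeric(num) / as.numeric(den)
      val[as.numeric(den) <= 0] <- NA_real_
      raw[f] <- val
    }
  }
  structure(list(crystal_id = crystal$crystal_id, raw = raw,
                 smr = gauss_smooth(raw, kernel_sigma),
                 kernel_sigma = kernel_sigma, n_frames = n_frames),
            class = "frame_profile")
}

#' @export
print.frame_profile <- function(x, ...) {
  cat(sprintf("frame profile '%s': %d frames, %d defined, mean SmRmerge %s\n",
              x$crystal_id, x$n_frames, sum(!is.na(x$smr)),
              fmt_num(mean(x$smr, na.rm = TRUE))))
  invisible(x)
}

#' Merged-data quality indicators
#'
#' Computes the full bundle of statistics the assembly logic consumes:
#' Rmerge, Rmeas, CC1/2, DelAnom, completeness, mean multiplicity and
#' mean I/sigma.
#'
#' @inheritParams cc_half
#' @param cell Reference cell for completeness (defaults to the average
#'   of the datasets' cells).
#' @param merged Optional precomputed non-anomalous `merged_dataset` for
#'   the same datasets/scales (avoids re-merging).
#' @return An object of class `stats_bundle` (a named list).
#' @export
dataset_stats <- function(datasets, pg, dmin, scales = NULL, seed = 1L,
                          cell = NULL, merged = NULL) {
  datasets <- as_dataset_list(datasets)
  if (is.null(merged))
    merged <- merge_datasets(datasets, pg, dmin, scales, anomalous = FALSE)
  if (is.null(cell)) cell <- merged$cell
  rf <- rfactor_core(datasets, pg, dmin, scales)
  tb <- merged$table
  structure(list(
    rmerge = rf$rmerge,
    rmeas = rf$rmeas,
    cc_half = cc_half(datasets, pg, dmin, scales, seed),
    delanom = delanom(datasets, pg, dmin, scales, seed),
    completeness = completeness(merged, cell, pg, dmin),
    mean_multiplicity = if (nrow(tb)) mean(tb$multiplicity) else NA_real_,
    mean_i_over_sig = if (nrow(tb)) mean(tb$I / tb$sigI) else NA_real_,
    n_unique = nrow(tb),
    n_obs = merged$n_obs
  ), class = "stats_bundle")
}

#' @export
print.stats_bundle <- function(x, ...) {
  cat(sprintf(paste0("Rmerge %s  Rmeas %s  CC1/2 %s  DelAnom %s\n",
                     "completeness %s%%  multiplicity %s  <I/sig> %s  (%d unique / %d obs)\n"),
              fmt_num(x$rmerge), fmt_num(x$rmeas), fmt_num(x$cc_half),
              fmt_num(x$delanom), fmt_num(x$completeness),
              fmt_num(x$mean_multiplicity), fmt_num(x$mean_i_over_sig),
              x$n_unique, x$n_obs))
  invisible(x)
}
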