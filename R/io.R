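# Readers and writers for the plain tabular observation format, and the
# simplified amplitude export. Input is deliberately a text table (one
# row per observation plus a sidecar unit-cell table) rather than
# detector master files: integration is upstream of this package, and an
# hdf5 adapter would attach at read_observations().

#' Write a study to observation and cell tables
#'
#' @param datasets List of `crystal_dataset` objects.
#' @param obs_path Path for the observation table (columns crystal_id,
#'   frame, h, k, l, intensity, sigma).
#' @param cell_path Path for the unit-cell sidecar (crystal_id, a, b, c,
#'   alpha, beta, gamma, n_frames).
#' @param sep Field separator (default tab).
#' @return Invisibly, the two paths.
#' @export
write_observations <- function(datasets, obs_path, cell_path, sep = "\t") {
  datasets <- as_dataset_list(datasets)
  obs <- do.call(rbind, lapply(datasets, function(ds)
    cbind(crystal_id = ds$crystal_id, ds$observations)))
  cells <- do.call(rbind, lapply(datasets, function(ds)
    data.frame(crystal_id = ds$crystal_id, a = ds$cell$a, b = ds$cell$b,
               c = ds$cell$c, alpha = ds$cell$alpha, beta = ds$cell$beta,
               gamma = ds$cell$gamma, n_frames = ds$n_frames)))
  utils::write.table(obs, obs_path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  utils::write.table(cells, cell_path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(c(obs_path, cell_path))
}

detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a study from observation and cell tables
#'
#' Parses tab- or comma-separated observation and unit-cell tables,
#' validates the invariants, and drops invalid rows (non-positive sigma,
#' zero index, non-positive frame) with a message naming how many rows
#' were rejected and which.
#'
#' @param obs_path Observation table with header columns crystal_id,
#'   frame, h, k, l, intensity, sigma.
#' @param cell_path Cell table with header columns crystal_id, a, b, c,
#'   alpha, beta, gamma and optionally n_frames.
#' @return Named list of `crystal_dataset` objects.
#' @export
read_observations <- function(obs_path, cell_path) {
  obs <- utils::read.table(obs_path, header = TRUE, sep = detect_sep(obs_path),
                           stringsAsFactors = FALSE)
  cells <- utils::read.table(cell_path, header = TRUE,
                             sep = detect_sep(cell_path),
                             stringsAsFactors = FALSE)
  need_obs <- c("crystal_id", "frame", "h", "k", "l", "intensity", "sigma")
  missing_cols <- setdiff(need_obs, names(obs))
  if (length(missing_cols))
    stop("observation table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  need_cell <- c("crystal_id", "a", "b", "c", "alpha", "beta", "gamma")
  missing_cols <- setdiff(need_cell, names(cells))
  if (length(missing_cols))
    stop("cell table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!nrow(obs)) {
    warning("observation table is empty")
    return(list())
  }
  bad <- !is.finite(obs$sigma) | obs$sigma <= 0 | obs$frame < 1 |
    (obs$h == 0 & obs$k == 0 & obs$l == 0)
  if (any(bad)) {
    message(sum(bad), " invalid observation row(s) rejected (rows ",
            paste(utils::head(which(bad), 20L), collapse = ", "), ")")
    obs <- obs[!bad, , drop = FALSE]
  }
  datasets <- list()
  for (i in seq_len(nrow(cells))) {
    cid <- as.character(cells$crystal_id[i])
    sub <- obs[obs$crystal_id == cid, , drop = FALSE]
    if (!nrow(sub)) next
    nf <- if ("n_frames" %in% names(cells)) cells$n_frames[i] else max(sub$frame)
    cell <- unit_cell(cells$a[i], cells$b[i], cells$c[i],
                      cells$alpha[i], cells$beta[i], cells$gamma[i])
    datasets[[cid]] <- crystal_dataset(cid, cell, sub[, -1L], n_frames = nf)
  }
  as_dataset_list(datasets)
}

#' Write a merged dataset as a reflection table
#'
#' Tab-separated columns h, k, l, I, sigI, multiplicity; in anomalous
#' mode the Friedel sign column is included.
#'
#' @param merged A `merged_dataset`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_merged <- function(merged, path) {
  tb <- merged$table
  out <- data.frame(h = tb$h, k = tb$k, l = tb$l)
  if (merged$anomalous) out$sign <- tb$sign
  out$I <- fmt_num(tb$I)
  out$sigI <- fmt_num(tb$sigI)
  out$multiplicity <- tb$multiplicity
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert merged intensities to amplitudes with free-set flags
#'
#' A simplified stand-in for the usual truncation step, not a
#' French-Wilson estimate: F = sqrt(max(I, 0)) with sigF = sigI / (2 F)
#' when F > 0 and sqrt(sigI) otherwise. A fraction of reflections is
#' flagged as the cross-validation (free) set, chosen uniformly without
#' replacement under the given seed.
#'
#' @param merged A `merged_dataset` (non-anomalous mode).
#' @param rfree_fraction Fraction of reflections flagged free, in
#'   (0, 0.5); default 0.05.
#' @param seed Integer seed for the free-set draw.
#' @param path Optional output path (tab-separated).
#' @return Data frame with columns h, k, l, F, sigF, free_flag.
#' @export
export_amplitudes <- function(merged, rfree_fraction = 0.05, seed = 1L,
                              path = NULL) {
  tb <- merged$table
  if (!nrow(tb)) stop("merged dataset is empty")
  if (rfree_fraction <= 0 || rfree_fraction >= 0.5)
    stop("rfree_fraction must lie in (0, 0.5)")
  f <- sqrt(pmax(tb$I, 0))
  sigf <- ifelse(f > 0, tb$sigI / (2 * f), sqrt(tb$sigI))
  n_free <- floor(rfree_fraction * nrow(tb))
  flag <- rep(0L, nrow(tb))
  if (n_free > 0) {
    idx <- local_seed(seed, sample.int(nrow(tb), n_free))
    flag[idx] <- 1L
  }
  out <- data.frame(h = tb$h, k = tb$k, l = tb$l, F = f, sigF = sigf,
                    free_flag = flag)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  out
}
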