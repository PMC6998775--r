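# End-to-end driver: wedge selection -> unit-cell classification ->
# per-class assembly with iterative rejection -> best-dataset selection,
# with a check.txt-style report, dendrogram and per-result output tree.

#' Run configuration for the assembly pipeline
#'
#' Validates the mutually dependent options of a full run. Frame
#' rejection presupposes the crystal-rejection context, so `rjframe`
#' without `rjxtal` is a configuration error; `reso_cchalf` defaults to
#' `reso + 1` angstrom when not supplied.
#'
#' @param spg Space-group or point-group symbol (reduced to its point
#'   group), e.g. `"p2221"` or `"222"`.
#' @param n_classes Desired number of unit-cell classes N.
#' @param reso Assembly resolution cutoff in angstroms.
#' @param reso_cchalf Statistics resolution for wedge scoring (default
#'   `reso + 1`).
#' @param rjxtal Enable iterative crystal rejection.
#' @param xtal_step Crystals removed per iteration.
#' @param rjframe Enable grid-search frame rejection (requires `rjxtal`).
#' @param decay_sequence Decay grid, default `c(5, 3, 2, 1)`.
#' @param completeness_threshold Rejection-loop gate in percent
#'   (default 90).
#' @param linkage `"ward"` or `"single"` clustering linkage.
#' @param criterion Ranking criterion, `"cc_half"` or `"delanom"`.
#' @param wedges Number of progressive wedges per crystal (default 10).
#' @param kernel_sigma SmRmerge smoothing width in frames.
#' @param seed Integer seed for every stochastic step.
#' @param outdir Output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(spg = "1", n_classes = 1L, reso = 2.5, reso_cchalf = NULL,
                       rjxtal = FALSE, xtal_step = 10L, rjframe = FALSE,
                       decay_sequence = c(5.0, 3.0, 2.0, 1.0),
                       completeness_threshold = 90,
                       linkage = c("ward", "single"),
                       criterion = c("cc_half", "delanom"),
                       wedges = 10L, kernel_sigma = 2, seed = 1L,
                       outdir = tempfile("xtalmerge")) {
  linkage <- match.arg(linkage)
  criterion <- match.arg(criterion)
  if (isTRUE(rjframe) && !isTRUE(rjxtal))
    stop("frame rejection (rjframe) requires crystal rejection (rjxtal)")
  rc <- resolution_config(reso, reso_cchalf)
  structure(list(pg = point_group(spg),
                 n_classes = as.integer(n_classes), reso = rc$reso,
                 reso_cchalf = rc$reso_cchalf, rjxtal = isTRUE(rjxtal),
                 xtal_step = as.integer(xtal_step),
                 rjframe = isTRUE(rjframe), decay_sequence = decay_sequence,
                 completeness_threshold = completeness_threshold,
                 linkage = linkage, criterion = criterion,
                 wedges = as.integer(wedges), kernel_sigma = kernel_sigma,
                 seed = as.integer(seed), outdir = outdir),
            class = "run_config")
}

result_dirname <- function(r) {
  sprintf("iter%02d_%s", r$iteration,
          if (is.na(r$decay)) "full" else paste0("decay", fmt_num(r$decay)))
}

write_stats_bundle <- function(stats, path) {
  keys <- c("rmerge", "rmeas", "cc_half", "delanom", "completeness",
            "mean_multiplicity", "mean_i_over_sig", "n_unique", "n_obs")
  writeLines(paste(keys, vapply(keys, function(k) fmt_num(stats[[k]]),
                                character(1)), sep = "\t"), path)
}

write_provenance <- function(r, path) {
  lines <- c(paste("class", r$class_label, sep = "\t"),
             paste("iteration", r$iteration, sep = "\t"),
             paste("decay", if (is.na(r$decay)) "none" else fmt_num(r$decay),
                   sep = "\t"),
             paste("n_crystals", r$n_crystals, sep = "\t"),
             paste("crystals", paste(r$crystal_ids, collapse = ","), sep = "\t"),
             vapply(r$crystal_ids, function(id)
               paste0("frames_", id, "\t",
                      paste(r$kept_frames[[id]], collapse = ",")),
               character(1)))
  writeLines(lines, path)
}

#' Run the full data-assembly pipeline
#'
#' Executes the three-step workflow on a study: (1) progressive-wedge
#' selection per crystal, (2) unit-cell classification into N classes,
#' (3) per-class assembly with the configured rejection loops, then ranks
#' every emitted dataset by CC1/2 and by DelAnom. Writes a check.txt
#' report (per crystal: cell, chosen wedge, CC1/2, class), a dendrogram
#' PDF, one directory per assembled result (merged reflection table,
#' statistics summary, provenance record) and a top-level summary table.
#'
#' @param datasets Named list of `crystal_dataset` objects, or `NULL` to
#'   read from `obs_path`/`cell_path`.
#' @param config A `run_config`.
#' @param obs_path,cell_path Input tables when `datasets` is `NULL`.
#' @return Invisibly, a list with `results` (all `assembly_result`s),
#'   `best` (per criterion), `wedge_report`, `assignment` and `outdir`.
#' @export
run_pipeline <- function(datasets = NULL, config = run_config(),
                         obs_path = NULL, cell_path = NULL) {
  if (is.null(datasets)) {
    if (is.null(obs_path) || is.null(cell_path))
      stop("either datasets or obs_path + cell_path must be supplied")
    datasets <- read_observations(obs_path, cell_path)
  }
  datasets <- as_dataset_list(datasets)
  if (!length(datasets)) stop("no crystals to assemble")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  pg <- config$pg

  ## step 1: progressive wedges
  sel <- select_wedges(datasets, pg, config$reso_cchalf,
                       q_total = config$wedges, seed = config$seed)
  if (!length(sel$datasets)) stop("every crystal was excluded by wedge selection")

  ## step 2: unit-cell classification
  kept <- sel$datasets
  if (length(kept) >= 2L && config$n_classes >= 1L) {
    feats <- cell_features(lapply(kept, `[[`, "cell"))
    assignment <- cluster_cells(feats, min(config$n_classes, length(kept)),
                                config$linkage)
    export_dendrogram(assignment, file.path(config$outdir, "dendrogram.pdf"))
    labels <- assignment$labels
  } else {
    assignment <- NULL
    labels <- stats::setNames(rep(1L, length(kept)), names(kept))
  }

  ## check.txt-style report
  check <- sel$report
  check$class <- NA_integer_
  check$class[match(names(labels), check$crystal_id)] <- labels
  cellrows <- do.call(rbind, lapply(datasets, function(ds)
    data.frame(crystal_id = ds$crystal_id, a = ds$cell$a, b = ds$cell$b,
               c = ds$cell$c, alpha = ds$cell$alpha, beta = ds$cell$beta,
               gamma = ds$cell$gamma)))
  check <- merge(cellrows, check, by = "crystal_id", sort = TRUE)
  num_cols <- vapply(check, is.numeric, logical(1))
  check_out <- check
  check_out[num_cols] <- lapply(check[num_cols], fmt_num)
  utils::write.table(check_out, file.path(config$outdir, "check.txt"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  ## step 3: per-class assembly
  rj <- rejection_config(xtal_step = config$xtal_step,
                         decay_sequence = config$decay_sequence,
                         completeness_threshold = config$completeness_threshold,
                         reject_crystals = config$rjxtal,
                         reject_frames = config$rjframe,
                         kernel_sigma = config$kernel_sigma)
  results <- list()
  for (cls in sort(unique(labels))) {
    class_data <- kept[names(labels)[labels == cls]]
    res <- tryCatch(
      assemble_class(class_data, rj, pg, config$reso, seed = config$seed,
                     class_label = cls),
      error = function(e) {
        message("class ", cls, " skipped: ", conditionMessage(e))
        list()
      })
    cls_dir <- file.path(config$outdir, sprintf("class_%02d", cls))
    dir.create(cls_dir, showWarnings = FALSE)
    for (r in res) {
      rdir <- file.path(cls_dir, result_dirname(r))
      dir.create(rdir, showWarnings = FALSE)
      write_merged(r$merged, file.path(rdir, "merged.tsv"))
      write_stats_bundle(r$stats, file.path(rdir, "stats.txt"))
      write_provenance(r, file.path(rdir, "provenance.txt"))
    }
    results <- c(results, res)
  }
  if (!length(results)) stop("no class produced an assembled dataset")

  ## summary ranked by both criteria
  summary <- do.call(rbind, lapply(results, function(r)
    data.frame(class = r$class_label, iteration = r$iteration,
               decay = ifelse(is.na(r$decay), "none", fmt_num(r$decay)),
               n_crystals = r$n_crystals,
               n_frames = sum(lengths(r$kept_frames)),
               rmerge = r$stats$rmerge, rmeas = r$stats$rmeas,
               cc_half = r$stats$cc_half, delanom = r$stats$delanom,
               completeness = r$stats$completeness,
               multiplicity = r$stats$mean_multiplicity,
               i_over_sig = r$stats$mean_i_over_sig)))
  summary$rank_cchalf <- rank(-summary$cc_half, ties.method = "first",
                              na.last = "keep")
  summary$rank_delanom <- if (all(is.na(summary$delanom))) NA_integer_
    else rank(-summary$delanom, ties.method = "first", na.last = "keep")
  sum_out <- summary
  num_cols <- vapply(sum_out, is.numeric, logical(1))
  sum_out[num_cols] <- lapply(sum_out[num_cols], fmt_num)
  utils::write.table(sum_out, file.path(config$outdir, "summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  best <- list(cc_half = tryCatch(select_best(results, "cc_half"),
                                  error = function(e) NULL),
               delanom = tryCatch(select_best(results, "delanom"),
                                  error = function(e) NULL))
  invisible(list(results = results, best = best, summary = summary,
                 wedge_report = sel$report, assignment = assignment,
                 outdir = config$outdir))
}
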