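# Step 2 of the workflow: agglomerative clustering of the selected
# crystals by unit-cell parameters. Single linkage keeps the largest
# possible class together (useful for anomalous signal); Ward linkage
# maximizes class separation (more assembled datasets).

#' Standardized unit-cell feature matrix
#'
#' Builds the M x 6 matrix of (a, b, c, alpha, beta, gamma), each column
#' centered and divided by its sample standard deviation. Parameters that
#' do not vary (e.g. symmetry-fixed 90 degree angles) contribute an
#' all-zero column rather than a division error, so they cannot influence
#' the clustering.
#'
#' @param cells List of `unit_cell` objects (M >= 2).
#' @return Numeric matrix with one row per cell.
#' @export
cell_features <- function(cells) {
  if (length(cells) < 2L) stop("at least two cells are required")
  X <- t(vapply(cells, function(cl)
    unlist(cl[c("a", "b", "c", "alpha", "beta", "gamma")]), numeric(6)))
  colnames(X) <- c("a", "b", "c", "alpha", "beta", "gamma")
  if (!is.null(names(cells))) rownames(X) <- names(cells)
  sds <- apply(X, 2L, stats::sd)
  X <- sweep(X, 2L, colMeans(X))
  nz <- sds > 0
  X[, nz] <- sweep(X[, nz, drop = FALSE], 2L, sds[nz], "/")
  X[, !nz] <- 0
  attr(X, "feature_sd") <- sds
  X
}

#' Cluster crystals by unit-cell parameters
#'
#' Agglomerative hierarchical clustering (Euclidean distance on the
#' standardized features) cut to exactly `n_classes` classes. Class
#' labels are renumbered by descending class size, so class 1 is always
#' the largest and the assembly's primary candidate.
#'
#' @param features Matrix from [cell_features()].
#' @param n_classes Desired number of classes N (1 <= N <= M).
#' @param linkage `"ward"` (default; Ward's D2 on Euclidean distances) or
#'   `"single"`.
#' @return An object of class `class_assignment`: `labels` (named integer
#'   vector), `hclust` (the merge history), `linkage_method` and
#'   `feature_sd`.
#' @export
cluster_cells <- function(features, n_classes, linkage = c("ward", "single")) {
  linkage <- match.arg(linkage)
  m <- nrow(features)
  n_classes <- as.integer(n_classes)
  if (n_classes < 1L || n_classes > m)
    stop("n_classes must lie in [1, number of crystals]")
  hc <- stats::hclust(stats::dist(features),
                      method = if (linkage == "ward") "ward.D2" else "single")
  cut <- stats::cutree(hc, k = n_classes)
  sizes <- table(cut)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- stats::setNames(seq_len(n_classes), names(sizes)[ord])
  labels <- stats::setNames(as.integer(relabel[as.character(cut)]), names(cut))
  structure(list(labels = labels, hclust = hc, linkage_method = linkage,
                 n_classes = n_classes, feature_sd = attr(features, "feature_sd")),
            class = "class_assignment")
}

#' @export
print.class_assignment <- function(x, ...) {
  sizes <- table(x$labels)
  cat(sprintf("%d classes (%s linkage): sizes %s\n", x$n_classes,
              x$linkage_method, paste(as.integer(sizes), collapse = ", ")))
  invisible(x)
}

#' Write the clustering dendrogram to a PDF
#'
#' @param assignment A `class_assignment` (or bare `hclust` object).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
export_dendrogram <- function(assignment, path) {
  hc <- if (inherits(assignment, "hclust")) assignment else assignment$hclust
  grDevices::pdf(path, width = 8, height = 5)
  on.exit(grDevices::dev.off())
  graphics::plot(hc, main = "Unit-cell classification",
                 xlab = "crystal", ylab = "merge height", sub = "")
  invisible(path)
}
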