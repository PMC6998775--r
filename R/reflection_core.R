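#' Construct a unit cell
#'
#' Creates a validated triclinic unit cell. Lengths are in angstroms and
#' angles in degrees; the derived metric tensor must be positive definite
#' (equivalently, the cell volume must be positive).
#'
#' @param a,b,c Cell edge lengths in angstroms (> 0).
#' @param alpha,beta,gamma Cell angles in degrees (strictly between 0 and 180).
#' @return An object of class `unit_cell`.
#' @examples
#' unit_cell(40, 50, 60)
#' unit_cell(30, 30, 30, 90, 120, 90)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  lens <- c(a = a, b = b, c = c)
  angs <- c(alpha = alpha, beta = beta, gamma = gamma)
  if (!all(is.finite(lens)) || any(lens <= 0))
    stop("cell lengths must be finite and > 0")
  if (!all(is.finite(angs)) || any(angs <= 0) || any(angs >= 180))
    stop("cell angles must lie strictly between 0 and 180 degrees")
  cell <- structure(as.list(c(lens, angs)), class = "unit_cell")
  if (cell_volume(cell) <= 0 || !is.finite(cell_volume(cell)))
    stop("degenerate unit cell: metric tensor is not positive definite")
  cell
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.3f b=%.3f c=%.3f alpha=%.2f beta=%.2f gamma=%.2f\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Unit-cell volume
#'
#' @param cell A `unit_cell`.
#' @return Volume in cubic angstroms.
#' @export
cell_volume <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (arg <= 0) return(0)
  cell$a * cell$b * cell$c * sqrt(arg)
}

# Direct-space metric tensor G (3x3); G[i,j] = a_i . a_j
cell_metric <- function(cell) {
  ca <- cos(cell$alpha * pi / 180)
  cb <- cos(cell$beta * pi / 180)
  cg <- cos(cell$gamma * pi / 180)
  a <- cell$a; b <- cell$b; cc <- cell$c
  matrix(c(a * a,      a * b * cg, a * cc * cb,
           a * b * cg, b * b,      b * cc * ca,
           a * cc * cb, b * cc * ca, cc * cc), 3, 3, byrow = TRUE)
}

# Reciprocal metric tensor G* = G^-1
cell_gstar <- function(cell) solve(cell_metric(cell))

#' Resolution (d-spacing) of a reflection
#'
#' Computes d = 1 / |s| for Miller index (h, k, l) using the full triclinic
#' reciprocal metric, where s is the reciprocal-lattice vector of the
#' reflection. Symmetric under hkl -> -hkl.
#'
#' @param cell A `unit_cell`.
#' @param hkl Integer vector of length 3, or an n x 3 matrix of indices.
#' @return d-spacing(s) in angstroms.
#' @examples
#' d_spacing(unit_cell(10, 10, 10), c(1, 0, 0))  # 10
#' d_spacing(unit_cell(10, 10, 10), c(1, 1, 1))  # 10 / sqrt(3)
#' @export
d_spacing <- function(cell, hkl) {
  H <- to_hkl_matrix(hkl)
  if (any(rowSums(H != 0L) == 0L))
    stop("d-spacing of the (0,0,0) index is undefined")
  d <- d_spacing_matrix(cell, H)
  if (is.matrix(hkl)) d else d[[1L]]
}

# vectorized core, no zero-index validation (callers filter)
d_spacing_matrix <- function(cell, H) {
  gs <- cell_gstar(cell)
  1 / sqrt(rowSums((H %*% gs) * H))
}

to_hkl_matrix <- function(hkl) {
  if (is.matrix(hkl)) {
    stopifnot(ncol(hkl) == 3L)
    H <- hkl
  } else {
    stopifnot(length(hkl) == 3L)
    H <- matrix(hkl, 1L, 3L)
  }
  storage.mode(H) <- "double"
  H
}

## ---- point groups -----------------------------------------------------

# Rotation generators acting on column vectors (h, k, l). Trigonal and
# hexagonal groups use hexagonal axes; monoclinic unique axis is b.
.pg_generators <- local({
  m <- function(...) matrix(c(...), 3, 3, byrow = TRUE)
  two_b   <- m(-1, 0, 0,  0, 1, 0,  0, 0, -1)   # 2-fold along b
  two_c   <- m(-1, 0, 0,  0, -1, 0,  0, 0, 1)   # 2-fold along c
  two_a   <- m(1, 0, 0,  0, -1, 0,  0, 0, -1)   # 2-fold along a
  four_c  <- m(0, -1, 0,  1, 0, 0,  0, 0, 1)    # 4-fold along c
  three_c <- m(0, 1, 0,  -1, -1, 0,  0, 0, 1)   # 3-fold along c (hexagonal)
  two_hk  <- m(0, 1, 0,  1, 0, 0,  0, 0, -1)    # 2-fold in the a,b plane
  cyc3    <- m(0, 0, 1,  1, 0, 0,  0, 1, 0)     # body-diagonal 3-fold
  list(
    "1"   = list(),
    "2"   = list(two_b),
    "222" = list(two_c, two_a),
    "4"   = list(four_c),
    "422" = list(four_c, two_a),
    "3"   = list(three_c),
    "32"  = list(three_c, two_hk),
    "6"   = list(three_c, two_c),
    "622" = list(three_c, two_c, two_hk),
    "23"  = list(two_c, two_a, cyc3),
    "432" = list(two_c, two_a, cyc3, four_c)
  )
})

# close a set of integer matrices under multiplication (small groups only)
close_group <- function(gens) {
  key <- function(M) paste(as.integer(round(M)), collapse = ",")
  mats <- list(diag(3))
  names(mats) <- key(mats[[1L]])
  queue <- gens
  while (length(queue)) {
    M <- queue[[1L]]; queue <- queue[-1L]
    k <- key(M)
    if (!is.null(mats[[k]])) next
    mats[[k]] <- M
    for (N in mats) {
      queue <- c(queue, list(M %*% N), list(N %*% M))
    }
    if (length(mats) > 96L) stop("group closure did not converge")
  }
  unname(mats)
}

# common macromolecular space-group symbols -> point group of the rotations
.sg_to_pg <- c(
  p1 = "1",
  p2 = "2", p21 = "2", c2 = "2", c21 = "2", i2 = "2",
  p222 = "222", p2221 = "222", p21212 = "222", p212121 = "222",
  c222 = "222", c2221 = "222", f222 = "222", i222 = "222", i212121 = "222",
  p4 = "4", p41 = "4", p42 = "4", p43 = "4", i4 = "4", i41 = "4",
  p422 = "422", p4212 = "422", p4122 = "422", p41212 = "422",
  p4222 = "422", p42212 = "422", p4322 = "422", p43212 = "422",
  i422 = "422", i4122 = "422",
  p3 = "3", p31 = "3", p32 = "3", r3 = "3", h3 = "3",
  p312 = "32", p321 = "32", p3112 = "32", p3121 = "32",
  p3212 = "32", p3221 = "32", r32 = "32", h32 = "32",
  p6 = "6", p61 = "6", p65 = "6", p62 = "6", p64 = "6", p63 = "6",
  p622 = "622", p6122 = "622", p6522 = "622", p6222 = "622",
  p6422 = "622", p6322 = "622",
  p23 = "23", f23 = "23", i23 = "23", p213 = "23", i213 = "23",
  p432 = "432", p4232 = "432", f432 = "432", f4132 = "432",
  i432 = "432", p4332 = "432", p4132 = "432", i4132 = "432"
)

#' Construct a point group
#'
#' A point group is the set of proper rotation matrices acting on Miller
#' indices under which observations are merged. Built-in groups cover the
#' common macromolecular cases: 1, 2, 222, 4, 422, 3, 32, 6, 622, 23 and
#' 432 (trigonal/hexagonal groups in hexagonal axes; monoclinic unique
#' axis b). Names are matched case-insensitively, and common space-group
#' symbols such as `"P212121"` or `"p2221"` are reduced to their point
#' group by a lookup table (translations stripped). Alternatively a list
#' of integer 3x3 rotation matrices may be supplied; it is closed under
#' multiplication and validated.
#'
#' @param name Point-group or space-group symbol, e.g. `"222"`, `"p2221"`.
#' @param rotations Optional list of 3x3 integer matrices (determinant
#'   +/-1) to use instead of a built-in group.
#' @return An object of class `point_group` with elements `name` and
#'   `rotations` (the full list of rotation matrices, identity included).
#' @examples
#' point_group("222")
#' point_group("p212121")   # reduces to 222
#' @export
point_group <- function(name = "1", rotations = NULL) {
  if (is.null(rotations)) {
    norm <- gsub("[ _()]", "", tolower(as.character(name)))
    pg_name <- if (norm %in% names(.pg_generators)) norm else unname(.sg_to_pg[norm])
    if (is.na(pg_name) || is.null(pg_name))
      stop(sprintf("unknown point-group or space-group symbol '%s'", name))
    rots <- close_group(.pg_generators[[pg_name]])
  } else {
    pg_name <- as.character(name)
    rots <- lapply(rotations, function(M) {
      M <- as.matrix(M)
      if (!all(dim(M) == c(3L, 3L)) || any(abs(M - round(M)) > 1e-9))
        stop("rotations must be 3x3 integer matrices")
      M <- round(M)
      if (abs(abs(det(M)) - 1) > 1e-9)
        stop("rotation matrices must have determinant +1 or -1")
      M
    })
    rots <- close_group(rots)
  }
  structure(list(name = pg_name, rotations = rots), class = "point_group")
}

#' @export
print.point_group <- function(x, ...) {
  cat(sprintf("point group %s (%d rotations)\n", x$name, length(x$rotations)))
  invisible(x)
}

#' Map Miller indices to the canonical asymmetric unit
#'
#' Reduces an index to a canonical representative: the lexicographic
#' maximum over (h, k, l) of the orbit under the point-group rotations
#' together with their Friedel (inversion) images, so that a Bijvoet pair
#' always shares one canonical index. The returned `friedel_sign` is +1
#' when the original index reaches the canonical one through a proper
#' rotation alone and -1 when the inversion is required, i.e. it labels
#' the I(+)/I(-) mate; centric reflections (reachable both ways) get +1.
#' Mapping a canonical index returns itself with sign +1.
#'
#' @param hkl Integer vector of length 3 (not all zero).
#' @param pg A `point_group`.
#' @param anomalous Logical; retained for interface symmetry with merging.
#'   The canonical index always folds Friedel mates together; the sign
#'   carries the hemisphere, which is only consumed in anomalous mode.
#' @return List with `hkl` (integer canonical index) and `friedel_sign`.
#' @examples
#' map_to_asu(c(-1, -2, -3), point_group("1"))   # (1,2,3), sign -1
#' @export
map_to_asu <- function(hkl, pg, anomalous = FALSE) {
  stopifnot(length(hkl) == 3L)
  if (all(hkl == 0)) stop("cannot map the (0,0,0) index")
  red <- asu_reduce(matrix(as.double(hkl), 1L, 3L), pg)
  list(hkl = as.integer(red$hkl[1L, ]), friedel_sign = as.integer(red$sign[1L]))
}

# Vectorized ASU reduction. H: n x 3 numeric matrix of integer indices.
# Returns list(hkl = n x 3 canonical matrix, sign = +/-1 vector).
# Proper rotations are scanned first with a strict comparison, so on ties
# (centric reflections) the +1 branch wins deterministically.
asu_reduce <- function(H, pg) {
  rots <- pg$rotations
  n <- nrow(H)
  best <- H %*% t(rots[[1L]])
  sign <- rep.int(1L, n)
  apply_cand <- function(cand, s) {
    gt <- (cand[, 1L] > best[, 1L]) |
      (cand[, 1L] == best[, 1L] & cand[, 2L] > best[, 2L]) |
      (cand[, 1L] == best[, 1L] & cand[, 2L] == best[, 2L] & cand[, 3L] > best[, 3L])
    if (any(gt)) {
      best[gt, ] <<- cand[gt, , drop = FALSE]
      sign[gt] <<- s
    }
  }
  for (R in rots[-1L]) apply_cand(H %*% t(R), 1L)
  for (R in rots) apply_cand(-(H %*% t(R)), -1L)
  list(hkl = best, sign = sign)
}

#' Enumerate symmetry-unique reflections to a resolution limit
#'
#' `unique_reflections()` lists every distinct canonical (Friedel-reduced)
#' Miller index with d-spacing >= `dmin`; `enumerate_unique()` returns
#' their count, the denominator of the completeness statistic. The index
#' search cube is bounded per axis by floor(length / dmin), which cannot
#' miss a valid index because |h| <= a / d for any reflection.
#'
#' @param cell A `unit_cell`.
#' @param pg A `point_group`.
#' @param dmin High-resolution limit in angstroms (> 0).
#' @return `unique_reflections()`: a data.frame with columns `h`, `k`,
#'   `l`, `d` (one row per unique reflection); `enumerate_unique()`: an
#'   integer count.
#' @examples
#' enumerate_unique(unit_cell(10, 10, 10), point_group("1"), 10)  # 3
#' @export
unique_reflections <- function(cell, pg, dmin) {
  if (!is.finite(dmin) || dmin <= 0) stop("dmin must be > 0")
  hmax <- floor(cell$a / dmin)
  kmax <- floor(cell$b / dmin)
  lmax <- floor(cell$c / dmin)
  if (hmax < 0 || kmax < 0 || lmax < 0 || (hmax == 0 && kmax == 0 && lmax == 0))
    return(data.frame(h = integer(), k = integer(), l = integer(), d = numeric()))
  grid <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax))
  grid <- grid[rowSums(grid != 0) > 0, , drop = FALSE]
  storage.mode(grid) <- "double"
  d <- d_spacing_matrix(cell, grid)
  keep <- d >= dmin
  grid <- grid[keep, , drop = FALSE]
  d <- d[keep]
  if (nrow(grid) == 0L)
    return(data.frame(h = integer(), k = integer(), l = integer(), d = numeric()))
  red <- asu_reduce(grid, pg)$hkl
  key <- paste(red[, 1L], red[, 2L], red[, 3L])
  first <- !duplicated(key)
  out <- data.frame(h = as.integer(red[first, 1L]),
                    k = as.integer(red[first, 2L]),
                    l = as.integer(red[first, 3L]),
                    d = d[first])
  out[order(-out$d, out$h, out$k, out$l), , drop = FALSE]
}

#' @rdname unique_reflections
#' @export
enumerate_unique <- function(cell, pg, dmin) {
  nrow(unique_reflections(cell, pg, dmin))
}

## ---- observations and crystal datasets --------------------------------

#' Construct a single-crystal dataset
#'
#' Bundles one crystal's unit cell with its observed reflections: one row
#' per measured intensity on one frame. Frames are 1-based; intensities
#' may be negative (post background subtraction) but sigmas must be
#' positive.
#'
#' @param crystal_id Character identifier.
#' @param cell A `unit_cell`.
#' @param observations A data.frame with columns `frame`, `h`, `k`, `l`,
#'   `intensity`, `sigma`.
#' @param n_frames Number of frames in the rotation series; defaults to
#'   the maximum observed frame.
#' @param validate Check invariants (disable only for internally derived
#'   subsets, e.g. after frame rejection, where frame gaps are expected).
#' @return An object of class `crystal_dataset`.
#' @export
crystal_dataset <- function(crystal_id, cell, observations,
                            n_frames = max(observations$frame),
                            validate = TRUE) {
  stopifnot(inherits(cell, "unit_cell"))
  req <- c("frame", "h", "k", "l", "intensity", "sigma")
  missing_cols <- setdiff(req, names(observations))
  if (length(missing_cols))
    stop("observations missing column(s): ", paste(missing_cols, collapse = ", "))
  obs <- as.data.frame(observations)[req]
  if (validate && nrow(obs)) {
    if (any(!is.finite(obs$sigma) | obs$sigma <= 0))
      stop("all observation sigmas must be finite and > 0")
    if (any(obs$frame < 1L | obs$frame > n_frames))
      stop("observation frames must lie in [1, n_frames]")
    if (any(obs$h == 0 & obs$k == 0 & obs$l == 0))
      stop("the (0,0,0) index cannot be observed")
  }
  structure(list(crystal_id = as.character(crystal_id), cell = cell,
                 n_frames = as.integer(n_frames), observations = obs),
            class = "crystal_dataset")
}

#' @export
print.crystal_dataset <- function(x, ...) {
  cat(sprintf("crystal '%s': %d frames, %d observations\n",
              x$crystal_id, x$n_frames, nrow(x$observations)))
  invisible(x)
}

# subset a crystal to a set of frames; frames keep their original numbers
subset_frames <- function(crystal, frames) {
  obs <- crystal$observations
  crystal_dataset(crystal$crystal_id, crystal$cell,
                  obs[obs$frame %in% frames, , drop = FALSE],
                  n_frames = crystal$n_frames, validate = FALSE)
}

#' Resolution configuration
#'
#' Holds the two resolution cutoffs of the workflow: `reso`, at which data
#' are merged and assembled, and `reso_cchalf`, the (lower) resolution at
#' which wedge CC1/2 statistics are computed. When `reso_cchalf` is not
#' supplied it defaults to `reso + 1` angstrom.
#'
#' @param reso Assembly resolution cutoff in angstroms.
#' @param reso_cchalf Statistics resolution for wedge scoring; default
#'   `reso + 1`.
#' @return An object of class `resolution_config`.
#' @export
resolution_config <- function(reso, reso_cchalf = NULL) {
  if (!is.finite(reso) || reso <= 0) stop("reso must be > 0")
  if (is.null(reso_cchalf)) reso_cchalf <- reso + 1
  if (reso_cchalf < reso)
    stop("reso_cchalf must be >= reso (statistics resolution is lower)")
  structure(list(reso = reso, reso_cchalf = reso_cchalf),
            class = "resolution_config")
}
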