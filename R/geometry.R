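# Subregion bookkeeping: equal-volume dorso-ventral splitting of the core
# and concentric-shell zoning of space around cell bodies.

#' Split a binary mask into equal-volume dorsal and ventral halves
#'
#' A single cut plane along the dorso-ventral axis is chosen so that the two
#' halves' voxel volumes are as equal as possible (exhaustively optimal over
#' cut positions); among equally good cuts the one assigning more volume to
#' the dorsal side wins.  The halves are disjoint and their union is the
#' input, so dorsal + ventral volume equals the input volume exactly, and
#' the imbalance can never exceed the volume of one cut-plane slab.
#'
#' @param mask an [lc_mask()] (nonempty).
#' @param axis `"z"`, `"y"` or `"x"`; the dorso-ventral axis (default y).
#' @param dorsal_low if `TRUE` (default) the dorsal side is towards low
#'   coordinates on `axis`.
#' @return list with `dorsal` and `ventral` ([lc_mask()]), `cut_index`
#'   (number of slices on the dorsal side) and `cut_um` (physical cut
#'   coordinate).
#' @export
split_dorsoventral <- function(mask, axis = "y", dorsal_low = TRUE) {
  stopifnot(inherits(mask, "lc_mask"))
  if (!any(mask$data)) stop("mask is empty")
  ax <- match(match.arg(axis, c("z", "y", "x")), c("z", "y", "x"))
  d <- dim(mask$data)
  counts <- apply(mask$data, ax, sum)
  n <- length(counts)
  total <- sum(counts)
  low <- cumsum(counts)                 # volume on the low-coordinate side
  imbalance <- abs(2 * low - total)     # after k slices on the low side
  k <- which(imbalance == min(imbalance))
  # ties: put the extra slab on the dorsal side
  k <- if (dorsal_low) max(k) else min(k)
  sel_low <- seq_len(n) <= k
  slicer <- function(keep) {
    m <- mask$data
    if (ax == 1) m[!keep, , ] <- FALSE
    else if (ax == 2) m[, !keep, ] <- FALSE
    else m[, , !keep] <- FALSE
    lc_mask(m, mask$voxel_size_um)
  }
  dorsal <- slicer(if (dorsal_low) sel_low else !sel_low)
  ventral <- slicer(if (dorsal_low) !sel_low else sel_low)
  vs_ax <- mask$voxel_size_um[ax]
  list(dorsal = dorsal, ventral = ventral,
       cut_index = k, cut_um = (k - 0.5) * vs_ax, axis = axis,
       dorsal_low = dorsal_low)
}

#' Assign voxels to concentric shells around cell bodies
#'
#' Every foreground voxel of `query_mask` is assigned to the shell of its
#' *nearest* centroid (an exact partition; overlapping spheres from multiple
#' cells are not double counted): index 0 for distances below
#' `inner_edge_um`, index k (1..n_shells) for distances in
#' `[inner + (k-1) w, inner + k w)`, and the sentinel -1 beyond the last
#' shell.  Distances are physical um from voxel centres.  The default inner
#' edge of 50 um reflects the 100 um-wide zoning whose reference band is
#' 50-150 um, implying a soma-proximal 0-50 um band.
#'
#' @param centroids n x 3 matrix (x, y, z um) or a CellTable data frame.
#' @param query_mask an [lc_mask()].
#' @param inner_edge_um,width_um,n_shells shell geometry (um).
#' @return integer array of shell indices (`NA` outside `query_mask`).
#' @export
shell_zones <- function(centroids, query_mask, inner_edge_um = 50,
                        width_um = 100, n_shells = 5) {
  stopifnot(inherits(query_mask, "lc_mask"))
  pts <- as_points(centroids)
  if (nrow(pts) < 1) stop("need at least one centroid")
  if (inner_edge_um < 0 || width_um <= 0 || n_shells < 1)
    stop("invalid shell geometry")
  d <- dim(query_mask$data)
  fg <- which(query_mask$data)
  out <- array(NA_integer_, dim = d)
  if (!length(fg)) return(out)
  dist <- cpp_min_dist_to_points(as.integer(fg), as.integer(d),
                                 query_mask$voxel_size_um, pts)
  idx <- ifelse(dist < inner_edge_um, 0L,
                1L + as.integer(floor((dist - inner_edge_um) / width_um)))
  idx[idx > n_shells] <- -1L
  out[fg] <- idx
  out
}

#' Shell-resolved AT8 process volume profile
#'
#' Measures the AT8+ process volume in each concentric shell around the
#' supplied cell bodies, optionally restricted to one subregion, and
#' normalizes to fractions over the shells (the "outside" sentinel volume
#' is reported separately and excluded from the normalization).
#'
#' @param process_mask an [lc_mask()] of AT8+ process voxels.
#' @param centroids cell-body centroids (x, y, z um).
#' @param regions optional [region_mask()]; `region` names the subregion to
#'   restrict to.
#' @param region subregion name used when `regions` is given.
#' @param inner_edge_um,width_um,n_shells shell geometry.
#' @return data frame (class `shell_profile`) with columns `shell`,
#'   `r_lo_um`, `r_hi_um`, `process_volume_um3`, `fraction`; attributes
#'   `n_cells`, `outside_volume_um3` and `empty` (TRUE when there is no
#'   process signal, in which case the profile is all zero).
#' @export
shell_profile <- function(process_mask, centroids, regions = NULL,
                          region = "core", inner_edge_um = 50,
                          width_um = 100, n_shells = 5) {
  stopifnot(inherits(process_mask, "lc_mask"))
  query <- process_mask
  if (!is.null(regions)) {
    rm_ <- mask_from_regions(regions, region)
    query <- lc_mask(process_mask$data & rm_$data, process_mask$voxel_size_um)
  }
  vox3 <- voxel_volume_um3(process_mask)
  shells <- seq(0, n_shells)
  r_lo <- c(0, inner_edge_um + (shells[-1] - 1) * width_um)
  r_hi <- c(inner_edge_um, inner_edge_um + shells[-1] * width_um)
  empty <- !any(query$data)
  if (empty) {
    vol <- rep(0, n_shells + 1)
    outside <- 0
  } else {
    z <- shell_zones(centroids, query, inner_edge_um, width_um, n_shells)
    zz <- z[!is.na(z)]
    vol <- vapply(shells, function(k) sum(zz == k) * vox3, numeric(1))
    outside <- sum(zz == -1L) * vox3
  }
  frac <- if (sum(vol) > 0) vol / sum(vol) else rep(0, length(vol))
  out <- data.frame(shell = shells, r_lo_um = r_lo, r_hi_um = r_hi,
                    process_volume_um3 = vol, fraction = frac)
  attr(out, "n_cells") <- nrow(as_points(centroids))
  attr(out, "outside_volume_um3") <- outside
  attr(out, "empty") <- empty
  class(out) <- c("shell_profile", "data.frame")
  out
}
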