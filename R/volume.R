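# Core containers: volumes, binary masks and labelled region masks.
# Arrays are [z, y, x]; voxel_size_um is (dz, dy, dx); coordinates are
# (x, y, z) um with the origin at the centre of voxel (0, 0, 0).

#' Single-channel volumetric image
#'
#' @param data 3D numeric array indexed `[z, y, x]` with non-negative
#'   intensities.
#' @param voxel_size_um positive voxel dimensions `(dz, dy, dx)` in um.
#'   The study's native sampling is `c(2, 1.51, 1.51)`.
#' @param channel `"TH"` (noradrenergic marker) or `"AT8"`
#'   (hyperphosphorylated tau).
#' @return An object of class `lc_volume`.
#' @export
lc_volume <- function(data, voxel_size_um, channel = c("TH", "AT8")) {
  channel <- match.arg(channel)
  stopifnot(is.array(data), length(dim(data)) == 3)
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) == 1) voxel_size_um <- rep(voxel_size_um, 3)
  if (length(voxel_size_um) != 3 || any(!is.finite(voxel_size_um)) ||
      any(voxel_size_um <= 0))
    stop("voxel_size_um must be three positive finite values (dz, dy, dx)")
  if (min(data, na.rm = TRUE) < 0) stop("intensities must be non-negative")
  structure(list(data = data, voxel_size_um = voxel_size_um, channel = channel),
            class = "lc_volume")
}

#' @export
print.lc_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lc_volume> channel %s, %d x %d x %d (z,y,x), voxel %.3g x %.3g x %.3g um\n",
              x$channel, d[1], d[2], d[3],
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3]))
  invisible(x)
}

#' Binary mask with physical voxel size
#'
#' @param data 3D logical array `[z, y, x]`.
#' @param voxel_size_um voxel dimensions `(dz, dy, dx)` in um.
#' @return An object of class `lc_mask`.
#' @export
lc_mask <- function(data, voxel_size_um) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  storage.mode(data) <- "logical"
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) == 1) voxel_size_um <- rep(voxel_size_um, 3)
  stopifnot(length(voxel_size_um) == 3, all(voxel_size_um > 0))
  structure(list(data = data, voxel_size_um = voxel_size_um), class = "lc_mask")
}

#' @export
print.lc_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<lc_mask> %d x %d x %d (z,y,x), %d foreground voxels, voxel %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3], sum(x$data),
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3]))
  invisible(x)
}

#' Labelled subregion mask of the LC/PC complex
#'
#' @param labels 3D integer array `[z, y, x]`; 0 = background.
#' @param voxel_size_um voxel dimensions `(dz, dy, dx)` in um.
#' @param label_names named integer vector mapping subregion names to labels;
#'   must cover every nonzero label present.
#' @return An object of class `lc_regionmask`.
#' @export
region_mask <- function(labels, voxel_size_um,
                        label_names = c(core = 1L, shell = 2L, A4 = 3L,
                                        subcoeruleus = 4L)) {
  stopifnot(is.array(labels), length(dim(labels)) == 3)
  storage.mode(labels) <- "integer"
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) == 1) voxel_size_um <- rep(voxel_size_um, 3)
  stopifnot(length(voxel_size_um) == 3, all(voxel_size_um > 0))
  present <- setdiff(unique(as.integer(labels)), 0L)
  if (!all(present %in% label_names))
    stop("labels present in the grid but missing from label_names: ",
         paste(setdiff(present, label_names), collapse = ", "))
  structure(list(labels = labels, voxel_size_um = voxel_size_um,
                 label_names = label_names),
            class = "lc_regionmask")
}

#' @export
print.lc_regionmask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<lc_regionmask> %d x %d x %d (z,y,x), voxel %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3],
              x$voxel_size_um[1], x$voxel_size_um[2], x$voxel_size_um[3]))
  for (nm in names(x$label_names)) {
    n <- sum(x$labels == x$label_names[[nm]])
    cat(sprintf("  %-14s label %d: %d voxels (%.4g mm^3)\n", nm,
                x$label_names[[nm]], n, n * voxel_volume_um3(x) / 1e9))
  }
  invisible(x)
}

#' Physical volume of one voxel in cubic micrometres
#' @param x an `lc_volume`, `lc_mask` or `lc_regionmask`.
#' @return scalar um^3.
#' @export
voxel_volume_um3 <- function(x) prod(x$voxel_size_um)

#' Extract a binary mask for one or more subregions
#'
#' @param regions an `lc_regionmask`.
#' @param which character vector of subregion names (e.g. `"core"`).
#' @return An `lc_mask` covering the union of the requested subregions.
#' @export
mask_from_regions <- function(regions, which = "core") {
  stopifnot(inherits(regions, "lc_regionmask"))
  bad <- setdiff(which, names(regions$label_names))
  if (length(bad)) stop("unknown subregion(s): ", paste(bad, collapse = ", "))
  keep <- regions$label_names[which]
  m <- array(regions$labels %in% keep, dim = dim(regions$labels))
  lc_mask(m, regions$voxel_size_um)
}

# ---- internal coordinate helpers -------------------------------------------

# 1-based linear indices -> (x, y, z) um coordinates of voxel centres
idx_to_um <- function(idx, dim, voxel_size_um) {
  i0 <- idx - 1L
  z <- i0 %% dim[1]
  r <- i0 %/% dim[1]
  y <- r %% dim[2]
  x <- r %/% dim[2]
  cbind(x = x * voxel_size_um[3], y = y * voxel_size_um[2],
        z = z * voxel_size_um[1])
}

# (x, y, z) um -> 1-based linear voxel index (NA when outside the grid)
um_to_idx <- function(pts, dim, voxel_size_um) {
  pts <- as_points(pts)
  ix <- as.integer(round(pts[, 1] / voxel_size_um[3]))
  iy <- as.integer(round(pts[, 2] / voxel_size_um[2]))
  iz <- as.integer(round(pts[, 3] / voxel_size_um[1]))
  ok <- ix >= 0 & iy >= 0 & iz >= 0 &
    ix < dim[3] & iy < dim[2] & iz < dim[1]
  out <- rep(NA_integer_, nrow(pts))
  out[ok] <- iz[ok] + dim[1] * (iy[ok] + dim[2] * ix[ok]) + 1L
  out
}

# coerce to an n x 3 numeric matrix with columns x, y, z (um)
as_points <- function(pts) {
  if (is.data.frame(pts)) {
    if (all(c("x_um", "y_um", "z_um") %in% names(pts)))
      pts <- as.matrix(pts[, c("x_um", "y_um", "z_um")])
    else pts <- as.matrix(pts[, 1:3])
  }
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  pts <- unname(as.matrix(pts))
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3) stop("points must have 3 columns (x, y, z) in um")
  colnames(pts) <- c("x", "y", "z")
  pts
}

# TRUE for points whose containing voxel is inside the logical mask
points_in_mask <- function(pts, mask) {
  idx <- um_to_idx(pts, dim(mask$data), mask$voxel_size_um)
  !is.na(idx) & mask$data[idx]
}

# run code with a temporary RNG state seeded from `seed` (NULL = leave alone)
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
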