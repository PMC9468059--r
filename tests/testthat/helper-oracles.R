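# Independent oracles and shared fixtures.  Oracles are deliberately naive
# (all-pairs, exhaustive scans) and stay independent of the package code
# paths they check.

# all-pairs brute-force nearest-neighbour distances
brute_nn <- function(pts) {
  n <- nrow(pts)
  D <- as.matrix(stats::dist(pts))
  diag(D) <- Inf
  unname(apply(D, 1, min))
}

# brute-force connected components under a distance threshold (strict <)
brute_components <- function(pts, thr) {
  n <- nrow(pts)
  if (n == 0) return(integer(0))
  D <- as.matrix(stats::dist(pts))
  adj <- D < thr
  diag(adj) <- FALSE
  comp <- integer(n)
  k <- 0
  for (i in seq_len(n)) {
    if (comp[i]) next
    k <- k + 1
    q <- i
    comp[i] <- k
    while (length(q)) {
      c0 <- q[1]
      q <- q[-1]
      nb <- which(adj[c0, ] & comp == 0L)
      comp[nb] <- k
      q <- c(q, nb)
    }
  }
  comp
}

# greedy one-to-one matching of detections to truth within a tolerance;
# returns the number of matched pairs
greedy_match <- function(truth, det, tol_um = 10) {
  if (nrow(truth) == 0 || nrow(det) == 0) return(0L)
  D <- as.matrix(stats::dist(rbind(truth, det)))
  D <- D[seq_len(nrow(truth)), nrow(truth) + seq_len(nrow(det)), drop = FALSE]
  used <- logical(nrow(det))
  hits <- 0L
  for (i in order(apply(D, 1, min))) {
    j <- which.min(ifelse(used, Inf, D[i, ]))
    if (is.finite(D[i, j]) && D[i, j] <= tol_um) {
      used[j] <- TRUE
      hits <- hits + 1L
    }
  }
  hits
}

xyz <- function(df) as.matrix(df[, c("x_um", "y_um", "z_um")])

# small box mask: side_um cube at voxel_um resolution
box_mask <- function(side_um = 1000, voxel_um = 20) {
  n <- round(side_um / voxel_um)
  lc_mask(array(TRUE, c(n, n, n)), voxel_um)
}

# tube mask (cylinder along x), as used by the NNI acceptance target
tube_mask <- function(radius_um = 500, length_um = 4000, voxel_um = 20) {
  nz <- ny <- round(2.2 * radius_um / voxel_um)
  nx <- round(length_um / voxel_um)
  zc <- (nz - 1) * voxel_um / 2
  yc <- (ny - 1) * voxel_um / 2
  zum <- (seq_len(nz) - 1) * voxel_um
  yum <- (seq_len(ny) - 1) * voxel_um
  rad2 <- outer((zum - zc)^2, (yum - yc)^2, "+")
  a <- array(rad2 <= radius_um^2, c(nz, ny, nx))
  lc_mask(a, voxel_um)
}

# moderate phantom used by several recovery tests (4 um voxels)
recovery_phantom <- function(seed = 7, n_core = 80, at8 = 0.5,
                             dorsal_bias = 0.7) {
  phantom_config(grid_shape = c(z = 150, y = 160, x = 250),
                 voxel_size_um = c(4, 4, 4),
                 core_radius_um = 150, core_length_um = 700,
                 region_counts = c(core = n_core, shell = 0, A4 = 0,
                                   subcoeruleus = 0),
                 at8_fraction = at8, dorsal_bias = dorsal_bias,
                 seed = seed)
}
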