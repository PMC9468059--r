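# Spatial statistics: nearest-neighbour distances, the Monte-Carlo
# nearest-neighbour index (NNI), dense-cell detection, duo/minigroup
# component splitting and neighbouring-cell analysis.

#' Per-point 3D nearest-neighbour distances
#'
#' Euclidean nearest-neighbour distance for every point, via a uniform-grid
#' spatial index (exact; the test suite asserts agreement with the all-pairs
#' brute force).  Duplicate coordinates are allowed, give NN distance 0 and
#' are flagged via the `"duplicates"` attribute.
#'
#' @param points n x 3 matrix of (x, y, z) um coordinates (n >= 2).
#' @return numeric vector of NN distances (um).
#' @export
nn_distances <- function(points) {
  pts <- as_points(points)
  if (nrow(pts) < 2) stop("need at least 2 points")
  d <- cpp_nn_dist(pts)
  if (any(d == 0)) attr(d, "duplicates") <- which(d == 0)
  d
}

#' Monte-Carlo nearest-neighbour index
#'
#' NNI = (observed mean NN distance) / (mean over simulations of the mean NN
#' distance of equally many uniform-random points in the same mask).  Values
#' below 1 indicate clustering; the Monte-Carlo null inside the same mask
#' inherently accounts for boundary effects, so no analytic edge correction
#' is applied.  The denominator averages per-simulation means; because every
#' simulation draws exactly `nrow(points)` points, this coincides with the
#' pooled-distance average.
#'
#' @param points observed points (x, y, z um), all inside `mask`.
#' @param mask an [lc_mask()] (or [lc_regionmask()] plus `regions`).
#' @param n_sims number of CSR simulations (>= 1).
#' @param seed RNG seed for the simulations.
#' @param regions subregion selector when `mask` is a region mask.
#' @return object of class `nni_result`.
#' @export
nni <- function(points, mask, n_sims = 100, seed = NULL, regions = "core") {
  pts <- as_points(points)
  if (nrow(pts) < 2) stop("need at least 2 points inside the mask")
  if (n_sims < 1) stop("n_sims must be >= 1")
  if (inherits(mask, "lc_regionmask")) mask <- mask_from_regions(mask, regions)
  inside <- points_in_mask(pts, mask)
  if (!all(inside))
    stop("points outside the mask: rows ",
         paste(utils::head(which(!inside), 10), collapse = ", "),
         if (sum(!inside) > 10) " ..." else "")
  obs <- nn_distances(pts)
  n <- nrow(pts)
  sim_means <- with_seed(seed, {
    vapply(seq_len(n_sims), function(s) {
      mean(nn_distances(make_point_pattern(mask, n, "CSR")))
    }, numeric(1))
  })
  mean_sim <- mean(sim_means)
  structure(list(n_points = n,
                 observed_nn_um = as.numeric(obs),
                 mean_observed_um = mean(obs),
                 sim_means_um = sim_means,
                 mean_simulated_um = mean_sim,
                 nni = mean(obs) / mean_sim,
                 n_sims = n_sims,
                 seed = seed),
            class = "nni_result")
}

#' @export
print.nni_result <- function(x, ...) {
  cat(sprintf("<nni_result> n=%d, observed mean NN %.2f um, simulated %.2f um (%d sims), NNI = %.3f\n",
              x$n_points, x$mean_observed_um, x$mean_simulated_um,
              x$n_sims, x$nni))
  invisible(x)
}

#' Paired t test of simulated vs observed mean NN distances
#'
#' Classical paired Student t on the per-case differences.  When the
#' differences have zero standard deviation the test is degenerate: t = 0,
#' p = 1 for identically zero differences, otherwise t = +/-Inf with p = 0
#' (documented convention).
#'
#' @param observed,simulated equal-length vectors of per-case mean NN
#'   distances (n >= 2 pairs).
#' @return list with `statistic`, `df`, `p_value`, `mean_difference`, `n`.
#' @export
paired_sim_vs_obs_test <- function(observed, simulated) {
  if (length(observed) != length(simulated))
    stop("observed and simulated must have equal length")
  n <- length(observed)
  if (n < 2) stop("need at least 2 pairs")
  d <- observed - simulated
  s <- sd(d)
  if (s == 0) {
    if (mean(d) == 0) {
      t <- 0
      p <- 1
    } else {
      t <- sign(mean(d)) * Inf
      p <- 0
    }
  } else {
    t <- mean(d) / (s / sqrt(n))
    p <- 2 * pt(-abs(t), df = n - 1)
  }
  list(statistic = t, df = n - 1, p_value = p, mean_difference = mean(d),
       n = n)
}

#' Flag dense (clustered) cells
#'
#' A cell is *dense* when its nearest-neighbour distance is strictly below
#' `factor` times the mean NN distance of the pattern (the criterion is
#' "closer than", hence strict; the default factor is 0.75).
#'
#' @param points (x, y, z um) coordinates (n >= 2).
#' @param factor threshold factor in (0, 1].
#' @return list with `dense` (logical), `dense_threshold_um`, `nn_um`.
#' @export
dense_cells <- function(points, factor = 0.75) {
  if (!is.numeric(factor) || length(factor) != 1 || factor <= 0 || factor > 1)
    stop("factor must lie in (0, 1]")
  nn <- nn_distances(points)
  thr <- factor * mean(nn)
  list(dense = as.numeric(nn) < thr, dense_threshold_um = thr,
       nn_um = as.numeric(nn))
}

#' Split dense cells into duos, minigroups and large groups
#'
#' Builds a graph on the dense cells with edges between pairs strictly
#' closer than `link_threshold_um` (default: the dense threshold itself) and
#' extracts connected components: size 2 = duo, size 3-9 = minigroup,
#' size > 9 = large group (counted separately; with the default link
#' threshold every dense cell has a dense partner in range, so singleton
#' components only arise with a custom, smaller link threshold).
#'
#' @param points all cell coordinates (x, y, z um).
#' @param dense logical dense flags (from [dense_cells()]).
#' @param link_threshold_um linkage distance (um).
#' @return list with `component_id` (per cell, NA when not dense),
#'   `component_sizes`, `duo_count`, `minigroup_count`, `large_group_count`,
#'   `singleton_count`.
#' @export
split_components <- function(points, dense, link_threshold_um) {
  pts <- as_points(points)
  stopifnot(length(dense) == nrow(pts))
  comp <- rep(NA_integer_, nrow(pts))
  di <- which(dense)
  if (!length(di)) {
    return(list(component_id = comp, component_sizes = integer(0),
                duo_count = 0L, minigroup_count = 0L,
                large_group_count = 0L, singleton_count = 0L))
  }
  dp <- pts[di, , drop = FALSE]
  m <- length(di)
  adj <- as.matrix(stats::dist(dp)) < link_threshold_um
  diag(adj) <- FALSE
  cid <- integer(m)
  ncomp <- 0
  for (i in seq_len(m)) {
    if (cid[i]) next
    ncomp <- ncomp + 1
    queue <- i
    cid[i] <- ncomp
    while (length(queue)) {
      c0 <- queue[[1]]
      queue <- queue[-1]
      nbrs <- which(adj[c0, ] & cid == 0L)
      cid[nbrs] <- ncomp
      queue <- c(queue, nbrs)
    }
  }
  comp[di] <- cid
  sizes <- as.integer(table(cid))
  list(component_id = comp,
       component_sizes = sizes,
       duo_count = sum(sizes == 2L),
       minigroup_count = sum(sizes >= 3L & sizes <= 9L),
       large_group_count = sum(sizes > 9L),
       singleton_count = sum(sizes == 1L))
}

#' Flag immediate neighbouring AT8+ cells
#'
#' A dense cell is *neighbouring* when its NN distance is equal to or
#' shorter than the mean NN distance of the TH+ cells of the same scan
#' (non-strict comparison per the definition "equal or shorter").
#'
#' @param nn_um per-cell NN distances of the AT8+ pattern.
#' @param dense logical dense flags.
#' @param th_mean_nn_um mean NN distance of the TH+ cells (>= 0).
#' @return logical flags (a subset of `dense`).
#' @export
neighbouring_cells <- function(nn_um, dense, th_mean_nn_um) {
  if (!is.numeric(th_mean_nn_um) || th_mean_nn_um < 0)
    stop("th_mean_nn_um must be non-negative")
  stopifnot(length(nn_um) == length(dense))
  dense & (nn_um <= th_mean_nn_um)
}

#' Normalize a count to 100 AT8+ cells
#'
#' @param count count(s) to normalize.
#' @param n_at8_cells number of AT8+ cells; 0 gives NA with a warning.
#' @return `100 * count / n_at8_cells`.
#' @export
per_hundred <- function(count, n_at8_cells) {
  if (n_at8_cells == 0) {
    warning("n_at8_cells is 0: per-100 rate undefined")
    return(rep(NA_real_, length(count)))
  }
  100 * count / n_at8_cells
}

#' Full dense/duo/minigroup/neighbouring cluster analysis
#'
#' Convenience wrapper chaining [dense_cells()], [split_components()],
#' [neighbouring_cells()] and [per_hundred()] for one case/subregion.
#'
#' @param points AT8+ cell coordinates (x, y, z um).
#' @param factor dense threshold factor (default 0.75).
#' @param link_threshold_um linkage distance; default = dense threshold.
#' @param th_mean_nn_um mean TH+ NN distance (enables neighbouring flags).
#' @return object of class `cluster_result`.
#' @export
cluster_analysis <- function(points, factor = 0.75, link_threshold_um = NULL,
                             th_mean_nn_um = NULL) {
  pts <- as_points(points)
  dc <- dense_cells(pts, factor)
  link <- if (is.null(link_threshold_um)) dc$dense_threshold_um else link_threshold_um
  sc <- split_components(pts, dc$dense, link)
  n <- nrow(pts)
  nb <- if (!is.null(th_mean_nn_um))
    neighbouring_cells(dc$nn_um, dc$dense, th_mean_nn_um) else NULL
  res <- list(n_points = n,
              dense = dc$dense,
              dense_threshold_um = dc$dense_threshold_um,
              link_threshold_um = link,
              nn_um = dc$nn_um,
              component_id = sc$component_id,
              component_sizes = sc$component_sizes,
              duo_count = sc$duo_count,
              minigroup_count = sc$minigroup_count,
              large_group_count = sc$large_group_count,
              singleton_count = sc$singleton_count,
              neighbouring = nb,
              duos_per_100 = per_hundred(sc$duo_count, n),
              minigroups_per_100 = per_hundred(sc$minigroup_count, n),
              neighbouring_per_100 = if (!is.null(nb))
                per_hundred(sum(nb), n) else NA_real_)
  class(res) <- "cluster_result"
  res
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cells, %d dense (thr %.2f um): %d duos, %d minigroups, %d large groups\n",
              x$n_points, sum(x$dense), x$dense_threshold_um,
              x$duo_count, x$minigroup_count, x$large_group_count))
  if (!is.null(x$neighbouring))
    cat(sprintf("  neighbouring cells: %d (%.2f per 100)\n",
                sum(x$neighbouring), x$neighbouring_per_100))
  invisible(x)
}
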