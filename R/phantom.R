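# Synthetic LC/PC phantom generator.  Emulates the statistical structure of
# cleared-tissue two-channel (TH / AT8) light-sheet volumes: a tube-shaped,
# cell-dense core with surrounding low-density subregions, stage-dependent
# AT8+ fractions, a dorsal-over-ventral AT8 bias, clustered AT8+ somas
# (duos/minigroups), soma ellipsoids with dendrite and axon tubes, and
# microscope noise.  Every run records ground truth for recovery tests.

BRAAK_GROUPS <- c("B0", "B12", "B34", "B6")
FORM_LEVELS <- c("intact_pretangle", "partial_atrophy", "severe_atrophy",
                 "tangle_like")

# process-volume completeness per degeneration form (dendritic tree trimming)
FORM_PROCESS_FACTOR <- c(intact_pretangle = 1, partial_atrophy = 0.6,
                         severe_atrophy = 0.2, tangle_like = 0)

default_form_probs <- function(group) {
  switch(group,
    B0  = c(intact_pretangle = 0.97, partial_atrophy = 0.03,
            severe_atrophy = 0, tangle_like = 0),
    B12 = c(intact_pretangle = 0.80, partial_atrophy = 0.15,
            severe_atrophy = 0.04, tangle_like = 0.01),
    B34 = c(intact_pretangle = 0.40, partial_atrophy = 0.30,
            severe_atrophy = 0.20, tangle_like = 0.10),
    B6  = c(intact_pretangle = 0.15, partial_atrophy = 0.30,
            severe_atrophy = 0.30, tangle_like = 0.25))
}

#' Configuration of the synthetic LC/PC phantom
#'
#' Defaults describe a desk-scale stand-in for the study system: a
#' caudo-rostrally elongated cell-dense core tube with an annular shell
#' around its rostral third, a dorsomedial A4 band and a ventrolateral
#' scattered subcoeruleus.  The native scan sampling is 1.51 x 1.51 x 2 um;
#' the phantom defaults to a 10 um isotropic grid because all geometry is
#' computed in physical um and is therefore voxel-size invariant.  Soma
#' semi-axes (default 15 x 9 x 9 um) are an assumption, not a measured value.
#'
#' @param grid_shape voxel counts `(z, y, x)`.
#' @param voxel_size_um voxel dimensions `(dz, dy, dx)` in um.
#' @param core_radius_um,core_length_um geometry of the core tube.
#' @param shell_outer_factor outer radius of the shell annulus as a multiple
#'   of `core_radius_um`.
#' @param region_densities TH+ cells per mm^3 per subregion (named).
#' @param region_counts optional named integer vector of exact TH+ cell
#'   counts per subregion; overrides `region_densities` where given.
#' @param braak_group one of `"B0"`, `"B12"`, `"B34"`, `"B6"`.
#' @param at8_fraction fraction of TH+ cells that are AT8+: either a single
#'   number for the chosen group or a named vector over groups.  The default
#'   (0.02 / 0.05 / 0.15 / 0.6) mirrors the qualitative increase of burden
#'   with stage and is a free generator choice, not a measured claim.
#' @param dorsal_bias probability that a core AT8+ cell lies in the dorsal
#'   half of the core.
#' @param cluster_params list with `mean_size` (mean cells per cluster),
#'   `max_size` (cap, clusters beyond the duo/minigroup range are not
#'   generated by default), `p_clustered` (fraction of AT8+ cells recruited
#'   via clusters rather than singly) and `sigma_um` (Gaussian dispersion
#'   used by [make_point_pattern()] in `"thomas"` mode).
#' @param duo_rate probability that a placed TH+ soma receives a close
#'   "hugging" partner soma.
#' @param body_fraction target AT8 cell-body share of the total AT8+ volume
#'   for a morphologically intact cell (the core body:process ratio is about
#'   1:1, hence the default 0.5).  Degenerating forms scale their process
#'   volume down by `FORM_PROCESS_FACTOR`.
#' @param soma_axes_um ellipsoid semi-axes (along, across, across) in um.
#' @param dendrite_radius_um,axon_radius_um tube radii in um (proximal
#'   dendrites are 3-4 um thick, axons 1-2 um thin).
#' @param dendrite_length_um maximum dendrite extent from the soma.
#' @param n_dendrites dendrites per AT8+ cell (LC neurons carry 3-5).
#' @param min_separation_um hard-core minimum distance between soma centres
#'   (somas do not interpenetrate).
#' @param form_probs optional probabilities over the four degeneration forms;
#'   default depends on `braak_group`.
#' @param p_low_intensity,p_inhomogeneous probabilities of the "low" soma
#'   intensity signature (0.3x amplitude) and of granular multiplicative
#'   soma texture.
#' @param noise list with `background`, `amplitude` and `gaussian_sd`
#'   (16-bit-scale intensity units).
#' @param seed integer RNG seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(z = 100, y = 140, x = 320),
                           voxel_size_um = c(10, 10, 10),
                           core_radius_um = 300,
                           core_length_um = 2400,
                           shell_outer_factor = 1.5,
                           region_densities = c(core = 800, shell = 120,
                                                A4 = 100, subcoeruleus = 80),
                           region_counts = NULL,
                           braak_group = "B12",
                           at8_fraction = c(B0 = 0.02, B12 = 0.05,
                                            B34 = 0.15, B6 = 0.6),
                           dorsal_bias = 0.65,
                           cluster_params = list(mean_size = 3, max_size = 9,
                                                 p_clustered = 0.6,
                                                 sigma_um = 30),
                           duo_rate = 0.03,
                           body_fraction = 0.5,
                           soma_axes_um = c(15, 9, 9),
                           dendrite_radius_um = 3.5,
                           axon_radius_um = 1.5,
                           dendrite_length_um = 150,
                           n_dendrites = 4,
                           min_separation_um = 32,
                           form_probs = NULL,
                           p_low_intensity = 0.25,
                           p_inhomogeneous = 0.25,
                           noise = list(background = 200, amplitude = 2000,
                                        gaussian_sd = 100),
                           seed = 1L) {
  braak_group <- match.arg(braak_group, BRAAK_GROUPS)
  if (length(voxel_size_um) == 1) voxel_size_um <- rep(voxel_size_um, 3)
  if (length(at8_fraction) > 1) {
    if (is.null(names(at8_fraction)))
      names(at8_fraction) <- BRAAK_GROUPS[seq_along(at8_fraction)]
    at8 <- unname(at8_fraction[[braak_group]])
  } else at8 <- unname(at8_fraction)
  if (is.null(form_probs)) form_probs <- default_form_probs(braak_group)
  form_probs <- form_probs / sum(form_probs)

  cfg <- list(grid_shape = as.integer(grid_shape),
              voxel_size_um = as.numeric(voxel_size_um),
              core_radius_um = core_radius_um,
              core_length_um = core_length_um,
              shell_outer_factor = shell_outer_factor,
              region_densities = region_densities,
              region_counts = region_counts,
              braak_group = braak_group,
              at8_fraction = at8,
              at8_fraction_by_group = if (length(at8_fraction) > 1)
                at8_fraction else NULL,
              dorsal_bias = dorsal_bias,
              cluster_params = cluster_params,
              duo_rate = duo_rate,
              body_fraction = body_fraction,
              soma_axes_um = as.numeric(soma_axes_um),
              dendrite_radius_um = dendrite_radius_um,
              axon_radius_um = axon_radius_um,
              dendrite_length_um = dendrite_length_um,
              n_dendrites = n_dendrites,
              min_separation_um = min_separation_um,
              form_probs = form_probs,
              p_low_intensity = p_low_intensity,
              p_inhomogeneous = p_inhomogeneous,
              noise = noise,
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  geom <- c(cfg$voxel_size_um, cfg$core_radius_um, cfg$core_length_um,
            cfg$soma_axes_um, cfg$dendrite_radius_um, cfg$axon_radius_um,
            cfg$dendrite_length_um, cfg$min_separation_um)
  if (any(!is.finite(geom)) || any(geom <= 0))
    stop("all geometric parameters must be positive and finite")
  fr <- c(cfg$at8_fraction, cfg$dorsal_bias, cfg$body_fraction)
  if (any(fr < 0) || any(fr > 1))
    stop("at8_fraction, dorsal_bias and body_fraction must lie in [0, 1]")
  if (any(cfg$grid_shape < 2)) stop("grid_shape too small")
  ext <- (cfg$grid_shape - 1) * cfg$voxel_size_um # (z, y, x) physical extent
  if (cfg$core_length_um > ext[3] ||
      2 * cfg$core_radius_um > ext[2] || 2 * cfg$core_radius_um > ext[1])
    stop("core tube does not fit in the grid: increase grid_shape or shrink the core")
  invisible(cfg)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat(sprintf("<phantom_config> %s, grid %s (z,y,x) @ %s um, core r=%g L=%g um, AT8 fraction %.3g, seed %d\n",
              x$braak_group, paste(x$grid_shape, collapse = "x"),
              paste(signif(x$voxel_size_um, 3), collapse = "x"),
              x$core_radius_um, x$core_length_um, x$at8_fraction, x$seed))
  invisible(x)
}

#' Build the labelled LC/PC subregion mask for a phantom
#'
#' Deterministic (seed-independent) geometry: a caudo-rostrally elongated
#' cylinder (core), an annular shell around its rostral third, a dorsomedial
#' A4 band and a ventrolateral set of subcoeruleus ellipsoids.  Labels are
#' pairwise disjoint; structures that fall outside the grid are clipped.
#'
#' @param config a [phantom_config()].
#' @return An [region_mask()] with labels core=1, shell=2, A4=3,
#'   subcoeruleus=4.
#' @export
make_region_masks <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  d <- config$grid_shape            # (nz, ny, nx)
  vs <- config$voxel_size_um        # (dz, dy, dx)
  R <- config$core_radius_um
  L <- config$core_length_um
  zc <- (d[1] - 1) * vs[1] / 2
  yc <- (d[2] - 1) * vs[2] / 2
  xc <- (d[3] - 1) * vs[3] / 2

  zum <- (seq_len(d[1]) - 1) * vs[1]
  yum <- (seq_len(d[2]) - 1) * vs[2]
  xum <- (seq_len(d[3]) - 1) * vs[3]

  # radial^2 distance from the core axis, per (z, y) plane position
  rad2 <- outer((zum - zc)^2, (yum - yc)^2, "+") # nz x ny
  in_x_core <- xum >= (xc - L / 2) & xum <= (xc + L / 2)
  labels <- array(0L, dim = d)

  core_zy <- rad2 <= R^2
  labels[, , in_x_core][rep(core_zy, sum(in_x_core))] <- 1L

  # shell: annulus around the rostral third of the core
  in_x_shell <- xum >= (xc + L / 6) & xum <= (xc + L / 2)
  shell_zy <- rad2 > R^2 & rad2 <= (config$shell_outer_factor * R)^2
  sub <- labels[, , in_x_shell]
  sub[rep(shell_zy, sum(in_x_shell)) & sub == 0L] <- 2L
  labels[, , in_x_shell] <- sub

  # A4: dorsomedial band (dorsal = low y) over the rostral half
  in_x_a4 <- xum >= xc & xum <= (xc + L / 2)
  a4_zy <- outer(abs(zum - zc) <= 0.8 * R,
                 (yum >= yc - 2.1 * R) & (yum <= yc - 1.6 * R), "&")
  sub <- labels[, , in_x_a4]
  sub[rep(a4_zy, sum(in_x_a4)) & sub == 0L] <- 3L
  labels[, , in_x_a4] <- sub

  # subcoeruleus: scattered ventrolateral ellipsoids (deterministic layout)
  sc_ax <- c(150, 120, 100) * (R / 300)  # semi-axes (x, y, z) scale with core
  sc_fracs <- c(0.12, 0.32, 0.52, 0.72)  # caudal half, along the tube
  sc_side <- c(1, -1, 1, -1)             # alternate lateral side (z)
  for (k in seq_along(sc_fracs)) {
    cx <- xc - L / 2 + sc_fracs[k] * L
    cy <- yc + 1.8 * R
    cz <- zc + sc_side[k] * 1.2 * R
    inx <- which(abs(xum - cx) <= sc_ax[1])
    iny <- which(abs(yum - cy) <= sc_ax[2])
    inz <- which(abs(zum - cz) <= sc_ax[3])
    if (!length(inx) || !length(iny) || !length(inz)) next
    q <- outer(((zum[inz] - cz) / sc_ax[3])^2,
               ((yum[iny] - cy) / sc_ax[2])^2, "+")
    for (ix in inx) {
      qq <- q + ((xum[ix] - cx) / sc_ax[1])^2
      sub <- labels[inz, iny, ix, drop = FALSE]
      sel <- qq <= 1 & sub[, , 1] == 0L
      sub[, , 1][sel] <- 4L
      labels[inz, iny, ix] <- sub
    }
  }
  region_mask(labels, vs)
}

#' Generate a 3D point pattern inside a mask
#'
#' `"CSR"` draws complete-spatial-randomness points (the Monte-Carlo null of
#' the nearest-neighbour index): a uniformly chosen foreground voxel plus a
#' uniform jitter within the voxel, which is exactly uniform over the
#' digitized mask.  `"thomas"` draws a Thomas cluster process: CSR parents
#' and Gaussian-dispersed offspring; offspring falling outside the mask are
#' resampled (not discarded) so the requested `n` is exact.  `"lattice"`
#' returns a regular grid restricted to the mask (dispersed pattern).
#'
#' @param mask an [lc_mask()] (or [lc_regionmask()], in which case `regions`
#'   selects the subregion).
#' @param n number of points (ignored by `"lattice"` when `spacing_um` is
#'   given; otherwise sets the lattice intensity).
#' @param mode `"CSR"`, `"thomas"` or `"lattice"`.
#' @param n_parents,sigma_um Thomas parameters: number of CSR parents and
#'   isotropic Gaussian dispersion (um).
#' @param spacing_um lattice spacing (um).
#' @param regions subregion name(s) when `mask` is a region mask.
#' @param seed optional RNG seed (local to this call).
#' @param max_tries resampling cap per offspring point.
#' @return n x 3 matrix of (x, y, z) um coordinates.
#' @export
make_point_pattern <- function(mask, n, mode = c("CSR", "thomas", "lattice"),
                               n_parents = 40, sigma_um = 30,
                               spacing_um = NULL, regions = "core",
                               seed = NULL, max_tries = 10000) {
  mode <- match.arg(mode)
  if (inherits(mask, "lc_regionmask")) mask <- mask_from_regions(mask, regions)
  stopifnot(inherits(mask, "lc_mask"))
  if (n < 0) stop("n must be >= 0")
  empty <- matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z")))
  if (n == 0 && mode != "lattice") return(empty)
  fg <- which(mask$data)
  if (!length(fg)) stop("mask is empty")
  vs <- mask$voxel_size_um
  d <- dim(mask$data)

  csr <- function(k) {
    idx <- fg[sample.int(length(fg), k, replace = TRUE)]
    ctr <- idx_to_um(idx, d, vs)
    jit <- cbind(runif(k, -vs[3] / 2, vs[3] / 2),
                 runif(k, -vs[2] / 2, vs[2] / 2),
                 runif(k, -vs[1] / 2, vs[1] / 2))
    ctr + jit
  }

  with_seed(seed, {
    pts <- switch(mode,
      CSR = csr(n),
      thomas = {
        if (n_parents < 1) stop("n_parents must be >= 1")
        parents <- csr(n_parents)
        per <- rep(n %/% n_parents, n_parents)
        extra <- n %% n_parents
        if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1
        out <- matrix(NA_real_, n, 3)
        row <- 1
        for (p in seq_len(n_parents)) {
          for (o in seq_len(per[p])) {
            ok <- FALSE
            for (tr in seq_len(max_tries)) {
              cand <- parents[p, ] + rnorm(3, 0, sigma_um)
              if (isTRUE(points_in_mask(matrix(cand, 1), mask))) {
                out[row, ] <- cand
                ok <- TRUE
                break
              }
            }
            if (!ok)
              stop("thomas offspring resampling exceeded max_tries = ",
                   max_tries, "; parent too far from the mask for sigma_um = ",
                   sigma_um)
            row <- row + 1
          }
        }
        out
      },
      lattice = {
        ctr <- idx_to_um(fg, d, vs)
        lo <- apply(ctr, 2, min)
        hi <- apply(ctr, 2, max)
        s <- spacing_um
        if (is.null(s)) {
          vol <- length(fg) * prod(vs)
          if (n == 0) return(empty)
          s <- (vol / n)^(1 / 3)
        }
        gx <- seq(lo[1] + s / 2, hi[1], by = s)
        gy <- seq(lo[2] + s / 2, hi[2], by = s)
        gz <- seq(lo[3] + s / 2, hi[3], by = s)
        g <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
        g[points_in_mask(g, mask), , drop = FALSE]
      })
    colnames(pts) <- c("x", "y", "z")
    attr(pts, "mode") <- mode
    pts
  })
}

# sequential-inhibition CSR placement: uniform draws rejected when closer
# than min_sep to an accepted centre (somas do not interpenetrate)
place_somas <- function(mask, n, min_sep, max_tries_factor = 500) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  fg <- which(mask$data)
  if (!length(fg)) stop("cannot place somas: region mask is empty")
  vs <- mask$voxel_size_um
  d <- dim(mask$data)
  out <- matrix(NA_real_, n, 3)
  got <- 0
  tries <- 0
  cap <- max_tries_factor * n
  while (got < n) {
    tries <- tries + 1
    if (tries > cap)
      stop("could not place ", n, " somas with min separation ", min_sep,
           " um: requested density exceeds the available volume")
    idx <- fg[sample.int(length(fg), 1)]
    cand <- idx_to_um(idx, d, vs)[1, ] +
      c(runif(1, -vs[3] / 2, vs[3] / 2), runif(1, -vs[2] / 2, vs[2] / 2),
        runif(1, -vs[1] / 2, vs[1] / 2))
    if (got > 0) {
      dd <- sqrt(colSums((t(out[seq_len(got), , drop = FALSE]) - cand)^2))
      if (min(dd) < min_sep) next
    }
    got <- got + 1
    out[got, ] <- cand
  }
  colnames(out) <- c("x", "y", "z")
  out
}

# random-walk polyline from `start` with persistent direction; returns the
# vertex list (rows of x,y,z)
walk_polyline <- function(start, dir0, n_steps, step_um, persistence = 0.75) {
  verts <- matrix(NA_real_, n_steps + 1, 3)
  verts[1, ] <- start
  dir <- dir0 / sqrt(sum(dir0^2))
  for (s in seq_len(n_steps)) {
    pert <- rnorm(3)
    dir <- persistence * dir + (1 - persistence) * pert / sqrt(sum(pert^2))
    dir <- dir / sqrt(sum(dir^2))
    verts[s + 1, ] <- verts[s, ] + step_um * dir
  }
  verts
}

rand_unit <- function() {
  v <- rnorm(3)
  v / sqrt(sum(v^2))
}

#' Generate a two-channel synthetic LC/PC volume with ground truth
#'
#' Places TH+ somas per subregion (hard-core inhibition, occasional
#' "hugging" duos), selects a clustered, dorsally biased AT8+ subset
#' (AT8+ cells are always a subset of TH+ cells), paints soma ellipsoids,
#' dendrite tubes and one thin axon per AT8+ cell with degeneration-form
#' dependent process completeness, and adds background plus Gaussian noise.
#'
#' @param config a [phantom_config()].
#' @return A list of class `lc_phantom`: `th` and `at8` ([lc_volume()]),
#'   `regions` ([region_mask()]), and `truth` with the per-cell table
#'   (`cells`), the dorso-ventral cut (`dv_cut_um`), per-compartment voxel
#'   counts and the seed/config used.
#' @export
make_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  regions <- make_region_masks(config)
  d <- dim(regions$labels)
  vs <- regions$voxel_size_um
  vox3 <- prod(vs)
  core_mask <- mask_from_regions(regions, "core")
  dv <- split_dorsoventral(core_mask)
  dv_cut <- dv$cut_um

  with_seed(config$seed, {
    region_names <- names(regions$label_names)
    cells <- list()
    cid <- 0
    for (rn in region_names) {
      m <- mask_from_regions(regions, rn)
      nvox <- sum(m$data)
      if (!nvox) next
      n_r <- if (!is.null(config$region_counts) &&
                 rn %in% names(config$region_counts)) {
        as.integer(config$region_counts[[rn]])
      } else {
        round(config$region_densities[[rn]] * nvox * vox3 / 1e9)
      }
      if (n_r == 0) next
      max_possible <- nvox * vox3 / (4 / 3 * pi * prod(config$soma_axes_um))
      if (n_r > max_possible)
        stop("region ", rn, ": ", n_r,
             " somas exceed the available volume (max ~",
             floor(max_possible), ")")
      pts <- place_somas(m, n_r, config$min_separation_um)
      is_duo <- rep(FALSE, n_r)
      # hugging duos: partner somas just beyond touching distance
      gap <- 1.15 * 2 * max(config$soma_axes_um)
      extra <- list()
      for (i in seq_len(n_r)) {
        if (runif(1) < config$duo_rate) {
          for (tr in 1:50) {
            cand <- pts[i, ] + gap * rand_unit()
            if (isTRUE(points_in_mask(matrix(cand, 1), m))) {
              extra[[length(extra) + 1]] <- cand
              break
            }
          }
        }
      }
      if (length(extra)) {
        pts <- rbind(pts, do.call(rbind, extra))
        is_duo <- c(is_duo, rep(TRUE, length(extra)))
      }
      nn <- nrow(pts)
      cells[[rn]] <- data.frame(
        cell_id = cid + seq_len(nn),
        x_um = pts[, 1], y_um = pts[, 2], z_um = pts[, 3],
        subregion = rn, hugging_partner = is_duo,
        stringsAsFactors = FALSE)
      cid <- cid + nn
    }
    cells <- do.call(rbind, cells)
    rownames(cells) <- NULL
    n_th <- nrow(cells)
    cells$dorsal <- cells$y_um < dv_cut
    cells$marker <- "TH"
    cells$cluster_id <- NA_integer_

    # ---- AT8+ subset: dorsally biased, clustered within the core ----------
    f_at8 <- config$at8_fraction
    core_idx <- which(cells$subregion == "core")
    n_at8_core <- round(f_at8 * length(core_idx))
    if (n_at8_core > 0) {
      n_dorsal <- rbinom(1, n_at8_core, config$dorsal_bias)
      n_ventral <- n_at8_core - n_dorsal
      sel <- integer(0)
      clid <- 0
      for (half in c("dorsal", "ventral")) {
        pool <- core_idx[if (half == "dorsal") cells$dorsal[core_idx]
                         else !cells$dorsal[core_idx]]
        need <- if (half == "dorsal") n_dorsal else n_ventral
        need <- min(need, length(pool))
        taken <- logical(length(pool))
        got <- 0
        while (got < need) {
          cp <- config$cluster_params
          clustered <- runif(1) < cp$p_clustered
          size <- if (clustered) {
            min(max(2, 1 + rpois(1, cp$mean_size - 1)), cp$max_size)
          } else 1
          size <- min(size, need - got)
          free <- which(!taken)
          seed_i <- free[sample.int(length(free), 1)]
          members <- seed_i
          if (size > 1) {
            others <- free[free != seed_i]
            if (length(others)) {
              dd <- sqrt((cells$x_um[pool[others]] - cells$x_um[pool[seed_i]])^2 +
                         (cells$y_um[pool[others]] - cells$y_um[pool[seed_i]])^2 +
                         (cells$z_um[pool[others]] - cells$z_um[pool[seed_i]])^2)
              members <- c(seed_i, others[order(dd)][seq_len(min(size - 1,
                                                                 length(others)))])
            }
          }
          taken[members] <- TRUE
          clid <- clid + 1
          cells$cluster_id[pool[members]] <- clid
          sel <- c(sel, pool[members])
          got <- got + length(members)
        }
      }
      cells$marker[sel] <- "AT8+TH"
    }
    # other subregions: unbiased random AT8+ subset at the same fraction
    for (rn in setdiff(region_names, "core")) {
      ridx <- which(cells$subregion == rn)
      k <- round(f_at8 * length(ridx))
      if (k > 0)
        cells$marker[ridx[sample.int(length(ridx), k)]] <- "AT8+TH"
    }

    at8_idx <- which(cells$marker == "AT8+TH")
    cells$form_label <- "unclassified"
    cells$intensity_class <- NA_character_
    if (length(at8_idx)) {
      cells$form_label[at8_idx] <- sample(FORM_LEVELS, length(at8_idx),
                                          replace = TRUE,
                                          prob = config$form_probs)
      u <- runif(length(at8_idx))
      cells$intensity_class[at8_idx] <-
        ifelse(u < config$p_low_intensity, "low",
               ifelse(u < config$p_low_intensity + config$p_inhomogeneous,
                      "inhomogeneous", "homogeneous"))
    }

    # ---- paint channels ----------------------------------------------------
    th_shape <- array(0, dim = d)
    at8_shape <- array(0, dim = d)
    th_owner <- array(0L, dim = d)
    at8_owner <- array(0L, dim = d)
    dimv <- as.integer(d)
    ax <- config$soma_axes_um

    cells$soma_voxels <- 0L
    cells$process_voxels <- 0L
    cells$n_branches_true <- 0L

    orient_for <- function(rn) {
      if (rn == "core" || rn == "shell") c(1, 0, 0)      # rostro-caudal
      else if (rn == "subcoeruleus") c(0, 1, 0)          # dorso-ventral
      else rand_unit()
    }

    for (i in seq_len(n_th)) {
      ctr <- c(cells$x_um[i], cells$y_um[i], cells$z_um[i])
      cells$soma_voxels[i] <- cpp_paint_ellipsoid(
        th_shape, th_owner, dimv, vs, ctr, ax, orient_for(cells$subregion[i]),
        1.0, 1L)
    }

    f <- config$body_fraction
    for (i in at8_idx) {
      ctr <- c(cells$x_um[i], cells$y_um[i], cells$z_um[i])
      amp_mult <- if (identical(cells$intensity_class[i], "low")) 0.3 else 1.0
      soma_n <- cpp_paint_ellipsoid(at8_shape, at8_owner, dimv, vs, ctr, ax,
                                    orient_for(cells$subregion[i]),
                                    amp_mult, 1L)
      cells$soma_voxels[i] <- soma_n
      w <- FORM_PROCESS_FACTOR[[cells$form_label[i]]]
      if (f >= 1 || w <= 0) next
      budget <- soma_n * (1 / f - 1) * w
      painted <- 0
      nb <- 0
      step <- 10
      # one thin axon for forms that retain processes beyond severe atrophy
      if (w > 0.2 && painted < budget) {
        verts <- walk_polyline(ctr + max(ax) * rand_unit(), rand_unit(),
                               n_steps = ceiling(1.5 * config$dendrite_length_um / step),
                               step_um = step)
        nb <- nb + 1
        for (s in seq_len(nrow(verts) - 1)) {
          painted <- painted + cpp_paint_capsule(
            at8_shape, at8_owner, dimv, vs, verts[s, ], verts[s + 1, ],
            config$axon_radius_um, amp_mult, 2L)
          if (painted >= budget) break
        }
      }
      # dendrites, round-robin until the process budget is consumed
      nd <- config$n_dendrites
      if (painted < budget && nd > 0) {
        steps_max <- ceiling(config$dendrite_length_um / step)
        vlist <- lapply(seq_len(nd), function(k)
          walk_polyline(ctr + max(ax) * rand_unit(), rand_unit(),
                        steps_max, step))
        started <- rep(FALSE, nd)
        done <- FALSE
        for (s in seq_len(steps_max)) {
          for (k in seq_len(nd)) {
            painted <- painted + cpp_paint_capsule(
              at8_shape, at8_owner, dimv, vs, vlist[[k]][s, ],
              vlist[[k]][s + 1, ], config$dendrite_radius_um, amp_mult, 2L)
            if (!started[k]) { started[k] <- TRUE; nb <- nb + 1 }
            if (painted >= budget) { done <- TRUE; break }
          }
          if (done) break
        }
      }
      cells$process_voxels[i] <- painted
      cells$n_branches_true[i] <- nb
      # granular multiplicative texture for inhomogeneously filled somas
      if (identical(cells$intensity_class[i], "inhomogeneous")) {
        box <- soma_bbox_indices(ctr, ax, d, vs)
        if (length(box)) {
          tex <- pmin(pmax(exp(rnorm(length(box), 0, 0.45)), 0.25), 2.0)
          sel <- at8_shape[box] > 0 & at8_owner[box] == 1L
          at8_shape[box[sel]] <- at8_shape[box[sel]] * tex[sel]
        }
      }
    }

    noise <- config$noise
    n_tot <- prod(d)
    th_img <- noise$background + noise$amplitude * th_shape +
      array(rnorm(n_tot, 0, noise$gaussian_sd), dim = d)
    at8_img <- noise$background + noise$amplitude * at8_shape +
      array(rnorm(n_tot, 0, noise$gaussian_sd), dim = d)
    th_img[th_img < 0] <- 0
    th_img[th_img > 65535] <- 65535
    at8_img[at8_img < 0] <- 0
    at8_img[at8_img > 65535] <- 65535

    truth <- list(cells = cells,
                  dv_cut_um = dv_cut,
                  at8_soma_voxels = sum(at8_owner == 1L),
                  at8_process_voxels = sum(at8_owner == 2L),
                  seed = config$seed,
                  config = config)
    structure(list(th = lc_volume(th_img, vs, "TH"),
                   at8 = lc_volume(at8_img, vs, "AT8"),
                   regions = regions,
                   at8_owner = at8_owner,
                   truth = truth),
              class = "lc_phantom")
  })
}

# 1-based linear indices of the axis-aligned bounding box of an ellipsoid
soma_bbox_indices <- function(center_xyz, semi_axes, dim, vs) {
  r <- max(semi_axes)
  ix <- seq(max(0, floor((center_xyz[1] - r) / vs[3])),
            min(dim[3] - 1, ceiling((center_xyz[1] + r) / vs[3])))
  iy <- seq(max(0, floor((center_xyz[2] - r) / vs[2])),
            min(dim[2] - 1, ceiling((center_xyz[2] + r) / vs[2])))
  iz <- seq(max(0, floor((center_xyz[3] - r) / vs[1])),
            min(dim[1] - 1, ceiling((center_xyz[3] + r) / vs[1])))
  if (!length(ix) || !length(iy) || !length(iz)) return(integer(0))
  g <- expand.grid(z = iz, y = iy, x = ix)
  as.integer(g$z + dim[1] * (g$y + dim[2] * g$x) + 1)
}

#' @export
print.lc_phantom <- function(x, ...) {
  tab <- table(x$truth$cells$subregion)
  cat(sprintf("<lc_phantom> %s: %d TH+ cells (%s), %d AT8+, seed %d\n",
              x$truth$config$braak_group, nrow(x$truth$cells),
              paste(names(tab), tab, sep = "=", collapse = ", "),
              sum(x$truth$cells$marker == "AT8+TH"), x$truth$seed))
  invisible(x)
}
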