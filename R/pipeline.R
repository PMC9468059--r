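# Orchestration: reproducible end-to-end runs tying the phantom generator,
# segmentation, quantification, spatial statistics and reporting together,
# with a JSON run manifest carrying seeds and config hashes.

#' Pipeline run configuration
#'
#' The default phantom is a compact 5 um-isotropic block (the default
#' 10 um phantom grid cannot support the 5 um body/process opening, whose
#' radius must be at least one voxel).
#'
#' @param phantom a [phantom_config()].
#' @param detect a [detect_params()].
#' @param opening_radius_um body/process opening radius (um).
#' @param min_soma_volume_um3 minimum body-component volume.
#' @param nni_sims Monte-Carlo simulations for the NNI.
#' @param dense_factor dense-cell threshold factor.
#' @param shell_inner_um,shell_width_um,n_shells shell-zoning geometry.
#' @param write_tiff also write TIFF stacks (slower, larger).
#' @param seed run seed (overrides the phantom seed).
#' @return list of class `run_config`.
#' @export
run_config <- function(phantom = phantom_config(
                         grid_shape = c(z = 100, y = 120, x = 160),
                         voxel_size_um = 5,
                         core_radius_um = 150, core_length_um = 600,
                         region_counts = c(core = 60, shell = 8, A4 = 4,
                                           subcoeruleus = 4),
                         at8_fraction = 0.3),
                       detect = detect_params(),
                       opening_radius_um = 5,
                       min_soma_volume_um3 = 1000,
                       nni_sims = 100,
                       dense_factor = 0.75,
                       shell_inner_um = 50, shell_width_um = 100,
                       n_shells = 5,
                       write_tiff = FALSE,
                       seed = NULL) {
  if (!is.null(seed)) phantom$seed <- as.integer(seed)
  structure(list(phantom = phantom, detect = detect,
                 opening_radius_um = opening_radius_um,
                 min_soma_volume_um3 = min_soma_volume_um3,
                 nni_sims = nni_sims, dense_factor = dense_factor,
                 shell_inner_um = shell_inner_um,
                 shell_width_um = shell_width_um, n_shells = n_shells,
                 write_tiff = write_tiff,
                 seed = phantom$seed),
            class = "run_config")
}

#' Run the end-to-end pipeline on a synthetic phantom
#'
#' Stages: `simulate` (phantom + ground truth), `segment` (TH soma
#' detection, AT8 thresholding, body/process split, AT8 body centroids),
#' `quantify` (regional burden table, shell profile), `spatialstats`
#' (NNI + cluster analysis on AT8+ bodies in the core), `report`
#' (simulated-vs-observed paired summary).  All tabular outputs are CSV
#' with a seed/config-hash header; a JSON manifest lists every artifact.
#' Rerunning with the same seed reproduces every output byte-identically.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created if missing).
#' @param stages subset of stages to run (in canonical order).  Later
#'   stages require earlier ones in the same call.
#' @return the manifest (invisibly), a list also written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = run_config(), outdir = "lctau_run",
                         stages = c("simulate", "segment", "quantify",
                                    "spatialstats", "report")) {
  stopifnot(inherits(config, "run_config"))
  canonical <- c("simulate", "segment", "quantify", "spatialstats", "report")
  stages <- match.arg(stages, canonical, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  chash <- config_hash(config)
  outputs <- character(0)
  emit <- function(tbl, name) {
    p <- file.path(outdir, name)
    write_table_csv(tbl, p, seed = seed, config_hash = chash)
    outputs <<- c(outputs, p)
    p
  }
  state <- new.env(parent = emptyenv())

  need <- function(what, stage_needed) {
    if (!exists(what, envir = state))
      stop("stage requires '", stage_needed, "' to run first (missing ",
           what, ")")
    get(what, envir = state)
  }

  if ("simulate" %in% stages) {
    ph <- make_phantom(config$phantom)
    assign("phantom", ph, envir = state)
    emit(ph$truth$cells, "truth_cells.csv")
    write_json_config(config$phantom, file.path(outdir, "phantom_config.json"))
    outputs <- c(outputs, file.path(outdir, "phantom_config.json"))
    if (config$write_tiff) {
      for (nm in c("th", "at8")) {
        p <- file.path(outdir, paste0(nm, ".tif"))
        write_tiff_stack(ph[[nm]], p)
        outputs <- c(outputs, p)
      }
      p <- file.path(outdir, "regions.tif")
      write_tiff_stack(ph$regions, p)
      outputs <- c(outputs, p)
    }
  }

  if ("segment" %in% stages) {
    ph <- need("phantom", "simulate")
    th_cells <- detect_cells(ph$th, config$detect)
    vs <- ph$th$voxel_size_um
    at8_fg <- threshold_foreground(ph$at8,
                                   config$detect$tophat_radius_um)
    comp <- split_body_process(at8_fg, config$opening_radius_um,
                               config$min_soma_volume_um3)
    at8_cells <- body_centroids(comp$body, config$min_soma_volume_um3)
    # subregion + dorsal assignment by centroid membership
    annotate <- function(cells, marker) {
      if (!nrow(cells)) {
        cells$marker <- character(0)
        cells$subregion <- character(0)
        cells$dorsal <- logical(0)
        return(cells)
      }
      idx <- um_to_idx(cells, dim(ph$regions$labels), vs)
      lab <- ifelse(is.na(idx), 0L, ph$regions$labels[idx])
      nm <- names(ph$regions$label_names)[match(lab, ph$regions$label_names)]
      cells$marker <- marker
      cells$subregion <- ifelse(lab == 0L, "background", nm)
      cells$dorsal <- cells$y_um < ph$truth$dv_cut_um
      cells
    }
    th_cells <- annotate(th_cells, "TH")
    at8_cells <- annotate(at8_cells, "AT8+TH")
    assign("th_cells", th_cells, envir = state)
    assign("at8_cells", at8_cells, envir = state)
    assign("compartments", comp, envir = state)
    emit(th_cells, "th_cells.csv")
    emit(at8_cells, "at8_cells.csv")
  }

  if ("quantify" %in% stages) {
    ph <- need("phantom", "simulate")
    comp <- need("compartments", "segment")
    th_cells <- need("th_cells", "segment")
    at8_cells <- need("at8_cells", "segment")
    cells <- rbind(th_cells, at8_cells)
    burden <- regional_burden(comp, cells, ph$regions,
                              dv_cut_um = ph$truth$dv_cut_um,
                              case_id = sprintf("phantom_seed%d", seed))
    assign("burden", burden, envir = state)
    emit(as.data.frame(burden), "burden.csv")
    core_at8 <- at8_cells[at8_cells$subregion == "core", , drop = FALSE]
    if (nrow(core_at8) >= 1) {
      prof <- shell_profile(comp$process, core_at8, ph$regions, "core",
                            config$shell_inner_um, config$shell_width_um,
                            config$n_shells)
      emit(as.data.frame(prof), "shell_profile.csv")
    }
  }

  if ("spatialstats" %in% stages) {
    ph <- need("phantom", "simulate")
    th_cells <- need("th_cells", "segment")
    at8_cells <- need("at8_cells", "segment")
    core_mask <- mask_from_regions(ph$regions, "core")
    core_at8 <- at8_cells[at8_cells$subregion == "core", , drop = FALSE]
    core_th <- th_cells[th_cells$subregion == "core", , drop = FALSE]
    if (nrow(core_at8) >= 2) {
      # clamp detected centroids into the mask (half-voxel edge effects)
      pts <- as_points(core_at8)
      keep <- points_in_mask(pts, core_mask)
      res <- nni(pts[keep, , drop = FALSE], core_mask,
                 n_sims = config$nni_sims, seed = seed + 1L)
      th_nn <- if (nrow(core_th) >= 2)
        mean(nn_distances(as_points(core_th))) else NA_real_
      cl <- cluster_analysis(pts[keep, , drop = FALSE],
                             factor = config$dense_factor,
                             th_mean_nn_um = if (is.na(th_nn)) NULL else th_nn)
      stats_tbl <- data.frame(
        n_at8 = res$n_points, mean_observed_nn_um = res$mean_observed_um,
        mean_simulated_nn_um = res$mean_simulated_um, nni = res$nni,
        n_sims = res$n_sims, dense_threshold_um = cl$dense_threshold_um,
        n_dense = sum(cl$dense), duo_count = cl$duo_count,
        minigroup_count = cl$minigroup_count,
        large_group_count = cl$large_group_count,
        duos_per_100 = cl$duos_per_100,
        minigroups_per_100 = cl$minigroups_per_100,
        th_mean_nn_um = th_nn,
        n_neighbouring = if (!is.null(cl$neighbouring))
          sum(cl$neighbouring) else NA_integer_,
        neighbouring_per_100 = cl$neighbouring_per_100)
      assign("spatial", list(nni = res, cluster = cl), envir = state)
      emit(stats_tbl, "spatial_stats.csv")
    }
  }

  if ("report" %in% stages) {
    sp <- if (exists("spatial", envir = state))
      get("spatial", envir = state) else NULL
    rep_ <- list(seed = seed, config_hash = chash)
    if (!is.null(sp)) {
      rep_$nni <- sp$nni$nni
      rep_$sim_vs_obs <- paired_sim_vs_obs_test(
        rep(sp$nni$mean_observed_um, length(sp$nni$sim_means_um)),
        sp$nni$sim_means_um)
    }
    p <- file.path(outdir, "report.json")
    jsonlite::write_json(rep_, p, auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
    outputs <- c(outputs, p)
  }

  manifest <- list(package = "lctau",
                   version = as.character(utils::packageVersion("lctau")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"),
                   seed = seed, config_hash = chash,
                   stages = stages, outdir = outdir,
                   outputs = basename(outputs))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
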