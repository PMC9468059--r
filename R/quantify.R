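# Regional burden quantification, dorso-ventral proportions, body/process
# proportions and the semiquantitative five-grade score.

#' Per-subregion AT8 burden table
#'
#' For each subregion: AT8+ volume (body + process voxels), subregion
#' volume, their ratio, TH+ and AT8+ cell counts, AT8+ cells per mm^3 and
#' per 100 TH+ cells, body/process volume fractions — plus dorsal and
#' ventral variants of the volumes and counts, using a single cut plane
#' (by default the equal-volume dorso-ventral cut of the core).  Dorsal and
#' ventral values sum to the whole-region values exactly.
#'
#' @param compartments a `compartment_masks` list from
#'   [split_body_process()] (or a list with `body` and `process`
#'   [lc_mask()]s).
#' @param cells CellTable data frame with `x_um`, `y_um`, `z_um`, `marker`
#'   (`"TH"` / `"AT8+TH"`) and `subregion`.
#' @param regions an [region_mask()], grid-aligned with the compartments.
#' @param dv_cut_um dorso-ventral cut coordinate (um along y); default: the
#'   equal-volume cut of the core.  Dorsal = low y.
#' @param case_id optional case identifier column.
#' @return data frame of class `burden_table`.
#' @export
regional_burden <- function(compartments, cells, regions, dv_cut_um = NULL,
                            case_id = NA_character_) {
  stopifnot(inherits(regions, "lc_regionmask"))
  body <- compartments$body
  proc <- compartments$process
  if (!all(dim(body$data) == dim(regions$labels)))
    stop("compartment masks and region mask are not grid-aligned")
  vs <- regions$voxel_size_um
  vox3 <- prod(vs)
  if (is.null(dv_cut_um))
    dv_cut_um <- split_dorsoventral(mask_from_regions(regions, "core"))$cut_um
  d <- dim(regions$labels)
  # voxel y coordinates: dorsal = y below the cut
  ny_dorsal <- sum(((seq_len(d[2]) - 1) * vs[2]) < dv_cut_um)
  dorsal_sel <- seq_len(d[2]) <= ny_dorsal

  rows <- lapply(names(regions$label_names), function(rn) {
    lab <- regions$label_names[[rn]]
    sel <- regions$labels == lab
    n_sub <- sum(sel)
    bodyv <- sum(body$data & sel)
    procv <- sum(proc$data & sel)
    at8v <- bodyv + procv
    seld <- sel
    seld[, !dorsal_sel, ] <- FALSE
    bodyd <- sum(body$data & seld)
    procd <- sum(proc$data & seld)
    cc <- cells[cells$subregion == rn, , drop = FALSE]
    n_th <- nrow(cc)
    at8 <- cc$marker == "AT8+TH"
    n_at8 <- sum(at8)
    dors <- cc$y_um < dv_cut_um
    sub_mm3 <- n_sub * vox3 / 1e9
    data.frame(
      case_id = case_id, subregion = rn,
      subregion_volume_um3 = n_sub * vox3,
      at8_volume_um3 = at8v * vox3,
      at8_volume_fraction = if (n_sub) at8v / n_sub else NA_real_,
      n_th_cells = n_th, n_at8_cells = n_at8,
      at8_cells_per_mm3 = if (sub_mm3 > 0) n_at8 / sub_mm3 else NA_real_,
      at8_per_100_th = if (n_th) 100 * n_at8 / n_th else NA_real_,
      body_volume_um3 = bodyv * vox3,
      process_volume_um3 = procv * vox3,
      body_volume_fraction = if (at8v) bodyv / at8v else NA_real_,
      process_volume_fraction = if (at8v) procv / at8v else NA_real_,
      dorsal_at8_volume_um3 = (bodyd + procd) * vox3,
      ventral_at8_volume_um3 = (at8v - bodyd - procd) * vox3,
      dorsal_n_at8_cells = sum(at8 & dors),
      ventral_n_at8_cells = sum(at8 & !dors),
      dorsal_n_th_cells = sum(dors),
      ventral_n_th_cells = sum(!dors),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "dv_cut_um") <- dv_cut_um
  class(out) <- c("burden_table", "data.frame")
  out
}

#' Average bilateral blocks of the same case
#'
#' Averages all numeric columns over blocks, per case and subregion
#' (bilateral samples of one subject are averaged before group statistics).
#'
#' @param tbl a burden table with `case_id` and `subregion` columns.
#' @return data frame with one row per case x subregion.
#' @export
average_blocks <- function(tbl) {
  num <- vapply(tbl, is.numeric, logical(1))
  ag <- stats::aggregate(tbl[num],
                         by = list(case_id = tbl$case_id,
                                   subregion = tbl$subregion),
                         FUN = mean)
  ag
}

#' Body vs process percentage of the AT8+ volume
#'
#' @param compartments a `compartment_masks` list; or pass `body_um3` and
#'   `process_um3` directly.
#' @param regions,region optional subregion restriction.
#' @param body_um3,process_um3 direct volumes (bypass the masks).
#' @return named vector `c(body_pct, process_pct)` summing to 100, or NAs
#'   (with attribute `undefined = TRUE`) when the total is zero.
#' @export
body_process_proportion <- function(compartments = NULL, regions = NULL,
                                    region = "core", body_um3 = NULL,
                                    process_um3 = NULL) {
  if (is.null(body_um3)) {
    stopifnot(!is.null(compartments))
    bm <- compartments$body$data
    pm <- compartments$process$data
    if (!is.null(regions)) {
      sel <- mask_from_regions(regions, region)$data
      bm <- bm & sel
      pm <- pm & sel
    }
    vox3 <- voxel_volume_um3(compartments$body)
    body_um3 <- sum(bm) * vox3
    process_um3 <- sum(pm) * vox3
  }
  tot <- body_um3 + process_um3
  if (tot == 0) {
    out <- c(body_pct = NA_real_, process_pct = NA_real_)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  c(body_pct = 100 * body_um3 / tot, process_pct = 100 * process_um3 / tot)
}

SCORE_LEVELS <- c("0", "0/+", "+", "++", "+++")

#' Semiquantitative five-grade score
#'
#' Grade "0" = structure not detected (count 0); "0/+" = a single cell (or
#' extremely sparse debris) in the entire scan (count 1); "+", "++", "+++"
#' = sparse, moderate and high density by configurable cut-points.  The
#' numeric cut-points are config-only stand-ins: the original grades are
#' defined verbally, not numerically.  Monotone in the count.
#'
#' @param count non-negative count(s) (or density) of the examined
#'   structure.
#' @param thresholds strictly increasing cut-points `c(sparse, moderate)`:
#'   counts <= sparse score "+", <= moderate "++", above "+++".
#' @return ordered factor over `0 < 0/+ < + < ++ < +++` (integer rank =
#'   `as.integer(.) - 1`).
#' @export
semiquant_score <- function(count, thresholds = c(sparse = 10, moderate = 100)) {
  if (length(thresholds) != 2 || diff(thresholds) <= 0 || thresholds[1] <= 1)
    stop("thresholds must be strictly increasing and exceed 1")
  if (any(count < 0)) stop("counts must be non-negative")
  g <- ifelse(count == 0, "0",
       ifelse(count == 1, "0/+",
       ifelse(count <= thresholds[1], "+",
       ifelse(count <= thresholds[2], "++", "+++"))))
  factor(g, levels = SCORE_LEVELS, ordered = TRUE)
}

#' Stage-level group summary (mean +/- SEM)
#'
#' @param tbl data frame of per-case values.
#' @param value name of the value column.
#' @param group name of the grouping column (e.g. Braak group).
#' @param by optional additional stratifier (e.g. subregion).
#' @return data frame with `n`, `mean`, `sem` (NA when n = 1) per group.
#' @export
group_summary <- function(tbl, value, group, by = NULL) {
  keys <- c(group, by)
  f <- interaction(tbl[keys], drop = TRUE, lex.order = TRUE)
  sp <- split(tbl[[value]], f)
  sp <- sp[vapply(sp, length, integer(1)) > 0]
  ids <- do.call(rbind, strsplit(names(sp), ".", fixed = TRUE))
  out <- data.frame(ids, stringsAsFactors = FALSE)
  names(out) <- keys
  out$n <- vapply(sp, length, integer(1))
  out$mean <- vapply(sp, mean, numeric(1))
  out$sem <- vapply(sp, function(v)
    if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_, numeric(1))
  rownames(out) <- NULL
  out
}
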