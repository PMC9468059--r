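# Regional burden, dorso-ventral additivity, body/process proportions,
# semiquantitative scoring and group summaries.

make_simple_world <- function(vox = 10) {
  # analytic world: a half-box "core" region containing a body ball
  # (r <= 80 um) wrapped in a process shell (80-130 um)
  n <- round(600 / vox)
  labels <- array(0L, c(n, n, n))
  labels[, , (0:(n - 1)) * vox < 300] <- 1L
  reg <- region_mask(labels, vox, c(core = 1L, shell = 2L, A4 = 3L,
                                    subcoeruleus = 4L))
  g <- expand.grid(z = (0:(n - 1)) * vox, y = (0:(n - 1)) * vox,
                   x = (0:(n - 1)) * vox)
  r <- sqrt((g$z - 300)^2 + (g$y - 300)^2 + (g$x - 150)^2)
  body <- array(r <= 80, c(n, n, n))
  proc <- array(r > 80 & r <= 130, c(n, n, n))
  cells <- data.frame(cell_id = 1:3, x_um = c(150, 180, 450),
                      y_um = c(300, 120, 400), z_um = c(300, 300, 300),
                      marker = c("AT8+TH", "TH", "TH"),
                      subregion = c("core", "core", "background"))
  list(regions = reg,
       comp = list(body = lc_mask(body, vox), process = lc_mask(proc, vox)),
       cells = cells)
}

test_that("empty AT8 masks give zero burdens and zero fractions", {
  w <- make_simple_world()
  empty <- lc_mask(array(FALSE, dim(w$regions$labels)),
                   w$regions$voxel_size_um)
  tbl <- regional_burden(list(body = empty, process = empty),
                         w$cells[0, ], w$regions, dv_cut_um = 200)
  expect_true(all(tbl$at8_volume_um3 == 0))
  nonempty <- tbl$subregion_volume_um3 > 0
  expect_true(all(tbl$at8_volume_fraction[nonempty] == 0))
})

test_that("dorsal + ventral equals the whole region exactly", {
  w <- make_simple_world()
  tbl <- regional_burden(w$comp, w$cells, w$regions, dv_cut_um = 310)
  core <- tbl[tbl$subregion == "core", ]
  expect_equal(core$dorsal_at8_volume_um3 + core$ventral_at8_volume_um3,
               core$at8_volume_um3)
  expect_identical(core$dorsal_n_th_cells + core$ventral_n_th_cells,
                   core$n_th_cells)
  expect_identical(core$dorsal_n_at8_cells + core$ventral_n_at8_cells,
                   core$n_at8_cells)
  expect_equal(core$body_volume_fraction + core$process_volume_fraction, 1)
})

test_that("burden recovers the painted AT8 fraction of the phantom core", {
  ph <- make_phantom(recovery_phantom(seed = 7))
  fg <- threshold_foreground(ph$at8)
  comp <- split_body_process(fg, 5)
  tr <- ph$truth$cells
  tr$marker <- tr$marker
  tbl <- regional_burden(comp, tr, ph$regions,
                         dv_cut_um = ph$truth$dv_cut_um)
  core <- tbl[tbl$subregion == "core", ]
  truth_frac <- sum(ph$at8_owner > 0 & ph$regions$labels == 1L) /
    sum(ph$regions$labels == 1L)
  expect_lt(abs(core$at8_volume_fraction - truth_frac), 0.02)
})

test_that("volumes are scale-consistent across voxel sizes", {
  w1 <- make_simple_world(10)
  w2 <- make_simple_world(12.6) # ~2x voxel volume
  t1 <- regional_burden(w1$comp, w1$cells, w1$regions, dv_cut_um = 200)
  t2 <- regional_burden(w2$comp, w2$cells, w2$regions, dv_cut_um = 200)
  c1 <- t1[t1$subregion == "core", ]
  c2 <- t2[t2$subregion == "core", ]
  expect_lt(abs(c2$at8_volume_um3 - c1$at8_volume_um3) / c1$at8_volume_um3,
            0.05)
  expect_lt(abs(c2$at8_volume_fraction - c1$at8_volume_fraction), 0.02)
  expect_lt(abs(c2$body_volume_fraction - c1$body_volume_fraction), 0.02)
})

test_that("body/process proportions sum to 100 and flag zero totals", {
  w <- make_simple_world()
  pp <- body_process_proportion(w$comp, w$regions, "core")
  expect_equal(sum(pp), 100)
  und <- body_process_proportion(body_um3 = 0, process_um3 = 0)
  expect_true(all(is.na(und)))
  expect_true(attr(und, "undefined"))
  # shell-like regime: body fraction 0.15 puts the process share in the
  # 70-95% band reported for the pericoerulear subregions
  pp2 <- body_process_proportion(body_um3 = 15, process_um3 = 85)
  expect_gte(pp2[["process_pct"]], 70)
  expect_lte(pp2[["process_pct"]], 95)
})

test_that("semiquantitative score follows the five-grade definition", {
  expect_identical(as.character(semiquant_score(0)), "0")
  expect_identical(as.character(semiquant_score(1)), "0/+")
  expect_identical(as.character(semiquant_score(5)), "+")
  expect_identical(as.character(semiquant_score(50)), "++")
  expect_identical(as.character(semiquant_score(500)), "+++")
  # monotone over a wide count range
  s <- semiquant_score(0:1000)
  expect_true(all(diff(as.integer(s)) >= 0))
  expect_error(semiquant_score(5, thresholds = c(100, 10)), "increasing")
  expect_error(semiquant_score(-1), "non-negative")
})

test_that("group summaries: hand-computed mean/SEM, single-case NA", {
  tbl <- data.frame(group = c("B0", "B0", "B0", "B6"),
                    v = c(1, 2, 6, 10))
  gs <- group_summary(tbl, "v", "group")
  b0 <- gs[gs$group == "B0", ]
  expect_equal(b0$mean, 3)
  expect_equal(b0$sem, sd(c(1, 2, 6)) / sqrt(3))
  expect_true(is.na(gs$sem[gs$group == "B6"]))
  expect_identical(gs$n, c(3L, 1L))
})

test_that("bilateral blocks of one case are averaged", {
  tbl <- data.frame(case_id = c("c1", "c1", "c2"),
                    subregion = "core",
                    at8_volume_um3 = c(10, 20, 5))
  av <- average_blocks(tbl)
  expect_equal(sort(av$at8_volume_um3), c(5, 15))
})

test_that("stage groups follow the generator's monotone AT8 ordering", {
  counts <- vapply(c("B0", "B12", "B34", "B6"), function(g) {
    cfg <- phantom_config(grid_shape = c(z = 40, y = 60, x = 100),
                          voxel_size_um = 10, core_radius_um = 120,
                          core_length_um = 600,
                          region_counts = c(core = 100, shell = 0, A4 = 0,
                                            subcoeruleus = 0),
                          braak_group = g, seed = 17)
    ph <- make_phantom(cfg)
    sum(ph$truth$cells$marker == "AT8+TH")
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})
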