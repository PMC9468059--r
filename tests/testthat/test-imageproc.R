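# Soma detection, body/process decomposition, morphometrics, classification.

test_that("detect_cells: degenerate inputs and parameter validation", {
  v <- lc_volume(array(0, c(10, 10, 10)), 10, "TH")
  expect_identical(nrow(detect_cells(v)), 0L)
  expect_error(detect_params(tophat_radius_um = -1), "parameters")
  expect_error(detect_params(min_volume_um3 = 0), "parameters")
})

test_that("detect_cells recovers phantom somas with high recall/precision", {
  ph <- make_phantom(recovery_phantom(seed = 7, at8 = 0))
  tr <- ph$truth$cells
  det <- detect_cells(ph$th)
  hits <- greedy_match(xyz(tr), xyz(det), tol_um = 10)
  expect_gte(hits / nrow(tr), 0.95)   # recall
  expect_gte(hits / nrow(det), 0.95)  # precision
})

test_that("watershed splits hugging duos into two detections", {
  cfg <- phantom_config(grid_shape = c(z = 80, y = 80, x = 100),
                        voxel_size_um = 4, core_radius_um = 120,
                        core_length_um = 300,
                        region_counts = c(core = 2, shell = 0, A4 = 0,
                                          subcoeruleus = 0),
                        duo_rate = 1, at8_fraction = 0,
                        min_separation_um = 36, seed = 3)
  ph <- make_phantom(cfg)
  expect_identical(nrow(ph$truth$cells), 4L) # 2 placed + 2 hugging partners
  det <- detect_cells(ph$th)
  expect_identical(nrow(det), 4L)
  expect_identical(greedy_match(xyz(ph$truth$cells), xyz(det), 10), 4L)
})

test_that("detect_cells is translation-equivariant for whole-voxel shifts", {
  cfg <- phantom_config(grid_shape = c(z = 60, y = 60, x = 80),
                        voxel_size_um = 5, core_radius_um = 100,
                        core_length_um = 250,
                        region_counts = c(core = 5, shell = 0, A4 = 0,
                                          subcoeruleus = 0),
                        at8_fraction = 0, duo_rate = 0, seed = 9)
  ph <- make_phantom(cfg)
  a <- ph$th$data
  shift <- c(2L, 3L, 4L) # voxels along (z, y, x)
  b <- array(ph$truth$config$noise$background, dim = dim(a))
  b[(1 + shift[1]):dim(a)[1], (1 + shift[2]):dim(a)[2],
    (1 + shift[3]):dim(a)[3]] <-
    a[1:(dim(a)[1] - shift[1]), 1:(dim(a)[2] - shift[2]),
      1:(dim(a)[3] - shift[3])]
  # fixed threshold and no top-hat so the pipeline is exactly shift-invariant
  par <- detect_params(threshold = 1000, background_subtract = FALSE)
  d1 <- detect_cells(ph$th, par)
  d2 <- detect_cells(lc_volume(b, 5, "TH"), par)
  expect_identical(nrow(d1), nrow(d2))
  off_um <- shift * 5
  o1 <- xyz(d1)[order(xyz(d1)[, 1]), , drop = FALSE]
  o2 <- xyz(d2)[order(xyz(d2)[, 1]), , drop = FALSE]
  # (x, y, z) offset corresponding to the (z, y, x) voxel shift
  expect_equal(o2, o1 + rep(off_um[c(3, 2, 1)], each = nrow(o1)),
               tolerance = 1e-8)
})

test_that("opening removes thin tubes but preserves thick balls", {
  # 2 um radius tube at 1 um voxels -> all process
  d <- c(21, 21, 60)
  a <- array(FALSE, d)
  for (x in 1:60) a[9:13, 9:13, x] <-
    outer((9:13 - 11)^2, (9:13 - 11)^2, "+") <= 4
  comp <- split_body_process(lc_mask(a, 1), 5, min_soma_volume_um3 = 10)
  expect_identical(sum(comp$body$data), 0L)
  expect_identical(comp$process$data, a)

  # 15 um radius ball at 2 um voxels -> essentially all body
  n <- 21
  ctr <- (n - 1) / 2
  g <- expand.grid(z = 0:(n - 1), y = 0:(n - 1), x = 0:(n - 1))
  ball <- array((g$z - ctr)^2 + (g$y - ctr)^2 + (g$x - ctr)^2 <= (15 / 2)^2,
                c(n, n, n))
  comp <- split_body_process(lc_mask(ball, 2), 5, min_soma_volume_um3 = 100)
  expect_lt(sum(comp$process$data) / sum(ball), 0.05)
})

test_that("body + process exactly partition the AT8 foreground", {
  set.seed(21)
  for (rep in 1:5) {
    a <- array(runif(20 * 20 * 20) < 0.2, c(20, 20, 20))
    comp <- split_body_process(lc_mask(a, 4), 5, min_soma_volume_um3 = 200)
    expect_false(any(comp$body$data & comp$process$data))
    expect_identical(comp$body$data | comp$process$data, a)
  }
})

test_that("split_body_process recovers the phantom body fraction", {
  ph <- make_phantom(recovery_phantom(seed = 7))
  fg <- threshold_foreground(ph$at8)
  comp <- split_body_process(fg, 5)
  share <- sum(comp$body$data) / sum(fg$data)
  expect_lt(abs(share - 0.5), 0.1)
})

test_that("opening radius below one voxel instructs resampling", {
  a <- array(TRUE, c(4, 4, 4))
  expect_error(split_body_process(lc_mask(a, 10), 5), "resample")
})

test_that("morphometrics: closed forms and branch counting", {
  one <- array(FALSE, c(5, 5, 5))
  one[3, 3, 3] <- TRUE
  m <- morphometrics(one, 10)
  expect_equal(m$volume_um3, 1000)
  expect_equal(m$surface_area_um2, 600)
  expect_identical(m$n_branches, 0L)

  tube <- array(FALSE, c(7, 7, 30))
  tube[3:4, 3:4, 2:28] <- TRUE
  expect_identical(morphometrics(tube, 2)$n_branches, 1L)

  y3 <- array(FALSE, c(30, 30, 30))
  y3[15, 15, 2:15] <- TRUE
  for (i in 0:12) {
    y3[15 + i, 15, 15 + i] <- TRUE
    y3[15 - i, 15, 15 + i] <- TRUE
  }
  expect_identical(morphometrics(y3, 2, prune_um = 3)$n_branches, 2L)

  expect_error(morphometrics(array(FALSE, c(3, 3, 3)), 10), "empty")
})

test_that("morphometrics volume is exactly additive over disjoint parts", {
  a <- array(FALSE, c(10, 10, 30))
  a[2:4, 2:4, 2:6] <- TRUE
  b <- array(FALSE, c(10, 10, 30))
  b[6:8, 6:8, 20:28] <- TRUE
  both <- a | b
  expect_equal(morphometrics(a, 3)$volume_um3 + morphometrics(b, 3)$volume_um3,
               sum(both) * 27)
})

test_that("classify_form: boundary rules, tie-breaks and monotonicity check", {
  f <- data.frame(soma_volume_um3 = 100, process_volume_um3 = 0,
                  n_branches = 0L)
  expect_identical(as.character(classify_form(f)$form_label), "tangle_like")
  thr <- form_thresholds()
  f2 <- data.frame(ratio = thr$r_partial + 1e-9, n_branches = 3L)
  expect_identical(as.character(classify_form(f2)$form_label),
                   "intact_pretangle")
  f3 <- data.frame(ratio = thr$r_partial, n_branches = 3L) # inclusive cut
  expect_identical(as.character(classify_form(f3)$form_label),
                   "partial_atrophy")
  expect_error(form_thresholds(r_tangle = 0.5, r_severe = 0.3), "monotone")
})

test_that("generator form labels are recovered at default thresholds", {
  cfg <- phantom_config(grid_shape = c(z = 150, y = 160, x = 250),
                        voxel_size_um = 4, core_radius_um = 150,
                        core_length_um = 700,
                        region_counts = c(core = 120, shell = 0, A4 = 0,
                                          subcoeruleus = 0),
                        at8_fraction = 0.9, braak_group = "B34", seed = 11)
  ph <- make_phantom(cfg)
  tr <- subset(ph$truth$cells, marker == "AT8+TH")
  feats <- data.frame(soma_volume_um3 = tr$soma_voxels,
                      process_volume_um3 = tr$process_voxels,
                      n_branches = tr$n_branches_true)
  pred <- classify_form(feats)$form_label
  expect_gte(mean(as.character(pred) == tr$form_label), 0.9)
})

test_that("soma intensity statistics are exact on a constructed volume", {
  a <- array(0, c(6, 6, 6))
  lab <- array(0L, c(6, 6, 6))
  a[1:2, 1:2, 1] <- c(100, 100, 100, 300)   # mean 150, sd 100
  lab[1:2, 1:2, 1] <- 1L
  a[5, 5, 5] <- 700                          # single-voxel soma
  lab[5, 5, 5] <- 2L
  st <- soma_intensity_stats(lc_volume(a, 4, "AT8"), lab)
  expect_equal(st$soma_mean_intensity, c(150, 700))
  expect_equal(st$soma_cv[1], sd(c(100, 100, 100, 300)) / 150)
  # low vs homogeneous separation via classify_form
  f <- data.frame(ratio = c(1, 1), n_branches = c(3L, 3L),
                  soma_mean_intensity = st$soma_mean_intensity,
                  soma_cv = st$soma_cv)
  out <- classify_form(f, form_thresholds(low_intensity_cut = 400,
                                          cv_cut = 0.25))
  expect_identical(out$intensity_class, c("low", "homogeneous"))
})
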