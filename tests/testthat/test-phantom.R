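# Phantom generator: region-mask geometry, point patterns, ground truth.

test_that("region masks: four disjoint labels, seed-independent geometry", {
  cfg <- phantom_config()
  rm1 <- make_region_masks(cfg)
  expect_setequal(setdiff(unique(as.integer(rm1$labels)), 0L), 1:4)

  cfg2 <- phantom_config(seed = 999)
  rm2 <- make_region_masks(cfg2)
  expect_identical(rm1$labels, rm2$labels)
})

test_that("core cylinder voxel volume matches the analytic volume within 5%", {
  cfg <- phantom_config(grid_shape = c(z = 110, y = 110, x = 440),
                        voxel_size_um = c(10, 10, 10),
                        core_radius_um = 500, core_length_um = 4000)
  rm_ <- make_region_masks(cfg)
  core <- mask_from_regions(rm_, "core")
  vox_mm3 <- sum(core$data) * voxel_volume_um3(core) / 1e9
  expect_lt(abs(vox_mm3 - pi * 0.5^2 * 4) / (pi * 0.5^2 * 4), 0.05)
})

test_that("a core that does not fit raises a parameter error", {
  expect_error(phantom_config(grid_shape = c(z = 20, y = 20, x = 20),
                              voxel_size_um = 10,
                              core_radius_um = 300, core_length_um = 2400),
               "does not fit")
})

test_that("point patterns: n = 0, containment, CSR uniformity", {
  m <- box_mask(1000, 20)
  expect_equal(nrow(make_point_pattern(m, 0, "CSR")), 0)
  expect_error(make_point_pattern(lc_mask(array(FALSE, c(4, 4, 4)), 10),
                                  5, "CSR"), "empty")

  p <- make_point_pattern(m, 10000, "CSR", seed = 42)
  expect_true(all(lctau:::points_in_mask(p, m)))
  # halves of the box: binomial oracle, 4 SD band
  half <- mean(p[, 1] < 490)  # physical midpoint of voxel centres 0..980
  expect_lt(abs(half - 0.5), 4 * sqrt(0.25 / 10000))
})

test_that("thomas patterns have exact n and shorter NN distances than CSR", {
  m <- box_mask(1000, 20)
  wins <- vapply(1:20, function(s) {
    th <- make_point_pattern(m, 200, "thomas", n_parents = 40,
                             sigma_um = 30, seed = s)
    cs <- make_point_pattern(m, 200, "CSR", seed = 1000 + s)
    expect_identical(nrow(th), 200L)
    expect_true(all(lctau:::points_in_mask(th, m)))
    mean(nn_distances(th)) < mean(nn_distances(cs))
  }, logical(1))
  expect_true(all(wins))
})

test_that("phantom determinism: identical config+seed gives identical output", {
  cfg <- phantom_config(grid_shape = c(z = 50, y = 70, x = 80),
                        voxel_size_um = 10, core_radius_um = 120,
                        core_length_um = 400,
                        region_counts = c(core = 20, shell = 3, A4 = 2,
                                          subcoeruleus = 2),
                        at8_fraction = 0.5, seed = 5)
  p1 <- make_phantom(cfg)
  p2 <- make_phantom(cfg)
  expect_identical(p1$th$data, p2$th$data)
  expect_identical(p1$at8$data, p2$at8$data)
  expect_identical(p1$truth$cells, p2$truth$cells)
})

test_that("ground truth: requested counts, containment, marker nesting", {
  cfg <- phantom_config(grid_shape = c(z = 60, y = 80, x = 120),
                        voxel_size_um = 10, core_radius_um = 150,
                        core_length_um = 700,
                        region_counts = c(core = 50, shell = 10, A4 = 5,
                                          subcoeruleus = 5),
                        duo_rate = 0, at8_fraction = 0.4, seed = 2)
  ph <- make_phantom(cfg)
  tr <- ph$truth$cells
  expect_identical(sum(tr$subregion == "core"), 50L)
  # every centroid lies inside its recorded subregion mask
  for (rn in unique(tr$subregion)) {
    m <- mask_from_regions(ph$regions, rn)
    pts <- xyz(tr[tr$subregion == rn, ])
    expect_true(all(lctau:::points_in_mask(pts, m)))
  }
  # AT8+ is a subset of TH+ by construction (single table, marker field)
  expect_true(all(tr$marker %in% c("TH", "AT8+TH")))
  # soma and process compartments are disjoint in the owner grid
  expect_identical(sum(ph$at8_owner == 1L) + sum(ph$at8_owner == 2L),
                   sum(ph$at8_owner > 0L))
})

test_that("default stage parameters give monotone AT8+ fractions", {
  fr <- vapply(c("B0", "B12", "B34", "B6"), function(g)
    phantom_config(braak_group = g)$at8_fraction, numeric(1))
  expect_true(all(diff(fr) > 0))
})

test_that("ground-truth AT8 body share approximates body_fraction", {
  ph <- make_phantom(recovery_phantom(seed = 7))
  share <- ph$truth$at8_soma_voxels /
    (ph$truth$at8_soma_voxels + ph$truth$at8_process_voxels)
  expect_lt(abs(share - 0.5), 0.05)
})

test_that("dorsal bias is recovered within 4 binomial SD", {
  cfg <- phantom_config(grid_shape = c(z = 80, y = 100, x = 200),
                        voxel_size_um = 10, core_radius_um = 250,
                        core_length_um = 1600,
                        region_counts = c(core = 600, shell = 0, A4 = 0,
                                          subcoeruleus = 0),
                        min_separation_um = 25,
                        at8_fraction = 0.5, dorsal_bias = 0.7, seed = 11)
  ph <- make_phantom(cfg)
  tr <- ph$truth$cells
  at8 <- tr[tr$marker == "AT8+TH", ]
  expect_gte(nrow(at8), 290) # ~300 requested
  expect_lt(abs(mean(at8$dorsal) - 0.7),
            4 * sqrt(0.7 * 0.3 / nrow(at8)))
})
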