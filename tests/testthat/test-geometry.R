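# Dorso-ventral splitting and concentric-shell zoning.

test_that("symmetric cylinder splits into exactly equal halves", {
  core <- mask_from_regions(make_region_masks(phantom_config()), "core")
  dv <- split_dorsoventral(core)
  expect_identical(sum(dv$dorsal$data), sum(dv$ventral$data))
})

test_that("random blobs: cut is optimal (exhaustive-scan oracle) and bounded", {
  set.seed(31)
  for (rep in 1:10) {
    a <- array(runif(15 * 20 * 15) < 0.4, c(15, 20, 15))
    if (!any(a)) next
    m <- lc_mask(a, 8)
    dv <- split_dorsoventral(m)
    counts <- apply(a, 2, sum)
    # oracle: scan every cut position
    best <- min(abs(2 * cumsum(counts) - sum(counts)))
    got <- abs(sum(dv$dorsal$data) - sum(dv$ventral$data))
    expect_identical(got, as.integer(best))
    expect_lte(got, max(counts)) # at most one cut-plane slab
  }
})

test_that("dorsal/ventral partition the input on random masks", {
  set.seed(32)
  for (rep in 1:100) {
    a <- array(runif(8 * 10 * 8) < 0.5, c(8, 10, 8))
    if (!any(a)) next
    dv <- split_dorsoventral(lc_mask(a, 10))
    expect_false(any(dv$dorsal$data & dv$ventral$data))
    expect_identical(dv$dorsal$data | dv$ventral$data, a)
  }
  expect_error(split_dorsoventral(lc_mask(array(FALSE, c(3, 3, 3)), 10)),
               "empty")
})

test_that("shell indices follow the stated band arithmetic", {
  m <- lc_mask(array(TRUE, c(3, 3, 60)), 10)
  z <- shell_zones(cbind(0, 0, 0), m)
  expect_identical(z[1, 1, 4], 0L)   # voxel at 30 um: inner band
  expect_identical(z[1, 1, 13], 1L)  # 120 um: the 50-150 band
  expect_identical(z[1, 1, 21], 2L)  # 200 um: 150-250
  # beyond the last shell: sentinel
  expect_identical(z[1, 1, 60], -1L) # 590 um with 5 shells (max 550)
  expect_error(shell_zones(matrix(numeric(0), 0, 3), m), "centroid")
})

test_that("voxels are assigned to the shell of their nearest centroid", {
  m <- lc_mask(array(TRUE, c(3, 3, 60)), 10)
  cents <- rbind(c(0, 0, 0), c(400, 0, 0))
  z <- shell_zones(cents, m)
  expect_identical(z[1, 1, 7], 1L) # 60 um from first, 340 from second
  # brute-force oracle over every foreground voxel
  fg <- which(m$data)
  um <- lctau:::idx_to_um(fg, dim(m$data), m$voxel_size_um)
  d_or <- pmin(sqrt(rowSums((um - rep(cents[1, ], each = nrow(um)))^2)),
               sqrt(rowSums((um - rep(cents[2, ], each = nrow(um)))^2)))
  idx_or <- ifelse(d_or < 50, 0L, 1L + floor((d_or - 50) / 100))
  idx_or[idx_or > 5] <- -1L
  expect_identical(z[fg], as.integer(idx_or))
})

test_that("shell profile: bounded processes yield zero outer fractions", {
  ph <- make_phantom(recovery_phantom(seed = 13, n_core = 30))
  fg <- threshold_foreground(ph$at8)
  comp <- split_body_process(fg, 5)
  tr <- subset(ph$truth$cells, marker == "AT8+TH")
  prof <- shell_profile(comp$process, tr, ph$regions, "core")
  # dendrites extend at most ~225 um (1.5 x dendrite_length); beyond shell 2
  # nothing remains
  expect_true(all(prof$fraction[prof$shell >= 3] == 0))
  expect_equal(sum(prof$fraction), 1, tolerance = 1e-9)
})

test_that("isotropically decaying density gives non-increasing fractions", {
  n <- 121
  vox <- 10
  ctr <- (n - 1) / 2 * vox
  g <- expand.grid(z = (0:(n - 1)) * vox, y = (0:(n - 1)) * vox,
                   x = (0:(n - 1)) * vox)
  r <- sqrt((g$z - ctr)^2 + (g$y - ctr)^2 + (g$x - ctr)^2)
  set.seed(44)
  a <- array(runif(n^3) < exp(-r / 40), c(n, n, n))
  prof <- shell_profile(lc_mask(a, vox), cbind(ctr, ctr, ctr))
  fr <- prof$fraction[prof$shell >= 1]
  expect_true(all(diff(fr) <= 1e-12))
})

test_that("empty process mask yields a flagged zero profile, not an error", {
  m <- lc_mask(array(FALSE, c(5, 5, 5)), 10)
  prof <- shell_profile(m, cbind(0, 0, 0))
  expect_true(attr(prof, "empty"))
  expect_true(all(prof$process_volume_um3 == 0))
})

test_that("shell volumes agree across voxel sizes (discretization tolerance)", {
  mk <- function(vox) {
    n <- round(600 / vox) + 1
    ctr <- 300
    g <- expand.grid(z = (0:(n - 1)) * vox, y = (0:(n - 1)) * vox,
                     x = (0:(n - 1)) * vox)
    r <- sqrt((g$z - ctr)^2 + (g$y - ctr)^2 + (g$x - ctr)^2)
    a <- array(r <= 260, c(n, n, n)) # solid ball of process
    shell_profile(lc_mask(a, vox), cbind(ctr, ctr, ctr))
  }
  p1 <- mk(10)
  p2 <- mk(5)
  expect_equal(p1$fraction, p2$fraction, tolerance = 0.02)
})
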