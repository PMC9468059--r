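# NN distances, Monte-Carlo NNI, dense cells, duo/minigroup components,
# neighbouring cells.

test_that("nn_distances: hand examples and degenerate inputs", {
  expect_equal(nn_distances(rbind(c(0, 0, 0), c(10, 0, 0))), c(10, 10))
  expect_equal(as.numeric(nn_distances(cbind(c(0, 10, 25), 0, 0))),
               c(10, 10, 15))
  expect_error(nn_distances(cbind(1, 1, 1)), "at least 2")
  d <- nn_distances(rbind(c(1, 2, 3), c(1, 2, 3), c(9, 9, 9)))
  expect_equal(d[1:2], c(0, 0))
  expect_identical(attr(d, "duplicates"), 1:2)
})

test_that("spatial-index NN equals the brute force on random patterns", {
  set.seed(51)
  for (rep in 1:10) {
    n <- sample(100:500, 1)
    pts <- cbind(runif(n, 0, 2000), runif(n, 0, 1000), runif(n, 0, 500))
    expect_equal(as.numeric(nn_distances(pts)), brute_nn(pts))
  }
})

test_that("NNI is calibrated on CSR input", {
  m <- box_mask(1000, 25)
  nnis <- vapply(1:20, function(s) {
    p <- make_point_pattern(m, 500, "CSR", seed = s)
    nni(p, m, n_sims = 100, seed = 5000 + s)$nni
  }, numeric(1))
  expect_gte(mean(nnis >= 0.95 & nnis <= 1.05), 0.95)
})

test_that("clustered input gives NNI < 1; lattice gives NNI > 1", {
  m <- box_mask(1000, 25)
  th <- make_point_pattern(m, 200, "thomas", n_parents = 40, sigma_um = 30,
                           seed = 3)
  expect_lt(nni(th, m, n_sims = 50, seed = 4)$nni, 1)
  lat <- make_point_pattern(m, 500, "lattice")
  expect_gt(nni(lat, m, n_sims = 50, seed = 5)$nni, 1)
})

test_that("NNI decreases monotonically with Thomas dispersion sigma", {
  m <- box_mask(1000, 25)
  med <- vapply(c(100, 50, 25), function(sig) {
    median(vapply(1:20, function(s) {
      p <- make_point_pattern(m, 200, "thomas", n_parents = 40,
                              sigma_um = sig, seed = 100 * sig + s)
      nni(p, m, n_sims = 20, seed = 7000 + 100 * sig + s)$nni
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med) < 0))
})

test_that("points outside the mask are reported by row", {
  m <- box_mask(500, 25)
  pts <- rbind(c(100, 100, 100), c(9000, 0, 0))
  expect_error(nni(pts, m, n_sims = 5), "rows 2")
})

test_that("paired sim-vs-obs t test: hand example and degenerate branches", {
  r0 <- paired_sim_vs_obs_test(c(1, 2, 3), c(1, 2, 3))
  expect_identical(r0$statistic, 0)
  expect_identical(r0$p_value, 1)
  r1 <- paired_sim_vs_obs_test(c(2, 3, 4, 5), c(1, 2, 3, 4)) # sd(d) = 0
  expect_identical(r1$statistic, Inf)
  expect_identical(r1$p_value, 0)
  obs <- c(10, 12, 9, 14, 11)
  sim <- c(11, 13, 10, 13, 13)
  d <- obs - sim
  r2 <- paired_sim_vs_obs_test(obs, sim)
  expect_equal(r2$statistic, mean(d) / (sd(d) / sqrt(5)))
  expect_equal(r2$p_value, 2 * pt(-abs(r2$statistic), 4))
  expect_error(paired_sim_vs_obs_test(1, 1), "at least 2")
})

test_that("dense cells: worked 6-point example and boundary logic", {
  two <- rbind(c(0, 0, 0), c(8, 0, 0))
  dc2 <- dense_cells(two)
  expect_equal(dc2$dense_threshold_um, 6)
  expect_false(any(dc2$dense)) # d < 0.75 d is false
  pts <- cbind(c(0, 5, 100, 108, 200, 300), 0, 0)
  dc <- dense_cells(pts)
  expect_equal(dc$dense_threshold_um, 0.75 * mean(c(5, 5, 8, 8, 92, 100)))
  expect_equal(dc$dense_threshold_um, 27.25)
  expect_identical(which(dc$dense), 1:4)
  expect_error(dense_cells(pts, factor = 0), "factor")
  expect_error(dense_cells(pts, factor = 1.2), "factor")
})

test_that("components: duos, chains and the empty dense set", {
  pts <- cbind(c(0, 5, 100, 108, 200, 300), 0, 0)
  dc <- dense_cells(pts)
  sc <- split_components(pts, dc$dense, dc$dense_threshold_um)
  expect_identical(sc$duo_count, 2L)
  expect_identical(sc$minigroup_count, 0L)
  expect_identical(sc$component_id[1], sc$component_id[2])
  expect_identical(sc$component_id[3], sc$component_id[4])
  expect_false(identical(sc$component_id[1], sc$component_id[3]))

  chain <- cbind(seq(0, 40, by = 10), 0, 0) # string of pearls
  sc2 <- split_components(chain, rep(TRUE, 5), 12)
  expect_identical(sc2$minigroup_count, 1L)
  expect_identical(sc2$component_sizes, 5L)

  sc3 <- split_components(chain, rep(FALSE, 5), 12)
  expect_identical(length(sc3$component_sizes), 0L)
})

test_that("components match a brute-force oracle on random patterns", {
  set.seed(52)
  for (rep in 1:10) {
    n <- 60
    pts <- cbind(runif(n, 0, 300), runif(n, 0, 300), runif(n, 0, 300))
    dc <- dense_cells(pts)
    sc <- split_components(pts, dc$dense, dc$dense_threshold_um)
    dense_pts <- pts[dc$dense, , drop = FALSE]
    if (nrow(dense_pts) == 0) next
    oc <- brute_components(dense_pts, dc$dense_threshold_um)
    # same partition up to labelling
    got <- sc$component_id[dc$dense]
    expect_identical(length(unique(got)), length(unique(oc)))
    expect_true(all(tapply(oc, got, function(v) length(unique(v))) == 1))
  }
})

test_that("neighbouring cells: non-strict threshold and subset property", {
  pts <- cbind(c(0, 5, 100, 108, 200, 300), 0, 0)
  dc <- dense_cells(pts)
  nb <- neighbouring_cells(dc$nn_um, dc$dense, 6)
  expect_identical(which(nb), 1:2) # NN 5 <= 6; 8 > 6
  nb5 <- neighbouring_cells(dc$nn_um, dc$dense, 5) # equality counts
  expect_identical(which(nb5), 1:2)
  expect_error(neighbouring_cells(dc$nn_um, dc$dense, -1), "non-negative")
  set.seed(53)
  for (rep in 1:100) {
    p <- cbind(runif(30, 0, 200), runif(30, 0, 200), runif(30, 0, 200))
    dcc <- dense_cells(p)
    nbb <- neighbouring_cells(dcc$nn_um, dcc$dense, runif(1, 0, 50))
    expect_true(all(!nbb | dcc$dense))
  }
  # zero threshold: only coincident points qualify
  dup <- rbind(c(0, 0, 0), c(0, 0, 0), c(50, 0, 0), c(60, 0, 0))
  dcd <- dense_cells(dup)
  expect_identical(which(neighbouring_cells(dcd$nn_um, dcd$dense, 0)), 1:2)
})

test_that("per-100 normalization", {
  expect_equal(per_hundred(3, 150), 2)
  expect_equal(per_hundred(0, 37), 0)
  expect_equal(per_hundred(c(7, 11), 200), c(3.5, 5.5))
  expect_warning(out <- per_hundred(2, 0), "undefined")
  expect_true(is.na(out))
})

test_that("all point statistics are invariant to input ordering", {
  set.seed(54)
  pts <- cbind(runif(80, 0, 400), runif(80, 0, 400), runif(80, 0, 400))
  perm <- sample(80)
  a <- cluster_analysis(pts, th_mean_nn_um = 40)
  b <- cluster_analysis(pts[perm, ], th_mean_nn_um = 40)
  expect_equal(a$dense_threshold_um, b$dense_threshold_um)
  expect_identical(a$dense[perm], b$dense)
  expect_identical(sort(a$component_sizes), sort(b$component_sizes))
  expect_identical(a$duo_count, b$duo_count)
  expect_identical(a$minigroup_count, b$minigroup_count)
  expect_identical(a$neighbouring[perm], b$neighbouring)
})
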