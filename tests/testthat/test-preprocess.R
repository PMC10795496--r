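test_that("pass-through filter keeps closed intervals exactly", {
  pc <- point_cloud(cbind(0, 0, c(100, 400, 900)))
  out <- passthrough_filter(pc, list(z = c(200, 600)))
  expect_equal(npoints(out), 1)
  expect_equal(out$points[1, 3], 400)

  # boundary point exactly at min is kept (closed interval)
  pc2 <- point_cloud(cbind(c(200, 199.999), 0, 0))
  expect_equal(npoints(passthrough_filter(pc2, list(x = c(200, 300)))), 1)

  expect_error(passthrough_filter(pc, list()), "at least one axis")
  expect_error(passthrough_filter(pc, list(z = c(1, 2))), "every point")
})

test_that("excess-green filtering separates vegetation from soil and gray", {
  expect_equal(excess_green(matrix(c(0, 255, 0), 1)), 2)
  expect_equal(excess_green(matrix(c(128, 128, 128), 1)), 0)
  cols <- rbind(c(0, 255, 0),      # pure green: kept
                c(139, 69, 19),    # brown soil: removed (ExG ~ -0.32)
                c(128, 128, 128))  # gray: removed at 0.2
  pc <- point_cloud(rand_cloud(3), cols)
  out <- color_threshold_filter(pc, 0.2)
  expect_equal(npoints(out), 1)
  expect_equal(out$colors[1, ], c(0, 255, 0))

  # threshold -2 is the identity (lower bound of the index)
  expect_equal(npoints(color_threshold_filter(pc, -2)), 3)
  expect_error(color_threshold_filter(point_cloud(rand_cloud(3))), "colors")
})

test_that("statistical outlier removal drops exactly the far point", {
  grid <- cbind(as.matrix(expand.grid(1:20, 1:20)), 0)
  pc <- point_cloud(rbind(grid, c(50, 50, 50)))
  out <- statistical_outlier_removal(pc, k = 8, std_mult = 2)
  expect_equal(npoints(out), 400)
  expect_false(any(out$points[, 3] == 50))

  # uniform grid with no outlier keeps >= 99% (corners are the only points
  # whose neighbour statistic strays far beyond the global spread)
  out2 <- statistical_outlier_removal(point_cloud(grid), k = 8, std_mult = 2.5)
  expect_gte(npoints(out2) / 400, 0.99)

  # identical duplicated points: zero variance, all retained
  dup <- point_cloud(matrix(1, 50, 3) + 0)
  expect_equal(npoints(statistical_outlier_removal(dup, k = 5, 1)), 50)
  expect_error(statistical_outlier_removal(dup, k = 50, 1), "more than k")
})

test_that("filters are subsets with colors paired, and compose reproducibly", {
  set.seed(37)
  pts <- rand_cloud(300, scale = 50)
  cols <- matrix(sample(0:255, 900, TRUE), ncol = 3)
  pc <- point_cloud(pts, cols)
  run <- function() {
    a <- passthrough_filter(pc, list(x = c(-60, 60), z = c(-40, 40)))
    b <- color_threshold_filter(a, -1.5)
    statistical_outlier_removal(b, k = 10, std_mult = 2)
  }
  o1 <- run(); o2 <- run()
  expect_identical(o1$points, o2$points)
  # every output row is an input row with its original color
  key_in <- apply(cbind(pts, cols), 1, paste, collapse = ",")
  key_out <- apply(cbind(o1$points, o1$colors), 1, paste, collapse = ",")
  expect_true(all(key_out %in% key_in))
  expect_lte(npoints(o1), npoints(pc))
})

test_that("region growing separates parallel planes and labels leaves", {
  g <- as.matrix(expand.grid(seq(0, 40, length.out = 32),
                             seq(0, 40, length.out = 32)))
  pc <- point_cloud(rbind(cbind(g, 0), cbind(g, 100)))
  seg <- region_growing_segment(pc)
  expect_length(seg$clusters, 2)
  expect_equal(sort(lengths(seg$clusters)), c(1024, 1024))
  # clusters plus residual partition the input
  all_idx <- sort(c(unlist(seg$clusters), seg$residual))
  expect_identical(all_idx, seq_len(2048L))
  expect_equal(anyDuplicated(unlist(seg$clusters)), 0L)
})

test_that("a smooth synthetic leaf segments into one dominant cluster", {
  fx <- sample_leaf(leaf_spec(points = 4000, noise_sd = 0,
                              fold_amplitude = 1.5, seed = 3))
  seg <- region_growing_segment(fx$cloud,
                                segmentation_config(smoothness_deg = 8))
  expect_length(seg$clusters, 1)
  expect_gte(length(seg$clusters[[1]]) / 4000, 0.95)
})

test_that("a two-leaf plant splits into clusters matching the true labels", {
  pl <- make_plant(list(leaf_spec(points = 1500, noise_sd = 0.2, seed = 1),
                        leaf_spec(points = 1500, noise_sd = 0.2, seed = 2)),
                   phyllotaxis_angle = 180, inclination = 30, seed = 5)
  seg <- region_growing_segment(
    point_cloud(pl$cloud$points),
    segmentation_config(smoothness_deg = 6, min_cluster = 150))
  expect_gte(length(seg$clusters), 2)
  overlap <- vapply(seg$clusters[1:2], function(ix)
    max(mean(pl$labels[ix] == 1), mean(pl$labels[ix] == 2)), 0)
  expect_true(all(overlap >= 0.9))
})
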