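test_that("flat leaf area matches the closed-form outline integral", {
  sp <- leaf_spec(length = 100, max_width = 50, outline_shape = 1,
                  bend_curvature = 0, fold_amplitude = 0, noise_sd = 0,
                  points = 500, seed = 7)
  # area = 2 L integral w(u) du = 2 L (W/2)(2/pi) = 2 L W / pi
  expect_equal(leaf_reference_area(sp), 2 * 100 * 50 / pi / 100,
               tolerance = 1e-3)
  # corrugation strictly adds area for the same outline
  folded <- leaf_spec(length = 100, max_width = 50, outline_shape = 1,
                      bend_curvature = 0, fold_amplitude = 2, fold_count = 3,
                      noise_sd = 0, points = 500, seed = 7)
  expect_gt(leaf_reference_area(folded), leaf_reference_area(sp))
})

test_that("quadrature converges and fixtures are seed-deterministic", {
  sp <- leaf_spec(points = 500, seed = 3)
  a1 <- leaf_reference_area(sp, 512)
  a2 <- leaf_reference_area(sp, 1024)
  expect_lt(abs(a1 - a2) / a2, 1e-4)
  f1 <- sample_leaf(sp)
  f2 <- sample_leaf(sp)
  expect_identical(f1$cloud$points, f2$cloud$points)
  expect_equal(npoints(f1$cloud), 500)
  expect_gt(f1$reference_area, 0)
})

test_that("sampling density is uniform by surface area", {
  sp <- leaf_spec(points = 8000, noise_sd = 0, fold_amplitude = 1.5, seed = 11)
  fx <- sample_leaf(sp)
  surf <- leafcomplete:::.leaf_surface(sp)
  # bin points into u-strips of equal surface area via the cumulative
  # area profile, then chi-square against the uniform expectation
  n <- 400
  uu <- (seq_len(n) - 0.5) / n
  strip <- vapply(uu, function(u)
    sum(surf$darea(u, -1 + 2 * (seq_len(n) - 0.5) / n)) * (2 / n), 0)
  cum <- cumsum(strip) / sum(strip)
  brk <- vapply((1:9) / 10, function(q) uu[which.min(abs(cum - q))], 0)
  bins <- cut(fx$uv[, 1], c(0, brk, 1))
  p <- chisq.test(table(bins))$p.value
  expect_gt(p, 0.01)
})

test_that("plants carry consistent labels and a color-separable soil disc", {
  specs <- list(leaf_spec(points = 800, seed = 1),
                leaf_spec(points = 800, seed = 2))
  pl <- make_plant(specs, soil = TRUE, seed = 4)
  expect_equal(sum(pl$labels >= 1), 1600)
  expect_true(all(table(pl$labels[pl$labels >= 1]) == 800))
  # ExG threshold removes (almost) all soil while keeping the leaves
  kept <- color_threshold_filter(pl$cloud, 0.2)
  soil_pts <- pl$cloud$points[pl$labels == 0, , drop = FALSE]
  kept_key <- apply(kept$points, 1, paste, collapse = ",")
  soil_kept <- mean(apply(soil_pts, 1, paste, collapse = ",") %in% kept_key)
  expect_lt(soil_kept, 0.01)
  leaf_pts <- pl$cloud$points[pl$labels >= 1, , drop = FALSE]
  leaf_kept <- mean(apply(leaf_pts, 1, paste, collapse = ",") %in% kept_key)
  expect_gt(leaf_kept, 0.95)

  # a single leaf plant is the leaf up to the placement transform
  one <- make_plant(specs[1], seed = 4)
  expect_equal(npoints(one$cloud), 800)
  d <- as.matrix(dist(one$cloud$points[1:50, ]))
  fx <- sample_leaf(specs[[1]])
  d0 <- as.matrix(dist(fx$cloud$points[1:50, ]))
  expect_equal(d, d0, tolerance = 1e-9)
})

test_that("the z-buffer view reproduces visibility geometry", {
  # unobstructed flat leaf seen from above: nearly all points visible
  flat <- sample_leaf(leaf_spec(bend_curvature = 0, fold_amplitude = 0,
                                points = 2000, noise_sd = 0, seed = 2))
  v <- simulate_rgbd_view(flat$cloud, resolution = 256)
  expect_gte(length(v$kept_idx) / 2000, 0.95)

  # two offset parallel sheets: the lower one loses exactly the pixels
  # owned by the upper one
  g <- as.matrix(expand.grid(seq(0, 40, 0.8), seq(0, 40, 0.8)))
  lower <- cbind(g, 0)
  upper <- cbind(g[g[, 1] <= 20, , drop = FALSE], 10)  # covers half
  both <- rbind(lower, upper)
  v2 <- simulate_rgbd_view(both, resolution = 64)
  lower_idx <- seq_len(nrow(lower))
  vis_lower <- intersect(v2$kept_idx, lower_idx)
  expect_lt(length(vis_lower) / nrow(lower), 1)
  # z-buffer oracle: recompute pixel ownership directly
  res <- 64L
  ext <- c(range(both[, 1]), range(both[, 2]))
  px <- pmin(pmax(ceiling((both[, 1] - ext[1]) / (ext[2] - ext[1]) * res), 1L), res)
  py <- pmin(pmax(ceiling((both[, 2] - ext[3]) / (ext[4] - ext[3]) * res), 1L), res)
  pix <- (py - 1L) * res + px
  hidden_lower <- setdiff(lower_idx, v2$kept_idx)
  upper_pix <- unique(pix[-lower_idx])
  expect_true(all(pix[hidden_lower] %in% upper_pix))

  # doubling the resolution never decreases the visible count
  v_lo <- simulate_rgbd_view(flat$cloud, resolution = 64)
  v_hi <- simulate_rgbd_view(flat$cloud, resolution = 128)
  expect_gte(length(v_hi$kept_idx), length(v_lo$kept_idx))
})
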