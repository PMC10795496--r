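test_that("Delaunay 2.5D handles canonical planar cases", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  m <- delaunay_25d(sq)
  expect_equal(nrow(m$triangles), 2)
  expect_equal(mesh_area(m), 0.01)  # 1 mm^2 = 0.01 cm^2

  g <- cbind(as.matrix(expand.grid(0:9, 0:9)), 0)
  mg <- delaunay_25d(g)
  expect_equal(nrow(mg$triangles), 162)  # 2 (10-1)^2
  expect_identical(mg$vertices, g + 0)   # vertex positions unchanged

  big <- cbind(as.matrix(expand.grid(seq(0, 100, 2), seq(0, 100, 2))), 0)
  expect_equal(mesh_area(delaunay_25d(big)), 100, tolerance = 1e-9)

  line <- cbind(1:20, 1:20, 0)
  expect_error(delaunay_25d(line), "collinear")
})

test_that("long-edge pruning keeps concave outlines hollow", {
  set.seed(97)
  th <- runif(4000, 0, 2 * pi)
  r <- runif(4000, 8, 10)                     # annulus-like crescent
  keep <- th < 1.5 * pi
  cres <- cbind(r[keep] * cos(th[keep]), r[keep] * sin(th[keep]), 0)
  m <- delaunay_25d(cres, prune_factor = 3)
  full <- delaunay_25d(cres, prune_factor = 1e9)
  elen <- function(msh) {
    e <- rbind(msh$triangles[, 1:2], msh$triangles[, 2:3],
               msh$triangles[, c(3, 1)])
    sqrt(rowSums((msh$vertices[e[, 1], ] - msh$vertices[e[, 2], ])^2))
  }
  expect_lte(max(elen(m)), 3 * median(elen(full)))
  # no triangle spans the central hole or the concave gap
  cent <- (m$vertices[m$triangles[, 1], ] + m$vertices[m$triangles[, 2], ] +
             m$vertices[m$triangles[, 3], ]) / 3
  expect_gt(min(sqrt(rowSums(cent[, 1:2]^2))), 6)
  # pruned planar area never exceeds the convex-hull area
  hull <- grDevices::chull(cres[, 1:2])
  hx <- cres[hull, 1]; hy <- cres[hull, 2]
  hull_area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2 / 100
  expect_lt(mesh_area(m), hull_area)
})

test_that("Laplacian smoothing contracts spikes but fixes the boundary", {
  g <- cbind(as.matrix(expand.grid(0:10, 0:10)), 0)
  m <- delaunay_25d(g)
  expect_identical(laplace_smooth(m, iterations = 0L)$vertices, m$vertices)
  # planar mesh is a fixed point
  sm <- laplace_smooth(m, iterations = 5L, lam = 0.5)
  expect_lt(max(abs(sm$vertices - m$vertices)), 1e-12)
  # one interior spike decays strictly every iteration
  spiked <- m
  apex <- which(spiked$vertices[, 1] == 5 & spiked$vertices[, 2] == 5)
  spiked$vertices[apex, 3] <- 4
  h <- numeric(6); h[1] <- 4
  cur <- spiked
  for (it in 1:5) {
    cur <- laplace_smooth(cur, iterations = 1L, lam = 0.5)
    h[it + 1] <- cur$vertices[apex, 3]
  }
  expect_true(all(diff(h) < 0))
  expect_identical(cur$triangles, m$triangles)
  # boundary vertices never move
  ed <- leafcomplete:::.mesh_edges(m$triangles)
  bnd <- unique(as.vector(ed$edges[ed$count == 1L, ]))
  sm2 <- laplace_smooth(spiked, iterations = 10L, lam = 0.5)
  expect_identical(sm2$vertices[bnd, ], spiked$vertices[bnd, ])
})

test_that("mesh area is invariant under rigid motion", {
  set.seed(101)
  fx <- sample_leaf(leaf_spec(points = 2500, noise_sd = 0, seed = 5))
  m <- delaunay_25d(fx$cloud)
  a0 <- mesh_area(m)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  m2 <- triangle_mesh(m$vertices %*% t(R) +
                        matrix(c(10, -4, 2), nrow(m$vertices), 3, byrow = TRUE),
                      m$triangles)
  expect_equal(mesh_area(m2), a0, tolerance = 1e-9)
})

test_that("mesh area tracks the analytic and quadrature references", {
  # flat blade through the full pipeline (smoothing is a no-op on a plane)
  flat <- leaf_spec(length = 100, max_width = 50, outline_shape = 1,
                    bend_curvature = 0, fold_amplitude = 0, noise_sd = 0,
                    points = 60000, seed = 4)
  analytic <- 2 * 100 * 50 / pi / 100   # cm^2
  expect_equal(leaf_reference_area(flat), analytic, tolerance = 1e-3)
  res <- leaf_area_pipeline(sample_leaf(flat)$cloud)
  expect_lt(abs(res$area_cm2 - analytic) / analytic, 0.01)

  # folded and bent blade against the quadrature oracle (>= 5 points/mm^2)
  curved <- leaf_spec(length = 160, max_width = 90, outline_shape = 1.4,
                      bend_curvature = 0.005, fold_amplitude = 1,
                      fold_count = 2, noise_sd = 0, points = 100, seed = 6)
  ref <- leaf_reference_area(curved)
  curved$points <- as.integer(round(ref * 100 * 8))   # 8 points per mm^2
  fx <- sample_leaf(curved)
  a <- mesh_area(delaunay_25d(fx$cloud))
  expect_lt(abs(a - ref) / ref, 0.02)
})

test_that("occlusion strictly reduces measured area", {
  flat <- sample_leaf(leaf_spec(length = 100, max_width = 50,
                                outline_shape = 1, bend_curvature = 0,
                                fold_amplitude = 0, noise_sd = 0,
                                points = 8000, seed = 9))
  full_area <- leaf_area_pipeline(flat$cloud)$area_cm2
  occ <- occlude(normalize_unit_sphere(flat$cloud)$cloud,
                 generate_viewpoints(21)[2, ], 0.2)
  norm <- normalize_unit_sphere(flat$cloud)
  kept_world <- point_cloud(sweep(occ$kept$points * norm$K, 2, norm$G, "+"))
  occ_area <- leaf_area_pipeline(kept_world)$area_cm2
  expect_lt(occ_area, full_area)
  expect_lt(occ_area, flat$reference_area)
})
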