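test_that("unit-sphere normalisation is exact and invertible", {
  res <- normalize_unit_sphere(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(res$cloud$points, rbind(c(-1, 0, 0), c(1, 0, 0)))
  expect_equal(res$G, c(1, 0, 0))
  expect_equal(res$K, 1)

  set.seed(43)
  pts <- rand_cloud(200, scale = 80)
  r1 <- normalize_unit_sphere(pts)
  expect_equal(max(sqrt(rowSums(r1$cloud$points^2))), 1)
  # already-normalised cloud: K ~ 1, near identity
  r2 <- normalize_unit_sphere(r1$cloud)
  expect_equal(r2$K, 1, tolerance = 1e-12)
  # inversion
  back <- sweep(r1$cloud$points * r1$K, 2, r1$G, "+")
  expect_lt(max(abs(back - pts)), 1e-6)
  expect_error(normalize_unit_sphere(matrix(1, 5, 3)), "zero scale")
})

test_that("viewpoint lattice is deterministic with unit norms", {
  vp <- generate_viewpoints(21)
  expect_equal(dim(vp), c(21, 3))
  expect_true(all(abs(sqrt(rowSums(vp^2)) - 1) < 1e-9))
  expect_identical(vp, generate_viewpoints(21))
  v2 <- generate_viewpoints(2)
  ang <- acos(sum(v2[1, ] * v2[2, ])) * 180 / pi
  expect_gt(ang, 90)
  expect_error(generate_viewpoints(0), "at least one")
})

test_that("occlusion removes exactly the ranked farthest points", {
  # collinear points on the x axis, viewpoint at the +x pole: the removed
  # half is the one with smallest x
  pts <- cbind(seq(-1, 1, length.out = 10), 0, 0)
  occ <- occlude(pts, c(1, 0, 0), 0.5)
  expect_equal(sort(occ$removed$points[, 1]), pts[1:5, 1])
  expect_equal(length(occ$removed_idx), 5)

  set.seed(47)
  cl <- normalize_unit_sphere(rand_cloud(1000))$cloud
  occ2 <- occlude(cl, generate_viewpoints(21)[4, ], 0.2)
  expect_equal(npoints(occ2$removed), 200)
  # kept and removed partition the input
  expect_identical(sort(c(occ2$kept_idx, occ2$removed_idx)), 1:1000)
  # label consistency: removed indices are exactly the m largest distances
  d <- sqrt(rowSums(sweep(cl$points, 2, generate_viewpoints(21)[4, ])^2))
  expect_setequal(occ2$removed_idx, order(-d, seq_along(d))[1:200])
  expect_error(occlude(pts, c(1, 0, 0), 0.01), "removes 0")
})

test_that("samples have fixed sizes at every ratio and reject small leaves", {
  fx <- sample_leaf(leaf_spec(points = 4100, seed = 3))
  for (r in c(0.2, 0.35, 0.5)) {
    smp <- build_sample(fx$cloud, 2, r, seed = 9)
    expect_s3_class(smp, "completion_sample")
    expect_equal(nrow(smp$incomplete), 2048)
    expect_equal(nrow(smp$missing_gt), 512)
    # disjoint subsets of the normalised leaf, inside the unit sphere
    expect_lte(max(sqrt(rowSums(smp$incomplete^2))), 1 + 1e-6)
    ki <- apply(smp$incomplete, 1, paste, collapse = ",")
    kg <- apply(smp$missing_gt, 1, paste, collapse = ",")
    expect_length(intersect(ki, kg), 0)
  }
  # a 2,559-point leaf cannot support ratio 0.5 (kept 1,280 < 2,048)
  small <- sample_leaf(leaf_spec(points = 2559, seed = 4))
  rej <- build_sample(small$cloud, 1, 0.5, seed = 1)
  expect_s3_class(rej, "sample_rejection")
  expect_match(rej$reason, "insufficient")
  # determinism
  s1 <- build_sample(fx$cloud, 5, 0.35, seed = 123)
  s2 <- build_sample(fx$cloud, 5, 0.35, seed = 123)
  expect_identical(s1$incomplete, s2$incomplete)
  expect_identical(s1$missing_gt, s2$missing_gt)
})

test_that("corpus counts multiply out and the manifest tracks rejections", {
  fx <- sample_leaf(leaf_spec(points = 4100, seed = 6))
  ds <- build_dataset(list(leafA = fx$cloud), seed = 1)
  expect_equal(nrow(ds$manifest), 63)   # 1 leaf x 21 viewpoints x 3 ratios
  expect_equal(sum(ds$manifest$accepted), 63)
  expect_length(ds$samples, 63)

  # a leaf too small for ratio 0.5 is rejected with a recorded reason
  small <- sample_leaf(leaf_spec(points = 3500, seed = 7))
  ds2 <- build_dataset(list(a = fx$cloud, b = small$cloud),
                       n_viewpoints = 3, seed = 1)
  rej <- ds2$manifest[!ds2$manifest$accepted, ]
  expect_true(all(rej$leaf_id == "b" & rej$ratio == 0.5))
  expect_true(all(nzchar(rej$reason)))
})

test_that("the 7:3 split is by leaf and leak-free", {
  specs <- random_leaf_specs(10, seed = 53, points = 2600, noise_sd = 0.2)
  leaves <- lapply(specs, function(s) sample_leaf(s)$cloud)
  ds <- build_dataset(leaves, ratios = 0.2, n_viewpoints = 3, seed = 2)
  ds <- split_dataset(ds, seed = 7)
  by_leaf <- tapply(ds$manifest$split, ds$manifest$leaf_id,
                    function(x) length(unique(x)))
  expect_true(all(by_leaf == 1))  # every leaf wholly in one split
  expect_equal(length(unique(ds$manifest$leaf_id[ds$manifest$split == "train"])), 7)
  expect_equal(length(unique(ds$manifest$leaf_id[ds$manifest$split == "validation"])), 3)
  # same seed, same split; no sample in both splits by construction
  ds2 <- split_dataset(ds, seed = 7)
  expect_identical(ds$manifest$split, ds2$manifest$split)
  expect_error(split_dataset(build_dataset(leaves[1], ratios = 0.2,
                                           n_viewpoints = 3, seed = 2)),
               "at least 2 leaves")
})
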