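# Shared (memoised) trained model and corpora for the heavier end-to-end
# tests, so training happens once per test run.

.test_cache <- new.env(parent = emptyenv())

# pose-canonicalised synthetic leaves for corpus building. With
# mirror = TRUE each leaf is also included rotated 180 degrees in-plane
# (same leaf id, so splits stay leak-free): the canonicalisation's
# major-axis sign is unstable on near-symmetric blades, and training on
# both orientations makes the completion equivariant to that flip.
canonical_leaves <- function(specs, mirror = FALSE) {
  base <- lapply(specs, function(s) normalize_pose(sample_leaf(s)$cloud)$cloud)
  if (!mirror) return(base)
  flipped <- lapply(base, function(cl)
    point_cloud(cl$points %*% diag(c(-1, -1, 1))))
  out <- c(base, flipped)
  names(out) <- c(names(base), names(base))
  out
}

# forward pose transform: world -> canonical frame of a pose record
pose_forward <- function(X, rec) {
  (sweep(as_points(X), 2, rec$G) / rec$K) %*% t(rec$R)
}

# Occlusion corpus constructed in the frame available at deployment: each
# incomplete cloud is pose-normalised by ITSELF (as a real capture must
# be, since the full leaf is unknown at inference) and the missing ground
# truth is mapped through the same pose record. Mirrored copies make the
# model robust to the major-axis sign flip. Sample shapes match the
# standard corpus (2,048 / 512).
deployment_corpus <- function(specs, ratios, n_viewpoints, seed,
                              n_in = 2048L, n_gt = 512L) {
  vps <- generate_viewpoints(n_viewpoints)
  samples <- list()
  leaf_ids <- character()
  k <- 0L
  for (li in seq_along(specs)) {
    leaf <- normalize_pose(sample_leaf(specs[[li]])$cloud)$cloud
    norm <- normalize_unit_sphere(leaf)
    for (vi in seq_len(n_viewpoints)) for (r in ratios) {
      occ <- occlude(norm$cloud, vps[vi, ], r)
      kept_w <- sweep(occ$kept$points * norm$K, 2, norm$G, "+")
      rem_w <- sweep(occ$removed$points * norm$K, 2, norm$G, "+")
      np <- normalize_pose(kept_w)
      gt <- pose_forward(rem_w, np$record)
      for (mir in c(FALSE, TRUE)) {
        M <- if (mir) diag(c(-1, -1, 1)) else diag(3)
        inc_c <- np$cloud$points %*% M
        gt_c <- gt %*% M
        k <- k + 1L
        samples[[k]] <- structure(list(
          incomplete = inc_c[ifps_sample(inc_c, n_in, 1L), , drop = FALSE],
          missing_gt = gt_c[ifps_sample(gt_c, n_gt, 1L), , drop = FALSE],
          leaf_id = names(specs)[li], viewpoint_id = vi, ratio = r,
          source_style = "rgbd_like"), class = "completion_sample")
        leaf_ids[k] <- names(specs)[li]
      }
    }
  }
  manifest <- data.frame(sample_id = seq_len(k), leaf_id = leaf_ids,
                         accepted = TRUE, stringsAsFactors = FALSE)
  structure(list(samples = samples, manifest = manifest, seed = seed),
            class = "completion_dataset")
}

# tiny completion model trained on a moderate synthetic corpus in the
# deployment frame; used by the area-improvement benchmark
bench_model <- function() {
  if (!is.null(.test_cache$bench)) return(.test_cache$bench)
  specs <- random_leaf_specs(15, seed = 11, points = 4100, noise_sd = 0.5)
  ds <- deployment_corpus(specs, c(0.2, 0.35), 11L, seed = 5L)
  ds <- split_dataset(ds, seed = 5)
  fit <- pfnet(ds, net = pfnet_config("tiny"),
               control = train_control(batch_size = 8, learning_rate = 1e-3,
                                       epochs = 10, seed = 1))
  .test_cache$bench <- fit
  fit
}

# occlude a leaf fixture at a ratio from one of the lattice viewpoints and
# measure leaf area before and after completion (in world mm)
area_error_pair <- function(fx, model, viewpoint_id, ratio = 0.2) {
  ref <- fx$reference_area
  vp <- generate_viewpoints(21)[viewpoint_id, ]
  norm <- normalize_unit_sphere(fx$cloud)
  occ <- occlude(norm$cloud, vp, ratio)
  kept_world <- point_cloud(sweep(occ$kept$points * norm$K, 2, norm$G, "+"))
  a_occ <- leaf_area_pipeline(kept_world)$area_cm2
  np <- normalize_pose(kept_world)
  n_in <- model$net$input_scales[1]
  inc <- np$cloud$points[ifps_sample(np$cloud, n_in, 1L), , drop = FALSE]
  world <- recover_pose(complete_cloud(inc, model)$fused, np$record)
  a_comp <- leaf_area_pipeline(world)$area_cm2
  c(occluded = abs(a_occ - ref) / ref, completed = abs(a_comp - ref) / ref)
}
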