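#' End-to-end pipeline orchestration
#'
#' Wires the stages of the reconstruction workflow - synthetic plant
#' generation, preprocessing/segmentation, occlusion-corpus construction,
#' network training, per-leaf completion with pose recovery, and leaf-area
#' measurement - behind one declarative configuration. Every run writes
#' its fully-resolved configuration and a manifest (every produced file
#' with a content hash) next to its outputs, and is reproducible from
#' (config, seed).
#'
#' @name pipeline
NULL

.pc_check_keys <- function(block, allowed, where) {
  bad <- setdiff(names(block), allowed)
  if (length(bad))
    stop("unknown configuration key(s) in ", where, ": ",
         paste(bad, collapse = ", "))
  block
}

#' Pipeline configuration
#'
#' Unknown keys are rejected (typo safety). Defaults describe a small but
#' complete synthetic run; real uses override per-stage blocks.
#'
#' @param seed global seed; every stage derives its randomness from it
#' @param out_dir output directory
#' @param simulate,preprocess,dataset,train,reconstruct,area per-stage
#'   option lists (see source for keys)
#' @return a list of class `"pipeline_config"`
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("leafrun"),
                            simulate = list(), preprocess = list(),
                            dataset = list(), train = list(),
                            reconstruct = list(), area = list()) {
  sim <- utils::modifyList(list(n_leaves = 3L, points = 4000L, noise_sd = 0.4,
                                soil = TRUE, background = FALSE,
                                resolution = 220L),
                           .pc_check_keys(simulate,
                             c("n_leaves", "points", "noise_sd", "soil",
                               "background", "resolution"), "simulate"))
  pre <- utils::modifyList(list(color_threshold = 0.2, sor_k = 20L,
                                sor_std = 1.5, normal_k = 20L,
                                smoothness_deg = 6, curvature_max = 1.0,
                                min_cluster = 150L),
                           .pc_check_keys(preprocess,
                             c("color_threshold", "sor_k", "sor_std",
                               "normal_k", "smoothness_deg", "curvature_max",
                               "min_cluster"), "preprocess"))
  ds <- utils::modifyList(list(n_leaves = 6L, points = 1400L, noise_sd = 0.4,
                               ratios = 0.25, n_viewpoints = 5L,
                               n_in = 512L, n_gt = 128L),
                          .pc_check_keys(dataset,
                            c("n_leaves", "points", "noise_sd", "ratios",
                              "n_viewpoints", "n_in", "n_gt"), "dataset"))
  tr <- utils::modifyList(list(widths = c(16L, 32L, 64L), latent = 128L,
                               scales = c(512L, 256L, 128L),
                               outputs = c(128L, 64L, 32L),
                               batch_size = 8L, learning_rate = 1e-3,
                               epochs = 3L),
                          .pc_check_keys(train,
                            c("widths", "latent", "scales", "outputs",
                              "batch_size", "learning_rate", "epochs"),
                            "train"))
  rc <- .pc_check_keys(reconstruct, character(), "reconstruct")
  ar <- utils::modifyList(list(prune_factor = 3, iterations = 10L, lam = 0.5),
                          .pc_check_keys(area,
                            c("prune_factor", "iterations", "lam"), "area"))
  if (ds$n_in != tr$scales[1] || ds$n_gt != tr$outputs[1])
    stop("dataset sample sizes must match the network scales/outputs")
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 simulate = sim, preprocess = pre, dataset = ds,
                 train = tr, reconstruct = rc, area = ar),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with top-level keys matching [pipeline_config()]
#'   arguments
#' @return a `"pipeline_config"`
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  .pc_check_keys(raw, c("seed", "out_dir", "simulate", "preprocess",
                        "dataset", "train", "reconstruct", "area"),
                 "pipeline config")
  do.call(pipeline_config, raw)
}

#' Run the reconstruction pipeline
#'
#' Executes the requested stages in workflow order. Later stages consume
#' the artifacts of earlier ones; a missing input raises an error naming
#' the stage that should have produced it. Each stage is deterministic
#' given identical inputs, configuration and seed, so re-running a
#' configuration reproduces the manifest hashes.
#'
#' @param config a [pipeline_config()]
#' @param stages ordered subset of
#'   `c("simulate", "preprocess", "dataset", "train", "reconstruct", "area")`
#' @return invisibly, a manifest list: produced files with MD5 hashes plus
#'   per-stage summaries
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "preprocess", "dataset",
                                    "train", "reconstruct", "area")) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c("simulate", "preprocess", "dataset", "train",
                  "reconstruct", "area")
  stages <- all_stages[all_stages %in% stages]
  if (length(setdiff(stages, all_stages)))
    stop("unknown stage(s)")
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  state <- list()
  files <- character()
  summaries <- list()
  note <- function(msg, ...) message(sprintf("[pipeline] %s", sprintf(msg, ...)))

  for (stage in stages) {
    if (stage == "simulate") {
      sc <- config$simulate
      specs <- random_leaf_specs(sc$n_leaves, seed = config$seed,
                                 points = sc$points, noise_sd = sc$noise_sd)
      plant <- make_plant(specs, soil = sc$soil, background = sc$background,
                          seed = config$seed)
      view <- simulate_rgbd_view(plant$cloud, resolution = sc$resolution)
      raw_path <- file.path(out, "raw_view.ply")
      write_cloud(view$cloud, raw_path)
      files <- c(files, raw_path)
      state$raw <- view$cloud
      state$raw_labels <- plant$labels[view$kept_idx]
      summaries$simulate <- list(n_leaves = sc$n_leaves,
                                 visible_points = npoints(view$cloud))
      note("simulate: %d visible points from %d leaves",
           npoints(view$cloud), sc$n_leaves)
    } else if (stage == "preprocess") {
      if (is.null(state$raw))
        stop("preprocess needs the raw capture; run stage 'simulate' first")
      pc <- config$preprocess
      plantc <- color_threshold_filter(state$raw, pc$color_threshold)
      plantc <- statistical_outlier_removal(plantc, pc$sor_k, pc$sor_std)
      seg <- region_growing_segment(plantc, segmentation_config(
        normal_k = pc$normal_k, smoothness_deg = pc$smoothness_deg,
        curvature_max = pc$curvature_max, min_cluster = pc$min_cluster))
      leaf_dir <- file.path(out, "leaves")
      if (!dir.exists(leaf_dir)) dir.create(leaf_dir)
      state$leaves <- lapply(seg$clusters, function(ix) pc_subset(plantc, ix))
      for (i in seq_along(state$leaves)) {
        p <- file.path(leaf_dir, sprintf("leaf%02d.ply", i))
        write_cloud(state$leaves[[i]], p)
        files <- c(files, p)
      }
      summaries$preprocess <- list(clusters = lengths(seg$clusters),
                                   residual = length(seg$residual))
      note("preprocess: %d leaf clusters (residual %d points)",
           length(seg$clusters), length(seg$residual))
    } else if (stage == "dataset") {
      dc <- config$dataset
      specs <- random_leaf_specs(dc$n_leaves, seed = config$seed + 101L,
                                 points = dc$points, noise_sd = dc$noise_sd)
      leaves <- lapply(specs, sample_leaf)
      ds <- build_dataset(leaves, ratios = dc$ratios,
                          n_viewpoints = dc$n_viewpoints,
                          seed = config$seed, n_in = dc$n_in, n_gt = dc$n_gt)
      state$dataset <- split_dataset(ds, seed = config$seed)
      summaries$dataset <- list(samples = sum(ds$manifest$accepted),
                                rejected = sum(!ds$manifest$accepted))
      note("dataset: %d samples", sum(ds$manifest$accepted))
    } else if (stage == "train") {
      if (is.null(state$dataset))
        stop("train needs the occlusion corpus; run stage 'dataset' first")
      tc <- config$train
      net <- pfnet_config(cmlp_widths = tc$widths, latent_dim = tc$latent,
                          input_scales = tc$scales, output_sizes = tc$outputs)
      fit <- pfnet(state$dataset, net = net,
                   control = train_control(batch_size = tc$batch_size,
                                           learning_rate = tc$learning_rate,
                                           epochs = tc$epochs,
                                           seed = config$seed))
      state$fit <- fit
      log_path <- file.path(out, "train_log.csv")
      utils::write.csv(fit$log[, c("epoch", "train_loss", "val_loss",
                                   "val_cd", "alpha", "beta")],
                       log_path, row.names = FALSE)
      files <- c(files, log_path)
      summaries$train <- list(final_train_loss = utils::tail(fit$log$train_loss, 1),
                              final_val_cd = utils::tail(fit$log$val_cd, 1))
      note("train: final validation CD %.5f", utils::tail(fit$log$val_cd, 1))
    } else if (stage == "reconstruct") {
      if (is.null(state$leaves))
        stop("reconstruct needs segmented leaves; run stage 'preprocess' first")
      if (is.null(state$fit))
        stop("reconstruct needs a trained model; run stage 'train' first")
      n_in <- state$fit$net$input_scales[1]
      rec_dir <- file.path(out, "reconstructed")
      if (!dir.exists(rec_dir)) dir.create(rec_dir)
      state$reconstructed <- list()
      skipped <- 0L
      for (i in seq_along(state$leaves)) {
        leaf <- state$leaves[[i]]
        if (npoints(leaf) < n_in) { skipped <- skipped + 1L; next }
        np <- normalize_pose(leaf)
        inc <- np$cloud$points[ifps_sample(np$cloud, n_in, 1L), , drop = FALSE]
        comp <- complete_cloud(inc, state$fit)
        world <- recover_pose(comp$fused, np$record)
        p <- file.path(rec_dir, sprintf("leaf%02d_completed.ply", i))
        write_cloud(world, p)
        pose_p <- file.path(rec_dir, sprintf("leaf%02d.pose.json", i))
        jsonlite::write_json(list(G = np$record$G, K = np$record$K,
                                  R = np$record$R), pose_p,
                             auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
        files <- c(files, p, pose_p)
        state$reconstructed[[length(state$reconstructed) + 1L]] <-
          list(index = i, world = world, observed = leaf)
      }
      summaries$reconstruct <- list(completed = length(state$reconstructed),
                                    skipped_small = skipped)
      note("reconstruct: completed %d leaves (%d too small)",
           length(state$reconstructed), skipped)
    } else if (stage == "area") {
      if (is.null(state$reconstructed))
        stop("area needs completed leaves; run stage 'reconstruct' first")
      ac <- config$area
      rows <- lapply(state$reconstructed, function(r) {
        comp <- leaf_area_pipeline(r$world, ac$prune_factor, ac$iterations,
                                   ac$lam)
        obs <- leaf_area_pipeline(r$observed, ac$prune_factor, ac$iterations,
                                  ac$lam)
        data.frame(leaf = r$index,
                   area_completed_cm2 = comp$area_cm2,
                   area_observed_cm2 = obs$area_cm2)
      })
      report <- do.call(rbind, rows)
      area_path <- file.path(out, "area_report.json")
      jsonlite::write_json(report, area_path, digits = NA)
      files <- c(files, area_path)
      summaries$area <- report
      note("area: reported %d leaves", nrow(report))
    }
  }

  cfg_path <- file.path(out, "resolved_config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  files <- c(files, cfg_path)
  manifest <- list(seed = config$seed, stages = stages,
                   files = data.frame(path = files,
                                      md5 = unname(tools::md5sum(files)),
                                      stringsAsFactors = FALSE),
                   summaries = summaries)
  man_path <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
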