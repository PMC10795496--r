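#' Occlusion training-corpus construction
#'
#' Complete single-leaf clouds are normalised to the unit sphere, observed
#' from a set of viewpoints placed on that sphere, occluded by eliminating
#' the points farthest from each viewpoint at fixed missing ratios, and
#' subsampled by iterative farthest point sampling into fixed-size training
#' pairs: a 2,048-point incomplete cloud and its 512-point missing ground
#' truth. The missing ratio decides *which* points are removed, never *how
#' many* points a sample contains.
#'
#' @name dataset
NULL

#' Normalise a cloud to the unit sphere
#'
#' Subtracts the centroid and divides by the maximum point norm, so the
#' returned cloud has maximum norm exactly 1. The centroid `G` (mm) and
#' scale `K` (mm per unit) suffice to invert the transform.
#'
#' @param cloud a [point_cloud()] or matrix; points must not all coincide
#' @return list with `cloud` (normalised [point_cloud()]), `G` (length-3
#'   centroid, mm) and `K` (scalar scale, mm)
#' @export
normalize_unit_sphere <- function(cloud) {
  colors <- if (inherits(cloud, "point_cloud")) cloud$colors
  pts <- as_points(cloud)
  G <- colMeans(pts)
  centred <- sweep(pts, 2, G)
  K <- sqrt(max(rowSums(centred^2)))
  if (K <= 0) stop("cannot normalise: all points identical (zero scale)")
  normalize <- centred / K
  list(cloud = point_cloud(normalize, colors), G = G, K = K)
}

#' Deterministic viewpoints on the unit sphere
#'
#' Places `n` viewpoints on the unit sphere with the Fibonacci (golden
#' angle) lattice: near-uniform coverage, reproducible bit-for-bit across
#' runs and platforms. These simulate diversified sensor positions around
#' the leaf.
#'
#' @param n number of viewpoints (default 21)
#' @return an `n` x 3 matrix of unit vectors
#' @export
generate_viewpoints <- function(n = 21L) {
  if (n < 1L) stop("need at least one viewpoint")
  i <- seq_len(n) - 1
  z <- 1 - 2 * (i + 0.5) / n
  r <- sqrt(pmax(1 - z^2, 0))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Occlude a normalised cloud from a viewpoint
#'
#' Ranks points by Euclidean distance to the viewpoint (ties broken by
#' original index) and removes exactly `round(ratio * n)` (half-up)
#' farthest points; kept and removed partition the input. The default
#' removes the *farthest* points, the literal reading of eliminating
#' points far away from the viewpoint; `mode = "nearest"` is available
#' because part of the completion literature occludes the nearest points
#' instead.
#'
#' @param cloud normalised [point_cloud()] or matrix
#' @param viewpoint length-3 unit vector on the bounding sphere
#' @param ratio missing ratio in (0, 1); the corpus uses 0.20 / 0.35 / 0.50
#' @param mode `"farthest"` (default) or `"nearest"`
#' @return list with `kept` and `removed` ([point_cloud()]s) and the
#'   corresponding index vectors `kept_idx`, `removed_idx`
#' @export
occlude <- function(cloud, viewpoint, ratio, mode = c("farthest", "nearest")) {
  mode <- match.arg(mode)
  pts <- as_points(cloud)
  n <- nrow(pts)
  if (ratio <= 0 || ratio >= 1) stop("ratio must lie in (0, 1)")
  m <- .round_half_up(ratio * n)
  if (m == 0L || m == n)
    stop("ratio ", ratio, " removes ", m, " of ", n, " points")
  d2 <- rowSums(sweep(pts, 2, viewpoint)^2)
  ord <- if (mode == "farthest") order(-d2, seq_len(n)) else order(d2, seq_len(n))
  removed_idx <- sort(ord[seq_len(m)])
  kept_idx <- setdiff(seq_len(n), removed_idx)
  list(kept = point_cloud(pts[kept_idx, , drop = FALSE]),
       removed = point_cloud(pts[removed_idx, , drop = FALSE]),
       kept_idx = kept_idx, removed_idx = removed_idx)
}

#' Build one completion training sample
#'
#' Normalises the leaf to the unit sphere, occludes it from the given
#' viewpoint at the given missing ratio, and subsamples with iterative
#' farthest point sampling: the incomplete input to `n_in` points (2,048)
#' and the missing ground truth to `n_gt` points (512). The two subsets are
#' disjoint subsets of the normalised source leaf, and the sample carries
#' no colors (the network consumes XYZ only).
#'
#' @param leaf a complete single-leaf [point_cloud()]
#' @param viewpoint_id viewpoint index, 1-based, into `viewpoints`
#' @param ratio missing ratio in (0, 1)
#' @param seed integer controlling the (deterministic) FPS start points
#' @param viewpoints matrix of unit vectors (default the 21-point lattice)
#' @param n_in,n_gt sample sizes (defaults 2048 / 512)
#' @param leaf_id,source_style provenance metadata stored on the sample
#' @param mode occlusion mode, see [occlude()]
#' @return an object of class `"completion_sample"` (fields `incomplete`,
#'   `missing_gt`, metadata), or a `"sample_rejection"` carrying the reason
#'   when the leaf has too few points for the requested ratio (callers
#'   record the rejection instead of crashing)
#' @export
build_sample <- function(leaf, viewpoint_id, ratio, seed = 1L,
                         viewpoints = generate_viewpoints(21L),
                         n_in = 2048L, n_gt = 512L,
                         leaf_id = NA_character_, source_style = "sfm_like",
                         mode = "farthest") {
  norm <- normalize_unit_sphere(leaf)
  pts <- norm$cloud$points
  n <- nrow(pts)
  m <- .round_half_up(ratio * n)
  if (n - m < n_in || m < n_gt) {
    return(structure(list(reason = sprintf(
      "insufficient points: kept %d < %d or removed %d < %d",
      n - m, n_in, m, n_gt)), class = "sample_rejection"))
  }
  occ <- occlude(pts, viewpoints[viewpoint_id, ], ratio, mode = mode)
  start_in <- (abs(as.integer(seed)) %% nrow(occ$kept$points)) + 1L
  start_gt <- (abs(as.integer(seed)) %% nrow(occ$removed$points)) + 1L
  inc <- occ$kept$points[ifps_sample(occ$kept, n_in, start_in), , drop = FALSE]
  gt <- occ$removed$points[ifps_sample(occ$removed, n_gt, start_gt), , drop = FALSE]
  structure(list(incomplete = inc, missing_gt = gt,
                 leaf_id = leaf_id, viewpoint_id = viewpoint_id,
                 ratio = ratio, source_style = source_style,
                 G = norm$G, K = norm$K, seed = seed),
            class = "completion_sample")
}

#' @export
print.completion_sample <- function(x, ...) {
  cat(sprintf("completion_sample: %d-point input + %d-point ground truth (leaf %s, viewpoint %d, ratio %.2f, %s)\n",
              nrow(x$incomplete), nrow(x$missing_gt),
              x$leaf_id, x$viewpoint_id, x$ratio, x$source_style))
  invisible(x)
}

#' Build the full occlusion corpus
#'
#' One sample per (leaf, viewpoint, ratio) combination, minus rejections
#' of leaves too small for a ratio; the manifest records every tally and
#' every rejection with its reason. 150 leaves with 21 viewpoints and
#' ratios 0.20/0.35/0.50 give 9,450 samples; 80 leaves give 5,040.
#'
#' @param leaves list of complete single-leaf [point_cloud()]s (or
#'   `leaf_fixture`s from [sample_leaf()])
#' @param ratios missing ratios (default `c(0.20, 0.35, 0.50)`)
#' @param n_viewpoints number of sphere viewpoints (default 21)
#' @param seed global corpus seed; per-sample seeds are derived from it
#' @param n_in,n_gt sample sizes (2048 / 512)
#' @param source_style corpus acquisition style tag (`"sfm_like"` or
#'   `"rgbd_like"`), carried as metadata so two-stage training can select
#'   corpora
#' @param store `"memory"` keeps all samples; `"none"` verifies and tallies
#'   each sample, then discards the clouds (manifest only)
#' @param mode occlusion mode, see [occlude()]
#' @return object of class `"completion_dataset"`: list with `samples`
#'   (possibly empty when `store = "none"`), `manifest` (data frame), and
#'   the build parameters
#' @export
build_dataset <- function(leaves, ratios = c(0.20, 0.35, 0.50),
                          n_viewpoints = 21L, seed = 1L,
                          n_in = 2048L, n_gt = 512L,
                          source_style = "sfm_like",
                          store = c("memory", "none"),
                          mode = "farthest") {
  store <- match.arg(store)
  if (length(leaves) < 1L) stop("need at least one leaf")
  vps <- generate_viewpoints(n_viewpoints)
  leaf_ids <- names(leaves)
  if (is.null(leaf_ids)) leaf_ids <- sprintf("leaf%03d", seq_along(leaves))
  rows <- vector("list", length(leaves) * n_viewpoints * length(ratios))
  samples <- if (store == "memory") vector("list", length(rows))
  k <- 0L
  n_acc <- 0L
  for (li in seq_along(leaves)) {
    leaf <- leaves[[li]]
    if (inherits(leaf, "leaf_fixture")) leaf <- leaf$cloud
    for (vi in seq_len(n_viewpoints)) {
      for (ri in seq_along(ratios)) {
        k <- k + 1L
        sseed <- (abs(as.integer(seed)) + 7919L * (k %% 250000L)) %% 2147483647L
        smp <- build_sample(leaf, vi, ratios[ri], seed = sseed,
                            viewpoints = vps, n_in = n_in, n_gt = n_gt,
                            leaf_id = leaf_ids[li],
                            source_style = source_style, mode = mode)
        ok <- inherits(smp, "completion_sample")
        rows[[k]] <- data.frame(
          sample_id = k, leaf_id = leaf_ids[li], viewpoint_id = vi,
          ratio = ratios[ri], accepted = ok,
          n_in = if (ok) nrow(smp$incomplete) else NA_integer_,
          n_gt = if (ok) nrow(smp$missing_gt) else NA_integer_,
          reason = if (ok) "" else smp$reason,
          stringsAsFactors = FALSE)
        if (ok) {
          n_acc <- n_acc + 1L
          if (store == "memory") samples[[n_acc]] <- smp
        }
      }
    }
  }
  if (n_acc == 0L) stop("every (leaf, viewpoint, ratio) combination was rejected")
  manifest <- do.call(rbind, rows)
  structure(list(samples = if (store == "memory") samples[seq_len(n_acc)],
                 manifest = manifest, seed = seed,
                 ratios = ratios, n_viewpoints = n_viewpoints,
                 n_in = n_in, n_gt = n_gt, source_style = source_style),
            class = "completion_dataset")
}

#' @export
print.completion_dataset <- function(x, ...) {
  acc <- sum(x$manifest$accepted)
  cat(sprintf("completion_dataset: %d samples (%d rejected) from %d leaves x %d viewpoints x %d ratios [%s]\n",
              acc, sum(!x$manifest$accepted),
              length(unique(x$manifest$leaf_id)), x$n_viewpoints,
              length(x$ratios), x$source_style))
  if (!is.null(x$manifest$split))
    cat(sprintf("  split: %d train / %d validation (by leaf)\n",
                sum(x$manifest$split == "train" & x$manifest$accepted),
                sum(x$manifest$split == "validation" & x$manifest$accepted)))
  invisible(x)
}

#' Assign a train/validation split by leaf
#'
#' Splits at the *leaf* level: all samples of one leaf share a split, so no
#' sibling view of a validation leaf leaks into training. Leaf counts
#' realise the requested ratio to within one leaf (round half-up).
#'
#' @param dataset a `completion_dataset`
#' @param ratio training fraction (default 0.7, the 7:3 split)
#' @param seed shuffle seed
#' @return the dataset with a `split` column (`"train"`/`"validation"`)
#'   added to its manifest
#' @export
split_dataset <- function(dataset, ratio = 0.7, seed = 1L) {
  stopifnot(inherits(dataset, "completion_dataset"))
  leaves <- unique(dataset$manifest$leaf_id)
  if (length(leaves) < 2L) stop("need at least 2 leaves to split")
  if (nrow(dataset$manifest) < 2L) stop("need at least 2 samples to split")
  n_train <- .round_half_up(ratio * length(leaves))
  n_train <- max(1L, min(length(leaves) - 1L, n_train))
  had_seed <- exists(".Random.seed", envir = globalenv())
  if (had_seed) saved <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  shuffled <- sample(leaves)
  if (had_seed) assign(".Random.seed", saved, envir = globalenv())
  train_leaves <- shuffled[seq_len(n_train)]
  dataset$manifest$split <- ifelse(dataset$manifest$leaf_id %in% train_leaves,
                                   "train", "validation")
  dataset$split_seed <- seed
  dataset$split_ratio <- ratio
  dataset
}

# Accepted samples of one split as a plain list.
.dataset_samples <- function(dataset, split = NULL) {
  stopifnot(inherits(dataset, "completion_dataset"))
  if (is.null(dataset$samples))
    stop("dataset was built with store = 'none'; clouds were not retained")
  if (is.null(split)) return(dataset$samples)
  if (is.null(dataset$manifest$split))
    stop("dataset has no split; call split_dataset() first")
  acc <- dataset$manifest[dataset$manifest$accepted, ]
  dataset$samples[acc$split == split]
}
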