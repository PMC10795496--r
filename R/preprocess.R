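#' Preprocessing filters and segmentation
#'
#' Extraction of the target plant from a raw RGB-D capture: pass-through
#' (axis interval) filtering, color-threshold filtering on an excess-green
#' index, statistical outlier removal, and region-growing segmentation into
#' single-leaf clouds. Filters only ever remove points, and colors stay
#' paired with their points.
#'
#' @name preprocess
NULL

#' Filter configuration
#'
#' @param axis_bounds named list with optional `x`, `y`, `z` entries, each a
#'   closed interval `c(min, max)` in mm
#' @param color_rule excess-green index threshold in `[-2, 2]`
#' @param sor_k neighbour count for statistical outlier removal (>= 1)
#' @param sor_std standard-deviation multiplier (> 0)
#' @return a list of class `"filter_config"`
#' @export
filter_config <- function(axis_bounds = list(), color_rule = 0.2,
                          sor_k = 50L, sor_std = 1.0) {
  for (ax in names(axis_bounds)) {
    b <- axis_bounds[[ax]]
    if (!is.null(b) && (length(b) != 2L || b[1] >= b[2]))
      stop("axis bound for ", ax, " must be c(min, max) with min < max")
  }
  if (color_rule < -2 || color_rule > 2) stop("color_rule must lie in [-2, 2]")
  if (sor_k < 1L) stop("sor_k must be >= 1")
  if (sor_std <= 0) stop("sor_std must be > 0")
  structure(list(axis_bounds = axis_bounds, color_rule = color_rule,
                 sor_k = as.integer(sor_k), sor_std = sor_std),
            class = "filter_config")
}

#' Segmentation configuration
#'
#' @param normal_k neighbours used for normal/curvature estimation
#' @param smoothness_deg normal-deviation admission threshold, degrees,
#'   in (0, 90)
#' @param curvature_max curvature threshold above which a point stops
#'   seeding further growth
#' @param min_cluster minimum points per accepted leaf cluster (>= 3)
#' @return a list of class `"segmentation_config"`
#' @export
segmentation_config <- function(normal_k = 30L, smoothness_deg = 3.0,
                                curvature_max = 1.0, min_cluster = 200L) {
  if (smoothness_deg <= 0 || smoothness_deg >= 90)
    stop("smoothness_deg must lie in (0, 90)")
  if (min_cluster < 3L) stop("min_cluster must be >= 3")
  if (normal_k < 3L) stop("normal_k must be >= 3")
  structure(list(normal_k = as.integer(normal_k),
                 smoothness_deg = smoothness_deg,
                 curvature_max = curvature_max,
                 min_cluster = as.integer(min_cluster)),
            class = "segmentation_config")
}

#' Pass-through (straight-through) filter
#'
#' Keeps exactly the points inside all stated closed per-axis intervals.
#'
#' @param cloud a [point_cloud()]
#' @param bounds named list with entries among `x`, `y`, `z`, each
#'   `c(min, max)` in mm; at least one axis must be bounded
#' @return filtered [point_cloud()]; errors if no point survives
#' @export
passthrough_filter <- function(cloud, bounds) {
  stopifnot(inherits(cloud, "point_cloud"))
  axes <- intersect(names(bounds), c("x", "y", "z"))
  axes <- axes[!vapply(bounds[axes], is.null, TRUE)]
  if (length(axes) == 0L) stop("at least one axis must be bounded")
  keep <- rep(TRUE, npoints(cloud))
  for (ax in axes) {
    b <- bounds[[ax]]
    if (length(b) != 2L || b[1] >= b[2])
      stop("bound for axis ", ax, " must be c(min, max) with min < max")
    col <- match(ax, c("x", "y", "z"))
    keep <- keep & cloud$points[, col] >= b[1] & cloud$points[, col] <= b[2]
  }
  if (!any(keep))
    stop("pass-through filter removed every point (bounds on axis ",
         paste(axes, collapse = ", "), ")")
  pc_subset(cloud, which(keep))
}

#' Excess-green index of RGB colors
#'
#' ExG = 2g - r - b with channels normalised to `[0, 1]`; ranges over
#' `[-2, 2]` and separates green vegetation from soil, pot and background
#' across illumination better than raw channel cutoffs.
#'
#' @param colors N x 3 RGB matrix in `[0, 255]`
#' @return numeric vector of ExG values
#' @export
excess_green <- function(colors) {
  cn <- colors / 255
  2 * cn[, 2] - cn[, 1] - cn[, 3]
}

#' Color-threshold filter
#'
#' Keeps points whose excess-green index exceeds `threshold`.
#'
#' @param cloud a colored [point_cloud()]
#' @param threshold greenness cutoff (default 0.2); `-2` keeps everything
#' @return filtered [point_cloud()]
#' @export
color_threshold_filter <- function(cloud, threshold = 0.2) {
  stopifnot(inherits(cloud, "point_cloud"))
  if (is.null(cloud$colors))
    stop("color-threshold filter requires a cloud with colors")
  keep <- which(excess_green(cloud$colors) > threshold)
  if (length(keep) == 0L)
    stop("color-threshold filter removed every point (threshold ",
         threshold, ")")
  pc_subset(cloud, keep)
}

#' Statistical outlier removal
#'
#' Removes points whose mean distance to their `k` nearest neighbours
#' exceeds the global mean plus `std_mult` standard deviations of that
#' per-point statistic.
#'
#' @param cloud a [point_cloud()] with more than `k` points
#' @param k neighbour count (default 50)
#' @param std_mult standard-deviation multiplier (default 1.0)
#' @return filtered [point_cloud()]
#' @export
statistical_outlier_removal <- function(cloud, k = 50L, std_mult = 1.0) {
  stopifnot(inherits(cloud, "point_cloud"))
  n <- npoints(cloud)
  if (n <= k) stop("statistical filter needs more than k = ", k, " points")
  kn <- knn_self_cpp(cloud$points, as.integer(k))
  mean_d <- rowMeans(kn$dist)
  cutoff <- mean(mean_d) + std_mult * stats::sd(mean_d)
  keep <- which(mean_d <= cutoff)
  if (length(keep) == 0L) stop("statistical filter removed every point")
  pc_subset(cloud, keep)
}

# Per-point normals and curvature from the covariance of the normal_k
# nearest neighbours. Curvature is lambda_min / (l1+l2+l3); degenerate
# (collinear) neighbourhoods yield NA normals.
.estimate_normals <- function(pts, k) {
  n <- nrow(pts)
  kn <- knn_self_cpp(pts, as.integer(min(k, n - 1L)))
  normals <- matrix(NA_real_, n, 3)
  curv <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nb <- pts[c(i, kn$idx[i, ]), , drop = FALSE]
    cv <- stats::cov(nb)
    eg <- eigen(cv, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    tot <- sum(lam)
    if (tot <= 0 || lam[2] <= 1e-12 * tot) next  # collinear / degenerate
    normals[i, ] <- eg$vectors[, 3]
    curv[i] <- lam[3] / tot
  }
  list(normals = normals, curvature = curv, knn = kn$idx)
}

#' Region-growing segmentation into leaves
#'
#' Estimates per-point normals and curvature from `normal_k` neighbours,
#' then grows regions from low-curvature seeds: a neighbour is admitted
#' when its normal deviates from the current point's normal by less than
#' `smoothness_deg` (normals are sign-ambiguous, so the acute angle is
#' used), and continues the growth only while its curvature stays below
#' `curvature_max`. Clusters smaller than `min_cluster` go to the residual.
#' Seeds are processed in increasing-curvature order with the point index
#' as tie-break, so the segmentation is fully deterministic.
#'
#' @param cloud a [point_cloud()] with at least `min_cluster` points
#' @param cfg a [segmentation_config()]
#' @return list with `clusters` (list of integer index vectors, sorted by
#'   size descending), `residual` (integer indices), `normals`, `curvature`
#' @export
region_growing_segment <- function(cloud, cfg = segmentation_config()) {
  stopifnot(inherits(cloud, "point_cloud"),
            inherits(cfg, "segmentation_config"))
  pts <- cloud$points
  n <- nrow(pts)
  if (n < cfg$min_cluster)
    stop("cloud smaller than min_cluster (", cfg$min_cluster, ")")
  est <- .estimate_normals(pts, cfg$normal_k)
  ok <- !is.na(est$curvature)
  cos_thr <- cos(cfg$smoothness_deg * pi / 180)
  label <- integer(n)  # 0 = unassigned
  next_label <- 0L
  seed_order <- order(est$curvature, seq_len(n), na.last = TRUE)
  for (s in seed_order) {
    if (label[s] != 0L || !ok[s]) next
    next_label <- next_label + 1L
    label[s] <- next_label
    queue <- s
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      np <- est$normals[p, ]
      for (j in est$knn[p, ]) {
        if (label[j] != 0L || !ok[j]) next
        if (abs(sum(np * est$normals[j, ])) < cos_thr) next
        label[j] <- next_label
        if (est$curvature[j] < cfg$curvature_max) queue <- c(queue, j)
      }
    }
  }
  groups <- split(seq_len(n), label)
  residual <- as.integer(unlist(groups[names(groups) == "0"], use.names = FALSE))
  groups <- groups[names(groups) != "0"]
  sizes <- lengths(groups)
  small <- sizes < cfg$min_cluster
  residual <- sort(c(residual, unlist(groups[small], use.names = FALSE)))
  clusters <- groups[!small]
  clusters <- clusters[order(lengths(clusters), decreasing = TRUE)]
  names(clusters) <- NULL
  list(clusters = lapply(clusters, as.integer),
       residual = as.integer(residual),
       normals = est$normals, curvature = est$curvature)
}
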