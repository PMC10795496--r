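#' Point-set distance metrics
#'
#' Chamfer distance, earth mover's distance and Hausdorff distance between
#' two point clouds, used both as training losses and as evaluation measures
#' of reconstruction precision.
#'
#' @name metrics
NULL

# Nearest neighbour of each row of `query` among rows of `ref`.
# Brute force below 1,000 reference points, kd-tree above; both back ends
# are exact and break distance ties toward the lowest reference index, so
# results are identical either way.
.nn <- function(query, ref, method = c("auto", "brute", "kdtree")) {
  method <- match.arg(method)
  if (method == "auto") method <- if (nrow(ref) > 1000L) "kdtree" else "brute"
  if (method == "brute") nn_brute_cpp(query, ref) else nn_kdtree_cpp(query, ref)
}

#' Chamfer distance between two point clouds
#'
#' Sum over both directions of the reduced squared nearest-neighbour
#' distances:
#' \deqn{d_{cd}(S_1,S_2)=\mathrm{red}_{x\in S_1}\min_{y\in S_2}\|x-y\|_2^2 +
#'       \mathrm{red}_{y\in S_2}\min_{x\in S_1}\|x-y\|_2^2}
#' where the reduction is the mean by default (making the value independent
#' of set size, and matching the "mean nearest square distance" reading of
#' the loss); `reduction = "sum"` gives the literal plain-sum form.
#'
#' @param s1,s2 point clouds (or N x 3 matrices); both non-empty
#' @param reduction `"mean"` (default) or `"sum"`
#' @return non-negative scalar, mm^2; symmetric in its arguments
#' @export
chamfer_distance <- function(s1, s2, reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  a <- as_points(s1); b <- as_points(s2)
  if (nrow(a) < 1L || nrow(b) < 1L) stop("chamfer distance of an empty cloud")
  red <- if (reduction == "mean") mean else sum
  red(.nn(a, b)$d2) + red(.nn(b, a)$d2)
}

#' Earth mover's distance between equal-size point clouds
#'
#' Mean Euclidean cost of the optimal one-to-one assignment between the two
#' sets, computed exactly (Hungarian algorithm). Intended for evaluation,
#' not for training: cost grows cubically with the set size.
#'
#' @param s1,s2 point clouds of equal cardinality (n <= 4096)
#' @return non-negative scalar, mm
#' @export
earth_movers_distance <- function(s1, s2) {
  a <- as_points(s1); b <- as_points(s2)
  if (nrow(a) != nrow(b))
    stop("EMD requires equal cardinality (", nrow(a), " vs ", nrow(b), ")")
  if (nrow(a) > 4096L) stop("exact EMD limited to n <= 4096")
  emd_cpp(a, b)
}

#' Hausdorff distance between two point clouds
#'
#' Symmetric by default: the larger of the two directed maxima of
#' nearest-neighbour distance. `directed = TRUE` gives only the
#' `a`-to-`b` directed maximum.
#'
#' @param a,b non-empty point clouds
#' @param directed return only the directed distance from `a` to `b`
#' @return non-negative scalar, mm
#' @export
hausdorff_distance <- function(a, b, directed = FALSE) {
  pa <- as_points(a); pb <- as_points(b)
  if (nrow(pa) < 1L || nrow(pb) < 1L) stop("Hausdorff distance of an empty cloud")
  dab <- sqrt(max(.nn(pa, pb)$d2))
  if (directed) return(dab)
  max(dab, sqrt(max(.nn(pb, pa)$d2)))
}

#' Nearest-neighbour distance report
#'
#' For every point of `reconstructed`, the distance to its nearest point of
#' `reference`; summarised as the RMSE of those distances, the directed and
#' symmetric Hausdorff distances, and the fraction of points below each
#' threshold.
#'
#' @param reconstructed,reference non-empty point clouds
#' @param thresholds numeric vector of distances in mm (may be empty, in
#'   which case only RMSE and Hausdorff figures are reported)
#' @return an object of class `"distance_report"` with fields `rmse`,
#'   `hausdorff` (symmetric), `max_directed` and `fraction_below`
#'   (named by threshold, non-decreasing, in `[0, 1]`)
#' @export
nn_distance_report <- function(reconstructed, reference, thresholds = numeric()) {
  a <- as_points(reconstructed); b <- as_points(reference)
  if (nrow(a) < 1L || nrow(b) < 1L) stop("distance report of an empty cloud")
  d <- sqrt(.nn(a, b)$d2)
  thresholds <- sort(as.numeric(thresholds))
  frac <- vapply(thresholds, function(t) mean(d <= t), 0)
  names(frac) <- format(thresholds, trim = TRUE)
  structure(list(rmse = sqrt(mean(d^2)),
                 hausdorff = max(max(d), sqrt(max(.nn(b, a)$d2))),
                 max_directed = max(d),
                 fraction_below = frac),
            class = "distance_report")
}

#' @export
print.distance_report <- function(x, ...) {
  cat(sprintf("distance report: RMSE %.4f mm, Hausdorff %.4f mm (directed %.4f)\n",
              x$rmse, x$hausdorff, x$max_directed))
  if (length(x$fraction_below))
    for (i in seq_along(x$fraction_below))
      cat(sprintf("  fraction below %s mm: %.3f\n",
                  names(x$fraction_below)[i], x$fraction_below[i]))
  invisible(x)
}

#' Rigidly align one cloud onto another
#'
#' Applies an optional isotropic scale, then a centroid shift, then
#' iterative-closest-point refinement (point-to-point, Kabsch rotation
#' update). The scale is applied once up front and never optimised inside
#' the ICP loop: clouds are first brought to metric millimetres, then
#' registered. Deterministic given its inputs.
#'
#' @param source,target point clouds with at least 10 points and
#'   non-degenerate spread (rank >= 2)
#' @param scale_hint optional isotropic scale applied to `source` first
#' @param max_iter,tol ICP iteration cap and RMSE-change convergence
#'   tolerance
#' @return list with `transform` (list `scale`, `R` 3x3, `t` length-3 so that
#'   `aligned = scale * source %*% t(R) + t`), `aligned` (matrix), `rmse`
#'   and `iterations`
#' @export
align_clouds <- function(source, target, scale_hint = NULL,
                         max_iter = 60L, tol = 1e-10) {
  s <- as_points(source); tg <- as_points(target)
  if (nrow(s) < 10L || nrow(tg) < 10L)
    stop("alignment needs at least 10 points per cloud")
  for (m in list(s, tg)) {
    sv <- svd(scale(m, scale = FALSE), nu = 0, nv = 0)$d
    if (sv[2] < 1e-9 * max(sv[1], 1)) stop("degenerate cloud (rank < 2)")
  }
  sc <- if (is.null(scale_hint)) 1 else as.numeric(scale_hint)
  cur <- s * sc
  R_tot <- diag(3)
  t_tot <- colMeans(tg) - colMeans(cur)
  cur <- sweep(cur, 2, t_tot, "+")
  prev_rmse <- Inf
  it <- 0L
  repeat {
    it <- it + 1L
    nn <- .nn(cur, tg)
    corr <- tg[nn$idx, , drop = FALSE]
    cs <- colMeans(cur); ct <- colMeans(corr)
    H <- crossprod(sweep(cur, 2, cs), sweep(corr, 2, ct))
    sv <- svd(H)
    Rk <- sv$v %*% diag(c(1, 1, sign(det(sv$v %*% t(sv$u))))) %*% t(sv$u)
    tk <- ct - as.vector(Rk %*% cs)
    cur <- cur %*% t(Rk) + matrix(tk, nrow(cur), 3, byrow = TRUE)
    R_tot <- Rk %*% R_tot
    t_tot <- as.vector(Rk %*% t_tot) + tk
    rmse <- sqrt(mean(.nn(cur, tg)$d2))
    if (it >= max_iter || abs(prev_rmse - rmse) < tol) break
    prev_rmse <- rmse
  }
  list(transform = list(scale = sc, R = R_tot, t = t_tot),
       aligned = cur, rmse = rmse, iterations = it)
}

#' Iterative farthest point sampling
#'
#' Greedy max-min subsampling: after the start point, each selected index
#' maximises the minimum Euclidean distance to all previously selected
#' points (ties broken toward the lowest index). Preserves the shape
#' skeleton far better than random sampling and is the downsampler used
#' throughout dataset construction and the multi-scale encoder.
#'
#' @param cloud a point cloud or N x 3 matrix
#' @param k number of points to select, `1 <= k <= N`
#' @param start index of the first selected point (default 1)
#' @return integer vector of `k` distinct indices in order of selection
#' @export
ifps_sample <- function(cloud, k, start = 1L) {
  pts <- as_points(cloud)
  n <- nrow(pts)
  if (k < 1L) stop("k must be positive")
  if (k > n) stop("k (", k, ") exceeds point count (", n, ")")
  if (start < 1L || start > n) stop("start index out of range")
  as.integer(fps_cpp(pts, as.integer(k), as.integer(start)))
}

# round-half-up, used wherever the pipeline turns a ratio into a count
.round_half_up <- function(x) floor(x + 0.5)
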