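#' Pose normalisation and recovery
#'
#' An arbitrarily posed real leaf must enter the network in the canonical
#' frame the training corpus was built in, and the completed cloud must be
#' restored to world coordinates afterwards. Normalisation strips colors,
#' translates by the centroid `G`, scales by `K` to the unit sphere, and
#' rotates by a plane-fit attitude correction `R`; the pose record (G, K,
#' R) exactly inverts the transform.
#'
#' Canonical frame conventions: the fitted leaf normal maps to -z (leaf
#' facing downward) and the in-plane major axis (largest-variance
#' direction) maps to +y, with the sign of the major axis chosen toward
#' positive apex skewness. The in-plane alignment is automated (no manual
#' fine-tuning step): the major-axis convention is a documented choice.
#'
#' @name pose
NULL

#' Total-least-squares leaf plane normal
#'
#' Direction of least variance of the centred cloud (smallest principal
#' component), robust to steep leaves where an ordinary z-on-xy regression
#' would fail. The sign is chosen so the normal has a negative z component
#' (facing downward); for an exactly vertical plane the first nonzero
#' component is made positive.
#'
#' @param cloud a cloud with at least 3 non-collinear points
#' @return unit length-3 normal vector
#' @export
fit_leaf_plane <- function(cloud) {
  pts <- as_points(cloud)
  if (nrow(pts) < 3L) stop("plane fit needs at least 3 points")
  cv <- stats::cov(pts)
  eg <- eigen(cv, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  if (lam[2] <= 1e-12 * max(lam[1], 1e-300))
    stop("degenerate cloud: points are collinear")
  nv <- eg$vectors[, 3]
  if (abs(nv[3]) > 1e-12) {
    if (nv[3] > 0) nv <- -nv
  } else {
    first <- which(abs(nv) > 1e-12)[1]
    if (nv[first] < 0) nv <- -nv
  }
  nv / sqrt(sum(nv^2))
}

#' Normalise a leaf cloud into the canonical network frame
#'
#' @param cloud a valid leaf [point_cloud()] (colors, if any, are stripped)
#' @return list with `cloud` (canonical [point_cloud()], max norm 1) and
#'   `record` (a `"pose_record"`: centroid `G` in mm, scale `K` in mm per
#'   unit, rotation `R` with the canonical axes as rows)
#' @export
normalize_pose <- function(cloud) {
  pts <- as_points(cloud)
  G <- colMeans(pts)
  centred <- sweep(pts, 2, G)
  K <- sqrt(max(rowSums(centred^2)))
  if (K <= 0) stop("degenerate cloud: zero scale")
  Xs <- centred / K
  nv <- fit_leaf_plane(Xs)
  # major axis: largest-variance direction within the fitted plane
  P <- diag(3) - tcrossprod(nv)
  proj <- Xs %*% P
  eg <- eigen(stats::cov(proj), symmetric = TRUE)
  a <- eg$vectors[, 1]
  a <- a - sum(a * nv) * nv
  a <- a / sqrt(sum(a^2))
  t_along <- as.vector(Xs %*% a)
  skew <- mean((t_along - mean(t_along))^3)
  if (skew < 0) a <- -a  # tie toward positive apex skewness
  ez <- -nv
  ey <- a
  ex <- c(ey[2] * ez[3] - ey[3] * ez[2],
          ey[3] * ez[1] - ey[1] * ez[3],
          ey[1] * ez[2] - ey[2] * ez[1])
  R <- rbind(ex, ey, ez)
  dimnames(R) <- NULL
  record <- structure(list(G = G, K = K, R = R), class = "pose_record")
  .check_pose_record(record)
  list(cloud = point_cloud(Xs %*% t(R)), record = record)
}

.check_pose_record <- function(rec, tol = 1e-6) {
  if (!is.list(rec) || is.null(rec$R) || is.null(rec$G) || is.null(rec$K))
    stop("invalid pose record")
  R <- rec$R
  if (max(abs(crossprod(R) - diag(3))) > tol || abs(det(R) - 1) > tol)
    stop("pose record rotation is not orthonormal with determinant +1")
  if (rec$K <= 0) stop("pose record scale must be positive")
  invisible(rec)
}

#' @export
print.pose_record <- function(x, ...) {
  cat(sprintf("pose_record: G = (%.3f, %.3f, %.3f) mm, K = %.3f mm\n",
              x$G[1], x$G[2], x$G[3], x$K))
  invisible(x)
}

#' Restore a canonical cloud to world coordinates
#'
#' Exact inverse of [normalize_pose()]: rotate by the transpose of `R`,
#' scale by `K`, translate by `G`.
#'
#' @param cloud canonical-frame cloud (e.g. a completed fusion)
#' @param record the `"pose_record"` captured during normalisation
#' @return world-frame [point_cloud()]
#' @export
recover_pose <- function(cloud, record) {
  .check_pose_record(record)
  pts <- as_points(cloud)
  point_cloud(sweep((pts %*% record$R) * record$K, 2, record$G, "+"))
}
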