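#' Surface reconstruction and leaf-area measurement
#'
#' A completed leaf cloud is turned into a surface by Delaunay 2.5D
#' triangulation (2D Delaunay of the points projected onto their best-fit
#' plane, with the connectivity lifted back to 3D), refined by Laplacian
#' smoothing with the boundary held fixed, and measured: the leaf area is
#' the sum of triangle areas, reported in cm^2.
#'
#' @name mesh
NULL

#' Triangle mesh objects
#'
#' @param vertices N x 3 coordinate matrix (mm)
#' @param triangles M x 3 integer matrix of vertex indices (1-based)
#' @return object of class `"triangle_mesh"`
#' @export
triangle_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- matrix(as.integer(as.matrix(triangles)), ncol = 3)
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles),
            class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d triangles, area %.3f cm^2\n",
              nrow(x$vertices), nrow(x$triangles), mesh_area(x)))
  invisible(x)
}

# per-triangle areas in mm^2
.tri_areas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1], , drop = FALSE]
  b <- vertices[triangles[, 2], , drop = FALSE]
  c_ <- vertices[triangles[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

#' Delaunay 2.5D triangulation
#'
#' Projects the points onto their total-least-squares plane, triangulates
#' the 2D projection (incremental Delaunay), and lifts the connectivity
#' back to the unmodified 3D vertex positions. Triangles with any edge
#' longer than `prune_factor` times the median edge length are removed,
#' which cleans up the convex-hull bridges that would otherwise span
#' concave leaf outlines; the pruning factor is the one load-bearing
#' parameter of the surface step.
#'
#' @param cloud a cloud with at least 3 non-collinear points
#' @param prune_factor edge-length multiplier for boundary/concavity
#'   cleanup (default 3)
#' @return a [triangle_mesh()] whose vertices are the input points
#' @export
delaunay_25d <- function(cloud, prune_factor = 3) {
  pts <- as_points(cloud)
  if (nrow(pts) < 3L) stop("triangulation needs at least 3 points")
  centred <- sweep(pts, 2, colMeans(pts))
  eg <- eigen(stats::cov(centred), symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  if (lam[2] <= 1e-12 * max(lam[1], 1e-300))
    stop("all points collinear: no surface to triangulate")
  uv <- centred %*% eg$vectors[, 1:2]
  dup <- duplicated(uv)
  keep <- which(!dup)
  if (length(keep) < 3L) stop("fewer than 3 distinct projected points")
  tri_local <- delaunay2d_cpp(uv[keep, 1], uv[keep, 2])
  tri <- matrix(keep[tri_local], ncol = 3)
  if (nrow(tri) == 0L) stop("triangulation produced no triangles")
  # prune long edges (3D lengths)
  edge_len <- function(i, j)
    sqrt(rowSums((pts[i, , drop = FALSE] - pts[j, , drop = FALSE])^2))
  e1 <- edge_len(tri[, 1], tri[, 2])
  e2 <- edge_len(tri[, 2], tri[, 3])
  e3 <- edge_len(tri[, 3], tri[, 1])
  med <- stats::median(c(e1, e2, e3))
  ok <- e1 <= prune_factor * med & e2 <= prune_factor * med &
        e3 <= prune_factor * med
  tri <- tri[ok, , drop = FALSE]
  if (nrow(tri) == 0L) stop("pruning removed every triangle")
  areas <- .tri_areas(pts, tri)
  tri <- tri[areas > 1e-12 * stats::median(areas), , drop = FALSE]
  triangle_mesh(pts, tri)
}

# unique edges with incidence counts; edges stored as (min, max) pairs
.mesh_edges <- function(triangles) {
  e <- rbind(triangles[, c(1, 2)], triangles[, c(2, 3)], triangles[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  key <- paste(e[, 1], e[, 2])
  cnt <- table(key)
  first <- !duplicated(key)
  list(edges = e[first, , drop = FALSE],
       count = as.integer(cnt[key[first]]))
}

#' Laplacian mesh smoothing with fixed boundary
#'
#' Moves every interior vertex toward the average of its 1-ring neighbours
#' by a factor `lam`, repeated `iterations` times (synchronous updates),
#' with the displacement restricted to the surface-normal direction of the
#' mesh's best-fit plane - the natural fairing for a 2.5D surface. The
#' restriction makes an already-planar mesh an exact fixed point (no
#' tangential drift), while off-plane noise and spikes contract at every
#' pass. Boundary vertices - the leaf outline, and hence the area
#' perimeter - are held fixed, because shrinking the boundary would bias
#' the area systematically. Connectivity is unchanged.
#'
#' @param mesh a [triangle_mesh()]
#' @param iterations smoothing passes (0 = identity)
#' @param lam step factor in (0, 1]
#' @return the smoothed [triangle_mesh()]
#' @export
laplace_smooth <- function(mesh, iterations = 10L, lam = 0.5) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (lam <= 0 || lam > 1) stop("lam must lie in (0, 1]")
  if (iterations == 0L) return(mesh)
  V <- mesh$vertices
  centred <- sweep(V, 2, colMeans(V))
  nv <- eigen(stats::cov(centred), symmetric = TRUE)$vectors[, 3]
  h <- as.vector(centred %*% nv)  # height over the best-fit plane
  ed <- .mesh_edges(mesh$triangles)
  boundary <- unique(as.vector(ed$edges[ed$count == 1L, ]))
  src <- c(ed$edges[, 1], ed$edges[, 2])
  dst <- c(ed$edges[, 2], ed$edges[, 1])
  deg <- tabulate(src, nbins = nrow(V))
  movable <- setdiff(which(deg > 0), boundary)
  for (it in seq_len(iterations)) {
    nbr_sum <- rowsum(h[dst], src, reorder = TRUE)  # sorted unique src rows
    rows <- as.integer(rownames(nbr_sum))
    mean_h <- h
    mean_h[rows] <- nbr_sum / deg[rows]
    h[movable] <- h[movable] + lam * (mean_h[movable] - h[movable])
  }
  h0 <- as.vector(centred %*% nv)
  triangle_mesh(V + outer(h - h0, nv), mesh$triangles)
}

#' Mesh surface area
#'
#' Sum over triangles of half the cross-product norm, converted from mm^2
#' to cm^2 (internal geometry stays in mm; areas are reported in cm^2).
#'
#' @param mesh a non-empty [triangle_mesh()]
#' @return area in cm^2
#' @export
mesh_area <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  if (nrow(mesh$triangles) == 0L) stop("mesh has no triangles")
  sum(.tri_areas(mesh$vertices, mesh$triangles)) / 100
}

#' Leaf area from a point cloud
#'
#' The full surface pipeline: Delaunay 2.5D triangulation, Laplacian
#' smoothing with fixed boundary, and mesh-area measurement.
#'
#' @param cloud a single-leaf cloud
#' @param prune_factor see [delaunay_25d()]
#' @param iterations,lam see [laplace_smooth()]
#' @return list with `area_cm2` and the smoothed `mesh`
#' @export
leaf_area_pipeline <- function(cloud, prune_factor = 3,
                               iterations = 10L, lam = 0.5) {
  mesh <- laplace_smooth(delaunay_25d(cloud, prune_factor), iterations, lam)
  list(area_cm2 = mesh_area(mesh), mesh = mesh)
}

#' Write a mesh to PLY or OBJ
#'
#' @param mesh a [triangle_mesh()]
#' @param path destination (`.ply` or `.obj`)
#' @return `invisible(path)`
#' @export
write_mesh <- function(mesh, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %.10g %.10g %.10g", mesh$vertices[, 1],
                       mesh$vertices[, 2], mesh$vertices[, 3]), con)
    writeLines(sprintf("f %d %d %d", mesh$triangles[, 1],
                       mesh$triangles[, 2], mesh$triangles[, 3]), con)
  } else if (ext == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             paste("element vertex", nrow(mesh$vertices)),
             "property double x", "property double y", "property double z",
             paste("element face", nrow(mesh$triangles)),
             "property list uchar int vertex_indices", "end_header")
    body_v <- sprintf("%.17g %.17g %.17g", mesh$vertices[, 1],
                      mesh$vertices[, 2], mesh$vertices[, 3])
    body_f <- sprintf("3 %d %d %d", mesh$triangles[, 1] - 1L,
                      mesh$triangles[, 2] - 1L, mesh$triangles[, 3] - 1L)
    writeLines(c(hdr, body_v, body_f), path)
  } else stop("unsupported mesh format: ", ext)
  invisible(path)
}
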