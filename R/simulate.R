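#' Parametric synthetic leaves and plants
#'
#' A controllable stand-in for real cabbage captures: single-leaf surfaces
#' (curved, folded, boundary-irregular) with analytically-integrated
#' reference areas, multi-leaf rosette "plants" with inter-leaf occlusion
#' and ground-truth per-leaf labels, and a z-buffer-style single-view
#' sampler that emulates 2.5D RGB-D imaging.
#'
#' The blade is the parametric surface over `u in [0,1]` (along the midrib)
#' and `v in [-1,1]` (across the blade):
#' \deqn{x = v\,w(u),\quad y = u\,L,\quad
#'       z = \frac{1-\cos(c L u)}{c} + A\sin(2\pi f v)}
#' with half-width outline `w(u) = (W/2) sin(pi u)^s`, midrib arc curvature
#' `c` (1/mm), fold amplitude `A` (mm) and fold count `f`.
#'
#' @name simulate
NULL

#' Specification of a synthetic leaf
#'
#' Defaults emulate a flowering Chinese cabbage leaf: a large blade
#' (180 x 120 mm) with a gentle midrib bend, a few millimetre-scale folds
#' across the blade, and sub-millimetre sensor noise.
#'
#' @param length blade length along the midrib, mm (> 0)
#' @param max_width maximum blade width, mm (> 0)
#' @param outline_shape exponent of the half-width outline (ovate-to-obovate
#'   form; 1 = sinusoidal outline)
#' @param bend_curvature midrib arc curvature, 1/mm (0 = flat midrib)
#' @param fold_amplitude amplitude of cross-blade folds, mm
#' @param fold_count number of fold waves across the blade (integer)
#' @param noise_sd isotropic Gaussian sensor noise, mm (>= 0)
#' @param points target sample count (>= 100)
#' @param seed RNG seed; all randomness of the fixture flows from it
#' @return a list of class `"leaf_spec"`
#' @export
leaf_spec <- function(length = 180, max_width = 120, outline_shape = 1.5,
                      bend_curvature = 0.004, fold_amplitude = 2,
                      fold_count = 3L, noise_sd = 0.5,
                      points = 4100L, seed = 1L) {
  if (length <= 0 || max_width <= 0) stop("length and max_width must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (points < 100L) stop("points must be >= 100")
  if (outline_shape <= 0) stop("outline_shape must be > 0")
  structure(list(length = length, max_width = max_width,
                 outline_shape = outline_shape,
                 bend_curvature = bend_curvature,
                 fold_amplitude = fold_amplitude,
                 fold_count = as.integer(fold_count),
                 noise_sd = noise_sd, points = as.integer(points),
                 seed = as.integer(seed)),
            class = "leaf_spec")
}

# Surface map and area element |r_u x r_v| of the noise-free blade.
# The fold amplitude is tapered along the midrib by sin(pi u): folds die
# out at the base and tip as they do on a real blade. Without the taper
# the analytic area acquires a zero-width ribbon of folded surface at the
# tip (the cross-blade slope diverges as the outline width vanishes) that
# no physically sampled point cloud can represent.
.leaf_surface <- function(spec) {
  L <- spec$length; W <- spec$max_width; s <- spec$outline_shape
  cc <- spec$bend_curvature; A <- spec$fold_amplitude; f <- spec$fold_count
  w <- function(u) (W / 2) * sin(pi * u)^s
  wprime <- function(u) (W / 2) * s * sin(pi * u)^(s - 1) * cos(pi * u) * pi
  zb <- function(u) if (abs(cc) > 1e-12) (1 - cos(cc * L * u)) / cc else 0 * u
  zbu <- function(u) if (abs(cc) > 1e-12) L * sin(cc * L * u) else 0 * u
  list(
    position = function(u, v)
      cbind(v * w(u), u * L,
            zb(u) + A * sin(2 * pi * f * v) * sin(pi * u)),
    darea = function(u, v) {
      wu <- w(u); wpu <- wprime(u)
      zuu <- zbu(u) + A * sin(2 * pi * f * v) * pi * cos(pi * u)
      zvv <- A * 2 * pi * f * cos(2 * pi * f * v) * sin(pi * u)
      sqrt((L * zvv)^2 + (zuu * wu - v * wpu * zvv)^2 + (L * wu)^2)
    })
}

#' Reference surface area of a leaf spec by dense quadrature
#'
#' Midpoint quadrature of the first fundamental form of the noise-free
#' surface on an `n x n` grid (default 1024, i.e. over 10^6 cells). This
#' oracle is independent of the mesh-based area measurement: it discretises
#' the *parametric* surface, not a triangulation of sampled points.
#'
#' @param spec a [leaf_spec()]
#' @param n quadrature cells per parametric axis
#' @return surface area in cm^2
#' @export
leaf_reference_area <- function(spec, n = 1024L) {
  surf <- .leaf_surface(spec)
  u <- (seq_len(n) - 0.5) / n           # cell centres in [0,1]
  v <- -1 + 2 * (seq_len(n) - 0.5) / n  # cell centres in [-1,1]
  du <- 1 / n; dv <- 2 / n
  total <- 0
  for (i in seq_len(n))  # loop over u to bound memory; vectorised in v
    total <- total + sum(surf$darea(u[i], v)) * du * dv
  total / 100  # mm^2 -> cm^2
}

#' Sample a synthetic leaf fixture
#'
#' Draws `spec$points` locations approximately uniformly *by surface area*
#' (rejection sampling against the area element), adds isotropic Gaussian
#' noise, and attaches the quadrature reference area. `style = "clustered"`
#' modulates the sampling density with smooth synthetic "texture" hotspots,
#' emulating feature-clustered photogrammetric (SFM) point densities, while
#' `"uniform"` emulates the per-pixel uniformity of RGB-D captures.
#'
#' @param spec a [leaf_spec()]
#' @param style `"uniform"` or `"clustered"`
#' @return an object of class `"leaf_fixture"`: list with `cloud`
#'   ([point_cloud()]), `spec`, `reference_area` (cm^2, noise-free),
#'   `uv` (per-point parametric coordinates) and `style`
#' @export
sample_leaf <- function(spec, style = c("uniform", "clustered")) {
  style <- match.arg(style)
  stopifnot(inherits(spec, "leaf_spec"))
  surf <- .leaf_surface(spec)
  had_seed <- exists(".Random.seed", envir = globalenv())
  if (had_seed) saved <- get(".Random.seed", envir = globalenv())
  on.exit(if (had_seed) assign(".Random.seed", saved, envir = globalenv()))
  set.seed(spec$seed)

  # density bound for rejection sampling
  gu <- seq(0.001, 0.999, length.out = 200)
  gv <- seq(-1, 1, length.out = 121)
  dmax <- max(outer(gu, gv, function(a, b) surf$darea(a, b))) * 1.05

  texture <- NULL
  if (style == "clustered") {
    nh <- 6L
    hot <- cbind(stats::runif(nh, 0.1, 0.9), stats::runif(nh, -0.8, 0.8))
    texture <- function(u, v) {
      dens <- 0.25
      for (h in seq_len(nh))
        dens <- dens + exp(-((u - hot[h, 1])^2 + 0.25 * (v - hot[h, 2])^2) /
                             (2 * 0.06^2))
      pmin(dens, 4) / 4
    }
  }

  need <- spec$points
  uv <- matrix(0, 0, 2)
  while (nrow(uv) < need) {
    m <- max(2L * need, 4096L)
    u <- stats::runif(m); v <- stats::runif(m, -1, 1)
    p <- surf$darea(u, v) / dmax
    if (!is.null(texture)) p <- p * texture(u, v)
    acc <- stats::runif(m) < p
    uv <- rbind(uv, cbind(u[acc], v[acc]))
  }
  uv <- uv[seq_len(need), , drop = FALSE]
  pts <- surf$position(uv[, 1], uv[, 2])
  if (spec$noise_sd > 0)
    pts <- pts + matrix(stats::rnorm(length(pts), sd = spec$noise_sd), ncol = 3)
  structure(list(cloud = point_cloud(pts),
                 spec = spec,
                 reference_area = leaf_reference_area(spec),
                 uv = uv, style = style),
            class = "leaf_fixture")
}

#' @export
print.leaf_fixture <- function(x, ...) {
  cat(sprintf("leaf_fixture: %d points, reference area %.2f cm^2 (%s sampling)\n",
              npoints(x$cloud), x$reference_area, x$style))
  invisible(x)
}

#' Draw a corpus of random leaf specs
#'
#' Convenience generator for corpora: specs vary in size, outline, bend and
#' folding within ranges typical of flowering Chinese cabbage leaves.
#'
#' @param n number of specs
#' @param seed corpus seed
#' @param points per-leaf sample count
#' @param noise_sd sensor noise, mm
#' @return named list of [leaf_spec()]s
#' @export
random_leaf_specs <- function(n, seed = 1L, points = 4100L, noise_sd = 0.5) {
  had_seed <- exists(".Random.seed", envir = globalenv())
  if (had_seed) saved <- get(".Random.seed", envir = globalenv())
  on.exit(if (had_seed) assign(".Random.seed", saved, envir = globalenv()))
  set.seed(seed)
  specs <- lapply(seq_len(n), function(i) {
    len <- stats::runif(1, 120, 240)
    leaf_spec(length = len,
              max_width = len * stats::runif(1, 0.5, 0.75),
              outline_shape = stats::runif(1, 1.0, 2.2),
              bend_curvature = stats::runif(1, 0.001, 0.006),
              fold_amplitude = stats::runif(1, 0.5, 2.5),
              fold_count = sample(2:3, 1),
              noise_sd = noise_sd, points = points,
              seed = sample.int(2^30, 1))
  })
  names(specs) <- sprintf("leaf%03d", seq_len(n))
  specs
}

#' Assemble a synthetic plant from leaves
#'
#' Arranges leaves around a vertical axis at the phyllotactic spiral angle
#' with a common inclination, colors each leaf a randomised green, and
#' optionally adds a brown soil disc and a gray background wall for
#' preprocessing tests. Ground-truth per-point labels are returned:
#' positive integers for leaves, 0 for soil, -1 for background.
#'
#' @param specs list of [leaf_spec()]s (one leaf each)
#' @param phyllotaxis_angle spiral angle between successive leaves, degrees
#' @param inclination leaf inclination from horizontal, degrees
#' @param soil,background add a soil disc / background wall
#' @param seed color/extras RNG seed
#' @return list with `cloud` (colored [point_cloud()]), `labels` (integer
#'   per-point), and `fixtures` (the per-leaf [sample_leaf()] outputs in
#'   plant coordinates are *not* stored; fixtures are in leaf-local frames)
#' @export
make_plant <- function(specs, phyllotaxis_angle = 137.5, inclination = 35,
                       soil = FALSE, background = FALSE, seed = 1L) {
  if (length(specs) < 1L) stop("need at least one leaf spec")
  had_seed <- exists(".Random.seed", envir = globalenv())
  if (had_seed) saved <- get(".Random.seed", envir = globalenv())
  on.exit(if (had_seed) assign(".Random.seed", saved, envir = globalenv()))
  set.seed(seed)
  pts_all <- list(); col_all <- list(); lab_all <- list(); fixtures <- list()
  inc <- inclination * pi / 180
  Rx <- rbind(c(1, 0, 0), c(0, cos(inc), -sin(inc)), c(0, sin(inc), cos(inc)))
  for (i in seq_along(specs)) {
    fx <- sample_leaf(specs[[i]])
    fixtures[[i]] <- fx
    ang <- (i - 1) * phyllotaxis_angle * pi / 180
    Rz <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
    p <- fx$cloud$points %*% t(Rx) %*% t(Rz)
    p[, 3] <- p[, 3] + (i - 1) * 2  # slight rosette lift per leaf
    n <- nrow(p)
    base <- c(stats::runif(1, 30, 80), stats::runif(1, 150, 220),
              stats::runif(1, 20, 70))
    cols <- cbind(pmin(pmax(base[1] + stats::rnorm(n, 0, 8), 0), 255),
                  pmin(pmax(base[2] + stats::rnorm(n, 0, 8), 0), 255),
                  pmin(pmax(base[3] + stats::rnorm(n, 0, 8), 0), 255))
    pts_all[[length(pts_all) + 1L]] <- p
    col_all[[length(col_all) + 1L]] <- cols
    lab_all[[length(lab_all) + 1L]] <- rep(i, n)
  }
  extent <- max(sqrt(rowSums(do.call(rbind, pts_all)[, 1:2, drop = FALSE]^2)))
  if (soil) {
    ns <- 1500L
    r <- extent * 1.2 * sqrt(stats::runif(ns))
    th <- stats::runif(ns, 0, 2 * pi)
    p <- cbind(r * cos(th), r * sin(th), stats::rnorm(ns, -3, 0.5))
    cols <- cbind(pmin(pmax(139 + stats::rnorm(ns, 0, 10), 0), 255),
                  pmin(pmax(69 + stats::rnorm(ns, 0, 8), 0), 255),
                  pmin(pmax(19 + stats::rnorm(ns, 0, 6), 0), 255))
    pts_all[[length(pts_all) + 1L]] <- p
    col_all[[length(col_all) + 1L]] <- cols
    lab_all[[length(lab_all) + 1L]] <- rep(0L, ns)
  }
  if (background) {
    nb <- 1000L
    p <- cbind(stats::runif(nb, -2 * extent, 2 * extent),
               rep(2 * extent, nb) + stats::rnorm(nb, 0, 2),
               stats::runif(nb, -50, 4 * extent))
    cols <- matrix(pmin(pmax(128 + stats::rnorm(3 * nb, 0, 6), 0), 255),
                   ncol = 3)
    pts_all[[length(pts_all) + 1L]] <- p
    col_all[[length(col_all) + 1L]] <- cols
    lab_all[[length(lab_all) + 1L]] <- rep(-1L, nb)
  }
  list(cloud = point_cloud(do.call(rbind, pts_all), do.call(rbind, col_all)),
       labels = as.integer(unlist(lab_all)),
       fixtures = fixtures)
}

#' Single-view RGB-D visibility sampling
#'
#' Emulates 2.5D imaging with a top-down orthographic z-buffer: points are
#' binned into a square pixel grid seen from above and only the highest
#' (nearest-to-camera) point per pixel is kept. This produces the self- and
#' inter-leaf occlusion holes, and the per-pixel uniform spacing, that are
#' characteristic of single-view RGB-D captures.
#'
#' @param plant a [point_cloud()] or matrix (e.g. from [make_plant()])
#' @param resolution pixels per axis of the square grid
#' @param extent optional `c(xmin, xmax, ymin, ymax)` footprint; default is
#'   the bounding box of the cloud
#' @return list with `cloud` (visible [point_cloud()]) and `kept_idx`
#'   (indices into the input cloud)
#' @export
simulate_rgbd_view <- function(plant, resolution = 256L, extent = NULL) {
  colors <- if (inherits(plant, "point_cloud")) plant$colors
  pts <- as_points(plant)
  if (is.null(extent))
    extent <- c(range(pts[, 1]), range(pts[, 2]))
  px <- pmin(pmax(ceiling((pts[, 1] - extent[1]) /
                            max(extent[2] - extent[1], 1e-9) * resolution), 1L),
             resolution)
  py <- pmin(pmax(ceiling((pts[, 2] - extent[3]) /
                            max(extent[4] - extent[3], 1e-9) * resolution), 1L),
             resolution)
  pix <- (py - 1L) * resolution + px
  ord <- order(pix, -pts[, 3], seq_len(nrow(pts)))  # per pixel: highest first
  keep <- ord[!duplicated(pix[ord])]
  keep <- sort(keep)
  if (length(keep) == 0L) stop("no visible points")
  list(cloud = point_cloud(pts[keep, , drop = FALSE],
                           if (!is.null(colors)) colors[keep, , drop = FALSE]),
       kept_idx = keep)
}
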