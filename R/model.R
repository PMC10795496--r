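#' The point-fractal completion network
#'
#' A multi-resolution encoder (MRE) with combined multi-layer perception
#' (CMLP) feature extraction and a point-pyramid decoder (PPD). The input
#' incomplete cloud (2,048 points, XYZ only) is downsampled by iterative
#' farthest point sampling to three scales; each scale passes through a
#' shared per-point MLP whose last three layer outputs are max-pooled and
#' concatenated (mixing low- and high-level features); the three scale
#' features are fused by an MLP into a latent vector V; and the decoder
#' emits three resolutions of the predicted missing region, coarse to fine
#' (64, 128, 512 points), each finer level predicted as offsets around its
#' parent points. Implemented in plain matrix algebra with hand-derived
#' gradients (verified against finite differences in the test suite).
#'
#' @name model
NULL

#' Network configuration
#'
#' @param preset `"default"` (encoder widths 64-128-256-512-1024, latent
#'   1024) or `"tiny"` (16-32-64, latent 128), the latter sized for CPU
#'   tests and the scaled-down synthetic benchmark
#' @param input_scales point counts of the three encoder scales, strictly
#'   decreasing; the first is the required input size
#' @param cmlp_widths per-layer feature widths of the shared MLP
#' @param latent_dim size of the fused latent vector V
#' @param output_sizes decoder resolutions, strictly decreasing; each must
#'   divide the previous (children per parent point)
#' @param dec_hidden width of the decoder's shared hidden layer
#' @param pooled_layers how many trailing encoder layers are max-pooled
#' @return a list of class `"pfnet_config"`
#' @export
pfnet_config <- function(preset = c("default", "tiny"),
                         input_scales = c(2048L, 1024L, 512L),
                         cmlp_widths = NULL, latent_dim = NULL,
                         output_sizes = c(512L, 128L, 64L),
                         dec_hidden = NULL, pooled_layers = 3L) {
  preset <- match.arg(preset)
  if (is.null(cmlp_widths))
    cmlp_widths <- if (preset == "tiny") c(16L, 32L, 64L)
                   else c(64L, 128L, 256L, 512L, 1024L)
  if (is.null(latent_dim)) latent_dim <- if (preset == "tiny") 128L else 1024L
  if (is.null(dec_hidden)) dec_hidden <- latent_dim
  input_scales <- as.integer(input_scales)
  output_sizes <- as.integer(output_sizes)
  if (any(diff(input_scales) >= 0) || any(input_scales <= 0))
    stop("input_scales must be strictly decreasing and positive")
  if (any(diff(output_sizes) >= 0) || any(output_sizes <= 0))
    stop("output_sizes must be strictly decreasing and positive")
  if (length(output_sizes) != 3L) stop("exactly three output sizes expected")
  if (any(output_sizes[-3] %% output_sizes[-1] != 0))
    stop("each output size must be a multiple of the next (children per parent)")
  pooled_layers <- min(as.integer(pooled_layers), length(cmlp_widths))
  feat_dim <- sum(utils::tail(cmlp_widths, pooled_layers))
  structure(list(input_scales = input_scales,
                 cmlp_widths = as.integer(cmlp_widths),
                 latent_dim = as.integer(latent_dim),
                 output_sizes = output_sizes,
                 dec_hidden = as.integer(dec_hidden),
                 pooled_layers = pooled_layers,
                 feat_dim = feat_dim, preset = preset),
            class = "pfnet_config")
}

#' @export
print.pfnet_config <- function(x, ...) {
  cat(sprintf("pfnet_config (%s): scales %s | CMLP %s (pool last %d -> %d) | latent %d | outputs %s\n",
              x$preset, paste(x$input_scales, collapse = "/"),
              paste(x$cmlp_widths, collapse = "-"), x$pooled_layers,
              x$feat_dim, x$latent_dim,
              paste(x$output_sizes, collapse = "/")))
  invisible(x)
}

.init_mat <- function(nin, nout) {
  lim <- 1 / sqrt(nin)
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}
.init_vec <- function(nin, nout) {
  lim <- 1 / sqrt(nin)
  stats::runif(nout, -lim, lim)
}

#' Initialise network weights
#'
#' Uniform fan-in initialisation, reproducible from the seed. Encoders of
#' the three scales have separate parameters.
#'
#' @param config a [pfnet_config()]
#' @param seed RNG seed
#' @return nested list of weight matrices (class `"pfnet_weights"`)
#' @export
pfnet_init <- function(config = pfnet_config(), seed = 1L) {
  had_seed <- exists(".Random.seed", envir = globalenv())
  if (had_seed) saved <- get(".Random.seed", envir = globalenv())
  on.exit(if (had_seed) assign(".Random.seed", saved, envir = globalenv()))
  set.seed(seed)
  ww <- config$cmlp_widths
  enc <- lapply(1:3, function(s) {
    dims <- c(3L, ww)
    list(W = lapply(seq_along(ww), function(l) .init_mat(dims[l], dims[l + 1])),
         b = lapply(seq_along(ww), function(l) .init_vec(dims[l], dims[l + 1])))
  })
  fus <- list(W1 = .init_mat(3L * config$feat_dim, config$latent_dim),
              b1 = .init_vec(3L * config$feat_dim, config$latent_dim),
              W2 = .init_mat(config$latent_dim, config$latent_dim),
              b2 = .init_vec(config$latent_dim, config$latent_dim))
  os <- config$output_sizes
  dec <- list(Wh = .init_mat(config$latent_dim, config$dec_hidden),
              bh = .init_vec(config$latent_dim, config$dec_hidden),
              Wy3 = .init_mat(config$dec_hidden, os[3] * 3L),
              by3 = .init_vec(config$dec_hidden, os[3] * 3L),
              Wy2 = .init_mat(config$dec_hidden, os[2] * 3L),
              by2 = .init_vec(config$dec_hidden, os[2] * 3L),
              Wy1 = .init_mat(config$dec_hidden, os[1] * 3L),
              by1 = .init_vec(config$dec_hidden, os[1] * 3L))
  structure(list(enc = enc, fus = fus, dec = dec), class = "pfnet_weights")
}

#' Multi-scale downsampling of the network input
#'
#' Scale 1 is the input itself; the smaller scales are iterative farthest
#' point sampling subsets of it (start index 1, hence deterministic).
#'
#' @param cloud input cloud with exactly `scales[1]` points
#' @param scales the three scale sizes
#' @return list of three coordinate matrices
#' @export
multiscale_downsample <- function(cloud, scales = c(2048L, 1024L, 512L)) {
  pts <- as_points(cloud)
  if (nrow(pts) != scales[1])
    stop("input must have exactly ", scales[1], " points, got ", nrow(pts))
  out <- vector("list", length(scales))
  out[[1]] <- pts
  for (s in seq_along(scales)[-1])
    out[[s]] <- pts[ifps_sample(pts, scales[s], start = 1L), , drop = FALSE]
  out
}

# shared-MLP forward for one scale; returns pooled feature and cache
.cmlp_forward <- function(X, enc, config) {
  L <- length(enc$W)
  Hs <- vector("list", L)   # post-activation outputs
  Ms <- vector("list", L)   # relu masks
  H <- X
  n <- nrow(X)
  for (l in seq_len(L)) {
    Z <- H %*% enc$W[[l]] + matrix(enc$b[[l]], n, length(enc$b[[l]]), byrow = TRUE)
    Ms[[l]] <- Z > 0
    H <- Z * Ms[[l]]
    Hs[[l]] <- H
  }
  pooled <- utils::tail(seq_len(L), config$pooled_layers)
  ams <- list(); feats <- list()
  for (l in pooled) {
    am <- max.col(t(Hs[[l]]), ties.method = "first")
    ams[[as.character(l)]] <- am
    feats[[as.character(l)]] <- Hs[[l]][cbind(am, seq_len(ncol(Hs[[l]])))]
  }
  list(feature = unlist(feats, use.names = FALSE),
       cache = list(X = X, Hs = Hs, Ms = Ms, ams = ams, pooled = pooled))
}

.cmlp_backward <- function(dfeat, enc, cache, config) {
  L <- length(enc$W)
  widths <- vapply(enc$W, ncol, 0L)
  dW <- vector("list", L); db <- vector("list", L)
  # split pooled-feature gradient back per layer
  segs <- list(); off <- 0L
  for (l in cache$pooled) {
    segs[[as.character(l)]] <- dfeat[(off + 1L):(off + widths[l])]
    off <- off + widths[l]
  }
  dH_next <- NULL  # gradient flowing from layer above
  for (l in rev(seq_len(L))) {
    n <- nrow(cache$Hs[[l]])
    dH <- if (is.null(dH_next)) matrix(0, n, widths[l]) else dH_next
    key <- as.character(l)
    if (!is.null(segs[[key]])) {
      am <- cache$ams[[key]]
      idx <- cbind(am, seq_len(widths[l]))
      dH[idx] <- dH[idx] + segs[[key]]
    }
    dZ <- dH * cache$Ms[[l]]
    Hprev <- if (l == 1L) cache$X else cache$Hs[[l - 1L]]
    dW[[l]] <- crossprod(Hprev, dZ)
    db[[l]] <- colSums(dZ)
    dH_next <- if (l > 1L) dZ %*% t(enc$W[[l]]) else NULL
  }
  list(W = dW, b = db)
}

#' Encode one scale with the combined multi-layer perception
#'
#' Per-point features through successive shared nonlinear layers, with the
#' last `pooled_layers` layer outputs max-pooled and concatenated. The
#' max-pool makes the feature invariant to any permutation of the input
#' points.
#'
#' @param cloud point cloud or matrix at one of the configured scales
#' @param weights network weights from [pfnet_init()]
#' @param config the matching [pfnet_config()]
#' @param scale which encoder (1, 2 or 3)
#' @return numeric feature vector of length `config$feat_dim`
#' @export
cmlp_encode <- function(cloud, weights, config = pfnet_config(), scale = 1L) {
  .cmlp_forward(as_points(cloud), weights$enc[[scale]], config)$feature
}

#' Fuse the three scale features into the latent vector V
#'
#' @param scales list of three clouds/matrices from [multiscale_downsample()]
#' @param weights,config network weights and configuration
#' @return numeric latent vector of length `config$latent_dim`
#' @export
mre_encode <- function(scales, weights, config = pfnet_config()) {
  f <- unlist(lapply(1:3, function(s)
    .cmlp_forward(as_points(scales[[s]]), weights$enc[[s]], config)$feature))
  g <- matrix(f, 1L)
  a1 <- g %*% weights$fus$W1 + matrix(weights$fus$b1, 1L)
  h1 <- pmax(a1, 0)
  as.vector(h1 %*% weights$fus$W2 + matrix(weights$fus$b2, 1L))
}

#' Decode the latent vector into the point pyramid
#'
#' Fully connected branches over a shared hidden layer emit the coarsest
#' prediction directly; each finer level is predicted as offsets around its
#' parent points (every coarse point spawns a fixed number of children), so
#' the generated clouds change gradually from rough to fine.
#'
#' @param v latent vector of length `config$latent_dim`
#' @param weights,config network weights and configuration
#' @return object of class `"ppd_output"`: list `y1`, `y2`, `y3` of sizes
#'   `output_sizes[1]` x 3 (finest) down to `output_sizes[3]` x 3
#' @export
ppd_decode <- function(v, weights, config = pfnet_config()) {
  fw <- .decoder_forward(matrix(v, 1L), weights$dec, config)
  out <- fw[c("y1", "y2", "y3")]
  if (!all(vapply(out, function(m) all(is.finite(m)), TRUE)))
    stop("non-finite activations in decoder output")
  structure(out, class = "ppd_output")
}

.decoder_forward <- function(V, dec, config) {
  os <- config$output_sizes
  hin <- V %*% dec$Wh + matrix(dec$bh, 1L)
  maskd <- hin > 0
  hd <- hin * maskd
  tomat <- function(f, o) matrix(f, o, 3L, byrow = TRUE)
  y3 <- tomat(hd %*% dec$Wy3 + matrix(dec$by3, 1L), os[3])
  off2 <- tomat(hd %*% dec$Wy2 + matrix(dec$by2, 1L), os[2])
  off1 <- tomat(hd %*% dec$Wy1 + matrix(dec$by1, 1L), os[1])
  parent2 <- rep(seq_len(os[3]), each = os[2] %/% os[3])
  parent1 <- rep(seq_len(os[2]), each = os[1] %/% os[2])
  y2 <- y3[parent2, , drop = FALSE] + off2
  y1 <- y2[parent1, , drop = FALSE] + off1
  list(y1 = y1, y2 = y2, y3 = y3, hd = hd, maskd = maskd,
       parent1 = parent1, parent2 = parent2)
}

.decoder_backward <- function(dY1, dY2, dY3, V, dec, cache) {
  dOff1 <- dY1
  dY2t <- dY2 + rowsum(dY1, cache$parent1, reorder = TRUE)
  dOff2 <- dY2t
  dY3t <- dY3 + rowsum(dY2t, cache$parent2, reorder = TRUE)
  flat <- function(m) matrix(as.vector(t(m)), 1L)
  d1 <- flat(dOff1); d2 <- flat(dOff2); d3 <- flat(dY3t)
  hd <- cache$hd
  dhd <- d1 %*% t(dec$Wy1) + d2 %*% t(dec$Wy2) + d3 %*% t(dec$Wy3)
  dhin <- dhd * cache$maskd
  list(grads = list(Wh = crossprod(V, dhin), bh = as.vector(dhin),
                    Wy3 = crossprod(hd, d3), by3 = as.vector(d3),
                    Wy2 = crossprod(hd, d2), by2 = as.vector(d2),
                    Wy1 = crossprod(hd, d1), by1 = as.vector(d1)),
       dV = dhin %*% t(dec$Wh))
}

# Full forward pass with cache (single sample).
.pf_forward <- function(weights, scales, config) {
  encc <- vector("list", 3L)
  feats <- vector("list", 3L)
  for (s in 1:3) {
    fw <- .cmlp_forward(as_points(scales[[s]]), weights$enc[[s]], config)
    encc[[s]] <- fw$cache
    feats[[s]] <- fw$feature
  }
  g <- matrix(unlist(feats), 1L)
  a1 <- g %*% weights$fus$W1 + matrix(weights$fus$b1, 1L)
  mask1 <- a1 > 0
  h1 <- a1 * mask1
  V <- h1 %*% weights$fus$W2 + matrix(weights$fus$b2, 1L)
  decc <- .decoder_forward(V, weights$dec, config)
  list(y1 = decc$y1, y2 = decc$y2, y3 = decc$y3, V = as.vector(V),
       cache = list(enc = encc, g = g, mask1 = mask1, h1 = h1, V = V,
                    dec = decc))
}

.pf_backward <- function(weights, cache, dY1, dY2, dY3, config) {
  db <- .decoder_backward(dY1, dY2, dY3, cache$V, weights$dec, cache$dec)
  dV <- db$dV
  dW2 <- crossprod(cache$h1, dV)
  db2 <- as.vector(dV)
  dh1 <- dV %*% t(weights$fus$W2)
  da1 <- dh1 * cache$mask1
  dW1 <- crossprod(cache$g, da1)
  db1 <- as.vector(da1)
  dg <- as.vector(da1 %*% t(weights$fus$W1))
  Fd <- config$feat_dim
  enc_g <- vector("list", 3L)
  for (s in 1:3) {
    seg <- dg[((s - 1L) * Fd + 1L):(s * Fd)]
    enc_g[[s]] <- .cmlp_backward(seg, weights$enc[[s]], cache$enc[[s]], config)
  }
  list(enc = enc_g,
       fus = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2),
       dec = db$grads)
}

# chamfer distance (mean reduction) with gradient w.r.t. the prediction
.cd_with_grad <- function(pred, gt) {
  na <- nrow(pred); nb <- nrow(gt)
  fwd <- .nn(pred, gt)
  bwd <- .nn(gt, pred)
  value <- mean(fwd$d2) + mean(bwd$d2)
  grad <- 2 * (pred - gt[fwd$idx, , drop = FALSE]) / na
  contrib <- 2 * (pred[bwd$idx, , drop = FALSE] - gt) / nb
  agg <- rowsum(contrib, bwd$idx, reorder = TRUE)
  rows <- as.integer(rownames(agg))
  grad[rows, ] <- grad[rows, ] + agg
  list(value = value, grad = grad)
}

#' Multi-stage completion loss
#'
#' The training loss: chamfer distance of the finest prediction against the
#' missing ground truth, plus `alpha` and `beta` weighted chamfer terms of
#' the two coarser predictions against ground truths derived from the
#' missing cloud by iterative farthest point sampling:
#' `L = d_cd(Y1, Ygt) + alpha d_cd(Y2, Ygt2) + beta d_cd(Y3, Ygt3)`.
#'
#' @param pred a `"ppd_output"` (or list with `y1`, `y2`, `y3`)
#' @param ygt missing ground-truth cloud (matrix or [point_cloud()]) whose
#'   size matches `y1`
#' @param alpha,beta stage weights (see [alpha_beta_at()])
#' @param reduction chamfer reduction, `"mean"` (default) or `"sum"`
#' @return non-negative scalar
#' @export
multistage_loss <- function(pred, ygt, alpha, beta,
                            reduction = c("mean", "sum")) {
  reduction <- match.arg(reduction)
  gt <- as_points(ygt)
  if (nrow(gt) != nrow(pred$y1))
    stop("ground truth size ", nrow(gt), " does not match y1 size ",
         nrow(pred$y1))
  gt2 <- gt[ifps_sample(gt, nrow(pred$y2), 1L), , drop = FALSE]
  gt3 <- gt[ifps_sample(gt, nrow(pred$y3), 1L), , drop = FALSE]
  chamfer_distance(pred$y1, gt, reduction) +
    alpha * chamfer_distance(pred$y2, gt2, reduction) +
    beta * chamfer_distance(pred$y3, gt3, reduction)
}

# loss + full gradient for one prepared sample
.pf_loss_grad <- function(weights, scales, gt, gt2, gt3, alpha, beta, config) {
  fw <- .pf_forward(weights, scales, config)
  l1 <- .cd_with_grad(fw$y1, gt)
  l2 <- .cd_with_grad(fw$y2, gt2)
  l3 <- .cd_with_grad(fw$y3, gt3)
  loss <- l1$value + alpha * l2$value + beta * l3$value
  grads <- .pf_backward(weights, fw$cache, l1$grad, alpha * l2$grad,
                        beta * l3$grad, config)
  list(loss = loss, grads = grads, cd1 = l1$value)
}

#' Complete an incomplete leaf cloud
#'
#' Runs the forward pass and returns the finest predicted missing cloud
#' together with the fused result. The fused cloud is the union of the
#' observed input and the prediction: the observed points are never
#' rewritten (they appear verbatim as the first rows of the fusion).
#'
#' @param incomplete cloud with exactly `config$input_scales[1]` points
#' @param model a fitted [pfnet()] object, or a list with elements
#'   `weights` and `config`
#' @return list with `predicted_missing` and `fused` ([point_cloud()]s)
#' @export
complete_cloud <- function(incomplete, model) {
  weights <- if (inherits(model, "pfnet")) model$weights else model$weights
  config <- if (inherits(model, "pfnet")) model$net else model$config
  pts <- as_points(incomplete)
  scales <- multiscale_downsample(pts, config$input_scales)
  fw <- .pf_forward(weights, scales, config)
  if (!all(is.finite(fw$y1))) stop("non-finite prediction")
  list(predicted_missing = point_cloud(fw$y1),
       fused = point_cloud(rbind(pts, fw$y1)))
}
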