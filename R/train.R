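#' Training the completion network
#'
#' Two-stage training: a first stage on photogrammetry-style (SFM-like)
#' leaf corpora, then transfer learning on RGB-D-style corpora with the
#' same hyperparameters, compensating for a small dataset. The stage
#' weights of the multi-stage loss follow a piecewise-constant schedule
#' that shifts emphasis from coarse to fine detail as training progresses.
#'
#' @name train
NULL

#' The stage-weight schedule of the multi-stage loss
#'
#' Piecewise-constant (alpha, beta): (0.01, 0.02) for the first 30% of
#' epochs, (0.05, 0.1) until 80%, and (0.1, 0.2) for the remainder. With
#' the default 100 epochs the intervals are exactly \[0,30), \[30,80),
#' \[80,100).
#'
#' @param epochs total epoch count
#' @param break_fractions interval start points as fractions of `epochs`
#' @param alphas,betas per-interval weights
#' @return a data frame of class `"loss_schedule"` with columns `start`,
#'   `end`, `alpha`, `beta` (intervals `[start, end)`, 0-based epochs)
#' @export
alpha_beta_schedule <- function(epochs = 100L,
                                break_fractions = c(0, 0.3, 0.8),
                                alphas = c(0.01, 0.05, 0.1),
                                betas = c(0.02, 0.1, 0.2)) {
  stopifnot(length(break_fractions) == length(alphas),
            length(alphas) == length(betas),
            all(alphas > 0), all(betas > 0))
  starts <- .round_half_up(break_fractions * epochs)
  # short runs can collapse intervals; keep the later weights at a tied start
  keep <- !duplicated(starts, fromLast = TRUE) & starts < epochs
  starts <- starts[keep]; alphas <- alphas[keep]; betas <- betas[keep]
  ends <- c(starts[-1], epochs)
  if (length(starts) == 0L || starts[1] != 0L || any(ends <= starts))
    stop("schedule intervals must cover [0, epochs)")
  structure(data.frame(start = starts, end = ends,
                       alpha = alphas, beta = betas),
            class = c("loss_schedule", "data.frame"),
            epochs = as.integer(epochs))
}

#' Stage weights at a given epoch
#'
#' @param epoch 0-based epoch index, `0 <= epoch < epochs`
#' @param schedule an [alpha_beta_schedule()]
#' @return named numeric vector `c(alpha = , beta = )`
#' @export
alpha_beta_at <- function(epoch, schedule = alpha_beta_schedule()) {
  total <- attr(schedule, "epochs")
  if (epoch < 0 || epoch >= total)
    stop("epoch ", epoch, " outside [0, ", total, ")")
  row <- which(epoch >= schedule$start & epoch < schedule$end)
  c(alpha = schedule$alpha[row], beta = schedule$beta[row])
}

#' Training configuration
#'
#' Defaults are the full-scale training settings: batch size 24, learning
#' rate 1e-4, 100 epochs, Adam without weight decay or learning-rate decay.
#' Scaled-down runs (e.g. the tiny preset on a small synthetic corpus)
#' override them.
#'
#' @param batch_size samples per optimisation step (last partial batch kept)
#' @param learning_rate Adam step size
#' @param epochs number of epochs
#' @param schedule an [alpha_beta_schedule()]; defaults to the standard
#'   schedule stretched over `epochs`
#' @param seed RNG seed controlling initialisation and shuffling
#' @param checkpoint_every save a checkpoint every this many epochs
#'   (0 = never); requires `out_dir`
#' @param out_dir directory for checkpoints and logs
#' @param dry_run iterate the epoch loop recording the schedule without
#'   touching data or optimising (schedule audits)
#' @return a list of class `"train_control"`
#' @export
train_control <- function(batch_size = 24L, learning_rate = 1e-4,
                          epochs = 100L, schedule = NULL, seed = 1L,
                          checkpoint_every = 0L, out_dir = NULL,
                          dry_run = FALSE) {
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (is.null(schedule)) schedule <- alpha_beta_schedule(epochs)
  if (attr(schedule, "epochs") != epochs)
    stop("schedule covers ", attr(schedule, "epochs"),
         " epochs but control asks for ", epochs)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 schedule = schedule, seed = as.integer(seed),
                 checkpoint_every = as.integer(checkpoint_every),
                 out_dir = out_dir, dry_run = isTRUE(dry_run)),
            class = "train_control")
}

# ---- nested-list parameter algebra (weights, grads, Adam moments) ----------

.w_zero <- function(w) {
  if (is.list(w)) lapply(w, .w_zero) else w * 0
}
.w_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a)); names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- .w_map2(a[[i]], b[[i]], f)
    out
  } else f(a, b)
}
.w_leaves <- function(w) {
  if (is.list(w)) unlist(lapply(w, .w_leaves), recursive = FALSE)
  else list(w)
}

.adam_init <- function(weights) list(m = .w_zero(weights), v = .w_zero(weights), t = 0L)

.adam_step <- function(weights, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  state$m <- .w_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- .w_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  upd <- .w_map2(state$m, state$v,
                 function(m, v) (m / bc1) / (sqrt(v / bc2) + eps))
  weights <- .w_map2(weights, upd, function(w, u) w - lr * u)
  list(weights = weights, state = state)
}

# cache scales and IFPS-derived coarse ground truths once per sample
.prepare_samples <- function(samples, config) {
  os <- config$output_sizes
  lapply(samples, function(s) {
    gt <- s$missing_gt
    list(scales = multiscale_downsample(s$incomplete, config$input_scales),
         gt = gt,
         gt2 = gt[ifps_sample(gt, os[2], 1L), , drop = FALSE],
         gt3 = gt[ifps_sample(gt, os[3], 1L), , drop = FALSE])
  })
}

#' Train one stage of the completion network
#'
#' Optimises the multi-stage chamfer loss over the training split with the
#' scheduled stage weights, evaluating the validation split every epoch
#' (multi-stage loss with that epoch's weights, plus the plain finest-level
#' chamfer distance for schedule-independent comparison). The loss
#' trajectory is reproducible under a fixed seed.
#'
#' @param data a `completion_dataset` with a split (see [split_dataset()]);
#'   may be `NULL` for `dry_run` controls
#' @param control a [train_control()]
#' @param net a [pfnet_config()]
#' @param init optional initial weights (a `pfnet` fit, a weights list, or
#'   a checkpoint path) for transfer learning or resuming
#' @return an object of class `"pfnet"`: list with `weights`, `log`
#'   (one row per epoch: losses, the (alpha, beta) actually used, wall
#'   time, checkpoint path), `net`, `control`, `provenance`
#' @export
train_stage <- function(data, control = train_control(),
                        net = pfnet_config(), init = NULL) {
  provenance <- "cold_start"
  init_weights <- NULL
  if (!is.null(init)) {
    if (inherits(init, "pfnet")) {
      if (!identical(init$net[c("input_scales", "cmlp_widths", "latent_dim",
                                "output_sizes", "dec_hidden")],
                     net[c("input_scales", "cmlp_widths", "latent_dim",
                           "output_sizes", "dec_hidden")]))
        stop("incompatible checkpoint: network configuration differs")
      init_weights <- init$weights
      provenance <- "transfer"
    } else if (is.character(init)) {
      ck <- readRDS(init)
      init_weights <- ck$weights
      provenance <- paste0("checkpoint:", init)
    } else {
      init_weights <- init
      provenance <- "transfer"
    }
  }

  if (control$dry_run) {
    log <- do.call(rbind, lapply(seq_len(control$epochs) - 1L, function(e) {
      ab <- alpha_beta_at(e, control$schedule)
      data.frame(epoch = e, train_loss = NA_real_, val_loss = NA_real_,
                 val_cd = NA_real_, alpha = ab["alpha"], beta = ab["beta"],
                 seconds = 0, checkpoint = NA_character_)
    }))
    rownames(log) <- NULL
    fit <- list(weights = init_weights, log = log, net = net,
                control = control, provenance = provenance,
                call = sys.call())
    class(fit) <- "pfnet"
    return(fit)
  }

  set.seed(control$seed)
  weights <- if (is.null(init_weights)) pfnet_init(net, seed = control$seed)
             else init_weights
  train_s <- .prepare_samples(.dataset_samples(data, "train"), net)
  val_s <- .prepare_samples(.dataset_samples(data, "validation"), net)
  if (length(train_s) == 0L) stop("empty training split")
  state <- .adam_init(weights)
  logs <- vector("list", control$epochs)
  for (epoch in seq_len(control$epochs) - 1L) {
    t0 <- proc.time()[["elapsed"]]
    ab <- alpha_beta_at(epoch, control$schedule)
    ord <- sample(length(train_s))
    batch_starts <- seq(1L, length(ord), by = control$batch_size)
    ep_loss <- 0
    for (bs in batch_starts) {
      idx <- ord[bs:min(bs + control$batch_size - 1L, length(ord))]
      acc <- NULL
      bloss <- 0
      for (i in idx) {
        s <- train_s[[i]]
        lg <- .pf_loss_grad(weights, s$scales, s$gt, s$gt2, s$gt3,
                            ab["alpha"], ab["beta"], net)
        if (!is.finite(lg$loss))
          stop("non-finite training loss at epoch ", epoch,
               " (diverged); lower the learning rate")
        bloss <- bloss + lg$loss
        acc <- if (is.null(acc)) lg$grads
               else .w_map2(acc, lg$grads, `+`)
      }
      nb <- length(idx)
      acc <- .w_map2(acc, acc, function(a, b) a / nb)
      st <- .adam_step(weights, acc, state, control$learning_rate)
      weights <- st$weights
      state <- st$state
      ep_loss <- ep_loss + bloss
    }
    ep_loss <- ep_loss / length(train_s)
    val_loss <- NA_real_; val_cd <- NA_real_
    if (length(val_s) > 0L) {
      vl <- 0; vc <- 0
      for (s in val_s) {
        fw <- .pf_forward(weights, s$scales, net)
        c1 <- chamfer_distance(fw$y1, s$gt)
        vl <- vl + c1 +
          ab["alpha"] * chamfer_distance(fw$y2, s$gt2) +
          ab["beta"] * chamfer_distance(fw$y3, s$gt3)
        vc <- vc + c1
      }
      val_loss <- vl / length(val_s)
      val_cd <- vc / length(val_s)
    }
    ckpath <- NA_character_
    if (control$checkpoint_every > 0L && !is.null(control$out_dir) &&
        (epoch + 1L) %% control$checkpoint_every == 0L) {
      if (!dir.exists(control$out_dir))
        dir.create(control$out_dir, recursive = TRUE)
      ckpath <- file.path(control$out_dir,
                          sprintf("checkpoint_epoch%03d.rds", epoch))
      saveRDS(list(weights = weights, net = net, epoch = epoch,
                   schema = 1L), ckpath)
    }
    logs[[epoch + 1L]] <- data.frame(
      epoch = epoch, train_loss = ep_loss, val_loss = val_loss,
      val_cd = val_cd, alpha = ab["alpha"], beta = ab["beta"],
      seconds = proc.time()[["elapsed"]] - t0, checkpoint = ckpath)
  }
  log <- do.call(rbind, logs)
  rownames(log) <- NULL
  fit <- list(weights = weights, log = log, net = net, control = control,
              provenance = provenance, call = sys.call())
  class(fit) <- "pfnet"
  fit
}

#' Transfer learning on an RGB-D-style corpus
#'
#' Identical to [train_stage()] initialised from the first-stage weights;
#' all layers are updated (no freezing), and the hyperparameters are
#' expected to remain those of the first stage.
#'
#' @param rgbd_dataset second-stage `completion_dataset` (with split)
#' @param control a [train_control()]
#' @param stage1 the first-stage `pfnet` fit (or its weights)
#' @return a `pfnet` fit with provenance `"transfer"`
#' @export
transfer_learn <- function(rgbd_dataset, control, stage1) {
  net <- if (inherits(stage1, "pfnet")) stage1$net else pfnet_config()
  train_stage(rgbd_dataset, control, net, init = stage1)
}

#' Fit the point-fractal completion network
#'
#' The top-level fitting interface: trains the network on an occlusion
#' corpus (optionally as stage 2 of a transfer-learning pair) and returns
#' a fitted model with the usual methods (`print`, `summary`, `predict`,
#' `plot`, `coef`).
#'
#' @param data a `completion_dataset` with a train/validation split
#' @param net a [pfnet_config()]
#' @param control a [train_control()]
#' @param init optional initial weights / stage-1 fit for transfer learning
#' @return an object of class `"pfnet"`
#' @examples
#' \donttest{
#' specs <- random_leaf_specs(4, seed = 3, points = 2600, noise_sd = 0.2)
#' leaves <- lapply(specs, sample_leaf)
#' ds <- split_dataset(build_dataset(leaves, ratios = 0.2, n_viewpoints = 3),
#'                     seed = 1)
#' fit <- pfnet(ds, net = pfnet_config("tiny"),
#'              control = train_control(batch_size = 4, learning_rate = 1e-3,
#'                                      epochs = 2))
#' print(fit)
#' }
#' @export
pfnet <- function(data, net = pfnet_config(), control = train_control(),
                  init = NULL) {
  fit <- train_stage(data, control, net, init)
  fit$call <- match.call()
  fit
}

#' @export
print.pfnet <- function(x, ...) {
  cat("Point-fractal completion network\n")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  print(x$net)
  np <- sum(vapply(.w_leaves(x$weights), length, 0L))
  cat(sprintf("Parameters: %s | init: %s\n",
              format(np, big.mark = ","), x$provenance))
  if (nrow(x$log) && !all(is.na(x$log$train_loss))) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("Trained %d epochs | final train loss %.5f | final validation CD %.5f\n",
                nrow(x$log), last$train_loss, last$val_cd))
  }
  invisible(x)
}

#' @export
summary.pfnet <- function(object, ...) {
  print(object)
  if (nrow(object$log) && !all(is.na(object$log$train_loss))) {
    cat("\nLoss trajectory (epoch / train loss / validation CD / alpha / beta):\n")
    show <- object$log[unique(round(seq(1, nrow(object$log), length.out = 10))),
                       c("epoch", "train_loss", "val_cd", "alpha", "beta")]
    print(show, row.names = FALSE, digits = 4)
  }
  invisible(object)
}

#' Predict the missing region of an incomplete cloud
#'
#' @param object a fitted `pfnet`
#' @param newdata an incomplete cloud with exactly the configured input
#'   size (a [point_cloud()], matrix, or `completion_sample`)
#' @param type `"missing"` for the predicted missing points, `"fused"` for
#'   the input with the prediction appended (observed points verbatim)
#' @param ... unused
#' @return a [point_cloud()]
#' @export
predict.pfnet <- function(object, newdata,
                          type = c("missing", "fused"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "completion_sample")) newdata <- newdata$incomplete
  out <- complete_cloud(newdata, object)
  if (type == "missing") out$predicted_missing else out$fused
}

#' @export
coef.pfnet <- function(object, ...) object$weights

#' Plot training and validation loss curves
#'
#' @param x a fitted `pfnet`
#' @param ... passed to [graphics::matplot()]
#' @export
plot.pfnet <- function(x, ...) {
  lg <- x$log
  if (!nrow(lg) || all(is.na(lg$train_loss)))
    stop("no recorded losses to plot")
  graphics::matplot(lg$epoch, cbind(lg$train_loss, lg$val_cd), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss",
                    main = "training loss / validation CD", ...)
  graphics::legend("topright", c("train loss", "validation CD"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}
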