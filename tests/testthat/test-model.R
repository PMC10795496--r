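# micro configuration used for exact/numeric checks
micro_cfg <- pfnet_config(input_scales = c(32L, 16L, 8L),
                          cmlp_widths = c(4L, 6L, 8L), latent_dim = 10L,
                          output_sizes = c(8L, 4L, 2L), dec_hidden = 12L)

test_that("multi-scale downsampling nests IFPS subsets of the input", {
  set.seed(59)
  inc <- rand_cloud(2048)
  sc <- multiscale_downsample(inc)
  expect_equal(vapply(sc, nrow, 0L), c(2048L, 1024L, 512L))
  key <- apply(inc, 1, paste, collapse = ",")
  expect_true(all(apply(sc[[3]], 1, paste, collapse = ",") %in% key))
  expect_identical(sc, multiscale_downsample(inc))
  expect_error(multiscale_downsample(rand_cloud(100)), "exactly 2048")
})

test_that("CMLP features are permutation invariant with the documented width", {
  w <- pfnet_init(pfnet_config(), seed = 2)
  set.seed(61)
  cl <- rand_cloud(64)
  f <- cmlp_encode(cl, w, pfnet_config())
  expect_length(f, 256 + 512 + 1024)   # pooled last three of 64..1024
  expect_identical(f, cmlp_encode(cl[sample(64), ], w, pfnet_config()))
  f2 <- cmlp_encode(rand_cloud(64), w, pfnet_config())
  expect_false(isTRUE(all.equal(f, f2)))
})

test_that("the fused latent vector is reproducible and permutation invariant", {
  w <- pfnet_init(micro_cfg, seed = 5)
  set.seed(67)
  scales <- multiscale_downsample(rand_cloud(32), micro_cfg$input_scales)
  v <- mre_encode(scales, w, micro_cfg)
  expect_length(v, micro_cfg$latent_dim)
  perm <- lapply(scales, function(m) m[sample(nrow(m)), ])
  expect_identical(v, mre_encode(perm, w, micro_cfg))
  expect_identical(v, mre_encode(scales, pfnet_init(micro_cfg, seed = 5),
                                 micro_cfg))
})

test_that("the pyramid decoder emits exact sizes and zero maps to origin", {
  w <- pfnet_init(micro_cfg, seed = 6)
  v <- rnorm(micro_cfg$latent_dim)
  out <- ppd_decode(v, w, micro_cfg)
  expect_equal(vapply(out, nrow, 0L, USE.NAMES = FALSE), c(8L, 4L, 2L))
  expect_identical(out, ppd_decode(v, w, micro_cfg))
  # zero latent with zero-initialised output heads -> all points at origin
  w0 <- w
  for (nm in c("Wy1", "by1", "Wy2", "by2", "Wy3", "by3"))
    w0$dec[[nm]] <- w0$dec[[nm]] * 0
  out0 <- ppd_decode(rep(0, micro_cfg$latent_dim), w0, micro_cfg)
  expect_true(all(unlist(out0[c("y1", "y2", "y3")]) == 0))
})

test_that("the multi-stage loss matches a by-hand miniature evaluation", {
  # 4/2/1-point miniature, evaluated manually against the chamfer oracle
  gt <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  gt2 <- gt[ifps_sample(gt, 2, 1L), ]
  gt3 <- gt[ifps_sample(gt, 1, 1L), , drop = FALSE]
  pred <- list(y1 = gt + 0.1, y2 = gt2 - 0.2, y3 = gt3 + 0.5)
  alpha <- 0.05; beta <- 0.1
  manual <- oracle_chamfer(pred$y1, gt) + alpha * oracle_chamfer(pred$y2, gt2) +
    beta * oracle_chamfer(pred$y3, gt3)
  expect_equal(multistage_loss(pred, gt, alpha, beta), manual,
               tolerance = 1e-9)
  # perfect prediction gives zero; alpha = beta = 0 reduces to the y1 term
  expect_equal(multistage_loss(list(y1 = gt, y2 = gt2, y3 = gt3), gt, 1, 1), 0)
  expect_equal(multistage_loss(pred, gt, 0 + 1e-300, 0 + 1e-300),
               oracle_chamfer(pred$y1, gt), tolerance = 1e-9)
  expect_error(multistage_loss(pred, gt[1:3, ], 1, 1), "does not match")
})

test_that("analytic gradients match finite differences everywhere", {
  set.seed(71)
  w <- pfnet_init(micro_cfg, seed = 3)
  inc <- rand_cloud(32)
  gt <- rand_cloud(8)
  scales <- multiscale_downsample(inc, micro_cfg$input_scales)
  gt2 <- gt[ifps_sample(gt, 4, 1L), ]
  gt3 <- gt[ifps_sample(gt, 2, 1L), ]
  lg <- leafcomplete:::.pf_loss_grad(w, scales, gt, gt2, gt3, 0.3, 0.7,
                                     micro_cfg)
  get_leaf <- function(obj, path) { for (p in path) obj <- obj[[p]]; obj }
  set_leaf <- function(obj, path, i, delta) {
    leaf <- get_leaf(obj, path); leaf[i] <- leaf[i] + delta
    setr <- function(o, pth) {
      if (length(pth) == 0) return(leaf)
      o[[pth[[1]]]] <- setr(o[[pth[[1]]]], pth[-1]); o
    }
    setr(obj, path)
  }
  paths <- list(list("dec", "Wy1"), list("dec", "Wy2"), list("dec", "Wh"),
                list("dec", "by3"), list("fus", "W1"), list("fus", "W2"),
                list("enc", 1L, "W", 1L), list("enc", 2L, "W", 3L),
                list("enc", 3L, "b", 2L))
  eps <- 1e-6
  for (path in paths) {
    g_ana <- get_leaf(lg$grads, path)
    for (i in sample(length(g_ana), min(3, length(g_ana)))) {
      lp <- leafcomplete:::.pf_loss_grad(set_leaf(w, path, i, eps), scales,
                                         gt, gt2, gt3, 0.3, 0.7, micro_cfg)$loss
      lm <- leafcomplete:::.pf_loss_grad(set_leaf(w, path, i, -eps), scales,
                                         gt, gt2, gt3, 0.3, 0.7, micro_cfg)$loss
      expect_equal(g_ana[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }
  # gradient flows: every parameter group carries nonzero gradient
  norms <- vapply(leafcomplete:::.w_leaves(lg$grads),
                  function(g) sum(abs(g)), 0)
  expect_true(all(norms > 0))
})

test_that("completion preserves the observed points verbatim", {
  set.seed(73)
  w <- pfnet_init(micro_cfg, seed = 9)
  inc <- rand_cloud(32)
  out <- complete_cloud(inc, list(weights = w, config = micro_cfg))
  expect_equal(npoints(out$fused), 32 + 8)
  expect_identical(out$fused$points[1:32, ], inc)
  expect_equal(npoints(out$predicted_missing), 8)
  expect_error(complete_cloud(rand_cloud(10),
                              list(weights = w, config = micro_cfg)),
               "exactly 32")
})

test_that("configuration invariants are enforced", {
  expect_error(pfnet_config(input_scales = c(512L, 512L, 256L)),
               "strictly decreasing")
  expect_error(pfnet_config(output_sizes = c(500L, 128L, 64L)), "multiple")
  cfg <- pfnet_config("tiny")
  expect_equal(cfg$feat_dim, 16 + 32 + 64)
  expect_equal(cfg$latent_dim, 128L)
})
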