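# Independent brute-force oracles used to cross-check the package's
# implementations. These deliberately share no code with the package paths
# they verify.

# greedy max-min farthest point sampling, O(n * k) with explicit
# per-step scans; ties toward the lowest index
oracle_fps <- function(pts, k, start = 1L) {
  n <- nrow(pts)
  sel <- start
  d <- sqrt(rowSums(sweep(pts, 2, pts[start, ])^2))
  while (length(sel) < k) {
    nxt <- which.max(d)  # which.max takes the first (lowest-index) maximum
    sel <- c(sel, nxt)
    d <- pmin(d, sqrt(rowSums(sweep(pts, 2, pts[nxt, ])^2)))
  }
  as.integer(sel)
}

# exhaustive-permutation earth mover's distance (n <= 8)
oracle_emd <- function(A, B) {
  n <- nrow(A)
  cost <- outer(seq_len(n), seq_len(n), Vectorize(function(i, j)
    sqrt(sum((A[i, ] - B[j, ])^2))))
  best <- Inf
  rec <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > n) { best <<- acc; return() }
    for (j in which(!used)) {
      used[j] <- TRUE
      rec(i + 1L, used, acc + cost[i, j])
      used[j] <- FALSE
    }
  }
  rec(1L, rep(FALSE, n), 0)
  best / n
}

# plain dense-matrix chamfer (mean reduction) and Hausdorff
oracle_cross_d2 <- function(A, B) {
  outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * A %*% t(B)
}
oracle_chamfer <- function(A, B, reduction = "mean") {
  D <- pmax(oracle_cross_d2(A, B), 0)
  red <- if (reduction == "mean") mean else sum
  red(apply(D, 1, min)) + red(apply(D, 2, min))
}
oracle_hausdorff <- function(A, B) {
  D <- sqrt(pmax(oracle_cross_d2(A, B), 0))
  max(max(apply(D, 1, min)), max(apply(D, 2, min)))
}

rand_cloud <- function(n, scale = 1) matrix(stats::rnorm(3 * n, sd = scale), ncol = 3)
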