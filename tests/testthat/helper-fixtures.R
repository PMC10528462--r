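`%||%` <- function(a, b) if (is.null(a)) b else a

# small synthetic fixtures built in code; all randomness under fixed seeds

# tiny functional dataset with q = 2 covariates on common grids
tiny_dataset <- function(n = 3, n_t = 5, n_s = 5, seed = 1, with_y = TRUE) {
  set.seed(seed)
  tg <- seq(0, 1, length.out = n_t)
  sg <- seq(0, 1, length.out = n_s)
  x <- lapply(1:2, function(j) array(rnorm(n * n_t * n_s), c(n, n_t, n_s)))
  y <- if (with_y) matrix(rnorm(n * n_t), n, n_t)
  fcrsel:::new_fcr_dataset(y, x, tg, sg)
}

# random evaluation points (t, u-list) for kernel property checks
random_points <- function(m, n_s, q = 2, seed = 1) {
  set.seed(seed)
  lapply(seq_len(m), function(i) {
    list(t = runif(1), u = lapply(seq_len(q), function(j) runif(n_s, -1, 1)))
  })
}

# Gram matrix of one scheme component over a point list
component_gram <- function(scheme, v, pts, s_grid) {
  m <- length(pts)
  G <- matrix(0, m, m)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    G[a, b] <- rk_component(scheme, v, pts[[a]]$t, pts[[a]]$u,
                            pts[[b]]$t, pts[[b]]$u, s_grid)
  }
  G
}

# brute-force nested-loop double quadrature of Sigma_v entries through the
# pointwise kernel (uncentered construction)
brute_sigma_v <- function(op, data, scheme, v) {
  n <- op$n; K <- op$K
  tg <- data$t_grid; wt <- fcrsel:::trap_weights(tg)
  B <- matrix(0, n * K, n * K)
  for (i in seq_len(n)) for (k in seq_len(K)) {
    for (j in seq_len(n)) for (l in seq_len(K)) {
      acc <- 0
      for (a in seq_along(tg)) for (b in seq_along(tg)) {
        ui <- lapply(data$x, function(arr) arr[i, a, ])
        uj <- lapply(data$x, function(arr) arr[j, b, ])
        acc <- acc + wt[a] * wt[b] * op$basis$eta[a, k] *
          rk_component(scheme, v, tg[a], ui, tg[b], uj, data$s_grid) *
          op$basis$eta[b, l]
      }
      B[i + (k - 1) * n, j + (l - 1) * n] <- acc
    }
  }
  B
}

# orthonormalized {1, k1(t)} score basis with exact scores for given curves:
# lets solver tests work with a full-rank null-space design even when the
# response curves themselves are collinear
manual_nullspace_basis <- function(Y, t_grid) {
  w <- fcrsel:::trap_weights(t_grid)
  B <- cbind(1, k1(t_grid))
  # Gram-Schmidt in the quadrature inner product
  e1 <- B[, 1] / sqrt(sum(w * B[, 1]^2))
  v2 <- B[, 2] - sum(w * B[, 2] * e1) * e1
  e2 <- v2 / sqrt(sum(w * v2^2))
  eta <- cbind(e1, e2)
  nu <- Y %*% (w * eta)
  structure(list(eta = eta, nu = nu, values = rep(1, 2), t_grid = t_grid,
                 K = 2L, n = nrow(Y)),
            class = "fcr_efpc")
}

# project fitted curves onto a basis (independent quadrature projection)
project_curves <- function(curves, basis) {
  w <- fcrsel:::trap_weights(basis$t_grid)
  curves %*% (w * basis$eta)
}
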