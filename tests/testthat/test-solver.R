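# block-update steps are verified against independent numerical oracles
# (generic optimizers, grid searches, random feasible points) on tiny
# instances, then the assembled backfitting loop against a brute-force
# profile minimizer

make_small_op <- function(n = 3, n_t = 5, seed = 41, K_max = NULL,
                          center = TRUE) {
  ds <- tiny_dataset(n = n, n_t = n_t, n_s = 4, seed = seed)
  op <- fcr_operators(ds, fcr_scheme(2), K_max = K_max, center = center)
  list(ds = ds, op = op)
}

test_that("c-step solves the ridge-stabilized normal equations", {
  s <- make_small_op()
  op <- s$op
  theta <- rep(1, 10)
  Sth <- combine_sigma(op$Sigma, theta)
  d0 <- fcrsel:::update_d(op$Y, op$T, 0, c(0, 1), op$n)
  # zero residual gives zero coefficients
  cc <- fcrsel:::update_c(op$T %*% d0, op$T, d0, Sth, 1e-3, op$n)
  expect_lt(max(abs(cc)), 1e-10)
  # penalty dominance: ||c|| decreases monotonically in tau0
  norms <- vapply(c(1e-3, 1e-1, 10), function(t0) {
    sqrt(sum(fcrsel:::update_c(op$Y, op$T, d0, Sth, t0, op$n)^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
  # objective value at the returned c matches a generic numerical minimizer
  obj <- function(cc) {
    r <- op$Y - as.vector(op$T %*% d0) - as.vector(Sth %*% cc)
    sum(r^2) / op$n + 1e-2 * sum(cc * (Sth %*% cc))
  }
  c_hat <- fcrsel:::update_c(op$Y, op$T, d0, Sth, 1e-2, op$n)
  o <- stats::optim(c_hat * 0, obj, method = "BFGS",
                    control = list(maxit = 500, reltol = 1e-14))
  expect_lte(obj(c_hat), o$value + 1e-8)
})

test_that("d-step reduces to OLS, respects the unpenalized constant, and matches a grid search", {
  set.seed(42)
  Tm <- cbind(1, rnorm(30))
  y <- rnorm(30)
  d_ols <- fcrsel:::update_d(y, Tm, 0, c(0, 1), 10)
  expect_equal(d_ols, as.vector(qr.coef(qr(Tm), y)))
  # enormous penalty with w1 = (0, 1): constant survives, slope dies
  d_big <- fcrsel:::update_d(y, Tm, 1e6, c(0, 1), 10)
  expect_equal(d_big[2], 0)
  expect_equal(d_big[1], mean(y), tolerance = 1e-8)
  # moderate penalty: objective no worse than a fine 2-d grid search
  lam <- 0.3; w1 <- c(0.5, 1); n <- 10
  d_hat <- fcrsel:::update_d(y, Tm, lam, w1, n)
  obj <- function(d) sum((y - Tm %*% d)^2) / n + lam * sum(w1 * abs(d))
  grid <- as.matrix(expand.grid(seq(-1, 1, length.out = 121),
                                seq(-1, 1, length.out = 121)))
  expect_lte(obj(d_hat), min(apply(grid, 1, obj)) + 1e-8)
})

test_that("theta-step QP: budget edge cases, scalar closed form, feasible-point oracle", {
  expect_equal(fcrsel:::qp_nonneg_budget(matrix(2), -1, 1, 0)$theta, 0)
  expect_error(fcrsel:::qp_nonneg_budget(matrix(2), -1, 1, -1), "nonnegative")
  # Q = 1: quadratic vertex clipped to [0, M / w]
  for (cse in list(c(h = 2, f = -1, w = 1, M = 5),    # interior
                   c(h = 2, f = -10, w = 1, M = 2),   # budget-clipped
                   c(h = 2, f = 1, w = 1, M = 5))) {  # clipped at zero
    th <- fcrsel:::qp_nonneg_budget(matrix(cse["h"]), cse["f"], cse["w"],
                                    cse["M"])$theta
    expect_equal(th, min(max(-cse[["f"]] / cse[["h"]], 0),
                         cse[["M"]] / cse[["w"]]), tolerance = 1e-9)
  }
  # random instances: no random feasible point does better, and the exact
  # active-set path agrees with the bisection solver
  set.seed(43)
  for (rep in 1:20) {
    Q <- 4
    A <- matrix(rnorm(Q * 6), Q)
    H <- tcrossprod(A) / 6
    f <- rnorm(Q); w <- runif(Q, 0.5, 2); M <- runif(1, 0.2, 3)
    obj <- function(th) 0.5 * sum(th * (H %*% th)) + sum(f * th)
    sol <- fcrsel:::qp_nonneg_budget(H, f, w, M)
    expect_true(all(sol$theta >= 0))
    expect_lte(sum(w * sol$theta), M * (1 + 1e-8))
    cand <- matrix(runif(1000 * Q), 1000, Q)
    cand <- cand * (M * runif(1000) / as.vector(cand %*% w))
    expect_lte(obj(sol$theta), min(apply(cand, 1, obj)) + 1e-9)
    bis <- fcrsel:::qp_nonneg_budget_bisect(H, f, w, M)
    expect_equal(obj(sol$theta), obj(bis$theta), tolerance = 1e-7)
  }
})

test_that("backfit recovers null-space coefficients from noiseless data", {
  tg <- seq(0, 1, length.out = 15)
  d_true <- c(1.3, -0.7)
  n <- 4
  Y_curves <- matrix(rep(d_true[1] + d_true[2] * k1(tg), n), n, byrow = TRUE)
  basis <- manual_nullspace_basis(Y_curves, tg)
  ds <- tiny_dataset(n = n, n_t = 15, n_s = 4, seed = 44, with_y = FALSE)
  ds$y <- Y_curves
  op <- fcr_operators(ds, fcr_scheme(2), basis = basis)
  fit <- backfit(op, tau0 = 1e-3, M = 4)
  expect_lt(max(abs(fit$theta)), 1e-6)
  expect_equal(length(fit$selected), 0L)
  expect_equal(fit$d, d_true, tolerance = 1e-3)
})

test_that("backfit sweeps are monotone, deterministic, and flag non-convergence", {
  s <- make_small_op(seed = 45)
  fit <- backfit(s$op, tau0 = 1e-2, M = 20, max_iter = 15)
  expect_true(all(diff(fit$trace) <= 1e-9))
  fit2 <- backfit(s$op, tau0 = 1e-2, M = 20, max_iter = 15)
  expect_identical(fit$c, fit2$c)
  expect_identical(fit$theta, fit2$theta)
  fit1 <- backfit(s$op, tau0 = 1e-2, M = 20, max_iter = 1)
  expect_false(fit1$converged)
  expect_equal(fit1$iters, 1L)
})

test_that("backfit objective matches a brute-force profile minimizer on a tiny instance", {
  # n = 2, K = 1, 5-point grids, two components kept
  ds <- tiny_dataset(n = 2, n_t = 5, n_s = 5, seed = 46)
  op <- fcr_operators(ds, fcr_scheme(2), K_max = 1, center = FALSE)
  op$Sigma <- op$Sigma[c(1, 8)]
  op$Sigma_stack <- NULL
  tau0 <- 1e-2; M <- 2
  fit <- backfit(op, tau0 = tau0, M = M, w2 = c(1, 1), tol = 1e-12,
                 max_iter = 200)
  # oracle: exact joint (c, d) solve for fixed theta, minimized over a fine
  # grid on the feasible triangle {theta >= 0, sum(theta) <= M}
  inner <- function(theta) {
    Sth <- combine_sigma(op$Sigma, theta, c(1, 1))
    d <- c(0, 0)
    for (it in 1:400) {
      cc <- fcrsel:::update_c(op$Y, op$T, d, Sth, tau0, op$n)
      d_new <- fcrsel:::update_d(op$Y - as.vector(Sth %*% cc), op$T, 0,
                                 c(0, 1), op$n)
      if (max(abs(d_new - d)) < 1e-13) { d <- d_new; break }
      d <- d_new
    }
    r <- op$Y - as.vector(op$T %*% d) - as.vector(Sth %*% cc)
    sum(r^2) / op$n + tau0 * sum(cc * (Sth %*% cc))
  }
  grid <- seq(0, M, length.out = 81)
  vals <- outer(grid, grid, Vectorize(function(a, b) {
    if (a + b > M) NA_real_ else inner(c(a, b))
  }))
  expect_lte(fit$objective, min(vals, na.rm = TRUE) + 1e-6)
})

test_that("fitted curves reproduce the fitted scores (representer consistency)", {
  s <- make_small_op(n = 4, n_t = 7, seed = 47)
  fit <- backfit(s$op, tau0 = 1e-2, M = 6)
  fitted_scores <- as.vector(s$op$T %*% fit$d) +
    as.vector(combine_sigma(s$op$Sigma, fit$theta) %*% fit$c)
  curves <- fcrsel:::predict_curves(s$op, fit, s$ds$x)
  expect_lt(max(abs(as.vector(project_curves(curves, s$op$basis)) -
                      fitted_scores)), 1e-6)
  # theta = 0 makes the prediction independent of the covariates and equal
  # to the basis reconstruction of the null-space curve
  fit0 <- fit
  fit0$theta <- rep(0, 10)
  other <- tiny_dataset(n = 4, n_t = 7, n_s = 4, seed = 48)
  p1 <- fcrsel:::predict_curves(s$op, fit0, s$ds$x)
  p2 <- fcrsel:::predict_curves(s$op, fit0, other$x)
  expect_equal(p1, p2)
  null_curve <- fit$d[1] + fit$d[2] * k1(s$ds$t_grid)
  expect_equal(p1[1, ], as.vector(project_curves(rbind(null_curve),
                                                 s$op$basis) %*%
                                    t(s$op$basis$eta)))
})

test_that("rescaling the response rescales coefficients and predictions", {
  s <- make_small_op(n = 4, n_t = 7, seed = 49)
  a <- 3
  op2 <- s$op
  op2$Y <- a * op2$Y
  fit1 <- backfit(s$op, tau0 = 1e-2, M = 5, tol = 1e-10, max_iter = 30)
  fit2 <- backfit(op2, tau0 = 1e-2, M = 5, tol = 1e-10, max_iter = 30)
  expect_equal(fit2$d, a * fit1$d, tolerance = 1e-5)
  p1 <- fcrsel:::predict_curves(s$op, fit1, s$ds$x)
  p2 <- fcrsel:::predict_curves(op2, fit2, s$ds$x)
  expect_equal(p2, a * p1, tolerance = 1e-4)
})

test_that("threshold_selected handles zero, mixed, and tied scales", {
  expect_equal(threshold_selected(rep(0, 5)), integer(0))
  expect_equal(threshold_selected(c(4.157, 0.819, 0, 0)), c(1L, 2L))
  expect_equal(threshold_selected(rep(2, 6)), 1:6)
})

test_that("tuning selection: degenerate grids, CV bookkeeping, tie-breaking", {
  s <- make_small_op(n = 6, n_t = 6, seed = 50)
  op <- s$op
  expect_error(select_tuning(op, numeric(0), 1), "non-empty")
  one <- select_tuning(op, 0.05, 3, criterion = "bic")
  expect_equal(one$tau0, 0.05)
  expect_equal(one$M, 3)
  # CV score equals an independent refit-per-fold loop
  tun <- select_tuning(op, 0.05, c(2, 4), criterion = "cv", folds = 3,
                       seed = 7, rule = "min", max_iter = 6)
  fold_id <- fcrsel:::fold_assignment(op$n, 3, 7)
  sse <- c(`4` = 0, `2` = 0)
  for (f in 1:3) {
    tr <- which(fold_id != f); va <- which(fold_id == f)
    so <- fcrsel:::sub_operators(op, tr)
    idx <- fcrsel:::score_indices(va, op$n, op$K)
    init_f <- NULL
    for (Mv in c(4, 2)) {  # descending budgets, warm-started as in the loop
      ff <- backfit(so, tau0 = 0.05, M = Mv, init = init_f, max_iter = 6)
      init_f <- list(theta = ff$theta, d = ff$d, mu = ff$mu)
      pred <- fcrsel:::predict_scores_subset(op, ff, tr, va, op$scheme$w2)
      sse[as.character(Mv)] <- sse[as.character(Mv)] +
        sum((op$Y[idx] - pred)^2) / length(va)
    }
  }
  for (Mv in c(4, 2)) {
    got <- tun$scores$score[tun$scores$M == Mv]
    expect_equal(got, unname(sse[as.character(Mv)]) / 3, tolerance = 1e-10)
  }
})

test_that("ridge estimator: penalty dominance, interpolation, selection contract", {
  s <- make_small_op(n = 3, n_t = 6, seed = 51)
  op <- s$op
  # enormous penalty leaves only the null-space projection
  f_big <- fit_l2(op, lambda_grid = 1e6)
  fitted_big <- as.vector(op$T %*% f_big$d) +
    as.vector(combine_sigma(op$Sigma, f_big$theta) %*% f_big$c)
  d0 <- fcrsel:::update_d(op$Y, op$T, 0, c(0, 1), op$n)
  expect_equal(fitted_big, as.vector(op$T %*% d0), tolerance = 1e-4)
  # tiny penalty interpolates the scores on a 3-subject toy
  f_small <- fit_l2(op, lambda_grid = 1e-9)
  fitted_small <- as.vector(op$T %*% f_small$d) +
    as.vector(combine_sigma(op$Sigma, f_small$theta) %*% f_small$c)
  expect_lt(sum((op$Y - fitted_small)^2), 1e-4 * sum(op$Y^2))
  # no selection is performed: every component is reported
  expect_equal(f_small$selected, 1:10)
  expect_equal(f_small$theta, rep(1, 10))
  # empty component set falls back to the null-space regression
  f_null <- fit_l2(op, lambda_grid = 0.1, selected = integer(0))
  expect_equal(f_null$d, d0, tolerance = 1e-8)
  expect_equal(f_null$c, rep(0, length(op$Y)))
  expect_error(fit_l2(op, lambda_grid = numeric(0)), "non-empty")
})

test_that("selection-then-refit reduces to its limiting cases", {
  s <- make_small_op(n = 5, n_t = 6, seed = 52)
  op <- s$op
  # a vanishing budget selects nothing: refit equals null-space regression
  f0 <- fit_l1_l2(op, tau0_grid = 1e-2, M_grid = 1e-9,
                  lambda_grid = c(0.1), criterion = "bic")
  expect_equal(length(f0$stage1$selected), 0L)
  d0 <- fcrsel:::update_d(op$Y, op$T, 0, c(0, 1), op$n)
  expect_equal(f0$d, d0, tolerance = 1e-6)
  # when everything is selected the refit equals the plain ridge estimator
  f_all <- fit_l2(op, lambda_grid = c(0.1), selected = 1:10)
  f_ref <- fit_l2(op, lambda_grid = c(0.1))
  expect_equal(f_all$c, f_ref$c)
  expect_equal(f_all$d, f_ref$d)
})
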