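# ---------------------------------------------------------------------------
# Block backfitting solver for the penalized score regression
#
#   (1/n) ||Y - T d - Sigma(theta) c||^2 + lambda1 sum_k w1k |d_k|
#        + tau0 c' Sigma(theta) c,   s.t. theta >= 0, w2' theta <= M,
#
# alternating exact minimization over c (ridge-stabilized linear solve),
# d (2-dim weighted lasso), and theta (nonnegative budget-constrained QP).
# ---------------------------------------------------------------------------

solve_spd <- function(A, b) {
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch)) {
    diag(A) <- diag(A) + 1e-8 * mean(abs(diag(A))) + 1e-12
    ch <- chol(A)
  }
  backsolve(ch, backsolve(ch, b, transpose = TRUE))
}

# c-step: solve (Sigma + n tau0 I) c = Y - T d (plus 1e-10 diagonal jitter);
# a global minimizer of the c-block objective for PSD Sigma.
update_c <- function(Y, Tm, d, Sigma_theta, tau0, n) {
  r <- Y - as.vector(Tm %*% d)
  A <- Sigma_theta
  diag(A) <- diag(A) + n * tau0 + 1e-10
  as.vector(solve_spd(A, r))
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

# d-step: 2-coefficient weighted lasso
#   min (1/n)||Ystar - T d||^2 + lambda1 sum w1k |d_k|
# by cyclic coordinate descent with closed-form soft-thresholding.
update_d <- function(Ystar, Tm, lambda1, w1, n) {
  if (lambda1 <= 0 || all(w1 == 0)) {
    d <- qr.coef(qr(Tm), Ystar)
    d[is.na(d)] <- 0
    return(as.vector(d))
  }
  p <- ncol(Tm)
  d <- rep(0, p)
  cn <- colSums(Tm^2)
  r <- Ystar
  for (it in seq_len(200L)) {
    delta_max <- 0
    for (j in seq_len(p)) {
      if (cn[j] <= 0) next
      z <- sum(Tm[, j] * r) + cn[j] * d[j]
      dj <- soft_threshold(z, n * lambda1 * w1[j] / 2) / cn[j]
      if (dj != d[j]) {
        r <- r - Tm[, j] * (dj - d[j])
        delta_max <- max(delta_max, abs(dj - d[j]))
        d[j] <- dj
      }
    }
    if (delta_max < 1e-12) break
  }
  d
}

# cyclic coordinate descent for min 0.5 th' H th + f' th, th >= 0
nnls_cd <- function(H, f, start = NULL, maxit = 500L, tol = 1e-11) {
  Q <- length(f)
  th <- if (is.null(start)) rep(0, Q) else pmax(start, 0)
  g <- as.vector(H %*% th) + f
  dh <- diag(H)
  scale <- max(th, 1e-300)
  for (it in seq_len(maxit)) {
    delta_max <- 0
    for (v in seq_len(Q)) {
      newv <- if (dh[v] <= 0) 0 else max(0, th[v] - g[v] / dh[v])
      dlt <- newv - th[v]
      if (dlt != 0) {
        g <- g + H[, v] * dlt
        th[v] <- newv
        if (newv > scale) scale <- newv
        if (abs(dlt) > delta_max) delta_max <- abs(dlt)
      }
    }
    if (delta_max <= tol * (1 + scale)) break
  }
  th
}

# primal active-set solver for min 0.5 th' H th + f' th, th >= 0, w' th <= M.
# Iterates on the free set: solves the KKT system (with or without the
# budget equality), drops negative coordinates, adds the most negative
# reduced gradient. Returns NULL if it fails to settle (caller falls back
# to coordinate descent with multiplier bisection).
qp_active_set <- function(H, f, w, M, start = NULL) {
  Q <- length(f)
  free <- if (!is.null(start)) which(start > 0) else seq_len(Q)
  if (!length(free)) free <- which.min(f)
  for (it in seq_len(8L * Q + 8L)) {
    repeat {
      # budget-inactive solve on the free set
      th <- rep(0, Q); mu <- 0
      sol <- tryCatch(solve(H[free, free, drop = FALSE], -f[free]),
                      error = function(e) NULL)
      if (is.null(sol)) return(NULL)
      if (sum(w[free] * sol) > M) {
        # budget active: equality-constrained KKT solve
        kk <- length(free)
        Kmat <- rbind(cbind(H[free, free, drop = FALSE], w[free]),
                      c(w[free], 0))
        sol2 <- tryCatch(solve(Kmat, c(-f[free], M)), error = function(e) NULL)
        if (is.null(sol2)) return(NULL)
        sol <- sol2[seq_len(kk)]
        mu <- sol2[kk + 1L]
      }
      if (all(sol >= -1e-12)) { th[free] <- pmax(sol, 0); break }
      drop_v <- free[which.min(sol)]
      free <- setdiff(free, drop_v)
      if (!length(free)) { th <- rep(0, Q); mu <- max(0, mu); break }
    }
    if (mu < 0) {
      # budget multiplier negative: treat budget as inactive and retry with
      # the free set intact minus nothing; guard against cycling
      mu <- 0
    }
    g <- as.vector(H %*% th) + f + mu * w
    zero <- setdiff(seq_len(Q), which(th > 0))
    viol <- zero[g[zero] < -1e-10 * (1 + max(abs(f)))]
    if (!length(viol)) {
      if (sum(w * th) > M * (1 + 1e-9)) return(NULL)
      return(list(theta = th, mu = max(mu, 0)))
    }
    free <- union(which(th > 0), viol[which.min(g[viol])])
  }
  NULL
}

# min 0.5 th' H th + f' th  s.t. th >= 0, w' th <= M: nonnegative coordinate
# descent plus bisection on the budget multiplier (warm-startable via
# `mu_start` from the previous call).
qp_nonneg_budget_bisect <- function(H, f, w, M, start = NULL, mu_start = NULL) {
  Q <- length(f)
  if (M < 0) rlang::abort("budget `M` must be nonnegative.")
  if (M == 0) return(list(theta = rep(0, Q), mu = 0))
  diag(H) <- diag(H) + 1e-12 * (mean(abs(diag(H))) + 1)
  th <- nnls_cd(H, f, start = start)
  if (sum(w * th) <= M * (1 + 1e-10)) return(list(theta = th, mu = 0))
  # bracket the multiplier, preferring the previous solution's value
  lo <- 0
  hi <- if (!is.null(mu_start) && mu_start > 0) mu_start else 1
  th_hi <- nnls_cd(H, f + hi * w, start = th)
  it <- 0
  while (sum(w * th_hi) > M && it < 60L) {
    lo <- hi; hi <- hi * 2; it <- it + 1
    th_hi <- nnls_cd(H, f + hi * w, start = th_hi)
  }
  th_feas <- th_hi; mu_feas <- hi
  for (it in seq_len(60L)) {
    mid <- (lo + hi) / 2
    th_mid <- nnls_cd(H, f + mid * w, start = th_feas)
    bud <- sum(w * th_mid)
    if (bud > M) lo <- mid else { hi <- mid; th_feas <- th_mid; mu_feas <- mid }
    if (hi - lo < 1e-10 * (1 + hi) ||
        (bud <= M && bud >= M * (1 - 1e-9))) break
  }
  bud <- sum(w * th_feas)
  if (bud > M) th_feas <- th_feas * (M / bud)
  list(theta = th_feas, mu = mu_feas)
}

# theta-step: min (1/n)||Y - T d - R theta||^2 + tau0 c' R theta
# s.t. theta >= 0, w2' theta <= M
update_theta <- function(Y, Tm, d, R, tau0, c_coef, M, w2, n, start = NULL,
                         mu_start = NULL) {
  r <- Y - as.vector(Tm %*% d)
  H <- (2 / n) * crossprod(R)
  f <- as.vector(-(2 / n) * crossprod(R, r) + tau0 * crossprod(R, c_coef))
  qp_nonneg_budget(H, f, w2, M, start = start, mu_start = mu_start)
}

# front end: exact active-set solve with coordinate-descent fallback
qp_nonneg_budget <- function(H, f, w, M, start = NULL, mu_start = NULL) {
  if (M < 0) rlang::abort("budget `M` must be nonnegative.")
  if (M == 0) return(list(theta = rep(0, length(f)), mu = 0))
  Hr <- H
  diag(Hr) <- diag(Hr) + 1e-12 * (mean(abs(diag(H))) + 1)
  sol <- qp_active_set(Hr, f, w, M, start = start)
  if (!is.null(sol)) return(sol)
  qp_nonneg_budget_bisect(H, f, w, M, start = start, mu_start = mu_start)
}

# budget-form objective, with u = Sigma(theta) c = R theta
objective_l1 <- function(Y, Tm, d, u, c_coef, lambda1, w1, tau0, n) {
  r <- Y - as.vector(Tm %*% d) - u
  sum(r^2) / n + lambda1 * sum(w1 * abs(d)) + tau0 * sum(c_coef * u)
}

#' Components retained by the selection estimator
#'
#' Indices of components whose estimated scale exceeds
#' `eps * max(max(theta), 1)`; the small relative floor absorbs the tiny
#' positive values numerical QP solutions leave at inactive coordinates.
#'
#' @param theta nonnegative vector of component scales.
#' @param eps relative threshold (default `1e-6`).
#' @return integer vector of selected component indices.
#' @export
threshold_selected <- function(theta, eps = 1e-6) {
  which(theta > eps * max(max(theta), 1))
}

#' Block backfitting for the component-selection estimator
#'
#' Alternates exact block updates of the representer coefficients `c`, the
#' null-space coefficients `d`, and the component scales `theta` (nonnegative,
#' total weighted budget at most `M`) until the penalized objective
#' stabilizes. The objective trace over full sweeps is non-increasing.
#'
#' @param op operator matrices from [fcr_operators()] (or any list with
#'   elements `Y`, `T`, `Sigma`, `n`).
#' @param lambda1 L1 penalty on the null-space coefficients (weighted by
#'   `w1`; the default `w1 = c(0, 1)` leaves the constant unpenalized).
#' @param tau0 ridge-type penalty on the representer term.
#' @param M budget bound on `sum(w2 * theta)`.
#' @param w1,w2 penalty weights.
#' @param init optional list with starting values `theta` and/or `d`.
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter maximum number of full sweeps.
#' @return list with `c`, `d`, `theta`, `selected`, `trace`, `converged`,
#'   `iters`, `objective`, and the tuning values used.
#' @export
backfit <- function(op, lambda1 = 0, tau0 = 1e-3, M = 2 * sqrt(length(op$Sigma)),
                    w1 = c(0, 1), w2 = NULL, init = NULL, tol = 1e-5,
                    max_iter = 20L) {
  Y <- op$Y; Tm <- op$T; Sigma <- op$Sigma; n <- op$n
  Q <- length(Sigma)
  if (is.null(w2)) w2 <- if (!is.null(op$scheme)) op$scheme$w2 else rep(1, Q)
  theta <- if (!is.null(init$theta)) init$theta else rep(1, Q)
  d <- if (!is.null(init$d)) init$d else update_d(Y, Tm, 0, w1, n)
  mu <- init$mu
  nK <- length(Y)
  Sstack <- op$Sigma_stack
  if (is.null(Sstack)) Sstack <- do.call(rbind, Sigma)
  w2rep <- rep(1 / w2, each = nK)
  c_coef <- rep(0, nK)
  trace <- numeric(0)
  obj <- Inf
  converged <- FALSE
  iters <- 0L
  for (sweep_i in seq_len(max_iter)) {
    iters <- sweep_i
    Sth <- combine_sigma(Sigma, theta, w2)
    c_coef <- update_c(Y, Tm, d, Sth, tau0, n)
    R <- matrix(as.vector(Sstack %*% c_coef) * w2rep, nK, Q)
    d <- update_d(Y - as.vector(R %*% theta), Tm, lambda1, w1, n)
    ts <- update_theta(Y, Tm, d, R, tau0, c_coef, M, w2, n,
                       start = theta, mu_start = mu)
    theta <- ts$theta; mu <- ts$mu
    obj_new <- objective_l1(Y, Tm, d, as.vector(R %*% theta), c_coef,
                            lambda1, w1, tau0, n)
    trace <- c(trace, obj_new)
    if (is.finite(obj) && abs(obj - obj_new) <= tol * max(1, abs(obj_new))) {
      obj <- obj_new
      converged <- TRUE
      break
    }
    obj <- obj_new
  }
  list(c = c_coef, d = d, theta = theta, mu = mu,
       selected = threshold_selected(theta),
       trace = trace, converged = converged, iters = iters,
       objective = obj,
       tuning = list(lambda1 = lambda1, tau0 = tau0, M = M, w1 = w1, w2 = w2))
}

# --------------------------------------------------------------------------
# tuning selection
# --------------------------------------------------------------------------

score_indices <- function(subjects, n, K) {
  as.vector(outer(subjects, (seq_len(K) - 1L) * n, "+"))
}

sub_operators <- function(op, subjects) {
  idx <- score_indices(subjects, op$n, op$K)
  Sigma <- lapply(op$Sigma, function(S) S[idx, idx, drop = FALSE])
  list(Y = op$Y[idx], T = op$T[idx, , drop = FALSE],
       Sigma = Sigma, Sigma_stack = do.call(rbind, Sigma),
       n = length(subjects), K = op$K, scheme = op$scheme)
}

# predicted scores for `val` subjects from a fit on `train` subjects
predict_scores_subset <- function(op, fit, train, val, w2) {
  idx_tr <- score_indices(train, op$n, op$K)
  idx_va <- score_indices(val, op$n, op$K)
  pred <- as.vector(op$T[idx_va, , drop = FALSE] %*% fit$d)
  for (v in seq_along(op$Sigma)) {
    if (fit$theta[v] != 0) {
      pred <- pred + (fit$theta[v] / w2[v]) *
        as.vector(op$Sigma[[v]][idx_va, idx_tr, drop = FALSE] %*% fit$c)
    }
  }
  pred
}

fold_assignment <- function(n, folds, seed) {
  set.seed(seed)
  sample(rep(seq_len(folds), length.out = n))
}

#' Tuning-parameter selection for the selection estimator
#'
#' Selects `(tau0, M)` (and optionally `lambda1`) over a grid by subject-level
#' k-fold cross-validation of the score prediction error, or by BIC on the
#' full fit. Ties are broken toward smaller `M`, then larger `tau0`. The CV
#' folds keep all K scores of a subject together and reuse the full-sample
#' score basis.
#'
#' @param op operator matrices from [fcr_operators()].
#' @param tau0_grid,M_grid,lambda1_grid numeric grids (scalars allowed).
#' @param criterion `"bic"` or `"cv"`.
#' @param rule for CV, `"1se"` picks the smallest budget whose score is
#'   within one standard error of the minimum (sparser models preferred, as
#'   in penalized-regression practice); `"min"` picks the score minimizer.
#' @param folds number of CV folds (criterion `"cv"`).
#' @param seed integer seed controlling fold assignment.
#' @param w1,w2,tol,max_iter passed to [backfit()].
#' @return list with the chosen `tau0`, `M`, `lambda1` and a tibble `scores`
#'   of the whole grid.
#' @export
select_tuning <- function(op, tau0_grid, M_grid, lambda1_grid = 0,
                          criterion = c("bic", "cv"), folds = 5L, seed = 1L,
                          rule = c("1se", "min"),
                          w1 = c(0, 1), w2 = NULL, tol = 1e-5, max_iter = 20L) {
  criterion <- match.arg(criterion)
  rule <- match.arg(rule)
  if (!length(tau0_grid) || !length(M_grid) || !length(lambda1_grid)) {
    rlang::abort("tuning grids must be non-empty.")
  }
  if (is.null(w2)) w2 <- if (!is.null(op$scheme)) op$scheme$w2 else rep(1, length(op$Sigma))
  nK <- length(op$Y)
  fold_id <- if (criterion == "cv") fold_assignment(op$n, folds, seed) else NULL
  subs <- if (criterion == "cv") {
    lapply(seq_len(folds), function(f) {
      tr <- which(fold_id != f)
      list(train = tr, val = which(fold_id == f), op = sub_operators(op, tr))
    })
  }
  rows <- list()
  for (l1 in lambda1_grid) {
    for (t0 in tau0_grid) {
      init <- NULL
      fold_init <- vector("list", folds)
      for (M in sort(M_grid, decreasing = TRUE)) {
        if (criterion == "bic") {
          fit <- backfit(op, lambda1 = l1, tau0 = t0, M = M, w1 = w1, w2 = w2,
                         init = init, tol = tol, max_iter = max_iter)
          init <- list(theta = fit$theta, d = fit$d, mu = fit$mu)
          R <- compute_R(op$Sigma, fit$c, w2)
          rss <- sum((op$Y - as.vector(op$T %*% fit$d) -
                        as.vector(R %*% fit$theta))^2)
          # effective degrees of freedom of the ridge-type score smoother at
          # the fitted component scales, plus the null-space dimension
          A <- combine_sigma(op$Sigma, fit$theta, w2)
          diag(A) <- diag(A) + op$n * t0 + 1e-10
          df <- nK - (op$n * t0) * sum(diag(chol2inv(chol(A)))) +
            sum(fit$d != 0)
          score <- nK * log(rss / nK + 1e-300) + df * log(nK)
        } else {
          fold_scores <- numeric(folds)
          for (fi in seq_along(subs)) {
            fd <- subs[[fi]]
            f_fit <- backfit(fd$op, lambda1 = l1, tau0 = t0, M = M, w1 = w1,
                             w2 = w2, init = fold_init[[fi]], tol = tol,
                             max_iter = max_iter)
            fold_init[[fi]] <- list(theta = f_fit$theta, d = f_fit$d,
                                    mu = f_fit$mu)
            pred <- predict_scores_subset(op, f_fit, fd$train, fd$val, w2)
            idx_va <- score_indices(fd$val, op$n, op$K)
            fold_scores[fi] <- sum((op$Y[idx_va] - pred)^2) / length(fd$val)
          }
          score <- mean(fold_scores)
          se <- stats::sd(fold_scores) / sqrt(folds)
        }
        rows[[length(rows) + 1L]] <-
          tibble::tibble(lambda1 = l1, tau0 = t0, M = M, score = score,
                         se = if (criterion == "cv") se else NA_real_)
      }
    }
  }
  scores <- dplyr::bind_rows(rows)
  ord <- order(scores$score, scores$M, -scores$tau0)
  pick <- scores[ord[1L], ]
  if (criterion == "cv" && rule == "1se") {
    eligible <- scores[scores$score <= pick$score + pick$se, ]
    pick <- eligible[order(eligible$M, -eligible$tau0, eligible$score), ][1L, ]
  }
  list(lambda1 = pick$lambda1, tau0 = pick$tau0, M = pick$M,
       criterion = criterion, rule = rule, scores = scores)
}

# --------------------------------------------------------------------------
# ridge-type (all-component) estimation, and selection-then-refit
# --------------------------------------------------------------------------

# exact joint minimizer of (1/n)||Y - T d - Sigma c||^2 + lambda c' Sigma c
# over (c, d): c = A^{-1}(Y - T d) with A = Sigma + n lambda I, and d solves
# the 2x2 system T' A^{-1} T d = T' A^{-1} Y.
solve_l2 <- function(Y, Tm, Sigma_tot, lambda, n) {
  A <- Sigma_tot
  diag(A) <- diag(A) + n * lambda + 1e-10
  W <- solve_spd(A, cbind(Y, Tm))
  M2 <- crossprod(Tm, W[, -1, drop = FALSE])
  rhs <- crossprod(Tm, W[, 1])
  d <- tryCatch(as.vector(solve(M2, rhs)), error = function(e) {
    dd <- qr.coef(qr(M2), rhs); dd[is.na(dd)] <- 0; as.vector(dd)
  })
  c_coef <- as.vector(W[, 1] - W[, -1, drop = FALSE] %*% d)
  list(c = c_coef, d = d)
}

#' Ridge-type estimator over a fixed component set
#'
#' Minimizes \eqn{(1/n)\sum_i \int (y_i - f)^2 + \lambda \sum_v \|P_v
#' f\|^2} with all component scales fixed at one (no selection), over the
#' components in `selected` (default all). `lambda` is chosen from
#' `lambda_grid` by subject-level cross-validation (or BIC using the
#' effective degrees of freedom of the linear smoother).
#'
#' @inheritParams select_tuning
#' @param lambda_grid grid of ridge penalties.
#' @param selected integer component subset (default all components).
#' @return a fit list as from [backfit()] with `theta` the 0/1 indicator of
#'   `selected` and tuning recording the chosen `lambda`.
#' @export
fit_l2 <- function(op, lambda_grid = 10^seq(-6, 0, length.out = 7),
                   selected = NULL, criterion = c("bic", "cv"), folds = 5L,
                   seed = 1L, w2 = NULL) {
  criterion <- match.arg(criterion)
  if (!length(lambda_grid)) rlang::abort("`lambda_grid` must be non-empty.")
  Q <- length(op$Sigma)
  if (is.null(w2)) w2 <- if (!is.null(op$scheme)) op$scheme$w2 else rep(1, Q)
  if (is.null(selected)) selected <- seq_len(Q)
  theta <- as.numeric(seq_len(Q) %in% selected)
  nK <- length(op$Y)
  if (length(selected)) {
    Sigma_tot <- combine_sigma(op$Sigma, theta, w2)
  } else {
    Sigma_tot <- matrix(0, nK, nK)
  }
  best <- NULL
  scores <- list()
  if (length(lambda_grid) == 1L) {
    lambda_best <- lambda_grid
  } else if (criterion == "cv") {
    # per fold, one eigendecomposition of the training block serves every
    # lambda; validation scores are predicted through the cross block
    fold_id <- fold_assignment(op$n, folds, seed)
    sse <- matrix(0, length(lambda_grid), folds)
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f); va <- which(fold_id == f)
      idx_tr <- score_indices(tr, op$n, op$K)
      idx_va <- score_indices(va, op$n, op$K)
      S_tr <- matrix(0, length(idx_tr), length(idx_tr))
      S_cross <- matrix(0, length(idx_va), length(idx_tr))
      for (v in selected) {
        S_tr <- S_tr + op$Sigma[[v]][idx_tr, idx_tr] / w2[v]
        S_cross <- S_cross + op$Sigma[[v]][idx_va, idx_tr] / w2[v]
      }
      ed <- eigen(S_tr, symmetric = TRUE)
      ev <- pmax(ed$values, 0)
      T_tr <- op$T[idx_tr, , drop = FALSE]
      VtY <- as.vector(crossprod(ed$vectors, op$Y[idx_tr]))
      VtT <- crossprod(ed$vectors, T_tr)
      n_tr <- length(tr)
      for (li in seq_along(lambda_grid)) {
        a <- 1 / (ev + n_tr * lambda_grid[li] + 1e-10)
        G2 <- crossprod(VtT, a * VtT)
        rhs <- crossprod(VtT, a * VtY)
        d <- tryCatch(as.vector(solve(G2, rhs)), error = function(e) {
          dd <- qr.coef(qr(G2), rhs); dd[is.na(dd)] <- 0; as.vector(dd)
        })
        cc <- as.vector(ed$vectors %*% (a * (VtY - as.vector(VtT %*% d))))
        pred <- as.vector(op$T[idx_va, , drop = FALSE] %*% d) +
          as.vector(S_cross %*% cc)
        sse[li, f] <- sum((op$Y[idx_va] - pred)^2)
      }
    }
    for (li in seq_along(lambda_grid)) {
      scores[[length(scores) + 1L]] <- tibble::tibble(
        lambda = lambda_grid[li], score = sum(sse[li, ]) / op$n)
    }
  } else {
    # one eigendecomposition serves the whole lambda grid: ridge solves,
    # residuals and effective df are all O(nK^2) per lambda in the eigenbasis
    ed <- eigen(Sigma_tot, symmetric = TRUE)
    ev <- pmax(ed$values, 0)
    VtY <- as.vector(crossprod(ed$vectors, op$Y))
    VtT <- crossprod(ed$vectors, op$T)
    for (lambda in lambda_grid) {
      a <- 1 / (ev + op$n * lambda + 1e-10)
      G2 <- crossprod(VtT, a * VtT)
      rhs <- crossprod(VtT, a * VtY)
      d <- tryCatch(as.vector(solve(G2, rhs)), error = function(e) {
        dd <- qr.coef(qr(G2), rhs); dd[is.na(dd)] <- 0; as.vector(dd)
      })
      rcoef <- VtY - as.vector(VtT %*% d)
      resid2 <- sum(((op$n * lambda + 1e-10) * a * rcoef)^2)
      df <- sum(ev * a) + 2
      scores[[length(scores) + 1L]] <- tibble::tibble(
        lambda = lambda,
        score = nK * log(resid2 / nK + 1e-300) + df * log(nK))
    }
  }
  if (length(scores)) {
    sc <- dplyr::bind_rows(scores)
    lambda_best <- sc$lambda[order(sc$score, sc$lambda)][1L]
    best <- sc
  }
  sol <- solve_l2(op$Y, op$T, Sigma_tot, lambda_best, op$n)
  if (!length(selected)) sol$c <- rep(0, nK)
  list(c = sol$c, d = sol$d, theta = theta, selected = selected,
       trace = numeric(0), converged = TRUE, iters = 1L,
       objective = NA_real_,
       tuning = list(lambda = lambda_best, w2 = w2, scores = best))
}

#' Selection estimator with tuning, and selection-then-refit
#'
#' `fit_l1()` runs [select_tuning()] then a final continuation [backfit()]
#' at the chosen tuning. With `tau0_grid = NULL` it first fits the
#' ridge-type estimator with all components ([fit_l2()]) and fixes `tau0`
#' at its chosen penalty. `fit_l1_l2()` additionally refits the selected
#' component set with the ridge-type estimator; an empty selected set falls
#' back to the null-space regression.
#'
#' @inheritParams select_tuning
#' @param tau0_grid,M_grid,lambda1_grid tuning grids; `M_grid` defaults to
#'   `c(0.25, 0.5, 1, 2, 4) * sqrt(Q)` and `tau0_grid` to the fixed value
#'   `1e-3` (only the budget is tuned; `tau0` and `M` are a redundant pair
#'   at the optimum, so `tau0` merely fixes the scale). `tau0_grid = NULL`
#'   instead fixes `tau0` at the stage-0 ridge level described above.
#' @param lambda_grid ridge grid for the stage-0 fit and the refit stage.
#' @param final_max_iter sweep cap for the final continuation fits (the
#'   cross-validation fold fits use the cheaper `max_iter`).
#' @return a fit list as from [backfit()]; for `fit_l1_l2()` the refit, with
#'   the first-stage fit attached as `stage1`. The final fit is obtained by
#'   continuation: refitting along the descending budget path down to the
#'   chosen `M`, each fit warm-started from the previous one.
#' @export
fit_l1 <- function(op, tau0_grid = 1e-3, M_grid = NULL, lambda1_grid = 0,
                   lambda_grid = 10^seq(-6, 0, length.out = 7),
                   criterion = c("cv", "bic"), folds = 5L, seed = 1L,
                   rule = c("1se", "min"),
                   w1 = c(0, 1), w2 = NULL, tol = 1e-5, max_iter = 4L,
                   final_max_iter = 12L) {
  criterion <- match.arg(criterion)
  rule <- match.arg(rule)
  Q <- length(op$Sigma)
  if (is.null(M_grid)) M_grid <- c(0.25, 0.5, 1, 2, 4) * sqrt(Q)
  if (is.null(w2)) w2 <- if (!is.null(op$scheme)) op$scheme$w2 else rep(1, Q)
  if (is.null(tau0_grid)) {
    stage0 <- fit_l2(op, lambda_grid = lambda_grid, criterion = criterion,
                     folds = folds, seed = seed, w2 = w2)
    tau0_grid <- stage0$tuning$lambda
  }
  tun <- select_tuning(op, tau0_grid, M_grid, lambda1_grid,
                       criterion = criterion, folds = folds, seed = seed,
                       rule = rule, w1 = w1, w2 = w2, tol = tol,
                       max_iter = max_iter)
  # continuation: refit along the descending budget path down to the chosen
  # M, warm-starting each fit from the previous one (the same homotopy the
  # tuning fits follow); this suppresses spurious small positive scales that
  # a cold start at an intermediate budget can retain
  path <- sort(M_grid[M_grid >= tun$M], decreasing = TRUE)
  init <- NULL
  for (M in path) {
    fit <- backfit(op, lambda1 = tun$lambda1, tau0 = tun$tau0, M = M,
                   w1 = w1, w2 = w2, init = init, tol = tol,
                   max_iter = final_max_iter)
    init <- list(theta = fit$theta, d = fit$d, mu = fit$mu)
  }
  fit$tuning$criterion <- tun$criterion
  fit$tuning$rule <- tun$rule
  fit$tuning$scores <- tun$scores
  fit
}

#' @rdname fit_l1
#' @export
fit_l1_l2 <- function(op, tau0_grid = 1e-3, M_grid = NULL, lambda1_grid = 0,
                      lambda_grid = 10^seq(-6, 0, length.out = 7),
                      criterion = c("cv", "bic"), folds = 5L, seed = 1L,
                      rule = c("1se", "min"),
                      w1 = c(0, 1), w2 = NULL, tol = 1e-5, max_iter = 4L,
                      final_max_iter = 12L) {
  stage1 <- fit_l1(op, tau0_grid, M_grid, lambda1_grid,
                   lambda_grid = lambda_grid,
                   criterion = criterion, folds = folds, seed = seed,
                   rule = rule, w1 = w1, w2 = w2, tol = tol,
                   max_iter = max_iter, final_max_iter = final_max_iter)
  refit <- fit_l2(op, lambda_grid = lambda_grid, selected = stage1$selected,
                  criterion = criterion, folds = folds, seed = seed, w2 = w2)
  refit$stage1 <- stage1
  refit
}
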