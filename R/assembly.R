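# ---------------------------------------------------------------------------
# Finite-dimensional operator assembly.
#
# Index conventions: the score vector Y, representer coefficients c and the
# rows of T and Sigma_v use the printed ordering a = i + (k - 1) n (subject i
# fastest). Internally, kernel Gram matrices over (subject, time) pairs use
# row (i - 1) T + t (time fastest within subject); `score_perm` maps between
# the two orderings.
# ---------------------------------------------------------------------------

# curves matrix for covariate j: (n*T) x S, row (i-1)*T + t
covariate_rows <- function(arr) {
  d <- dim(arr)
  matrix(aperm(arr, c(2L, 1L, 3L)), nrow = d[1] * d[2], ncol = d[3])
}

# Gaussian Gram matrices over all (subject, time) pairs, one per covariate
covariate_grams <- function(U_list, s_grid, U2_list = NULL) {
  lapply(seq_along(U_list), function(j) {
    U2 <- if (is.null(U2_list)) U_list[[j]] else U2_list[[j]]
    gaussian_gram(U_list[[j]], U2, s_grid)
  })
}

# permutation p with p[i + (k-1)*n] = (i-1)*K + k
score_perm <- function(n, K) {
  rep((seq_len(n) - 1L) * K, times = K) + rep(seq_len(K), each = n)
}

# full (n1*T) x (n2*T) kernel matrix of component v between two point sets,
# given tiled t-factor dims and covariate grams in (i-outer, t-inner) order
component_gram_big <- function(component, tf_mats, covgrams, n1, n2) {
  G <- NULL
  for (term in component$terms) {
    M <- kronecker(matrix(1, n1, n2), tf_mats[[term$t]])
    for (j in term$cov) M <- M * covgrams[[j]]
    G <- if (is.null(G)) M else G + M
  }
  G
}

#' Null-space design matrix of basis-projected regressors
#'
#' The nK x 2 matrix `T` with entries \eqn{a_{ikj} = \int_0^1 \phi_j(t)
#' \eta_k(t) dt} in row \eqn{i + (k-1) n}, where \eqn{\phi_1 = 1},
#' \eqn{\phi_2 = k_1(t)}. The entries do not depend on the subject index i,
#' so rows are replicated across subjects.
#'
#' @param basis an [efpc()] object.
#' @param n number of subjects (default the basis sample size).
#' @return nK x 2 numeric matrix.
#' @export
compute_T <- function(basis, n = basis$n) {
  w <- trap_weights(basis$t_grid)
  Phi <- cbind(1, k1(basis$t_grid))
  A <- crossprod(basis$eta, w * Phi)           # K x 2
  A[rep(seq_len(basis$K), each = n), , drop = FALSE]
}

#' Assemble the operator matrices of the penalized score regression
#'
#' Computes every finite-dimensional object the backfitting solver needs: the
#' score vector `Y` (\eqn{\nu_{ik}}, ordered \eqn{i + (k-1)n}), the null-space
#' design `T`, and one symmetric nK x nK Gram block \eqn{\Sigma_v} per
#' penalized component, with entries
#' \eqn{b^v_{ikjl} = \int\!\!\int \eta_k(t) K_v((t, x_i(t,\cdot)), (t',
#' x_j(t',\cdot))) \eta_l(t')\, dt\, dt'} (trapezoidal quadrature on the
#' stored grids). Matrices are symmetrized after assembly.
#'
#' By default the Gaussian covariate kernels are empirically centered
#' (`center = TRUE`): each Gram matrix is double-centered against the pooled
#' training distribution of covariate curves, the finite-sample realization
#' of the side condition that the covariate spaces contain no constants.
#' Without it, products of uncentered kernels can absorb main effects and
#' the ANOVA decomposition loses empirical identifiability. The Sobolev
#' factors in `t` satisfy their side conditions analytically and are never
#' centered.
#'
#' @param data an `fcr_dataset` with responses.
#' @param basis an [efpc()] object for the responses (default computed here).
#' @param scheme an [fcr_scheme()] with `q` matching the data.
#' @param K,fraction,K_max passed to [efpc()] when `basis` is `NULL`.
#' @param center empirically center the covariate kernel Gram matrices.
#' @return object of class `fcr_operators`.
#' @export
fcr_operators <- function(data, scheme, basis = NULL, K = NULL,
                          fraction = NULL, K_max = NULL, center = TRUE) {
  stopifnot(inherits(data, "fcr_dataset"), inherits(scheme, "fcr_scheme"))
  if (scheme$q != data$q) rlang::abort("scheme and data disagree on q.")
  if (is.null(basis)) {
    basis <- efpc(data$y, data$t_grid, K = K, fraction = fraction, K_max = K_max)
  }
  n <- data$n; Kb <- basis$K; tg <- data$t_grid
  U <- lapply(data$x, covariate_rows)
  cg <- covariate_grams(U, data$s_grid)
  cinfo <- list(on = center)
  if (center) {
    cinfo$m <- lapply(cg, colMeans)
    cinfo$g <- vapply(cg, mean, numeric(1))
    cg <- lapply(seq_along(cg), function(j) {
      sweep(sweep(cg[[j]], 2L, cinfo$m[[j]]), 1L, cinfo$m[[j]]) + cinfo$g[j]
    })
  }
  tf_mats <- list(one = tfac_matrix("one", tg),
                  lin = tfac_matrix("lin", tg),
                  np  = tfac_matrix("np", tg))
  wt <- trap_weights(tg)
  Ew <- wt * basis$eta                                   # T x K, quadrature-weighted
  IE <- Matrix::bdiag(rep(list(Matrix::Matrix(Ew)), n))  # (nT) x (nK), i-outer
  p <- score_perm(n, Kb)
  Sigma <- vector("list", scheme$Q)
  for (v in seq_len(scheme$Q)) {
    G <- component_gram_big(scheme$components[[v]], tf_mats, cg, n, n)
    B <- as.matrix(Matrix::crossprod(IE, G %*% IE))      # (nK) x (nK), i-outer
    B <- (B + t(B)) / 2
    Sigma[[v]] <- B[p, p]                                # row ordering i + (k-1)n
  }
  structure(
    list(
      Y = as.vector(basis$nu),
      T = compute_T(basis, n),
      Sigma = Sigma,
      n = n, K = Kb, Q = scheme$Q,
      scheme = scheme, basis = basis,
      t_grid = tg, s_grid = data$s_grid,
      U = U, subjects = data$subjects, center = cinfo
    ),
    class = "fcr_operators"
  )
}

# centered cross Gram between query curves and the training curves, using
# the training-sample centering statistics stored in `op`
cross_grams <- function(op, U_new) {
  cg <- covariate_grams(U_new, op$s_grid, op$U)
  if (isTRUE(op$center$on)) {
    cg <- lapply(seq_along(cg), function(j) {
      a <- rowMeans(cg[[j]])
      sweep(sweep(cg[[j]], 2L, op$center$m[[j]]), 1L, a) + op$center$g[j]
    })
  }
  cg
}

#' @method print fcr_operators
#' @export
print.fcr_operators <- function(x, ...) {
  cat("<fcr_operators> n = ", x$n, ", K = ", x$K, " scores/subject, Q = ",
      x$Q, " component Gram blocks of dim ", x$n * x$K, "\n", sep = "")
  invisible(x)
}

#' Combine component Gram blocks
#'
#' \eqn{\Sigma(\theta) = \sum_v w_{2,v}^{-1}\theta_v \Sigma_v} (exact
#' linearity in `theta`).
#'
#' @param Sigma list of Q symmetric nK x nK matrices.
#' @param theta nonnegative Q-vector.
#' @param w2 positive Q-vector of weights.
#' @return nK x nK matrix.
#' @export
combine_sigma <- function(Sigma, theta, w2 = rep(1, length(Sigma))) {
  if (length(theta) != length(Sigma)) rlang::abort("dimension mismatch.")
  out <- matrix(0, nrow(Sigma[[1]]), ncol(Sigma[[1]]))
  for (v in seq_along(Sigma)) {
    if (theta[v] != 0) out <- out + (theta[v] / w2[v]) * Sigma[[v]]
  }
  out
}

#' Design matrix of the component-scale step
#'
#' The nK x Q matrix `R` whose v-th column is \eqn{w_{2,v}^{-1}\Sigma_v c},
#' so that \eqn{\Sigma(\theta) c = R\theta} identically.
#'
#' @inheritParams combine_sigma
#' @param c_coef representer coefficient vector of length nK.
#' @return nK x Q matrix.
#' @export
compute_R <- function(Sigma, c_coef, w2 = rep(1, length(Sigma))) {
  if (length(c_coef) != nrow(Sigma[[1]])) rlang::abort("dimension mismatch.")
  vapply(seq_along(Sigma), function(v) as.vector(Sigma[[v]] %*% c_coef) / w2[v],
         numeric(length(c_coef)))
}

#' Representer basis functions of one component
#'
#' Evaluates \eqn{\xi_{ik}(t, x(t,\cdot)) = \int_0^1 K_v((t, x(t,\cdot)),
#' (t', x_i(t',\cdot))) \eta_k(t') dt'} on the time grid, for training
#' subject `i` and basis index `k`, at a query covariate path `x_new`.
#'
#' @param op an [fcr_operators()] object.
#' @param v component index.
#' @param i training-subject index.
#' @param k basis index.
#' @param x_new list of `q` matrices (T x S), the query covariate surfaces;
#'   default the training surfaces of subject `i` themselves.
#' @return numeric vector: the curve \eqn{t \mapsto \xi_{ik}(t, x(t,\cdot))}.
#' @export
compute_xi <- function(op, v, i, k, x_new = NULL) {
  stopifnot(inherits(op, "fcr_operators"))
  tg <- op$t_grid; nT <- length(tg)
  rows_i <- (i - 1L) * nT + seq_len(nT)
  if (is.null(x_new)) {
    Uq <- lapply(op$U, function(U) U[rows_i, , drop = FALSE])
  } else {
    Uq <- x_new
  }
  cg <- lapply(cross_grams(op, Uq), function(G) G[, rows_i, drop = FALSE])
  tf_mats <- list(one = tfac_matrix("one", tg),
                  lin = tfac_matrix("lin", tg),
                  np  = tfac_matrix("np", tg))
  G <- component_gram_big(op$scheme$components[[v]], tf_mats, cg, 1L, 1L)
  w <- trap_weights(tg)
  as.vector(G %*% (w * op$basis$eta[, k]))
}
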