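#' Empirical functional principal components of response curves
#'
#' Computes an orthonormal (in trapezoidal \eqn{L^2[0,1]}) basis
#' \eqn{\eta_1, \dots, \eta_K} for the observed response curves, as
#' eigenfunctions of the empirical covariance operator of the *uncentered*
#' curves, together with the score matrix \eqn{\nu_{ik} = \langle y_i,
#' \eta_k\rangle}. The curves are not mean-centered: the regression function
#' absorbs the mean, and the score expansion is taken of the curves
#' themselves.
#'
#' The decomposition is computed from the n x n Gram matrix of the curves
#' (exact in the span of the data, O(n^3) regardless of grid size). The sign
#' of each eigenfunction is fixed so its largest-magnitude grid value is
#' positive.
#'
#' @param Y n x T matrix of curves on the common grid `t_grid` (one row per
#'   subject), or a long data frame with columns `subject_id`, `t`, `y`.
#' @param t_grid increasing time grid in `[0, 1]`; inferred from the data
#'   frame input.
#' @param K number of components to retain (at most the numerical rank);
#'   default all numerically nonzero ones.
#' @param fraction optionally, retain the smallest K whose eigenvalues reach
#'   this cumulative fraction of total score energy.
#' @param K_max optional hard cap on K.
#' @return object of class `fcr_efpc`: list with `eta` (T x K basis curves),
#'   `nu` (n x K scores), `values` (eigenvalues), `t_grid`, `K`, `n`.
#' @examples
#' tg <- seq(0, 1, length.out = 40)
#' Y <- rbind(sin(2 * pi * tg), cos(2 * pi * tg))
#' b <- efpc(Y, tg)
#' crossprod(b$eta, trap_weights(tg) * b$eta)  # ~ identity
#' @export
efpc <- function(Y, t_grid = NULL, K = NULL, fraction = NULL, K_max = NULL) {
  if (is.data.frame(Y)) {
    ds <- response_to_matrix(Y)
    Y <- ds$y
    if (is.null(t_grid)) t_grid <- ds$t_grid
  }
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < 1L) rlang::abort("need at least one curve.")
  if (is.null(t_grid)) rlang::abort("`t_grid` is required for matrix input.")
  if (ncol(Y) != length(t_grid)) rlang::abort("curves and `t_grid` disagree.")
  if (!is.null(K) && K > n) rlang::abort("`K` cannot exceed the number of curves.")
  w <- trap_weights(t_grid)
  G <- tcrossprod(sweep(Y, 2L, sqrt(w), "*"))
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  total <- sum(vals)
  rank <- sum(vals > max(total, .Machine$double.eps) * 1e-12)
  rank <- max(rank, 1L)
  Keff <- if (is.null(K)) rank else min(K, rank)
  if (!is.null(fraction)) {
    cum <- cumsum(vals) / max(total, .Machine$double.eps)
    Keff <- min(Keff, max(1L, which(cum >= fraction)[1L]))
  }
  if (!is.null(K_max)) Keff <- min(Keff, K_max)
  V <- e$vectors[, seq_len(Keff), drop = FALSE]
  lam <- vals[seq_len(Keff)]
  eta <- crossprod(Y, V)
  eta <- sweep(eta, 2L, sqrt(lam), "/")
  # sign convention: largest-magnitude value positive
  for (k in seq_len(Keff)) {
    m <- which.max(abs(eta[, k]))
    if (eta[m, k] < 0) eta[, k] <- -eta[, k]
  }
  nu <- Y %*% (w * eta)
  structure(
    list(eta = eta, nu = nu, values = lam, all_values = vals,
         t_grid = t_grid, K = Keff, n = n),
    class = "fcr_efpc"
  )
}

#' @method print fcr_efpc
#' @export
print.fcr_efpc <- function(x, ...) {
  cat("<fcr_efpc> ", x$K, " components from ", x$n, " curves on ",
      length(x$t_grid), " grid points\n", sep = "")
  cat("  eigenvalues: ", paste(signif(utils::head(x$values, 5), 4), collapse = ", "),
      if (x$K > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Project a curve onto an EFPC basis
#'
#' Trapezoidal inner products \eqn{\langle y, \eta_k\rangle} of a curve (or
#' rows of a matrix of curves) with each basis function.
#'
#' @param basis an [efpc()] object.
#' @param y numeric vector on the basis grid, or a matrix with one curve per
#'   row.
#' @return numeric vector of K scores (or a matrix of score rows).
#' @export
efpc_scores <- function(basis, y) {
  stopifnot(inherits(basis, "fcr_efpc"))
  w <- trap_weights(basis$t_grid)
  if (is.matrix(y)) {
    if (ncol(y) != length(basis$t_grid)) rlang::abort("grid mismatch.")
    return(y %*% (w * basis$eta))
  }
  if (length(y) != length(basis$t_grid)) rlang::abort("grid mismatch.")
  as.vector(crossprod(basis$eta, w * y))
}
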