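# predict regression-function curves for new covariate surfaces
# x_new: list of q arrays [m, T, S]; returns m x T matrix
predict_curves <- function(op, fit, x_new, w2 = NULL) {
  if (is.null(w2)) w2 <- op$scheme$w2
  tg <- op$t_grid; nT <- length(tg)
  m <- dim(x_new[[1]])[1]
  U_new <- lapply(x_new, covariate_rows)
  cg <- cross_grams(op, U_new)
  tf_mats <- list(one = tfac_matrix("one", tg),
                  lin = tfac_matrix("lin", tg),
                  np  = tfac_matrix("np", tg))
  # z[(i-1)T + t'] = sum_k w_{t'} eta_k(t') c_ik
  Ew <- trap_weights(tg) * op$basis$eta
  p <- score_perm(op$n, op$K)
  c_io <- numeric(length(fit$c)); c_io[p] <- fit$c
  z <- as.vector(Matrix::bdiag(rep(list(Matrix::Matrix(Ew)), op$n)) %*% c_io)
  kern <- rep(0, m * nT)
  for (v in seq_len(op$scheme$Q)) {
    if (fit$theta[v] != 0) {
      Gx <- component_gram_big(op$scheme$components[[v]], tf_mats, cg, m, op$n)
      kern <- kern + (fit$theta[v] / w2[v]) * as.vector(Gx %*% z)
    }
  }
  kern <- t(matrix(kern, nrow = nT, ncol = m))
  null_part <- matrix(as.vector(cbind(1, k1(tg)) %*% fit$d), m, nT,
                      byrow = TRUE)
  # The estimator lives in the score domain: the data inform the fit only
  # through projections onto the empirical score basis, so the reported
  # curve is the basis reconstruction of the predicted scores. Components
  # of the kernel sections (and of the null-space functions) orthogonal to
  # the basis are not identified by the criterion and are dropped; with an
  # untruncated basis on n >= |t-grid| subjects the reconstruction is the
  # identity. Projection preserves every score, so fitted curves reproduce
  # the fitted scores exactly.
  wq <- trap_weights(tg)
  pred <- null_part + kern
  (pred %*% (wq * op$basis$eta)) %*% t(op$basis$eta)
}

#' Fit a nonparametric functional concurrent regression
#'
#' Estimates \eqn{y_i(t) = f(t, x_i(t,\cdot)) + \epsilon_i(t)} with a
#' smoothing-spline ANOVA decomposition of `f` over a tensor-product RKHS,
#' from long-format tables. Three estimators are available: `"l1"` performs
#' budget-constrained component selection (nonnegative scales `theta`, tuned
#' by BIC or cross-validation); `"l2"` is the ridge-type estimator with all
#' components kept; `"l1l2"` refits the `"l1"`-selected components with the
#' ridge penalty.
#'
#' @param response data frame with columns `subject_id`, `t`, `y`, or an
#'   `fcr_dataset` with responses (then `covariates` is ignored).
#' @param covariates data frame with columns `subject_id`, `j`, `t`, `s`, `x`.
#' @param scheme `"full"` or `"merged"` ANOVA decomposition (see
#'   [fcr_scheme()]); the number of covariates is taken from the data.
#' @param method `"l1"`, `"l2"` or `"l1l2"`.
#' @param K,fraction,K_max empirical functional principal component
#'   truncation (see [efpc()]); the default keeps every numerically nonzero
#'   component.
#' @param tau0_grid,M_grid,lambda1_grid,lambda_grid,criterion,folds,rule,final_max_iter
#'   tuning controls (see [fit_l1()], [fit_l2()]).
#' @param seed integer seed for fold assignment.
#' @param w1,w2 penalty weights (defaults: constant unpenalized, unit
#'   component weights).
#' @param standardize z-score the response values before fitting
#'   (predictions are returned on the original scale).
#' @param tol,max_iter backfitting convergence controls.
#' @return object of class `fcr_fit`; see [predict.fcr_fit()],
#'   [tidy.fcr_fit()], [glance.fcr_fit()], [augment.fcr_fit()],
#'   [autoplot.fcr_fit()].
#' @export
fcr_fit <- function(response, covariates = NULL,
                    scheme = c("full", "merged"),
                    method = c("l1", "l2", "l1l2"),
                    K = NULL, fraction = 1, K_max = NULL,
                    tau0_grid = 1e-3, M_grid = NULL, lambda1_grid = 0,
                    lambda_grid = 10^seq(-6, 0, length.out = 7),
                    criterion = c("cv", "bic"), folds = 5L, seed = 1L,
                    rule = c("1se", "min"), w1 = c(0, 1), w2 = NULL,
                    standardize = FALSE, tol = 1e-5, max_iter = 4L,
                    final_max_iter = 12L) {
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  rule <- match.arg(rule)
  data <- if (inherits(response, "fcr_dataset")) response
          else fcr_data(response, covariates)
  if (is.null(data$y)) rlang::abort("the dataset has no response curves.")
  center <- 0; scale_ <- 1
  if (standardize) {
    center <- mean(data$y); scale_ <- stats::sd(as.vector(data$y))
    if (scale_ <= 0) scale_ <- 1
    data$y <- (data$y - center) / scale_
  }
  sch <- fcr_scheme(data$q, match.arg(scheme), w2 = w2)
  op <- fcr_operators(data, sch, K = K, fraction = fraction, K_max = K_max)
  fit <- switch(method,
    l1 = fit_l1(op, tau0_grid, M_grid, lambda1_grid,
                lambda_grid = lambda_grid, criterion = criterion,
                folds = folds, seed = seed, rule = rule, w1 = w1, tol = tol,
                max_iter = max_iter, final_max_iter = final_max_iter),
    l2 = fit_l2(op, lambda_grid = lambda_grid, criterion = criterion,
                folds = folds, seed = seed),
    l1l2 = fit_l1_l2(op, tau0_grid, M_grid, lambda1_grid,
                     lambda_grid = lambda_grid, criterion = criterion,
                     folds = folds, seed = seed, rule = rule, w1 = w1,
                     tol = tol, max_iter = max_iter,
                     final_max_iter = final_max_iter)
  )
  structure(
    list(method = method, scheme = sch, basis = op$basis, op = op, fit = fit,
         data = data, seed = seed,
         standardize = list(on = standardize, center = center, scale = scale_)),
    class = "fcr_fit"
  )
}

#' @method print fcr_fit
#' @export
print.fcr_fit <- function(x, ...) {
  cat("<fcr_fit> method = ", x$method, ", scheme = ", x$scheme$scheme_id,
      ", n = ", x$op$n, ", K = ", x$op$K, "\n", sep = "")
  sel <- x$fit$selected
  cat("  selected components (", length(sel), "/", x$scheme$Q, "): ",
      paste(x$scheme$labels[sel], collapse = ", "), "\n", sep = "")
  th <- x$fit$theta[sel]
  if (length(th)) {
    cat("  theta: ", paste(signif(th, 4), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Predict the regression function for new covariate surfaces
#'
#' Evaluates the fitted \eqn{\hat f(t, x(t,\cdot))} on the training time grid
#' for each subject in `new_data`, via the representer expansion. With
#' `new_data = NULL` the training covariates are used.
#'
#' @param object an [fcr_fit()].
#' @param new_data an `fcr_dataset`, or a covariate data frame with columns
#'   `subject_id`, `j`, `t`, `s`, `x` on the training grids.
#' @param ... unused.
#' @return tibble with columns `subject_id`, `t`, `.fitted`.
#' @export
predict.fcr_fit <- function(object, new_data = NULL, ...) {
  if (is.null(new_data)) {
    nd <- object$data
  } else if (inherits(new_data, "fcr_dataset")) {
    nd <- new_data
  } else {
    nd <- fcr_data(NULL, new_data)
  }
  if (nd$q != object$scheme$q) {
    rlang::abort("covariate count of `new_data` does not match the fitted scheme.")
  }
  if (length(nd$s_grid) != length(object$op$s_grid) ||
      any(abs(nd$s_grid - object$op$s_grid) > 1e-8)) {
    rlang::abort("`new_data` must be sampled on the training s grid.")
  }
  fhat <- predict_curves(object$op, object$fit, nd$x)
  fhat <- fhat * object$standardize$scale + object$standardize$center
  tibble::tibble(
    subject_id = rep(nd$subjects, times = length(object$op$t_grid)),
    t = rep(object$op$t_grid, each = nd$n),
    .fitted = as.vector(fhat)
  )
}

#' Tidy the component scales of a fit
#'
#' @param x an [fcr_fit()].
#' @param ... unused.
#' @return tibble with one row per penalized component: `term`, `theta`,
#'   `selected`, `w2`.
#' @method tidy fcr_fit
#' @export
tidy.fcr_fit <- function(x, ...) {
  tibble::tibble(
    term = x$scheme$labels,
    theta = x$fit$theta,
    selected = seq_len(x$scheme$Q) %in% x$fit$selected,
    w2 = x$scheme$w2
  )
}

#' One-row fit summary
#'
#' @param x an [fcr_fit()].
#' @param ... unused.
#' @return one-row tibble: sample size, score dimension, scheme, method,
#'   number of selected components, tuning values, convergence.
#' @method glance fcr_fit
#' @export
glance.fcr_fit <- function(x, ...) {
  tn <- x$fit$tuning
  tibble::tibble(
    n = x$op$n, K = x$op$K, Q = x$scheme$Q,
    scheme = x$scheme$scheme_id, method = x$method,
    n_selected = length(x$fit$selected),
    tau0 = tn$tau0 %||% NA_real_,
    M = tn$M %||% NA_real_,
    lambda = tn$lambda %||% NA_real_,
    converged = isTRUE(x$fit$converged),
    sweeps = x$fit$iters %||% NA_integer_,
    objective = x$fit$objective %||% NA_real_
  )
}

#' Training data with fitted regression curves
#'
#' @param x an [fcr_fit()].
#' @param ... unused.
#' @return tibble with `subject_id`, `t`, `y`, `.fitted`, `.resid`.
#' @method augment fcr_fit
#' @export
augment.fcr_fit <- function(x, ...) {
  pred <- predict.fcr_fit(x)
  y <- x$data$y * x$standardize$scale + x$standardize$center
  out <- dplyr::mutate(pred, y = as.vector(y), .before = ".fitted")
  dplyr::mutate(out, .resid = .data$y - .data$.fitted)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
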