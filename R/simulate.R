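# ---------------------------------------------------------------------------
# Synthetic functional data: Gaussian-process covariate surfaces and the
# three benchmark regression functions.
# ---------------------------------------------------------------------------

gp_cov_rbf <- function(s) exp(-outer(s, s, "-")^2 / 2)
gp_cov_rq  <- function(s) 1 / (1 + outer(s, s, "-")^2)

#' Zero-mean Gaussian-process paths over the s grid
#'
#' Draws `n` independent paths of a zero-mean Gaussian process on `s_grid`
#' with the squared-exponential kernel \eqn{\exp(-(s_1-s_2)^2/2)}
#' (`"rbf"`) or the rational quadratic kernel \eqn{1/(1+(s_1-s_2)^2)}
#' (`"rq"`). A 1e-10 diagonal jitter guards the Cholesky factor.
#'
#' @param n number of paths.
#' @param s_grid grid in `[0, 1]`.
#' @param kernel `"rbf"` or `"rq"`.
#' @return n x length(s_grid) matrix of paths.
#' @export
gen_gp_paths <- function(n, s_grid, kernel = c("rbf", "rq")) {
  kernel <- match.arg(kernel)
  C <- switch(kernel, rbf = gp_cov_rbf(s_grid), rq = gp_cov_rq(s_grid))
  diag(C) <- diag(C) + 1e-10
  L <- chol(C)
  matrix(rnorm(n * length(s_grid)), n, length(s_grid)) %*% L
}

#' Generate functional covariate surfaces
#'
#' Two covariate surfaces per subject:
#' \eqn{x_{ij}(t, s) = \cos(2\pi x^*_{ij}(t, s))} with
#' \eqn{x^*_{ij}(t, s) = t + g_{ij}(s)}, where \eqn{g_{ij}} is one zero-mean
#' Gaussian-process path per (subject, covariate) shared across `t`
#' (squared-exponential kernel for j = 1, rational quadratic for j = 2), so
#' that \eqn{x^*} has mean function \eqn{\mu(t) = t}. Setting
#' `independent_t = TRUE` instead draws an independent path for every time
#' point.
#'
#' @param n number of subjects.
#' @param t_grid,s_grid grids in `[0, 1]`.
#' @param independent_t draw a fresh GP path per time point (default one
#'   path per subject/covariate shared across `t`).
#' @return list of 2 arrays `[n, length(t_grid), length(s_grid)]`.
#' @export
gen_covariates <- function(n, t_grid, s_grid, independent_t = FALSE) {
  nT <- length(t_grid); nS <- length(s_grid)
  kernels <- c("rbf", "rq")
  lapply(kernels, function(kn) {
    if (independent_t) {
      g <- array(gen_gp_paths(n * nT, s_grid, kn), c(n, nT, nS))
    } else {
      g0 <- gen_gp_paths(n, s_grid, kn)             # n x S
      g <- aperm(array(g0, c(n, nS, nT)), c(1, 3, 2))
    }
    xstar <- g + rep(t_grid, each = n)              # broadcast over s
    cos(2 * pi * xstar)
  })
}

#' Benchmark regression functions
#'
#' Evaluates the true regression function on the time grid for each subject:
#' \itemize{
#' \item M1: \eqn{1 + 5\cos(2\pi t)/3} (no covariate effect); the alternative
#'   reading \eqn{1 + 5\cos^3(2\pi t)} is available via `m1_form = "cubed"`.
#' \item M2: \eqn{1 + 0.5 t + 10\int x_1^3 ds + 5\int x_2^3 ds +
#'   10 \int x_1^3 ds \int x_2^3 ds}.
#' \item M3: \eqn{1 + 5\cos(2\pi t) + 10\int x_1 x_2\, ds}.
#' }
#' Integrals over `s` are trapezoidal.
#'
#' @param model `"M1"`, `"M2"` or `"M3"`.
#' @param x list of 2 covariate arrays `[n, T, S]`.
#' @param t_grid,s_grid grids.
#' @param m1_form `"scaled"` (default) or `"cubed"`.
#' @return n x T matrix of true regression curves.
#' @export
true_f <- function(model, x, t_grid, s_grid, m1_form = c("scaled", "cubed")) {
  m1_form <- match.arg(m1_form)
  n <- dim(x[[1]])[1]; nT <- length(t_grid)
  ws <- trap_weights(s_grid)
  int_s <- function(arr) {            # [n, T, S] -> n x T
    matrix(arr, n * nT, length(s_grid)) %*% ws |> matrix(n, nT)
  }
  tc <- matrix(t_grid, n, nT, byrow = TRUE)
  switch(model,
    M1 = {
      curve <- if (m1_form == "scaled") 1 + 5 * cos(2 * pi * t_grid) / 3
               else 1 + 5 * cos(2 * pi * t_grid)^3
      matrix(curve, n, nT, byrow = TRUE)
    },
    M2 = {
      a1 <- int_s(x[[1]]^3); a2 <- int_s(x[[2]]^3)
      1 + 0.5 * tc + 10 * a1 + 5 * a2 + 10 * a1 * a2
    },
    M3 = {
      a12 <- int_s(x[[1]] * x[[2]])
      matrix(1 + 5 * cos(2 * pi * t_grid), n, nT, byrow = TRUE) + 10 * a12
    },
    rlang::abort("unknown model; use \"M1\", \"M2\" or \"M3\".")
  )
}

#' Truly active components of a benchmark model
#'
#' Indices (within a decomposition scheme) of the components that are
#' nonzero in the benchmark regression functions: the nonparametric `t` main
#' effect for M1; both covariate main effects and their nonparametric
#' interaction for M2; the nonparametric `t` main effect plus the covariate
#' interaction for M3.
#'
#' @param model `"M1"`, `"M2"` or `"M3"`.
#' @param scheme an [fcr_scheme()] with q = 2.
#' @return integer vector of component indices.
#' @export
truth_components <- function(model, scheme) {
  labs <- switch(model,
    M1 = "t_np",
    M2 = c("x1", "x2", "x1:x2"),
    M3 = c("t_np", "x1:x2"),
    rlang::abort("unknown model.")
  )
  idx <- match(labs, scheme$labels)
  if (anyNA(idx)) rlang::abort("scheme does not contain the truth components.")
  idx
}

#' Simulate a functional concurrent regression dataset
#'
#' Generates training and test sets under one of the benchmark designs:
#' Gaussian-process covariate surfaces (see [gen_covariates()]), responses
#' \eqn{y_i(t) = f(t, x_i(t,\cdot)) + \epsilon_i(t)} with
#' \eqn{\epsilon_i(t)} independent \eqn{N(0, \sigma^2)} white noise on the
#' time grid.
#'
#' @param model `"M1"`, `"M2"` or `"M3"`.
#' @param n training-set size.
#' @param nt test-set size.
#' @param sigma noise standard deviation.
#' @param t_grid,s_grid common grids (default 50 equispaced points).
#' @param seed integer seed.
#' @param m1_form,independent_t see [true_f()], [gen_covariates()].
#' @return object of class `fcr_sim`: list with `train` and `test`
#'   (`fcr_dataset`s), true curves `f_train`, `f_test`, and the
#'   configuration.
#' @export
fcr_simulate <- function(model, n, nt = 50L, sigma = 0.22,
                         t_grid = seq(0, 1, length.out = 50),
                         s_grid = seq(0, 1, length.out = 50),
                         seed = 1L, m1_form = c("scaled", "cubed"),
                         independent_t = FALSE) {
  m1_form <- match.arg(m1_form)
  if (n < 2L || nt < 1L || sigma < 0) {
    rlang::abort("need n >= 2, nt >= 1, sigma >= 0.")
  }
  set.seed(seed)
  make_set <- function(m, prefix) {
    x <- gen_covariates(m, t_grid, s_grid, independent_t)
    f <- true_f(model, x, t_grid, s_grid, m1_form)
    y <- f + sigma * matrix(rnorm(m * length(t_grid)), m, length(t_grid))
    ds <- new_fcr_dataset(y, x, t_grid, s_grid,
                          subjects = paste0(prefix, seq_len(m)))
    list(ds = ds, f = f)
  }
  tr <- make_set(n, "train_")
  te <- make_set(nt, "test_")
  structure(
    list(train = tr$ds, test = te$ds, f_train = tr$f, f_test = te$f,
         config = list(model = model, n = n, nt = nt, sigma = sigma,
                       seed = seed, m1_form = m1_form,
                       independent_t = independent_t)),
    class = "fcr_sim"
  )
}

#' @method print fcr_sim
#' @export
print.fcr_sim <- function(x, ...) {
  cfg <- x$config
  cat("<fcr_sim> model ", cfg$model, ": n = ", cfg$n, " train, ", cfg$nt,
      " test subjects, sigma = ", cfg$sigma, ", seed = ", cfg$seed, "\n",
      sep = "")
  invisible(x)
}
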