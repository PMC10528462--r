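#' Scaled Bernoulli polynomial kernels on [0, 1]
#'
#' Building blocks of the cubic-spline Sobolev space on \eqn{[0,1]} used for
#' the time argument of the regression surface: `k1(x) = x - 1/2`,
#' `k2(x) = (k1(x)^2 - 1/12 * 2) / 2` i.e. \eqn{k_2 = \tfrac12 k_1^2 - \tfrac1{12}},
#' and \eqn{k_4 = \tfrac1{24} k_1^4 - \tfrac12 k_1^2 + \tfrac7{240}}.
#' They are (up to scaling) the Bernoulli polynomials \eqn{B_1, B_2, B_4}
#' evaluated at `x`.
#'
#' @param x numeric vector, typically in `[0, 1]`.
#' @return numeric vector of the same length as `x`.
#' @examples
#' k1(0.5)      # 0
#' k2(c(0, 1))  # both 1/24
#' @export
k1 <- function(x) x - 0.5

#' @rdname k1
#' @export
k2 <- function(x) 0.5 * k1(x)^2 - 1 / 12

#' @rdname k1
#' @export
k4 <- function(x) k1(x)^4 / 24 - k1(x)^2 / 2 + 7 / 240

#' Reproducing kernel of the nonparametric part of the cubic Sobolev space
#'
#' The kernel of the subspace of the Sobolev space
#' \eqn{\{f : f, f' \mathrm{abs. cont.}, \int (f'')^2 < \infty\}} orthogonal to
#' the constant and linear functions:
#' \eqn{K(t, t') = k_2(t) k_2(t') - k_4(|t - t'|)}.
#'
#' @param t,t2 numeric vectors in `[0, 1]` (recycled to common length).
#' @return numeric vector of kernel values.
#' @examples
#' rk_sobolev(0.5, 0.5)
#' @export
rk_sobolev <- function(t, t2) k2(t) * k2(t2) - k4(abs(t - t2))

# Sobolev kernel matrix over two grids
sobolev_matrix <- function(tg, tg2 = tg) {
  outer(tg, tg2, rk_sobolev)
}

#' Gaussian kernel between square-integrable functions
#'
#' \eqn{K(u, u') = \exp(-\|u - u'\|^2 / 2)} with
#' \eqn{\|u\|^2 = \int_0^1 u^2(s)\,ds} evaluated by trapezoidal quadrature on
#' `s_grid`. The bandwidth is fixed at 1.
#'
#' @param u,u2 numeric vectors: function values on `s_grid`.
#' @param s_grid increasing grid in `[0, 1]` shared by `u` and `u2`.
#' @return scalar kernel value in `(0, 1]`.
#' @examples
#' s <- seq(0, 1, length.out = 50)
#' rk_gaussian(rep(0, 50), rep(1, 50), s)  # exp(-1/2)
#' @export
rk_gaussian <- function(u, u2, s_grid) {
  if (length(u) != length(s_grid) || length(u2) != length(s_grid)) {
    rlang::abort("`u`, `u2` and `s_grid` must have the same length (shared grid).")
  }
  w <- trap_weights(s_grid)
  exp(-sum(w * (u - u2)^2) / 2)
}

# Gaussian kernel Gram matrix between rows of U (m x S) and U2 (m2 x S),
# curves sampled on s_grid. Uses the weighted-distance expansion
# ||u-v||^2 = ||u||^2 + ||v||^2 - 2<u,v>.
gaussian_gram <- function(U, U2, s_grid) {
  w <- trap_weights(s_grid)
  Uw <- sweep(U2, 2L, w, "*")
  cross <- tcrossprod(U, Uw)
  n1 <- as.vector(U^2 %*% w)
  n2 <- as.vector(U2^2 %*% w)
  d2 <- outer(n1, n2, "+") - 2 * cross
  exp(-pmax(d2, 0) / 2)
}

# ---------------------------------------------------------------------------
# ANOVA decomposition schemes
# ---------------------------------------------------------------------------

# a component is a list of terms; each term has a t-factor in
# {"one", "lin", "np"} and an integer vector of covariate indices (possibly
# empty). Merged components carry several terms whose kernels are summed.
new_component <- function(label, terms) list(label = label, terms = terms)

component_label <- function(tfac, cov) {
  parts <- switch(tfac, one = character(0), lin = "t_lin", np = "t_np")
  paste(c(parts, paste0("x", cov)), collapse = ":")
}

#' Construct a tensor-product ANOVA decomposition scheme
#'
#' Enumerates the penalized component kernels of the smoothing-spline ANOVA
#' decomposition of \eqn{f(t, u_1, \dots, u_q)} over the tensor product of the
#' cubic Sobolev space in `t` and Gaussian-kernel spaces in each functional
#' covariate \eqn{u_j}. The unpenalized null space is spanned by
#' \eqn{\phi_1 = 1} and \eqn{\phi_2 = k_1(t)}.
#'
#' The `"full"` scheme keeps every component separate: Q = 22 components for
#' `q = 3` and Q = 10 for `q = 2`, ordered as the nonparametric `t` main
#' effect, then for each covariate-subset size the plain, linear-t, and
#' nonparametric-t products. The `"merged"` scheme (`q = 3` only, Q = 10)
#' merges each pair of t-by-covariate interactions
#' (\eqn{k_1 k_1' K_j + K^{(1)}_2 K_j}) into a single additive component and
#' keeps only plain pairwise covariate interactions.
#'
#' @param q number of functional covariates (2 or 3).
#' @param scheme `"full"` or `"merged"`.
#' @param w2 optional nonnegative component weights (default all 1).
#' @return an object of class `fcr_scheme`: list with `q`, `scheme_id`,
#'   `components`, `Q`, `labels`, `w2`.
#' @examples
#' fcr_scheme(2, "full")$Q   # 10
#' fcr_scheme(3, "full")$Q   # 22
#' @export
fcr_scheme <- function(q, scheme = c("full", "merged"), w2 = NULL) {
  scheme <- match.arg(scheme)
  if (!q %in% c(2L, 3L)) rlang::abort("`q` must be 2 or 3.")
  if (scheme == "merged" && q != 3L) {
    rlang::abort("the merged scheme is defined for q = 3 only.")
  }
  comps <- list(new_component("t_np", list(list(t = "np", cov = integer(0)))))
  subsets_by_size <- function(m) utils::combn(seq_len(q), m, simplify = FALSE)
  if (scheme == "full") {
    for (m in seq_len(q)) {
      for (tf in c("one", "lin", "np")) {
        for (sub in subsets_by_size(m)) {
          comps <- c(comps, list(new_component(
            component_label(tf, sub),
            list(list(t = tf, cov = sub))
          )))
        }
      }
    }
  } else {
    for (j in seq_len(q)) {
      comps <- c(comps, list(new_component(
        component_label("one", j),
        list(list(t = "one", cov = j))
      )))
    }
    for (j in seq_len(q)) {
      comps <- c(comps, list(new_component(
        paste0("t:x", j),
        list(list(t = "lin", cov = j), list(t = "np", cov = j))
      )))
    }
    for (sub in subsets_by_size(2L)) {
      comps <- c(comps, list(new_component(
        component_label("one", sub),
        list(list(t = "one", cov = sub))
      )))
    }
  }
  Q <- length(comps)
  if (is.null(w2)) w2 <- rep(1, Q)
  if (length(w2) != Q || any(w2 <= 0)) {
    rlang::abort("`w2` must contain Q positive weights.")
  }
  structure(
    list(
      q = as.integer(q),
      scheme_id = paste0(scheme, "_q", q),
      components = comps,
      Q = Q,
      labels = vapply(comps, `[[`, character(1), "label"),
      w2 = w2
    ),
    class = "fcr_scheme"
  )
}

#' @method print fcr_scheme
#' @export
print.fcr_scheme <- function(x, ...) {
  cat("<fcr_scheme> ", x$scheme_id, ": Q = ", x$Q,
      " penalized components, q = ", x$q, " functional covariates\n", sep = "")
  cat("  null space: {1, k1(t)}\n")
  cat("  components: ", paste(x$labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# t-factor kernel value(s); t, t2 numeric
tfac_eval <- function(tf, t, t2) {
  switch(tf,
    one = rep(1, max(length(t), length(t2))),
    lin = k1(t) * k1(t2),
    np  = rk_sobolev(t, t2),
    rlang::abort("unknown t-factor")
  )
}

tfac_matrix <- function(tf, tg, tg2 = tg) {
  switch(tf,
    one = matrix(1, length(tg), length(tg2)),
    lin = outer(k1(tg), k1(tg2)),
    np  = sobolev_matrix(tg, tg2),
    rlang::abort("unknown t-factor")
  )
}

#' Evaluate one ANOVA component kernel at a pair of points
#'
#' Evaluates \eqn{K_v((t, u), (t', u'))} for component `v` of a decomposition
#' scheme, where `u` and `u2` are lists of covariate curves sampled on
#' `s_grid`. Merged components are sums of their term kernels.
#'
#' @param scheme an [fcr_scheme()].
#' @param v component index in `1:Q`.
#' @param t,t2 time points in `[0, 1]`.
#' @param u,u2 lists of `q` numeric vectors (covariate curves on `s_grid`).
#' @param s_grid grid for the covariate argument.
#' @return scalar kernel value.
#' @export
rk_component <- function(scheme, v, t, u, t2, u2, s_grid) {
  stopifnot(inherits(scheme, "fcr_scheme"))
  if (v < 1 || v > scheme$Q) rlang::abort("component index `v` out of range.")
  val <- 0
  for (term in scheme$components[[v]]$terms) {
    x <- tfac_eval(term$t, t, t2)
    for (j in term$cov) x <- x * rk_gaussian(u[[j]], u2[[j]], s_grid)
    val <- val + x
  }
  val
}

#' Evaluate the combined kernel \eqn{K^*}
#'
#' \eqn{K^*((t,u),(t',u')) = \sum_v w_{2,v}^{-1} \theta_v K_v((t,u),(t',u'))}
#' with nonnegative component scales `theta`.
#'
#' @inheritParams rk_component
#' @param theta nonnegative vector of length Q.
#' @return scalar kernel value.
#' @export
rk_combined <- function(scheme, theta, t, u, t2, u2, s_grid) {
  stopifnot(inherits(scheme, "fcr_scheme"))
  if (length(theta) != scheme$Q || any(theta < 0)) {
    rlang::abort("`theta` must be Q nonnegative values.")
  }
  vals <- vapply(seq_len(scheme$Q), function(v) {
    if (theta[v] == 0) return(0)
    theta[v] / scheme$w2[v] * rk_component(scheme, v, t, u, t2, u2, s_grid)
  }, numeric(1))
  sum(vals)
}
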