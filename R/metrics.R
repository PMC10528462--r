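#' Root mean squared L2 prediction error over test curves
#'
#' \eqn{\mathrm{RMSE} = \sqrt{\frac{1}{n_t}\sum_i \|f_i - \hat f_i\|_{L^2[0,1]}^2}}
#' with the squared norms evaluated by trapezoidal quadrature.
#'
#' @param f_true,f_hat matrices of curves (one row per subject) on `t_grid`.
#' @param t_grid common time grid.
#' @return scalar RMSE.
#' @examples
#' tg <- seq(0, 1, length.out = 50)
#' f <- matrix(sin(2 * pi * tg), 3, 50, byrow = TRUE)
#' fcr_rmse(f, f + 1, tg)  # 1
#' @export
fcr_rmse <- function(f_true, f_hat, t_grid) {
  f_true <- as.matrix(f_true); f_hat <- as.matrix(f_hat)
  if (!all(dim(f_true) == dim(f_hat)) || ncol(f_true) != length(t_grid)) {
    rlang::abort("curve matrices and `t_grid` must agree in dimension.")
  }
  w <- trap_weights(t_grid)
  sq <- as.vector((f_true - f_hat)^2 %*% w)
  sqrt(mean(sq))
}

#' Selection accuracy of a recovered component set
#'
#' Confusion of `selected` against the true active set over all Q
#' components; nonzero components are the positives. Returns specificity
#' TN/(TN+FP), sensitivity TP/(TP+FN), and F1 = 2TP/(2TP+FN+FP). A metric
#' whose denominator counts no events (e.g. sensitivity with no positives)
#' is reported as 1 and flagged in `degenerate`.
#'
#' @param selected integer vector of selected component indices.
#' @param truth integer vector of truly active component indices.
#' @param Q total number of components.
#' @return one-row tibble: `tp`, `tn`, `fp`, `fn`, `spe`, `sen`, `f1`,
#'   `degenerate`.
#' @export
selection_metrics <- function(selected, truth, Q) {
  if (length(truth) && (min(truth) < 1 || max(truth) > Q)) {
    rlang::abort("`truth` must be a subset of 1..Q.")
  }
  all_v <- seq_len(Q)
  pos <- all_v %in% truth
  sel <- all_v %in% selected
  tp <- sum(pos & sel); fn <- sum(pos & !sel)
  fp <- sum(!pos & sel); tn <- sum(!pos & !sel)
  degenerate <- character(0)
  rate <- function(num, den, name) {
    if (den == 0) { degenerate <<- c(degenerate, name); return(1) }
    num / den
  }
  spe <- rate(tn, tn + fp, "spe")
  sen <- rate(tp, tp + fn, "sen")
  f1 <- rate(2 * tp, 2 * tp + fn + fp, "f1")
  tibble::tibble(tp = tp, tn = tn, fp = fp, fn = fn,
                 spe = spe, sen = sen, f1 = f1,
                 degenerate = paste(degenerate, collapse = ","))
}
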