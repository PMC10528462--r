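#' Read a functional dataset from long-format CSV files
#'
#' @param response_path CSV with columns `subject_id`, `t`, `y` (or `NULL`).
#' @param covariates_path CSV with columns `subject_id`, `j`, `t`, `s`, `x`.
#' @return an `fcr_dataset` (see [fcr_data()]).
#' @export
read_fcr_data <- function(response_path, covariates_path) {
  response <- if (!is.null(response_path)) {
    readr::read_csv(response_path, show_col_types = FALSE)
  }
  covariates <- readr::read_csv(covariates_path, show_col_types = FALSE)
  fcr_data(response, covariates)
}

fit_file_version <- "1.0"

#' Serialize a fitted model to JSON (and back)
#'
#' Writes everything needed to reload a fit and predict with it: component
#' scales with their labels, null-space and representer coefficients, tuning
#' values, seed, the score basis, the grids, and the training data. Numbers
#' are written at full precision, so the round trip is exact.
#'
#' @param fit an [fcr_fit()].
#' @param path file path.
#' @return `path`, invisibly; `read_fcr_fit()` returns the restored
#'   `fcr_fit`.
#' @export
write_fcr_fit <- function(fit, path) {
  stopifnot(inherits(fit, "fcr_fit"))
  obj <- list(
    version = fit_file_version,
    method = fit$method,
    scheme = list(q = fit$scheme$q, scheme_id = fit$scheme$scheme_id,
                  labels = fit$scheme$labels, w2 = fit$scheme$w2),
    t_grid = fit$op$t_grid,
    s_grid = fit$op$s_grid,
    subjects = fit$op$subjects,
    basis = list(eta = fit$basis$eta, nu = fit$basis$nu,
                 values = fit$basis$values, K = fit$basis$K),
    coef = list(c = fit$fit$c, d = fit$fit$d, theta = fit$fit$theta,
                selected = fit$fit$selected,
                converged = isTRUE(fit$fit$converged)),
    tuning = fit$fit$tuning[intersect(names(fit$fit$tuning),
                                      c("lambda1", "tau0", "M", "lambda"))],
    seed = fit$seed,
    standardize = fit$standardize,
    # name the per-covariate centering vectors so the JSON round trip keeps
    # them as a list rather than collapsing them into a matrix
    center = local({
      cc <- fit$op$center
      if (!is.null(cc$m)) names(cc$m) <- paste0("x", seq_along(cc$m))
      cc
    }),
    y = fit$data$y,
    x = lapply(fit$data$x, function(a) list(dim = dim(a), values = as.vector(a)))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fcr_fit
#' @export
read_fcr_fit <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$version, fit_file_version)) {
    rlang::abort(sprintf("fit file version %s not supported (expected %s).",
                         obj$version, fit_file_version))
  }
  sch_type <- sub("_q[0-9]+$", "", obj$scheme$scheme_id)
  scheme <- fcr_scheme(obj$scheme$q, sch_type, w2 = obj$scheme$w2)
  if (!identical(scheme$labels, obj$scheme$labels)) {
    rlang::abort("component labels in the fit file do not match the scheme.")
  }
  x <- lapply(obj$x, function(a) array(a$values, dim = a$dim))
  data <- new_fcr_dataset(as.matrix(obj$y), x, obj$t_grid, obj$s_grid,
                          subjects = obj$subjects)
  basis <- structure(
    list(eta = as.matrix(obj$basis$eta), nu = as.matrix(obj$basis$nu),
         values = obj$basis$values, t_grid = obj$t_grid,
         K = obj$basis$K, n = data$n),
    class = "fcr_efpc"
  )
  center <- obj$center
  if (is.null(center)) center <- list(on = FALSE)
  op <- structure(
    list(Y = as.vector(basis$nu), T = compute_T(basis, data$n), Sigma = NULL,
         n = data$n, K = basis$K, Q = scheme$Q, scheme = scheme,
         basis = basis, t_grid = obj$t_grid, s_grid = obj$s_grid,
         U = lapply(x, covariate_rows), subjects = obj$subjects,
         center = center),
    class = "fcr_operators"
  )
  fit <- list(c = obj$coef$c, d = obj$coef$d, theta = obj$coef$theta,
              selected = as.integer(obj$coef$selected),
              converged = obj$coef$converged, trace = numeric(0),
              iters = NA_integer_, objective = NA_real_,
              tuning = obj$tuning)
  structure(
    list(method = obj$method, scheme = scheme, basis = basis, op = op,
         fit = fit, data = data, seed = obj$seed,
         standardize = obj$standardize),
    class = "fcr_fit"
  )
}
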