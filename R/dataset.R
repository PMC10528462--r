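# internal constructor: y n x T matrix (or NULL), x list of q arrays [n, T, S]
new_fcr_dataset <- function(y, x, t_grid, s_grid, subjects = NULL) {
  n <- if (!is.null(y)) nrow(y) else dim(x[[1]])[1]
  if (is.null(subjects)) subjects <- as.character(seq_len(n))
  structure(
    list(y = y, x = x, t_grid = t_grid, s_grid = s_grid,
         subjects = subjects, n = n, q = length(x)),
    class = "fcr_dataset"
  )
}

#' @method print fcr_dataset
#' @export
print.fcr_dataset <- function(x, ...) {
  cat("<fcr_dataset> ", x$n, " subjects, ", x$q, " functional covariates\n",
      sep = "")
  cat("  t grid: ", length(x$t_grid), " points; s grid: ",
      length(x$s_grid), " points; response: ",
      if (is.null(x$y)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

response_to_matrix <- function(response) {
  req <- c("subject_id", "t", "y")
  if (!all(req %in% names(response))) {
    rlang::abort("response table needs columns subject_id, t, y.")
  }
  if (!is.numeric(response$t) || !is.numeric(response$y)) {
    rlang::abort("response columns `t` and `y` must be numeric.")
  }
  t_grid <- sort(unique(response$t))
  subjects <- unique(as.character(response$subject_id))
  y <- matrix(NA_real_, length(subjects), length(t_grid),
              dimnames = list(subjects, NULL))
  ti <- match(response$t, t_grid)
  si <- match(as.character(response$subject_id), subjects)
  y[cbind(si, ti)] <- response$y
  if (anyNA(y)) {
    bad <- which(is.na(y), arr.ind = TRUE)[1L, ]
    rlang::abort(sprintf(
      "missing response value for subject %s at t = %g.",
      subjects[bad[1L]], t_grid[bad[2L]]
    ))
  }
  list(y = y, t_grid = t_grid, subjects = subjects)
}

#' Assemble a functional dataset from long-format tables
#'
#' Builds the internal container for a functional concurrent regression
#' dataset from two long-format data frames: a response table with columns
#' `subject_id`, `t`, `y`, and a covariate table with columns `subject_id`,
#' `j` (covariate index), `t`, `s`, `x` holding the covariate surfaces
#' \eqn{x_{ij}(t, s)}. Grids are inferred as the sorted unique values and
#' must be complete for every subject; row order is irrelevant.
#'
#' @param response data frame with columns `subject_id`, `t`, `y`, or `NULL`
#'   for a covariate-only dataset (prediction input).
#' @param covariates data frame with columns `subject_id`, `j`, `t`, `s`, `x`.
#' @return object of class `fcr_dataset`.
#' @export
fcr_data <- function(response, covariates) {
  req <- c("subject_id", "j", "t", "s", "x")
  if (!all(req %in% names(covariates))) {
    rlang::abort("covariate table needs columns subject_id, j, t, s, x.")
  }
  for (col in c("j", "t", "s", "x")) {
    if (!is.numeric(covariates[[col]])) {
      rlang::abort(sprintf("covariate column `%s` must be numeric.", col))
    }
  }
  t_grid <- sort(unique(covariates$t))
  s_grid <- sort(unique(covariates$s))
  js <- sort(unique(covariates$j))
  if (!identical(as.integer(js), seq_along(js))) {
    rlang::abort("covariate indices `j` must be 1, 2, ... with no gaps.")
  }
  subjects <- unique(as.character(covariates$subject_id))

  resp <- NULL
  if (!is.null(response)) {
    resp <- response_to_matrix(response)
    if (!isTRUE(all.equal(resp$t_grid, t_grid))) {
      rlang::abort("response and covariate tables use different t grids.")
    }
    if (!setequal(resp$subjects, subjects)) {
      rlang::abort("response and covariate tables cover different subjects.")
    }
    subjects <- resp$subjects
  }

  nT <- length(t_grid); nS <- length(s_grid); n <- length(subjects)
  x <- vector("list", length(js))
  si <- match(as.character(covariates$subject_id), subjects)
  ti <- match(covariates$t, t_grid)
  ssi <- match(covariates$s, s_grid)
  for (j in seq_along(js)) {
    arr <- array(NA_real_, c(n, nT, nS))
    rows <- which(covariates$j == js[j])
    arr[cbind(si[rows], ti[rows], ssi[rows])] <- covariates$x[rows]
    if (anyNA(arr)) {
      bad <- which(is.na(arr), arr.ind = TRUE)[1L, ]
      rlang::abort(sprintf(
        "missing covariate value for subject %s, covariate %d, t = %g, s = %g.",
        subjects[bad[1L]], j, t_grid[bad[2L]], s_grid[bad[3L]]
      ))
    }
    x[[j]] <- arr
  }
  new_fcr_dataset(resp$y, x, t_grid, s_grid, subjects)
}

#' Long-format tables from a functional dataset
#'
#' Inverse of [fcr_data()]: returns the response and covariate tables as
#' tibbles.
#'
#' @param data an `fcr_dataset`.
#' @return list with tibbles `response` (possibly `NULL`) and `covariates`.
#' @export
fcr_tables <- function(data) {
  stopifnot(inherits(data, "fcr_dataset"))
  response <- NULL
  if (!is.null(data$y)) {
    response <- tibble::tibble(
      subject_id = rep(data$subjects, times = length(data$t_grid)),
      t = rep(data$t_grid, each = data$n),
      y = as.vector(data$y)
    )
  }
  cov_one <- function(j) {
    arr <- data$x[[j]]
    tibble::tibble(
      subject_id = rep(data$subjects, times = length(data$t_grid) * length(data$s_grid)),
      j = j,
      t = rep(rep(data$t_grid, each = data$n), times = length(data$s_grid)),
      s = rep(data$s_grid, each = data$n * length(data$t_grid)),
      x = as.vector(arr)
    )
  }
  covariates <- dplyr::bind_rows(lapply(seq_len(data$q), cov_one))
  list(response = response, covariates = covariates)
}
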