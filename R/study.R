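# fit all requested estimators for one simulated replicate
run_one_rep <- function(model, n, sigma, rep_id, rep_seed, methods, p) {
  sim <- fcr_simulate(model, n, nt = p$nt, sigma = sigma,
                      t_grid = p$t_grid, s_grid = p$s_grid,
                      seed = rep_seed, m1_form = p$m1_form)
  sch <- fcr_scheme(2L, p$scheme)
  op <- fcr_operators(sim$train, sch, fraction = p$fraction, K_max = p$K_max)
  truth <- truth_components(model, sch)
  out <- list()
  add_row <- function(method, fit, sel_metrics) {
    rmse <- NA_real_
    if (isTRUE(p$compute_rmse)) {
      fhat <- predict_curves(op, fit, sim$test$x)
      rmse <- fcr_rmse(sim$f_test, fhat, p$t_grid)
    }
    row <- tibble::tibble(
      model = model, n = n, sigma = sigma, rep = rep_id, seed = rep_seed,
      method = method, rmse = rmse,
      n_selected = length(fit$selected),
      selected = paste(sch$labels[fit$selected], collapse = ";"),
      K = op$K
    )
    if (!is.null(sel_metrics)) {
      row <- dplyr::bind_cols(row, sel_metrics[, c("spe", "sen", "f1")])
    } else {
      row$spe <- NA_real_; row$sen <- NA_real_; row$f1 <- NA_real_
    }
    out[[length(out) + 1L]] <<- row
  }
  l1fit <- NULL
  if (any(c("l1", "l1l2") %in% methods)) {
    l1fit <- fit_l1(op, tau0_grid = p$tau0_grid, M_grid = p$M_grid,
                    criterion = p$criterion, folds = p$folds, seed = rep_seed,
                    rule = p$rule, max_iter = p$max_iter,
                    final_max_iter = p$final_max_iter)
  }
  if ("l1" %in% methods) {
    add_row("l1", l1fit, selection_metrics(l1fit$selected, truth, sch$Q))
  }
  if ("l2" %in% methods) {
    # ridge over all components; penalty level by BIC on the score smoother
    add_row("l2", fit_l2(op, lambda_grid = p$lambda_grid, criterion = "bic",
                         folds = p$folds, seed = rep_seed), NULL)
  }
  if ("l1l2" %in% methods) {
    refit <- fit_l2(op, lambda_grid = p$lambda_grid, criterion = "bic",
                    selected = l1fit$selected, folds = p$folds,
                    seed = rep_seed)
    add_row("l1l2", refit, NULL)
  }
  dplyr::bind_rows(out)
}

#' Simulation study of the three estimators
#'
#' Replicates the benchmark designs over a grid of (model, n, sigma) cells:
#' for each replicate it simulates training and test data
#' ([fcr_simulate()]), fits the requested estimators, and records test-set
#' RMSE ([fcr_rmse()]) for every method plus selection accuracy
#' ([selection_metrics()]) for the selection estimator. Replicate seeds are
#' derived from `seed`, so cells and methods are paired across the same
#' simulated data.
#'
#' @param cells data frame with columns `model`, `n`, `sigma`, one row per
#'   design cell; default the full crossing of `models`, `n`, `sigma`.
#' @param models,n,sigma used to build `cells` when it is `NULL`.
#' @param reps replicates per cell.
#' @param methods subset of `c("l1", "l2", "l1l2")`.
#' @param nt test-set size.
#' @param t_points,s_points number of equispaced grid points.
#' @param seed master seed; all replicate seeds derive from it.
#' @param scheme,fraction,K_max,tau0_grid,M_grid,criterion,folds,rule,lambda_grid,max_iter,final_max_iter
#'   estimation controls (see [fcr_fit()] and [fit_l1()]).
#' @param m1_form reading of the M1 regression function (see [true_f()]).
#' @param compute_rmse evaluate test-set prediction error (skip for
#'   selection-accuracy-only runs).
#' @param out_dir optional directory; writes `audit.csv` (per-replicate
#'   rows), `table1.csv` (RMSE summary), `table2.csv` (selection summary)
#'   and `config.json`.
#' @return object of class `fcr_study`: list with per-replicate `results`,
#'   cell-level `summary`, and the `config`.
#' @export
fcr_study <- function(cells = NULL, models = c("M1", "M2", "M3"),
                      n = c(20L, 40L, 80L), sigma = c(0.22, 0.5),
                      reps = 50L, methods = c("l1", "l2", "l1l2"),
                      nt = 50L, t_points = 21L, s_points = 21L, seed = 1L,
                      scheme = "full", fraction = 1, K_max = 10L,
                      tau0_grid = 1e-3, M_grid = NULL,
                      criterion = "cv", folds = 5L, rule = "1se",
                      lambda_grid = 10^seq(-6, 0, length.out = 7),
                      max_iter = 3L, final_max_iter = 12L,
                      m1_form = "scaled", compute_rmse = TRUE,
                      out_dir = NULL) {
  if (is.null(cells)) {
    cells <- tidyr::expand_grid(model = models, n = n, sigma = sigma)
  }
  cells <- tibble::as_tibble(cells)
  stopifnot(all(c("model", "n", "sigma") %in% names(cells)), reps >= 1)
  p <- list(nt = nt, t_grid = seq(0, 1, length.out = t_points),
            s_grid = seq(0, 1, length.out = s_points),
            scheme = scheme, fraction = fraction, K_max = K_max,
            tau0_grid = tau0_grid, M_grid = M_grid, criterion = criterion,
            folds = folds, rule = rule, lambda_grid = lambda_grid,
            max_iter = max_iter, final_max_iter = final_max_iter,
            m1_form = m1_form, compute_rmse = compute_rmse)
  set.seed(seed)
  # one seed per replicate, shared across cells, so comparisons between
  # cells (sample size, noise level) are paired over common seeds
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  rows <- list()
  failures <- 0L
  for (ci in seq_len(nrow(cells))) {
    for (r in seq_len(reps)) {
      res <- tryCatch(
        run_one_rep(cells$model[ci], cells$n[ci], cells$sigma[ci],
                    r, rep_seeds[r], methods, p),
        error = function(e) {
          warning(sprintf("replicate %d of cell %d failed: %s",
                          r, ci, conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (is.null(res)) failures <- failures + 1L else {
        rows[[length(rows) + 1L]] <- res
      }
    }
  }
  results <- dplyr::bind_rows(rows)
  summary <- summarize_study(results)
  config <- c(p[c("nt", "scheme", "fraction", "K_max", "tau0_grid",
                  "criterion", "folds", "rule", "m1_form")],
              list(t_points = t_points, s_points = s_points, reps = reps,
                   seed = seed, methods = methods, n_failed = failures))
  out <- structure(list(results = results, summary = summary,
                        config = config),
                   class = "fcr_study")
  if (!is.null(out_dir)) write_study(out, out_dir)
  out
}

summarize_study <- function(results) {
  if (!nrow(results)) return(tibble::tibble())
  results |>
    dplyr::group_by(.data$model, .data$n, .data$sigma, .data$method) |>
    dplyr::summarise(
      reps = dplyr::n(),
      mean_rmse = mean(.data$rmse), sd_rmse = stats::sd(.data$rmse),
      mean_spe = mean(.data$spe), sd_spe = stats::sd(.data$spe),
      mean_sen = mean(.data$sen), sd_sen = stats::sd(.data$sen),
      mean_f1 = mean(.data$f1), sd_f1 = stats::sd(.data$f1),
      .groups = "drop"
    )
}

write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(study$results, file.path(out_dir, "audit.csv"))
  tab1 <- study$summary |>
    dplyr::select("model", "n", "sigma", "method", "mean_rmse", "sd_rmse")
  readr::write_csv(tab1, file.path(out_dir, "table1.csv"))
  tab2 <- study$summary |>
    dplyr::filter(.data$method == "l1") |>
    dplyr::select("model", "n", "sigma", "mean_spe", "sd_spe",
                  "mean_sen", "sd_sen", "mean_f1", "sd_f1")
  readr::write_csv(tab2, file.path(out_dir, "table2.csv"))
  jsonlite::write_json(study$config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @method print fcr_study
#' @export
print.fcr_study <- function(x, ...) {
  cat("<fcr_study> ", nrow(x$results), " replicate fits over ",
      nrow(dplyr::distinct(x$results, .data$model, .data$n, .data$sigma)),
      " design cells\n", sep = "")
  print(x$summary, n = 20)
  invisible(x)
}

#' @method tidy fcr_study
#' @export
tidy.fcr_study <- function(x, ...) x$summary

#' @method glance fcr_study
#' @export
glance.fcr_study <- function(x, ...) {
  tibble::tibble(
    cells = nrow(dplyr::distinct(x$results, .data$model, .data$n, .data$sigma)),
    reps = x$config$reps,
    methods = paste(x$config$methods, collapse = ","),
    n_failed = x$config$n_failed
  )
}
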