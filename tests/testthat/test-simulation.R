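test_that("covariate surfaces are cosines of a unit-mean-slope Gaussian process", {
  tg <- seq(0, 1, length.out = 7); sg <- seq(0, 1, length.out = 9)
  set.seed(61)
  x <- gen_covariates(5, tg, sg)
  expect_length(x, 2L)
  expect_equal(dim(x[[1]]), c(5L, 7L, 9L))
  expect_true(all(abs(unlist(x)) <= 1))
  # determinism through the caller's seed
  set.seed(61)
  x2 <- gen_covariates(5, tg, sg)
  expect_identical(x, x2)
})

test_that("GP paths have the stated mean and covariance (Monte Carlo)", {
  sg <- seq(0, 1, length.out = 15)
  nmc <- 2000
  for (kn in c("rbf", "rq")) {
    set.seed(62)
    g <- gen_gp_paths(nmc, sg, kn)
    # zero mean within 3 standard errors, so x*(t, s) = t + g(s) has mean t
    se <- apply(g, 2, sd) / sqrt(nmc)
    expect_true(all(abs(colMeans(g)) <= 3 * se))
    # covariance at fixed point pairs matches the kernel within 3 SE
    C_true <- switch(kn, rbf = fcrsel:::gp_cov_rbf(sg),
                     rq = fcrsel:::gp_cov_rq(sg))
    for (pair in list(c(1, 8), c(3, 12), c(5, 5))) {
      a <- pair[1]; b <- pair[2]
      chat <- mean(g[, a] * g[, b])
      se_c <- sd(g[, a] * g[, b]) / sqrt(nmc)
      expect_lt(abs(chat - C_true[a, b]), 3 * se_c + 1e-12)
    }
  }
})

test_that("benchmark regression functions match hand evaluations", {
  tg <- seq(0, 1, length.out = 11); sg <- seq(0, 1, length.out = 13)
  ones <- array(1, c(2, 11, 13)); zeros <- array(0, c(2, 11, 13))
  tc <- matrix(tg, 2, 11, byrow = TRUE)
  # M2 with x1 = x2 = 1: 1 + 0.5 t + 10 + 5 + 10
  expect_equal(true_f("M2", list(ones, ones), tg, sg), 26 + 0.5 * tc)
  # M2 with x2 = 0: the x2 terms vanish
  set.seed(63)
  x1 <- array(runif(2 * 11 * 13, -1, 1), c(2, 11, 13))
  a1 <- matrix(apply(x1^3, c(1, 2), function(v) {
    sum(fcrsel:::trap_weights(sg) * v)
  }), 2, 11)
  expect_equal(true_f("M2", list(x1, zeros), tg, sg), 1 + 0.5 * tc + 10 * a1)
  # M3 with x1 = 0: the interaction vanishes
  expect_equal(true_f("M3", list(zeros, ones), tg, sg),
               matrix(1 + 5 * cos(2 * pi * tg), 2, 11, byrow = TRUE))
  # M1 has no covariate effect, in either reading of the formula
  expect_equal(true_f("M1", list(x1, ones), tg, sg),
               matrix(1 + 5 * cos(2 * pi * tg) / 3, 2, 11, byrow = TRUE))
  expect_equal(true_f("M1", list(x1, ones), tg, sg, m1_form = "cubed"),
               matrix(1 + 5 * cos(2 * pi * tg)^3, 2, 11, byrow = TRUE))
  expect_error(true_f("M9", list(x1, ones), tg, sg), "unknown model")
})

test_that("simulated responses are the truth plus white noise of the stated level", {
  sim0 <- fcr_simulate("M2", n = 4, nt = 2, sigma = 0,
                       t_grid = seq(0, 1, length.out = 9),
                       s_grid = seq(0, 1, length.out = 9), seed = 64)
  expect_equal(sim0$train$y, sim0$f_train)
  sim <- fcr_simulate("M1", n = 300, nt = 1, sigma = 0.22,
                      t_grid = seq(0, 1, length.out = 21),
                      s_grid = seq(0, 1, length.out = 9), seed = 65)
  noise <- sim$train$y - sim$f_train
  expect_lt(abs(var(as.vector(noise)) / 0.22^2 - 1), 0.05)
  # same seed reproduces the dataset exactly
  sim2 <- fcr_simulate("M1", n = 300, nt = 1, sigma = 0.22,
                       t_grid = seq(0, 1, length.out = 21),
                       s_grid = seq(0, 1, length.out = 9), seed = 65)
  expect_identical(sim$train$y, sim2$train$y)
  expect_error(fcr_simulate("M1", n = 1), "n >= 2")
})

test_that("RMSE is the root mean squared L2 distance over test subjects", {
  tg <- seq(0, 1, length.out = 50)
  f <- matrix(rnorm(3 * 50), 3, 50)
  expect_equal(fcr_rmse(f, f, tg), 0)
  expect_equal(fcr_rmse(f, f + 1, tg), 1)
  e <- matrix(rnorm(3 * 50), 3, 50)
  expect_equal(fcr_rmse(f, f + 2 * e, tg), 2 * fcr_rmse(f, f + e, tg))
  expect_error(fcr_rmse(f, f[, -1], tg), "dimension")
})

test_that("selection metrics follow the confusion-count formulas", {
  perfect <- selection_metrics(c(1, 8), c(1, 8), 10)
  expect_equal(c(perfect$spe, perfect$sen, perfect$f1), c(1, 1, 1))
  # TP = 2, FN = 1, FP = 1, TN = 6
  m <- selection_metrics(c(1, 2, 4), c(1, 2, 3), 10)
  expect_equal(c(m$tp, m$fn, m$fp, m$tn), c(2, 1, 1, 6))
  expect_equal(m$sen, 2 / 3)
  expect_equal(m$spe, 6 / 7)
  expect_equal(m$f1, 2 * 2 / (4 + 1 + 1))
  # nothing selected: zero sensitivity
  expect_equal(selection_metrics(integer(0), c(1, 2), 10)$sen, 0)
  # no positives at all: sensitivity degenerates to 1 and is flagged
  d <- selection_metrics(integer(0), integer(0), 10)
  expect_equal(d$sen, 1)
  expect_match(d$degenerate, "sen")
  expect_error(selection_metrics(1, 11, 10), "subset")
})

test_that("truth sets map models to the right components of the q = 2 scheme", {
  sch <- fcr_scheme(2)
  expect_equal(sch$labels[truth_components("M1", sch)], "t_np")
  expect_setequal(sch$labels[truth_components("M2", sch)],
                  c("x1", "x2", "x1:x2"))
  expect_setequal(sch$labels[truth_components("M3", sch)],
                  c("t_np", "x1:x2"))
})

test_that("study harness bookkeeping: audit rows, summaries, paired seeds", {
  cells <- tibble::tibble(model = c("M2", "M2"), n = c(8L, 8L),
                          sigma = c(0.22, 0.5))
  st <- fcr_study(cells = cells, reps = 2, methods = "l1", nt = 3,
                  t_points = 9, s_points = 9, seed = 99, K_max = 4,
                  M_grid = c(0.5, 2), folds = 2)
  expect_s3_class(st$results, "tbl_df")
  expect_equal(nrow(st$results), 4L)
  # replicate seeds are shared across cells (paired comparisons)
  seeds1 <- st$results$seed[st$results$sigma == 0.22]
  seeds2 <- st$results$seed[st$results$sigma == 0.5]
  expect_identical(sort(seeds1), sort(seeds2))
  # summary means equal the means of the stored per-replicate values
  s22 <- st$summary[st$summary$sigma == 0.22, ]
  expect_equal(s22$mean_rmse,
               mean(st$results$rmse[st$results$sigma == 0.22]))
  # a single replicate yields an NA standard deviation
  st1 <- fcr_study(cells = cells[1, ], reps = 1, methods = "l1", nt = 2,
                   t_points = 9, s_points = 9, seed = 100, K_max = 4,
                   M_grid = 1, folds = 2)
  expect_true(is.na(st1$summary$sd_rmse))
  # study outputs are written as plain tables plus a config echo
  out <- file.path(tempdir(), "study-out")
  fcr_study(cells = cells[1, ], reps = 1, methods = "l1", nt = 2,
            t_points = 9, s_points = 9, seed = 100, K_max = 4,
            M_grid = 1, folds = 2, out_dir = out)
  expect_true(all(file.exists(file.path(out,
    c("audit.csv", "table1.csv", "table2.csv", "config.json")))))
})
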