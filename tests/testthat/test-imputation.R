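test_that("intersect_genes restricts both matrices to shared genes in order", {
  a <- make_expr(matrix(1:6, 3, 2), genes = c("A", "B", "C"))
  b <- make_expr(matrix(7:12, 3, 2), genes = c("B", "C", "D"),
                 samples = c("t1", "t2"))
  out <- intersect_genes(a, b)
  expect_equal(rownames(out$train), c("B", "C"))
  expect_identical(rownames(out$train), rownames(out$test))

  # identical gene lists: unchanged
  out2 <- intersect_genes(a, make_expr(matrix(0, 3, 2), genes = c("A", "B", "C")))
  expect_identical(unclass(out2$train), unclass(a))

  # shuffled test order comes back in training order
  b2 <- make_expr(matrix(7:12, 3, 2), genes = c("D", "C", "B"))
  out3 <- intersect_genes(a, b2)
  expect_identical(rownames(out3$test), c("B", "C"))

  expect_error(intersect_genes(a, make_expr(matrix(1:2, 1, 2), genes = "A")),
               "fewer than 2 shared")
})

test_that("homogenize equalizes sorted sample vectors (pooled QN)", {
  # definitional 2-sample worked example
  tr <- make_expr(matrix(c(2, 4, 6), 3, 1), samples = "A")
  te <- make_expr(matrix(c(3, 5, 7), 3, 1), samples = "B")
  out <- homogenize(tr, te)
  expect_equal(unname(unclass(out$train)[, 1]), c(2.5, 4.5, 6.5))
  expect_equal(unname(unclass(out$test)[, 1]), c(2.5, 4.5, 6.5))

  # defining property + fixed point on random input
  tr <- random_expr(30, 5, seed = 1)
  te <- random_expr(30, 4, seed = 2)
  rownames(te) <- rownames(tr)
  out <- homogenize(tr, te)
  pooled <- cbind(unclass(out$train), unclass(out$test))
  sorted <- apply(pooled, 2, sort)
  for (j in 2:ncol(sorted)) expect_equal(sorted[, j], sorted[, 1])
  again <- homogenize(out$train, out$test)
  expect_equal(unclass(again$train), unclass(out$train), tolerance = 1e-12)

  # already-common sorted vector is untouched
  same <- make_expr(matrix(c(1, 2, 3, 3, 1, 2), 3, 2))
  out2 <- homogenize(same, same)
  expect_equal(unclass(out2$train), unclass(same))

  # zero-variance sample is named in the error
  flat <- make_expr(cbind(s1 = c(1, 1, 1), s2 = c(1, 2, 3)))
  expect_error(homogenize(flat, te[1:3, ]), "s1")
})

test_that("variance filter keeps top-variance genes, ties by gene id", {
  x <- make_expr(rbind(a = c(0, 0, 0), b = c(0, 1, 2), c = c(0, 2, 4),
                       d = c(0, 3, 6)))
  expect_identical(filter_low_variance(x, 1), x)
  kept <- filter_low_variance(x, 0.5)
  expect_equal(rownames(kept), c("c", "d"))
  # exact tie: genes y and z identical variance, lexicographically y wins
  ty <- make_expr(rbind(z = c(0, 1), y = c(1, 2), a = c(0, 5)))
  expect_equal(rownames(filter_low_variance(ty, 2 / 3)), c("y", "a"))
  expect_error(filter_low_variance(x, 0))
})

test_that("ridge matches the closed-form oracle on the 1-feature example", {
  # x = (-1, 0, 1), y = (1, 2, 3), lambda = 1: slope 2/3, intercept 2
  ex <- make_expr(matrix(c(-1, 0, 1), 1, 3), genes = "g1")
  cfg <- run_config(ridge_penalty_grid = 1)
  m <- fit_ridge(ex, c(1, 2, 3), cfg, drug_id = "toy")
  expect_equal(unname(m$coefficients), 2 / 3, tolerance = 1e-12)
  expect_equal(m$intercept, 2)
  expect_equal(m$penalty, 1)
  # fitted value at the middle training point (x = 0) is the intercept
  expect_equal(unname(predict_ic50(m, ex))[2], 2)
  # prediction at a new sample with x = 2
  new <- make_expr(matrix(2, 1, 1), genes = "g1", samples = "new")
  expect_equal(unname(predict_ic50(m, new)), 2 + 2 / 3 * 2)
})

test_that("ridge equals direct standardized normal-equation solves", {
  for (i in 1:10) {
    set.seed(100 + i)
    n <- sample(5:15, 1)
    p <- sample(2:20, 1)
    lam <- 10^runif(1, -2, 2)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    ex <- make_expr(t(X))
    m <- fit_ridge(ex, y, run_config(ridge_penalty_grid = lam))
    o <- oracle_ridge(X, y, lam)
    expect_equal(unname(m$coefficients), o$beta, tolerance = 1e-8)
    expect_equal(unname(predict_ic50(m, ex)), o$fitted, tolerance = 1e-8)
  }
})

test_that("ridge limits: OLS at lambda 0, training mean at huge lambda", {
  set.seed(7)
  n <- 12; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  y <- rnorm(n)
  ex <- make_expr(t(X))
  m0 <- fit_ridge(ex, y, run_config(ridge_penalty_grid = 0))
  ols <- lm(y ~ scale(X))
  expect_equal(unname(m0$coefficients), unname(coef(ols)[-1]), tolerance = 1e-8)
  mBig <- fit_ridge(ex, y, run_config(ridge_penalty_grid = 1e8))
  expect_lt(max(abs(predict_ic50(mBig, ex) - mean(y))), 1e-3)
})

test_that("shrinkage is monotone in lambda and CV breaks ties toward less", {
  set.seed(11)
  X <- matrix(rnorm(30 * 10), 30, 10)
  y <- X[, 1] + rnorm(30, sd = 0.5)
  ex <- make_expr(t(X))
  grid <- 10^seq(-2, 3, length.out = 6)
  norms <- sapply(grid, function(l)
    sqrt(sum(fit_ridge(ex, y, run_config(ridge_penalty_grid = l))$coefficients^2)))
  expect_true(all(diff(norms) <= 1e-10))
  m <- fit_ridge(ex, y, run_config(ridge_penalty_grid = grid, cv_folds = 5))
  expect_true(m$penalty %in% grid)
  expect_true(abs(m$training_summary$cv_correlation) <= 1)
})

test_that("degenerate responses are handled as documented", {
  ex <- random_expr(5, 8, seed = 3)
  expect_warning(m <- fit_ridge(ex, rep(4, 8), run_config()), "constant")
  expect_equal(unname(predict_ic50(m, ex)), rep(4, 8))
  expect_error(fit_ridge(ex, rnorm(8), run_config(cv_folds = 10)), "folds")
  # missing model gene in cohort
  full <- fit_ridge(ex, rnorm(8), run_config(ridge_penalty_grid = 1))
  expect_error(predict_ic50(full, ex[1:3, ]), "missing model genes")
})

test_that("impute_all is deterministic, shaped per cohort and permutation-safe", {
  params <- synthetic_truth_params(n_candidates = 2,
                                   platform_effects = default_platform_effects(1))
  panel <- generate_cell_line_panel(40, 100, 5, params, seed = 5)
  tum <- generate_tumor_cohorts(15, truth = panel$truth, seed = 6)
  cfg <- run_config(seed = 2, cv_folds = 5)
  co <- tum$cohorts[[1]]
  p1 <- suppressMessages(impute_all(panel$expression, panel$response,
                                    list(co, co), cfg))
  expect_equal(unclass(p1[[1]]), unclass(p1[[2]]))
  expect_equal(ncol(p1[[1]]), 5)
  expect_equal(rownames(p1[[1]]), colnames(co))
  # permuting cohort sample order permutes predictions identically
  perm <- sample(ncol(co))
  co2 <- as_expr_perm <- expression_matrix(unclass(co)[, perm], platform(co))
  p2 <- suppressMessages(impute_all(panel$expression, panel$response,
                                    list(co2), cfg))[[1]]
  expect_equal(bare(p2), bare(p1[[1]])[colnames(co2), ], tolerance = 1e-10)
})

test_that("imputation recovers planted signal on held-out tumors", {
  panel <- generate_cell_line_panel(150, 400, 8, seed = 9)
  tum <- generate_tumor_cohorts(120, truth = panel$truth, seed = 10)
  cfg <- run_config(seed = 3, cv_folds = 5)
  preds <- suppressMessages(impute_all(panel$expression, panel$response,
                                       tum$cohorts, cfg))
  # predicted cisplatin IC50 tracks the true resistance activity
  ct <- cor.test(unclass(preds[[1]])[, "cisplatin"], tum$true_soc_resistance)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})
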