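test_that("min-max normalization maps columns to [0,1] and is idempotent", {
  m <- matrix(c(2, 4, 6, 5, 5, 5), ncol = 2)
  expect_warning(norm <- minmax_normalize(m), "constant")
  expect_equal(norm[, 1], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(norm[, 2], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(attr(norm, "constant_features"), "2")

  ft <- feature_table(matrix(runif(40, 1, 9), 10, 4))
  n1 <- minmax_normalize(ft)
  n2 <- minmax_normalize(n1)
  expect_equal(n1$abundance, n2$abundance)
  expect_true(all(apply(n1$abundance, 2, min) == 0))
  expect_true(all(apply(n1$abundance, 2, max) == 1))
})

test_that("model_error and r_squared follow their definitions", {
  expect_equal(model_error(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(model_error(c(0, 1), c(1, 0)), 1)
  expect_equal(model_error(c(0.2, 0.4), c(0.3, 0.3)), 0.1)
  expect_error(model_error(1:3, 1:2), "equal")

  obs <- c(0, 1, 2)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  expect_equal(r_squared(obs, c(0, 1, 3)), 0.5)
  expect_error(r_squared(c(1, 1), c(1, 2)), "variance")
})

test_that("joint fits recover generating parameters from clean data", {
  set.seed(42)
  X <- matrix(runif(60, 0.05, 1), 20, 3)
  cs <- cassette_assignment(rep(1, 3))
  truth <- joint_model_params(c(0.8, 1.5, 0.6), 2)
  y <- olmstead_predict(X, truth, cs)
  fit <- fit_joint_model(X, y, cs, model = "olmstead", seed = 3)
  expect_lt(fit$test_rmse, 1e-3)
  expect_equal(fit$params$ec50, truth$ec50, tolerance = 0.15)

  # degenerate to a single-chemical Hill fit under CA
  hp <- hill_params(0.5, 1.8)
  x1 <- matrix(seq(0.05, 1, length.out = 20), ncol = 1)
  fit1 <- fit_joint_model(x1, hill_effect(drop(x1), hp), model = "ca", seed = 5)
  expect_equal(fit1$params$ec50, hp$ec50, tolerance = 0.05)
  expect_equal(fit1$params$power, hp$p, tolerance = 0.05)
})

test_that("joint fits are deterministic and reject unfittable input", {
  set.seed(1)
  X <- matrix(runif(30), 10, 3)
  y <- runif(10, 0.2, 0.8)
  cs <- cassette_assignment(c(1, 1, 2))
  a <- fit_joint_model(X, y, cs, seed = 99)
  b <- fit_joint_model(X, y, cs, seed = 99)
  expect_identical(a$params, b$params)
  expect_identical(a$train_idx, b$train_idx)
  expect_equal(a$test_rmse, b$test_rmse)

  expect_error(fit_joint_model(X, rep(0.4, 10), cs, seed = 1), "unfittable")
  expect_error(fit_joint_model(X[1:3, ], y[1:3], cs, seed = 1), "4 samples")
})

test_that("multi-start search matches the exhaustive grid oracle", {
  set.seed(8)
  for (case in list(list(p = 1, m = 1), list(p = 2, m = 1), list(p = 2, m = 2))) {
    X <- matrix(runif(15 * case$p, 0.05, 2), 15, case$p)
    labels <- rep(seq_len(case$m), length.out = case$p)
    truth_ec <- runif(case$p, 0.3, 3)
    truth_pw <- runif(case$m, 0.5, 3)
    y <- pmin(pmax(olmstead_oracle(X, truth_ec, truth_pw, labels) +
                     rnorm(15, 0, 0.03), 0), 1)
    fit <- qparscreen:::fit_joint_core(X, y, labels, n_starts = 32)
    oracle <- grid_fit_oracle(X, y, labels, n_grid = 51)
    expect_lte(fit$value, oracle * 1.01)
  }
})

test_that("PLS baseline matches linear ground truths", {
  set.seed(4)
  # centred orthogonal predictors: the single-component identity is exact
  X <- qr.Q(qr(scale(matrix(rnorm(120), 40, 3), scale = FALSE)))
  y_lin <- 2 * X[, 1]
  expect_gt(pls_baseline(X, y_lin, n_components = 1)$r_squared, 0.999)

  # with all components on full-rank X, PLS equals ordinary least squares
  y <- drop(X %*% c(1, -2, 0.5)) + rnorm(40, 0, 0.3)
  pf <- pls_baseline(X, y, n_components = 3)
  ols <- lm(y ~ X)
  expect_equal(pf$fitted, unname(fitted(ols)), tolerance = 1e-8)
  expect_equal(unname(pf$coefficients), unname(coef(ols)[-1]), tolerance = 1e-8)

  # prediction on new data is consistent with the fitted coefficients
  Xn <- matrix(rnorm(15), 5, 3)
  expect_equal(predict(pf, Xn), drop(Xn %*% pf$coefficients) + pf$intercept)
  expect_error(pls_baseline(X, y, n_components = 4), "n_components")
})

test_that("PLS adequacy collapses under label permutation", {
  set.seed(10)
  X <- matrix(rlnorm(66 * 5, 0, 0.4), 66, 5)
  y <- 0.3 * minmax_normalize(X)[, 1] + rnorm(66, 0, 0.02)
  r2_perm <- replicate(100,
    pls_baseline(X, sample(y), n_components = 1)$r_squared)
  expect_lt(median(r2_perm), 0.1)
  expect_gt(pls_baseline(X, y, n_components = 1)$r_squared, 0.5)
})
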