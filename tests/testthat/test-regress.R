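test_that("OLS recovers exact and degenerate fits", {
  m <- fit_ols(cbind(x = c(0, 1, 2)), c(1, 3, 5))
  expect_equal(unname(coef(m)), c(1, 2), tolerance = 1e-12)
  m <- fit_ols(cbind(x = rnorm(10)), rep(2.5, 10))
  expect_equal(unname(m$coefficients), 0, tolerance = 1e-10)
  expect_equal(m$intercept, 2.5, tolerance = 1e-10)
})

test_that("OLS equals the normal-equations oracle on a random system", {
  set.seed(101)
  X <- matrix(rnorm(200), 50, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  y <- rnorm(50)
  m <- fit_ols(X, y)
  expect_equal(unname(coef(m)), unname(pinv_coef(X, y)), tolerance = 1e-8)
  # residual orthogonality to every model column
  e <- y - predict(m)
  for (j in 1:4)
    expect_lt(abs(sum(e * X[, j])), 1e-8 * sqrt(sum(e^2) * sum(X[, j]^2)))
  expect_lt(abs(sum(e)), 1e-8)
})

test_that("rank-deficient designs are rejected with the column named", {
  X <- cbind(a = 1:10, b = 2 * (1:10))
  expect_error(fit_ols(X, rnorm(10)), "collinear")
})

test_that("the published equation is evaluated with frozen coefficients", {
  zero <- setNames(numeric(6), names(EQ1_COEFFICIENTS))
  expect_identical(predict_published(zero), -1.44)
  v <- zero; v["MWC4"] <- 1
  expect_equal(predict_published(v), -0.64)
  v <- zero; v["MWC4"] <- 2; v["SubFPC171"] <- 1; v["IC0"] <- 1
  expect_equal(predict_published(v), -0.11)
  expect_error(predict_published(zero[-1L]), "missing descriptor")
})

test_that("the published predictor is exactly affine", {
  set.seed(5)
  zero <- setNames(numeric(6), names(EQ1_COEFFICIENTS))
  for (k in 1:20) {
    a <- setNames(runif(6, 0, 5), names(EQ1_COEFFICIENTS))
    b <- setNames(runif(6, 0, 5), names(EQ1_COEFFICIENTS))
    expect_equal(predict_published(a) + predict_published(b) -
                   predict_published(zero),
                 predict_published(a + b), tolerance = 1e-12)
  }
})

test_that("rmse follows its definition and bounds the mean error", {
  expect_equal(rmse(1:5, 1:5), 0)
  expect_equal(rmse(c(0, 2), c(0, 0)), sqrt(2))
  expect_error(rmse(1:3, 1:2), "length mismatch")
  set.seed(2)
  for (k in 1:10) {
    y <- rnorm(30); yh <- rnorm(30)
    expect_gte(rmse(y, yh), abs(mean(y - yh)))
  }
})

test_that("Q2_loo equals the literal leave-one-out refit loop", {
  set.seed(8)
  X <- matrix(rnorm(40), 20, 2)
  y <- rnorm(20)
  brute <- vapply(1:20, function(i) {
    m <- fit_ols(X[-i, , drop = FALSE], y[-i])
    predict(m, X[i, , drop = FALSE])
  }, numeric(1L))
  q2_brute <- 1 - sum((y - brute)^2) / sum((y - mean(y))^2)
  expect_equal(q2_loo(X, y), q2_brute, tolerance = 1e-10)
})

test_that("Q2_loo is 1 on noiseless data and <= R2 in general", {
  set.seed(9)
  X <- matrix(rnorm(100), 50, 2)
  y_exact <- 2 + X %*% c(1, -1)
  expect_equal(q2_loo(X, drop(y_exact)), 1, tolerance = 1e-10)
  for (k in 1:10) {
    Xr <- matrix(rnorm(120), 40, 3)
    yr <- rnorm(40)
    m <- fit_ols(Xr, yr)
    expect_lte(q2_loo(Xr, yr), r_squared(yr, predict(m)) + 1e-12)
  }
})

test_that("Q2_loo of a response unrelated to X is near or below zero", {
  set.seed(10)
  q2 <- replicate(30, {
    X <- matrix(rnorm(80), 40, 2)
    q2_loo(X, rnorm(40))
  })
  expect_lt(mean(q2), 0.05)
})

test_that("k-fold CV is seeded, near-exact on clean data, noise-calibrated", {
  set.seed(12)
  X <- matrix(rnorm(200), 100, 2)
  y_clean <- drop(1 + X %*% c(2, -1))
  cv <- kfold_cv(X, y_clean, k = 5L, seed = 42L)
  expect_lt(cv$rmse_cv, 1e-8)
  expect_identical(cv, kfold_cv(X, y_clean, k = 5L, seed = 42L))
  cv2 <- kfold_cv(X, y_clean, k = 5L, seed = 43L)
  expect_false(identical(cv$folds, cv2$folds))
  # with sigma = 0.8 noise at n = 500 the CV error sits near sigma
  Xn <- matrix(rnorm(1000), 500, 2)
  yn <- drop(Xn %*% c(1, 1)) + rnorm(500, 0, 0.8)
  cvn <- kfold_cv(Xn, yn, k = 5L, seed = 1L)
  expect_lt(abs(cvn$rmse_cv - 0.8), 0.08)
  expect_error(kfold_cv(X, y_clean, k = 101L), "k <= n")
})

test_that("Y-scrambling destroys a chance-free model", {
  set.seed(13)
  X <- matrix(rnorm(200), 200, 1)
  y <- rnorm(200)
  ys <- y_scramble(X, y, n_perm = 50L, seed = 7L)
  expect_lt(ys$r2_yscr, 0.05)
  expect_length(ys$r2_values, 50L)
  expect_true(is.finite(ys$sd))
  # identity permutation control equals the training R2
  m <- fit_ols(X, y)
  ys_id <- y_scramble(X, y, perms = list(seq_len(200)))
  expect_equal(ys_id$r2_yscr, r_squared(y, predict(m)), tolerance = 1e-12)
})

test_that("Williams plot leverages behave like hat values", {
  expect_equal(round(h_star(920, 6), 3), 0.023)
  expect_equal(h_star(100, 3), 0.12)
  set.seed(14)
  X <- matrix(rnorm(240), 80, 3)
  y <- drop(X %*% c(1, 0.5, -1)) + rnorm(80, 0, 0.5)
  model <- fit_ols(X, y)
  w <- williams(model)
  expect_true(all(w$h >= 0 & w$h <= 1))
  expect_equal(sum(w$h), 3 + 1, tolerance = 1e-8)   # trace of the hat matrix
  expect_equal(attr(w, "h_star"), 3 * 4 / 80)
  # a far-away new point is flagged structural, not response
  far <- matrix(c(10, 10, 10), 1, dimnames = list(NULL, colnames(model$X)))
  wn <- williams(model, X_new = far)
  expect_true(wn$structural_outlier)
  # raw-residual mode with threshold 3 flags a corrupted response
  y2 <- y; y2[5L] <- y2[5L] + 10
  w2 <- williams(fit_ols(X, y2), resid_threshold = 3,
                 residual_type = "raw")
  expect_true(w2$response_outlier[5L])
})

test_that("OLS recovers planted coefficients within 3 standard errors", {
  g <- gen_regression(sim_spec(n = 500L, noise_sd = 0.8, seed = 21L))
  m <- fit_ols(g$X, g$y)
  fit <- summary(lm(g$y ~ g$X))
  se <- fit$coefficients[-1L, "Std. Error"]
  expect_true(all(abs(m$coefficients - g$beta) <= 3 * se))
})

test_that("validate_regression assembles a coherent report", {
  g <- gen_regression(sim_spec(n = 200L, noise_sd = 0.8, seed = 3L))
  rep <- validate_regression(g$X[1:150, ], g$y[1:150],
                             g$X[151:200, ], g$y[151:200],
                             n_perm = 10L, seed = 2L)
  expect_lte(rep$Q2_loo, rep$R2)
  expect_gte(rep$RMSE_tr, 0)
  expect_lt(rep$R2_yscr, 0.2)
  expect_true(is.finite(rep$RMSE_ext) && is.finite(rep$R2_ext))
  expect_equal(rep$h_star, 3 * 4 / 150)
})
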