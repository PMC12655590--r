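true_coeffs <- c(alpha = 0.02, beta = 2e-5, phi = 5, gamma = 0.8)

test_that("parametric prediction follows the bias model", {
  expect_equal(predict_parametric(700, c(alpha = 0, beta = 0, phi = 0, gamma = 0)), 700)
  expect_equal(predict_parametric(1000, c(alpha = 0.02, beta = 0, phi = 5, gamma = 0)), 1025)
  # linear in phi with unit slope
  d <- c(300, 650, 1200)
  p0 <- predict_parametric(d, c(alpha = 0.1, beta = 1e-5, phi = 2, gamma = 0.3))
  p1 <- predict_parametric(d, c(alpha = 0.1, beta = 1e-5, phi = 3, gamma = 0.3))
  expect_equal(p1 - p0, rep(1, 3))
  expect_error(predict_parametric(-1, true_coeffs), class = "tp_domain_error")
})

test_that("least squares recovers noiseless coefficients exactly", {
  pairs <- make_depth_pairs(50, coeffs = true_coeffs, noise_sd = 0, seed = 3)
  co <- fit_parametric(pairs$d_c, pairs$d_b)
  expect_equal(co, true_coeffs, tolerance = 1e-6)
  # identity data -> all-zero coefficients
  d <- seq(400, 900, length.out = 40)
  co0 <- fit_parametric(d, d)
  expect_lt(max(abs(co0)), 1e-8)
  expect_error(fit_parametric(c(1, 1, 1, 1), c(1, 1, 1, 1)), class = "tp_format_error")
})

test_that("coefficient bias shrinks with sample size under noise", {
  err_at <- function(n) {
    pairs <- make_depth_pairs(n, coeffs = true_coeffs, noise_sd = 1, seed = 11)
    co <- fit_parametric(pairs$d_c, pairs$d_b)
    sum(abs(co - true_coeffs) / pmax(abs(true_coeffs), 1e-3))
  }
  expect_lt(err_at(5000), err_at(50))
})

test_that("residuals match the definition and hand arithmetic", {
  pairs <- make_depth_pairs(30, coeffs = true_coeffs, noise_sd = 0, seed = 5)
  co <- fit_parametric(pairs$d_c, pairs$d_b)
  expect_lt(max(abs(hdrm_residuals(pairs$d_c, pairs$d_b, co))), 1e-7)
  # mean of least-squares residuals is ~0 (intercept in the design)
  pn <- make_depth_pairs(200, coeffs = true_coeffs, noise_sd = 2, seed = 6)
  con <- fit_parametric(pn$d_c, pn$d_b)
  expect_lt(abs(mean(hdrm_residuals(pn$d_c, pn$d_b, con))), 1e-8)
  # hand computation on three points
  co_h <- c(alpha = 0.1, beta = 0, phi = 10, gamma = 0)
  d_c <- c(100, 200, 300); d_b <- c(125, 230, 340)
  expect_equal(hdrm_residuals(d_c, d_b, co_h),
               d_b - (1.1 * d_c + 10))
})

test_that("extended features and standardization follow the definitions", {
  f <- build_features(1)
  expect_equal(as.numeric(f), c(1, 1, 1, log(2), 1))
  X <- build_features(runif(100, 400, 900))
  st <- standardize_features(X)
  expect_lt(max(abs(colMeans(st$X_norm))), 1e-10)
  expect_equal(apply(st$X_norm, 2, sd), rep(1, 5), ignore_attr = TRUE)
  # round trip (relative; cubic features reach 1e9)
  back <- unstandardize_features(st$X_norm, st$mu, st$sigma)
  expect_lt(max(abs(back - X) / pmax(abs(X), 1)), 1e-12)
  # held-out data reuses training statistics (no re-fit)
  X2 <- build_features(runif(20, 400, 900))
  st2 <- standardize_features(X2, st$mu, st$sigma)
  expect_equal(st2$mu, st$mu)
  expect_gt(max(abs(colMeans(st2$X_norm))), 1e-10)   # not re-centered
  expect_error(standardize_features(build_features(rep(500, 12))),
               class = "tp_degenerate_error")
  expect_error(build_features(c(1, -2)), class = "tp_domain_error")
})

test_that("residual forest fits constants exactly and is seed-deterministic", {
  X <- standardize_features(build_features(runif(60, 400, 900)))$X_norm
  # constant response: the forest package warns about degenerate regression
  f_const <- suppressWarnings(fit_residual_forest(X, rep(3.5, 60), seed = 1))
  expect_equal(predict_residual(f_const, X), rep(3.5, 60), tolerance = 1e-9)
  e <- 4 * sin(X[, 1] * 2) + rnorm(60, sd = 0.1)
  fa <- fit_residual_forest(X, e, seed = 9)
  fb <- fit_residual_forest(X, e, seed = 9)
  expect_identical(predict_residual(fa, X), predict_residual(fb, X))
  expect_gt(regression_metrics(e, predict_residual(fa, X))$r2, 0.5)
  expect_error(fit_residual_forest(X[1:5, ], e[1:5]), class = "tp_format_error")
})

test_that("hybrid correction improves on parametric and raw depth", {
  pairs <- make_depth_pairs(120, coeffs = true_coeffs, noise_sd = 1, seed = 8,
                            structure_amp = 5, structure_period = 150)
  tr <- 1:100; te <- 101:120
  model <- hdrm_fit(pairs$d_c[tr], pairs$d_b[tr], seed = 42)
  d_fin <- correct_depth(model, pairs$d_c[te])
  d_par <- predict_parametric(pairs$d_c[te], model$coeffs)
  rmse <- function(x) regression_metrics(pairs$d_b[te], x)$rmse
  expect_lte(rmse(d_fin), rmse(d_par))
  expect_lte(rmse(d_fin), rmse(pairs$d_c[te]))
  # forest trained on all-zero residuals leaves the parametric stage alone
  p0 <- make_depth_pairs(60, coeffs = true_coeffs, noise_sd = 0, seed = 2)
  m0 <- hdrm_fit(p0$d_c, p0$d_b, seed = 1)
  expect_equal(correct_depth(m0, p0$d_c),
               predict_parametric(p0$d_c, m0$coeffs), tolerance = 1e-5)
})

test_that("cross-validation folds are disjoint, exhaustive and near-exact on clean data", {
  pairs <- make_depth_pairs(64, coeffs = true_coeffs, noise_sd = 0, seed = 13)
  # noiseless data leaves near-constant residuals; the forest warns
  cv <- suppressWarnings(hdrm_cross_validate(pairs$d_c, pairs$d_b, k = 10, seed = 42))
  expect_identical(nrow(cv), 10L)
  expect_lt(max(cv$rmse_param), 1e-6)
  expect_lte(diff(range(cv$n)), 1)
  folds <- attr(cv, "folds")
  expect_identical(sort(unname(unlist(folds))), 1:64)
  expect_error(hdrm_cross_validate(pairs$d_c[1:5], pairs$d_b[1:5], k = 10),
               class = "tp_format_error")
})
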