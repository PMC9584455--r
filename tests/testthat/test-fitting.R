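test_that("centering moves energy to the grid center and is idempotent", {
  g <- grid_2d(14, 36)
  W <- matrix(0, 2, g$n)
  W[1, 1] <- 1 # delta at pixel (0, 0)
  cm <- build_v1_cov(g, 2, 1)
  W[2, ] <- cm$C[, g$center[1] * g$width + g$center[2] + 1] # already centered
  out <- center_receptive_fields(rf_set(W, g))
  m1 <- matrix(out$W[1, ], 14, 36, byrow = TRUE)
  expect_equal(unname(which(m1 == 1, arr.ind = TRUE)[1, ]) - 1, c(7, 18))
  expect_equal(out$W[2, ], W[2, ]) # centered field unchanged
  twice <- center_receptive_fields(out)
  expect_equal(twice$W, out$W)
  zero <- rf_set(matrix(0, 1, g$n), g)
  expect_warning(center_receptive_fields(zero), "all-zero")
})

test_that("normalized Frobenius distance behaves like a normalized metric", {
  g <- grid_small()
  A <- build_sensilla_cov(g, 50, 200, gamma = 20)
  expect_equal(frobenius_distance(A, A), 0)
  expect_equal(frobenius_distance(A, matrix(0, g$n, g$n)), 1)
  expect_error(frobenius_distance(A$C, diag(3)), "shapes")
  # symmetry and triangle inequality on random unit-trace triples
  set.seed(81)
  mats <- replicate(3, {
    M <- crossprod(matrix(rnorm(100), 10))
    M / sum(diag(M))
  }, simplify = FALSE)
  nf <- function(x, y) norm(x - y, "F")
  expect_equal(nf(mats[[1]], mats[[2]]), nf(mats[[2]], mats[[1]]))
  expect_lte(nf(mats[[1]], mats[[3]]),
             nf(mats[[1]], mats[[2]]) + nf(mats[[2]], mats[[3]]) + 1e-12)
})

test_that("sensilla fit recovers exact on-grid parameters from the model itself", {
  g <- grid_1d(80, 0.5)
  truth <- build_sensilla_cov(g, 75, 200, gamma = 12.17)
  fit <- fit_covariance_params(truth, "sensilla")
  expect_equal(fit$par$f_lo, 75)
  expect_equal(fit$par$f_hi, 200)
  expect_equal(fit$par$gamma, 12.17, tolerance = 1e-6)
  expect_lt(fit$distance, 1e-6)
  # distance evaluated at the exact truth is numerically zero
  expect_lt(frobenius_distance(truth, build_sensilla_cov(g, 75, 200,
                                                         gamma = 12.17)), 1e-12)
  # truth is the argmin over the whole evaluated search trace
  expect_true(all(fit$trace$distance >= fit$distance - 1e-12))
})

test_that("fourier and V1 fits recover their generating parameters", {
  g <- grid_1d(60, 1)
  st <- build_stationary_cov(g, 50, 150)
  ff <- fit_covariance_params(st, "fourier")
  expect_equal(ff$par$f_lo, 50)
  expect_equal(ff$par$f_hi, 150)
  expect_lt(ff$distance, 1e-10)
  g2 <- grid_2d(10, 10)
  vt <- build_v1_cov(g2, s = 2.2, f = 1.1)
  fv <- fit_covariance_params(vt, "v1")
  expect_equal(fv$par$s, 2.2, tolerance = 1e-3)
  expect_equal(fv$par$f, 1.1, tolerance = 1e-3)
  expect_lt(fv$distance, 1e-5)
  ti <- build_null_cov("v1_translation_invariant", g2, f = 1.4)
  ft <- fit_covariance_params(ti, "v1_translation_invariant")
  expect_equal(ft$par$f, 1.4, tolerance = 1e-3)
})

test_that("null-model distances rank below the structured fit on sensilla data", {
  g <- grid_1d(80, 0.5)
  truth <- build_sensilla_cov(g, 75, 200, gamma = 12.17)
  Cd <- empirical_covariance(gen_synthetic_rf_population(truth, 500, seed = 82))
  d_model <- fit_covariance_params(Cd, "sensilla")$distance
  d_fourier <- fit_covariance_params(Cd, "fourier")$distance
  d_unstr <- fit_covariance_params(Cd, "unstructured")$distance
  expect_lt(d_model, d_fourier)
  expect_lt(d_fourier, d_unstr)
})

test_that("finite-sample covariance converges at roughly root-m rate", {
  g <- grid_small()
  cm <- build_sensilla_cov(g, 50, 200, gamma = 20)
  ds <- vapply(c(100, 1000, 10000), function(m) {
    frobenius_distance(finite_sample_covariance(cm, m, seed = 83), cm)
  }, numeric(1))
  expect_true(all(diff(ds) < 0))
  # each tenfold increase shrinks the distance by at least a factor 2
  expect_lt(ds[2] / ds[1], 0.5)
  expect_lt(ds[3] / ds[2], 0.5)
  expect_identical(finite_sample_covariance(cm, 50, seed = 84)$C,
                   finite_sample_covariance(cm, 50, seed = 84)$C)
})

test_that("spectral report compares curves, variance, and subspace angles", {
  g <- grid_small()
  cm <- build_sensilla_cov(g, 50, 200, gamma = 20)
  sp0 <- spectral_compare(cm, cm, k = 5)
  expect_equal(sp0$values$data, sp0$values$model)
  expect_lt(max(sp0$principal_angles$model), 1e-6)
  fin <- finite_sample_covariance(cm, 300, seed = 85)
  sp <- spectral_compare(fin, cm, finite_sample_covariance(cm, 95, seed = 86),
                         k = 5)
  for (v in sp$values) expect_equal(sum(v), 1, tolerance = 1e-10)
  expect_true(all(diff(sp$variance_explained) >= 0))
  expect_error(spectral_compare(cm, cm, k = g$n + 1), "exceeds")
})
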