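test_that("stationary covariance is Toeplitz with unit-diagonal structure", {
  g <- grid_small()
  # single harmonic, no normalization distortion checked via ratios
  cm <- build_stationary_cov(g, f_lo = 50, f_hi = 50)
  C <- cm$C
  # stationarity: entries depend only on t - t'
  for (off in c(0, 3, 11)) {
    band <- C[cbind(1:(g$n - off), (1 + off):g$n)]
    expect_lt(diff(range(band)), 1e-12)
  }
  # diagonal is constant = sum of spectral weights (cos 0), here rescaled to
  # trace d, so every diagonal entry is exactly 1
  expect_equal(unname(diag(C)), rep(1, g$n), tolerance = 1e-12)
})

test_that("stationary eigenbasis matches analytic sinusoids (dense-solver oracle)", {
  # d = 8 over 1 s: natural frequencies are exactly k Hz; passband {1, 2}
  g <- grid_1d(8, 125)
  cm <- build_stationary_cov(g, f_lo = 1, f_hi = 2)
  e <- eigendecompose(cm)
  expect_equal(sum(e$values > 1e-8), 4)
  # flat spectrum: each sinusoid pair carries eigenvalue d/4 after trace-d
  # normalization (grid scaling sum_t cos^2 = d/2)
  expect_equal(e$values[1:4], rep(2, 4), tolerance = 1e-10)
  tt <- g$times
  analytic <- cbind(cos(2 * pi * 1 * tt), sin(2 * pi * 1 * tt),
                    cos(2 * pi * 2 * tt), sin(2 * pi * 2 * tt))
  ang <- principal_angles(e$vectors[, 1:4], analytic)
  expect_lt(max(ang), 1e-7)
})

test_that("compound-angle expansion equals the difference form entrywise", {
  g <- grid_small()
  ks <- 2:5
  lam2 <- c(1, 0.5, 2, 0.25)
  L <- g$duration / 1000
  tt <- g$times
  direct <- matrix(0, g$n, g$n)
  for (i in seq_along(ks)) {
    wk <- 2 * pi * ks[i] / L
    direct <- direct + lam2[i] *
      (outer(cos(wk * tt), cos(wk * tt)) + outer(sin(wk * tt), sin(wk * tt)))
  }
  diff_form <- matrix(0, g$n, g$n)
  for (i in seq_along(ks)) {
    wk <- 2 * pi * ks[i] / L
    diff_form <- diff_form + lam2[i] * cos(wk * outer(tt, tt, "-"))
  }
  expect_lt(max(abs(direct - diff_form)), 1e-12)
})

test_that("sensilla covariance has the separable exponential decay", {
  g <- grid_small()
  gamma <- 12
  cm <- build_sensilla_cov(g, 75, 200, gamma = gamma)
  # C(t,t)/C(0,0) = exp(-2 t / gamma), unaffected by trace normalization
  ratio <- diag(cm$C) / cm$C[1, 1]
  expect_equal(ratio, exp(-2 * g$times / (gamma / 1000)), tolerance = 1e-10)
  # dividing out the envelope recovers a Toeplitz matrix
  env <- exp(-g$times / (gamma / 1000))
  S <- cm$C / tcrossprod(env)
  off <- S[cbind(1:(g$n - 5), 6:g$n)]
  expect_lt(diff(range(off)), 1e-8)
})

test_that("sensilla covariance at the fitted parameters is banded and decaying", {
  # 40 ms window: positive main diagonal flanked by negative side-lobes
  # (near half the center period of the passband), everything decaying
  # away from the origin
  g <- grid_1d(80, 0.5)
  cm <- build_sensilla_cov(g, 75, 200, gamma = 12.17)
  dmain <- diag(cm$C)
  expect_true(all(dmain > 0))
  expect_lt(dmain[40], dmain[1])
  expect_lt(dmain[80], dmain[40])
  # negative side-lobe within the first half-period (~3.6 ms = 8 samples)
  expect_lt(min(cm$C[1, 2:10]), 0)
  # magnitudes decay away from the origin corner
  expect_lt(max(abs(cm$C[60:80, 60:80])), 0.05 * max(abs(cm$C[1:20, 1:20])))
})

test_that("gamma -> infinity recovers the stationary model", {
  g <- grid_small()
  big <- build_sensilla_cov(g, 75, 200, gamma = 1e9)
  st <- build_stationary_cov(g, 75, 200)
  expect_equal(big$C, st$C, tolerance = 1e-6)
})

test_that("empty passband is rejected with an informative error", {
  g <- grid_small() # 40 ms -> harmonic spacing 25 Hz
  expect_error(build_stationary_cov(g, 26, 49), "empty passband")
  expect_error(build_stationary_cov(g, 26, 49), "25")
  expect_error(build_sensilla_cov(g, 75, 200, gamma = -1), "gamma")
  expect_error(build_stationary_cov(g, 600, 700), "Nyquist")
})

test_that("band edges are inclusive and k = 0 needs f_lo = 0", {
  g <- grid_small()
  cm <- build_stationary_cov(g, 25, 50) # edges exactly on harmonics 1, 2
  expect_equal(cm$params$harmonics, 1:2)
  cm0 <- build_stationary_cov(g, 0, 50)
  expect_true(0 %in% cm0$params$harmonics)
})

# pixel squared-distance oracle for the V1 checks
pixel_sqdist_test <- function(g) {
  outer(g$coords[, 1], g$coords[, 1], "-")^2 +
    outer(g$coords[, 2], g$coords[, 2], "-")^2
}

test_that("V1 covariance is symmetric, localized, and monotone in f", {
  g <- grid_2d(6, 6)
  cm <- build_v1_cov(g, s = 1.5, f = 1)
  expect_lt(max(abs(cm$C - t(cm$C))), 1e-12)
  # before normalization C(c, c) = 1: check via the unnormalized formula
  d2c <- (g$coords[, 1] - g$center[1])^2 + (g$coords[, 2] - g$center[2])^2
  ci <- which(d2c == 0)
  un <- exp(-pixel_sqdist_test(g) / 2) * tcrossprod(exp(-d2c / (2 * 1.5^2)))
  expect_equal(un[ci, ci], 1)
  # increasing f at fixed s strictly increases every off-diagonal entry
  Cs <- lapply(c(0.5, 1, 2), function(f) {
    m <- build_v1_cov(g, s = 1.5, f = f, trace_target = NULL)
    m$C
  })
  off <- upper.tri(Cs[[1]])
  expect_true(all(Cs[[2]][off] > Cs[[1]][off]))
  expect_true(all(Cs[[3]][off] > Cs[[2]][off]))
  expect_error(build_v1_cov(g, 1, 1, center = c(10, 2)), "outside")
})

test_that("null models: identity, fourier consistency, translation invariance", {
  g <- grid_1d(10, 1)
  un <- build_null_cov("unstructured", g)
  expect_equal(un$C, diag(10))
  expect_equal(sum(diag(un$C)), 10)
  g2 <- grid_small()
  fo <- build_null_cov("fourier", g2, f_lo = 75, f_hi = 200)
  limit <- build_sensilla_cov(g2, 75, 200, gamma = 1e9)
  expect_equal(fo$C, limit$C, tolerance = 1e-6)
  gv <- grid_2d(4, 5)
  ti <- build_null_cov("v1_translation_invariant", gv, f = 1)
  # depends only on t - t': compare pixel pairs with equal displacement
  idx <- function(r, c) r * gv$width + c + 1
  expect_equal(ti$C[idx(0, 0), idx(1, 2)], ti$C[idx(2, 1), idx(3, 3)])
  expect_equal(ti$C[idx(0, 1), idx(0, 3)], ti$C[idx(3, 2), idx(3, 4)])
})

test_that("trace normalization rescales values and preserves eigenvectors", {
  g <- grid_small()
  cm <- build_sensilla_cov(g, 75, 200, gamma = 12)
  e1 <- eigendecompose(cm)
  cm2 <- normalize_trace(cm, 2)
  expect_equal(sum(diag(cm2$C)), 2, tolerance = 1e-12)
  e2 <- eigendecompose(cm2)
  expect_equal(e2$vectors, e1$vectors)
  expect_equal(e2$values, e1$values * 2 / g$n, tolerance = 1e-12)
  expect_error(normalize_trace(cm, -1), "positive")
})

test_that("eigendecomposition reconstructs, clips, and rejects bad input", {
  set.seed(42)
  A <- matrix(rnorm(100), 10)
  C <- crossprod(A) # random PSD from known factors
  e <- eigendecompose(C)
  expect_lt(norm(C - e$vectors %*% (t(e$vectors) * e$values), "F") / norm(C, "F"),
            1e-8)
  expect_true(all(diff(e$values) <= 1e-12))
  v <- rnorm(6)
  e1 <- eigendecompose(tcrossprod(v))
  expect_equal(e1$values[1], sum(v^2))
  expect_lt(max(abs(e1$values[-1])), 1e-12 * sum(v^2))
  expect_error(eigendecompose(matrix(rnorm(16), 4)), "asymmetric")
  bad <- diag(c(1, 1, -0.5))
  expect_error(eigendecompose(bad), "negative eigenvalue")
})

test_that("Hermite wavelet basis matches its closed-form structure", {
  g <- grid_2d(12, 12)
  hb <- hermite_eigenbasis(g, s = 2, f = 1, k_max = 10)
  # leading eigenfunction is a strictly positive Gaussian blob
  expect_true(all(hb$functions[, 1] > 0))
  # eigenvalue ratio between successive total orders is the constant c3
  vals <- hb$values
  expect_equal(vals[2] / vals[1], unname(hb$constants["c3"]), tolerance = 1e-12)
  expect_equal(vals[4] / vals[2], unname(hb$constants["c3"]), tolerance = 1e-12)
  # eigenvalues within a total order are equal
  expect_equal(vals[2], vals[3])
  expect_equal(vals[4], vals[5])
  expect_equal(sum(vals), 1)
  expect_error(hermite_eigenbasis(g, 2, 1, k_max = 1e5), "grid size")
})

test_that("analytic Hermite basis agrees with the numerical eigendecomposition", {
  g <- grid_2d(12, 12)
  cm <- build_v1_cov(g, s = 2, f = 1)
  e <- eigendecompose(cm)
  hb <- hermite_eigenbasis(g, s = 2, f = 1, k_max = 10)
  ang <- principal_angles(e$vectors[, 1:10], hb$functions)
  expect_lt(max(ang) * 180 / pi, 10) # discretization tolerance, see vignette
  nv <- e$values[1:10] / sum(e$values[1:10])
  expect_lt(max(abs(log(nv / hb$values))), 0.25)
})

test_that("all constructors produce symmetric PSD trace-normalized matrices", {
  g <- grid_small()
  g2 <- grid_2d(6, 7)
  models <- list(
    build_stationary_cov(g, 50, 200),
    build_sensilla_cov(g, 75, 200, gamma = 12.17),
    build_v1_cov(g2, 2, 0.8),
    build_null_cov("unstructured", g),
    build_null_cov("fourier", g, f_lo = 25, f_hi = 100),
    build_null_cov("v1_translation_invariant", g2, f = 1.2)
  )
  for (m in models) {
    d <- nrow(m$C)
    expect_lt(max(abs(m$C - t(m$C))), 1e-10)
    expect_equal(sum(diag(m$C)) / d, 1, tolerance = 1e-10)
    e <- eigendecompose(m)
    expect_true(all(e$values >= 0))
    expect_equal(crossprod(e$vectors), diag(d), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})
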