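test_that("hidden features implement the ReLU projection exactly", {
  W <- rbind(c(1, 0, 0), c(0, -1, 0))
  net <- rfn(W)
  expect_equal(hidden_features(net, matrix(0, 2, 3)), matrix(0, 2, 2))
  expect_equal(drop(hidden_features(net, c(-3, 2, 5))), c(0, 0))
  expect_equal(drop(hidden_features(net, c(3, -2, 5))), c(3, 2))
  # positive homogeneity
  X <- matrix(rnorm(12), 4, 3)
  expect_equal(hidden_features(net, 2.5 * X), 2.5 * hidden_features(net, X))
  expect_error(hidden_features(net, matrix(0, 2, 5)), "columns")
})

test_that("evaluate_error reports the misclassification fraction", {
  g <- grid_small()
  cm <- build_sensilla_cov(g, 50, 200, gamma = 20)
  train <- gen_frequency_detection(100, grid = g, f1 = 100, seed = 61)
  net <- train_rfn(rfn(sample_weights(cm, 20, seed = 62)), train, seed = 1)
  expect_error(evaluate_error(rfn(net$W), train), "readout")
  err <- evaluate_error(net, train)
  expect_gte(err, 0)
  expect_lte(err, 1)
  # perfect predictions give exactly zero
  fake <- train
  fake$y <- predict(net$readout, hidden_features(net, train$X))
  expect_equal(evaluate_error(net, fake), 0)
})

test_that("error curves are reproducible with monotone-improving structure", {
  g <- grid_small()
  cm <- build_sensilla_cov(g, 75, 125, gamma = 20)
  train <- gen_frequency_detection(250, f1 = 100, grid = g, seed = 63)
  test <- gen_frequency_detection(150, f1 = 100, grid = g, seed = 64)
  ec <- error_curve_experiment(cm, train, test, c(4, 16), repeats = 3,
                               seed = 65)
  ec2 <- error_curve_experiment(cm, train, test, c(4, 16), repeats = 3,
                                seed = 65)
  expect_identical(ec$runs$test_error, ec2$runs$test_error)
  expect_equal(nrow(ec$runs), 6)
  expect_equal(ec$summary$se,
               tapply(ec$runs$test_error, ec$runs$m, sd) / sqrt(3),
               ignore_attr = TRUE)
  # wider compatible networks do at least as well (up to repeat noise)
  expect_lte(ec$summary$mean_error[2],
             ec$summary$mean_error[1] + 3 * max(ec$summary$se, 0.01))
  expect_error(error_curve_experiment(cm, train, test, integer(0)), "empty")
})

test_that("compatible structured weights beat classical weights at small m", {
  train <- gen_frequency_detection(500, seed = 66)
  test <- gen_frequency_detection(250, seed = 67)
  cm <- sensilla_compatible()
  st <- error_curve_experiment(cm, train, test, 15, repeats = 3, seed = 68)
  cl <- error_curve_experiment(NULL, train, test, 15, repeats = 3, seed = 68)
  expect_lt(st$summary$mean_error, cl$summary$mean_error)
})

test_that("few-shot training (5 per class) runs with the standard protocol", {
  g <- grid_small()
  cm <- build_sensilla_cov(g, 75, 125, gamma = 20)
  train <- gen_frequency_detection(5, f1 = 100, grid = g, seed = 69)
  test <- gen_frequency_detection(100, f1 = 100, grid = g, seed = 70)
  net <- train_rfn(rfn(sample_weights(cm, 30, seed = 71)), train, seed = 1)
  err <- evaluate_error(net, test)
  expect_lt(err, 0.5) # beats chance even from 10 examples
})

test_that("V1 weight banks have uniform centers and localized energy", {
  g <- grid_2d(8, 10)
  bank <- v1_weight_bank(g, s = 2, f = 0.5, m = 4000, seed = 72)
  expect_identical(bank$W, v1_weight_bank(g, 2, 0.5, 4000, seed = 72)$W)
  centers <- bank$provenance$centers
  # chi-square uniformity over the 80 pixels
  counts <- table(factor(centers[, 1] * 10 + centers[, 2], levels = 0:79))
  chi <- sum((counts - 50)^2 / 50)
  expect_lt(chi, qchisq(1 - 1e-6, df = 79)) # sanity, not significance chasing
  # energy center of mass lies within s of the recorded center (small f),
  # checked on interior-centered fields to avoid boundary truncation
  ok <- which(centers[, 1] %in% 2:5 & centers[, 2] %in% 2:7)
  for (i in ok[1:20]) {
    fld <- matrix(bank$W[i, ], 8, 10, byrow = TRUE)^2
    com <- c(sum(rowSums(fld) * 0:7), sum(colSums(fld) * 0:9)) / sum(fld)
    expect_lt(sqrt(sum((com - centers[i, ])^2)), 2)
  }
})

test_that("per-center product sampling reproduces the localized V1 covariance", {
  # the bank samples envelope * stationary-draw; its second moment at a
  # fixed center must match build_v1_cov (Monte-Carlo oracle)
  g <- grid_2d(7, 7)
  s <- 1.5
  f <- 0.8
  cm <- build_v1_cov(g, s, f)
  base <- build_null_cov("v1_translation_invariant", g, f = f,
                         trace_target = NULL)
  e <- eigendecompose(base)
  A <- t(e$vectors) * sqrt(e$values)
  r2 <- (g$coords[, 1] - g$center[1])^2 + (g$coords[, 2] - g$center[2])^2
  env <- exp(-r2 / (2 * s^2))
  set.seed(73)
  U <- matrix(rnorm(20000 * g$n), 20000) %*% A
  W <- sweep(U, 2, env, "*")
  scale <- g$n / sum(env^2)
  emp <- crossprod(W) / nrow(W) * scale
  expect_lt(norm(emp - cm$C, "F") / norm(cm$C, "F"), 0.05)
})
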