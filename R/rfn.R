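#' Random feature networks
#'
#' A random feature network (RFN) is a two-layer network `h = relu(W x)`,
#' `yhat = beta' h + beta0`, whose hidden weights `W` are sampled once and
#' frozen; only the linear readout is trained ([fit_readout()]). With
#' `W` drawn from a structured covariance the hidden layer computes a
#' randomized projection of the stimulus into the covariance eigenbasis,
#' filtering out components outside the model's passband. There is no
#' hidden-unit threshold.
#'
#' @param weights a `structrf_rfset` (e.g. from [sample_weights()]) or a
#'   plain m x d matrix.
#' @return an object of class `structrf_rfn` with elements `W`,
#'   `nonlinearity` (`"relu"`) and `readout` (`NULL` until trained).
#' @examples
#' cs <- build_sensilla_cov(grid_1d(200, 0.5), 10, 60, gamma = 50)
#' net <- rfn(sample_weights(cs, 25, seed = 1))
#' @export
rfn <- function(weights) {
  W <- if (inherits(weights, "structrf_rfset")) weights$W else weights
  if (!is.matrix(W)) stop("'weights' must be a matrix or structrf_rfset")
  structure(list(W = W, nonlinearity = "relu", readout = NULL),
            class = "structrf_rfn")
}

#' @export
print.structrf_rfn <- function(x, ...) {
  cat(sprintf("RFN: %d hidden neurons, d = %d, readout %s\n",
              nrow(x$W), ncol(x$W),
              if (is.null(x$readout)) "untrained" else
                sprintf("trained (C = %g)", x$readout$C)))
  invisible(x)
}

#' Hidden-layer features
#'
#' `H = relu(X W^T)` entrywise; rows are stimuli, columns hidden neurons.
#' The ReLU is positively homogeneous, so any overall weight scale can be
#' absorbed into the readout.
#'
#' @param model a `structrf_rfn` (or matrix of hidden weights).
#' @param X n x d stimulus matrix (or single length-d vector).
#' @return n x m feature matrix.
#' @export
hidden_features <- function(model, X) {
  W <- if (inherits(model, "structrf_rfn")) model$W else model
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != ncol(W)) {
    stop(sprintf("stimuli have %d columns but hidden weights expect %d",
                 ncol(X), ncol(W)))
  }
  pmax(tcrossprod(X, W), 0)
}

#' Train an RFN readout on a labeled dataset
#'
#' @param model a `structrf_rfn`.
#' @param data a `structrf_dataset` (or list with `X`, `y`).
#' @param seed seed for the cross-validation fold assignment.
#' @inheritParams fit_readout
#' @return the model with `readout` filled in.
#' @export
train_rfn <- function(model, data, seed = NULL, C_grid = 10^(-3:3), folds = 5) {
  stopifnot(inherits(model, "structrf_rfn"))
  H <- hidden_features(model, data$X)
  model$readout <- fit_readout(H, data$y, seed = seed, C_grid = C_grid,
                               folds = folds)
  model
}

#' Misclassification rate of a trained RFN
#'
#' @param model a trained `structrf_rfn`.
#' @param data test data (`X`, `y`).
#' @return misclassification fraction in `[0, 1]`.
#' @export
evaluate_error <- function(model, data) {
  stopifnot(inherits(model, "structrf_rfn"))
  if (is.null(model$readout)) stop("model has no trained readout")
  pred <- predict(model$readout, hidden_features(model, data$X))
  mean(pred != data$y)
}

# Per-subclass misclassification of a trained RFN (diagnostic for the
# incompatible-weights failure mode).
subclass_errors <- function(model, data) {
  pred <- predict(model$readout, hidden_features(model, data$X))
  tapply(pred != data$y, data$meta$subclass, mean)
}

#' Test-error curve over hidden-layer widths
#'
#' For each neuron count, samples `repeats` fresh hidden-weight banks
#' (from the structured covariance, or spherical Gaussian when
#' `cov = NULL`), trains the SVM readout on the training set, and records
#' the test error; reports the mean and standard error over repeats. Weight
#' banks and CV folds get deterministic sub-seeds derived from `seed`.
#'
#' @param cov a `structrf_cov`, or `NULL` for classical unstructured
#'   (identity-covariance) weights.
#' @param train,test `structrf_dataset`s.
#' @param neuron_counts vector of hidden-layer widths.
#' @param repeats random networks per width (default 5).
#' @param seed integer master seed.
#' @param keep_subclass_errors record per-subclass test errors per run.
#' @return an object of class `structrf_error_curve`: data frame `summary`
#'   (m, mean_error, se), data frame `runs` (m, repeat, seed, test_error),
#'   and optionally `subclass` errors.
#' @export
error_curve_experiment <- function(cov, train, test, neuron_counts,
                                   repeats = 5, seed = NULL,
                                   keep_subclass_errors = FALSE) {
  if (length(neuron_counts) == 0L) stop("'neuron_counts' is empty")
  d <- ncol(train$X)
  runs <- list()
  sub <- list()
  ctr <- 0L
  for (mi in seq_along(neuron_counts)) {
    m <- neuron_counts[mi]
    for (r in seq_len(repeats)) {
      ctr <- ctr + 1L
      s <- derive_seed(seed %||% 0L, ctr)
      W <- if (is.null(cov)) {
        with_seed(s, matrix(stats::rnorm(m * d), nrow = m, byrow = TRUE))
      } else {
        sample_weights(cov, m, seed = s)$W
      }
      net <- train_rfn(rfn(W), train, seed = derive_seed(s, 1L))
      err <- evaluate_error(net, test)
      runs[[ctr]] <- data.frame(m = m, rep = r, seed = s, test_error = err)
      if (keep_subclass_errors && !is.null(test$meta$subclass)) {
        se <- subclass_errors(net, test)
        sub[[ctr]] <- data.frame(m = m, rep = r, subclass = names(se),
                                 error = as.numeric(se))
      }
    }
  }
  runs <- do.call(rbind, runs)
  summ <- do.call(rbind, lapply(split(runs, runs$m), function(g) {
    data.frame(m = g$m[1], mean_error = mean(g$test_error),
               se = stats::sd(g$test_error) / sqrt(nrow(g)))
  }))
  summ <- summ[order(summ$m), ]
  rownames(summ) <- NULL
  structure(list(summary = summ, runs = runs,
                 subclass = if (length(sub)) do.call(rbind, sub) else NULL,
                 repeats = repeats, seed = seed),
            class = "structrf_error_curve")
}

#' @export
print.structrf_error_curve <- function(x, ...) {
  cat(sprintf("Error curve (%d repeats per width):\n", x$repeats))
  print(transform(x$summary,
                  mean_error = sprintf("%.2f%%", 100 * mean_error),
                  se = sprintf("%.2f%%", 100 * se)),
        row.names = FALSE)
  invisible(x)
}

#' V1 weight bank with uniformly random centers
#'
#' Samples `m` fields from the localized V1 covariance, each with its own
#' center drawn uniformly at random over the pixel grid, so that the bank
#' covers the whole image. Sampling uses the locally-stationary product
#' form: a draw from the translation-invariant kernel
#' `exp(-||t - t'||^2 / (2 f^2))` multiplied entrywise by the Gaussian
#' envelope `exp(-||t - c||^2 / (2 s^2))`, which has exactly the per-center
#' V1 covariance. Each field is rescaled so its generating covariance has
#' trace `d` (boundary truncation makes the raw trace center-dependent).
#'
#' @inheritParams build_v1_cov
#' @param m number of hidden weights.
#' @param seed integer seed.
#' @return a `structrf_rfset`; `provenance$centers` records the m centers.
#' @export
v1_weight_bank <- function(grid, s, f, m, seed = NULL) {
  stopifnot(inherits(grid, "structrf_grid2d"))
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("'m' must be >= 1")
  base <- build_null_cov("v1_translation_invariant", grid, f = f,
                         trace_target = NULL)
  e <- eigendecompose(base)
  A <- t(e$vectors) * sqrt(e$values) # z %*% A gives a draw from base
  d <- grid$n
  out <- with_seed(seed, {
    centers <- cbind(sample.int(grid$height, m, replace = TRUE) - 1L,
                     sample.int(grid$width, m, replace = TRUE) - 1L)
    W <- matrix(0, m, d)
    for (i in seq_len(m)) {
      u <- drop(stats::rnorm(d) %*% A)
      r2 <- (grid$coords[, 1] - centers[i, 1])^2 +
        (grid$coords[, 2] - centers[i, 2])^2
      env <- exp(-r2 / (2 * s^2))
      tr_c <- sum(env^2) # trace of the per-center covariance (g(0) = 1)
      W[i, ] <- env * u * sqrt(d / tr_c)
    }
    list(W = W, centers = centers)
  })
  new_rf_set(out$W, grid,
             provenance = list(kind = "v1_bank", seed = seed, s = s, f = f,
                               centers = out$centers))
}
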