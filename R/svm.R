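#' Linear SVM with squared hinge loss and l2 penalty
#'
#' The readout used throughout: minimize
#' `0.5 ||beta||^2 + C * sum_i max(0, 1 - y_i (h_i' beta + beta0))^2`
#' over `(beta, beta0)` for labels `y in {-1, +1}`. The objective is smooth
#' and convex, so it is minimized directly by BFGS with the analytic
#' gradient. The intercept is unpenalized. This is written in-package
#' because no installed package offers the l2-regularized *squared*-hinge
#' primal (libsvm-based fits use the plain hinge); the hinge-loss SVM from
#' e1071 serves as an independent cross-check in the test suite.
#'
#' @param H n x p feature matrix.
#' @param y labels; any two-level vector (coerced internally to -1/+1).
#' @param C regularization strength (larger = less regularization), the
#'   inverse-penalty convention in which strengths are tuned over
#'   `[1e-3, 1e3]`.
#' @param init optional warm-start parameter vector `c(beta, beta0)`.
#' @param maxit Newton iteration cap.
#' @return list with `beta`, `beta0`, `levels` (the two class labels, in the
#'   order mapped to -1/+1), `C`, `converged`.
#' @details The solver is a generalized Newton method (the objective is
#'   once differentiable with a piecewise-linear gradient; the generalized
#'   Hessian `I + 2C H_A' H_A` over the active set `A` of margin violators
#'   is used, as in primal squared-hinge solvers) with backtracking line
#'   search, which converges in a handful of iterations at these problem
#'   sizes.
#' @keywords internal
svm_squared_hinge <- function(H, y, C, init = NULL, maxit = 100) {
  lv <- sort(unique(y))
  if (length(lv) != 2L) stop("need exactly two classes")
  ys <- ifelse(y == lv[2L], 1, -1)
  p <- ncol(H)
  theta <- init %||% numeric(p + 1L)
  obj <- function(th) {
    f <- drop(H %*% th[1:p]) + th[p + 1L]
    xi <- pmax(0, 1 - ys * f)
    0.5 * sum(th[1:p]^2) + C * sum(xi^2)
  }
  fcur <- obj(theta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    fhat <- drop(H %*% theta[1:p]) + theta[p + 1L]
    xi <- pmax(0, 1 - ys * fhat)
    act <- xi > 0
    g <- c(theta[1:p], 0) - 2 * C * c(drop(crossprod(H, ys * xi)),
                                      sum(ys * xi))
    if (sqrt(sum(g^2)) < 1e-8 * max(1, sqrt(fcur))) {
      converged <- TRUE
      break
    }
    Ha <- cbind(H[act, , drop = FALSE], 1)
    Hess <- 2 * C * crossprod(Ha)
    diag(Hess) <- diag(Hess) + c(rep(1, p), 1e-10)
    step <- tryCatch(drop(solve(Hess, g)), error = function(e) g)
    t_ls <- 1
    repeat {
      fnew <- obj(theta - t_ls * step)
      if (fnew <= fcur - 1e-4 * t_ls * sum(g * step) || t_ls < 1e-8) break
      t_ls <- t_ls / 2
    }
    if (fnew >= fcur * (1 - 1e-12)) {
      theta <- theta - t_ls * step
      converged <- TRUE
      break
    }
    theta <- theta - t_ls * step
    fcur <- fnew
  }
  list(beta = theta[1:p], beta0 = theta[p + 1L], levels = lv, C = C,
       converged = converged)
}

svm_decision <- function(model, H) {
  drop(H %*% model$beta) + model$beta0
}

# Deterministic stratified fold assignment from a seed.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Fit the SVM readout with cross-validated regularization
#'
#' Trains the linear squared-hinge SVM readout on hidden-layer features,
#' selecting the regularization strength over a log-spaced grid in
#' `[1e-3, 1e3]` (7 values, decade resolution) by stratified 5-fold
#' cross-validation on the training set. Ties are broken toward the
#' smallest strength (strongest regularization); fold assignment is
#' deterministic given `seed`. Multiclass labels are handled one-vs-rest.
#'
#' @param H n x p training feature matrix.
#' @param y training labels (2 or more classes; at least 10 examples per
#'   class).
#' @param seed integer seed controlling fold assignment.
#' @param C_grid regularization grid (default `10^(-3:3)`).
#' @param folds number of CV folds.
#' @return an object of class `structrf_readout`: list with `beta`
#'   (p-vector, or p x K matrix one-vs-rest), `beta0`, `levels`, `C`
#'   (chosen strength), and `cv_table` (strength vs mean CV error).
#' @export
fit_readout <- function(H, y, seed = NULL, C_grid = 10^(-3:3), folds = 5) {
  if (is.null(dim(H))) H <- matrix(H, ncol = 1)
  lv <- sort(unique(y))
  if (length(lv) < 2L) stop("'y' has a single class")
  if (min(table(y)) < folds) stop("need at least 'folds' examples per class")
  fold <- stratified_folds(y, folds, seed)
  err_mat <- matrix(0, folds, length(C_grid))
  for (f in seq_len(folds)) {
    tr <- fold != f
    Htr <- H[tr, , drop = FALSE]
    Hte <- H[!tr, , drop = FALSE]
    init <- NULL # warm start along the regularization path within a fold
    for (ci in seq_along(C_grid)) {
      m <- fit_multiclass(Htr, y[tr], C_grid[ci], init = init)
      init <- m$theta
      err_mat[f, ci] <- mean(predict_multiclass(m, Hte) != y[!tr])
    }
  }
  cv_err <- colMeans(err_mat)
  best <- C_grid[which.min(cv_err)] # which.min takes the first = smallest C
  final <- fit_multiclass(H, y, best)
  structure(
    list(beta = final$beta, beta0 = final$beta0, levels = final$levels,
         C = best, cv_table = data.frame(C = C_grid, cv_error = cv_err)),
    class = "structrf_readout"
  )
}

# Binary fit, or one-vs-rest stack for >2 classes; `init` carries warm
# starts along the regularization path (a theta vector, or list per class).
fit_multiclass <- function(H, y, C, init = NULL) {
  lv <- sort(unique(y))
  if (length(lv) == 2L) {
    m <- svm_squared_hinge(H, y, C, init = init)
    return(list(beta = m$beta, beta0 = m$beta0, levels = lv, binary = TRUE,
                theta = c(m$beta, m$beta0)))
  }
  fits <- lapply(seq_along(lv), function(j) {
    svm_squared_hinge(H, ifelse(y == lv[j], "pos", "neg"), C,
                      init = if (is.list(init)) init[[j]] else NULL)
  })
  list(beta = vapply(fits, `[[`, numeric(ncol(H)), "beta"),
       beta0 = vapply(fits, `[[`, numeric(1), "beta0"),
       levels = lv, binary = FALSE,
       theta = lapply(fits, function(m) c(m$beta, m$beta0)))
}

predict_multiclass <- function(model, H) {
  if (model$binary %||% is.null(dim(model$beta))) {
    f <- drop(H %*% model$beta) + model$beta0
    model$levels[ifelse(f >= 0, 2L, 1L)]
  } else {
    scores <- sweep(H %*% model$beta, 2, model$beta0, "+")
    model$levels[max.col(scores, ties.method = "first")]
  }
}

#' @export
predict.structrf_readout <- function(object, newdata, ...) {
  m <- list(beta = object$beta, beta0 = object$beta0, levels = object$levels,
            binary = is.null(dim(object$beta)))
  predict_multiclass(m, newdata)
}
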