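#' Sample receptive-field weight banks from a covariance model
#'
#' Draws `m` i.i.d. rows `w ~ N(0, C)` via the Karhunen-Loeve construction
#' `w = Phi Lambda z` with `z ~ N(0, I)`. Sampling through the eigenbasis
#' (rather than a Cholesky factor) tolerates the rank-deficient covariances
#' that bandlimited models produce by design. The standard-normal stream is
#' consumed row by row, so increasing `m` with the same seed extends the
#' bank rather than reshuffling earlier draws.
#'
#' @param cov a `structrf_cov`.
#' @param m number of fields to draw (`m >= 1`).
#' @param seed integer seed; identical `(cov, m, seed)` gives bit-identical
#'   output.
#' @return an object of class `structrf_rfset`: list with `W` (m x d matrix,
#'   one receptive field per row), `grid`, and `provenance`.
#' @examples
#' cs <- build_sensilla_cov(grid_1d(200, 0.5), 10, 60, gamma = 50)
#' rfs <- sample_weights(cs, m = 5, seed = 1)
#' dim(rfs$W) # 5 200
#' @export
sample_weights <- function(cov, m, seed = NULL) {
  stopifnot(inherits(cov, "structrf_cov"))
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("'m' must be >= 1")
  e <- eigendecompose(cov)
  d <- nrow(cov$C)
  Z <- with_seed(seed, matrix(stats::rnorm(m * d), nrow = m, byrow = TRUE))
  W <- Z %*% (t(e$vectors) * sqrt(e$values)) # rows: (Phi Lambda z)^T
  new_rf_set(W, cov$grid,
             provenance = list(kind = "sampled", seed = seed,
                               params = cov$params))
}

new_rf_set <- function(W, grid, provenance = list(kind = "measured")) {
  if (!is.matrix(W) || nrow(W) < 1L) stop("'W' must be a matrix with >= 1 row")
  if (!is.null(grid) && ncol(W) != grid_size(grid)) {
    stop(sprintf("W has %d columns but the grid has %d points",
                 ncol(W), grid_size(grid)))
  }
  structure(list(W = W, grid = grid, provenance = provenance),
            class = "structrf_rfset")
}

#' Construct a receptive-field set from a matrix
#'
#' Wraps an m x d matrix of measured or externally produced receptive fields
#' (e.g. spike-triggered averages, one per row) together with its grid.
#'
#' @param W m x d matrix, one receptive field per row.
#' @param grid the [grid_1d()] or [grid_2d()] the columns live on.
#' @param provenance free-form provenance list.
#' @return a `structrf_rfset`.
#' @export
rf_set <- function(W, grid, provenance = list(kind = "measured")) {
  new_rf_set(W, grid, provenance)
}

#' @export
print.structrf_rfset <- function(x, ...) {
  cat(sprintf("Receptive-field set: %d fields x %d samples (%s)\n",
              nrow(x$W), ncol(x$W), x$provenance$kind %||% "unknown"))
  invisible(x)
}

#' Basis change of stimuli into the covariance eigenbasis
#'
#' Computes `x_tilde = Lambda Phi^T x` for each stimulus row: projection
#' onto the covariance eigenbasis followed by filtering with the eigenvalue
#' profile. Projecting a stimulus onto a structured weight `w ~ N(0, C)` is
#' distributed identically to projecting the transformed stimulus onto a
#' spherical Gaussian (`w^T x = z^T x_tilde`), so
#' `||x_tilde||^2 = x^T C x` and components of bandlimited covariances
#' outside the passband are exactly zero.
#'
#' @param cov a `structrf_cov`.
#' @param X stimulus matrix (n x d) or a single length-d vector.
#' @return n x d matrix of transformed stimuli.
#' @export
basis_change <- function(cov, X) {
  stopifnot(inherits(cov, "structrf_cov"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != nrow(cov$C)) {
    stop(sprintf("stimuli have %d columns but the covariance is %d x %d",
                 ncol(X), nrow(cov$C), nrow(cov$C)))
  }
  e <- eigendecompose(cov)
  sweep(X %*% e$vectors, 2, sqrt(e$values), "*")
}

#' Closed-form ReLU random-feature kernel (arc-cosine kernel, order 1)
#'
#' The infinite-width limit of `(1/m) sum_j relu(w_j^T x) relu(w_j^T x')`
#' for spherical Gaussian weights `w_j ~ N(0, I)`:
#' `k(x, x') = ||x|| ||x'|| / (2 pi) * (sin th + (pi - th) cos th)` with
#' `th` the angle between `x` and `x'`. Defined as 0 when either argument is
#' the zero vector.
#'
#' @param x,xp input vectors of equal length.
#' @return scalar kernel value.
#' @export
relu_arccos_kernel <- function(x, xp) {
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(xp^2))
  if (nx == 0 || ny == 0) return(0)
  cth <- sum(x * xp) / (nx * ny)
  cth <- min(1, max(-1, cth))
  th <- acos(cth)
  nx * ny / (2 * pi) * (sin(th) + (pi - th) * cth)
}

#' Effective kernel of a structured random feature network
#'
#' The structured ReLU random-feature kernel equals the unstructured
#' arc-cosine kernel evaluated on basis-changed inputs:
#' `k_struct(x, x') = k_unstruct(x_tilde, x_tilde')`.
#'
#' @inheritParams basis_change
#' @param x,xp input vectors of length d.
#' @return scalar kernel value.
#' @export
structured_kernel <- function(cov, x, xp) {
  xt <- basis_change(cov, rbind(x, xp))
  relu_arccos_kernel(xt[1, ], xt[2, ])
}

#' Empirical covariance of a receptive-field population
#'
#' `C_data = W^T W`, trace-normalized. No mean subtraction is performed: the
#' generative model is a zero-mean Gaussian process, so the data covariance
#' is the raw inner-product (second-moment) matrix of the fields.
#'
#' @param rfs a `structrf_rfset` with at least 2 fields.
#' @param trace_target trace normalization target (default d).
#' @return a `structrf_cov` with kind `"empirical"`.
#' @export
empirical_covariance <- function(rfs, trace_target = NULL) {
  stopifnot(inherits(rfs, "structrf_rfset"))
  if (nrow(rfs$W) < 2L) stop("need at least 2 receptive fields")
  C <- crossprod(rfs$W)
  if (all(C == 0)) stop("all-zero receptive fields: degenerate covariance")
  finish_cov(C, rfs$grid,
             list(kind = "empirical", m = nrow(rfs$W)),
             trace_target %||% ncol(rfs$W))
}
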