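#' Structured covariance models on discrete grids
#'
#' A covariance model couples a symmetric positive semidefinite matrix `C`
#' (d x d, where d is the grid size) with the grid it was evaluated on, the
#' generating parameters, and a lazily computed, cached eigendecomposition
#' `C = Phi Lambda^2 Phi^T`. Receptive fields are modeled as samples
#' `w ~ N(0, C)`; the eigenbasis is the Karhunen-Loeve basis in which
#' structured weights project and filter stimuli.
#'
#' Three families are provided:
#' * `build_stationary_cov()`: the stationary bandlimited model
#'   `C(t, t') = sum_k lambda_k^2 cos(omega_k (t - t'))`, with natural
#'   frequencies `omega_k = 2 pi k / L` and a flat unit spectrum on the
#'   passband unless per-harmonic weights are supplied. Its eigenbasis is the
#'   Fourier basis on `[0, L]`.
#' * `build_sensilla_cov()`: the locally stationary mechanosensor model,
#'   the stationary model multiplied by the separable decay
#'   `exp(-(t + t') / gamma)`; realizations are smooth, oscillatory,
#'   frequency-selective filters that decay away from stimulus onset, as in
#'   campaniform sensilla spike-triggered averages.
#' * `build_v1_cov()`: the localized image model
#'   `C(t, t') = exp(-||t - t'||^2 / (2 f^2)) *
#'   exp(-(||t - c||^2 + ||t' - c||^2) / (2 s^2))`
#'   whose realizations resemble V1 simple-cell receptive fields: smooth on
#'   the scale `f`, localized around the center `c` on the scale `s`.
#'
#' All constructors trace-normalize the returned matrix (default target
#' `Tr(C) = d`), which fixes the mean square weight amplitude
#' `E[||w||^2] = d` and makes covariances comparable across models.
#'
#' @name covariance_models
NULL

new_cov_model <- function(C, grid, params, eig = NULL) {
  cache <- new.env(parent = emptyenv())
  if (!is.null(eig)) cache$eig <- eig
  structure(
    list(C = C, grid = grid, params = params, cache = cache),
    class = "structrf_cov"
  )
}

#' @export
print.structrf_cov <- function(x, ...) {
  d <- nrow(x$C)
  cat(sprintf("Covariance model '%s': %d x %d, Tr = %.6g\n",
              x$params$kind, d, d, sum(diag(x$C))))
  pp <- x$params[setdiff(names(x$params), "kind")]
  pp <- pp[vapply(pp, function(v) is.numeric(v) && length(v) <= 2, logical(1))]
  if (length(pp)) {
    cat("  params:", paste(names(pp),
                           vapply(pp, function(v) paste(signif(v, 5), collapse = ","),
                                  character(1)),
                           sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# Harmonic indices k whose natural frequency k/L (Hz) falls in the inclusive
# band [f_lo, f_hi]. k = 0 (the constant term) enters only when f_lo == 0.
select_harmonics <- function(grid, f_lo, f_hi) {
  nf <- natural_frequencies(grid)
  eps <- 1e-9 * max(1, f_hi)
  keep <- nf$freq >= f_lo - eps & nf$freq <= f_hi + eps
  keep[nf$k == 0] <- keep[nf$k == 0] & f_lo <= eps
  nf$k[keep]
}

#' @rdname covariance_models
#' @param grid a [grid_1d()] (stationary, sensilla) or [grid_2d()] (V1).
#' @param f_lo,f_hi passband edges in Hz, `0 <= f_lo <= f_hi`; a harmonic
#'   `k` is included iff its natural frequency `k/L` lies in
#'   `[f_lo, f_hi]` (band edges inclusive).
#' @param weights optional nonnegative spectral weights `lambda_k^2`, one per
#'   selected harmonic (default: flat, all 1).
#' @param trace_target trace of the returned matrix (default `d`;
#'   use 2 for the fully-trained-network initialization convention).
#' @return an object of class `structrf_cov`.
#' @examples
#' g <- grid_1d(200, 0.5)
#' cs <- build_sensilla_cov(g, f_lo = 10, f_hi = 60, gamma = 50)
#' sum(diag(cs$C)) # 200
#' @export
build_stationary_cov <- function(grid, f_lo, f_hi, weights = NULL,
                                 trace_target = NULL) {
  if (!inherits(grid, "structrf_grid1d")) stop("stationary model needs a 1-D grid")
  check_band(grid, f_lo, f_hi)
  ks <- select_harmonics(grid, f_lo, f_hi)
  if (length(ks) == 0L) {
    stop(sprintf(paste0("empty passband: no natural frequency k/L falls in ",
                        "[%g, %g] Hz (grid resolution 1/L = %g Hz)"),
                 f_lo, f_hi, 1000 / grid$duration), call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, length(ks))
  if (length(weights) != length(ks) || any(weights < 0)) {
    stop(sprintf("'weights' must be %d nonnegative values (one per harmonic)",
                 length(ks)))
  }
  C <- stationary_cov_matrix(grid, ks, weights)
  params <- list(kind = "stationary", f_lo = f_lo, f_hi = f_hi,
                 harmonics = ks, weights = weights)
  finish_cov(C, grid, params, trace_target %||% grid$n)
}

check_band <- function(grid, f_lo, f_hi) {
  if (!is.numeric(f_lo) || !is.numeric(f_hi) || f_lo < 0 || f_hi < f_lo) {
    stop("need 0 <= f_lo <= f_hi")
  }
  nyq <- 1000 / (2 * grid$dt)
  if (f_lo > nyq) {
    stop(sprintf("passband [%g, %g] Hz lies beyond the Nyquist frequency %g Hz",
                 f_lo, f_hi, nyq))
  }
  invisible(TRUE)
}

stationary_cov_matrix <- function(grid, ks, weights) {
  L <- grid$duration / 1000
  tdiff <- outer(grid$times, grid$times, "-")
  C <- matrix(0, grid$n, grid$n)
  for (i in seq_along(ks)) {
    C <- C + weights[i] * cos(2 * pi * ks[i] / L * tdiff)
  }
  C
}

#' @rdname covariance_models
#' @param gamma decay constant in milliseconds; the separable factor
#'   `exp(-(t + t') / gamma)` localizes the fields near `t = 0`.
#' @export
build_sensilla_cov <- function(grid, f_lo, f_hi, gamma, weights = NULL,
                               trace_target = NULL) {
  if (!inherits(grid, "structrf_grid1d")) stop("sensilla model needs a 1-D grid")
  stopifnot_scalar_pos(gamma, "gamma")
  base <- build_stationary_cov(grid, f_lo, f_hi, weights, trace_target = NULL)
  env <- exp(-grid$times / (gamma / 1000))
  C <- base$C * tcrossprod(env) # exp(-(t + t')/gamma) = env(t) env(t')
  params <- base$params
  params$kind <- "sensilla"
  params$gamma <- gamma
  finish_cov(C, grid, params, trace_target %||% grid$n)
}

#' @rdname covariance_models
#' @param s receptive-field size in pixels (`s > 0`).
#' @param f spatial-frequency bandwidth in pixels (`f > 0`); smaller `f`
#'   gives higher spatial frequency content.
#' @param center length-2 field center, 0-based `(row, col)`; defaults to
#'   the grid center `floor(c(height, width) / 2)`.
#' @export
build_v1_cov <- function(grid, s, f, center = NULL, trace_target = NULL) {
  if (!inherits(grid, "structrf_grid2d")) stop("V1 model needs a 2-D grid")
  stopifnot_scalar_pos(s, "s")
  stopifnot_scalar_pos(f, "f")
  center <- center %||% grid$center
  check_center(grid, center)
  d2 <- pixel_sqdist(grid$coords)
  r2 <- (grid$coords[, 1] - center[1])^2 + (grid$coords[, 2] - center[2])^2
  env <- exp(-r2 / (2 * s^2))
  C <- exp(-d2 / (2 * f^2)) * tcrossprod(env)
  params <- list(kind = "v1", s = s, f = f, center = center)
  finish_cov(C, grid, params, trace_target %||% grid$n)
}

check_center <- function(grid, center) {
  if (length(center) != 2 ||
      center[1] < 0 || center[1] > grid$height - 1 ||
      center[2] < 0 || center[2] > grid$width - 1) {
    stop(sprintf("center (%s) outside the %d x %d grid",
                 paste(center, collapse = ", "), grid$height, grid$width))
  }
  invisible(TRUE)
}

pixel_sqdist <- function(coords) {
  outer(coords[, 1], coords[, 1], "-")^2 +
    outer(coords[, 2], coords[, 2], "-")^2
}

#' Null covariance models
#'
#' Reference models used as controls in covariance fitting:
#' `"unstructured"` is the identity (spherical Gaussian weights, i.e. white
#' noise receptive fields); `"fourier"` is the stationary bandlimited model
#' without the temporal decay; `"v1_translation_invariant"` drops the
#' spatially localizing factor of the V1 model, leaving the translation
#' invariant kernel `exp(-||t - t'||^2 / (2 f^2))`.
#'
#' @param kind one of `"unstructured"`, `"fourier"`,
#'   `"v1_translation_invariant"`.
#' @param grid the grid (1-D for fourier; any for unstructured; 2-D for the
#'   translation-invariant V1 model).
#' @param f_lo,f_hi passband (fourier only).
#' @param f spatial bandwidth in pixels (v1_translation_invariant only).
#' @inheritParams covariance_models
#' @export
build_null_cov <- function(kind = c("unstructured", "fourier",
                                    "v1_translation_invariant"),
                           grid, f_lo = NULL, f_hi = NULL, f = NULL,
                           trace_target = NULL) {
  kind <- match.arg(kind)
  if (kind == "unstructured") {
    d <- grid_size(grid)
    return(finish_cov(diag(d), grid, list(kind = "unstructured"),
                      trace_target %||% d))
  }
  if (kind == "fourier") {
    if (is.null(f_lo) || is.null(f_hi)) stop("fourier null model needs f_lo, f_hi")
    m <- build_stationary_cov(grid, f_lo, f_hi, trace_target = trace_target)
    m$params$kind <- "fourier"
    return(m)
  }
  if (!inherits(grid, "structrf_grid2d")) {
    stop("v1_translation_invariant needs a 2-D grid")
  }
  stopifnot_scalar_pos(f, "f")
  C <- exp(-pixel_sqdist(grid$coords) / (2 * f^2))
  finish_cov(C, grid, list(kind = "v1_translation_invariant", f = f),
             trace_target %||% grid$n)
}

finish_cov <- function(C, grid, params, trace_target) {
  model <- new_cov_model(C, grid, params)
  if (!is.null(trace_target)) model <- normalize_trace(model, trace_target)
  model
}

#' Rescale a covariance model to a target trace
#'
#' Multiplies the matrix by `target / Tr(C)`, rescaling any cached
#' eigenvalues consistently (eigenvectors are unchanged). The default
#' convention `Tr(C) = d` puts structured and unstructured weights on equal
#' footing (`E[||w||^2] = d`); `Tr(C) = 2` matches the Kaiming-style
#' initialization scale used for fully trained networks.
#'
#' @param model a `structrf_cov`.
#' @param target positive target trace.
#' @return the rescaled model.
#' @export
normalize_trace <- function(model, target) {
  stopifnot(inherits(model, "structrf_cov"))
  stopifnot_scalar_pos(target, "target")
  tr <- sum(diag(model$C))
  if (!is.finite(tr) || tr <= 0) stop("covariance trace must be positive")
  scale <- target / tr
  eig <- model$cache$eig
  out <- new_cov_model(model$C * scale, model$grid, model$params)
  if (!is.null(eig)) {
    eig$values <- eig$values * scale
    out$cache$eig <- eig
  }
  out$params$trace <- target
  out
}

#' Eigendecomposition of a covariance model
#'
#' Returns (and caches on the model) the eigendecomposition
#' `C = Phi Lambda^2 Phi^T` with eigenvalues sorted descending. Small
#' negative eigenvalues from floating point (above `-tol * lambda_max`) are
#' clipped to zero with a warning; anything more negative is an error, since
#' a genuinely indefinite matrix is not a covariance. Eigenvector signs are
#' fixed so the largest-magnitude entry of each column is positive, making
#' spectral reports reproducible across LAPACK builds.
#'
#' @param model a `structrf_cov`, or a plain symmetric matrix.
#' @param tol relative clipping tolerance for negative eigenvalues.
#' @return list with `vectors` (d x d orthonormal columns `Phi`) and
#'   `values` (the d eigenvalues `lambda_i^2`, descending).
#' @export
eigendecompose <- function(model, tol = 1e-8) {
  if (inherits(model, "structrf_cov")) {
    cached <- model$cache$eig
    if (!is.null(cached)) return(cached)
    C <- model$C
  } else {
    C <- model
  }
  if (!is.matrix(C) || nrow(C) != ncol(C)) stop("need a square matrix")
  asym <- max(abs(C - t(C)))
  if (asym > 1e-8 * max(1, max(abs(C)))) {
    stop(sprintf("matrix is asymmetric beyond tolerance (max |C - C^T| = %g)", asym))
  }
  e <- eigen((C + t(C)) / 2, symmetric = TRUE)
  lam <- e$values
  lmax <- max(lam, 0)
  bad <- lam < -tol * max(lmax, .Machine$double.eps)
  if (any(bad)) {
    stop(sprintf("matrix has a large negative eigenvalue (%g); not a covariance",
                 min(lam)))
  }
  if (any(lam < 0)) {
    lam[lam < 0] <- 0
  }
  vec <- fix_eigvec_signs(e$vectors)
  out <- list(vectors = vec, values = lam)
  if (inherits(model, "structrf_cov")) model$cache$eig <- out
  out
}

fix_eigvec_signs <- function(V) {
  piv <- apply(abs(V), 2, which.max)
  signs <- sign(V[cbind(piv, seq_len(ncol(V)))])
  signs[signs == 0] <- 1
  sweep(V, 2, signs, "*")
}

#' Analytic Hermite-wavelet eigenbasis of the V1 covariance
#'
#' The localized V1 covariance has a closed-form eigensystem: single-scale
#' Hermite wavelets. Writing `a = 1/(2 s^2)`, `b = 1/(2 f^2)` and
#' `c1 = sqrt(a^2 + 2 a b)`, the 1-D eigenfunctions are
#' `phi_k(t) = exp(-c1 t^2) H_k(c2 t)` with `c2 = sqrt(2 c1)` and physicist's
#' Hermite polynomials `H_k`; the eigenvalues decay geometrically with ratio
#' `c3 = b / (a + b + c1)`. In two dimensions the eigenfunctions are products
#' over the two axes indexed by a multi-index `(k1, k2)` with eigenvalue
#' proportional to `c3^(k1 + k2)`; a nonzero center just shifts the
#' functions. This closed form follows from Mehler's expansion of the
#' Gaussian kernel with a Gaussian localizer, the product structure of the
#' covariance, and is validated in the test suite against the numerical
#' eigendecomposition of [build_v1_cov()].
#'
#' Returned eigenfunctions are evaluated on the pixel grid and normalized to
#' unit grid norm; eigenvalues are normalized to sum to one over the
#' returned set. Because the continuous eigenfunctions are restricted to a
#' finite pixel lattice, they match the numerical eigenvectors only up to
#' discretization error, which grows with order `k1 + k2`.
#'
#' @inheritParams build_v1_cov
#' @param k_max number of leading eigenfunctions to return (at most `d`).
#' @return list with `functions` (d x k_max matrix, one eigenfunction per
#'   column), `values` (length-k_max eigenvalues, descending, summing to 1),
#'   `indices` (k_max x 2 multi-indices) and `constants`
#'   (`c1`, `c2`, `c3`).
#' @export
hermite_eigenbasis <- function(grid, s, f, center = NULL, k_max = 10) {
  if (!inherits(grid, "structrf_grid2d")) stop("need a 2-D grid")
  stopifnot_scalar_pos(s, "s")
  stopifnot_scalar_pos(f, "f")
  if (k_max > grid$n) stop("k_max exceeds the grid size")
  center <- center %||% grid$center
  check_center(grid, center)

  a <- 1 / (2 * s^2)
  b <- 1 / (2 * f^2)
  c1 <- sqrt(a^2 + 2 * a * b)
  c2 <- sqrt(2 * c1)
  c3 <- b / (a + b + c1)

  # enumerate multi-indices by total order (eigenvalue c3^(k1+k2) is
  # decreasing in total order); within an order, by k1 for determinism
  orders <- 0L
  while (sum(seq_len(orders + 1L)) < k_max) orders <- orders + 1L
  idx <- do.call(rbind, lapply(0:orders, function(o) cbind(k1 = 0:o, k2 = o - (0:o))))
  idx <- idx[seq_len(k_max), , drop = FALSE]

  x <- grid$coords[, 1] - center[1]
  y <- grid$coords[, 2] - center[2]
  max_k <- max(idx)
  Hx <- hermite_values(c2 * x, max_k)
  Hy <- hermite_values(c2 * y, max_k)
  gx <- exp(-c1 * x^2)
  gy <- exp(-c1 * y^2)
  fun <- matrix(0, grid$n, k_max)
  for (j in seq_len(k_max)) {
    v <- gx * Hx[, idx[j, 1] + 1L] * gy * Hy[, idx[j, 2] + 1L]
    nv <- sqrt(sum(v^2))
    if (nv > 0) v <- v / nv
    fun[, j] <- v
  }
  vals <- c3^(idx[, 1] + idx[, 2])
  list(functions = fun, values = vals / sum(vals), indices = idx,
       constants = c(c1 = c1, c2 = c2, c3 = c3))
}

# Physicist's Hermite polynomials H_0..H_k evaluated at x (three-term
# recurrence H_{n+1} = 2 x H_n - 2 n H_{n-1}); columns are orders 0..k.
hermite_values <- function(x, k) {
  H <- matrix(0, length(x), k + 1L)
  H[, 1] <- 1
  if (k >= 1) H[, 2] <- 2 * x
  if (k >= 2) {
    for (n in 1:(k - 1L)) {
      H[, n + 2L] <- 2 * x * H[, n + 1L] - 2 * n * H[, n]
    }
  }
  H
}
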