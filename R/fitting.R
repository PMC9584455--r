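#' Center receptive fields at the grid center
#'
#' Translates each 2-D field so that the center of mass of its energy
#' (squared magnitude) sits at the grid center, using nearest-integer pixel
#' shifts with zero padding (no interpolation, so measured fields are not
#' smoothed). All-zero fields are left in place with a warning. This is the
#' preprocessing applied to V1 populations before fitting the localized
#' covariance model, which then holds the center parameter fixed.
#'
#' @param rfs a `structrf_rfset` on a [grid_2d()].
#' @return the centered `structrf_rfset`.
#' @export
center_receptive_fields <- function(rfs) {
  stopifnot(inherits(rfs, "structrf_rfset"))
  grid <- rfs$grid
  if (!inherits(grid, "structrf_grid2d")) stop("centering needs a 2-D grid")
  h <- grid$height
  w <- grid$width
  ctr <- grid$center
  W <- rfs$W
  zero <- FALSE
  for (i in seq_len(nrow(W))) {
    field <- matrix(W[i, ], nrow = h, byrow = TRUE)
    energy <- field^2
    tot <- sum(energy)
    if (tot == 0) {
      zero <- TRUE
      next
    }
    com <- c(sum(rowSums(energy) * (0:(h - 1))),
             sum(colSums(energy) * (0:(w - 1)))) / tot
    shift <- ctr - round(com)
    W[i, ] <- as.vector(t(shift_matrix(field, shift[1], shift[2])))
  }
  if (zero) warning("all-zero field(s) left unshifted")
  rfs$W <- W
  rfs$provenance$centered <- TRUE
  rfs
}

shift_matrix <- function(M, dr, dc) {
  h <- nrow(M)
  w <- ncol(M)
  out <- matrix(0, h, w)
  src_r <- seq_len(h) - dr
  src_c <- seq_len(w) - dc
  ok_r <- src_r >= 1 & src_r <= h
  ok_c <- src_c >= 1 & src_c <= w
  out[which(ok_r), which(ok_c)] <- M[src_r[ok_r], src_c[ok_c], drop = FALSE]
  out
}

#' Normalized Frobenius distance between covariance matrices
#'
#' `||C_data - C_model||_F / ||C_data||_F`: 0 for a perfect fit, exactly 1
#' for the zero model. Both matrices should be normalized to the same trace
#' before comparison (the constructors' default trace-d normalization
#' takes care of this).
#'
#' @param C_data,C_model `structrf_cov` objects or plain matrices of the
#'   same shape.
#' @return nonnegative scalar.
#' @export
frobenius_distance <- function(C_data, C_model) {
  A <- if (inherits(C_data, "structrf_cov")) C_data$C else C_data
  B <- if (inherits(C_model, "structrf_cov")) C_model$C else C_model
  if (!all(dim(A) == dim(B))) stop("matrices have different shapes")
  norm(A - B, "F") / norm(A, "F")
}

#' Fit covariance-model parameters to a data covariance
#'
#' Minimizes the normalized Frobenius distance between a (trace-normalized)
#' data covariance and a parametric covariance model.
#'
#' For the temporal models (`"sensilla"`, `"fourier"`) the passband enters
#' only through which natural frequencies `k/L` it includes, so the band
#' edges are searched directly over the grid's natural frequencies (every
#' admissible harmonic interval is evaluated - an exhaustive search over
#' the discrete part of the parameter space); the decay constant `gamma` is
#' searched on a log-spaced grid and then polished by golden-section
#' refinement at the best band. For `"v1"` a log-spaced coarse grid over
#' `(s, f)` is followed by Nelder-Mead refinement in log-parameter space,
#' with the center held fixed at the grid center (data are assumed
#' pre-centered with [center_receptive_fields()]). `"unstructured"` has no
#' parameters and just reports the distance to the identity model.
#'
#' @param C_data a `structrf_cov` (e.g. from [empirical_covariance()]);
#'   its grid supplies the natural frequencies / pixel lattice.
#' @param kind model family: `"sensilla"`, `"fourier"`, `"v1"`,
#'   `"v1_translation_invariant"`, or `"unstructured"`.
#' @param band_max upper bound (Hz) on candidate band edges (temporal
#'   models); defaults to the Nyquist frequency.
#' @param gamma_range search range for `gamma` in ms (sensilla), default
#'   `c(1, duration)`.
#' @param sf_range search range in pixels for both `s` and `f` (V1),
#'   default `c(0.2, 20)`.
#' @param n_grid coarse-grid resolution per continuous parameter.
#' @return an object of class `structrf_fit`: list with `kind`, `par`
#'   (named best parameters), `distance`, `model` (the fitted
#'   `structrf_cov`) and `trace` (data frame of all evaluations).
#' @export
fit_covariance_params <- function(C_data,
                                  kind = c("sensilla", "fourier", "v1",
                                           "v1_translation_invariant",
                                           "unstructured"),
                                  band_max = NULL, gamma_range = NULL,
                                  sf_range = c(0.2, 20), n_grid = 15) {
  stopifnot(inherits(C_data, "structrf_cov"))
  kind <- match.arg(kind)
  grid <- C_data$grid
  d <- grid_size(grid)
  Cd <- C_data$C * (d / sum(diag(C_data$C)))
  nCd <- norm(Cd, "F")

  if (kind == "unstructured") {
    model <- build_null_cov("unstructured", grid)
    dist <- norm(Cd - model$C, "F") / nCd
    return(new_fit(kind, list(), dist, model,
                   data.frame(distance = dist)))
  }
  if (kind == "v1" || kind == "v1_translation_invariant") {
    return(fit_v1_family(Cd, nCd, grid, kind, sf_range, n_grid))
  }
  fit_temporal_family(Cd, nCd, grid, kind, band_max, gamma_range, n_grid)
}

new_fit <- function(kind, par, distance, model, trace) {
  structure(list(kind = kind, par = par, distance = distance, model = model,
                 trace = trace),
            class = "structrf_fit")
}

#' @export
print.structrf_fit <- function(x, ...) {
  cat(sprintf("Covariance fit '%s': distance = %.4f\n", x$kind, x$distance))
  if (length(x$par)) {
    cat("  ", paste(names(x$par), signif(unlist(x$par), 5), sep = " = ",
                    collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Temporal (sensilla / fourier) fit: exhaustive over harmonic intervals,
# grid + golden-section over gamma.
fit_temporal_family <- function(Cd, nCd, grid, kind, band_max, gamma_range,
                                n_grid) {
  if (!inherits(grid, "structrf_grid1d")) stop("temporal fit needs a 1-D grid")
  d <- grid$n
  L <- grid$duration / 1000
  band_max <- band_max %||% (1000 / (2 * grid$dt))
  k_max <- min(floor(d / 2), floor(band_max * L + 1e-9))
  if (k_max < 1) stop("empty search space: no harmonic below 'band_max'")
  tdiff <- outer(grid$times, grid$times, "-")
  # cumulative harmonic sums: Scum[[k]] = sum_{j<=k} cos(omega_j (t - t'))
  Scum <- vector("list", k_max)
  acc <- matrix(0, d, d)
  for (k in seq_len(k_max)) {
    acc <- acc + cos(2 * pi * k / L * tdiff)
    Scum[[k]] <- acc
  }
  bands <- do.call(rbind, lapply(seq_len(k_max), function(k1) {
    cbind(k1 = k1, k2 = k1:k_max)
  }))

  band_dist <- function(Emat) {
    # distance for every band, given an envelope matrix (or NULL)
    vapply(seq_len(nrow(bands)), function(b) {
      k1 <- bands[b, 1]
      k2 <- bands[b, 2]
      S <- Scum[[k2]] - if (k1 > 1) Scum[[k1 - 1]] else 0
      M <- if (is.null(Emat)) S else Emat * S
      M <- M * (d / sum(diag(M)))
      norm(Cd - M, "F") / nCd
    }, numeric(1))
  }

  if (kind == "fourier") {
    dists <- band_dist(NULL)
    best <- which.min(dists)
    par <- list(f_lo = unname(bands[best, 1]) / L,
                f_hi = unname(bands[best, 2]) / L)
    model <- build_stationary_cov(grid, par$f_lo, par$f_hi)
    model$params$kind <- "fourier"
    trace <- data.frame(f_lo = bands[, 1] / L, f_hi = bands[, 2] / L,
                        distance = dists)
    return(new_fit(kind, par, dists[best], model, trace))
  }

  gamma_range <- gamma_range %||% c(1, grid$duration)
  gammas <- exp(seq(log(gamma_range[1]), log(gamma_range[2]),
                    length.out = n_grid))
  env_for <- function(gamma_ms) {
    ev <- exp(-grid$times / (gamma_ms / 1000))
    tcrossprod(ev)
  }
  trace <- list()
  best <- list(dist = Inf)
  for (g in gammas) {
    dists <- band_dist(env_for(g))
    trace[[length(trace) + 1L]] <-
      data.frame(f_lo = bands[, 1] / L, f_hi = bands[, 2] / L, gamma = g,
                 distance = dists)
    i <- which.min(dists)
    if (dists[i] < best$dist) {
      best <- list(dist = dists[i], k1 = unname(bands[i, 1]),
                   k2 = unname(bands[i, 2]), gamma = g)
    }
  }
  # polish gamma at the best band over the bracketing grid interval
  gi <- which.min(abs(gammas - best$gamma))
  lo <- gammas[max(1, gi - 1L)]
  hi <- gammas[min(length(gammas), gi + 1L)]
  k1 <- best$k1
  k2 <- best$k2
  S <- Scum[[k2]] - if (k1 > 1) Scum[[k1 - 1]] else 0
  obj <- function(g) {
    M <- env_for(g) * S
    M <- M * (d / sum(diag(M)))
    norm(Cd - M, "F") / nCd
  }
  opt <- stats::optimize(obj, lower = lo, upper = hi, tol = 1e-10)
  gamma_best <- if (opt$objective < best$dist) opt$minimum else best$gamma
  dist_best <- min(opt$objective, best$dist)
  # golden-section accuracy is limited to ~sqrt(eps); the squared distance
  # is locally parabolic in gamma, so a few parabolic-vertex steps push a
  # perfect fit down to numerical zero
  for (i in 1:3) {
    h <- max(1e-7 * gamma_best, 1e-10) * 10^(1 - i)
    f0 <- obj(gamma_best)^2
    fm <- obj(gamma_best - h)^2
    fp <- obj(gamma_best + h)^2
    denom <- fm - 2 * f0 + fp
    if (denom <= 0) break
    cand <- gamma_best + h * (fm - fp) / (2 * denom)
    if (obj(cand) < dist_best) {
      gamma_best <- cand
      dist_best <- obj(cand)
    }
  }
  par <- list(f_lo = k1 / L, f_hi = k2 / L, gamma = gamma_best)
  model <- build_sensilla_cov(grid, par$f_lo, par$f_hi, par$gamma)
  new_fit(kind, par, dist_best, model, do.call(rbind, trace))
}

fit_v1_family <- function(Cd, nCd, grid, kind, sf_range, n_grid) {
  if (!inherits(grid, "structrf_grid2d")) stop("V1 fit needs a 2-D grid")
  d <- grid$n
  d2 <- pixel_sqdist(grid$coords)
  r2 <- (grid$coords[, 1] - grid$center[1])^2 +
    (grid$coords[, 2] - grid$center[2])^2
  ti_only <- kind == "v1_translation_invariant"
  build <- function(s, f) {
    M <- exp(-d2 / (2 * f^2))
    if (!ti_only) M <- M * tcrossprod(exp(-r2 / (2 * s^2)))
    M * (d / sum(diag(M)))
  }
  obj <- function(s, f) norm(Cd - build(s, f), "F") / nCd
  vals <- exp(seq(log(sf_range[1]), log(sf_range[2]), length.out = n_grid))
  if (ti_only) {
    dists <- vapply(vals, function(f) obj(1, f), numeric(1))
    i <- which.min(dists)
    opt <- stats::optimize(function(f) obj(1, f),
                           lower = vals[max(1, i - 1)],
                           upper = vals[min(length(vals), i + 1)])
    f_best <- if (opt$objective < dists[i]) opt$minimum else vals[i]
    dist <- min(opt$objective, dists[i])
    model <- build_null_cov("v1_translation_invariant", grid, f = f_best)
    return(new_fit(kind, list(f = f_best), dist, model,
                   data.frame(f = vals, distance = dists)))
  }
  grid_pts <- expand.grid(s = vals, f = vals)
  dists <- mapply(obj, grid_pts$s, grid_pts$f)
  i <- which.min(dists)
  start <- log(c(grid_pts$s[i], grid_pts$f[i]))
  polish <- stats::optim(start, function(p) obj(exp(p[1]), exp(p[2])),
                         method = "Nelder-Mead",
                         control = list(reltol = 1e-8, maxit = 300))
  if (polish$value < dists[i]) {
    par <- list(s = exp(polish$par[1]), f = exp(polish$par[2]))
    dist <- polish$value
  } else {
    par <- list(s = grid_pts$s[i], f = grid_pts$f[i])
    dist <- dists[i]
  }
  model <- build_v1_cov(grid, par$s, par$f)
  new_fit(kind, par, dist, model,
          cbind(grid_pts, distance = dists))
}

#' Finite-sample model covariance
#'
#' Empirical covariance of `m` fresh fields sampled from a covariance model
#' - the model's prediction for what a dataset of `m` recorded neurons
#' would look like. Small `m` reproduces the bumpy finite-sample structure
#' seen in measured covariances; the distance to the ideal model shrinks as
#' `m^(-1/2)`.
#'
#' @param cov a `structrf_cov`.
#' @param m number of sampled fields (>= 2).
#' @param seed integer seed.
#' @return a `structrf_cov` labeled kind `"finite"`.
#' @export
finite_sample_covariance <- function(cov, m, seed = NULL) {
  out <- empirical_covariance(sample_weights(cov, m, seed = seed))
  out$params$kind <- "finite"
  out$params$m <- m
  out
}

#' Spectral comparison of data, model, and finite-sample covariances
#'
#' Normalizes each covariance to unit trace (so eigenvalue curves sum to 1
#' and are directly comparable), extracts full eigenvalue curves and the
#' top-k eigenvectors, computes the variance explained by the leading data
#' eigenvectors, and measures principal angles between the leading-k
#' subspaces of data vs model (and finite model if given). Subspace angles
#' rather than vector-by-vector matching are used because near-degenerate
#' eigenvalues permute and rotate freely.
#'
#' @param C_data,C_model `structrf_cov` objects or matrices.
#' @param C_finite optional finite-sample model covariance.
#' @param k number of leading eigenvectors/subspace dimensions.
#' @return an object of class `structrf_spectral`: eigenvalue curves
#'   (`values`, each summing to 1), `vectors` (top-k of each), cumulative
#'   `variance_explained` of the data, and `principal_angles` (radians).
#' @export
spectral_compare <- function(C_data, C_model, C_finite = NULL, k = 5) {
  mats <- list(data = C_data, model = C_model)
  if (!is.null(C_finite)) mats$finite <- C_finite
  mats <- lapply(mats, function(x) {
    M <- if (inherits(x, "structrf_cov")) x$C else x
    M / sum(diag(M))
  })
  d <- nrow(mats$data)
  if (k > d) stop("k exceeds the matrix dimension")
  eigs <- lapply(mats, eigendecompose)
  values <- lapply(eigs, `[[`, "values")
  vectors <- lapply(eigs, function(e) e$vectors[, seq_len(k), drop = FALSE])
  angles <- lapply(vectors[-1], function(V) {
    principal_angles(vectors$data, V)
  })
  structure(
    list(values = values, vectors = vectors,
         variance_explained = cumsum(values$data),
         principal_angles = angles, k = k),
    class = "structrf_spectral"
  )
}

#' @export
print.structrf_spectral <- function(x, ...) {
  cat(sprintf("Spectral report (top %d):\n", x$k))
  cat(sprintf("  data variance explained by top %d: %.1f%%\n", x$k,
              100 * x$variance_explained[x$k]))
  for (nm in names(x$principal_angles)) {
    cat(sprintf("  max principal angle data vs %s: %.2f deg\n", nm,
                max(x$principal_angles[[nm]]) * 180 / pi))
  }
  invisible(x)
}

#' Principal angles between column subspaces
#'
#' @param U,V matrices with the same number of rows; orthonormalized
#'   internally via QR.
#' @return angles in radians, ascending, length `min(ncol(U), ncol(V))`.
#' @export
principal_angles <- function(U, V) {
  qu <- qr.Q(qr(U))
  qv <- qr.Q(qr(V))
  sv <- svd(crossprod(qu, qv))$d
  acos(pmin(1, pmax(-1, sv)))
}
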