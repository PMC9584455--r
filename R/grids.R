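#' Discrete stimulus grids
#'
#' Receptive fields and stimuli live on regular discretizations of a compact
#' domain: a time interval `[0, L]` sampled at `n` equally spaced points for
#' timeseries, or an integer pixel lattice for images. Public units are
#' milliseconds and Hz; pixel coordinates are 0-based with the field
#' flattened row-major (row index varies slowest).
#'
#' @param n_samples number of time samples (at least 2).
#' @param dt time step in milliseconds.
#' @return `grid_1d()` returns an object of class `structrf_grid1d` with
#'   elements `n`, `dt` (ms), `duration` (ms) and `times` (seconds).
#' @examples
#' g <- grid_1d(200, 0.5)   # 100 ms at 2 kHz
#' g$duration               # 100
#' @export
grid_1d <- function(n_samples, dt) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 2L) stop("'n_samples' must be >= 2")
  stopifnot_scalar_pos(dt, "dt")
  structure(
    list(
      n = n_samples,
      dt = dt,
      duration = n_samples * dt,
      # internal computations use seconds
      times = (seq_len(n_samples) - 1) * dt / 1000
    ),
    class = "structrf_grid1d"
  )
}

#' @rdname grid_1d
#' @param height,width pixel counts of the image lattice.
#' @return `grid_2d()` returns an object of class `structrf_grid2d` with
#'   elements `height`, `width`, `n` (= height * width), `coords`
#'   (n x 2 matrix of 0-based (row, col) pixel coordinates in row-major
#'   flattening order) and `center` (the default field center,
#'   `floor(c(height, width) / 2)`).
#' @export
grid_2d <- function(height, width) {
  height <- as.integer(height)
  width <- as.integer(width)
  if (is.na(height) || height < 1L || is.na(width) || width < 1L) {
    stop("'height' and 'width' must be >= 1")
  }
  coords <- cbind(
    row = rep(0:(height - 1L), each = width),
    col = rep(0:(width - 1L), times = height)
  )
  structure(
    list(
      height = height,
      width = width,
      n = height * width,
      coords = coords,
      center = c(floor(height / 2), floor(width / 2))
    ),
    class = "structrf_grid2d"
  )
}

#' @export
print.structrf_grid1d <- function(x, ...) {
  cat(sprintf("1-D grid: %d samples, dt = %g ms (%g ms at %g kHz)\n",
              x$n, x$dt, x$duration, 1 / x$dt))
  invisible(x)
}

#' @export
print.structrf_grid2d <- function(x, ...) {
  cat(sprintf("2-D pixel grid: %d x %d (d = %d), row-major\n",
              x$height, x$width, x$n))
  invisible(x)
}

grid_size <- function(grid) {
  if (inherits(grid, "structrf_grid1d") || inherits(grid, "structrf_grid2d")) {
    return(grid$n)
  }
  stop("not a structrf grid object")
}

# Natural (Fourier series) frequencies of a 1-D grid in Hz: f_k = k / L.
natural_frequencies <- function(grid, k_max = NULL) {
  L <- grid$duration / 1000 # seconds
  if (is.null(k_max)) k_max <- floor(grid$n / 2)
  k <- 0:k_max
  data.frame(k = k, freq = k / L)
}
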