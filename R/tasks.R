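#' Synthetic timeseries benchmark tasks
#'
#' Generators for the frequency-detection and frequency-XOR benchmarks:
#' binary classification of short noisy timeseries (by default 100 ms
#' sampled at 2 kHz, d = 200).
#'
#' *Detection*: positives are sinusoids `A sin(2 pi f1 t + phi)` with phase
#' `phi ~ Uniform[0, 2 pi)` plus white Gaussian noise at a power-ratio SNR
#' (default 1.76, i.e. 2.46 dB); negatives are white Gaussian noise whose
#' expected power matches the expected total power of the positives. The
#' random phase makes the task not linearly separable in the raw samples.
#'
#' *XOR*: four equal subclasses - pure `f1` and pure `f2` tones (label 1),
#' the `f1 + f2` mixture with independent random phases and white noise
#' (label 0). Tonal subclasses are corrupted at the same SNR; the noise
#' subclass is power-matched to the pure-tone subclasses.
#'
#' SNR is a power ratio: signal power divided by noise power, so with unit
#' amplitude (signal power `A^2/2`) the per-sample noise variance is
#' `A^2 / (2 snr)`. The mixture carries both components at amplitude `A`
#' (signal power `A^2`) with noise variance `A^2 / snr`.
#'
#' @param n_per_class examples per class (detection) or per subclass (XOR).
#' @param f1,f2 tone frequencies in Hz (below Nyquist; `f1 != f2` for XOR).
#' @param snr signal-to-noise power ratio (> 0).
#' @param amplitude sinusoid amplitude `A` (the overall scale is irrelevant
#'   to an SVM readout with tuned regularization).
#' @param grid the stimulus grid; default 100 ms at 2 kHz.
#' @param seed integer seed; generation is exactly reproducible.
#' @param keep_signal if `TRUE`, store the noiseless signal component in
#'   `meta$signal` (used for empirical SNR checks).
#' @return an object of class `structrf_dataset`: list with `X` (n x d),
#'   `y` (0/1 labels), and `meta` (task name, frequencies, snr, seed,
#'   per-row `subclass`).
#' @examples
#' ds <- gen_frequency_detection(10, seed = 1)
#' table(ds$y)
#' @export
gen_frequency_detection <- function(n_per_class, f1 = 50, snr = 1.76,
                                    amplitude = 1,
                                    grid = grid_1d(200, 0.5), seed = NULL,
                                    keep_signal = FALSE) {
  check_tone(grid, f1)
  if (!is.numeric(snr) || snr <= 0) stop("'snr' must be a positive power ratio")
  n <- as.integer(n_per_class)
  d <- grid$n
  tt <- grid$times
  sigma2 <- amplitude^2 / (2 * snr)           # noise variance, positives
  neg_sd <- sqrt(amplitude^2 / 2 + sigma2)    # power-matched negatives
  out <- with_seed(seed, {
    phi <- stats::runif(n, 0, 2 * pi)
    S <- amplitude * sin(outer(phi, 2 * pi * f1 * tt, "+"))
    Xpos <- S + matrix(stats::rnorm(n * d, sd = sqrt(sigma2)), n, d)
    Xneg <- matrix(stats::rnorm(n * d, sd = neg_sd), n, d)
    list(S = S, X = rbind(Xpos, Xneg))
  })
  meta <- list(task = "frequency_detection", f1 = f1, snr = snr,
               amplitude = amplitude, seed = seed,
               subclass = rep(c("tone", "noise"), each = n))
  if (keep_signal) meta$signal <- rbind(out$S, matrix(0, n, d))
  new_dataset(out$X, rep(c(1L, 0L), each = n), grid, meta)
}

check_tone <- function(grid, f) {
  nyq <- 1000 / (2 * grid$dt)
  if (!is.numeric(f) || f <= 0 || f >= nyq) {
    stop(sprintf("tone frequency %g Hz must lie in (0, Nyquist = %g Hz)", f, nyq))
  }
  invisible(TRUE)
}

#' @rdname gen_frequency_detection
#' @export
gen_frequency_xor <- function(n_per_class, f1 = 50, f2 = 80, snr = 1.76,
                              amplitude = 1,
                              grid = grid_1d(200, 0.5), seed = NULL,
                              keep_signal = FALSE) {
  check_tone(grid, f1)
  check_tone(grid, f2)
  if (f1 == f2) stop("XOR task needs f1 != f2")
  if (!is.numeric(snr) || snr <= 0) stop("'snr' must be a positive power ratio")
  n <- as.integer(n_per_class)
  d <- grid$n
  tt <- grid$times
  A <- amplitude
  sd_pure <- sqrt(A^2 / (2 * snr))
  sd_mix <- sqrt(A^2 / snr)                 # mixture signal power is A^2
  sd_noise <- sqrt(A^2 / 2 + A^2 / (2 * snr)) # matched to pure-tone power
  out <- with_seed(seed, {
    tone <- function(f) {
      A * sin(outer(stats::runif(n, 0, 2 * pi), 2 * pi * f * tt, "+"))
    }
    S1 <- tone(f1)
    S2 <- tone(f2)
    Smix <- tone(f1) + tone(f2)
    X <- rbind(
      S1 + matrix(stats::rnorm(n * d, sd = sd_pure), n, d),
      S2 + matrix(stats::rnorm(n * d, sd = sd_pure), n, d),
      Smix + matrix(stats::rnorm(n * d, sd = sd_mix), n, d),
      matrix(stats::rnorm(n * d, sd = sd_noise), n, d)
    )
    list(X = X, S = rbind(S1, S2, Smix, matrix(0, n, d)))
  })
  meta <- list(task = "frequency_xor", f1 = f1, f2 = f2, snr = snr,
               amplitude = amplitude, seed = seed,
               subclass = rep(c("f1", "f2", "mix", "noise"), each = n))
  if (keep_signal) meta$signal <- out$S
  new_dataset(out$X, rep(c(1L, 1L, 0L, 0L), each = n), grid, meta)
}

new_dataset <- function(X, y, grid, meta) {
  stopifnot(nrow(X) == length(y), all(is.finite(X)))
  structure(list(X = X, y = y, grid = grid, meta = meta),
            class = "structrf_dataset")
}

#' @export
print.structrf_dataset <- function(x, ...) {
  cat(sprintf("Labeled dataset '%s': %d x %d, classes: %s\n",
              x$meta$task %||% "custom", nrow(x$X), ncol(x$X),
              paste(names(table(x$y)), table(x$y), sep = ":", collapse = ", ")))
  invisible(x)
}

#' Synthetic receptive-field population with known ground truth
#'
#' Samples `m` fields from a covariance model and optionally adds white
#' measurement noise, recording the generating parameters. This stands in
#' for measured spike-triggered-average datasets in parameter-recovery
#' tests; it is a synthetic fixture generator, not a model of any
#' experimental noise process.
#'
#' @param cov a `structrf_cov` (the ground-truth model).
#' @param m number of fields.
#' @param noise_level measurement-noise power as a fraction of the mean
#'   per-sample field power (0 = noiseless).
#' @param seed integer seed.
#' @return a `structrf_rfset` whose `provenance` records the ground truth.
#' @export
gen_synthetic_rf_population <- function(cov, m, noise_level = 0, seed = NULL) {
  stopifnot(inherits(cov, "structrf_cov"))
  if (noise_level < 0) stop("'noise_level' must be >= 0")
  rfs <- sample_weights(cov, m, seed = seed)
  if (noise_level > 0) {
    d <- ncol(rfs$W)
    base_power <- sum(diag(cov$C)) / d
    noise <- with_seed(derive_seed(seed %||% 0L, 1L),
                       matrix(stats::rnorm(m * d, sd = sqrt(noise_level * base_power)),
                              m, d))
    rfs$W <- rfs$W + noise
  }
  rfs$provenance <- list(kind = "synthetic_population", seed = seed,
                         noise_level = noise_level, truth = cov$params)
  rfs
}
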