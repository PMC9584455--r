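#' Save and load receptive-field datasets
#'
#' Receptive-field sets are stored as a plain CSV matrix (one field per
#' row, no header) next to a JSON sidecar `<path>.json` holding the grid
#' metadata and provenance, so that a round trip reconstructs the object.
#' The CSV layout is also what external spike-triggered-average datasets
#' are expected to arrive in; grid metadata can alternatively be supplied
#' directly to [load_rf_dataset()].
#'
#' @param rfs a `structrf_rfset`.
#' @param path CSV file path.
#' @return `save_rf_set()` returns `path` invisibly.
#' @export
save_rf_set <- function(rfs, path) {
  stopifnot(inherits(rfs, "structrf_rfset"))
  utils::write.table(rfs$W, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(grid = grid_meta(rfs$grid),
               provenance = rfs$provenance["kind"])
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

grid_meta <- function(grid) {
  if (is.null(grid)) return(NULL)
  if (inherits(grid, "structrf_grid1d")) {
    list(type = "1d", n_samples = grid$n, dt = grid$dt)
  } else {
    list(type = "2d", height = grid$height, width = grid$width)
  }
}

grid_from_meta <- function(meta) {
  if (is.null(meta)) return(NULL)
  if (identical(meta$type, "1d")) {
    grid_1d(meta$n_samples, meta$dt)
  } else if (identical(meta$type, "2d")) {
    grid_2d(meta$height, meta$width)
  } else {
    stop("malformed grid metadata: unknown type '", meta$type %||% "", "'")
  }
}

#' @rdname save_rf_set
#' @param grid optional grid object; if omitted, read from the JSON
#'   sidecar written by [save_rf_set()].
#' @return `load_rf_dataset()` returns a `structrf_rfset`.
#' @export
load_rf_dataset <- function(path, grid = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  W <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(W) <- NULL
  if (is.null(grid)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar)) {
      stop("no grid supplied and no metadata sidecar found at ", sidecar)
    }
    grid <- grid_from_meta(jsonlite::read_json(sidecar)$grid)
  }
  if (ncol(W) != grid_size(grid)) {
    stop(sprintf("data have %d columns but the grid has %d points",
                 ncol(W), grid_size(grid)))
  }
  new_rf_set(W, grid, provenance = list(kind = "loaded", path = path))
}

#' Run a pipeline described by a configuration file
#'
#' Executes one named command (`sample`, `task`, `fit`, `rfn`, `train`)
#' from a YAML or JSON configuration and writes its outputs plus a manifest
#' (`manifest.json`: resolved configuration, package version, seed) to the
#' output directory, so every randomized run is reproducible from the
#' manifest alone. This is the engine behind the command-line interface in
#' `inst/cli/structrf.R`.
#'
#' @param config path to a YAML/JSON file, or an equivalent named list.
#'   Required keys: `command`, `out_dir`, `seed`; remaining keys are
#'   command-specific (see the CLI script for the schema by example).
#' @return invisibly, a list of the objects the command produced.
#' @export
run_config <- function(config) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  required <- c("command", "out_dir", "seed")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    stop("config is missing required key(s): ", paste(missing, collapse = ", "))
  }
  cmd <- config$command
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  result <- switch(
    cmd,
    sample = cmd_sample(config),
    task = cmd_task(config),
    fit = cmd_fit(config),
    rfn = cmd_rfn(config),
    train = cmd_train(config),
    stop("unknown command '", cmd, "'; expected sample/task/fit/rfn/train")
  )
  manifest <- list(config = config,
                   package = "structrf",
                   version = as.character(utils::packageVersion("structrf")),
                   seed = config$seed)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}

cov_from_config <- function(cfg) {
  model <- cfg$model %||% cfg$cov
  switch(
    model,
    sensilla = build_sensilla_cov(grid_1d(cfg$n_samples %||% 200,
                                          cfg$dt %||% 0.5),
                                  cfg$f_lo, cfg$f_hi, cfg$gamma),
    stationary = ,
    fourier = build_stationary_cov(grid_1d(cfg$n_samples %||% 200,
                                           cfg$dt %||% 0.5),
                                   cfg$f_lo, cfg$f_hi),
    v1 = build_v1_cov(grid_2d(cfg$height, cfg$width), cfg$s, cfg$f),
    unstructured = NULL,
    stop("unknown covariance model '", model, "'")
  )
}

cmd_sample <- function(cfg) {
  cov <- cov_from_config(cfg)
  if (is.null(cov)) {
    d <- (cfg$n_samples %||% 200)
    cov <- build_null_cov("unstructured", grid_1d(d, cfg$dt %||% 0.5))
  }
  rfs <- sample_weights(cov, cfg$m, seed = cfg$seed)
  save_rf_set(rfs, file.path(cfg$out_dir, "weights.csv"))
  list(rfs = rfs)
}

cmd_task <- function(cfg) {
  ds <- switch(cfg$name,
               freqdet = gen_frequency_detection(cfg$n_per_class,
                                                 seed = cfg$seed),
               freqxor = gen_frequency_xor(cfg$n_per_class, seed = cfg$seed),
               stop("unknown task '", cfg$name, "'"))
  utils::write.table(cbind(y = ds$y, ds$X),
                     file.path(cfg$out_dir, paste0(cfg$name, ".csv")),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  list(dataset = ds)
}

cmd_fit <- function(cfg) {
  rfs <- load_rf_dataset(cfg$data)
  if (inherits(rfs$grid, "structrf_grid2d")) {
    rfs <- center_receptive_fields(rfs)
  }
  Cd <- empirical_covariance(rfs)
  fit <- fit_covariance_params(Cd, kind = cfg$model)
  jsonlite::write_json(list(kind = fit$kind, par = fit$par,
                            distance = fit$distance),
                       file.path(cfg$out_dir, "fit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(fit = fit)
}

cmd_rfn <- function(cfg) {
  cov <- cov_from_config(cfg)
  train <- gen_frequency_split(cfg)
  curve <- error_curve_experiment(cov, train$train, train$test,
                                  neuron_counts = cfg$neurons,
                                  repeats = cfg$repeats %||% 5,
                                  seed = cfg$seed)
  utils::write.csv(curve$runs, file.path(cfg$out_dir, "results.csv"),
                   row.names = FALSE)
  jsonlite::write_json(curve$summary, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(curve = curve)
}

gen_frequency_split <- function(cfg) {
  gen <- switch(cfg$task %||% "freqdet",
                freqdet = gen_frequency_detection,
                freqxor = gen_frequency_xor,
                stop("unknown task '", cfg$task, "'"))
  classes <- if (identical(cfg$task, "freqxor")) 4L else 2L
  list(train = gen((cfg$n_train %||% 4000) / classes,
                   seed = derive_seed(cfg$seed, 1L)),
       test = gen((cfg$n_test %||% 1000) / classes,
                  seed = derive_seed(cfg$seed, 2L)))
}

cmd_train <- function(cfg) {
  cov <- cov_from_config(cfg)
  split <- gen_frequency_split(cfg)
  init <- if (is.null(cov)) {
    init_hidden_weights("kaiming", m = cfg$m, d = ncol(split$train$X),
                        seed = cfg$seed)
  } else {
    init_hidden_weights("structured", m = cfg$m, cov = cov, seed = cfg$seed)
  }
  trace <- train_full(init, split$train, split$test,
                      epochs = cfg$epochs %||% 100, lr = cfg$lr %||% 0.1)
  utils::write.csv(data.frame(epoch = seq_along(trace$loss),
                              loss = trace$loss,
                              test_error = trace$test_error),
                   file.path(cfg$out_dir, "trace.csv"), row.names = FALSE)
  list(trace = trace)
}
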