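#' Load and validate a run configuration from YAML
#'
#' The configuration mirrors [sweep_config()] plus stimulus and output
#' settings; unknown keys are rejected so typos fail loudly. The resolved
#' configuration (defaults filled in) is written next to the outputs by
#' [run_all()] so any result can be regenerated from it.
#'
#' @param path YAML file path.
#' @return A named list of class `run_config` with all defaults resolved.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # the total-neuron key is spelled n_neurons: a bare "N" is a boolean
  # token in YAML 1.1 and would be read back as FALSE
  defaults <- list(
    n_neurons = 300,
    N_E_grid = c(150, 180, 210, 225, 240, 255, 270, 280),
    lambda_grid = c(0.05, 0.15, 0.3), patch_side = 8,
    n_train_patches = 2000, n_eval_patches = 60, n_boot = 200,
    stimuli = "onef", image_paths = NULL, n_images = 10, image_side = 128,
    spectral_exponent = 1, whiten = TRUE,
    train = list(), lca = list(), seed = 1, outdir = "results",
    keep_cells = TRUE, verbose = FALSE)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- defaults
  cfg[names(raw)] <- raw
  if (!cfg$stimuli %in% c("onef", "file"))
    stop("stimuli must be 'onef' or 'file'")
  if (cfg$stimuli == "file" && is.null(cfg$image_paths))
    stop("stimuli = 'file' requires image_paths")
  structure(cfg, class = "run_config")
}

#' Write a run configuration back to YAML
#'
#' Round-trips with [load_config()].
#'
#' @param config A `run_config`.
#' @param path Output YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Export sweep or bootstrap results to disk
#'
#' Sweeps produce a tidy per-cell CSV, an optima CSV, a JSON summary, and a
#' three-panel PNG figure of the normalized measures; bootstrap results
#' produce a CSV of the replicate distributions and a JSON decision
#' report. Re-export is idempotent.
#'
#' @param x An `ei_sweep` or `ei_bootstrap`.
#' @param outdir Output directory (created if needed).
#' @param prefix File-name prefix (default from the object class).
#' @return Character vector of files written (invisibly).
#' @export
export_results <- function(x, outdir, prefix = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (inherits(x, "ei_sweep")) {
    prefix <- prefix %||% "sweep"
    f1 <- file.path(outdir, paste0(prefix, "_cells.csv"))
    tab <- x$table %||% data.frame(lambda = numeric(0), N_E = integer(0))
    utils::write.csv(tab, f1, row.names = FALSE)
    f2 <- file.path(outdir, paste0(prefix, "_optima.csv"))
    utils::write.csv(x$optima %||% data.frame(), f2, row.names = FALSE)
    curve <- optimal_ratio_curve(x)
    f3 <- file.path(outdir, paste0(prefix, "_summary.json"))
    jsonlite::write_json(list(optima = x$optima, coincidence = curve$coincidence),
                         f3, dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         na = "null")
    files <- c(f1, f2, f3)
    if (!is.null(x$table) && nrow(x$table) > 0) {
      f4 <- file.path(outdir, paste0(prefix, "_measures.png"))
      grDevices::png(f4, width = 1200, height = 420)
      plot(x)
      grDevices::dev.off()
      files <- c(files, f4)
    }
  } else if (inherits(x, "ei_bootstrap")) {
    prefix <- prefix %||% "bootstrap"
    f1 <- file.path(outdir, paste0(prefix, "_distributions.csv"))
    utils::write.csv(data.frame(replicate = seq_len(x$n_boot),
                                mean_tr_a = x$dist_a, mean_tr_b = x$dist_b),
                     f1, row.names = FALSE)
    f2 <- file.path(outdir, paste0(prefix, "_report.json"))
    jsonlite::write_json(x[c("mean_a", "mean_b", "p_a_sparser", "p_b_sparser",
                             "n_boot", "seed", "method")],
                         f2, auto_unbox = TRUE, digits = NA)
    files <- c(f1, f2)
  } else stop("don't know how to export objects of class ", class(x)[1])
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a dictionary or circuit to JSON
#'
#' Plain-text persistence for fitted objects: the dictionary stores its
#' feature matrix and training metadata; the circuit stores the
#' factorization (`U`, `Sigma`, `V`) together with `Phi`. Numbers are
#' written at full precision and round-trip through the paired readers.
#'
#' @param x An `sc_dictionary` or `ei_circuit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(x, path) {
  stopifnot(inherits(x, "sc_dictionary"))
  jsonlite::write_json(list(phi = as.vector(x$Phi), dim = dim(x$Phi),
                            patch_side = x$patch_side, lambda = x$lambda,
                            n_iter = x$n_iter, batch_size = x$batch_size,
                            lr = x$lr, seed = x$seed),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_dictionary <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(Phi = matrix(j$phi, j$dim[1], j$dim[2]),
                 patch_side = j$patch_side, lambda = j$lambda,
                 trace = NULL, n_iter = j$n_iter, batch_size = j$batch_size,
                 lr = j$lr, seed = j$seed),
            class = "sc_dictionary")
}

#' @rdname write_dictionary
#' @export
write_circuit <- function(x, path) {
  stopifnot(inherits(x, "ei_circuit"))
  jsonlite::write_json(list(phi = as.vector(x$Phi), dim = dim(x$Phi),
                            N_I = x$N_I, rectify = x$rectify),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dictionary
#' @export
read_circuit <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_circuit(matrix(j$phi, j$dim[1], j$dim[2]), N_I = j$N_I,
                rectify = j$rectify)
}

#' Run the whole pipeline from a configuration
#'
#' Builds or loads the stimulus set, runs the E:I sweep, and exports all
#' results plus the resolved configuration to the output directory. The
#' global seed fans out deterministically to the stimulus generator and
#' every sweep cell, so stages can be rerun independently.
#'
#' @param config A `run_config` (from [load_config()]) or a path to one.
#' @return The `ei_sweep`, invisibly; side effect: files in
#'   `config$outdir`.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  images <- if (config$stimuli == "onef") {
    generate_onef_images(config$n_images, config$image_side,
                         config$spectral_exponent, seed = config$seed + 100L)
  } else {
    load_images(config$image_paths, whiten = config$whiten)
  }
  sc <- sweep_config(N = config$n_neurons, N_E_grid = config$N_E_grid,
                     lambda_grid = config$lambda_grid, images = images,
                     patch_side = config$patch_side,
                     n_train_patches = config$n_train_patches,
                     n_eval_patches = config$n_eval_patches,
                     n_boot = config$n_boot, train = config$train,
                     lca = config$lca, seed = config$seed)
  sweep <- run_sweep(sc, keep_cells = config$keep_cells,
                     progress = config$verbose)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(config$outdir, "resolved_config.yaml"))
  export_results(sweep, config$outdir)
  invisible(sweep)
}
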