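#' Configure an E:I ratio sweep
#'
#' Bundles everything [run_sweep()] needs: the fixed neuron budget, the
#' grids of excitatory population sizes and sparsity levels, the stimulus
#' source, and training / solver / bootstrap settings. One dictionary is
#' trained per (lambda, N_E) cell, as in the study design.
#'
#' @param N Total neuron budget (N = N_E + N_I per cell).
#' @param N_E_grid Excitatory population sizes; each must satisfy
#'   `1 <= N - N_E <= N_E` so ratios run from 1:1 upward.
#' @param lambda_grid Sparsity levels to sweep.
#' @param images An `image_set` supplying training and evaluation patches
#'   (natural images or 1/f surrogates).
#' @param patch_side Patch side in pixels.
#' @param n_train_patches Training patches sampled per cell.
#' @param n_eval_patches Evaluation patches (shared per lambda).
#' @param n_boot Bootstrap replicates for standard errors.
#' @param train Named list of overrides for [train_dictionary()] (n_iter,
#'   batch_size, lr, decay, infer_iter, infer_tol).
#' @param lca Named list of overrides for [lca_encode()] (dt_over_tau,
#'   max_steps, tol).
#' @param seed Global seed; per-cell seeds are derived deterministically.
#' @return A `sweep_config` list.
#' @export
sweep_config <- function(N, N_E_grid, lambda_grid, images, patch_side,
                         n_train_patches = 2000, n_eval_patches = 100,
                         n_boot = 200, train = list(), lca = list(),
                         seed = 1) {
  stopifnot(length(N_E_grid) > 0, length(lambda_grid) > 0)
  N_E_grid <- sort(unique(as.integer(N_E_grid)))
  bad <- N - N_E_grid < 1 | N - N_E_grid > N_E_grid
  if (any(bad))
    stop("every N_E must satisfy 1 <= N - N_E <= N_E (ratios >= 1:1)")
  train_def <- list(n_iter = 150, batch_size = 100, lr = 1.0, decay = 100,
                    infer_iter = 150, infer_tol = 1e-5)
  train_def[names(train)] <- train
  lca_def <- list(dt_over_tau = 0.1, max_steps = 1500, tol = 1e-6)
  lca_def[names(lca)] <- lca
  structure(list(N = N, N_E_grid = N_E_grid, lambda_grid = lambda_grid,
                 images = images, patch_side = patch_side,
                 n_train_patches = n_train_patches,
                 n_eval_patches = n_eval_patches, n_boot = n_boot,
                 train = train_def, lca = lca_def, seed = seed),
            class = "sweep_config")
}

#' Configuration of the full-scale study protocol
#'
#' The headline protocol: 16x16 patches from the 10-image 512x512
#' pre-whitened natural image database, N = 1200 total neurons, 100
#' evaluation patches. Running it takes hours of dictionary training; it is
#' provided so the protocol is executable verbatim when the database and
#' the compute are available.
#'
#' @param images An `image_set` holding the 10 natural images (e.g. loaded
#'   via [load_images()]).
#' @param lambda_grid Sparsity levels (default 0.15, the headline level).
#' @param ... Overrides passed to [sweep_config()].
#' @return A `sweep_config`.
#' @export
full_scale_config <- function(images, lambda_grid = 0.15, ...) {
  sweep_config(N = 1200,
               N_E_grid = c(600, 700, 800, 850, 900, 950, 1000, 1025, 1050,
                            1075, 1100, 1125, 1150),
               lambda_grid = lambda_grid, images = images, patch_side = 16,
               n_train_patches = 20000, n_eval_patches = 100,
               train = list(n_iter = 2000), ...)
}

#' Canonical desk-scale study configuration
#'
#' The package's standard reduced replication of the full protocol,
#' preserving its geometry at quarter scale: 8x8 patches (d = 64),
#' N = 300 total neurons (N/d ~ 4.7 as at full scale, so the 1:1 cell is
#' ~2.3x overcomplete), an 8-point ratio grid from 1:1 to 14:1, and ten
#' synthetic 1/f images as the stimulus ensemble. Training and solver
#' settings are sized so a full three-lambda sweep runs in minutes on one
#' CPU.
#'
#' @param seed Integer seed (drives image generation and every cell).
#' @param lambda_grid Sparsity levels (default `c(0.05, 0.15, 0.3)`).
#' @return A `sweep_config`.
#' @export
desk_scale_config <- function(seed = 1, lambda_grid = c(0.05, 0.15, 0.3)) {
  imgs <- generate_onef_images(10, 128, 1, seed = seed + 400L)
  sweep_config(N = 300,
               N_E_grid = c(150, 180, 210, 225, 240, 255, 270, 280),
               lambda_grid = lambda_grid, images = imgs, patch_side = 8,
               n_train_patches = 1500, n_eval_patches = 40, n_boot = 150,
               train = list(n_iter = 80, batch_size = 75, infer_iter = 60,
                            infer_tol = 1e-4),
               lca = list(max_steps = 2000, tol = 3e-5), seed = seed)
}

#' Reduced configuration for multi-seed inhibition-trend analyses
#'
#' A further-scaled 6x6 / N = 170 version of [desk_scale_config()] with
#' the same N/d ratio, cheap enough to repeat over several seeds when
#' estimating how inhibitory structure (weight kurtosis, interneuron rate
#' statistics, total influence) changes with the sparsity level at the
#' per-lambda optimal ratios.
#'
#' @inheritParams desk_scale_config
#' @return A `sweep_config`.
#' @export
trend_scale_config <- function(seed = 1, lambda_grid = c(0.05, 0.15, 0.3)) {
  imgs <- generate_onef_images(6, 96, 1, seed = seed + 50L)
  sweep_config(N = 170, N_E_grid = c(85, 110, 125, 140, 150),
               lambda_grid = lambda_grid, images = imgs, patch_side = 6,
               n_train_patches = 800, n_eval_patches = 24, n_boot = 30,
               train = list(n_iter = 40, batch_size = 75, infer_iter = 50,
                            infer_tol = 1e-4),
               lca = list(max_steps = 1200, tol = 5e-5), seed = 100L + seed)
}

# Deterministic per-(lambda, N_E) seed fan-out, kept well below 2^31.
cell_seed <- function(seed, li, ni) {
  (seed * 7919L + li * 331L + ni * 17L) %% 2147483647L
}

# Bootstrap resampling indices honoring the image hierarchy: resample source
# images with replacement, then take their patches; plain patch resampling
# when all patches share one image.
boot_indices <- function(image_id, n_boot, seed) {
  set.seed(seed)
  n <- length(image_id)
  ids <- unique(image_id)
  lapply(seq_len(n_boot), function(b) {
    if (length(ids) > 1) {
      take <- sample(ids, length(ids), replace = TRUE)
      unlist(lapply(take, function(i) which(image_id == i)), use.names = FALSE)
    } else {
      sample.int(n, n, replace = TRUE)
    }
  })
}

#' Evaluate one (lambda, N_E) cell of the sweep
#'
#' Trains a dictionary for `N_E` excitatory cells at sparsity `lambda`,
#' builds the circuit with `N_I = N - N_E` interneurons, encodes the
#' evaluation patches with the LCA dynamics, and aggregates all performance
#' measures with bootstrap standard errors.
#'
#' @param config A `sweep_config`.
#' @param lambda Sparsity level (need not be on the grid).
#' @param N_E Excitatory population size.
#' @param seed Integer seed for this cell.
#' @param eval_set Optional list(patches, image_id) shared across cells;
#'   sampled from `config$images` when NULL.
#' @param boot_idx Optional list of bootstrap index vectors shared across
#'   cells; generated when NULL.
#' @return A `performance_record`: one-row data.frame of aggregate metrics
#'   and their bootstrap SEs, with attributes `per_patch` (per-patch metric
#'   vectors), `boot` (replicate means per metric), `i_rates`
#'   (per-interneuron mean rates), `weights` (pooled I->E sample), and
#'   `dictionary`, `circuit`.
#' @export
run_cell <- function(config, lambda, N_E, seed = config$seed,
                     eval_set = NULL, boot_idx = NULL) {
  N_I <- config$N - N_E
  if (N_I < 1 || N_I > N_E) stop("invalid cell: need 1 <= N - N_E <= N_E")
  if (is.null(eval_set))
    eval_set <- sample_patches(config$images, config$patch_side,
                               config$n_eval_patches, seed = seed + 1L)
  if (is.null(boot_idx))
    boot_idx <- boot_indices(eval_set$image_id, config$n_boot, seed + 2L)
  tr <- config$train
  dict <- train_dictionary(config$images, N_E = N_E, lambda = lambda,
                           n_iter = tr$n_iter, batch_size = tr$batch_size,
                           lr = tr$lr, decay = tr$decay,
                           infer_iter = tr$infer_iter,
                           infer_tol = tr$infer_tol,
                           n_patches = config$n_train_patches,
                           patch_side = config$patch_side, seed = seed)
  circuit <- build_circuit(dict, N_I = N_I)
  enc <- lca_encode(circuit, eval_set$patches, lambda,
                    dt_over_tau = config$lca$dt_over_tau,
                    max_steps = config$lca$max_steps, tol = config$lca$tol)
  n_eval <- nrow(eval_set$patches)
  err <- vapply(seq_len(n_eval), function(i)
    reconstruction_error(eval_set$patches[i, ], dict, enc$a[i, ]), 0)
  tr_vec <- vapply(seq_len(n_eval), function(i)
    tr_sparsity(abs(enc$a[i, ])), 0)
  energy <- vapply(seq_len(n_eval), function(i)
    metabolic_energy(abs(enc$a[i, ]), abs(enc$b[i, ]), N = config$N), 0)
  weights <- pooled_ie_weights(circuit)
  i_rates <- colMeans(abs(enc$b))
  infl <- inhibitory_influence(circuit, enc)
  boot_mean <- function(v) vapply(boot_idx, function(ix)
    mean(v[ix], na.rm = TRUE), 0)
  boot <- list(error = boot_mean(err), tr = boot_mean(tr_vec),
               energy = boot_mean(energy))
  rec <- data.frame(
    lambda = lambda, N_E = N_E, N_I = N_I, ratio = N_E / N_I,
    reconstruction_error = mean(err),
    tr_sparsity = mean(tr_vec, na.rm = TRUE),
    density = 1 - mean(tr_vec, na.rm = TRUE),
    energy = mean(energy),
    ie_weight_kurtosis = weight_kurtosis(weights),
    mean_I_rate = mean(i_rates),
    sd_I_rate = stats::sd(i_rates),
    total_inhibitory_influence = infl,
    se_error = stats::sd(boot$error), se_tr = stats::sd(boot$tr),
    se_energy = stats::sd(boot$energy),
    frac_converged = mean(enc$converged),
    median_steps = stats::median(enc$n_steps))
  structure(rec, class = c("performance_record", "data.frame"),
            per_patch = list(error = err, tr = tr_vec, energy = energy),
            boot = boot, i_rates = i_rates, weights = weights,
            dictionary = dict, circuit = circuit)
}

#' Run the full E:I ratio sweep
#'
#' Evaluates [run_cell()] over the lambda x N_E grid of a
#' [sweep_config()], locates the per-measure optimal ratio at each lambda
#' (reconstruction error, population density, metabolic energy — all
#' minimized), and attaches bootstrap uncertainties on the optima. Cells
#' whose training fails are recorded as invalid and skipped.
#'
#' @param config A `sweep_config`.
#' @param keep_cells Keep per-cell attributes (dictionaries, circuits,
#'   per-patch metrics) in the result; default FALSE to bound memory.
#' @param progress Print per-cell progress lines (default FALSE).
#' @return An object of class `ei_sweep`: list with `table` (one row per
#'   cell), `optima` (per lambda x measure: interpolated optimal ratio, SE,
#'   boundary flag), `config`, and `cells` (when kept).
#' @export
run_sweep <- function(config, keep_cells = FALSE, progress = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  rows <- list()
  cells <- list()
  opt_rows <- list()
  measures <- c(error = "reconstruction_error", density = "density",
                energy = "energy")
  for (li in seq_along(config$lambda_grid)) {
    lam <- config$lambda_grid[li]
    es_seed <- cell_seed(config$seed, li, 0L)
    eval_set <- sample_patches(config$images, config$patch_side,
                               config$n_eval_patches, seed = es_seed + 1L)
    boot_idx <- boot_indices(eval_set$image_id, config$n_boot, es_seed + 2L)
    recs <- vector("list", length(config$N_E_grid))
    for (ni in seq_along(config$N_E_grid)) {
      ne <- config$N_E_grid[ni]
      res <- tryCatch(
        run_cell(config, lam, ne, seed = cell_seed(config$seed, li, ni),
                 eval_set = eval_set, boot_idx = boot_idx),
        error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("cell (lambda=%g, N_E=%d) failed: %s", lam, ne,
                        conditionMessage(res)))
        next
      }
      if (progress)
        message(sprintf("lambda=%g N_E=%d: err=%.3f TR=%.3f", lam, ne,
                        res$reconstruction_error, res$tr_sparsity))
      recs[[ni]] <- res
      rows[[length(rows) + 1L]] <- as.data.frame(res)
      if (keep_cells)
        cells[[sprintf("lambda%g_NE%d", lam, ne)]] <- res
    }
    ok <- !vapply(recs, is.null, TRUE)
    if (sum(ok) >= 3) {
      ratios <- vapply(recs[ok], function(r) r$ratio, 0)
      for (m in names(measures)) {
        vals <- vapply(recs[ok], function(r) r[[measures[m]]], 0)
        boot_mat <- vapply(recs[ok], function(r) {
          b <- attr(r, "boot")
          switch(m, error = b$error, density = 1 - b$tr, energy = b$energy)
        }, numeric(config$n_boot))
        opt <- find_optimum(ratios, vals, boot_values = boot_mat)
        opt_rows[[length(opt_rows) + 1L]] <- data.frame(
          lambda = lam, measure = m, ratio_opt = opt$ratio,
          se = opt$se, boundary = opt$boundary,
          grid_step = grid_step_at(ratios, opt$ratio))
      }
    }
  }
  structure(list(table = do.call(rbind, rows),
                 optima = do.call(rbind, opt_rows),
                 config = config,
                 cells = if (keep_cells) cells else NULL),
            class = "ei_sweep")
}

# local grid spacing (in ratio units) around a point of the ratio grid
grid_step_at <- function(ratios, at) {
  ratios <- sort(ratios)
  i <- which.min(abs(ratios - at))
  steps <- diff(ratios)
  max(steps[max(1, i - 1):min(length(steps), i)])
}

#' Locate the optimum of a measure over the ratio grid
#'
#' Grid argmin refined by a local quadratic fit through the argmin and its
#' two neighbors; the uncertainty is the standard deviation of optima
#' recomputed on bootstrap-resampled series. A minimum at either end of the
#' grid is flagged as a boundary optimum (no interior optimum certified).
#'
#' @param ratios E:I ratio grid (any increasing coordinate).
#' @param values Measure at each grid point (minimized).
#' @param boot_values Optional matrix (replicates x grid points) of
#'   bootstrap-resampled series for the uncertainty.
#' @return List with `ratio` (interpolated argmin), `value`, `boundary`
#'   (logical), `se` (NA without `boot_values`).
#' @export
find_optimum <- function(ratios, values, boot_values = NULL) {
  stopifnot(length(ratios) == length(values), length(ratios) >= 3)
  ord <- order(ratios)
  ratios <- ratios[ord]; values <- values[ord]
  if (!is.null(boot_values)) boot_values <- boot_values[, ord, drop = FALSE]
  refine <- function(v) {
    i <- which.min(v)
    if (i == 1 || i == length(v)) return(list(ratio = ratios[i], boundary = TRUE))
    x <- ratios[(i - 1):(i + 1)]; y <- v[(i - 1):(i + 1)]
    co <- stats::coef(stats::lm(y ~ x + I(x^2)))
    vertex <- if (is.finite(co[3]) && co[3] > 0) -co[2] / (2 * co[3]) else ratios[i]
    vertex <- min(max(vertex, x[1]), x[3])   # stay inside the bracket
    list(ratio = vertex, boundary = FALSE)
  }
  main <- refine(values)
  se <- NA_real_
  if (!is.null(boot_values)) {
    reps <- apply(boot_values, 1, function(v) refine(v)$ratio)
    se <- stats::sd(reps)
  }
  list(ratio = main$ratio, value = min(values), boundary = main$boundary,
       se = se)
}

#' Optimal-ratio-versus-lambda curves and their coincidence
#'
#' Per performance measure, the curve of interpolated optimal E:I ratio as
#' a function of lambda, plus a coincidence statistic: the maximum pairwise
#' discrepancy between the three measures' optima at each lambda, compared
#' with the local grid spacing.
#'
#' @param sweep An `ei_sweep`.
#' @return List with `curve` (lambda x measure table of optima) and
#'   `coincidence` (per lambda: max pairwise discrepancy, grid step, and
#'   whether all optima agree within one step).
#' @export
optimal_ratio_curve <- function(sweep) {
  opt <- sweep$optima
  if (is.null(opt) || nrow(opt) == 0)
    return(list(curve = opt, coincidence = NULL))
  lams <- sort(unique(opt$lambda))
  coin <- do.call(rbind, lapply(lams, function(l) {
    o <- opt[opt$lambda == l, ]
    disc <- if (nrow(o) > 1) max(stats::dist(o$ratio_opt)) else 0
    data.frame(lambda = l, max_discrepancy = disc,
               grid_step = max(o$grid_step),
               within_one_step = disc <= max(o$grid_step),
               any_boundary = any(o$boundary))
  }))
  list(curve = opt, coincidence = coin)
}

#' Inhibitory structure and function at the per-lambda optima
#'
#' For each lambda, takes the grid cell nearest the reconstruction-error
#' optimum and tabulates the pooled I->E weight kurtosis, the mean and sd
#' of interneuron rates, and the total inhibitory influence. Pairwise
#' comparisons of interneuron rate populations across lambdas use Welch
#' t-tests on means and F-tests on variances with Bonferroni correction.
#'
#' @param sweep An `ei_sweep` run with `keep_cells = TRUE` (the rate
#'   populations live in the cell attributes).
#' @return List with `table` (one row per lambda) and `tests` (pairwise
#'   comparisons; NULL when fewer than two lambdas).
#' @export
inhibition_summary <- function(sweep) {
  opt <- sweep$optima
  if (is.null(opt) || nrow(opt) == 0)
    return(list(table = NULL, tests = NULL))
  if (is.null(sweep$cells))
    stop("run_sweep(..., keep_cells = TRUE) required for inhibition_summary")
  err_opt <- opt[opt$measure == "error", ]
  tab <- list(); rate_pops <- list()
  for (i in seq_len(nrow(err_opt))) {
    lam <- err_opt$lambda[i]
    sub <- sweep$table[sweep$table$lambda == lam, ]
    ne <- sub$N_E[which.min(abs(sub$ratio - err_opt$ratio_opt[i]))]
    cell <- sweep$cells[[sprintf("lambda%g_NE%d", lam, ne)]]
    tab[[i]] <- data.frame(lambda = lam, N_E = ne, ratio = ne / (sweep$config$N - ne),
                           kurtosis = cell$ie_weight_kurtosis,
                           mean_I_rate = cell$mean_I_rate,
                           sd_I_rate = cell$sd_I_rate,
                           influence = cell$total_inhibitory_influence,
                           total_spiking = (sweep$config$N - ne) * cell$mean_I_rate,
                           total_weight = sum(abs(attr(cell, "weights"))))
    rate_pops[[as.character(lam)]] <- attr(cell, "i_rates")
  }
  tests <- NULL
  if (length(rate_pops) >= 2) {
    prs <- utils::combn(names(rate_pops), 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
      x <- rate_pops[[prs[1, k]]]; y <- rate_pops[[prs[2, k]]]
      data.frame(lambda_a = as.numeric(prs[1, k]),
                 lambda_b = as.numeric(prs[2, k]),
                 p_mean = stats::t.test(x, y)$p.value,
                 p_var = stats::var.test(x, y)$p.value)
    }))
    tests$p_mean_adj <- stats::p.adjust(tests$p_mean, "bonferroni")
    tests$p_var_adj <- stats::p.adjust(tests$p_var, "bonferroni")
  }
  list(table = do.call(rbind, tab), tests = tests)
}

#' @export
print.ei_sweep <- function(x, ...) {
  cat(sprintf("ei_sweep: N = %d, %d lambda x %d ratio cells (%d evaluated)\n",
              x$config$N, length(x$config$lambda_grid),
              length(x$config$N_E_grid),
              if (is.null(x$table)) 0 else nrow(x$table)))
  if (!is.null(x$optima)) {
    cat("per-measure optimal E:I ratios:\n")
    print(x$optima, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @export
summary.ei_sweep <- function(object, ...) {
  curve <- optimal_ratio_curve(object)
  out <- list(optima = object$optima, coincidence = curve$coincidence,
              table = object$table)
  class(out) <- "summary.ei_sweep"
  out
}

#' @export
print.summary.ei_sweep <- function(x, ...) {
  cat("Optimal E:I ratio per measure and lambda:\n")
  print(x$optima, row.names = FALSE, digits = 3)
  if (!is.null(x$coincidence)) {
    cat("\nCoincidence of optima across measures:\n")
    print(x$coincidence, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Plot normalized performance measures against the E:I ratio
#'
#' One panel per measure (reconstruction error, population density,
#' metabolic energy), each normalized per lambda so the grid minimum maps
#' to 0 and the 1:1 value to 1; one curve per lambda with the interpolated
#' optimum marked.
#'
#' @param x An `ei_sweep`.
#' @param ... Unused.
#' @export
plot.ei_sweep <- function(x, ...) {
  tab <- x$table
  measures <- c(reconstruction_error = "Norm. reconstruction error",
                density = "Norm. population density",
                energy = "Norm. metabolic energy")
  lams <- sort(unique(tab$lambda))
  cols <- grDevices::hcl.colors(max(3, length(lams)), "Dark 3")
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (m in names(measures)) {
    first <- TRUE
    for (li in seq_along(lams)) {
      sub <- tab[tab$lambda == lams[li], ]
      sub <- sub[order(sub$ratio), ]
      v <- normalize_measure(sub[[m]], sub[[m]][which.min(sub$ratio)])
      if (first) {
        graphics::plot(sub$ratio, v, type = "b", col = cols[li], pch = 16,
                       xlab = "E:I ratio", ylab = measures[m], log = "x",
                       ylim = range(0, 1.2, v), main = measures[m])
        first <- FALSE
      } else graphics::lines(sub$ratio, v, type = "b", col = cols[li], pch = 16)
    }
    graphics::legend("topright", legend = sprintf("lambda=%g", lams),
                     col = cols[seq_along(lams)], lty = 1, bty = "n", cex = 0.8)
  }
  invisible(x)
}
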