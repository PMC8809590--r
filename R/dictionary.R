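#' Learn an overcomplete sparse-coding dictionary
#'
#' Fits the unit-norm feature matrix \eqn{\Phi} (receptive fields of the
#' excitatory population) that minimizes the sparse-coding objective
#' \eqn{\sum_\mu \tfrac12\|I_\mu - \Phi a_\mu\|^2 + \lambda\|a_\mu\|_1}
#' over a patch corpus, by alternating minimization: infer codes for a
#' minibatch, take a gradient step on \eqn{\Phi} along the reconstruction
#' residual, renormalize columns to unit norm.
#'
#' @param patches Training patches as rows (n x patch_dim), an `image_set`
#'   (patches are sampled from it), or a `planted_patches` object.
#' @param N_E Number of dictionary atoms (excitatory cells).
#' @param lambda Sparsity penalty used during training.
#' @param n_iter Number of minibatch updates.
#' @param batch_size Patches per minibatch.
#' @param lr Initial learning rate; decays as 1/(1 + it/decay).
#' @param decay Learning-rate decay constant in iterations.
#' @param infer_iter,infer_tol FISTA settings for the inference step.
#' @param holdout_every Record held-out energy every this many updates.
#' @param n_patches When `patches` is an `image_set`: number of training
#'   patches to sample.
#' @param patch_side When `patches` is an `image_set`: patch side length.
#' @param seed Integer seed (initial dictionary, batch order, sampling).
#' @return An object of class `sc_dictionary`: list with `Phi`
#'   (patch_dim x N_E, unit-norm columns), `patch_side`, `lambda`, `trace`
#'   (data.frame of held-out energy, reconstruction error and code L1 per
#'   checkpoint), and training metadata.
#' @examples
#' pp <- generate_planted_patches(8, 4, 500, p_active = 0.2, seed = 1)
#' d <- train_dictionary(pp, N_E = 8, lambda = 0.05, n_iter = 50, seed = 1)
#' print(d)
#' @export
train_dictionary <- function(patches, N_E, lambda, n_iter = 200,
                             batch_size = 100, lr = 1.0, decay = 100,
                             infer_iter = 200, infer_tol = 1e-6,
                             holdout_every = 20, n_patches = 5000,
                             patch_side = NULL, seed = 1) {
  if (N_E < 1) stop("N_E must be >= 1")
  if (inherits(patches, "image_set")) {
    if (is.null(patch_side)) stop("patch_side required for an image_set source")
    patches <- sample_patches(patches, patch_side, n_patches, seed = seed)$patches
  } else if (inherits(patches, "planted_patches")) {
    patches <- patches$patches
  }
  patches <- as.matrix(patches)
  n <- nrow(patches); d <- ncol(patches)
  side <- if (!is.null(patch_side)) patch_side else round(sqrt(d))
  if (n < batch_size) batch_size <- n
  set.seed(seed)
  Phi <- matrix(stats::rnorm(d * N_E), d, N_E)
  Phi <- sweep(Phi, 2, sqrt(colSums(Phi^2)), "/")
  n_hold <- min(200, n)
  hold_idx <- sample.int(n, n_hold)
  X_hold <- patches[hold_idx, , drop = FALSE]
  trace <- list()
  k <- 0
  energy_prev <- Inf
  lr_scale <- 1
  for (it in seq_len(n_iter)) {
    idx <- sample.int(n, batch_size)
    Xb <- t(patches[idx, , drop = FALSE])          # d x batch
    A <- t(infer_codes(Phi, patches[idx, , drop = FALSE], lambda,
                       max_iter = infer_iter, tol = infer_tol))
    R <- Xb - Phi %*% A                             # residual, d x batch
    step <- lr_scale * lr / (1 + it / decay)
    # per-atom normalized residual step: for atom j this is a relaxed exact
    # minimization of the batch quadratic along phi_j (scale-free in the
    # data), leaving atoms unused in the batch untouched
    s_j <- rowSums(A^2)
    Phi <- Phi + (R %*% t(A)) * rep(step / (s_j + 1e-8), each = d)
    nrm <- sqrt(colSums(Phi^2))
    dead <- nrm < 1e-12
    if (any(dead)) {                                # reseed collapsed atoms
      Phi[, dead] <- matrix(stats::rnorm(d * sum(dead)), d)
      nrm[dead] <- sqrt(colSums(Phi[, dead, drop = FALSE]^2))
    }
    Phi <- sweep(Phi, 2, nrm, "/")
    if (it %% holdout_every == 0 || it == n_iter) {
      Ah <- infer_codes(Phi, X_hold, lambda, max_iter = infer_iter,
                        tol = infer_tol)
      en <- mean(sc_energy(Phi, X_hold, Ah, lambda))
      if (!is.finite(en) || en > 2 * energy_prev) {
        lr_scale <- lr_scale / 2                    # diverging energy: back off
        message(sprintf("iteration %d: energy rose (%.4g); halving step size",
                        it, en))
      }
      energy_prev <- min(energy_prev, en)
      k <- k + 1
      trace[[k]] <- data.frame(
        iteration = it, energy = en,
        recon_error = mean(sqrt(rowSums((X_hold - Ah %*% t(Phi))^2)) /
                             pmax(sqrt(rowSums(X_hold^2)), .Machine$double.eps)),
        code_l1 = mean(rowSums(abs(Ah))))
    }
  }
  structure(list(Phi = Phi, patch_side = side, lambda = lambda,
                 trace = do.call(rbind, trace),
                 n_iter = n_iter, batch_size = batch_size, lr = lr,
                 seed = seed),
            class = "sc_dictionary")
}

#' @export
print.sc_dictionary <- function(x, ...) {
  cat(sprintf("sc_dictionary: %d atoms for %dx%d patches (lambda = %g)\n",
              ncol(x$Phi), x$patch_side, x$patch_side, x$lambda))
  if (!is.null(x$trace)) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  final held-out energy %.4g, reconstruction error %.3f\n",
                last$energy, last$recon_error))
  }
  invisible(x)
}

#' @export
coef.sc_dictionary <- function(object, ...) object$Phi

#' Encode new patches with a fitted dictionary
#'
#' @param object An `sc_dictionary`.
#' @param newdata Patches as rows.
#' @param lambda Penalty; defaults to the training value.
#' @param ... Passed to [infer_codes()].
#' @return Code matrix (rows aligned with `newdata`).
#' @export
predict.sc_dictionary <- function(object, newdata, lambda = object$lambda, ...) {
  infer_codes(object, newdata, lambda, ...)
}

#' Plot dictionary receptive fields as a montage
#'
#' @param x An `sc_dictionary`.
#' @param n_show Number of atoms to display (default up to 64).
#' @param ... Unused.
#' @export
plot.sc_dictionary <- function(x, n_show = min(64, ncol(x$Phi)), ...) {
  side <- x$patch_side
  ncol_grid <- ceiling(sqrt(n_show))
  nrow_grid <- ceiling(n_show / ncol_grid)
  op <- graphics::par(mfrow = c(nrow_grid, ncol_grid),
                      mar = c(0.1, 0.1, 0.1, 0.1))
  on.exit(graphics::par(op))
  for (i in seq_len(n_show)) {
    m <- matrix(x$Phi[, i], side, side)
    graphics::image(t(m[side:1, ]), col = grDevices::gray.colors(64),
                    axes = FALSE)
  }
  invisible(x)
}

#' Match learned atoms to a reference dictionary
#'
#' Greedy one-to-one matching by absolute cosine similarity; used for
#' parameter-recovery checks against a planted dictionary.
#'
#' @param learned,reference Dictionaries (matrices or `sc_dictionary`).
#' @return Data frame with one row per reference atom: `reference`,
#'   `learned` (matched column), `cosine` (absolute cosine similarity).
#' @export
match_atoms <- function(learned, reference) {
  L <- as_phi(learned); R <- as_phi(reference)
  L <- sweep(L, 2, sqrt(colSums(L^2)), "/")
  R <- sweep(R, 2, sqrt(colSums(R^2)), "/")
  C <- abs(crossprod(R, L))                       # ref x learned
  n_ref <- nrow(C)
  out <- data.frame(reference = seq_len(n_ref), learned = NA_integer_,
                    cosine = NA_real_)
  for (k in seq_len(min(dim(C)))) {
    best <- arrayInd(which.max(C), dim(C))
    out$learned[best[1]] <- best[2]
    out$cosine[best[1]] <- C[best[1], best[2]]
    C[best[1], ] <- -1
    C[, best[2]] <- -1
  }
  out
}
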