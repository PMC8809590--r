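#' Encode stimuli with the recurrent LCA circuit
#'
#' Integrates the locally competitive algorithm dynamics
#' \deqn{\tau \dot u = \Phi^T I - u - W a, \qquad a = T_\lambda(u)}
#' by forward Euler to a fixed point, with the recurrent term carried by the
#' circuit's rank-limited inhibitory factorization
#' (\eqn{W a = U\Sigma (V^T a) - \mathrm{diag}(U\Sigma V^T)\,a}; see
#' [recurrent_matrix()] for why the self term stays a leak). At
#' `N_I = N_E` the fixed point solves the sparse-coding objective exactly;
#' at lower ranks the circuit only approximates it — the approximation
#' quality across E:I ratios is the object of study.
#'
#' @param circuit An `ei_circuit`.
#' @param stimuli One patch (vector of length patch_dim) or a matrix with
#'   patches as rows.
#' @param lambda Sparsity penalty / threshold (>= 0).
#' @param dt_over_tau Euler step as a fraction of the membrane time
#'   constant, in (0, 1]; default 0.1.
#' @param max_steps Step cap (default 2000).
#' @param tol Convergence tolerance on max |du| per step (default 1e-6).
#' @param trace_energy Record the sparse-coding energy at every step
#'   (single-stimulus use; for diagnostics and descent checks).
#' @return An object of class `ei_encoding`: list with `a` (n x N_E code
#'   matrix), `b` (n x N_I inhibitory activities, \eqn{b = V^T a}), `u`
#'   (n x N_E internal states), `n_steps`, `converged`, `final_residual`,
#'   `lambda`, `dt_over_tau`, and `energy_trace` (NULL unless requested).
#' @examples
#' Phi <- qr.Q(qr(matrix(rnorm(16 * 4), 16)))[, 1:4]
#' circ <- build_circuit(Phi, N_I = 4)
#' enc <- lca_encode(circ, rnorm(16), lambda = 0.1)
#' enc$converged
#' @export
lca_encode <- function(circuit, stimuli, lambda, dt_over_tau = 0.1,
                       max_steps = 2000, tol = 1e-6, trace_energy = FALSE) {
  stopifnot(inherits(circuit, "ei_circuit"))
  if (lambda < 0) stop("lambda must be >= 0")
  if (dt_over_tau <= 0 || dt_over_tau > 1) stop("need 0 < dt_over_tau <= 1")
  if (is.vector(stimuli)) stimuli <- matrix(stimuli, nrow = 1)
  if (ncol(stimuli) != nrow(circuit$Phi)) stop("stimulus dimension mismatch")
  X <- t(stimuli)
  drive <- crossprod(circuit$Phi, X)
  U <- circuit$U; Sg <- circuit$Sigma; V <- circuit$V; dh <- circuit$d_hat
  Wmul <- function(a) U %*% (Sg * crossprod(V, a)) - dh * a
  energy_fn <- NULL
  if (trace_energy) {
    Phi <- circuit$Phi
    energy_fn <- function(A) mean(0.5 * colSums((X - Phi %*% A)^2) +
                                    lambda * colSums(abs(A)))
  }
  fit <- lca_fixed_point(drive, Wmul, lambda, dt = dt_over_tau,
                         max_steps = max_steps, tol = tol,
                         energy_fn = energy_fn)
  resid <- drive - fit$U - Wmul(fit$A)
  structure(list(a = t(fit$A), b = t(crossprod(V, fit$A)), u = t(fit$U),
                 n_steps = fit$iterations, converged = fit$converged,
                 final_residual = apply(abs(resid), 2, max) * dt_over_tau,
                 lambda = lambda, dt_over_tau = dt_over_tau,
                 energy_trace = fit$energies),
            class = "ei_encoding")
}

#' @export
print.ei_encoding <- function(x, ...) {
  cat(sprintf("ei_encoding: %d stimuli, %d E cells, %d I cells (lambda = %g)\n",
              nrow(x$a), ncol(x$a), ncol(x$b), x$lambda))
  cat(sprintf("  converged %d/%d, median steps %d, mean active fraction %.3f\n",
              sum(x$converged), length(x$converged),
              as.integer(stats::median(x$n_steps)),
              mean(x$a != 0)))
  invisible(x)
}

#' Encode a batch of patches, one result list entry per patch
#'
#' Convenience wrapper over [lca_encode()] that returns per-patch
#' `ei_encoding` objects (the batched matrix form in [lca_encode()] is what
#' the sweep uses internally).
#'
#' @param circuit An `ei_circuit`.
#' @param patches Matrix with patches as rows (may have zero rows).
#' @param lambda Sparsity penalty.
#' @param ... Solver settings passed to [lca_encode()].
#' @return List of `ei_encoding` objects, one per row of `patches`.
#' @export
lca_encode_batch <- function(circuit, patches, lambda, ...) {
  if (nrow(patches) == 0) return(list())
  enc <- lca_encode(circuit, patches, lambda, ...)
  lapply(seq_len(nrow(patches)), function(i) {
    structure(list(a = enc$a[i, , drop = FALSE], b = enc$b[i, , drop = FALSE],
                   u = enc$u[i, , drop = FALSE], n_steps = enc$n_steps[i],
                   converged = enc$converged[i],
                   final_residual = enc$final_residual[i],
                   lambda = enc$lambda, dt_over_tau = enc$dt_over_tau,
                   energy_trace = NULL),
              class = "ei_encoding")
  })
}
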