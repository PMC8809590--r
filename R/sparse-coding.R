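#' Soft thresholding
#'
#' Pointwise shrinkage nonlinearity \eqn{T_\lambda(u) = sign(u)\,
#' \max(|u|-\lambda, 0)}, the activation function of the LCA circuit and the
#' proximal operator of the \eqn{\ell_1} norm.
#'
#' @param u Numeric vector or matrix.
#' @param lambda Threshold (>= 0).
#' @return Object of the same shape as `u`.
#' @export
soft_threshold <- function(u, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  sign(u) * pmax(abs(u) - lambda, 0)
}

#' Sparse-coding energy of a set of codes
#'
#' Per-patch value of the sparse-coding objective
#' \eqn{E(a) = \tfrac12\|I - \Phi a\|_2^2 + \lambda \|a\|_1}.
#'
#' @param Phi Dictionary matrix (patch_dim x N_E) or `sc_dictionary`.
#' @param patches Matrix of patches as rows (n x patch_dim).
#' @param codes Matrix of codes as rows (n x N_E).
#' @param lambda Sparsity penalty.
#' @return Numeric vector of length n.
#' @export
sc_energy <- function(Phi, patches, codes, lambda) {
  Phi <- as_phi(Phi)
  R <- patches - codes %*% t(Phi)
  0.5 * rowSums(R^2) + lambda * rowSums(abs(codes))
}

as_phi <- function(Phi) {
  if (inherits(Phi, "sc_dictionary")) Phi$Phi else as.matrix(Phi)
}

#' Infer sparse codes for a set of patches
#'
#' Minimizes \eqn{\tfrac12\|I - \Phi a\|^2 + \lambda\|a\|_1} per patch,
#' either with an accelerated proximal-gradient method (FISTA) or by
#' integrating the full-rank LCA dynamics to a fixed point. The two solvers
#' reach the same objective value; the LCA route exists because it is the
#' circuit the package studies.
#'
#' @param Phi Dictionary matrix (patch_dim x N_E) or `sc_dictionary`.
#' @param patches Matrix with patches as rows (n x patch_dim); a single
#'   patch may be given as a vector.
#' @param lambda Sparsity penalty (>= 0).
#' @param solver `"proximal_gradient"` (default) or `"lca"`.
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance on the per-iterate change.
#' @return Matrix of codes as rows (n x N_E), with attribute `"converged"`
#'   (logical vector) and `"iterations"` (integer vector).
#' @export
infer_codes <- function(Phi, patches, lambda,
                        solver = c("proximal_gradient", "lca"),
                        max_iter = 2000, tol = 1e-8) {
  solver <- match.arg(solver)
  Phi <- as_phi(Phi)
  if (is.vector(patches)) patches <- matrix(patches, nrow = 1)
  if (ncol(patches) != nrow(Phi)) stop("patch dimension does not match dictionary")
  if (lambda < 0) stop("lambda must be >= 0")
  X <- t(patches)                       # d x n
  if (solver == "proximal_gradient") {
    fit <- fista_codes(Phi, X, lambda, max_iter = max_iter, tol = tol)
  } else {
    G <- crossprod(Phi)
    W <- G
    diag(W) <- diag(W) - 1
    fit <- lca_fixed_point(drive = crossprod(Phi, X), Wmul = function(a) W %*% a,
                           lambda = lambda, dt = 0.1, max_steps = max_iter,
                           tol = tol)
  }
  out <- t(fit$A)
  attr(out, "converged") <- fit$converged
  attr(out, "iterations") <- fit$iterations
  out
}

# FISTA on (1/2)||x - Phi a||^2 + lambda ||a||_1, all columns of X at once.
fista_codes <- function(Phi, X, lambda, max_iter = 2000, tol = 1e-8) {
  G <- crossprod(Phi)
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  if (L <= 0) L <- 1
  B <- crossprod(Phi, X)                # Phi^T x, K x n
  K <- ncol(Phi); n <- ncol(X)
  A <- matrix(0, K, n)
  Y <- A
  tk <- 1
  iters <- rep(max_iter, n)
  done <- rep(FALSE, n)
  for (it in seq_len(max_iter)) {
    grad <- G %*% Y - B
    A_new <- soft_threshold(Y - grad / L, lambda / L)
    delta <- abs(A_new - A)
    dmax <- if (n == 1) max(delta) else apply(delta, 2, max)
    newly <- !done & dmax < tol
    iters[newly] <- it
    done <- done | newly
    t_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Y <- A_new + ((tk - 1) / t_new) * (A_new - A)
    A <- A_new
    tk <- t_new
    if (all(done)) break
  }
  list(A = A, converged = done, iterations = iters)
}

# Forward-Euler LCA integration to a fixed point, all stimuli at once.
# drive = Phi^T I (K x n); Wmul(a) applies the recurrent matrix.
lca_fixed_point <- function(drive, Wmul, lambda, dt = 0.1, max_steps = 2000,
                            tol = 1e-6, guard = 1e8, energy_fn = NULL) {
  K <- nrow(drive); n <- ncol(drive)
  U <- matrix(0, K, n)
  A <- soft_threshold(U, lambda)
  steps <- rep(max_steps, n)
  done <- rep(FALSE, n)
  act <- seq_len(n)                 # columns still integrating; converged
  energies <- if (is.null(energy_fn)) NULL else numeric(0)
  for (it in seq_len(max_steps)) {  # columns are frozen at their fixed point
    dU <- drive[, act, drop = FALSE] - U[, act, drop = FALSE] -
      Wmul(A[, act, drop = FALSE])
    U[, act] <- U[, act, drop = FALSE] + dt * dU
    A[, act] <- soft_threshold(U[, act, drop = FALSE], lambda)
    if (!is.null(energy_fn)) energies <- c(energies, energy_fn(A))
    if (max(abs(U[, act])) > guard)
      stop("LCA dynamics diverged (|u| exceeded guard)")
    step_sz <- dt * apply(abs(dU), 2, max)
    newly <- step_sz < tol
    steps[act[newly]] <- it
    done[act[newly]] <- TRUE
    act <- act[!newly]
    if (length(act) == 0) break
  }
  list(A = A, U = U, converged = done, iterations = steps, energies = energies)
}

#' Check the l1 optimality certificate of a code
#'
#' At a minimizer of \eqn{\tfrac12\|I-\Phi a\|^2 + \lambda\|a\|_1} the
#' subgradient condition holds: \eqn{|\Phi^T(I-\Phi a)|_i \le \lambda} for
#' zero coefficients and \eqn{= \lambda\,\mathrm{sign}(a_i)} for nonzeros.
#'
#' @param Phi Dictionary matrix or `sc_dictionary`.
#' @param patch Single patch (vector).
#' @param code Code vector.
#' @param lambda Penalty.
#' @param tol Slack allowed on the certificate.
#' @return TRUE if the certificate holds within `tol`, with attribute
#'   `"violation"` giving the largest slack violation.
#' @export
kkt_certificate <- function(Phi, patch, code, lambda, tol = 1e-6) {
  Phi <- as_phi(Phi)
  g <- as.vector(crossprod(Phi, patch - Phi %*% code))
  nz <- code != 0
  viol <- max(c(abs(g[nz] - lambda * sign(code[nz])), abs(g[!nz]) - lambda, 0))
  structure(viol <= tol, violation = viol)
}
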