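#' Build a volume-constrained E/I circuit from a dictionary
#'
#' The ideal recurrent connectivity for the sparse-coding circuit is
#' \eqn{W = G - D} with \eqn{G = \Phi^T\Phi} the Gram matrix of the feature
#' set and \eqn{D} the identity. Interactions through \eqn{G} are
#' implemented disynaptically by a population of `N_I` inhibitory
#' interneurons: the rank-`N_I` truncated SVD \eqn{G \approx U\Sigma V^T}
#' (for this symmetric PSD matrix, the truncated eigendecomposition) is the
#' Frobenius-closest rank-`N_I` approximation; columns of `V` are E-to-I
#' input weights, `Sigma` entries are dendritic gains, columns of `U` are
#' I-to-E output weights.
#'
#' @param Phi An `sc_dictionary` or a patch_dim x N_E matrix with unit-norm
#'   columns.
#' @param N_I Size of the inhibitory population (1 <= N_I <= N_E).
#' @param rectify If TRUE, zero the negative entries of `U` and `V` after
#'   truncation (an interpretive step for structural analyses); the default
#'   FALSE keeps the raw factors, preserving the Frobenius-optimal
#'   approximation and the convergence behavior of the dynamics.
#' @return An object of class `ei_circuit`: list with `Phi`, `N_E`, `N_I`,
#'   `N`, `U` (N_E x N_I), `Sigma` (length N_I, non-increasing, >= 0), `V`
#'   (N_E x N_I), `sv_discarded` (the discarded spectrum), `rectify`, and
#'   `trunc_error` (Frobenius norm of `G - U Sigma V'`).
#' @examples
#' Phi <- qr.Q(qr(matrix(rnorm(64 * 16), 64)))[, 1:16]
#' circ <- build_circuit(Phi, N_I = 8)
#' print(circ)
#' @export
build_circuit <- function(Phi, N_I, rectify = FALSE) {
  dict <- if (inherits(Phi, "sc_dictionary")) Phi else NULL
  Phi <- as_phi(Phi)
  N_E <- ncol(Phi)
  if (N_I < 1 || N_I > N_E) stop("need 1 <= N_I <= N_E")
  G <- crossprod(Phi)
  eg <- eigen(G, symmetric = TRUE)
  vals <- pmax(eg$values, 0)                 # PSD up to round-off
  vecs <- eg$vectors
  # fix the eigenvector sign ambiguity: each I cell's input weights sum >= 0
  sgn <- ifelse(colSums(vecs) < 0, -1, 1)
  vecs <- sweep(vecs, 2, sgn, "*")
  U <- vecs[, seq_len(N_I), drop = FALSE]
  V <- U                                      # symmetric G: U = V
  Sigma <- vals[seq_len(N_I)]
  if (rectify) {
    U <- pmax(U, 0)
    V <- pmax(V, 0)
  }
  G_hat <- U %*% (Sigma * t(V))
  structure(list(Phi = Phi, dictionary = dict, N_E = N_E, N_I = N_I,
                 N = N_E + N_I, U = U, Sigma = Sigma, V = V,
                 d_hat = diag(G_hat),
                 sv_discarded = vals[-seq_len(N_I)], rectify = rectify,
                 trunc_error = norm(G - G_hat, "F")),
            class = "ei_circuit")
}

#' @export
print.ei_circuit <- function(x, ...) {
  cat(sprintf("ei_circuit: N = %d (N_E = %d, N_I = %d; E:I = %.2f:1)%s\n",
              x$N, x$N_E, x$N_I, x$N_E / x$N_I,
              if (x$rectify) ", rectified factors" else ""))
  cat(sprintf("  rank-%d truncation error |G - USV'|_F = %.3g\n",
              x$N_I, x$trunc_error))
  invisible(x)
}

#' Effective recurrent matrix of a circuit
#'
#' Returns the recurrent interaction matrix realized by the rank-limited
#' inhibitory population,
#' \eqn{W_{approx} = U\Sigma V^T - \mathrm{diag}(U\Sigma V^T)}: the
#' interneurons carry the couplings between distinct E cells while the self
#' term stays a true leak. At `N_I = N_E` the diagonal of the Gram matrix is
#' exactly 1 (unit-norm features), so `W_approx` equals the ideal
#' \eqn{\Phi^T\Phi - I} to machine precision. Keeping the self term out of
#' the truncation makes the effective interaction
#' \eqn{\hat G + (I - \mathrm{diag}\,\hat G)} positive definite, so the
#' dynamics converge at every rank; subtracting the full identity from a
#' truncated \eqn{\hat G} instead would leave active units with no leak and
#' the dynamics diverge whenever the stimulus drive has components outside
#' the interneuron subspace.
#'
#' @param circuit An `ei_circuit`.
#' @return N_E x N_E symmetric matrix.
#' @export
recurrent_matrix <- function(circuit) {
  W <- circuit$U %*% (circuit$Sigma * t(circuit$V))
  diag(W) <- 0
  W
}

#' Inhibitory interneuron activity for an excitatory code
#'
#' Each interneuron reads the excitatory population through its input
#' weights (a column of `V`): \eqn{b = V^T a}. Magnitudes `|b|` are used
#' wherever activities are interpreted as firing rates.
#'
#' @param circuit An `ei_circuit`.
#' @param a Excitatory code: vector of length N_E or matrix with codes as
#'   rows.
#' @return Vector of length N_I, or a matrix with rows aligned with `a`.
#' @export
inhibitory_activity <- function(circuit, a) {
  if (is.matrix(a)) {
    if (ncol(a) != circuit$N_E) stop("code length must be N_E")
    a %*% circuit$V
  } else {
    if (length(a) != circuit$N_E) stop("code length must be N_E")
    as.vector(crossprod(circuit$V, a))
  }
}

#' Pooled inhibitory-to-excitatory weight sample
#'
#' All `N_E * N_I` effective I-to-E synaptic weights of the circuit, with
#' the dendritic gain folded into the output synapses (entries of
#' `U %*% diag(Sigma)`); the sample used for weight-distribution and
#' kurtosis analyses. Set `fold_gain = FALSE` for the bare `U` entries.
#'
#' @param circuit An `ei_circuit`.
#' @param fold_gain Multiply each interneuron's output weights by its gain
#'   (default TRUE).
#' @return Numeric vector of length `N_E * N_I`.
#' @export
pooled_ie_weights <- function(circuit, fold_gain = TRUE) {
  W <- if (fold_gain) sweep(circuit$U, 2, circuit$Sigma, "*") else circuit$U
  as.vector(W)
}
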