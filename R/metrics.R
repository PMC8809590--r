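#' Relative stimulus reconstruction error
#'
#' \eqn{\|I - \Phi a\|_2 / \|I\|_2}: 0 for a perfect reconstruction, 1 for
#' the all-zero code.
#'
#' @param stimulus Stimulus vector (nonzero norm).
#' @param Phi Dictionary matrix or `sc_dictionary`.
#' @param code Code vector.
#' @return Scalar relative error.
#' @export
reconstruction_error <- function(stimulus, Phi, code) {
  Phi <- as_phi(Phi)
  nrm <- sqrt(sum(stimulus^2))
  if (nrm == 0) stop("stimulus has zero norm")
  sqrt(sum((stimulus - as.vector(Phi %*% code))^2)) / nrm
}

#' Treves-Rolls population sparsity
#'
#' The modified Treves-Rolls statistic
#' \deqn{TR = \frac{1}{1 - 1/N}\left[1 -
#'   \frac{(\sum_i a_i / N)^2}{\sum_i a_i^2 / N}\right]}
#' over the excitatory rates only: 1 when a single unit is active, 0 for
#' uniform activity, invariant to positive rescaling. Rates must be
#' magnitudes (non-negative); model activities are passed as `abs(a)`.
#'
#' @param rates Non-negative rate vector (length >= 2). Inhibitory units
#'   are excluded by the caller; the statistic is over the vector given.
#' @return TR value in [0, 1]; `NA` (flagged, excluded from averages) when
#'   all rates are zero.
#' @export
tr_sparsity <- function(rates) {
  n <- length(rates)
  if (n < 2) stop("need at least 2 units")
  if (any(rates < 0)) stop("rates must be non-negative magnitudes")
  s2 <- sum(rates^2)
  if (s2 == 0) return(NA_real_)
  (1 - (sum(rates) / n)^2 / (s2 / n)) / (1 - 1 / n)
}

#' Population activity density
#'
#' `1 - tr_sparsity(rates)`.
#'
#' @inheritParams tr_sparsity
#' @return Density in [0, 1], `NA` for all-zero input.
#' @export
population_density <- function(rates) 1 - tr_sparsity(rates)

#' Metabolic energy consumption of the network
#'
#' ATP budget combining a resting cost per neuron with a per-spike cost
#' times firing rate:
#' \deqn{E = (3.42\,N + \sum_i 7.1\,a_i + \sum_j 7.1\,b_j) \times 10^8
#'   \ \mathrm{ATP/s}}
#' with rates in Hz (rodent gray-matter budget; resting cost
#' 3.42e8 ATP/s per neuron, spike cost 7.1e8 ATP per spike).
#'
#' @param a_E Excitatory rates in Hz (non-negative magnitudes).
#' @param b_I Inhibitory rates in Hz (non-negative magnitudes).
#' @param N Total number of neurons paying the resting cost (defaults to
#'   `length(a_E) + length(b_I)`).
#' @return Energy in ATP molecules per second.
#' @export
metabolic_energy <- function(a_E, b_I, N = length(a_E) + length(b_I)) {
  if (any(a_E < 0) || any(b_I < 0)) stop("rates must be non-negative magnitudes")
  (3.42 * N + 7.1 * sum(a_E) + 7.1 * sum(b_I)) * 1e8
}

#' Normalize a performance measure across an E:I ratio series
#'
#' Rescales a measure so its minimum over the ratio grid maps to 0 and its
#' value at the 1:1 anchor maps to 1:
#' \deqn{(x - \min x) / (x_{1:1} - \min x).}
#' When the 1:1 value is itself the minimum the denominator vanishes; the
#' series is returned unnormalized with attribute `degenerate = TRUE`
#' rather than guessing.
#'
#' @param values Measure values over the ratio grid.
#' @param value_at_1to1 The measure at E:I = 1:1 (defaults to the first
#'   element).
#' @return Normalized series, with attribute `"degenerate"`.
#' @export
normalize_measure <- function(values, value_at_1to1 = values[1]) {
  lo <- min(values, na.rm = TRUE)
  den <- value_at_1to1 - lo
  if (!is.finite(den) || den <= 0)
    return(structure(values, degenerate = TRUE))
  structure((values - lo) / den, degenerate = FALSE)
}

#' Kurtosis of a weight sample
#'
#' Fourth standardized moment (Pearson convention: normal = 3), used on the
#' pooled I-to-E synaptic weight sample. `excess = TRUE` subtracts 3.
#'
#' @param x Numeric sample (length >= 4, nonzero variance).
#' @param excess Return excess kurtosis instead (default FALSE).
#' @return Scalar kurtosis.
#' @export
weight_kurtosis <- function(x, excess = FALSE) {
  if (length(x) < 4) stop("need at least 4 values")
  m <- mean(x)
  v <- mean((x - m)^2)
  if (v == 0) stop("zero-variance sample")
  k <- mean((x - m)^4) / v^2
  if (excess) k - 3 else k
}

#' Total inhibitory influence delivered to the excitatory population
#'
#' Mean over stimuli of the summed inhibitory current each encoding
#' delivers to E cells through the interneuron pathway: the drive is
#' \eqn{U\Sigma\,b} with \eqn{b = V^T a}, and under the sign convention of
#' the dynamics (\eqn{-Wa}) its positive entries are the inhibitory
#' component. The default sums those positive entries; `component = "all"`
#' sums magnitudes of the full drive. This quantity combines interneuron
#' activity with synaptic strengths; the study-level observation is that it
#' stays roughly constant across sparsity levels even as its components
#' shift. No standard closed form exists for it; this definition is a
#' documented modeling choice.
#'
#' @param circuit An `ei_circuit`.
#' @param encoding An `ei_encoding` (codes for >= 1 stimuli) or a code
#'   matrix with rows per stimulus.
#' @param component `"positive"` (default) or `"all"`.
#' @return Scalar mean influence.
#' @export
inhibitory_influence <- function(circuit, encoding,
                                 component = c("positive", "all")) {
  component <- match.arg(component)
  A <- if (inherits(encoding, "ei_encoding")) encoding$a else as.matrix(encoding)
  if (nrow(A) < 1) stop("need at least one encoding")
  B <- A %*% circuit$V                       # stimuli x N_I
  drive <- B %*% (circuit$Sigma * t(circuit$U))   # stimuli x N_E, = (U S b)'
  if (component == "positive") mean(rowSums(pmax(drive, 0)))
  else mean(rowSums(abs(drive)))
}
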