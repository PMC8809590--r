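#' Generate synthetic images with a power-law amplitude spectrum
#'
#' Draws Gaussian random fields whose radially averaged amplitude spectrum
#' falls off as \eqn{f^{-\gamma}}, the standard minimal surrogate for the
#' second-order statistics of natural images. With `spectral_exponent = 0`
#' the output is white noise.
#'
#' @param n Number of images.
#' @param side Image side length in pixels (>= 8; powers of two give the
#'   cleanest spectra).
#' @param spectral_exponent Power-law exponent \eqn{\gamma}; natural images
#'   are close to 1.
#' @param seed Integer seed; output is bit-reproducible given the seed.
#' @return An object of class `image_set`: a list with elements `images`
#'   (list of side x side matrices, each zero-mean), `side`, and
#'   `provenance = "onef_synthetic"`.
#' @examples
#' imgs <- generate_onef_images(2, side = 64, spectral_exponent = 1, seed = 1)
#' length(imgs$images)
#' @export
generate_onef_images <- function(n, side, spectral_exponent = 1, seed = 1) {
  if (n < 1 || side < 8) stop("need n >= 1 and side >= 8")
  if (spectral_exponent < 0) stop("spectral_exponent must be >= 0")
  set.seed(seed)
  # radial frequency grid in cycles/image (FFT ordering)
  f1 <- c(0:(floor(side / 2)), -(ceiling(side / 2) - 1):-1) / side
  fx <- matrix(f1, side, side)
  fy <- t(fx)
  fr <- sqrt(fx^2 + fy^2)
  amp <- ifelse(fr > 0, fr^(-spectral_exponent), 0) # kill DC -> zero mean
  images <- vector("list", n)
  for (k in seq_len(n)) {
    wn <- matrix(stats::rnorm(side * side), side, side)
    spec <- stats::fft(wn) * amp
    img <- Re(stats::fft(spec, inverse = TRUE)) / (side * side)
    img <- img - mean(img)
    images[[k]] <- img / stats::sd(img)
  }
  structure(list(images = images, side = side, provenance = "onef_synthetic"),
            class = "image_set")
}

#' @export
print.image_set <- function(x, ...) {
  cat(sprintf("image_set: %d images, %dx%d px, provenance '%s'\n",
              length(x$images), x$side, x$side, x$provenance))
  invisible(x)
}

#' Load grayscale images from PNG/TIFF files
#'
#' Reads each file as a 2-D luminance array (RGB channels are averaged) and
#' optionally applies the whitening filter of [whiten_image()]. Whitening
#' defaults ON for loaded raw images, matching the pre-whitened database the
#' sparse-coding literature trains on.
#'
#' @param paths Character vector of PNG or TIFF file paths.
#' @param whiten Apply the ramp whitening filter (default TRUE).
#' @return An `image_set` with provenance `"file"`.
#' @export
load_images <- function(paths, whiten = TRUE) {
  images <- lapply(paths, function(p) {
    ext <- tolower(tools::file_ext(p))
    img <- switch(ext,
      png = {
        if (!requireNamespace("png", quietly = TRUE)) stop("package 'png' required")
        png::readPNG(p)
      },
      tif = ,
      tiff = {
        if (!requireNamespace("tiff", quietly = TRUE)) stop("package 'tiff' required")
        tiff::readTIFF(p)
      },
      stop("unsupported image format: ", ext)
    )
    if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
    img <- img - mean(img)
    if (whiten) img <- whiten_image(img)
    img
  })
  side <- nrow(images[[1]])
  structure(list(images = images, side = side, provenance = "file"),
            class = "image_set")
}

#' Whiten an image with a ramp filter and low-pass rolloff
#'
#' Multiplies the spectrum by \eqn{f \exp(-(f/f_0)^4)}, flattening the
#' roughly 1/f amplitude spectrum of natural images while suppressing the
#' highest (noise-dominated) frequencies; the standard preprocessing for
#' sparse-coding dictionary training.
#'
#' @param img 2-D numeric matrix.
#' @param f0 Rolloff frequency in cycles/image (default 0.8 of Nyquist).
#' @return Whitened zero-mean matrix of the same size.
#' @export
whiten_image <- function(img, f0 = 0.4 * nrow(img)) {
  side <- nrow(img)
  f1 <- c(0:(floor(side / 2)), -(ceiling(side / 2) - 1):-1)
  fx <- matrix(f1, side, side)
  fy <- t(fx)
  fr <- sqrt(fx^2 + fy^2)
  filt <- fr * exp(-(fr / f0)^4)
  out <- Re(stats::fft(stats::fft(img) * filt, inverse = TRUE)) / (side * side)
  out - mean(out)
}

#' Extract square patches from an image set
#'
#' Samples patches at uniform random positions (overlap allowed) and returns
#' them as rows of a matrix together with the index of the source image, the
#' resampling unit used by the bootstrap standard errors.
#'
#' @param image_set An `image_set`.
#' @param patch_side Patch side length in pixels.
#' @param n_patches Number of patches to draw.
#' @param seed Integer seed.
#' @param zero_mean Subtract each patch's mean (default TRUE).
#' @return List with `patches` (n_patches x patch_side^2 matrix, patches as
#'   rows, column-major pixel order) and `image_id` (integer vector).
#' @export
sample_patches <- function(image_set, patch_side, n_patches, seed = 1,
                           zero_mean = TRUE) {
  stopifnot(inherits(image_set, "image_set"), patch_side >= 2)
  side <- image_set$side
  if (patch_side > side) stop("patch larger than image")
  set.seed(seed)
  n_img <- length(image_set$images)
  ids <- sample.int(n_img, n_patches, replace = TRUE)
  maxpos <- side - patch_side + 1
  rows <- sample.int(maxpos, n_patches, replace = TRUE)
  cols <- sample.int(maxpos, n_patches, replace = TRUE)
  out <- matrix(0, n_patches, patch_side^2)
  for (i in seq_len(n_patches)) {
    p <- image_set$images[[ids[i]]][rows[i]:(rows[i] + patch_side - 1),
                                    cols[i]:(cols[i] + patch_side - 1)]
    v <- as.vector(p)
    if (zero_mean) v <- v - mean(v)
    out[i, ] <- v
  }
  list(patches = out, image_id = ids)
}

#' Radially averaged amplitude spectrum of an image
#'
#' Utility for validating spectral properties of generated images: returns
#' mean FFT amplitude in integer frequency annuli.
#'
#' @param img 2-D numeric matrix.
#' @return Data frame with columns `freq` (cycles/image) and `amplitude`.
#' @export
radial_spectrum <- function(img) {
  side <- nrow(img)
  a <- Mod(stats::fft(img))
  f1 <- c(0:(floor(side / 2)), -(ceiling(side / 2) - 1):-1)
  fx <- matrix(f1, side, side)
  fr <- sqrt(fx^2 + t(fx)^2)
  ring <- round(fr)
  keep <- ring > 0 & ring <= floor(side / 2)
  amp <- tapply(a[keep], ring[keep], mean)
  data.frame(freq = as.numeric(names(amp)), amplitude = as.numeric(amp))
}

#' Generate patches from a planted dictionary
#'
#' Builds a random unit-norm dictionary and draws sparse coefficients
#' (zero with probability `1 - p_active`, otherwise Laplacian), then forms
#' `patches = coefficients %*% t(dictionary) + noise`. The stored parts
#' reassemble the patches exactly, making this the parameter-recovery
#' fixture for dictionary learning.
#'
#' @param K_true Number of planted atoms.
#' @param patch_side Patch side in pixels (patch dimension is its square).
#' @param n_patches Number of patches.
#' @param p_active Probability each coefficient is nonzero (0 < p < 1
#'   strictly, except the degenerate p = 0 all-zero case which is allowed).
#' @param noise_sd Gaussian pixel noise standard deviation (>= 0).
#' @param laplace_scale Scale of the Laplacian magnitude for active
#'   coefficients (default 1).
#' @param seed Integer seed.
#' @return Object of class `planted_patches`: list with `patches`
#'   (n_patches x patch_dim), `dictionary` (patch_dim x K_true, unit-norm
#'   columns), `coefficients` (n_patches x K_true), `noise`, `noise_sd`,
#'   `p_active`.
#' @export
generate_planted_patches <- function(K_true, patch_side, n_patches,
                                     p_active = 0.1, noise_sd = 0.01,
                                     laplace_scale = 1, seed = 1) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (p_active < 0 || p_active >= 1) stop("need 0 <= p_active < 1")
  set.seed(seed)
  d <- patch_side^2
  D <- matrix(stats::rnorm(d * K_true), d, K_true)
  D <- sweep(D, 2, sqrt(colSums(D^2)), "/")
  active <- matrix(stats::runif(n_patches * K_true) < p_active, n_patches, K_true)
  # Laplacian magnitudes with random sign
  mag <- matrix(stats::rexp(n_patches * K_true, rate = 1 / laplace_scale),
                n_patches, K_true)
  sgn <- matrix(sample(c(-1, 1), n_patches * K_true, replace = TRUE),
                n_patches, K_true)
  A <- active * mag * sgn
  noise <- matrix(stats::rnorm(n_patches * d, sd = noise_sd), n_patches, d)
  structure(list(patches = A %*% t(D) + noise, dictionary = D,
                 coefficients = A, noise = noise, noise_sd = noise_sd,
                 p_active = p_active),
            class = "planted_patches")
}

#' Generate hierarchical synthetic spike-count data
#'
#' Emulates the nesting of multi-subject electrophysiology: Poisson counts
#' per neuron and time bin, with log-normal multiplicative random effects on
#' rates at the subject and session levels. Population sparsity of the data
#' is controlled by the skew of the per-neuron base rates.
#'
#' @param n_subjects,n_sessions,n_trials Counts per level (all >= 1);
#'   sessions are per subject, trials per session.
#' @param n_neurons,n_bins Size of each trial's count matrix.
#' @param bin_width Bin width in seconds (> 0).
#' @param rates Per-neuron mean rates in Hz (length `n_neurons` or scalar).
#' @param subject_sd,session_sd Standard deviations of the log-normal rate
#'   multipliers at each level (defaults 0.2).
#' @param seed Integer seed.
#' @return Object of class `hier_spikes`: nested list
#'   `subjects -> sessions -> trials` of integer neuron x bin matrices, plus
#'   `bin_width`, `rates`, and the random-effect sds.
#' @export
generate_hier_spikes <- function(n_subjects, n_sessions, n_trials,
                                 n_neurons, n_bins, bin_width = 0.1,
                                 rates = 5, subject_sd = 0.2,
                                 session_sd = 0.2, seed = 1) {
  stopifnot(n_subjects >= 1, n_sessions >= 1, n_trials >= 1,
            n_neurons >= 1, n_bins >= 1, bin_width > 0)
  rates <- rep_len(rates, n_neurons)
  if (any(rates < 0) || any(!is.finite(rates))) stop("invalid rates")
  set.seed(seed)
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    subj_mult <- exp(stats::rnorm(1, 0, subject_sd))
    sessions <- vector("list", n_sessions)
    for (e in seq_len(n_sessions)) {
      sess_mult <- exp(stats::rnorm(1, 0, session_sd))
      lam <- rates * subj_mult * sess_mult * bin_width
      trials <- vector("list", n_trials)
      for (tr in seq_len(n_trials)) {
        trials[[tr]] <- matrix(stats::rpois(n_neurons * n_bins, rep(lam, n_bins)),
                               n_neurons, n_bins)
      }
      sessions[[e]] <- trials
    }
    subjects[[s]] <- sessions
  }
  structure(list(subjects = subjects, bin_width = bin_width, rates = rates,
                 subject_sd = subject_sd, session_sd = session_sd),
            class = "hier_spikes")
}

#' @export
print.hier_spikes <- function(x, ...) {
  tr <- x$subjects[[1]][[1]][[1]]
  cat(sprintf(paste0("hier_spikes: %d subjects x %d sessions x %d trials, ",
                     "%d neurons x %d bins (%.0f ms)\n"),
              length(x$subjects), length(x$subjects[[1]]),
              length(x$subjects[[1]][[1]]), nrow(tr), ncol(tr),
              1000 * x$bin_width))
  invisible(x)
}

#' Flatten a hierarchical spike dataset to a long data frame
#'
#' One row per (subject, session, trial, neuron, bin) count; the flat CSV
#' interchange format.
#'
#' @param x A `hier_spikes` object.
#' @param ... Unused.
#' @return A data.frame with columns subject, session, trial, neuron, bin,
#'   count.
#' @export
as.data.frame.hier_spikes <- function(x, ...) {
  rows <- list()
  k <- 1
  for (s in seq_along(x$subjects)) {
    for (e in seq_along(x$subjects[[s]])) {
      for (tr in seq_along(x$subjects[[s]][[e]])) {
        m <- x$subjects[[s]][[e]][[tr]]
        rows[[k]] <- data.frame(subject = s, session = e, trial = tr,
                                neuron = rep(seq_len(nrow(m)), ncol(m)),
                                bin = rep(seq_len(ncol(m)), each = nrow(m)),
                                count = as.vector(m))
        k <- k + 1
      }
    }
  }
  do.call(rbind, rows)
}

#' Write / read a hierarchical spike dataset as CSV
#'
#' @param x A `hier_spikes` object.
#' @param path CSV file path.
#' @export
write_hier_spikes <- function(x, path) {
  df <- as.data.frame(x)
  df <- cbind(df, bin_width = x$bin_width)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hier_spikes
#' @export
read_hier_spikes <- function(path) {
  df <- utils::read.csv(path)
  bw <- df$bin_width[1]
  n_neurons <- max(df$neuron)
  n_bins <- max(df$bin)
  subjects <- lapply(sort(unique(df$subject)), function(s) {
    ds <- df[df$subject == s, ]
    lapply(sort(unique(ds$session)), function(e) {
      de <- ds[ds$session == e, ]
      lapply(sort(unique(de$trial)), function(tr) {
        dt <- de[de$trial == tr, ]
        m <- matrix(0L, n_neurons, n_bins)
        m[cbind(dt$neuron, dt$bin)] <- dt$count
        m
      })
    })
  })
  structure(list(subjects = subjects, bin_width = bw, rates = NA,
                 subject_sd = NA, session_sd = NA),
            class = "hier_spikes")
}
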