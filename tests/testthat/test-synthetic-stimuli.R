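test_that("seeded generators are bit-reproducible", {
  a <- generate_onef_images(2, 64, 1, seed = 1)
  b <- generate_onef_images(2, 64, 1, seed = 1)
  expect_identical(a, b)
  p1 <- generate_planted_patches(10, 4, 50, p_active = 0.2, seed = 3)
  p2 <- generate_planted_patches(10, 4, 50, p_active = 0.2, seed = 3)
  expect_identical(p1, p2)
  s1 <- generate_hier_spikes(2, 2, 3, 5, 10, seed = 7)
  s2 <- generate_hier_spikes(2, 2, 3, 5, 10, seed = 7)
  expect_identical(s1, s2)
})

test_that("1/f images have the requested spectral slope and zero mean", {
  imgs <- generate_onef_images(3, 128, 1, seed = 2)
  for (img in imgs$images) {
    expect_true(all(is.finite(img)))
    expect_lt(abs(mean(img)), 1e-10)
    rs <- radial_spectrum(img)
    slope <- coef(lm(log(amplitude) ~ log(freq), data = rs))[2]
    expect_lt(abs(slope - (-1)), 0.15)
  }
  # exponent 0 is white noise: flat spectrum
  wn <- generate_onef_images(1, 128, 0, seed = 2)$images[[1]]
  rs <- radial_spectrum(wn)
  slope0 <- coef(lm(log(amplitude) ~ log(freq), data = rs))[2]
  expect_lt(abs(slope0), 0.1)
  expect_error(generate_onef_images(0, 64, 1, 1))
  expect_error(generate_onef_images(1, 4, 1, 1))
})

test_that("planted patches reassemble exactly from stored parts", {
  pp <- generate_planted_patches(12, 4, 80, p_active = 0.15, noise_sd = 0.05,
                                 seed = 5)
  expect_equal(pp$patches,
               pp$coefficients %*% t(pp$dictionary) + pp$noise,
               tolerance = 1e-12)
  expect_equal(colSums(pp$dictionary^2), rep(1, 12), tolerance = 1e-12)
  # empirical noise sd close to requested
  expect_lt(abs(sd(pp$noise) - 0.05) / 0.05, 0.1)
  # noiseless patches lie in span of active atoms
  p0 <- generate_planted_patches(6, 3, 20, p_active = 0.3, noise_sd = 0,
                                 seed = 6)
  for (i in 1:20) {
    act <- which(p0$coefficients[i, ] != 0)
    if (length(act) == 0) {
      expect_equal(sum(p0$patches[i, ]^2), 0)
    } else {
      D <- p0$dictionary[, act, drop = FALSE]
      resid <- p0$patches[i, ] - D %*% qr.solve(D, p0$patches[i, ])
      expect_lt(max(abs(resid)), 1e-10)
    }
  }
  # p_active = 0 gives pure noise
  pz <- generate_planted_patches(6, 3, 10, p_active = 0, noise_sd = 0.1,
                                 seed = 7)
  expect_true(all(pz$coefficients == 0))
  expect_error(generate_planted_patches(6, 3, 10, noise_sd = -1))
})

test_that("hierarchical spike counts match requested rates", {
  # no random effects, many bins: empirical rates within 5%
  hs <- generate_hier_spikes(1, 1, 1, n_neurons = 4, n_bins = 20000,
                             bin_width = 0.1, rates = c(2, 5, 10, 20),
                             subject_sd = 0, session_sd = 0, seed = 11)
  counts <- hs$subjects[[1]][[1]][[1]]
  emp <- rowMeans(counts) / 0.1
  expect_true(all(abs(emp - c(2, 5, 10, 20)) / c(2, 5, 10, 20) < 0.05))
  expect_true(all(counts >= 0))
  expect_error(generate_hier_spikes(1, 1, 1, 2, 10, rates = -3))
})

test_that("hier_spikes round-trips through the flat CSV format", {
  hs <- generate_hier_spikes(2, 2, 2, 4, 6, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_hier_spikes(hs, path)
  back <- read_hier_spikes(path)
  expect_equal(back$bin_width, hs$bin_width)
  for (s in 1:2) for (e in 1:2) for (tr in 1:2)
    expect_equal(back$subjects[[s]][[e]][[tr]],
                 hs$subjects[[s]][[e]][[tr]], ignore_attr = TRUE)
  unlink(path)
})

test_that("patch sampling is deterministic and zero-mean", {
  imgs <- generate_onef_images(3, 64, 1, seed = 1)
  a <- sample_patches(imgs, 8, 25, seed = 4)
  b <- sample_patches(imgs, 8, 25, seed = 4)
  expect_identical(a, b)
  expect_lt(max(abs(rowMeans(a$patches))), 1e-12)
  expect_true(all(a$image_id %in% 1:3))
})

test_that("whitening flattens a 1/f spectrum", {
  img <- generate_onef_images(1, 128, 1, seed = 9)$images[[1]]
  w <- whiten_image(img)
  rs <- radial_spectrum(w)
  low <- rs$amplitude[rs$freq <= 20]
  slope <- coef(lm(log(low) ~ log(rs$freq[rs$freq <= 20])))[2]
  expect_lt(abs(slope), 0.35)   # ~flat well below the rolloff
})
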