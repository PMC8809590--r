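test_that("find_optimum recovers a parabola vertex and flags boundaries", {
  ratios <- c(1, 2, 3, 4, 5, 6, 7)
  vertex <- 3.6
  vals <- (ratios - vertex)^2 + 0.5
  opt <- find_optimum(ratios, vals)
  expect_false(opt$boundary)
  expect_lt(abs(opt$ratio - vertex) / vertex, 0.01)
  # monotone series: boundary flag
  mono <- find_optimum(ratios, ratios * 2)
  expect_true(mono$boundary)
  expect_equal(mono$ratio, 1)
  # zero-variance bootstrap series: zero uncertainty
  bm <- matrix(rep(vals, 10), 10, byrow = TRUE)
  opt_b <- find_optimum(ratios, vals, boot_values = bm)
  expect_equal(opt_b$se, 0)
  expect_error(find_optimum(c(1, 2), c(1, 2)))
})

test_that("sweep config validates its grids", {
  imgs <- generate_onef_images(2, 32, 1, seed = 1)
  expect_error(sweep_config(N = 100, N_E_grid = c(40), lambda_grid = 0.1,
                            images = imgs, patch_side = 4),
               "1 <= N - N_E")
  expect_error(sweep_config(N = 100, N_E_grid = c(100), lambda_grid = 0.1,
                            images = imgs, patch_side = 4))
  cfg <- sweep_config(N = 100, N_E_grid = c(50, 60, 70), lambda_grid = 0.1,
                      images = imgs, patch_side = 4)
  expect_s3_class(cfg, "sweep_config")
})

test_that("a tiny sweep completes with finite metrics and full bookkeeping", {
  ts <- tiny_sweep()
  sw <- ts$sweep
  expect_equal(nrow(sw$table), 4)
  num <- sw$table[, c("reconstruction_error", "tr_sparsity", "density",
                      "energy", "ie_weight_kurtosis", "mean_I_rate",
                      "sd_I_rate", "total_inhibitory_influence")]
  expect_true(all(is.finite(as.matrix(num))))
  expect_true(all(num$density == 1 - num$tr_sparsity))
  expect_true(all(sw$table$energy >= 3.42 * 60 * 1e8))
  expect_equal(sw$table$N_E + sw$table$N_I, rep(60, 4))
  # optima recorded for all three measures
  expect_setequal(sw$optima$measure, c("error", "density", "energy"))
  curve <- optimal_ratio_curve(sw)
  expect_equal(nrow(curve$coincidence), 1)
})

test_that("duplicate cell seeds give identical records", {
  ts <- tiny_sweep()
  r1 <- run_cell(ts$cfg, 0.1, 36, seed = 77)
  r2 <- run_cell(ts$cfg, 0.1, 36, seed = 77)
  expect_equal(as.data.frame(r1), as.data.frame(r2), tolerance = 1e-12)
})

test_that("full-rank cell matches the ideal-circuit reconstruction error", {
  ts <- tiny_sweep()
  rec <- ts$sweep$cells[["lambda0.1_NE30"]]     # N_E = N_I = 30
  dict <- attr(rec, "dictionary")
  circ <- attr(rec, "circuit")
  expect_equal(circ$N_I, circ$N_E)
  # re-encode with the exact W via the proximal-gradient oracle
  imgs <- generate_onef_images(4, 64, 1, seed = 11)
  es_seed <- eisparse:::cell_seed(2, 1, 0L)
  ev <- sample_patches(imgs, 8, 25, seed = es_seed + 1L)
  codes <- infer_codes(dict, ev$patches, 0.1, max_iter = 4000, tol = 1e-10)
  err_ideal <- mean(sapply(seq_len(25), function(i)
    reconstruction_error(ev$patches[i, ], dict, codes[i, ])))
  expect_lt(abs(rec$reconstruction_error - err_ideal), 5e-3)
})

test_that("truncated codes never beat the full-rank code on the true objective", {
  # the full-rank fixed point minimizes the sparse-coding energy; circuits
  # with fewer interneurons only approximate the required competition, so
  # their codes score worse on the exact objective
  ts <- tiny_sweep()
  dict <- attr(ts$sweep$cells[["lambda0.1_NE42"]], "dictionary")
  imgs <- generate_onef_images(4, 64, 1, seed = 11)
  ev <- sample_patches(imgs, 8, 20, seed = 31)
  energy_at <- function(ni) {
    circ <- build_circuit(dict, ni)
    enc <- lca_encode(circ, ev$patches, 0.1, max_steps = 4000, tol = 1e-7)
    mean(sc_energy(dict, ev$patches, enc$a, 0.1))
  }
  e_full <- energy_at(42)
  for (ni in c(24, 12, 6))
    expect_gte(energy_at(ni), e_full - 1e-6)
})

test_that("inhibition summary tabulates optima and runs rate tests", {
  imgs <- generate_onef_images(3, 64, 1, seed = 12)
  cfg <- sweep_config(N = 60, N_E_grid = c(30, 36, 42, 48),
                      lambda_grid = c(0.05, 0.2), images = imgs,
                      patch_side = 8, n_train_patches = 500,
                      n_eval_patches = 20, n_boot = 40,
                      train = list(n_iter = 30, infer_iter = 40,
                                   infer_tol = 1e-4),
                      lca = list(max_steps = 1000, tol = 1e-5), seed = 3)
  sw <- run_sweep(cfg, keep_cells = TRUE)
  sm <- inhibition_summary(sw)
  expect_equal(nrow(sm$table), 2)
  expect_true(all(is.finite(sm$table$kurtosis)))
  expect_equal(nrow(sm$tests), 1)
  expect_true(all(sm$tests$p_mean_adj >= sm$tests$p_mean))
})
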