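# Small deterministic fixtures shared across test files.

# random dictionary with unit-norm columns
rand_dict <- function(d, K, seed = 1) {
  set.seed(seed)
  Phi <- matrix(rnorm(d * K), d, K)
  sweep(Phi, 2, sqrt(colSums(Phi^2)), "/")
}

# orthonormal dictionary (columns of a QR basis)
ortho_dict <- function(d, K, seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(d * d), d)))[, seq_len(K), drop = FALSE]
}

# shared cache so expensive sweeps are computed once per test run
.cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# small single-lambda sweep shared by the sweep and io tests
tiny_sweep <- function() cached("tiny_sweep", {
  imgs <- generate_onef_images(4, 64, 1, seed = 11)
  cfg <- sweep_config(N = 60, N_E_grid = c(30, 36, 42, 48), lambda_grid = 0.1,
                      images = imgs, patch_side = 8, n_train_patches = 600,
                      n_eval_patches = 25, n_boot = 50,
                      train = list(n_iter = 40, infer_iter = 50,
                                   infer_tol = 1e-4),
                      lca = list(max_steps = 1500, tol = 1e-5), seed = 2)
  list(cfg = cfg, sweep = run_sweep(cfg, keep_cells = TRUE))
})
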