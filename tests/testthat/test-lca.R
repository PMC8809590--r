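test_that("LCA handles trivial stimuli", {
  Phi <- rand_dict(16, 8, seed = 1)
  circ <- build_circuit(Phi, N_I = 8)
  enc <- lca_encode(circ, rep(0, 16), lambda = 0.2)
  expect_true(all(enc$a == 0))
  expect_true(enc$converged)
  expect_lte(enc$n_steps, 2)
  # scalar circuit: analytic fixed point a = I - lambda
  one <- build_circuit(matrix(1, 1, 1), 1)
  e1 <- lca_encode(one, 2, lambda = 0.5, max_steps = 5000, tol = 1e-12)
  expect_equal(as.vector(e1$a), 1.5, tolerance = 1e-6)
  expect_error(lca_encode(circ, rnorm(5), 0.1))
  expect_error(lca_encode(circ, rnorm(16), 0.1, dt_over_tau = 0))
})

test_that("full-rank LCA matches the proximal-gradient oracle", {
  for (k in 1:5) {
    Phi <- rand_dict(12, 20, seed = 30 + k)
    circ <- build_circuit(Phi, N_I = 20)
    x <- rnorm(12)
    lam <- 0.2
    enc <- lca_encode(circ, x, lam, max_steps = 30000, tol = 1e-11)
    oracle <- infer_codes(Phi, x, lam, max_iter = 5000, tol = 1e-12)
    e_lca <- sc_energy(Phi, matrix(x, 1), enc$a, lam)
    e_or <- sc_energy(Phi, matrix(x, 1), oracle, lam)
    expect_lt(abs(e_lca - e_or) / abs(e_or), 1e-6)
    # a = T_lambda(u) at return
    expect_equal(enc$a, soft_threshold(enc$u, lam), tolerance = 1e-12)
  }
})

test_that("energy descends along the trajectory after the transient", {
  Phi <- rand_dict(16, 24, seed = 6)
  circ <- build_circuit(Phi, N_I = 24)
  x <- rnorm(16)
  enc <- lca_encode(circ, x, 0.15, max_steps = 3000, tol = 1e-10,
                    trace_energy = TRUE)
  en <- enc$energy_trace
  late <- en[-(1:20)]
  expect_true(all(diff(late) <= 1e-8))
})

test_that("fixed-point consistency holds at convergence", {
  Phi <- rand_dict(16, 12, seed = 7)
  for (ni in c(12, 6)) {
    circ <- build_circuit(Phi, ni)
    x <- rnorm(16)
    enc <- lca_encode(circ, x, 0.1, max_steps = 20000, tol = 1e-10)
    expect_true(enc$converged)
    W <- recurrent_matrix(circ)
    resid <- crossprod(circ$Phi, x) - enc$u[1, ] - W %*% enc$a[1, ]
    expect_lt(max(abs(resid)), 1e-7)
  }
})

test_that("truncation by a zero singular value is exact", {
  # Phi with a rank-deficient Gram: last eigenvalue 0, so dropping it
  # changes nothing
  Phi <- rand_dict(8, 6, seed = 8)
  Phi[, 6] <- Phi[, 5]                      # duplicate atom -> rank 5 Gram
  ev <- eigen(crossprod(Phi), symmetric = TRUE, only.values = TRUE)$values
  expect_lt(ev[6], 1e-12)
  x <- rnorm(8)
  full <- lca_encode(build_circuit(Phi, 6), x, 0.2, max_steps = 20000,
                     tol = 1e-10)
  trunc <- lca_encode(build_circuit(Phi, 5), x, 0.2, max_steps = 20000,
                      tol = 1e-10)
  expect_equal(full$a, trunc$a, tolerance = 1e-6)
})

test_that("batch encoding equals per-stimulus encoding", {
  Phi <- rand_dict(16, 10, seed = 9)
  circ <- build_circuit(Phi, 5)
  X <- matrix(rnorm(64), 4, 16)
  batch <- lca_encode(circ, X, 0.1)
  for (i in 1:4) {
    single <- lca_encode(circ, X[i, ], 0.1)
    expect_equal(batch$a[i, ], single$a[1, ], tolerance = 1e-10)
  }
  # identical patches give identical rows
  Xd <- rbind(X[1, ], X[1, ])
  bd <- lca_encode(circ, Xd, 0.1)
  expect_identical(bd$a[1, ], bd$a[2, ])
  # empty batch
  expect_identical(lca_encode_batch(circ, X[0, , drop = FALSE], 0.1), list())
  lst <- lca_encode_batch(circ, X, 0.1)
  expect_length(lst, 4)
  expect_equal(lst[[2]]$a[1, ], batch$a[2, ])
})
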