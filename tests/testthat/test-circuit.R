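test_that("full-rank factorization reproduces the ideal connectivity", {
  Phi <- rand_dict(16, 8, seed = 1)
  circ <- build_circuit(Phi, N_I = 8)
  W_ideal <- crossprod(Phi); diag(W_ideal) <- 0
  expect_lt(norm(recurrent_matrix(circ) - W_ideal, "F"), 1e-10)
  expect_equal(circ$trunc_error, 0, tolerance = 1e-10)
  # orthonormal dictionary: G = I, recurrent interactions vanish
  Q <- ortho_dict(16, 8, seed = 2)
  c2 <- build_circuit(Q, N_I = 8)
  expect_lt(norm(recurrent_matrix(c2), "F"), 1e-10)
})

test_that("truncation error equals the discarded-singular-value formula", {
  Phi <- rand_dict(16, 8, seed = 3)
  ev <- eigen(crossprod(Phi), symmetric = TRUE, only.values = TRUE)$values
  for (ni in c(1, 3, 5, 7)) {
    circ <- build_circuit(Phi, N_I = ni)
    expect_equal(circ$trunc_error, sqrt(sum(ev[(ni + 1):8]^2)),
                 tolerance = 1e-10)
  }
  # Eckart-Young: error monotone non-increasing in N_I
  errs <- sapply(1:8, function(ni) build_circuit(Phi, ni)$trunc_error)
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("circuit structure invariants hold", {
  Phi <- rand_dict(12, 10, seed = 4)
  circ <- build_circuit(Phi, N_I = 4)
  expect_equal(circ$N, circ$N_E + circ$N_I)
  expect_true(all(circ$Sigma >= 0))
  expect_true(all(diff(circ$Sigma) <= 1e-12))       # non-increasing gains
  expect_true(all(colSums(circ$V) >= -1e-12))       # sign convention
  W <- recurrent_matrix(circ)
  expect_lt(norm(W - t(W), "F"), 1e-12)             # symmetric
  expect_error(build_circuit(Phi, 11))
  expect_error(build_circuit(Phi, 0))
})

test_that("inhibitory activity is the V-projection of the code", {
  Phi <- rand_dict(12, 8, seed = 5)
  circ <- build_circuit(Phi, N_I = 3)
  expect_equal(inhibitory_activity(circ, rep(0, 8)), rep(0, 3))
  a <- rnorm(8)
  b <- inhibitory_activity(circ, a)
  expect_equal(b, as.vector(crossprod(circ$V, a)))
  # rank-limited drive identity: U Sigma b == U Sigma V' a
  expect_equal(as.vector(circ$U %*% (circ$Sigma * b)),
               as.vector(circ$U %*% (circ$Sigma * t(circ$V)) %*% a),
               tolerance = 1e-12)
  # N_I = 1 reduces to a dot product
  c1 <- build_circuit(Phi, N_I = 1)
  expect_equal(inhibitory_activity(c1, a), sum(c1$V[, 1] * a))
  # matrix form agrees with vector form
  A <- matrix(rnorm(16), 2, 8)
  B <- inhibitory_activity(build_circuit(Phi, 3), A)
  expect_equal(B[1, ], inhibitory_activity(build_circuit(Phi, 3), A[1, ]))
})

test_that("pooled I->E weights fold the gain and scale linearly", {
  Phi <- rand_dict(12, 8, seed = 6)
  c1 <- build_circuit(Phi, N_I = 1)
  expect_length(pooled_ie_weights(c1), 8)
  c3 <- build_circuit(Phi, N_I = 3)
  w <- pooled_ie_weights(c3)
  expect_length(w, 8 * 3)
  expect_equal(w, as.vector(sweep(c3$U, 2, c3$Sigma, "*")))
  # doubling all gains doubles the pooled sample
  c3b <- c3; c3b$Sigma <- 2 * c3$Sigma
  expect_equal(pooled_ie_weights(c3b), 2 * w)
  expect_equal(pooled_ie_weights(c3, fold_gain = FALSE), as.vector(c3$U))
})

test_that("rectified factors are non-negative", {
  Phi <- rand_dict(12, 8, seed = 7)
  circ <- build_circuit(Phi, N_I = 4, rectify = TRUE)
  expect_true(all(circ$U >= 0))
  expect_true(all(circ$V >= 0))
})
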