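test_that("trial sparsity matches hand-computed bin cases", {
  # every bin one-hot -> 1
  m <- matrix(c(3, 0, 0, 0, 0, 2), 2, 3)        # bins: (3,0),(0,0),(0,2)
  expect_equal(trial_sparsity(m), 1)
  # uniform bins -> 0
  expect_equal(trial_sparsity(matrix(2, 3, 4)), 0)
  # 2 neurons, bins (1,1) and (1,0): mean of (0, 1) = 0.5
  expect_equal(trial_sparsity(cbind(c(1, 1), c(1, 0))), 0.5)
  # all-silent trial is flagged missing
  expect_true(is.na(trial_sparsity(matrix(0, 2, 3))))
  expect_error(trial_sparsity(matrix(1, 1, 5)))
  expect_error(trial_sparsity(matrix(-1, 2, 2)))
  # neuron relabeling and uniform rate scaling leave TR unchanged
  set.seed(1)
  cnt <- matrix(rpois(40, 2), 4, 10)
  expect_equal(trial_sparsity(cnt), trial_sparsity(cnt[c(3, 1, 4, 2), ]))
  expect_equal(trial_sparsity(cnt), trial_sparsity(5L * cnt))
})

test_that("hierarchical bootstrap is seeded and directionally calibrated", {
  a <- generate_hier_spikes(3, 2, 8, 10, 15, rates = c(rep(1, 8), 8, 12),
                            seed = 5)
  b <- generate_hier_spikes(3, 2, 8, 10, 15, rates = c(rep(1, 8), 8, 12),
                            seed = 6)
  r1 <- hierarchical_bootstrap(a, b, n_boot = 500, seed = 9)
  r2 <- hierarchical_bootstrap(a, b, n_boot = 500, seed = 9)
  expect_identical(r1, r2)
  expect_length(r1$dist_a, 500)
  expect_true(r1$p_a_sparser >= 0 && r1$p_a_sparser <= 1)
  # two-sided consistency of the directed p-values
  expect_gte(r1$p_a_sparser + r1$p_b_sparser, 1)   # ties counted both ways
})

test_that("identically generated groups give p near 0.5", {
  a <- generate_hier_spikes(4, 2, 10, 12, 20, rates = 4, seed = 21)
  b <- generate_hier_spikes(4, 2, 10, 12, 20, rates = 4, seed = 22)
  r <- hierarchical_bootstrap(a, b, n_boot = 2000, seed = 3)
  # 3 MC sds of a fair coin at n=2000 is ~0.034, but group-level variation
  # dominates; just require no decisive separation
  expect_gt(r$p_a_sparser, 0.05)
  expect_lt(r$p_a_sparser, 0.95)
})

test_that("completely separated groups give p = 0", {
  # group A: one-hot bins (TR 1); group B: uniform bins (TR 0)
  mk <- function(fill) {
    g <- generate_hier_spikes(2, 2, 3, 4, 5, rates = 1, seed = 1)
    for (s in seq_along(g$subjects))
      for (e in seq_along(g$subjects[[s]]))
        for (tr in seq_along(g$subjects[[s]][[e]]))
          g$subjects[[s]][[e]][[tr]] <- fill
    g
  }
  onehot <- matrix(0L, 4, 5); onehot[1, ] <- 3L
  a <- mk(onehot)
  b <- mk(matrix(2L, 4, 5))
  r <- hierarchical_bootstrap(a, b, n_boot = 300, seed = 2)
  expect_equal(r$p_a_sparser, 0)
  expect_equal(r$p_b_sparser, 1)
})

test_that("pooled bootstrap method ignores the hierarchy", {
  a <- generate_hier_spikes(3, 2, 6, 8, 10, rates = 3, seed = 31)
  b <- generate_hier_spikes(3, 2, 6, 8, 10, rates = 3, seed = 32)
  r <- hierarchical_bootstrap(a, b, n_boot = 400, seed = 4, method = "pooled")
  expect_equal(r$method, "pooled")
  expect_length(r$dist_a, 400)
})

test_that("compare_groups applies the Bonferroni correction", {
  mk_res <- function(p) structure(list(p_a_sparser = p), class = "ei_bootstrap")
  results <- list(h1 = mk_res(0.02), h2 = mk_res(0.5))
  tab <- compare_groups(results, alpha = 0.05)
  expect_equal(tab$threshold, rep(0.025, 2))
  expect_equal(tab$p_adjusted, c(0.04, 1))
  expect_equal(tab$significant, c(TRUE, FALSE))
  expect_error(compare_groups(results, hypotheses = "nope"),
               "unknown hypothesis")
})
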