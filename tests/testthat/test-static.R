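test_that("conjugate tree-parameter updates match digamma identities", {
  tr <- hier_tree(1)
  st <- list(e = c(0, 0, 0), n = c(0, 0, 0))
  up <- update_tree_params(st, tree = tr)
  expect_equal(up$a, rep(1, 3))
  expect_equal(up$b, rep(1, 3))
  expect_equal(up$Elog, rep(digamma(1) - digamma(2), 3))  # = -1
  expect_equal(up$Elog[1], -1)

  up2 <- update_tree_params(list(e = c(3, 0, 0), n = c(0, 0, 0)), tree = tr)
  expect_equal(up2$a[1], 4)
  expect_equal(up2$b[1], 1)

  # symmetric counts: <log theta> == <log(1-theta)>
  up3 <- update_tree_params(list(e = c(5, 5, 5), n = c(5, 5, 5)), tree = tr)
  expect_equal(up3$Elog, up3$Elog1m)
  expect_error(update_tree_params(list(e = -1, n = 0), tree = tr), "non-negative")
})

test_that("softmax assignment update is normalized, exact, and shift-invariant", {
  expect_equal(update_assignment(c(0, 0, 0, 0)), rep(1 / 4, 4))
  expect_equal(update_assignment(log(c(3, 1))), c(0.75, 0.25))
  f <- c(-3, 0.5, 2, -1)
  expect_equal(update_assignment(f), update_assignment(f + 17.3))
  expect_equal(sum(update_assignment(c(-1000, 0))), 1)
  expect_error(update_assignment(c(-Inf, -Inf)), "finite")
})

test_that("assignment field reproduces a hand-computed 3-vertex case", {
  # vertices a,b hard in leaf 1 form a 2-clique; c adjacent to both
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[1, 3] <- A[2, 3] <- 1
  A <- A + t(A)
  dimnames(A) <- list(c("a", "b", "c"), c("a", "b", "c"))
  sn <- snapshot(A)
  tr <- hier_tree(1)
  tau <- rbind(c(1, 0), c(1, 0), c(0.5, 0.5))
  st <- expected_counts(sn, tau, tr)
  tr <- update_tree_params(st, tree = tr)
  f <- assignment_field("c", sn, tau, tr)
  # by hand: d into leaf 1 = 2, m1 = 2, d into leaf 2 = 0, m2 = 0
  expect_equal(f[1], 2 * tr$Elog[2])          # within-leaf-1 edges
  expect_equal(f[2], 2 * tr$Elog[1])          # both edges cross the root
  expect_gt(f[1], f[2])                       # joining the clique is favored
  expect_error(assignment_field("zz", sn, tau, tr), "not active")

  # adding a constant to all node expectations shifts every leaf equally
  tr2 <- tr
  tr2$Elog <- tr$Elog + 0.7
  tr2$Elog1m <- tr$Elog1m + 0.7
  f2 <- assignment_field("c", sn, tau, tr2)
  expect_equal(update_assignment(f2), update_assignment(f))
})

test_that("static fit separates two disjoint cliques and is deterministic", {
  sn <- two_cliques_snapshot(5)
  fit <- fit_static(sn, depth = 1, seed = 42)
  cm <- co_membership(fit)
  expect_gt(min(cm[1:5, 1:5], na.rm = TRUE), 0.99)
  expect_lt(max(cm[1:5, 6:10]), 0.01)
  # global optimum: matches exhaustive collapsed posterior preference
  z_split <- rep(1:2, each = 5)
  z_merge <- rep(1, 10)
  tr <- hier_tree(1)
  expect_gt(
    collapsed_log_likelihood(dyhm:::hard_assignment_stats(sn, z_split, tr)),
    collapsed_log_likelihood(dyhm:::hard_assignment_stats(sn, z_merge, tr)))

  fit2 <- fit_static(sn, depth = 1, seed = 42)
  expect_identical(fit$tau, fit2$tau)
  expect_identical(fit$elbo_trace, fit2$elbo_trace)
})

test_that("a single clique is co-clustered by the collapsed likelihood and treated
           exchangeably by the mean field", {
  sn <- snapshot(clique_adjacency(1, 8))
  tr <- hier_tree(1)
  # the collapsed (exact) likelihood prefers the one-leaf configuration
  ll_one <- collapsed_log_likelihood(
    dyhm:::hard_assignment_stats(sn, rep(1L, 8), tr))
  ll_split <- collapsed_log_likelihood(
    dyhm:::hard_assignment_stats(sn, rep(1:2, each = 4), tr))
  expect_gt(ll_one, ll_split)
  # exact enumeration: the exchangeable flat-prior posterior spreads mass
  # over many splits of the clique, so pairwise co-membership sits well
  # below 1; MCMC and the mean field both reproduce that value
  post <- brute_posterior(sn, tr)
  co_exact <- sum(post$prob[post$assignments[, 1] == post$assignments[, 2]])
  mc <- sample_co_membership(sn, depth = 1, sweeps = 4e4, seed = 5)
  expect_equal(mc$comembership[1, 2], co_exact, tolerance = 0.03)
  # the mean field's symmetric optimum gives exactly 1/G = 0.5; it tracks
  # the exact value (~0.6) to within the oracle-agreement tolerance
  fit <- fit_static(sn, depth = 1, seed = 5)
  cm <- co_membership(fit)
  expect_equal(min(cm, na.rm = TRUE), 0.5, tolerance = 0.01)
  expect_lt(max(abs(cm - co_exact), na.rm = TRUE), 0.15)
})

test_that("the ELBO trace is monotone and the kernel agrees with the R reference", {
  sim <- generate_static(n_groups = c(4, 4), group_size = c(5, 5),
                         pwithin = 0.9, pbetween = 0.05, seed = 9)
  fit <- fit_static(sim$snapshot, depth = 2, seed = 9)
  expect_true(all(diff(fit$elbo_trace) > -1e-6 * (1 + abs(fit$elbo))))

  # kernel-reported bound equals the independent R implementation
  expect_equal(elbo(sim$snapshot, fit$tau, fit$tree), fit$elbo, tolerance = 1e-8)

  # converged memberships are a fixed point of the R-side update equations
  for (i in seq_len(nrow(fit$tau))) {
    f <- assignment_field(i, sim$snapshot, fit$tau, fit$tree)
    expect_equal(update_assignment(f), unname(fit$tau[i, ]), tolerance = 1e-4)
  }

  # hard-assignment identity: ELBO = collapsed log-likelihood - N log G
  sn <- two_cliques_snapshot(4)
  tr <- hier_tree(1)
  tau <- matrix(1e-12, 8, 2)
  tau[1:4, 1] <- 1; tau[5:8, 2] <- 1
  tau <- tau / rowSums(tau)
  st <- expected_counts(sn, tau, tr)
  tr <- update_tree_params(st, tree = tr)
  expect_equal(elbo(sn, tau, tr),
               collapsed_log_likelihood(st) - 8 * log(2), tolerance = 1e-6)
})

test_that("planted partitions at strong contrast are recovered", {
  f1 <- vapply(1:5, function(s) {
    sim <- generate_static(n_groups = c(5, 5), group_size = c(6, 6),
                           pwithin = 0.9, pbetween = 0.05, seed = s)
    fit <- fit_static(sim$snapshot, depth = 3, seed = s)
    f1_max(pr_curve(co_membership(fit),
                    pair_labels(sim$truth$labels, rownames(fit$tau))))
  }, numeric(1))
  expect_gte(mean(f1), 0.95)
})
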