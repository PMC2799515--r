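test_that("expected counts on degenerate inputs behave as specified", {
  tr <- hier_tree(1)
  # empty graph: all edge counts zero, non-edges carry the pair mass
  empty <- snapshot(matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3])))
  tau <- matrix(1 / 2, 3, 2)
  st <- expected_counts(empty, tau, tr)
  expect_equal(st$e, rep(0, 3))
  expect_equal(sum(st$n), 3)  # 3 vertex pairs

  # one edge, both endpoints hard in leaf 1
  sn <- snapshot(cbind("a", "b"))
  tau1 <- matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE)
  st1 <- expected_counts(sn, tau1, tr)
  expect_equal(st1$e[2], 1)  # leaf-1 node
  expect_equal(st1$e[1], 0)  # root split

  expect_error(expected_counts(sn, matrix(1, 3, 2), tr), "tau")
  expect_error(expected_counts(sn, matrix(c(2, 0, 1, 0), 2, 2, byrow = TRUE), tr),
               "normalized")
})

test_that("soft expected counts equal the brute-force assignment enumeration", {
  tr <- hier_tree(2)
  # 4-vertex path graph
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 3] <- A[3, 4] <- 1
  A <- A + t(A)
  dimnames(A) <- list(letters[1:4], letters[1:4])
  sn <- snapshot(A)
  set.seed(11)
  for (rep in 1:5) {
    tau <- matrix(rexp(16), 4, 4)
    tau <- tau / rowSums(tau)
    st <- expected_counts(sn, tau, tr)
    oracle <- brute_expected_counts(sn, tau, tr)
    expect_equal(st$e, oracle$e, tolerance = 1e-10)
    expect_equal(st$n, oracle$n, tolerance = 1e-10)
  }
})

test_that("hard-assignment counts partition all active pairs", {
  set.seed(21)
  for (rep in 1:5) {
    N <- 7
    A <- matrix(rbinom(N * N, 1, 0.4), N, N)
    A[lower.tri(A, diag = TRUE)] <- 0
    A <- A + t(A)
    dimnames(A) <- list(sprintf("v%d", 1:N), sprintf("v%d", 1:N))
    sn <- snapshot(A)
    tr <- hier_tree(3)
    z <- sample.int(tr$G, N, replace = TRUE)
    tau <- matrix(0, N, tr$G)
    tau[cbind(1:N, z)] <- 1
    st <- expected_counts(sn, tau, tr)
    expect_equal(sum(st$e), sum(A) / 2)
    expect_equal(sum(st$e) + sum(st$n), N * (N - 1) / 2)
    # matches direct counting by leaf-pair LCA
    hard <- dyhm:::hard_assignment_stats(sn, z, tr)
    expect_equal(st$e, hard$e, tolerance = 1e-10)
    expect_equal(st$n, hard$n, tolerance = 1e-10)
  }
})

test_that("collapsed likelihood matches Beta-function arithmetic", {
  expect_equal(collapsed_log_likelihood(list(e = 0, n = 0)), 0)
  expect_equal(collapsed_log_likelihood(list(e = 1, n = 0)), log(1 / 2))
  expect_equal(collapsed_log_likelihood(list(e = 2, n = 1)), log(1 / 12))
  expect_equal(collapsed_log_likelihood(list(e = c(0, 0, 0), n = c(0, 0, 0))), 0)
  expect_error(collapsed_log_likelihood(list(e = -1, n = 0)), "non-negative")
})

test_that("collapsed likelihood is invariant to vertex relabeling and mirror swaps", {
  set.seed(31)
  N <- 6
  A <- matrix(rbinom(N * N, 1, 0.5), N, N)
  A[lower.tri(A, diag = TRUE)] <- 0
  A <- A + t(A)
  dimnames(A) <- list(sprintf("v%d", 1:N), sprintf("v%d", 1:N))
  sn <- snapshot(A)
  tr <- hier_tree(2)
  z <- c(1, 1, 2, 3, 4, 2)
  ll <- collapsed_log_likelihood(dyhm:::hard_assignment_stats(sn, z, tr))

  # vertex relabeling: permute vertices and assignments together
  perm <- sample(N)
  A2 <- A[perm, perm]
  dimnames(A2) <- dimnames(A)
  ll_perm <- collapsed_log_likelihood(
    dyhm:::hard_assignment_stats(snapshot(A2), z[perm], tr))
  expect_equal(ll_perm, ll)

  # mirror swap of the left subtree of the root: leaves (1,2) -> (2,1)
  swap <- c(2, 1, 3, 4)
  ll_swap <- collapsed_log_likelihood(
    dyhm:::hard_assignment_stats(sn, swap[z], tr))
  expect_equal(ll_swap, ll)
  # mirror swap at the root: whole left and right subtrees exchange
  swap_root <- c(3, 4, 1, 2)
  ll_root <- collapsed_log_likelihood(
    dyhm:::hard_assignment_stats(sn, swap_root[z], tr))
  expect_equal(ll_root, ll)
})

test_that("node enrichment compares node density to global density", {
  tr <- hier_tree(1)
  # complete graph: every defined node density equals the global density
  K4 <- snapshot(clique_adjacency(1, 4))
  tau <- matrix(c(1, 0), 4, 2, byrow = TRUE)
  st <- expected_counts(K4, tau, tr)
  enr <- node_enrichment(st, K4)
  expect_equal(enr[2], 0)          # occupied leaf: density ratio 1
  expect_true(is.na(enr[1]))       # no cross pairs at the root

  # zero edges at a node with positive pair count -> clipped depletion
  A <- clique_adjacency(2, 3)
  sn <- snapshot(A)
  tau2 <- matrix(0, 6, 2)
  tau2[1:3, 1] <- 1; tau2[4:6, 2] <- 1
  st2 <- expected_counts(sn, tau2, tr)
  enr2 <- node_enrichment(st2, sn)
  expect_equal(enr2[1], -10)       # root split has 0 of 9 pairs
  expect_gt(enr2[2], 0)            # cliques denser than global

  expect_error(node_enrichment(st2, snapshot(matrix(0, 2, 2,
    dimnames = list(c("x", "y"), c("x", "y"))))), "empty")
})
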