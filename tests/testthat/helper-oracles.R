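# Independent oracles and small fixture builders used across the suite.

# adjacency of k disjoint cliques of size s
clique_adjacency <- function(k, s) {
  N <- k * s
  A <- matrix(0, N, N)
  for (g in seq_len(k)) {
    idx <- ((g - 1) * s + 1):(g * s)
    A[idx, idx] <- 1
  }
  diag(A) <- 0
  dimnames(A) <- list(sprintf("v%02d", 1:N), sprintf("v%02d", 1:N))
  A
}

two_cliques_snapshot <- function(s = 5) snapshot(clique_adjacency(2, s))

# Brute-force sufficient statistics: enumerate all G^N hard assignments,
# weight each by the product of tau rows, count edges/non-edges by
# leaf-pair lowest common ancestor. Exponential; for tiny fixtures only.
brute_expected_counts <- function(snapshot, tau, tree) {
  A <- snapshot$adj
  N <- nrow(A)
  G <- tree$G
  e <- n <- numeric(tree$n_nodes)
  grid <- as.matrix(expand.grid(rep(list(seq_len(G)), N)))
  for (row in seq_len(nrow(grid))) {
    z <- grid[row, ]
    w <- prod(tau[cbind(seq_len(N), z)])
    if (w == 0) next
    for (i in seq_len(N - 1)) for (j in (i + 1):N) {
      r <- tree$lca[z[i], z[j]]
      if (A[i, j] != 0) e[r] <- e[r] + w else n[r] <- n[r] + w
    }
  }
  list(e = e, n = n)
}

# exhaustive collapsed posterior over all hard assignments
brute_posterior <- function(snapshot, tree) {
  N <- nrow(snapshot$adj)
  grid <- as.matrix(expand.grid(rep(list(seq_len(tree$G)), N)))
  ll <- apply(grid, 1, function(z)
    collapsed_log_likelihood(dyhm:::hard_assignment_stats(snapshot, z, tree),
                             tree$prior))
  w <- exp(ll - max(ll))
  list(assignments = grid, prob = w / sum(w))
}

# hypergeometric upper tail by explicit combinatorial summation
brute_hyper_upper <- function(k, K, n, D) {
  js <- max(k, 0):min(K, D)
  sum(choose(K, js) * choose(n - K, D - js)) / choose(n, D)
}

# mean per-snapshot max-F1 of the shared-neighbor baseline against truth
hyper_f1_per_snapshot <- function(series, truth) {
  vapply(seq_along(series$snapshots), function(t) {
    sn <- series$snapshots[[t]]
    verts <- rownames(sn$adj)
    ranks <- rank_all_pairs(sn)
    score <- matrix(NA_real_, length(verts), length(verts),
                    dimnames = list(verts, verts))
    score[cbind(ranks$u, ranks$v)] <- -log(ranks$p)
    score[cbind(ranks$v, ranks$u)] <- -log(ranks$p)
    lab <- stats::setNames(truth$labels[verts, t], verts)
    f1_max(pr_curve(score, pair_labels(lab, verts)))
  }, numeric(1))
}

# area under a PR curve by trapezoid in recall
pr_area <- function(pr) {
  r <- c(0, pr$recall)
  p <- c(pr$precision[1], pr$precision)
  sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
}
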