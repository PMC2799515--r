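#' Expected edge and non-edge counts per tree node
#'
#' Under the mean-field membership `tau`, each vertex pair contributes to
#' exactly one tree node: the lowest common ancestor of the two leaves when
#' the vertices sit in different leaves, or the leaf itself when they share
#' one. These expected edge counts `e_r` and non-edge counts `n_r` are the
#' sufficient statistics of the per-node Bernoulli edge probabilities.
#' Pair-split probabilities use the independent product of the two tau
#' rows, as the factorized surrogate prescribes.
#'
#' Only active-active pairs are counted; inactive vertices contribute
#' nowhere.
#'
#' @param snapshot A [snapshot()].
#' @param tau Membership matrix, one row per active vertex (same order as
#'   `rownames(snapshot$adj)`), `G` columns, rows on the simplex.
#' @param tree A [hier_tree()] with `G` leaves.
#' @return Object of class `"dyhm_stats"`: list with per-node vectors `e`,
#'   `n` (length `2G - 1`; internal nodes first, then leaves in heap
#'   order) and `pairs = e + n`.
#' @examples
#' sn <- snapshot(cbind("a", "b"))
#' tr <- hier_tree(1)
#' tau <- matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE)
#' expected_counts(sn, tau, tr)$e   # the edge falls in leaf 1
#' @export
expected_counts <- function(snapshot, tau, tree) {
  stopifnot(inherits(snapshot, "dyhm_snapshot"), inherits(tree, "hier_tree"))
  tau <- as.matrix(tau)
  A <- snapshot$adj
  if (nrow(tau) != nrow(A) || ncol(tau) != tree$G)
    stop("tau must be (active vertices) x (leaves)")
  if (any(abs(rowSums(tau) - 1) > 1e-6))
    stop("tau rows must be normalized")
  G <- tree$G
  S <- crossprod(tau, A %*% tau)     # S[u,v] = sum_{i != j} tau_iu A_ij tau_jv
  C2 <- crossprod(tau)               # C2[u,v] = sum_i tau_iu tau_iv
  cs <- colSums(tau)
  e <- n <- numeric(tree$n_nodes)
  for (u in seq_len(G)) {
    # within-leaf pairs
    id <- G - 1L + u
    e[id] <- S[u, u] / 2
    n[id] <- (cs[u]^2 - C2[u, u]) / 2 - e[id]
    if (u < G) for (v in (u + 1L):G) {
      id <- tree$lca[u, v]
      e[id] <- e[id] + S[u, v]
      n[id] <- n[id] + (cs[u] * cs[v] - C2[u, v]) - S[u, v]
    }
  }
  n <- pmax(n, 0)                    # guard tiny negative round-off
  e <- pmax(e, 0)
  structure(list(e = e, n = n, pairs = e + n), class = "dyhm_stats")
}

#' Collapsed (marginal) log-likelihood of the hierarchical block model
#'
#' The Beta-Bernoulli conjugacy lets every per-node edge probability be
#' integrated out analytically: each node contributes
#' `log B(e_r + a0, n_r + b0) - log B(a0, b0)`, and the marginal
#' log-likelihood is the sum over all internal and terminal nodes.
#'
#' @param stats A [expected_counts()] result (or any list with `e`, `n`).
#' @param prior Length-2 Beta prior `c(a0, b0)`; default flat.
#' @return Scalar log marginal likelihood.
#' @examples
#' collapsed_log_likelihood(list(e = 1, n = 0))  # log(1/2)
#' @export
collapsed_log_likelihood <- function(stats, prior = c(1, 1)) {
  e <- stats$e; n <- stats$n
  if (any(e < 0) || any(n < 0)) stop("counts must be non-negative")
  a0 <- prior[1]; b0 <- prior[2]
  sum(lbeta(e + a0, n + b0) - lbeta(a0, b0))
}

#' Per-node edge enrichment relative to global density
#'
#' For each tree node, the log2 ratio of the node's edge density
#' `e_r / (e_r + n_r)` to the snapshot's overall edge density. Positive
#' values flag enrichment of within-cluster (leaves) or between-cluster
#' (internal nodes) edges; negative values depletion. Nodes with no vertex
#' pairs are `NA`; ratios are clipped to `[-floor, floor]` so empty-edge
#' nodes report as strong depletion rather than `-Inf`.
#'
#' @param stats A [expected_counts()] result.
#' @param snapshot The snapshot the counts came from (must have >= 1 edge).
#' @param floor Clip magnitude for the log2 ratio.
#' @return Numeric vector over nodes (heap order), `NA` where undefined.
#' @export
node_enrichment <- function(stats, snapshot, floor = 10) {
  m <- n_edges(snapshot)
  if (m < 1) stop("enrichment is undefined for an empty graph")
  nv <- nrow(snapshot$adj)
  dens <- m / (nv * (nv - 1) / 2)
  out <- rep(NA_real_, length(stats$e))
  has <- stats$pairs > 0
  ratio <- (stats$e[has] / stats$pairs[has]) / dens
  out[has] <- pmin(pmax(log2(ratio), -floor), floor)
  out
}
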