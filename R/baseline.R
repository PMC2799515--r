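#' Shared-neighbor hypergeometric p-value for one vertex pair
#'
#' The neighbor-sharing comparator: the probability, under random
#' placement, of two vertices sharing at least the observed number of
#' neighbors. With `n` the number of active vertices excluding `u` and
#' `v`, `K = |N(u) \ {v}|`, `D = |N(v) \ {u}|` and `k = |N(u) & N(v)|`,
#' the p-value is the upper tail `P(X >= k)` for
#' `X ~ Hypergeometric(n, K, D)`. Both endpoints are excluded from each
#' other's neighbor sets and from the universe. Smaller p-values are
#' stronger co-membership evidence.
#'
#' @param u,v Distinct active vertex ids (names or indices).
#' @param snapshot A [snapshot()].
#' @return p-value in `(0, 1]`.
#' @examples
#' sn <- snapshot(cbind(c("u", "u", "v", "v"), c("x", "y", "x", "y")))
#' shared_neighbor_pvalue("u", "v", sn)
#' @export
shared_neighbor_pvalue <- function(u, v, snapshot) {
  act <- active_vertices(snapshot)
  iu <- if (is.character(u)) match(u, act) else as.integer(u)
  iv <- if (is.character(v)) match(v, act) else as.integer(v)
  if (is.na(iu) || is.na(iv)) stop("vertex not active in snapshot")
  if (iu == iv) stop("u and v must differ")
  A <- snapshot$adj
  Nu <- which(A[iu, ] != 0); Nv <- which(A[iv, ] != 0)
  K <- length(setdiff(Nu, iv))
  D <- length(setdiff(Nv, iu))
  k <- length(intersect(Nu, Nv))
  n <- length(act) - 2L
  stats::phyper(k - 1, K, n - K, D, lower.tail = FALSE)
}

#' Rank all active vertex pairs by shared-neighbor significance
#'
#' Scores every unordered active pair with the hypergeometric p-value and
#' sorts ascending by p (ties broken by shared-neighbor count descending,
#' then lexicographic pair id), so stronger co-membership candidates come
#' first. The ranking score is `-log(p)`.
#'
#' @param snapshot A [snapshot()] with at least two active vertices.
#' @return Data frame with columns `u`, `v`, `shared`, `p`, `score`,
#'   ordered by rank. The universe convention (endpoints excluded) is
#'   attached as `attr(, "universe")`.
#' @export
rank_all_pairs <- function(snapshot) {
  act <- active_vertices(snapshot)
  N <- length(act)
  if (N < 2) stop("need at least two active vertices")
  A <- snapshot$adj
  shared <- A %*% A           # common-neighbor counts (diagonal = degree)
  idx <- which(upper.tri(A), arr.ind = TRUE)
  deg <- rowSums(A)
  i <- idx[, 1]; j <- idx[, 2]
  k <- shared[idx]
  K <- deg[i] - A[idx]        # exclude the other endpoint
  D <- deg[j] - A[idx]
  p <- stats::phyper(k - 1, K, (N - 2) - K, D, lower.tail = FALSE)
  out <- data.frame(u = act[i], v = act[j], shared = k, p = p,
                    score = -log(p), stringsAsFactors = FALSE)
  out <- out[order(out$p, -out$shared, out$u, out$v), ]
  rownames(out) <- NULL
  attr(out, "universe") <- "active vertices excluding both endpoints"
  out
}
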