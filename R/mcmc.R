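#' One collapsed Metropolis-Hastings step (reference implementation)
#'
#' Proposes moving one uniformly chosen vertex to a uniformly chosen
#' different leaf and accepts with probability
#' `min(1, exp(delta collapsed log-likelihood))`, the marginal likelihood
#' with all Beta edge probabilities integrated out. This R version
#' recomputes the collapsed likelihood from scratch and exists for
#' transparency and testing; [sample_co_membership()] runs the same chain
#' with incremental count updates in compiled code.
#'
#' @param assignment Integer vector of hard leaf assignments (1..G).
#' @param snapshot A [snapshot()].
#' @param tree A [hier_tree()] (topology and prior only).
#' @return List with the new `assignment`, `accepted`, `delta` (log-lik
#'   change of the proposal) and the proposal `(vertex, from, to)`.
#' @export
mh_step <- function(assignment, snapshot, tree) {
  N <- nrow(snapshot$adj)
  G <- tree$G
  stopifnot(length(assignment) == N, all(assignment >= 1 & assignment <= G))
  i <- sample.int(N, 1)
  others <- setdiff(seq_len(G), assignment[i])
  v <- others[sample.int(length(others), 1)]
  ll0 <- collapsed_log_likelihood(hard_assignment_stats(snapshot, assignment, tree),
                                  tree$prior)
  prop <- assignment
  prop[i] <- v
  ll1 <- collapsed_log_likelihood(hard_assignment_stats(snapshot, prop, tree),
                                  tree$prior)
  delta <- ll1 - ll0
  accepted <- delta >= 0 || log(stats::runif(1)) < delta
  list(assignment = if (accepted) prop else assignment,
       accepted = accepted, delta = delta,
       proposal = c(vertex = i, from = assignment[i], to = v))
}

# sufficient statistics of a hard assignment (exact counting by leaf-pair LCA)
hard_assignment_stats <- function(snapshot, assignment, tree) {
  A <- snapshot$adj
  N <- nrow(A)
  e <- n <- numeric(tree$n_nodes)
  if (N >= 2) for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    r <- tree$lca[assignment[i], assignment[j]]
    if (A[i, j] != 0) e[r] <- e[r] + 1 else n[r] <- n[r] + 1
  }
  structure(list(e = e, n = n, pairs = e + n), class = "dyhm_stats")
}

#' Co-membership scores from the collapsed posterior by MCMC
#'
#' Runs the collapsed Metropolis-Hastings chain over hard leaf
#' assignments and averages the same-leaf indicator over the retained
#' samples, giving the asymptotically exact pairwise co-membership
#' probabilities that the variational approximation is benchmarked
#' against.
#'
#' @param snapshot A [snapshot()].
#' @param depth Tree depth.
#' @param sweeps Total single-vertex proposal steps.
#' @param burn_in Discarded initial steps (default 20% of `sweeps`).
#' @param thin Keep every `thin`-th post-burn-in state.
#' @param seed Integer seed.
#' @param a0,b0 Beta prior.
#' @param keep_samples Also return the thinned assignment samples.
#' @param check Recompute counts from scratch every 1000 steps and stop
#'   on any disagreement with the incremental updates (debug aid).
#' @return Object of class `"dyhm_mcmc"`: `comembership` (symmetric
#'   matrix, `NA` diagonal, vertex dimnames), `acceptance_rate`,
#'   `n_samples`, `log_likelihood` and final state; `samples` when
#'   requested (rows = retained states).
#' @examples
#' sn <- generate_static(n_groups = c(2, 2), group_size = c(4, 4),
#'                       pwithin = c(1, 1), pbetween = c(0, 0), seed = 1)
#' run <- sample_co_membership(sn$snapshot, depth = 1, sweeps = 5000, seed = 1)
#' range(run$comembership, na.rm = TRUE)
#' @export
sample_co_membership <- function(snapshot, depth, sweeps = 1e5,
                                 burn_in = floor(sweeps * 0.2), thin = 10,
                                 seed = NULL, a0 = 1, b0 = 1,
                                 keep_samples = FALSE, check = FALSE) {
  stopifnot(inherits(snapshot, "dyhm_snapshot"), sweeps > burn_in)
  if (!is.null(seed)) set.seed(seed)
  tree <- hier_tree(depth, a0, b0)
  N <- nrow(snapshot$adj)
  init <- sample.int(tree$G, N, replace = TRUE)
  res <- cpp_mcmc(snapshot$adj, tree$G, tree$lca,
                  as.integer(sweeps), as.integer(burn_in), as.integer(thin),
                  a0, b0, init, keep_samples, check)
  dimnames(res$comembership) <- list(active_vertices(snapshot),
                                     active_vertices(snapshot))
  res$tree <- tree
  res$sweeps <- sweeps; res$burn_in <- burn_in; res$thin <- thin
  class(res) <- "dyhm_mcmc"
  res
}

#' @export
print.dyhm_mcmc <- function(x, ...) {
  cat(sprintf("Collapsed MCMC: %g steps (%g burn-in, thin %d), %g samples\n",
              x$sweeps, x$burn_in, x$thin, x$n_samples))
  cat(sprintf("acceptance rate %.3f, final collapsed log-lik %.3f\n",
              x$acceptance_rate, x$log_likelihood))
  invisible(x)
}
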