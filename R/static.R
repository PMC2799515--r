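#' Conjugate update of the tree's Beta parameters
#'
#' Given expected edge/non-edge counts, every node's Beta posterior is
#' `a_r = a0 + e_r`, `b_r = b0 + n_r`. The digamma expectations
#' `<log theta_r> = psi(a_r) - psi(a_r + b_r)` and
#' `<log(1 - theta_r)> = psi(b_r) - psi(a_r + b_r)` used by the
#' assignment updates are cached on the returned tree. A leaf with zero
#' occupancy simply keeps the prior.
#'
#' @param stats [expected_counts()] for the current membership.
#' @param prior Length-2 `c(a0, b0)`; defaults to the tree's own prior.
#' @param tree The [hier_tree()] to update.
#' @return The tree with updated `a`, `b` and cached `Elog`, `Elog1m`.
#' @export
update_tree_params <- function(stats, prior = NULL, tree) {
  stopifnot(inherits(tree, "hier_tree"))
  if (any(stats$e < 0) || any(stats$n < 0)) stop("counts must be non-negative")
  if (is.null(prior)) prior <- tree$prior
  tree$a <- prior[[1]] + stats$e
  tree$b <- prior[[2]] + stats$n
  dab <- digamma(tree$a + tree$b)
  tree$Elog <- digamma(tree$a) - dab
  tree$Elog1m <- digamma(tree$b) - dab
  tree
}

# ensure digamma expectations are cached
tree_expectations <- function(tree) {
  if (is.null(tree$Elog)) {
    dab <- digamma(tree$a + tree$b)
    tree$Elog <- digamma(tree$a) - dab
    tree$Elog1m <- digamma(tree$b) - dab
  }
  tree
}

#' Mean-field potential of one vertex over the leaves
#'
#' The unnormalized log-field driving a vertex's assignment update: for
#' leaf `u`, the sum over its ancestors `r` of
#' `d_opp * <log theta_r> + (m_opp - d_opp) * <log(1-theta_r)>`
#' (expected edges/non-edges from the vertex into the opposite side of
#' each split) plus the within-leaf term
#' `d_u * <log theta_u> + (m_u - d_u) * <log(1-theta_u)>`, where
#' `d_S = sum_{j != i} A_ij sum_{v in S} tau_jv` and `m_S` is the expected
#' occupancy of `S` excluding the vertex itself.
#'
#' This is the transparent reference implementation (explicit ancestry
#' walk); the fitting kernel computes the same quantity through the
#' leaf-pair LCA map.
#'
#' @param vertex Vertex id (name or index into the active set).
#' @param snapshot A [snapshot()].
#' @param tau Current membership matrix (active vertices x leaves).
#' @param tree A [hier_tree()] with up-to-date parameters.
#' @return Numeric vector of length `G`.
#' @export
assignment_field <- function(vertex, snapshot, tau, tree) {
  act <- active_vertices(snapshot)
  i <- if (is.character(vertex)) match(vertex, act) else as.integer(vertex)
  if (is.na(i) || i < 1 || i > length(act)) stop("vertex not active in snapshot")
  tree <- tree_expectations(tree)
  G <- tree$G
  A <- snapshot$adj
  # expected edges from i into each leaf, and occupancy excluding i
  d_leaf <- as.numeric(A[i, ] %*% tau)
  m_leaf <- colSums(tau) - tau[i, ]
  field <- numeric(G)
  for (u in seq_len(G)) {
    anc <- leaf_ancestry(tree, u)
    f <- 0
    for (k in seq_len(nrow(anc))) {
      r <- anc$node[k]
      opp <- anc$opposite[[k]]
      d <- sum(d_leaf[opp]); m <- sum(m_leaf[opp])
      f <- f + d * tree$Elog[r] + (m - d) * tree$Elog1m[r]
    }
    id <- G - 1L + u
    f <- f + d_leaf[u] * tree$Elog[id] + (m_leaf[u] - d_leaf[u]) * tree$Elog1m[id]
    field[u] <- f
  }
  field
}

#' Softmax assignment update
#'
#' Normalizes `exp(field)` onto the simplex (the Lagrange multiplier of
#' the sum-to-one constraint), stabilized by subtracting the maximum.
#' Entries are floored at `1e-12` and renormalized so later logarithms are
#' safe.
#'
#' @param field Finite numeric vector of per-leaf potentials.
#' @return Probability vector of the same length.
#' @export
update_assignment <- function(field) {
  if (all(!is.finite(field))) stop("assignment field has no finite entry")
  w <- exp(field - max(field, na.rm = TRUE))
  w[!is.finite(w)] <- 0
  p <- w / sum(w)
  p <- pmax(p, 1e-12)
  p / sum(p)
}

#' Variational lower bound (ELBO) for one snapshot
#'
#' The expected log-joint under the factorized surrogate minus the
#' surrogate's entropy: per-node expected Bernoulli log-likelihood of the
#' counts, plus the Beta prior-vs-posterior terms, plus the assignment
#' entropy, plus the (constant) uniform log-prior over leaf assignments.
#' Equals the negative KL divergence of the surrogate from the true
#' posterior up to the model's log-normalizer.
#'
#' @param snapshot A [snapshot()].
#' @param tau Membership matrix.
#' @param tree A [hier_tree()] (its `a`, `b` are used as-is).
#' @param prior Length-2 Beta prior; defaults to the tree's prior.
#' @return Scalar lower-bound value.
#' @export
elbo <- function(snapshot, tau, tree, prior = NULL) {
  stopifnot(inherits(tree, "hier_tree"))
  if (is.null(prior)) prior <- tree$prior
  tree <- tree_expectations(tree)
  st <- expected_counts(snapshot, tau, tree)
  val <- sum(st$e * tree$Elog + st$n * tree$Elog1m) +
    sum(lbeta(tree$a, tree$b) - lbeta(prior[[1]], prior[[2]]) +
          (prior[[1]] - tree$a) * tree$Elog + (prior[[2]] - tree$b) * tree$Elog1m)
  tpos <- tau[tau > 0]
  val - sum(tpos * log(tpos)) - nrow(tau) * log(tree$G)
}

# random hard (one-hot) membership rows; see the methods vignette for why
# hard initializations beat diffuse Dirichlet rows here
init_tau <- function(n, G) {
  z <- sample.int(G, n, replace = TRUE)
  m <- matrix(1e-12, n, G)
  m[cbind(seq_len(n), z)] <- 1
  m / rowSums(m)
}

# run the coordinate-ascent kernel for one restart on a series
run_kernel <- function(series, tree, lambda, tol, max_sweeps, tau0 = NULL,
                       warm_sweeps = 15L, warm_mult = 3, share = FALSE) {
  snaps <- series$snapshots
  A_list <- lapply(snaps, function(s) s$adj)
  universe <- snaps[[1]]$vertices
  glob_list <- lapply(snaps, function(s) match(active_vertices(s), universe))
  if (any(vapply(glob_list, anyNA, TRUE)))
    stop("snapshots must share one global vertex universe")
  nbrs <- neighbor_lists(series)
  if (is.null(tau0)) {
    # one random hard assignment per *global* vertex, shared across
    # snapshots: vertex identity persists over time, so a shared draw
    # starts the coupled snapshots aligned instead of label-scrambled
    base <- init_tau(length(universe), tree$G)
    tau0 <- lapply(glob_list, function(g) base[g, , drop = FALSE])
  }
  cpp_fit_series(A_list, tau0, glob_list, tree$lca, tree$G, nbrs,
                 lambda, tree$prior[[1]], tree$prior[[2]], tol, max_sweeps,
                 as.integer(warm_sweeps), warm_mult, share)
}

#' Fit the hierarchical block model to a single static snapshot
#'
#' Variational mean-field coordinate ascent: each sweep performs the
#' conjugate tree-parameter update followed by one asynchronous pass of
#' softmax assignment updates over the vertices in randomized order. The
#' bound is non-decreasing across sweeps; the best of `restarts` random
#' initializations (Dirichlet(1) rows) is returned.
#'
#' @param snapshot A [snapshot()] with at least one active vertex.
#' @param depth Tree depth; the model has `2^depth` leaves.
#' @param restarts Number of random restarts (default 7).
#' @param seed Integer seed; all randomness (initialization and update
#'   order) flows from it.
#' @param tol Convergence: relative change of the bound between sweeps.
#' @param max_sweeps Sweep cap; hitting it sets `converged = FALSE` with a
#'   warning.
#' @param a0,b0 Beta prior (flat by default).
#' @param warm_sweeps,warm_mult Symmetry-breaking warm start: for
#'   `warm_sweeps` initial sweeps the assignment field is multiplied by
#'   `warm_mult` (a sharpened, low-temperature softmax) before the
#'   monitored coordinate ascent begins. Random one-hot initializations
#'   plus this phase reliably escape the degenerate all-vertices-one-leaf
#'   fixed point; set `warm_sweeps = 0` for the plain ascent.
#' @return Object of class `c("dyhm_static", "dyhm")`; see [dyhm-methods]
#'   for the available methods. Key fields: `tau` (membership matrix with
#'   vertex rownames), `tree` (fitted [hier_tree()]), `elbo`,
#'   `elbo_trace`, `restart_elbos`, `converged`, `sweeps`.
#' @examples
#' sn <- generate_static(seed = 1, preset = "contrast")$snapshot
#' fit <- fit_static(sn, depth = 3, seed = 1)
#' fit
#' @export
fit_static <- function(snapshot, depth, restarts = 7, seed = NULL,
                       tol = 1e-6, max_sweeps = 500, a0 = 1, b0 = 1,
                       warm_sweeps = 15, warm_mult = 3) {
  stopifnot(inherits(snapshot, "dyhm_snapshot"))
  if (nrow(snapshot$adj) == 0) stop("snapshot has no active vertices")
  if (!is.null(seed)) set.seed(seed)
  series <- snapshot_series(list(snapshot))
  tree <- hier_tree(depth, a0, b0)
  best <- NULL
  scores <- numeric(restarts)
  for (r in seq_len(restarts)) {
    res <- run_kernel(series, tree, lambda = 0, tol, max_sweeps,
                      warm_sweeps = warm_sweeps, warm_mult = warm_mult)
    scores[r] <- res$elbo[1]
    if (is.null(best) || res$elbo[1] > best$elbo[1]) {
      best <- res
      best$restart_index <- r
    }
  }
  if (!best$converged)
    warning("reached max_sweeps before the bound converged")
  tau <- best$tau[[1]]
  rownames(tau) <- active_vertices(snapshot)
  tree$a <- as.numeric(best$a[[1]])
  tree$b <- as.numeric(best$b[[1]])
  tree <- tree_expectations(tree)
  structure(list(
    tau = tau, tree = tree, elbo = best$elbo[1],
    elbo_trace = -best$trace,   # kernel traces -ELBO
    restart_elbos = scores, restart_index = best$restart_index,
    converged = best$converged, sweeps = best$sweeps,
    snapshot = snapshot, depth = as.integer(depth), seed = seed,
    call = match.call()
  ), class = c("dyhm_static", "dyhm"))
}

#' Fit a hierarchical block model (static or dynamic)
#'
#' The formula-free front door: dispatches to [fit_static()] for a single
#' [snapshot()] and to [fit_dynamic()] for a [snapshot_series()].
#'
#' @param x A snapshot or snapshot series.
#' @param depth Tree depth (`2^depth` leaves).
#' @param ... Passed on to the fitting workhorse ([fit_static()] /
#'   [fit_dynamic()]), e.g. `lambda`, `restarts`, `seed`.
#' @return A fitted `"dyhm"` object.
#' @export
dyhm <- function(x, depth, ...) UseMethod("dyhm")

#' @rdname dyhm
#' @export
dyhm.dyhm_snapshot <- function(x, depth, ...) fit_static(x, depth, ...)

#' @rdname dyhm
#' @export
dyhm.dyhm_series <- function(x, depth, ...) fit_dynamic(x, depth, ...)
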