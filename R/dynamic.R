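#' Coupled assignment update for one vertex in a series
#'
#' The time-constrained analogue of the softmax update: with `field` the
#' static mean-field potential at snapshot `t` and `K` the number of
#' coupled neighbor snapshots where the vertex is also active,
#' `tau_u propto exp( (field_u + lambda * sum_s log tau_u(s)) / (1 + lambda K) )`.
#' `lambda = 0` recovers the independent static update; as
#' `lambda -> Inf` the update tends to the normalized geometric mean of
#' the neighboring memberships.
#'
#' @param field Per-leaf potential from [assignment_field()] at the
#'   current snapshot.
#' @param neighbor_tau List (possibly empty) of the vertex's membership
#'   vectors at the coupled snapshots where it is active.
#' @param lambda Smoothness weight, `>= 0`.
#' @return Probability vector over the leaves.
#' @export
coupled_assignment_update <- function(field, neighbor_tau = list(), lambda = 0) {
  if (lambda < 0) stop("lambda must be non-negative")
  K <- length(neighbor_tau)
  if (lambda == 0 || K == 0) return(update_assignment(field))
  lognbr <- Reduce(`+`, lapply(neighbor_tau, function(p) log(pmax(p, 1e-12))))
  update_assignment((field + lambda * lognbr) / (1 + lambda * K))
}

# per-snapshot seed for the separable lambda = 0 fit
derive_seed <- function(seed, t) (seed + 7919L * t) %% .Machine$integer.max

# Greedily permute each snapshot's leaf labels to maximize membership
# overlap with the previous snapshot. Leaf relabelings act only on the
# initialization gauge; the coupled fit then starts from temporally
# aligned labels instead of per-snapshot-arbitrary ones.
align_memberships <- function(taus, series = NULL) {
  G <- ncol(taus[[1]])
  verts <- if (is.null(series)) NULL else
    lapply(series$snapshots, active_vertices)
  for (t in seq_along(taus)[-1]) {
    if (is.null(verts)) {
      prev <- taus[[t - 1]]; cur <- taus[[t]]
    } else {
      common <- intersect(verts[[t - 1]], verts[[t]])
      if (!length(common)) next
      prev <- taus[[t - 1]][match(common, verts[[t - 1]]), , drop = FALSE]
      cur <- taus[[t]][match(common, verts[[t]]), , drop = FALSE]
    }
    ov <- crossprod(prev, cur)
    perm <- rep(NA_integer_, G)
    for (step in seq_len(G)) {
      idx <- which(ov == max(ov), arr.ind = TRUE)[1, ]
      perm[idx[2]] <- idx[1]
      ov[idx[1], ] <- -Inf
      ov[, idx[2]] <- -Inf
    }
    taus[[t]] <- taus[[t]][, order(perm), drop = FALSE]
  }
  taus
}

#' Fit the dynamic hierarchical block model to a snapshot series
#'
#' Coordinate descent on the time-constrained objective: the sum over
#' snapshots of the per-snapshot KL divergence of the factorized
#' surrogate from the model posterior, plus `lambda` times the KL
#' divergence between the memberships of coupled snapshots (for vertices
#' active in both). One global sweep passes the snapshots in index order;
#' within each snapshot the tree parameters are updated from the expected
#' counts, then one randomized asynchronous pass of coupled assignment
#' updates runs over the vertices.
#'
#' With the default `share_params = TRUE` the group-group interaction
#' structure is held constant over the series: all snapshots share one
#' set of Beta node posteriors, updated from the edge/non-edge counts
#' summed over snapshots. Sharing makes the leaf labels of different
#' snapshots identifiable relative to each other even without smoothing,
#' and the per-snapshot bounds comparable across `lambda`. With
#' `share_params = FALSE` each snapshot keeps its own Beta parameters
#' (only the topology and the smoothness penalty tie snapshots); in that
#' mode `lambda = 0` separates exactly over snapshots and the fit
#' dispatches to independent [fit_static()] runs with per-snapshot
#' derived seeds, bit-identical to running them yourself.
#'
#' @param series A [snapshot_series()].
#' @param depth Tree depth.
#' @param lambda Smoothness weight `>= 0`, or `"auto"` to pick it by
#'   [select_lambda()] on the default grid.
#' @param restarts,seed,tol,a0,b0,warm_sweeps,warm_mult As in
#'   [fit_static()].
#' @param max_sweeps Cap on global sweeps.
#' @param share_params One shared set of node Beta parameters across
#'   snapshots (default) versus per-snapshot parameters; see Details.
#' @param tau_init Optional list of membership matrices (one per
#'   snapshot) used as one additional, deterministic restart -- the hook
#'   [select_lambda()] uses to continue fits along its grid.
#' @return Object of class `c("dyhm_dynamic", "dyhm")`: `tau` (list of
#'   membership matrices), `trees` (list of fitted [hier_tree()]s),
#'   `elbo` (per snapshot), `objective_trace` (non-increasing), `lambda`,
#'   `converged`, plus the series and call. If `lambda = "auto"`, the
#'   selection table is attached as `$selection`.
#' @examples
#' sim <- generate_dynamic(pswitch = 0.05, T = 4, seed = 1)
#' fit <- fit_dynamic(sim$series, depth = 3, lambda = 1, seed = 1)
#' fit
#' @export
fit_dynamic <- function(series, depth, lambda = 1, restarts = 7, seed = NULL,
                        tol = 1e-6, max_sweeps = 500, a0 = 1, b0 = 1,
                        warm_sweeps = 15, warm_mult = 3, share_params = TRUE,
                        tau_init = NULL) {
  stopifnot(inherits(series, "dyhm_series"))
  if (identical(lambda, "auto")) {
    sel <- select_lambda(series, depth, restarts = restarts, seed = seed,
                         tol = tol, max_sweeps = max_sweeps, a0 = a0, b0 = b0,
                         warm_sweeps = warm_sweeps, warm_mult = warm_mult,
                         share_params = share_params)
    fit <- sel$fit
    fit$selection <- sel$scores
    return(fit)
  }
  if (!is.numeric(lambda) || lambda < 0) stop("lambda must be >= 0")
  T_ <- length(series$snapshots)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)

  if (lambda == 0 && !share_params) {
    # exactly separable objective: independent static fits, matched seeds
    fits <- lapply(seq_len(T_), function(t)
      fit_static(series$snapshots[[t]], depth, restarts = restarts,
                 seed = derive_seed(seed, t), tol = tol,
                 max_sweeps = max_sweeps, a0 = a0, b0 = b0,
                 warm_sweeps = warm_sweeps, warm_mult = warm_mult))
    obj_trace <- -vapply(fits, `[[`, numeric(1), "elbo")
    out <- structure(list(
      tau = lapply(fits, `[[`, "tau"),
      trees = lapply(fits, `[[`, "tree"),
      elbo = vapply(fits, `[[`, numeric(1), "elbo"),
      elbo_beta = 0,
      objective_trace = sum(obj_trace),
      lambda = 0, share_params = FALSE, restart_objectives = NULL,
      converged = all(vapply(fits, `[[`, logical(1), "converged")),
      sweeps = max(vapply(fits, `[[`, integer(1), "sweeps")),
      static_fits = fits,
      series = series, depth = as.integer(depth), seed = seed,
      call = match.call()
    ), class = c("dyhm_dynamic", "dyhm"))
    return(out)
  }

  set.seed(seed)
  tree <- hier_tree(depth, a0, b0)
  # structured restart: independent per-snapshot fits, leaves greedily
  # aligned across time, then refined under the coupled objective
  structured <- NULL
  if (lambda > 0 && length(series$snapshots) > 1) {
    # best-of-restarts independently per snapshot (valid: the lambda = 0,
    # per-snapshot-parameter objective separates over snapshots)
    best_tau <- NULL
    best_elbo <- NULL
    for (r0 in seq_len(restarts)) {
      res0 <- run_kernel(series, tree, 0, tol, max_sweeps,
                         warm_sweeps = warm_sweeps, warm_mult = warm_mult,
                         share = FALSE)
      if (is.null(best_tau)) {
        best_tau <- res0$tau
        best_elbo <- as.numeric(res0$elbo)
      } else {
        gain <- which(as.numeric(res0$elbo) > best_elbo)
        for (t in gain) {
          best_tau[[t]] <- res0$tau[[t]]
          best_elbo[t] <- res0$elbo[t]
        }
      }
    }
    structured <- align_memberships(best_tau, series)
  }
  inits <- list()
  if (!is.null(structured)) inits <- list(structured)  # counts as one restart
  inits <- c(inits, rep(list(NULL), max(restarts - length(inits), 0)))
  if (!is.null(tau_init)) inits <- c(inits, list(tau_init))
  best <- NULL
  scores <- rep(NA_real_, length(inits))
  for (r in seq_along(inits)) {
    res <- run_kernel(series, tree, lambda, tol, max_sweeps,
                      tau0 = inits[[r]],
                      warm_sweeps = if (is.null(inits[[r]])) warm_sweeps else 0L,
                      warm_mult = warm_mult,
                      share = share_params)
    scores[r] <- utils::tail(res$trace, 1)
    if (is.null(best) || scores[r] < min(scores[seq_len(r - 1)], Inf, na.rm = TRUE)) {
      best <- res
      best$restart_index <- r
    }
  }
  if (!best$converged)
    warning("reached max_sweeps before the objective converged")
  taus <- best$tau
  trees <- vector("list", T_)
  for (t in seq_len(T_)) {
    rownames(taus[[t]]) <- active_vertices(series$snapshots[[t]])
    tr <- tree
    tr$a <- as.numeric(best$a[[t]])
    tr$b <- as.numeric(best$b[[t]])
    trees[[t]] <- tree_expectations(tr)
  }
  structure(list(
    tau = taus, trees = trees, elbo = as.numeric(best$elbo),
    elbo_beta = best$elbo_beta,
    objective_trace = as.numeric(best$trace),
    lambda = lambda, share_params = share_params,
    restart_objectives = scores,
    restart_index = best$restart_index,
    converged = best$converged, sweeps = best$sweeps,
    series = series, depth = as.integer(depth), seed = seed,
    call = match.call()
  ), class = c("dyhm_dynamic", "dyhm"))
}

#' Observed leaf-to-leaf transitions in a fitted dynamic model
#'
#' Hard-assigns every active vertex per snapshot by `argmax tau`, then
#' records, for each coupled snapshot pair `(t, s)` with `t < s` and each
#' vertex active in both, the ordered leaf pair `u_t -> u_s` whenever the
#' leaf changes. `m` counts the distinct transitions observed at least
#' once; `M = G(G-1)` is the number possible. Alongside the transition
#' repertoire, the per-vertex switch events are tallied: `V` coupled
#' vertex observations, of which `W` changed leaf.
#'
#' @param fit A [fit_dynamic()] result.
#' @return Object of class `"dyhm_transitions"`: list with `m`, `M`,
#'   `V`, `W`, and `transitions` (data frame `from`, `to`, `count`).
#' @export
count_transitions <- function(fit) {
  stopifnot(inherits(fit, "dyhm_dynamic"))
  G <- 2L^fit$depth
  hard <- lapply(fit$tau, function(m) {
    z <- max.col(m, ties.method = "first")
    names(z) <- rownames(m)
    z
  })
  nb <- fit$series$neighbors
  tally <- new.env(parent = emptyenv())
  V <- 0L; W <- 0L
  if (nrow(nb)) for (k in seq_len(nrow(nb))) {
    t1 <- min(nb[k, ]); t2 <- max(nb[k, ])
    shared <- intersect(names(hard[[t1]]), names(hard[[t2]]))
    from <- hard[[t1]][shared]; to <- hard[[t2]][shared]
    mv <- from != to
    V <- V + length(shared)
    W <- W + sum(mv)
    for (key in paste(from[mv], to[mv], sep = "->")) {
      cur <- if (is.null(tally[[key]])) 0L else tally[[key]]
      tally[[key]] <- cur + 1L
    }
  }
  keys <- ls(tally)
  tr <- if (length(keys)) {
    parts <- do.call(rbind, strsplit(keys, "->", fixed = TRUE))
    data.frame(from = as.integer(parts[, 1]), to = as.integer(parts[, 2]),
               count = vapply(keys, function(k) tally[[k]], integer(1)),
               row.names = NULL)
  } else data.frame(from = integer(0), to = integer(0), count = integer(0))
  structure(list(m = length(keys), M = G * (G - 1L), V = V, W = W,
                 transitions = tr),
            class = "dyhm_transitions")
}

#' @export
print.dyhm_transitions <- function(x, ...) {
  cat(sprintf("Observed %d of %d possible directed leaf transitions\n",
              x$m, x$M))
  invisible(x)
}

#' Penalized likelihood of a fitted dynamic model
#'
#' The model-selection score for the smoothness weight: the variational
#' bound minus the transition penalty, `ELBO - log C(M, m)`, with `m`
#' the number of distinct observed directed leaf transitions and
#' `M = G(G-1)` the number possible. The penalty gives equal weight to
#' each of the `C(M, m)` models with exactly `m` transitions -- the
#' marginal of independent Bernoulli transition indicators with a
#' uniform rate prior, dropping the lambda-independent `log(M+1)`
#' constant -- so, in the regime `m < M/2`, every extra distinct
#' transition costs more than the last. (The binomial coefficient is
#' symmetric: a fit observing nearly all transitions pays little, which
#' matters for small trees; see the methods vignette for the
#' consequences.)
#'
#' @param fit A [fit_dynamic()] result.
#' @return Scalar score; larger is better.
#' @export
penalized_likelihood <- function(fit) {
  tt <- count_transitions(fit)
  beta <- if (is.null(fit$elbo_beta)) 0 else fit$elbo_beta
  sum(fit$elbo) + beta - lchoose(tt$M, tt$m)
}

#' Select the smoothness weight by penalized likelihood
#'
#' Fits the dynamic model at every `lambda` on the grid (ascending) and
#' keeps the fit maximizing [penalized_likelihood()]. Exact ties break
#' toward the larger `lambda` (the smoother model). Besides its random
#' restarts, each grid point is also warm-started from the previous grid
#' point's best fit (a continuation path); the per-`lambda` winner is
#' whichever run reaches the better coordinate-descent objective. The
#' continuation guards against the symmetry-broken local optima that
#' fresh random starts fall into once the coupling is strong.
#'
#' @param series A [snapshot_series()].
#' @param depth Tree depth.
#' @param grid Candidate `lambda` values.
#' @param restarts,seed,tol,max_sweeps,a0,b0,warm_sweeps,warm_mult Passed
#'   to [fit_dynamic()].
#' @return List with `lambda` (the selected value), `fit` (the fit at the
#'   selected value), and `scores` (data frame `lambda`, `penalized`,
#'   `elbo`, `m`).
#' @export
select_lambda <- function(series, depth,
                          grid = c(0, 0.1, 0.25, 0.5, 1, 2, 4, 8),
                          restarts = 7, seed = NULL, tol = 1e-6,
                          max_sweeps = 500, a0 = 1, b0 = 1,
                          warm_sweeps = 15, warm_mult = 3,
                          share_params = TRUE) {
  if (!length(grid)) stop("lambda grid is empty")
  grid <- sort(as.numeric(grid))
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  fits <- vector("list", length(grid))
  tau_prev <- NULL
  for (k in seq_along(grid)) {
    fits[[k]] <- fit_dynamic(series, depth, lambda = grid[k],
                             restarts = restarts, seed = seed,
                             tol = tol, max_sweeps = max_sweeps,
                             a0 = a0, b0 = b0,
                             warm_sweeps = warm_sweeps, warm_mult = warm_mult,
                             share_params = share_params,
                             tau_init = tau_prev)
    tau_prev <- lapply(fits[[k]]$tau, function(m) m)  # continuation
  }
  pen <- vapply(fits, penalized_likelihood, numeric(1))
  ms <- vapply(fits, function(f) count_transitions(f)$m, numeric(1))
  best <- max(which(pen >= max(pen) - 1e-9))  # tie toward larger lambda
  list(lambda = grid[best], fit = fits[[best]],
       scores = data.frame(lambda = grid, penalized = pen,
                           elbo = vapply(fits, function(f)
                             sum(f$elbo) + if (is.null(f$elbo_beta)) 0 else
                               f$elbo_beta, numeric(1)),
                           m = ms))
}
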