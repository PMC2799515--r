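#' Methods for fitted dynamic hierarchical block models
#'
#' Standard accessors for `"dyhm"` fits: `print` and `summary` describe
#' the fit; `coef` returns the per-node Beta parameters and posterior
#' mean edge probabilities; `predict` returns co-membership score
#' matrices (`type = "co_membership"`) or hard leaf assignments
#' (`type = "leaf"`); `logLik` returns the variational lower bound;
#' `simulate` draws new snapshots from the fitted model (hard leaf
#' assignments sampled from `tau`, edge probabilities from the Beta
#' posterior means); `plot` shows per-node edge enrichment by tree depth
#' and leaf occupancy.
#'
#' @param object,x A fitted `"dyhm"` object.
#' @param ... Unused.
#' @name dyhm-methods
NULL

fit_taus <- function(object)
  if (inherits(object, "dyhm_dynamic")) object$tau else list(object$tau)

fit_trees <- function(object)
  if (inherits(object, "dyhm_dynamic")) object$trees else list(object$tree)

fit_snapshots <- function(object)
  if (inherits(object, "dyhm_dynamic")) object$series$snapshots else
    list(object$snapshot)

#' @rdname dyhm-methods
#' @export
print.dyhm <- function(x, ...) {
  dyn <- inherits(x, "dyhm_dynamic")
  cat(sprintf("Dynamic hierarchical block model fit (%s)\n",
              if (dyn) sprintf("%d snapshots, lambda = %g",
                               length(x$tau), x$lambda) else "static"))
  cat(sprintf("tree depth %d (%d leaves); %s after %d sweeps\n",
              x$depth, 2^x$depth,
              if (x$converged) "converged" else "NOT converged", x$sweeps))
  beta <- if (is.null(x$elbo_beta)) 0 else x$elbo_beta
  cat(sprintf("variational bound: %.4f\n", sum(x$elbo) + beta))
  invisible(x)
}

#' @rdname dyhm-methods
#' @export
summary.dyhm <- function(object, ...) {
  taus <- fit_taus(object)
  occ <- Reduce(`+`, lapply(taus, colSums)) / length(taus)
  hard <- lapply(taus, function(m) max.col(m, ties.method = "first"))
  used <- sort(unique(unlist(hard)))
  out <- list(
    fit = object,
    mean_leaf_occupancy = occ,
    occupied_leaves = used,
    unoccupied_leaves = setdiff(seq_along(occ), used),
    elbo = object$elbo
  )
  class(out) <- "summary.dyhm"
  out
}

#' @export
print.summary.dyhm <- function(x, ...) {
  print(x$fit)
  G <- length(x$mean_leaf_occupancy)
  cat(sprintf("occupied leaves: %d of %d (unoccupied terminals are the\n",
              length(x$occupied_leaves), G))
  cat("depth-sufficiency diagnostic: deepen the tree until some remain)\n")
  cat("mean leaf occupancy:\n")
  print(round(x$mean_leaf_occupancy, 2))
  invisible(x)
}

#' @rdname dyhm-methods
#' @export
coef.dyhm <- function(object, ...) {
  trees <- fit_trees(object)
  do.call(rbind, lapply(seq_along(trees), function(t) {
    tr <- trees[[t]]
    G <- tr$G
    ids <- seq_len(tr$n_nodes)
    data.frame(snapshot = t, node = ids,
               kind = ifelse(ids < G, "internal", "leaf"),
               depth = floor(log2(ids)),
               a = tr$a, b = tr$b,
               theta = tr$a / (tr$a + tr$b))
  }))
}

#' @rdname dyhm-methods
#' @param type `"co_membership"` (default) or `"leaf"`.
#' @export
predict.dyhm <- function(object, type = c("co_membership", "leaf"), ...) {
  type <- match.arg(type)
  taus <- fit_taus(object)
  out <- lapply(taus, function(m) {
    if (type == "co_membership") co_membership(m)
    else stats::setNames(max.col(m, ties.method = "first"), rownames(m))
  })
  if (inherits(object, "dyhm_dynamic")) out else out[[1]]
}

#' @rdname dyhm-methods
#' @export
logLik.dyhm <- function(object, ...) {
  structure(sum(object$elbo), df = NA_integer_, class = "logLik")
}

#' @rdname dyhm-methods
#' @param nsim Number of simulated series/snapshots.
#' @param seed Optional seed.
#' @export
simulate.dyhm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  taus <- fit_taus(object)
  trees <- fit_trees(object)
  one <- function() {
    snaps <- lapply(seq_along(taus), function(t) {
      tau <- taus[[t]]; tr <- trees[[t]]
      N <- nrow(tau)
      z <- vapply(seq_len(N), function(i)
        sample.int(tr$G, 1, prob = tau[i, ]), 0L)
      theta <- tr$a / (tr$a + tr$b)
      A <- matrix(0, N, N, dimnames = list(rownames(tau), rownames(tau)))
      if (N >= 2) for (i in seq_len(N - 1)) for (j in (i + 1):N) {
        p <- theta[tr$lca[z[i], z[j]]]
        A[i, j] <- A[j, i] <- stats::rbinom(1, 1, p)
      }
      snapshot(A)
    })
    if (length(snaps) == 1) snaps[[1]] else
      snapshot_series(snaps, if (inherits(object, "dyhm_dynamic"))
        object$series$neighbors else NULL)
  }
  out <- replicate(nsim, one(), simplify = FALSE)
  if (nsim == 1) out[[1]] else out
}

#' @rdname dyhm-methods
#' @export
plot.dyhm <- function(x, ...) {
  taus <- fit_taus(x)
  trees <- fit_trees(x)
  snaps <- fit_snapshots(x)
  G <- trees[[1]]$G
  enr <- rowMeans(do.call(cbind, lapply(seq_along(taus), function(t) {
    st <- expected_counts(snaps[[t]], taus[[t]], trees[[t]])
    node_enrichment(st, snaps[[t]])
  })), na.rm = TRUE)
  occ <- Reduce(`+`, lapply(taus, colSums)) / length(taus)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  ids <- seq_len(2 * G - 1)
  cols <- ifelse(is.na(enr), "grey70",
                 ifelse(enr > 0, grDevices::rgb(0, 0.6, 0, 0.8),
                        grDevices::rgb(0.8, 0, 0, 0.8)))
  graphics::plot(floor(log2(ids)), enr, pch = ifelse(ids < G, 21, 22),
                 bg = cols, xlab = "node depth (root = 0)",
                 ylab = "log2 edge enrichment",
                 main = "within/between-cluster edge enrichment")
  graphics::abline(h = 0, lty = 3)
  graphics::barplot(occ, names.arg = seq_len(G), xlab = "leaf",
                    ylab = "mean occupancy",
                    main = "leaf occupancy (averaged over snapshots)")
  invisible(x)
}

#' Residual edge discrepancies of a fitted model
#'
#' Pearson-style residuals per vertex pair: observed adjacency minus the
#' fitted edge probability (the posterior mean of the governing node's
#' Bernoulli parameter, mixed over the pair's leaf assignments), divided
#' by its binomial standard deviation.
#'
#' @param object A fitted `"dyhm"` object.
#' @param ... Unused.
#' @return A matrix per snapshot (list for dynamic fits).
#' @export
residuals.dyhm <- function(object, ...) {
  taus <- fit_taus(object)
  trees <- fit_trees(object)
  snaps <- fit_snapshots(object)
  out <- lapply(seq_along(taus), function(t) {
    tau <- taus[[t]]; tr <- trees[[t]]
    theta <- tr$a / (tr$a + tr$b)
    thetaM <- matrix(theta[tr$lca], tr$G, tr$G)
    P <- tau %*% thetaM %*% t(tau)   # pairwise expected edge probability
    A <- snaps[[t]]$adj
    R <- (A - P) / sqrt(P * (1 - P))
    diag(R) <- NA_real_
    R
  })
  if (inherits(object, "dyhm_dynamic")) out else out[[1]]
}
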