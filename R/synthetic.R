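#' Edge-probability presets for the planted-partition generators
#'
#' `"contrast"` (Pwithin = 0.5, Pbetween = 0.05) is a separable regime
#' used for recovery benchmarks. `"paper-printed"` keeps the nearly
#' overlapping ranges Pwithin in \[0.05, 0.1\], Pbetween in \[0.05, 0.08\]
#' (draws violating Pwithin > Pbetween are rejected); it is preserved as
#' printed even though the resulting networks are close to unclusterable,
#' and is labeled as such in outputs.
#'
#' @param preset `"contrast"` or `"paper-printed"`.
#' @return List with `pwithin` and `pbetween` ranges (length-2 each).
#' @export
edge_preset <- function(preset = c("contrast", "paper-printed")) {
  preset <- match.arg(preset)
  switch(preset,
         "contrast" = list(pwithin = c(0.5, 0.5), pbetween = c(0.05, 0.05)),
         "paper-printed" = list(pwithin = c(0.05, 0.1), pbetween = c(0.05, 0.08)))
}

# symmetric Bernoulli adjacency given a label vector
plant_edges <- function(labels, pwithin, pbetween) {
  N <- length(labels)
  A <- matrix(0, N, N)
  if (N >= 2) {
    up <- which(upper.tri(A), arr.ind = TRUE)
    same <- labels[up[, 1]] == labels[up[, 2]]
    pr <- ifelse(same, pwithin, pbetween)
    draw <- stats::rbinom(nrow(up), 1, pr)
    A[up] <- draw
    A <- A + t(A)
  }
  A
}

#' Generate a static planted-partition network
#'
#' Draws the number of groups and the per-group sizes uniformly from the
#' given ranges, then the within/between edge probabilities from the
#' preset (or explicit ranges), rejecting parameter draws with
#' `pwithin <= pbetween`, and finally samples independent Bernoulli
#' edges: within-group pairs with `Pwithin`, between-group pairs with
#' `Pbetween`.
#'
#' @param n_groups Length-2 inclusive range for the number of groups
#'   (default 5..10).
#' @param group_size Length-2 inclusive range for vertices per group
#'   (default 5..10; each group's size is drawn independently).
#' @param pwithin,pbetween Length-2 ranges overriding `preset`.
#' @param preset See [edge_preset()].
#' @param seed Integer seed.
#' @param max_reject Abort after this many rejected parameter draws.
#' @return List with `snapshot` (a [snapshot()]), and `truth` of class
#'   `"dyhm_truth"`: `labels` (named integer vector), and the realized
#'   `params`.
#' @export
generate_static <- function(n_groups = c(5, 10), group_size = c(5, 10),
                            pwithin = NULL, pbetween = NULL,
                            preset = "contrast", seed = NULL,
                            max_reject = 1000) {
  if (!is.null(seed)) set.seed(seed)
  pr <- edge_preset(preset)
  if (!is.null(pwithin)) pr$pwithin <- rep(pwithin, length.out = 2)
  if (!is.null(pbetween)) pr$pbetween <- rep(pbetween, length.out = 2)
  for (att in seq_len(max_reject)) {
    pw <- stats::runif(1, pr$pwithin[1], pr$pwithin[2])
    pb <- stats::runif(1, pr$pbetween[1], pr$pbetween[2])
    if (pw > pb) break
    if (att == max_reject)
      stop("no parameter draw with pwithin > pbetween within ", max_reject,
           " attempts")
  }
  K <- n_groups[1] + sample.int(n_groups[2] - n_groups[1] + 1L, 1) - 1L
  sizes <- group_size[1] +
    sample.int(group_size[2] - group_size[1] + 1L, K, replace = TRUE) - 1L
  labels <- rep(seq_len(K), sizes)
  N <- length(labels)
  ids <- sprintf("v%03d", seq_len(N))
  names(labels) <- ids
  A <- plant_edges(labels, pw, pb)
  dimnames(A) <- list(ids, ids)
  truth <- structure(list(labels = labels,
                          params = list(K = K, sizes = sizes, pwithin = pw,
                                        pbetween = pb, preset = preset,
                                        seed = seed)),
                     class = "dyhm_truth")
  list(snapshot = snapshot(A), truth = truth)
}

#' Generate a dynamic planted-partition snapshot series
#'
#' Assigns `n_vertices` vertices to `n_groups` groups (balanced,
#' remainder round-robin), then for each of `T` snapshots draws fresh
#' Bernoulli edges from the current labels (within-group `pwithin`,
#' between-group `pbetween`), erases them, and lets every vertex switch,
#' independently with probability `pswitch`, to a group chosen uniformly
#' among the other `K - 1` groups. Group sizes therefore drift over time.
#' All vertices are active in every snapshot; the snapshot neighbor graph
#' couples consecutive pairs `(t, t+1)`.
#'
#' @param n_vertices Total vertices (default 30).
#' @param n_groups Number of groups (default 5).
#' @param pwithin,pbetween Scalars overriding `preset`.
#' @param pswitch Per-vertex, per-step switching probability.
#' @param T Number of snapshots (default 15).
#' @param preset See [edge_preset()] (the midpoint of each range is used
#'   when scalars are not given; for `"contrast"` that is 0.5 / 0.05).
#' @param seed Integer seed.
#' @return List with `series` (a [snapshot_series()]) and `truth`
#'   (class `"dyhm_truth"`, `labels` = vertices x snapshots matrix).
#' @examples
#' sim <- generate_dynamic(pswitch = 0, T = 3, seed = 1)
#' all(sim$truth$labels[, 1] == sim$truth$labels[, 3])
#' @export
generate_dynamic <- function(n_vertices = 30, n_groups = 5,
                             pwithin = NULL, pbetween = NULL,
                             pswitch = 0.05, T = 15,
                             preset = "contrast", seed = NULL) {
  stopifnot(pswitch >= 0, pswitch <= 1, T >= 1)
  if (!is.null(seed)) set.seed(seed)
  pr <- edge_preset(preset)
  pw <- if (is.null(pwithin)) mean(pr$pwithin) else pwithin
  pb <- if (is.null(pbetween)) mean(pr$pbetween) else pbetween
  ids <- sprintf("v%03d", seq_len(n_vertices))
  labels <- rep_len(seq_len(n_groups), n_vertices)  # balanced, round-robin tail
  lab_mat <- matrix(0L, n_vertices, T, dimnames = list(ids, NULL))
  snaps <- vector("list", T)
  for (t in seq_len(T)) {
    lab_mat[, t] <- labels
    A <- plant_edges(labels, pw, pb)
    dimnames(A) <- list(ids, ids)
    snaps[[t]] <- snapshot(A)
    if (t < T) {
      switch_draw <- stats::runif(n_vertices) < pswitch
      for (i in which(switch_draw)) {
        others <- setdiff(seq_len(n_groups), labels[i])
        labels[i] <- others[sample.int(length(others), 1)]
      }
    }
  }
  truth <- structure(list(labels = lab_mat,
                          params = list(n_vertices = n_vertices, K = n_groups,
                                        pwithin = pw, pbetween = pb,
                                        pswitch = pswitch, T = T,
                                        preset = preset, seed = seed)),
                     class = "dyhm_truth")
  list(series = snapshot_series(snaps), truth = truth)
}

#' @export
print.dyhm_truth <- function(x, ...) {
  p <- x$params
  if (is.matrix(x$labels))
    cat(sprintf("Planted truth: %d vertices, %d groups, %d snapshots (pswitch %g)\n",
                nrow(x$labels), p$K, ncol(x$labels), p$pswitch))
  else
    cat(sprintf("Planted truth: %d vertices in %d groups (pwithin %.3f, pbetween %.3f)\n",
                length(x$labels), p$K, p$pwithin, p$pbetween))
  invisible(x)
}
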