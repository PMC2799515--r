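#' Pairwise co-membership probabilities from a membership matrix
#'
#' Under the factorized surrogate the probability that two vertices sit
#' in the same leaf is `sum_u tau_iu tau_ju`. Computed once at the
#' converged memberships; no sampling is needed.
#'
#' @param tau Membership matrix (vertices x leaves, rows normalized) or a
#'   fitted `"dyhm"` object (static fits use their single snapshot).
#' @return Symmetric matrix of scores in `[0, 1]` with `NA` diagonal.
#' @examples
#' co_membership(matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE))[1, 2]  # 1
#' @export
co_membership <- function(tau) {
  if (inherits(tau, "dyhm_static")) tau <- tau$tau
  stopifnot(is.matrix(tau))
  m <- tcrossprod(tau)
  diag(m) <- NA_real_
  m
}

# upper-triangle vector of a symmetric pair matrix, aligned with pair_labels
pair_vector <- function(m) m[upper.tri(m)]

#' Same-group indicator for all vertex pairs of a snapshot
#'
#' @param labels Named integer vector of group labels covering (at least)
#'   the vertices in `vertices`.
#' @param vertices Character vector fixing the vertex order (use the
#'   rownames of the score matrix).
#' @return Logical vector over unordered pairs, upper-triangle order.
#' @export
pair_labels <- function(labels, vertices) {
  if (!all(vertices %in% names(labels)))
    stop("truth labels do not cover all scored vertices")
  z <- labels[vertices]
  outer(z, z, `==`)[upper.tri(diag(length(z)))]
}

#' Precision-recall curve for pairwise co-membership scores
#'
#' Sweeps a descending score threshold over the pairs; at each cut,
#' precision `TP/(TP+FP)` and recall `TP/(TP+FN)` against the planted
#' same-group pairs. Tied scores enter the confusion counts as one block,
#' so curves from heavily tied rankings (e.g. many p = 1 baseline pairs)
#' are handled deterministically.
#'
#' @param score Numeric vector of pair scores (larger = stronger
#'   co-membership evidence), or a symmetric score matrix.
#' @param label Logical/0-1 vector of pair truths aligned with `score`
#'   (see [pair_labels()]); required to contain at least one positive.
#' @return Object of class `"dyhm_pr"`: data frame with `threshold`,
#'   `tp`, `fp`, `precision`, `recall`.
#' @export
pr_curve <- function(score, label) {
  if (is.matrix(score)) score <- pair_vector(score)
  label <- as.logical(label)
  stopifnot(length(score) == length(label))
  keep <- !is.na(score) & !is.na(label)
  score <- score[keep]; label <- label[keep]
  P <- sum(label)
  if (P == 0) stop("no positive pairs in the truth")
  o <- order(score, decreasing = TRUE)
  s <- score[o]; l <- label[o]
  # block ends of tied scores
  ends <- sort(unique(c(which(diff(s) != 0), length(s))))
  tp <- cumsum(l)[ends]
  n_at <- ends
  out <- data.frame(threshold = s[ends], tp = tp, fp = n_at - tp,
                    precision = tp / n_at, recall = tp / P)
  class(out) <- c("dyhm_pr", "data.frame")
  out
}

#' Maximum F1 along a precision-recall curve
#'
#' The maximum harmonic mean `2PR/(P+R)` over the curve points (points
#' with `P = R = 0` are skipped).
#'
#' @param pr A [pr_curve()] result.
#' @return Scalar in `[0, 1]`.
#' @export
f1_max <- function(pr) {
  p <- pr$precision; r <- pr$recall
  ok <- (p + r) > 0
  if (!any(ok)) return(0)
  max(2 * p[ok] * r[ok] / (p[ok] + r[ok]))
}

#' Pooled precision-recall curve over replicates
#'
#' Amasses true/false-positive counts across replicates before computing
#' precision and recall: all pairs from all replicates enter one ranking
#' (scores must be comparable across replicates, as they are for
#' co-membership probabilities or a common baseline), ties as blocks.
#' This is pooling, not curve averaging, and the two differ whenever
#' replicates have unequal sizes or base rates.
#'
#' @param replicates List, one element per replicate, each a list with
#'   elements `score` and `label` as in [pr_curve()].
#' @return A `"dyhm_pr"` curve over the pooled counts.
#' @export
aggregate_pr <- function(replicates) {
  stopifnot(length(replicates) >= 1)
  score <- unlist(lapply(replicates, function(r)
    if (is.matrix(r$score)) pair_vector(r$score) else r$score))
  label <- unlist(lapply(replicates, `[[`, "label"))
  pr_curve(score, label)
}

#' Per-snapshot maximum F1 of a fitted dynamic model
#'
#' Convenience wrapper: co-membership per snapshot against the planted
#' same-group pairs, PR curve, max-F1. Pairs are evaluable only when both
#' vertices are active and labeled in the snapshot.
#'
#' @param fit A [fit_dynamic()] result.
#' @param truth A `"dyhm_truth"` from [generate_dynamic()] (or any labels
#'   matrix vertices x snapshots).
#' @return Numeric vector of max-F1 values, one per snapshot.
#' @export
f1_per_snapshot <- function(fit, truth) {
  labs <- if (inherits(truth, "dyhm_truth")) truth$labels else truth
  vapply(seq_along(fit$tau), function(t) {
    cm <- co_membership(fit$tau[[t]])
    verts <- rownames(fit$tau[[t]])
    lab_t <- stats::setNames(labs[verts, t], verts)
    f1_max(pr_curve(cm, pair_labels(lab_t, verts)))
  }, numeric(1))
}
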