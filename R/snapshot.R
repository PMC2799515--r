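#' A single network snapshot
#'
#' One observed network state: a global vertex set, an activity mask saying
#' which vertices are present in this snapshot, and a symmetric 0/1
#' adjacency over the active vertices (no self-loops). In a dynamic series
#' the same global vertex identifiers tie a vertex to itself across
#' snapshots.
#'
#' @param x Either a two-column edge table (character/factor/integer vertex
#'   ids, one undirected edge per row) or a symmetric 0/1 adjacency matrix
#'   with dimnames.
#' @param vertices Optional character vector of all global vertex ids
#'   (defaults to those appearing in `x`).
#' @param active Optional logical mask over `vertices` (default: all
#'   active). Edges touching inactive vertices are dropped.
#' @return An object of class `"dyhm_snapshot"`: list with `vertices`
#'   (character), `active` (named logical), and `adj` (dense 0/1 matrix
#'   over the active vertices, symmetric, zero diagonal).
#' @examples
#' sn <- snapshot(cbind(c("a", "b"), c("b", "c")))
#' sn$adj
#' @export
snapshot <- function(x, vertices = NULL, active = NULL) {
  if (is.matrix(x) && nrow(x) == ncol(x) && !is.null(rownames(x)) &&
      identical(rownames(x), colnames(x)) && (is.numeric(x) || is.logical(x))) {
    adj <- (x != 0) * 1
    if (!isTRUE(all.equal(adj, t(adj)))) stop("adjacency must be symmetric")
    diag(adj) <- 0
    verts <- if (is.null(vertices)) rownames(adj) else as.character(vertices)
    edges <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
    ed <- cbind(rownames(adj)[edges[, 1]], rownames(adj)[edges[, 2]])
  } else {
    ed <- as.matrix(x)
    if (ncol(ed) < 2 && nrow(ed) > 0) stop("edge table needs two columns")
    ed <- if (nrow(ed)) cbind(as.character(ed[, 1]), as.character(ed[, 2])) else
      matrix(character(0), 0, 2)
    verts <- if (is.null(vertices)) sort(unique(c(ed))) else as.character(vertices)
  }
  if (is.null(active)) active <- rep(TRUE, length(verts))
  if (length(active) != length(verts)) stop("'active' must match 'vertices'")
  names(active) <- verts
  act <- verts[active]
  adj <- matrix(0, length(act), length(act), dimnames = list(act, act))
  if (nrow(ed)) {
    keep <- ed[, 1] %in% act & ed[, 2] %in% act & ed[, 1] != ed[, 2]
    ed <- ed[keep, , drop = FALSE]
    adj[ed] <- 1
    adj[ed[, 2:1, drop = FALSE]] <- 1
  }
  structure(list(vertices = verts, active = active, adj = adj),
            class = "dyhm_snapshot")
}

#' @export
print.dyhm_snapshot <- function(x, ...) {
  cat(sprintf("Network snapshot: %d/%d vertices active, %d edges\n",
              sum(x$active), length(x$vertices), sum(x$adj) / 2))
  invisible(x)
}

n_edges <- function(snapshot) sum(snapshot$adj) / 2

active_vertices <- function(snapshot) rownames(snapshot$adj)

#' An ordered series of snapshots with a coupling graph
#'
#' Bundles snapshots with an undirected neighbor graph over snapshot
#' indices declaring which pairs are coupled by the smoothness penalty.
#' For a simple time course the neighbors are consecutive pairs; for a
#' tissue-by-stage grid they are the adjacent grid cells.
#'
#' @param snapshots List of [snapshot()] objects sharing a global vertex
#'   universe.
#' @param neighbors Two-column integer matrix of coupled snapshot index
#'   pairs, or `NULL` for consecutive coupling `(t, t+1)`.
#' @return An object of class `"dyhm_series"`.
#' @export
snapshot_series <- function(snapshots, neighbors = NULL) {
  stopifnot(length(snapshots) >= 1,
            all(vapply(snapshots, inherits, TRUE, "dyhm_snapshot")))
  T_ <- length(snapshots)
  if (is.null(neighbors)) {
    neighbors <- if (T_ > 1) cbind(seq_len(T_ - 1L), 2:T_) else
      matrix(integer(0), 0, 2)
  }
  neighbors <- matrix(as.integer(neighbors), ncol = 2)
  if (nrow(neighbors)) {
    if (any(neighbors < 1 | neighbors > T_))
      stop("neighbor pairs reference invalid snapshot indices")
    if (any(neighbors[, 1] == neighbors[, 2]))
      stop("self-coupling of a snapshot is not allowed")
    neighbors <- t(apply(neighbors, 1, sort))
    neighbors <- unique(neighbors)
  }
  structure(list(snapshots = snapshots, neighbors = neighbors),
            class = "dyhm_series")
}

#' @export
print.dyhm_series <- function(x, ...) {
  cat(sprintf("Snapshot series: %d snapshots, %d couplings\n",
              length(x$snapshots), nrow(x$neighbors)))
  invisible(x)
}

# symmetric neighbor lists: nbrs[[t]] = indices coupled to t
neighbor_lists <- function(series) {
  T_ <- length(series$snapshots)
  nbrs <- rep(list(integer(0)), T_)
  if (nrow(series$neighbors)) {
    for (k in seq_len(nrow(series$neighbors))) {
      t1 <- series$neighbors[k, 1]; t2 <- series$neighbors[k, 2]
      nbrs[[t1]] <- c(nbrs[[t1]], t2)
      nbrs[[t2]] <- c(nbrs[[t2]], t1)
    }
  }
  nbrs
}

#' Neighbor pairs for a tissue-by-stage grid of snapshots
#'
#' Expands a rows-by-columns grid layout into the couplings between
#' column-adjacent cells (same row, consecutive stages), the layout used
#' for spatial sections by developmental stages. Snapshots are assumed
#' ordered column-major: all rows of stage 1, then stage 2, and so on.
#' A 5-tissue by 3-stage layout with `rows_coupled = FALSE` yields
#' stage-adjacent couplings only.
#'
#' @param n_rows,n_cols Grid dimensions (e.g. tissues x stages).
#' @param rows_coupled Also couple row-adjacent cells within a stage.
#' @return Two-column integer matrix of snapshot index pairs.
#' @export
grid_neighbors <- function(n_rows, n_cols, rows_coupled = FALSE) {
  idx <- function(r, c) (c - 1L) * n_rows + r
  out <- NULL
  for (c in seq_len(n_cols - 1L)) for (r in seq_len(n_rows))
    out <- rbind(out, c(idx(r, c), idx(r, c + 1L)))
  if (rows_coupled)
    for (c in seq_len(n_cols)) for (r in seq_len(n_rows - 1L))
      out <- rbind(out, c(idx(r, c), idx(r + 1L, c)))
  matrix(as.integer(out), ncol = 2)
}
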