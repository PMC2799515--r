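#' Read an undirected edge list from a TSV file
#'
#' Two whitespace/tab-separated vertex-id columns per line, optional
#' header. Edges are undirected; duplicates (in either orientation) are
#' collapsed and self-loops dropped with a warning. Vertex ids are kept
#' as strings.
#'
#' @param path File path.
#' @param header Does the first line hold column names?
#' @return A [snapshot()].
#' @export
read_edge_list <- function(path, header = FALSE) {
  lines <- readLines(path)
  if (header && length(lines)) lines <- lines[-1]
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(snapshot(matrix(character(0), 0, 2)))
  parts <- strsplit(lines, "[\t ]+")
  bad <- which(vapply(parts, length, 0L) < 2)
  if (length(bad))
    stop(sprintf("malformed edge line %d: '%s'", bad[1] + header, lines[bad[1]]))
  ed <- t(vapply(parts, function(p) p[1:2], character(2)))
  loops <- ed[, 1] == ed[, 2]
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    ed <- ed[!loops, , drop = FALSE]
  }
  snapshot(ed)
}

#' Write a snapshot's edges as TSV
#' @param snapshot A [snapshot()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(snapshot, path) {
  A <- snapshot$adj
  idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  ed <- cbind(rownames(A)[idx[, 1]], rownames(A)[idx[, 2]])
  utils::write.table(ed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Iteratively prune low-degree vertices
#'
#' Removes vertices of degree `<= k` and repeats until every remaining
#' vertex has degree `> k` (the `k+1`-core peeling). The fixed point is
#' independent of removal order, so the result is deterministic.
#'
#' @param snapshot A [snapshot()].
#' @param k Degree threshold (default 3: vertices of degree at most 3 are
#'   peeled away, the filtering used before extracting active
#'   subnetworks).
#' @return The pruned [snapshot()]; removed vertices become inactive.
#' @export
prune_low_degree <- function(snapshot, k = 3) {
  stopifnot(k >= 0)
  A <- snapshot$adj
  keep <- rep(TRUE, nrow(A))
  repeat {
    idx <- which(keep)
    if (!length(idx)) break
    deg <- rowSums(A[idx, idx, drop = FALSE])
    drop <- deg <= k
    if (!any(drop)) break
    keep[idx[drop]] <- FALSE
  }
  kept <- rownames(A)[keep]
  active <- snapshot$active & names(snapshot$active) %in% kept
  snapshot(A[keep, keep, drop = FALSE], vertices = snapshot$vertices,
           active = active)
}

#' Read a vertex-activity matrix from TSV
#'
#' First column: vertex id; remaining columns: one per snapshot (header
#' gives the snapshot names). Values may be binary or real-valued.
#'
#' @param path File path.
#' @return Numeric matrix, vertices x snapshots, with dimnames.
#' @export
read_activity_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1]])
  m
}

#' Build a snapshot series from a base network and activity calls
#'
#' Per snapshot, the active vertex set is the set of base vertices whose
#' activity value meets the threshold (`value >= threshold`; with a
#' binary presence matrix and the default threshold 1, active = present),
#' and the snapshot is the subgraph of the base network induced on them.
#' Activity rows for vertices unknown to the base network are ignored
#' with a warning; base vertices missing from the matrix count as
#' inactive.
#'
#' @param base A [snapshot()] holding the superposition network (e.g. the
#'   pruned interaction compendium).
#' @param activity Matrix vertices x snapshots (see
#'   [read_activity_matrix()]).
#' @param threshold Activity call threshold (default 1).
#' @param neighbors Coupling pairs for [snapshot_series()]; default
#'   consecutive.
#' @return A [snapshot_series()].
#' @export
build_series <- function(base, activity, threshold = 1, neighbors = NULL) {
  stopifnot(inherits(base, "dyhm_snapshot"))
  unknown <- setdiff(rownames(activity), base$vertices)
  if (length(unknown)) {
    warning(sprintf("%d activity vertices unknown to the base network; ignored",
                    length(unknown)))
    activity <- activity[setdiff(rownames(activity), unknown), , drop = FALSE]
  }
  A <- base$adj
  snaps <- lapply(seq_len(ncol(activity)), function(t) {
    act_ids <- rownames(activity)[activity[, t] >= threshold]
    active <- stats::setNames(base$vertices %in% act_ids, base$vertices)
    if (!any(active)) warning(sprintf("snapshot %d has no active vertices", t))
    keep <- rownames(A) %in% base$vertices[active]
    snapshot(A[keep, keep, drop = FALSE], vertices = base$vertices,
             active = active)
  })
  snapshot_series(snaps, neighbors)
}

#' Read a snapshot-series description from YAML
#'
#' The YAML lists per-snapshot edge files (`snapshots: [{name, edges}]`,
#' paths relative to the YAML file), optionally an `activity` TSV plus
#' `threshold`, and `neighbors` as a list of index pairs. When an
#' activity matrix is given, the union of all edge files forms the base
#' network and [build_series()] applies; otherwise each edge file is one
#' fully active snapshot.
#'
#' @param path YAML file.
#' @return A [snapshot_series()].
#' @export
read_series <- function(path) {
  doc <- yaml::read_yaml(path)
  dir <- dirname(path)
  rel <- function(p) if (file.exists(p)) p else file.path(dir, p)
  nb <- if (!is.null(doc$neighbors))
    do.call(rbind, lapply(doc$neighbors, as.integer)) else NULL
  edge_files <- vapply(doc$snapshots, function(s)
    rel(if (is.list(s)) s$edges else s), character(1))
  if (!is.null(doc$activity)) {
    all_edges <- do.call(rbind, lapply(edge_files, function(f) {
      sn <- read_edge_list(f)
      idx <- which(upper.tri(sn$adj) & sn$adj != 0, arr.ind = TRUE)
      cbind(rownames(sn$adj)[idx[, 1]], rownames(sn$adj)[idx[, 2]])
    }))
    base <- snapshot(all_edges)
    act <- read_activity_matrix(rel(doc$activity))
    thr <- if (is.null(doc$threshold)) 1 else doc$threshold
    build_series(base, act, threshold = thr, neighbors = nb)
  } else {
    universe <- sort(unique(unlist(lapply(edge_files, function(f)
      read_edge_list(f)$vertices))))
    snaps <- lapply(edge_files, function(f) {
      sn <- read_edge_list(f)
      active <- stats::setNames(universe %in% sn$vertices, universe)
      idx <- which(upper.tri(sn$adj) & sn$adj != 0, arr.ind = TRUE)
      ed <- cbind(rownames(sn$adj)[idx[, 1]], rownames(sn$adj)[idx[, 2]])
      snapshot(ed, vertices = universe, active = active)
    })
    snapshot_series(snaps, nb)
  }
}

#' Write a series description plus edge files
#'
#' The inverse of [read_series()] for fully active snapshots: writes one
#' edge TSV per snapshot and a `series.yaml` referencing them.
#'
#' @param series A [snapshot_series()].
#' @param dir Output directory (created if needed).
#' @return Path of the written YAML, invisibly.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(series$snapshots))
  for (t in seq_along(series$snapshots)) {
    files[t] <- sprintf("snapshot_%02d.tsv", t)
    write_edge_list(series$snapshots[[t]], file.path(dir, files[t]))
  }
  doc <- list(snapshots = lapply(seq_along(files), function(t)
    list(name = sprintf("t%d", t), edges = files[t])),
    neighbors = lapply(seq_len(nrow(series$neighbors)), function(k)
      as.integer(series$neighbors[k, ])))
  out <- file.path(dir, "series.yaml")
  yaml::write_yaml(doc, out)
  invisible(out)
}

#' Write per-snapshot membership posteriors as TSV
#' @param fit A fitted `"dyhm"` object.
#' @param path Output file (columns: snapshot, vertex, leaf posteriors).
#' @return `path`, invisibly.
#' @export
write_membership <- function(fit, path) {
  taus <- if (inherits(fit, "dyhm_dynamic")) fit$tau else list(fit$tau)
  rows <- do.call(rbind, lapply(seq_along(taus), function(t) {
    data.frame(snapshot = t, vertex = rownames(taus[[t]]),
               leaf = max.col(taus[[t]], ties.method = "first"),
               taus[[t]], check.names = FALSE)
  }))
  names(rows)[-(1:3)] <- sprintf("tau_%d", seq_len(ncol(taus[[1]])))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
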