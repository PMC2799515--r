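#' Fixed-depth hierarchical tree with Beta edge-probability parameters
#'
#' Constructs a perfect binary tree of the given depth. Graph vertices are
#' assigned to the `G = 2^depth` terminal nodes (leaves); every node --
#' internal split or leaf -- carries a Beta posterior `(a_r, b_r)` over its
#' Bernoulli edge probability: internal nodes govern edges between their
#' left and right descendant leaf sets, leaves govern within-leaf edges.
#'
#' Nodes are heap-indexed: internal nodes are `1 .. G-1` (node `r` has
#' children `2r` and `2r+1`), and leaf `u` (indexed `1..G` left to right)
#' is node `G - 1 + u`. The left-to-right leaf order is the in-order
#' traversal of the terminals.
#'
#' @param depth Integer tree depth, `>= 1`. The tree has `2^depth` leaves.
#' @param a0,b0 Beta prior hyperparameters shared by all nodes. The default
#'   `a0 = b0 = 1` is the flat, non-informative prior.
#' @return An object of class `"hier_tree"`: a list with elements `depth`,
#'   `G` (leaf count), `n_nodes` (`2G - 1`), `a`, `b` (per-node Beta
#'   parameters, initialised at the prior), `prior = c(a0, b0)`, and `lca`
#'   (a `G x G` integer matrix giving, for two leaves, the node whose
#'   Bernoulli parameter their vertex pairs contribute to: the lowest
#'   common ancestor off the diagonal, the leaf's own node on it).
#' @examples
#' tr <- hier_tree(2)
#' tr$G                     # 4 leaves
#' leaf_ancestry(tr, 3)     # root (right side), then its right child (left side)
#' @seealso [leaf_ancestry()], [expected_counts()], [fit_static()]
#' @export
hier_tree <- function(depth, a0 = 1, b0 = 1) {
  depth <- as.integer(depth)
  if (length(depth) != 1L || is.na(depth) || depth < 1L)
    stop("'depth' must be a single integer >= 1")
  if (a0 <= 0 || b0 <= 0) stop("Beta prior parameters must be positive")
  G <- 2L^depth
  n_nodes <- 2L * G - 1L
  lca <- matrix(0L, G, G)
  for (u in seq_len(G)) {
    for (v in seq_len(G)) {
      if (u == v) {
        lca[u, v] <- G - 1L + u
      } else {
        # climb heap positions of the two leaves until they meet
        hu <- G + u - 1L  # heap position in a full tree of 2G-1 nodes
        hv <- G + v - 1L
        while (hu != hv) {
          if (hu > hv) hu <- hu %/% 2L else hv <- hv %/% 2L
        }
        lca[u, v] <- hu
      }
    }
  }
  structure(list(
    depth = depth, G = G, n_nodes = n_nodes,
    a = rep(a0, n_nodes), b = rep(b0, n_nodes),
    prior = c(a0 = a0, b0 = b0), lca = lca
  ), class = "hier_tree")
}

#' @export
print.hier_tree <- function(x, ...) {
  cat(sprintf("Hierarchical tree: depth %d, %d leaves, %d internal nodes\n",
              x$depth, x$G, x$G - 1L))
  cat(sprintf("Beta prior: a0 = %g, b0 = %g\n", x$prior[1], x$prior[2]))
  invisible(x)
}

# depth of a heap node (root = 0)
node_depth <- function(node) floor(log2(node))

# leaves (1..G) descending from heap node `node`
node_leaves <- function(tree, node) {
  G <- tree$G
  if (node >= G) return(node - G + 1L)           # terminal node
  lo <- node
  while (lo < G) lo <- 2L * lo                    # leftmost descendant heap id
  hi <- node
  while (hi < G) hi <- 2L * hi + 1L
  seq.int(lo - G + 1L, hi - G + 1L)
}

#' Root-to-leaf ancestry of a terminal node
#'
#' Returns the internal nodes on the path from the root to a leaf, each
#' annotated with the side (`"left"` or `"right"`) on which the leaf lies.
#' The `opposite` leaf sets across the ancestry, together with the leaf
#' itself, partition all leaves: every other leaf splits from `leaf` at
#' exactly one ancestor, its lowest common ancestor with `leaf`.
#'
#' @param tree A [hier_tree()].
#' @param leaf Leaf index in `1..G`.
#' @return A data frame with columns `node` (internal heap index), `side`,
#'   and a list column `opposite` holding the leaf indices on the other
#'   side of each split.
#' @export
leaf_ancestry <- function(tree, leaf) {
  stopifnot(inherits(tree, "hier_tree"))
  leaf <- as.integer(leaf)
  if (length(leaf) != 1L || is.na(leaf) || leaf < 1L || leaf > tree$G)
    stop("unknown leaf id")
  h <- tree$G + leaf - 1L
  nodes <- integer(0); sides <- character(0); opp <- list()
  while (h > 1L) {
    parent <- h %/% 2L
    side <- if (h %% 2L == 0L) "left" else "right"
    sib <- if (side == "left") 2L * parent + 1L else 2L * parent
    nodes <- c(parent, nodes)
    sides <- c(side, sides)
    opp <- c(list(node_leaves(tree, sib)), opp)
    h <- parent
  }
  out <- data.frame(node = nodes, side = sides, stringsAsFactors = FALSE)
  out$opposite <- opp
  out
}

#' Serialize a fitted or bare tree to JSON
#'
#' Writes node identifiers, children, Beta parameters and (optionally)
#' per-node edge enrichment as a JSON document.
#'
#' @param tree A [hier_tree()].
#' @param path Output file; if `NULL` the JSON string is returned.
#' @param enrichment Optional per-node enrichment vector from
#'   [node_enrichment()].
#' @return The JSON string, invisibly when written to `path`.
#' @export
tree_to_json <- function(tree, path = NULL, enrichment = NULL) {
  stopifnot(inherits(tree, "hier_tree"))
  G <- tree$G
  ids <- seq_len(tree$n_nodes)
  nodes <- lapply(ids, function(r) {
    nd <- list(
      id = r,
      kind = if (r < G) "internal" else "leaf",
      depth = node_depth(r),
      a = tree$a[r], b = tree$b[r]
    )
    if (r < G) nd$children <- c(2L * r, 2L * r + 1L)
    if (r >= G) nd$leaf_index <- r - G + 1L
    if (!is.null(enrichment)) nd$enrichment <- unname(enrichment[r])
    nd
  })
  doc <- list(depth = tree$depth, n_leaves = G,
              prior = as.list(tree$prior), nodes = nodes)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a tree back from its JSON serialization
#' @param path File written by [tree_to_json()].
#' @return A [hier_tree()] with the stored Beta parameters.
#' @export
tree_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  tr <- hier_tree(doc$depth, a0 = doc$prior$a0, b0 = doc$prior$b0)
  tr$a[doc$nodes$id] <- doc$nodes$a
  tr$b[doc$nodes$id] <- doc$nodes$b
  tr
}
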