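#' Arcs ancestral to a leaf set
#'
#' An arc (u, u') belongs to the ancestor set of a leaf set X when its head
#' u' has some descendant leaf in X.  The total weight of this arc set is
#' the rPSD value of X.
#'
#' @param net a `phylo_network`.
#' @param X character vector of leaf labels (a subset of `net$leaves`).
#' @return a data frame with columns `parent`, `child`, `weight`, one row
#'   per ancestral arc, sorted by (parent, child).
#' @export
ancestor_arcs <- function(net, X) {
  X <- .check_leafset(net, X)
  sel <- .ancestor_arc_mask(net, X)
  out <- data.frame(parent = net$parent[sel], child = net$child[sel],
                    weight = net$weight[sel], stringsAsFactors = FALSE)
  out[order(out$parent, out$child), , drop = FALSE]
}

# logical mask over arcs: head is an ancestor of some leaf in X
.ancestor_arc_mask <- function(net, X) {
  if (length(X) == 0) return(logical(length(net$parent)))
  anc <- .ancestor_nodes(net, X)
  net$child %in% anc
}

#' Cluster of a node
#'
#' The cluster of a node v is the set of labels of its descendant leaves.
#'
#' @param net a `phylo_network`.
#' @param v a node id.
#' @return sorted character vector of leaf labels.
#' @export
node_cluster <- function(net, v) {
  if (!v %in% net$nodes) stop("unknown node: ", v)
  sort(intersect(.descendant_nodes(net, v), net$leaves))
}

#' Blob decomposition of a network
#'
#' A blob is a biconnected component (of the underlying undirected graph)
#' with more than 2 nodes.  Each blob has a unique split node that is an
#' ancestor of all its nodes; its reticulations with no child inside the
#' blob are the exit reticulations, the rest are internal.
#'
#' @param net a `phylo_network`.
#' @return a list of blobs, each a list with components `nodes`, `arcs`
#'   (data frame of the blob's arcs), `split_node`, `exit_reticulations`,
#'   `internal_reticulations`.  Trees return an empty list.
#' @export
network_blobs <- function(net) {
  comps <- .bicomponents(net)
  retic <- reticulations(net)
  out <- list()
  for (ai in comps) {
    vs <- unique(c(net$parent[ai], net$child[ai]))
    if (length(vs) <= 2) next
    # reticulations belonging to this blob: all their in-arcs lie in one
    # biconnected component, so membership is "some in-arc is in the blob"
    blob_retic <- intersect(unique(net$child[ai]), retic)
    has_child_inside <- blob_retic %in% net$parent[ai]
    # split node: the unique blob node from which every blob node is
    # reachable along blob arcs
    sub <- list(parent = net$parent[ai], child = net$child[ai],
                nodes = vs)
    reach_all <- vapply(vs, function(v) {
      length(.descendant_nodes(sub, v)) == length(vs)
    }, logical(1))
    if (sum(reach_all) != 1)
      stop("blob without a unique split node (invalid network?)")
    out[[length(out) + 1L]] <- list(
      nodes = sort(vs),
      arcs = data.frame(parent = net$parent[ai], child = net$child[ai],
                        weight = net$weight[ai], stringsAsFactors = FALSE),
      split_node = vs[reach_all],
      exit_reticulations = sort(blob_retic[!has_child_inside]),
      internal_reticulations = sort(blob_retic[has_child_inside]))
  }
  out
}

# biconnected components as a list of arc-index vectors (igraph backend)
.bicomponents <- function(net) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$parent, to = net$child, stringsAsFactors = FALSE),
    directed = FALSE)
  bc <- igraph::biconnected_components(g)
  lapply(bc$component_edges, function(es) as.integer(es))
}

#' Level of a network
#'
#' The level is the maximum number of reticulations contained in a single
#' biconnected component; a level-0 network is a phylogenetic tree.
#'
#' @param net a `phylo_network`.
#' @return a nonnegative integer.
#' @export
network_level <- function(net) {
  retic <- reticulations(net)
  if (length(retic) == 0) return(0L)
  comps <- .bicomponents(net)
  max(vapply(comps, function(ai) {
    length(intersect(unique(net$child[ai]), retic))
  }, integer(1)))
}

#' Classify a network by level, arity and standard classes
#'
#' Reports the level, the reticulation arity (maximum reticulation
#' in-degree, 0 when the network is a tree), and the class predicates: a
#' network is semi-d-ary when every reticulation has in-degree at most d
#' (semibinary = semi-2-ary), binary when additionally every internal tree
#' node has out-degree 2, and a galled tree when it is semibinary of level
#' at most 1.
#'
#' @param net a `phylo_network`.
#' @return a list of class `"network_profile"` with components `level`,
#'   `arity`, `is_tree`, `is_binary`, `is_semibinary`, `is_galled_tree`.
#' @export
classify_network <- function(net) {
  indeg <- .in_degree(net)
  outdeg <- .out_degree(net)
  retic <- net$nodes[indeg >= 2L]
  arity <- if (length(retic) == 0) 0L else max(indeg[retic])
  lev <- network_level(net)
  semibinary <- arity <= 2L
  internal_tree <- setdiff(net$nodes[indeg <= 1L & outdeg > 0L], retic)
  structure(list(
    level = lev,
    arity = as.integer(arity),
    is_tree = lev == 0L,
    is_binary = semibinary && all(outdeg[internal_tree] == 2L),
    is_semibinary = semibinary,
    is_galled_tree = semibinary && lev <= 1L
  ), class = "network_profile")
}

#' @export
print.network_profile <- function(x, ...) {
  cat(sprintf("level %d, reticulation arity %d\n", x$level, x$arity))
  flags <- c(tree = x$is_tree, binary = x$is_binary,
             semibinary = x$is_semibinary, `galled tree` = x$is_galled_tree)
  cat("  classes:", if (any(flags)) paste(names(flags)[flags], collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Is a network semi-d-ary?
#'
#' @param net a `phylo_network`.
#' @param d integer at least 2.
#' @return `TRUE` when every reticulation has in-degree at most `d`
#'   (vacuously true for trees).
#' @export
is_semi_d_ary <- function(net, d) {
  classify_network(net)$arity <= d
}
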