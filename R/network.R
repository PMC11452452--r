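#' Construct a weighted rooted phylogenetic network
#'
#' A phylogenetic network is a rooted directed acyclic graph in which every
#' node of in-degree at least 2 (a reticulation) has out-degree exactly 1,
#' and whose leaves (out-degree 0) carry unique labels.  Arcs are weighted by
#' nonnegative reals, typically branch lengths or expected character change.
#' Elementary nodes (in-degree at most 1, out-degree 1) are permitted.
#'
#' Nodes are identified by character ids; a leaf's label is its id.
#'
#' @param parent character vector of arc tails.
#' @param child character vector of arc heads, parallel to `parent`.
#' @param weight numeric vector of nonnegative arc weights (recycled from a
#'   scalar); defaults to 1 for every arc.
#' @param validate if `TRUE` (default), stop on any structural violation.
#' @return an object of class `"phylo_network"`: a list with components
#'   `parent`, `child`, `weight`, `nodes`, `root`, `leaves` (sorted labels).
#' @examples
#' net <- phylo_network(c("r", "r", "v", "v"), c("v", "c", "a", "b"))
#' net$leaves
#' @export
phylo_network <- function(parent, child, weight = 1, validate = TRUE) {
  parent <- as.character(parent)
  child <- as.character(child)
  stopifnot(length(parent) == length(child))
  weight <- rep_len(as.numeric(weight), length(parent))
  nodes <- sort(unique(c(parent, child)))
  is_leaf <- !(nodes %in% parent)
  roots <- setdiff(nodes, child)
  net <- structure(
    list(parent = parent, child = child, weight = weight,
         nodes = nodes, root = if (length(roots) == 1) roots else NA_character_,
         leaves = sort(nodes[is_leaf])),
    class = "phylo_network")
  attr(net, "wscale") <- .weight_scale(weight)
  if (validate) {
    bad <- validate_network(net)
    if (length(bad) > 0)
      stop("invalid phylogenetic network: ", paste(bad, collapse = "; "))
  }
  net
}

# smallest p in 0..6 such that all weights are integral at scale 10^p,
# NA when no such p exists (then comparisons fall back to a tolerance)
.weight_scale <- function(w) {
  for (p in 0:6) {
    s <- w * 10^p
    if (all(abs(s - round(s)) < 1e-9 * pmax(1, abs(s)))) return(p)
  }
  NA_integer_
}

#' Validate a candidate phylogenetic network
#'
#' Checks the defining invariants: a unique root (in-degree 0), acyclicity,
#' out-degree exactly 1 at every reticulation (in-degree >= 2), unique leaf
#' labels, nonnegative weights, no parallel arcs, and connectivity from the
#' root.  Elementary nodes are legal and not reported.
#'
#' @param net a `phylo_network` (or a structurally similar list).
#' @return a character vector of violations; empty when the network is valid.
#' @export
validate_network <- function(net) {
  out <- character(0)
  if (length(net$parent) == 0)
    return("no root: network has no arcs")
  roots <- setdiff(unique(c(net$parent, net$child)), net$child)
  if (length(roots) == 0) out <- c(out, "no root (every node has a parent)")
  if (length(roots) > 1)
    out <- c(out, paste0("multiple roots: ", paste(sort(roots), collapse = ", ")))
  if (anyNA(net$weight) || any(net$weight < 0))
    out <- c(out, "negative or missing arc weight")
  key <- paste(net$parent, net$child, sep = "\r")
  if (anyDuplicated(key))
    out <- c(out, "parallel arcs present")
  indeg <- table(factor(net$child, levels = net$nodes))
  outdeg <- table(factor(net$parent, levels = net$nodes))
  retic <- net$nodes[indeg >= 2]
  bad_retic <- retic[outdeg[retic] != 1]
  if (length(bad_retic) > 0)
    out <- c(out, paste0("reticulation with out-degree != 1: ",
                         paste(bad_retic, collapse = ", ")))
  ord <- .topo_order(net)
  if (is.null(ord)) out <- c(out, "not acyclic")
  if (length(roots) == 1 && !is.null(ord)) {
    reach <- .descendant_nodes(net, roots)
    orphan <- setdiff(net$nodes, reach)
    if (length(orphan) > 0)
      out <- c(out, paste0("nodes unreachable from root: ",
                           paste(sort(orphan), collapse = ", ")))
  }
  out
}

# Kahn topological order of node ids, or NULL when the graph has a cycle
.topo_order <- function(net) {
  nodes <- net$nodes
  indeg <- as.integer(table(factor(net$child, levels = nodes)))
  names(indeg) <- nodes
  kids <- split(net$child, factor(net$parent, levels = nodes))
  queue <- sort(nodes[indeg == 0L])
  ord <- character(0)
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (u in kids[[v]]) {
      indeg[u] <- indeg[u] - 1L
      if (indeg[u] == 0L) queue <- sort(c(queue, u))
    }
  }
  if (length(ord) != length(nodes)) NULL else ord
}

# all nodes reachable from `from` (inclusive) following arcs forward
.descendant_nodes <- function(net, from) {
  kids <- split(net$child, factor(net$parent, levels = net$nodes))
  seen <- structure(logical(length(net$nodes)), names = net$nodes)
  stack <- from
  seen[from] <- TRUE
  while (length(stack) > 0) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    nxt <- kids[[v]]
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    stack <- c(stack, nxt)
  }
  net$nodes[seen]
}

# all nodes that are ancestors of some node in `of` (inclusive)
.ancestor_nodes <- function(net, of) {
  pars <- split(net$parent, factor(net$child, levels = net$nodes))
  seen <- structure(logical(length(net$nodes)), names = net$nodes)
  stack <- of
  seen[of] <- TRUE
  while (length(stack) > 0) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    nxt <- pars[[v]]
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    stack <- c(stack, nxt)
  }
  net$nodes[seen]
}

.in_degree <- function(net) {
  tab <- table(factor(net$child, levels = net$nodes))
  structure(as.integer(tab), names = net$nodes)
}

.out_degree <- function(net) {
  tab <- table(factor(net$parent, levels = net$nodes))
  structure(as.integer(tab), names = net$nodes)
}

#' Reticulation nodes of a network
#'
#' @param net a `phylo_network`.
#' @return character vector of node ids with in-degree at least 2.
#' @export
reticulations <- function(net) {
  net$nodes[.in_degree(net) >= 2L]
}

#' Total weight of a network
#'
#' @param net a `phylo_network`.
#' @return the sum of all arc weights.
#' @export
total_weight <- function(net) .exact_sum(net, rep(TRUE, length(net$weight)))

# sum of the weights of the selected arcs; uses scaled-integer summation when
# all weights are short decimal literals so that equal sums compare equal
.exact_sum <- function(net, sel) {
  p <- attr(net, "wscale")
  if (is.na(p)) return(sum(net$weight[sel]))
  sum(round(net$weight[sel] * 10^p)) / 10^p
}

#' @export
print.phylo_network <- function(x, ...) {
  prof <- classify_network(x)
  cat(sprintf("phylo_network: %d nodes, %d arcs, %d leaves, total weight %g\n",
              length(x$nodes), length(x$parent), length(x$leaves),
              total_weight(x)))
  cat(sprintf("  root %s; level %d; reticulation arity %d%s\n",
              x$root, prof$level, prof$arity,
              if (prof$is_tree) " (tree)"
              else if (prof$is_galled_tree) " (galled tree)" else ""))
  invisible(x)
}

#' Test two networks for identity up to internal node ids
#'
#' Networks are compared as labeled weighted graphs after canonically
#' renaming internal nodes: leaves must carry identical labels, and there
#' must be a bijection between internal nodes preserving arcs and weights.
#' Used to verify serialization round trips.
#'
#' @param a,b `phylo_network` objects.
#' @return `TRUE` or `FALSE`.
#' @export
network_identical <- function(a, b) {
  if (!setequal(a$leaves, b$leaves)) return(FALSE)
  if (length(a$parent) != length(a$parent)) return(FALSE)
  ca <- .canonical_ids(a)
  cb <- .canonical_ids(b)
  fa <- sort(paste(ca[a$parent], ca[a$child], format(a$weight, digits = 12)))
  fb <- sort(paste(cb[b$parent], cb[b$child], format(b$weight, digits = 12)))
  identical(fa, fb)
}

# deterministic canonical names for all nodes: leaves keep their labels,
# internal nodes are named by iterative refinement on (in/out neighborhood
# signatures with weights); ties broken by refinement stability plus an
# arbitrary-but-deterministic ordering of identical signatures
.canonical_ids <- function(net) {
  ids <- structure(net$nodes, names = net$nodes)
  sig <- ifelse(net$nodes %in% net$leaves, paste0("L:", net$nodes), "I")
  names(sig) <- net$nodes
  for (it in seq_len(length(net$nodes))) {
    dn <- vapply(net$nodes, function(v) {
      kidsig <- sort(paste0(sig[net$child[net$parent == v]], "|",
                            format(net$weight[net$parent == v], digits = 12)))
      parsig <- sort(paste0(format(net$weight[net$child == v], digits = 12)))
      paste0(sig[v], "(", paste(kidsig, collapse = ","), ")[",
             paste(parsig, collapse = ","), "]")
    }, character(1))
    new_sig <- match(dn, sort(unique(dn)))
    new_sig <- paste0(ifelse(net$nodes %in% net$leaves,
                             paste0("L:", net$nodes), "I"), new_sig)
    names(new_sig) <- net$nodes
    if (length(unique(new_sig)) == length(unique(sig)) && it > 1) {
      sig <- new_sig
      break
    }
    sig <- new_sig
  }
  # make names unique deterministically among equal signatures
  ave_rank <- stats::ave(seq_along(sig), sig, FUN = seq_along)
  out <- paste0(sig, "#", ave_rank)
  out[net$nodes %in% net$leaves] <- net$nodes[net$nodes %in% net$leaves]
  names(out) <- net$nodes
  out
}

# format a weight compactly without scientific notation or trailing zeros
.fmt_weight <- function(w) {
  s <- format(w, digits = 12, scientific = FALSE, trim = TRUE)
  has_dot <- grepl(".", s, fixed = TRUE)
  s[has_dot] <- sub("\\.$", "", sub("0+$", "", s[has_dot]))
  s
}

# check that X is a subset of the leaf labels, normalizing to sorted unique
.check_leafset <- function(net, X) {
  X <- unique(as.character(X))
  bad <- setdiff(X, net$leaves)
  if (length(bad) > 0)
    stop("unknown leaf label(s): ", paste(bad, collapse = ", "))
  sort(X)
}
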