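#' Rooted Phylogenetic Subnet Diversity
#'
#' The rPSD of a leaf set X (also called AllPaths-PD) is the total weight of
#' the subgraph induced by the ancestors of X: the sum of w(e) over all arcs
#' e with some descendant leaf in X.  On a phylogenetic tree it coincides
#' with Faith's rooted Phylogenetic Diversity.
#'
#' @param net a `phylo_network`.
#' @param X character vector of leaf labels.
#' @return a single nonnegative number, in the units of the arc weights.
#' @examples
#' net <- example1_fixture()
#' rpsd(net, c("x2", "x4"))
#' @export
rpsd <- function(net, X) {
  X <- .check_leafset(net, X)
  .exact_sum(net, .ancestor_arc_mask(net, X))
}

#' Phylogenetic Diversity on a tree
#'
#' Alias of [rpsd()] restricted to trees (level-0 networks), where the
#' ancestor subgraph is the subtree spanning the root and X.
#'
#' @inheritParams rpsd
#' @export
pd_tree <- function(net, X) {
  if (network_level(net) != 0L) stop("pd_tree requires a phylogenetic tree")
  rpsd(net, X)
}

#' rPSD of every leaf subset
#'
#' Computes the rPSD of all 2^n subsets of the leaves in one pass: for each
#' arc, its weight is added to the value of every subset intersecting the
#' cluster of the arc's head.  Subsets are encoded as bitmasks over the
#' sorted leaf labels (bit i-1 = leaf i).
#'
#' The returned vector carries an attribute `key`: an exactly comparable
#' encoding of the values (integer-scaled when all weights are short
#' decimal literals, the raw values otherwise) used for tie detection.
#'
#' @param net a `phylo_network` with at most 20 leaves.
#' @return numeric vector `v` of length 2^n, `v[mask + 1]` = rPSD of the
#'   subset encoded by `mask`.
#' @export
rpsd_table <- function(net) {
  n <- length(net$leaves)
  if (n > 20) stop("rpsd_table supports at most 20 leaves (got ", n, ")")
  masks <- 0:(2^n - 1)
  clm <- .cluster_masks(net)
  p <- attr(net, "wscale")
  exact <- !is.na(p)
  w <- if (exact) round(net$weight * 10^p) else net$weight
  acc <- numeric(2^n)
  for (i in seq_along(net$parent)) {
    hit <- bitwAnd(masks, clm[net$child[i]]) != 0L
    acc[hit] <- acc[hit] + w[i]
  }
  val <- if (exact) acc / 10^p else acc
  attr(val, "key") <- acc
  attr(val, "exact") <- exact
  val
}

# cluster of every node as a leaf bitmask, by reverse topological sweep
.cluster_masks <- function(net) {
  ord <- .topo_order(net)
  cm <- structure(integer(length(net$nodes)), names = net$nodes)
  idx <- match(net$nodes, net$leaves)
  cm[!is.na(idx)] <- as.integer(2^(idx[!is.na(idx)] - 1))
  for (v in rev(ord)) {
    kids <- net$child[net$parent == v]
    for (k in kids) cm[v] <- bitwOr(cm[v], cm[k])
  }
  cm
}

# comparable key for a single value (consistent with rpsd_table keys)
.val_key <- function(net, v) {
  p <- attr(net, "wscale")
  if (is.na(p)) v else round(v * 10^p)
}

# indices attaining the maximum of keys; float mode groups near-ties
.argmax_keys <- function(keys, exact, tol = 1e-9) {
  m <- max(keys)
  if (exact) which(keys == m) else which(keys >= m - tol * max(1, abs(m)))
}

#' Check order-theoretic properties of rPSD
#'
#' `check_monotone` verifies rPSD(X) <= rPSD(Y) for all X subsets of Y;
#' `check_subadditive` verifies rPSD(X u Y) <= rPSD(X) + rPSD(Y) for all
#' pairs; `check_submodular` verifies, for all X subsets of Y and every
#' leaf a outside Y, that rPSD(Y + a) - rPSD(Y) <= rPSD(X + a) - rPSD(X).
#' All three hold for rPSD on every phylogenetic network; violations
#' indicate a broken value function (see `fn`).
#'
#' @param net a `phylo_network` with at most 10 leaves (checks are
#'   exhaustive).
#' @param fn optional replacement value function taking a character vector
#'   of labels and returning a number; used to validate the checkers
#'   against deliberately broken diversity measures.
#' @param tol slack added to the right-hand sides to absorb float rounding
#'   (ignored when arc weights are exact decimals and `fn` is `NULL`).
#' @return a data frame of violations (zero rows when the property holds):
#'   columns `X`, `Y` (and `a` for submodularity) holding comma-joined
#'   label sets.
#' @export
check_monotone <- function(net, fn = NULL, tol = 1e-9) {
  v <- .value_keys(net, fn)
  n <- length(net$leaves)
  masks <- 0:(2^n - 1)
  slack <- if (attr(v, "exact")) 0 else tol * max(1, max(abs(v)))
  out <- list()
  for (X in masks) {
    sup <- masks[bitwAnd(masks, X) == X]
    bad <- sup[v[sup + 1] < v[X + 1] - slack]
    for (Y in bad) out[[length(out) + 1L]] <- c(X, Y)
  }
  .violation_df(net, out, c("X", "Y"))
}

#' @rdname check_monotone
#' @export
check_subadditive <- function(net, fn = NULL, tol = 1e-9) {
  v <- .value_keys(net, fn)
  n <- length(net$leaves)
  masks <- 0:(2^n - 1)
  slack <- if (attr(v, "exact")) 0 else tol * max(1, max(abs(v)))
  out <- list()
  for (X in masks) {
    un <- bitwOr(masks, X)
    bad <- masks[v[un + 1] > v[X + 1] + v[masks + 1] + slack]
    for (Y in bad) out[[length(out) + 1L]] <- c(X, Y)
  }
  .violation_df(net, out, c("X", "Y"))
}

#' @rdname check_monotone
#' @export
check_submodular <- function(net, fn = NULL, tol = 1e-9) {
  v <- .value_keys(net, fn)
  n <- length(net$leaves)
  masks <- 0:(2^n - 1)
  bits <- .leaf_bits(n)
  slack <- if (attr(v, "exact")) 0 else tol * max(1, max(abs(v)))
  out <- list()
  for (a in bits) {
    no_a <- masks[bitwAnd(masks, a) == 0L]
    marg <- v[bitwOr(no_a, a) + 1] - v[no_a + 1]
    names(marg) <- no_a
    for (Xi in seq_along(no_a)) {
      X <- no_a[Xi]
      sup <- no_a[bitwAnd(no_a, X) == X]
      bad <- sup[marg[as.character(sup)] > marg[Xi] + slack]
      for (Y in bad) out[[length(out) + 1L]] <- c(X, Y, a)
    }
  }
  .violation_df(net, out, c("X", "Y", "a"))
}

# comparison keys over all masks (integer-scaled when weights are exact
# decimals, so equalities hold exactly): rpsd_table or a user stub
.value_keys <- function(net, fn) {
  n <- length(net$leaves)
  if (n > 10) stop("exhaustive property checks require at most 10 leaves")
  if (is.null(fn)) {
    tab <- rpsd_table(net)
    k <- attr(tab, "key")
    attr(k, "exact") <- attr(tab, "exact")
    return(k)
  }
  masks <- 0:(2^n - 1)
  v <- vapply(masks, function(m) fn(.mask_to_set(net$leaves, m)), numeric(1))
  attr(v, "exact") <- FALSE
  v
}

.violation_df <- function(net, rows, cols) {
  if (length(rows) == 0) {
    df <- as.data.frame(matrix(character(0), ncol = length(cols)))
    names(df) <- cols
    return(df)
  }
  m <- do.call(rbind, rows)
  df <- as.data.frame(matrix("", nrow = nrow(m), ncol = length(cols)),
                      stringsAsFactors = FALSE)
  names(df) <- cols
  for (j in seq_along(cols)) {
    df[[j]] <- vapply(m[, j], function(mask) {
      .set_label(.mask_to_set(net$leaves, mask))
    }, character(1))
  }
  df
}
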