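# ---- weight models -------------------------------------------------------

# draw arc weights: "unit" = all 1; "int" = uniform integers in [wmin,wmax];
# "decimal" = uniform one-decimal values in [wmin, wmax]; "real" = uniform
# reals (comparisons then fall back to a tolerance)
.draw_weights <- function(nw, model, wmin = 1, wmax = 10) {
  switch(model,
    unit = rep(1, nw),
    int = sample(seq(wmin, wmax), nw, replace = TRUE),
    decimal = sample(seq(wmin * 10, wmax * 10), nw, replace = TRUE) / 10,
    real = stats::runif(nw, wmin, wmax),
    stop("unknown weight model: ", model))
}

# ---- random trees --------------------------------------------------------

#' Random weighted phylogenetic networks
#'
#' `random_tree` grows a rooted binary tree by sequential leaf attachment:
#' starting from a root with one leaf, each new leaf subdivides a
#' uniformly chosen arc.  `random_level_k` then inserts reticulation blobs
#' into tree arcs: each blob has a spine of tree nodes below a split node
#' and a chain of k reticulations of in-degree between 2 and d ending in a
#' single exit reticulation, so the resulting network is level-k and
#' semi-d-ary by construction; pendant leaves are then re-attached onto
#' spine nodes to diversify the clusters seen inside blobs.
#' `random_galled_tree` is the level-1 semibinary case.
#'
#' These samplers are convenience generators for testing and scanning;
#' they are deterministic per seed but make no claim of uniformity over
#' their class.
#'
#' @param n number of leaves (labelled `x1..xn`).
#' @param seed integer seed; `NULL` uses the current RNG stream.
#' @param weights weight model: `"unit"`, `"int"`, `"decimal"` or
#'   `"real"`.
#' @param wmin,wmax weight range for the non-unit models.
#' @return a validated `phylo_network`.
#' @export
random_tree <- function(n, seed = NULL, weights = "int", wmin = 1, wmax = 10) {
  stopifnot(n >= 1)
  .with_seed(seed, {
    leaves <- paste0("x", seq_len(n))
    parent <- "r"
    child <- leaves[1]
    nv <- 0L
    for (i in seq_len(n)[-1]) {
      ai <- sample.int(length(parent), 1)
      nv <- nv + 1L
      v <- paste0("v", nv)
      old_child <- child[ai]
      child[ai] <- v
      parent <- c(parent, v, v)
      child <- c(child, old_child, leaves[i])
    }
    phylo_network(parent, child, .draw_weights(length(parent), weights,
                                               wmin, wmax))
  })
}

# insert a blob into arc index ai of (parent, child): a spine a1..ap below
# the arc's tail and a chain of k reticulations with in-degrees drawn from
# 2..d, exiting through the last reticulation into the arc's head.
# Returns list(parent, child, internal) where internal marks the arc keys
# that must not host later blob insertions.
.insert_blob <- function(parent, child, ai, k, d, tag) {
  u <- parent[ai]; v <- child[ai]
  tvec <- vapply(seq_len(k), function(i) sample(2:d, 1), integer(1))
  if (d == 2) tvec <- rep(2L, k)
  p <- max(2L, max(tvec))
  a <- paste0("b", tag, "a", seq_len(p))
  h <- paste0("b", tag, "h", seq_len(k))
  np <- character(0); nc <- character(0)
  add <- function(x, y) { np <<- c(np, x); nc <<- c(nc, y) }
  add(u, a[1])
  for (i in seq_len(p - 1)) add(a[i], a[i + 1])
  for (i in seq_len(k)) {
    need <- tvec[i] - as.integer(i > 1)  # chain supplies one in-arc
    pars <- if (i == k) {
      if (need > 1) c(a[p], sample(a[-p], need - 1)) else a[p]
    } else {
      sample(a, need)
    }
    for (x in pars) add(x, h[i])
    if (i < k) add(h[i], h[i + 1])
  }
  add(h[k], v)
  parent <- c(parent[-ai], np)
  child <- c(child[-ai], nc)
  internal <- paste(np, nc, sep = "\r")
  internal <- internal[np != u & nc != v]  # the two bridges stay available
  list(parent = parent, child = child, internal = internal)
}

# detach a random movable pendant leaf (parent keeps out-degree >= 1) and
# re-attach it below `target`; no-op when no leaf qualifies
.move_leaf_below <- function(parent, child, target) {
  outdeg <- table(parent)
  is_leaf <- !(child %in% parent)
  movable <- which(is_leaf & outdeg[parent] >= 2 & parent != target &
                     child != target)
  if (length(movable) == 0) return(list(parent = parent, child = child))
  ai <- movable[sample.int(length(movable), 1)]
  leaf <- child[ai]
  parent <- c(parent[-ai], target)
  child <- c(child[-ai], leaf)
  list(parent = parent, child = child)
}

#' @rdname random_tree
#' @param k level: number of reticulations in the main blob.
#' @param d maximal reticulation in-degree (arity), `d >= 2`.
#' @param extra_galls number of additional single-reticulation galls to
#'   insert (`NULL` = randomly 0 or 1 when there is room).
#' @export
random_level_k <- function(n, k, d = 2, seed = NULL, weights = "int",
                           wmin = 1, wmax = 10, extra_galls = NULL) {
  k <- as.integer(k); d <- as.integer(d)
  stopifnot(n >= 2, k >= 1, d >= 2)
  .with_seed(seed, {
    for (attempt in 1:5) {
      tr <- random_tree(n, seed = NULL, weights = "unit")
      parent <- tr$parent; child <- tr$child
      forbidden <- character(0)
      n_extra <- if (!is.null(extra_galls)) extra_galls
                 else if (n >= 6) stats::rbinom(1, 1, 0.4) else 0
      blob_ks <- c(k, rep(1L, n_extra))
      for (b in seq_along(blob_ks)) {
        keys <- paste(parent, child, sep = "\r")
        ok <- which(!(keys %in% forbidden))
        if (length(ok) == 0) break
        ai <- ok[sample.int(length(ok), 1)]
        ins <- .insert_blob(parent, child, ai, blob_ks[b], d, tag = b)
        parent <- ins$parent; child <- ins$child
        forbidden <- c(forbidden, ins$internal)
        # pull some pendant leaves onto this blob's spine nodes
        spine <- grep(paste0("^b", b, "a"), unique(parent), value = TRUE)
        for (s in spine) {
          if (stats::runif(1) < 0.5) {
            mv <- .move_leaf_below(parent, child, s)
            parent <- mv$parent; child <- mv$child
          }
        }
      }
      net <- phylo_network(parent, child,
                           .draw_weights(length(parent), weights, wmin, wmax))
      prof <- classify_network(net)
      if (prof$level == k && prof$arity <= d) return(net)
    }
    stop("random_level_k: failed to generate a level-", k, " semi-", d,
         "-ary network after 5 attempts (n=", n, ")")
  })
}

#' @rdname random_tree
#' @export
random_galled_tree <- function(n, seed = NULL, weights = "int", wmin = 1,
                               wmax = 10, extra_galls = NULL) {
  random_level_k(n, k = 1L, d = 2L, seed = seed, weights = weights,
                 wmin = wmin, wmax = wmax, extra_galls = extra_galls)
}

# ---- worked-example fixtures ---------------------------------------------

#' The four-leaf galled-tree worked example
#'
#' A binary galled tree on leaves x1..x4 with one reticulation H (parents
#' p and q) whose 15 nonempty leaf-subset rPSD values are small integers:
#' the singleton values are 5, 6, 5, 4 and the full set scores 14.  The
#' network famously breaks the single-leaf exchange property: for
#' X = \{x1,x3,x4\} and X' = \{x2,x4\}, no single leaf can be moved from X
#' to X' without decreasing the summed rPSD, yet the two-for-one swap
#' (\{x1,x3\}, \{x2\}) restores it.  Its unique optimal pair is
#' \{x2,x4\} and its unique optimal triple is \{x1,x3,x4\}, so optimal
#' sets of consecutive sizes need not nest.
#'
#' The split of weight 1 across the three arcs touching H (0.5, 0.3, 0.2)
#' is not identifiable from the subset values, which only constrain their
#' sum; the values used here are a fixed convention.
#'
#' @return a `phylo_network` on 4 leaves with 9 nodes and 9 arcs.
#' @export
example1_fixture <- function() {
  phylo_network(
    parent = c("r", "r", "s", "s", "p", "q", "p", "q", "H"),
    child  = c("s", "x4", "p", "q", "x1", "x3", "H", "H", "x2"),
    weight = c(1, 4, 2, 2, 2, 2, 0.5, 0.3, 0.2))
}

#' The level-k caterpillar network with a reticulation chain
#'
#' A binary level-k network on leaves y, x1..xk: a caterpillar spine
#' r -> a1 -> ... -> a_{k-1} with a tree node v_i below each a_i (and v_k
#' below a_{k-1}), each v_i carrying leaf x_i and feeding a reticulation
#' H_i; the reticulations form a chain H_1 -> ... -> H_k ending in leaf y,
#' with the root feeding both a1 and H_1.  All k reticulations share one
#' blob, so the level is exactly k and the network is binary.
#'
#' With strictly positive weights, the pair X = \{x1..xk\}, X' = \{y\}
#' admits exactly one rPSD-improving pair in the family S_\{k,2\}: the
#' full swap (X, X') itself, which shows that the bound |A| - |B| <=
#' (d-1)k of the exchange family cannot be lowered.
#'
#' @param k number of reticulations, `k >= 2`.
#' @param weights,wmin,wmax,seed weight model as in [random_tree()]; for
#'   the extremal-pair property all weights must be strictly positive.
#' @return a `phylo_network` on k + 1 leaves.
#' @export
example2_network <- function(k, weights = "unit", wmin = 1, wmax = 10,
                             seed = NULL) {
  k <- as.integer(k)
  if (k < 2) stop("example2_network requires k >= 2")
  .with_seed(seed, {
    a <- paste0("a", seq_len(k - 1))
    v <- paste0("v", seq_len(k))
    h <- paste0("H", seq_len(k))
    x <- paste0("x", seq_len(k))
    parent <- c("r", "r",
                if (k > 2) a[seq_len(k - 2)],
                a[seq_len(k - 1)],
                a[k - 1],
                v,
                v,
                h[seq_len(k - 1)],
                h[k])
    child <- c(a[1], h[1],
               if (k > 2) a[2:(k - 1)],
               v[seq_len(k - 1)],
               v[k],
               x,
               h,
               h[2:k],
               "y")
    wts <- .draw_weights(length(parent), weights, wmin, wmax)
    if (weights == "real") wts <- pmax(wts, 1e-6)
    phylo_network(parent, child, wts)
  })
}
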