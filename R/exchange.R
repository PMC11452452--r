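#' Leaf-subset swap
#'
#' Replaces the subset S of X by the disjoint set T: returns (X \ S) u T.
#'
#' @param X,S,T character vectors of labels, with S a subset of X and T
#'   disjoint from X.
#' @return sorted character vector of size |X| - |S| + |T|.
#' @export
swap_leaves <- function(X, S, T = character(0)) {
  X <- unique(as.character(X)); S <- unique(as.character(S))
  T <- unique(as.character(T))
  if (!all(S %in% X)) stop("S must be a subset of X")
  if (length(intersect(T, X)) > 0) stop("T must be disjoint from X")
  sort(union(setdiff(X, S), T))
}

#' Exchange-pair families
#'
#' Defines the families of candidate swap pairs (A, B) (disjoint, with
#' |B| < |A|) within which an rPSD-improving pair is guaranteed to exist:
#' \describe{
#'   \item{`s0`}{the singleton moves (\{x\}, \{\}); the family behind the
#'     classical strong exchange property of PD on trees.}
#'   \item{`skd`}{the level/arity family for semi-d-ary level-k networks:
#'     for k = 1, `s0` plus all (A, B) with 1 <= |B| < |A| <= d; for
#'     k >= 2, `s0` plus all (A, B) with 1 <= |B| < |A| < dk and
#'     |A| - |B| <= (d-1)k.}
#'   \item{`sd`}{the refined level-1 family: `s0` plus all (A, \{b\}) with
#'     1 < |A| <= d.}
#' }
#'
#' @param kind one of `"s0"`, `"skd"`, `"sd"`.
#' @param k network level (required for `"skd"`, `k >= 1`).
#' @param d reticulation arity (required for `"skd"` and `"sd"`, `d >= 2`).
#' @return an object of class `"swap_family"`.
#' @export
swap_family <- function(kind = c("s0", "skd", "sd"), k = NULL, d = NULL) {
  kind <- match.arg(kind)
  if (kind == "skd") {
    stopifnot(!is.null(k), !is.null(d), k >= 1, d >= 2)
  } else if (kind == "sd") {
    stopifnot(!is.null(d), d >= 2)
    k <- 1L
  } else {
    k <- 0L; d <- 0L
  }
  structure(list(kind = kind, k = as.integer(k), d = as.integer(d)),
            class = "swap_family")
}

#' @export
print.swap_family <- function(x, ...) {
  cat(switch(x$kind,
             s0 = "swap family S_0 (single-leaf moves)\n",
             skd = sprintf("swap family S_{%d,%d}\n", x$k, x$d),
             sd = sprintf("swap family S_%d (level-1 refinement)\n", x$d)))
  invisible(x)
}

# admissible (|A|, |B|) size pairs of a family, ordered by (|A|, |B|);
# always includes the single move (1, 0)
.family_size_pairs <- function(fam) {
  sizes <- list(c(1L, 0L))
  if (fam$kind == "skd" && fam$k == 1L) {
    for (sa in 2:fam$d) for (sb in 1:(sa - 1L))
      sizes[[length(sizes) + 1L]] <- c(sa, sb)
  } else if (fam$kind == "skd") {
    hi <- fam$d * fam$k - 1L
    gap <- (fam$d - 1L) * fam$k
    if (hi >= 2L) {
      for (sa in 2:hi) {
        lo <- max(1L, sa - gap)  # the definition requires |B| >= 1
        for (sb in lo:(sa - 1L))
          sizes[[length(sizes) + 1L]] <- c(sa, sb)
      }
    }
  } else if (fam$kind == "sd") {
    for (sa in 2:fam$d) sizes[[length(sizes) + 1L]] <- c(sa, 1L)
  }
  m <- do.call(rbind, sizes)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

#' Closed-form size of an exchange-pair family
#'
#' The number of pairs in the family over a universe of n labels:
#' |S_0| = n, and for the level/arity families the double sum of
#' choose(n, |A|) * choose(n - |A|, |B|) over the admissible size pairs
#' (the inner index is clamped to |B| >= 1).
#'
#' @param fam a [swap_family()].
#' @param n number of labels.
#' @return an integer count.
#' @export
family_size <- function(fam, n) {
  sp <- .family_size_pairs(fam)
  sum(choose(n, sp[, 1]) * choose(n - sp[, 1], sp[, 2]))
}

#' Enumerate an exchange-pair family
#'
#' Yields every pair (A, B) of the family over the given labels exactly
#' once, ordered by (|A|, |B|, lexicographic on the sorted labels of A,
#' then of B).
#'
#' @param fam a [swap_family()].
#' @param labels character vector of labels.
#' @return a list of `list(A = , B = )` pairs.
#' @export
enumerate_family <- function(fam, labels) {
  labels <- sort(unique(as.character(labels)))
  sp <- .family_size_pairs(fam)
  out <- vector("list", family_size(fam, length(labels)))
  i <- 0L
  for (r in seq_len(nrow(sp))) {
    sa <- sp[r, 1]; sb <- sp[r, 2]
    if (sa > length(labels)) next
    As <- utils::combn(labels, sa, simplify = FALSE)
    for (A in As) {
      rest <- setdiff(labels, A)
      if (sb == 0L) {
        i <- i + 1L
        out[[i]] <- list(A = A, B = character(0))
      } else if (sb <= length(rest)) {
        for (B in utils::combn(rest, sb, simplify = FALSE)) {
          i <- i + 1L
          out[[i]] <- list(A = A, B = B)
        }
      }
    }
  }
  out[seq_len(i)]
}

#' Is a swap pair rPSD-improving for X, X'?
#'
#' A pair (A, B) with A in X \ X', B in X' \ X and |B| < |A| is improving
#' when rPSD(X) + rPSD(X') <= rPSD((X\A) u B) + rPSD((X'\B) u A).  The
#' inequality is non-strict, so the full swap (X \ X', X' \ X) of two sets
#' is always improving.
#'
#' @param net a `phylo_network`.
#' @param X,Xp leaf sets with |Xp| < |X|.
#' @param A,B the candidate pair.
#' @return `TRUE` or `FALSE`.
#' @export
is_improving <- function(net, X, Xp, A, B = character(0)) {
  X <- .check_leafset(net, X); Xp <- .check_leafset(net, Xp)
  A <- unique(as.character(A)); B <- unique(as.character(B))
  if (length(Xp) >= length(X)) stop("|X'| must be smaller than |X|")
  if (!all(A %in% setdiff(X, Xp))) stop("A must be a subset of X \\ X'")
  if (!all(B %in% setdiff(Xp, X))) stop("B must be a subset of X' \\ X")
  if (length(B) >= length(A)) stop("pair must have |B| < |A|")
  lhs <- .val_key(net, rpsd(net, X)) + .val_key(net, rpsd(net, Xp))
  rhs <- .val_key(net, rpsd(net, swap_leaves(X, A, B))) +
    .val_key(net, rpsd(net, swap_leaves(Xp, B, A)))
  tol <- if (is.na(attr(net, "wscale"))) 1e-9 * max(1, abs(lhs)) else 0
  lhs <= rhs + tol
}

#' Search for rPSD-improving pairs within a family
#'
#' Scans the pairs (A, B) of the family restricted to A in X \ X' and
#' B in X' \ X, in deterministic (|A|, |B|, lexicographic) order, and
#' returns the first improving pair or all of them.
#'
#' @param net a `phylo_network`.
#' @param X,Xp leaf sets with |Xp| < |X|.
#' @param fam a [swap_family()].
#' @param mode `"first"` or `"all"`.
#' @param values optional precomputed [rpsd_table()] for `net`.
#' @return `NULL` when no improving pair exists in the family; otherwise a
#'   `list(A =, B =)` (mode `"first"`) or a list of such pairs (`"all"`).
#' @export
find_improving_pair <- function(net, X, Xp, fam, mode = c("first", "all"),
                                values = NULL) {
  mode <- match.arg(mode)
  X <- .check_leafset(net, X); Xp <- .check_leafset(net, Xp)
  if (length(Xp) >= length(X)) stop("|X'| must be smaller than |X|")
  leaves <- net$leaves
  if (is.null(values)) values <- rpsd_table(net)
  kv <- attr(values, "key")
  exact <- attr(values, "exact")
  tol <- if (exact) 0 else 1e-9 * max(1, max(abs(kv)))
  Xm <- .mask_of(leaves, X); Xpm <- .mask_of(leaves, Xp)
  base <- kv[Xm + 1] + kv[Xpm + 1]
  Apool <- sort(setdiff(X, Xp)); Bpool <- sort(setdiff(Xp, X))
  sp <- .family_size_pairs(fam)
  hits <- list()
  for (r in seq_len(nrow(sp))) {
    sa <- sp[r, 1]; sb <- sp[r, 2]
    if (sa > length(Apool) || sb > length(Bpool)) next
    for (A in utils::combn(Apool, sa, simplify = FALSE)) {
      Am <- .mask_of(leaves, A)
      Bs <- if (sb == 0L) list(character(0))
            else utils::combn(Bpool, sb, simplify = FALSE)
      for (B in Bs) {
        Bm <- .mask_of(leaves, B)
        rhs <- kv[Xm - Am + Bm + 1] + kv[Xpm - Bm + Am + 1]
        if (rhs >= base - tol) {
          pair <- list(A = A, B = B)
          if (mode == "first") return(pair)
          hits[[length(hits) + 1L]] <- pair
        }
      }
    }
  }
  if (length(hits) == 0) NULL else hits
}

#' Verify the exchange property of rPSD over a family
#'
#' Iterates over pairs of leaf sets X, X' with |X'| < |X| (exhaustively,
#' or a seeded random sample) and reports the first pair admitting no
#' improving swap in the family.  On a semi-d-ary level-k network the
#' family S_{k,d} is guaranteed to contain an improving pair for every
#' X, X', so a non-`NULL` result there is a genuine counterexample.
#'
#' @param net a `phylo_network` (at most 10 leaves in exhaustive scope).
#' @param fam a [swap_family()].
#' @param scope `"exhaustive"`, or a `list(n_pairs =, seed =)` for a
#'   random sample of (X, X') pairs.
#' @return `NULL`, or `list(X =, Xp =)` for the first uncovered pair.
#' @export
verify_exchange_property <- function(net, fam, scope = "exhaustive") {
  leaves <- net$leaves
  n <- length(leaves)
  values <- rpsd_table(net)
  kv <- attr(values, "key")
  exact <- attr(values, "exact")
  tol <- if (exact) 0 else 1e-9 * max(1, max(abs(kv)))
  by_size <- .masks_by_size(n)
  pc <- .popcounts(n)
  pairs <- NULL
  if (identical(scope, "exhaustive")) {
    if (n > 10) stop("exhaustive scope requires at most 10 leaves")
    masks <- 0:(2^n - 1)
    Xs <- rep(masks, times = 2^n)
    Xps <- rep(masks, each = 2^n)
    keep <- pc[Xps + 1] < pc[Xs + 1]
    pairs <- cbind(Xs[keep], Xps[keep])
  } else {
    stopifnot(is.list(scope))
    pairs <- .with_seed(scope$seed, {
      m <- matrix(0L, nrow = scope$n_pairs, ncol = 2)
      i <- 0L
      while (i < scope$n_pairs) {
        a <- sample.int(2^n, 1) - 1L
        b <- sample.int(2^n, 1) - 1L
        if (pc[a + 1] == pc[b + 1]) next
        i <- i + 1L
        m[i, ] <- if (pc[a + 1] > pc[b + 1]) c(a, b) else c(b, a)
      }
      m
    })
  }
  sp <- .family_size_pairs(fam)
  for (row in seq_len(nrow(pairs))) {
    Xm <- pairs[row, 1]; Xpm <- pairs[row, 2]
    if (!.has_improving_mask(kv, tol, Xm, Xpm, sp, by_size))
      return(list(X = .mask_to_set(leaves, Xm), Xp = .mask_to_set(leaves, Xpm)))
  }
  NULL
}

# fast existence test for an improving pair, on bitmasks
.has_improving_mask <- function(kv, tol, Xm, Xpm, sp, by_size) {
  base <- kv[Xm + 1] + kv[Xpm + 1]
  Apool <- Xm - bitwAnd(Xm, Xpm)
  Bpool <- Xpm - bitwAnd(Xm, Xpm)
  for (r in seq_len(nrow(sp))) {
    sa <- sp[r, 1]; sb <- sp[r, 2]
    As <- .subsets_of(Apool, sa, by_size)
    if (length(As) == 0) next
    Bs <- if (sb == 0L) 0L else .subsets_of(Bpool, sb, by_size)
    if (length(Bs) == 0) next
    for (Am in As) {
      rhs <- kv[Xm - Am + Bs + 1] + kv[Xpm - Bs + Am + 1]
      if (any(rhs >= base - tol)) return(TRUE)
    }
  }
  FALSE
}

#' Locate a blob witnessing a level-1 improving pair
#'
#' On a semi-d-ary level-1 network, every improving pair of the form
#' (A, \{b\}) with |A| >= 2 is explained by a blob: there is a blob with
#' exit reticulation H and split node v such that X and the cluster of H
#' are disjoint, b lies in the cluster of H, and A lies in the cluster of
#' v.  This function returns such a witness, or `NULL` when no blob
#' qualifies (trees have no blobs and always return `NULL`).
#'
#' @param net a `phylo_network` of level at most 1.
#' @param X,Xp the leaf sets of the improving pair's context.
#' @param pair a `list(A =, B =)` with `B` a single label.
#' @return `NULL`, or `list(blob =, H =, split_node =)`.
#' @export
corollary1_witness <- function(net, X, Xp, pair) {
  if (network_level(net) > 1L)
    stop("corollary1_witness requires a level-<=1 network")
  X <- .check_leafset(net, X)
  A <- sort(unique(as.character(pair$A)))
  b <- as.character(pair$B)
  stopifnot(length(b) == 1)
  for (blob in network_blobs(net)) {
    cv <- node_cluster(net, blob$split_node)
    for (H in blob$exit_reticulations) {
      ch <- node_cluster(net, H)
      if (length(intersect(X, ch)) == 0 && b %in% ch && all(A %in% cv))
        return(list(blob = blob, H = H, split_node = blob$split_node))
    }
  }
  NULL
}
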