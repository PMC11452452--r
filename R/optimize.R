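# ---- value scorers -------------------------------------------------------

# A scorer evaluates rPSD on subsets encoded as bitmasks.  For small n it
# precomputes the full 2^n table; otherwise it scores per query from the
# per-arc cluster masks, memoizing results.  Keys are exactly comparable
# (integer-scaled) when all weights are short decimal literals.
.make_scorer <- function(net, values = NULL) {
  n <- length(net$leaves)
  p <- attr(net, "wscale")
  exact <- !is.na(p)
  scale <- if (exact) 10^p else 1
  if (is.null(values) && n <= 14) values <- rpsd_table(net)
  if (!is.null(values)) {
    kv <- attr(values, "key")
    return(list(key = function(masks) kv[masks + 1],
                exact = exact, scale = scale, n = n))
  }
  if (n > 30) stop("subset optimization supports at most 30 leaves")
  clmvec <- .cluster_masks(net)[net$child]
  w <- if (exact) round(net$weight * scale) else net$weight
  memo <- new.env(parent = emptyenv())
  key1 <- function(m) {
    k <- as.character(m)
    got <- memo[[k]]
    if (!is.null(got)) return(got)
    memo[[k]] <- sum(w[bitwAnd(clmvec, m) != 0L])
  }
  list(key = function(masks) vapply(masks, key1, numeric(1)),
       exact = exact, scale = scale, n = n)
}

# argmax over candidate masks under a scorer; returns list(masks, value)
.best_masks <- function(scorer, cand) {
  cand <- unique(cand)
  keys <- scorer$key(cand)
  idx <- .argmax_keys(keys, scorer$exact)
  list(masks = sort(cand[idx]), value = max(keys) / scorer$scale)
}

.opt_family <- function(net, m, masks, value) {
  structure(list(m = m, value = value,
                 sets = lapply(masks, function(mk) .mask_to_set(net$leaves, mk))),
            class = "opt_family")
}

#' @export
print.opt_family <- function(x, ...) {
  cat(sprintf("Opt_%d: value %g, %d set(s)\n", x$m, x$value, length(x$sets)))
  for (s in x$sets[seq_len(min(10, length(x$sets)))])
    cat("  {", paste(s, collapse = ","), "}\n", sep = "")
  if (length(x$sets) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
print.opt_sequence <- function(x, ...) {
  cat(sprintf("optimal sequence (%s):\n", attr(x, "method")))
  for (f in x) cat(sprintf("  m=%d value=%g sets=%d\n",
                           f$m, f$value, length(f$sets)))
  invisible(x)
}

# ---- brute force ---------------------------------------------------------

#' All rPSD-optimal leaf subsets of a given size, by enumeration
#'
#' Enumerates every subset of cardinality m, scores it, and returns the
#' exact maximum together with all argmax sets.  This is the oracle against
#' which the greedy algorithms are verified.
#'
#' @param net a `phylo_network` with at most 20 leaves.
#' @param m subset cardinality, between 0 and the number of leaves.
#' @param values optional precomputed [rpsd_table()].
#' @return an object of class `"opt_family"`: `list(m, value, sets)`.
#' @export
brute_force_opt <- function(net, m, values = NULL) {
  n <- length(net$leaves)
  if (n > 20) stop("brute force supports at most 20 leaves (got ", n, ")")
  if (m < 0 || m > n) stop("m must be between 0 and ", n)
  scorer <- .make_scorer(net, values)
  cand <- .masks_by_size(n)[[as.character(m)]]
  best <- .best_masks(scorer, cand)
  .opt_family(net, m, best$masks, best$value)
}

# ---- tau expansion / contraction -----------------------------------------

# candidate masks of tau_{B,A}(X) with (A,B) in fam, B in X, A outside X,
# |A| - |B| = j  (expand = TRUE), or of tau_{A,B}(X) with A in X, B outside,
# |A| - |B| = j (expand = FALSE)
.tau_candidate_masks <- function(Xm, j, fam, n, by_size, expand = TRUE) {
  full <- as.integer(2^n - 1)
  comp <- full - Xm
  sp <- .family_size_pairs(fam)
  sp <- sp[sp[, 1] - sp[, 2] == j, , drop = FALSE]
  out <- integer(0)
  for (r in seq_len(nrow(sp))) {
    sa <- sp[r, 1]; sb <- sp[r, 2]
    if (expand) {
      As <- .subsets_of(comp, sa, by_size)
      Bs <- if (sb == 0L) 0L else .subsets_of(Xm, sb, by_size)
    } else {
      As <- .subsets_of(Xm, sa, by_size)
      Bs <- if (sb == 0L) 0L else .subsets_of(comp, sb, by_size)
    }
    if (length(As) == 0 || length(Bs) == 0) next
    for (B in Bs) {
      out <- c(out, if (expand) Xm - B + As else Xm - As + B)
    }
  }
  unique(out)
}

#' Optimal tau-expansions and contractions of a leaf set
#'
#' `opt_tau_expand` forms every set of cardinality |X| + j obtained as
#' tau_{B,A}(X) = (X \ B) u A with (A, B) drawn from the family, B inside
#' X, A outside, |A| - |B| = j, and returns those of maximal rPSD.
#' `opt_tau_contract` is the mirror operation producing sets of
#' cardinality |X| - j.
#'
#' @param net a `phylo_network`.
#' @param X a leaf set.
#' @param j the cardinality step, `j >= 1`.
#' @param fam a [swap_family()].
#' @param values optional precomputed [rpsd_table()].
#' @return a list with components `sets` (list of optimal leaf sets) and
#'   `value` (their common rPSD).
#' @export
opt_tau_expand <- function(net, X, j, fam, values = NULL) {
  .opt_tau(net, X, j, fam, values, expand = TRUE)
}

#' @rdname opt_tau_expand
#' @export
opt_tau_contract <- function(net, X, j, fam, values = NULL) {
  .opt_tau(net, X, j, fam, values, expand = FALSE)
}

.opt_tau <- function(net, X, j, fam, values, expand) {
  X <- .check_leafset(net, X)
  n <- length(net$leaves)
  scorer <- .make_scorer(net, values)
  by_size <- .masks_by_size(n)
  Xm <- .mask_of(net$leaves, X)
  cand <- .tau_candidate_masks(Xm, j, fam, n, by_size, expand)
  if (length(cand) == 0)
    stop("no candidate ", if (expand) "expansion" else "contraction",
         " of step ", j, " exists in this family")
  best <- .best_masks(scorer, cand)
  list(sets = lapply(best$masks, function(mk) .mask_to_set(net$leaves, mk)),
       value = best$value)
}

# ---- greedy algorithms ---------------------------------------------------

.opt_sequence <- function(families, method, mode = "full") {
  structure(families, method = method, mode = mode, class = "opt_sequence")
}

# shared greedy driver: per step m, candidate masks are generated from the
# previous families by the supplied function(m, fams_masks) -> masks
.greedy_drive <- function(net, step_fun, method, max_sets = 10000) {
  n <- length(net$leaves)
  scorer <- .make_scorer(net)
  fam_masks <- vector("list", n + 1)
  fam_masks[[1]] <- 0L
  families <- vector("list", n + 1)
  families[[1]] <- .opt_family(net, 0L, 0L, 0)
  for (m in seq_len(n)) {
    cand <- step_fun(m, fam_masks, scorer)
    best <- .best_masks(scorer, cand)
    if (length(best$masks) > max_sets)
      stop("optimal family at m=", m, " exceeds max_sets=", max_sets)
    fam_masks[[m + 1]] <- best$masks
    families[[m + 1]] <- .opt_family(net, m, best$masks, best$value)
  }
  .opt_sequence(families, method)
}

#' Greedy rPSD optimization on phylogenetic trees
#'
#' Builds the families of PD-optimal sets of every cardinality by the
#' classical single-leaf greedy: each optimal family of size m is the
#' argmax over all sets obtained by adding one leaf to an optimal set of
#' size m - 1.  Exact on trees by the strong exchange property.
#'
#' @param net a `phylo_network` of level 0.
#' @param max_sets guard on the size of any optimal family.
#' @return an object of class `"opt_sequence"`: families for m = 0..n.
#' @export
greedy_tree <- function(net, max_sets = 10000) {
  if (network_level(net) != 0L) stop("greedy_tree requires a tree")
  n <- length(net$leaves)
  bits <- .leaf_bits(n)
  step <- function(m, fams, scorer) {
    prev <- fams[[m]]
    unique(unlist(lapply(prev, function(Y) {
      free <- bits[bitwAnd(Y, bits) == 0L]
      Y + free
    })))
  }
  .greedy_drive(net, step, "greedy_tree", max_sets)
}

#' Greedy rPSD optimization on galled trees
#'
#' On a galled tree (semibinary level-1 network) every rPSD-optimal set of
#' size m arises from an rPSD-optimal set of size m - 1 by optimally
#' adding one leaf or optimally replacing one leaf by two.  In full mode
#' the complete optimal families are propagated, which reproduces the
#' brute-force optima exactly.  In representative mode a single optimal
#' set per cardinality is tracked (sound on galled trees, where any
#' optimal tau-expansion of any optimal set is again optimal).
#'
#' @param net a galled tree (`classify_network(net)$is_galled_tree`).
#' @param mode `"full"` (all optimal sets) or `"representative"` (one
#'   optimal set per cardinality).
#' @param max_sets guard on the size of any optimal family.
#' @return an `"opt_sequence"`; in representative mode every family holds
#'   one set.
#' @export
greedy_galled <- function(net, mode = c("full", "representative"),
                          max_sets = 10000) {
  mode <- match.arg(mode)
  prof <- classify_network(net)
  if (!prof$is_galled_tree)
    stop("greedy_galled requires a galled tree (semibinary, level <= 1)")
  n <- length(net$leaves)
  by_size <- .masks_by_size(n)
  fam <- swap_family("skd", k = 1, d = 2)
  step <- function(m, fams, scorer) {
    prev <- fams[[m]]
    if (mode == "representative") prev <- prev[1]
    cand <- unlist(lapply(prev, function(Y) {
      .tau_candidate_masks(Y, 1L, fam, n, by_size, expand = TRUE)
    }))
    unique(cand)
  }
  seq <- .greedy_drive(net, step, "greedy_galled", max_sets)
  if (mode == "representative") {
    seq <- .opt_sequence(lapply(seq, function(f) {
      f$sets <- f$sets[1]
      f
    }), "greedy_galled", "representative")
  }
  seq
}

#' Greedy rPSD optimization on semibinary level-2 and semi-3-ary level-1
#' networks
#'
#' Every rPSD-optimal set of size m on these networks arises from an
#' optimal set of size m - 1 by optimally adding a leaf, replacing one
#' leaf by two, or replacing two leaves by three, or from an optimal set
#' of size m - 2 by replacing one leaf by three.  The two-for-three pool
#' is skipped on semi-3-ary level-1 networks, where the refined level-1
#' exchange family makes it redundant.  Full optimal families are
#' propagated at every step.
#'
#' @param net a semibinary network of level at most 2, or a semi-3-ary
#'   network of level at most 1.
#' @param max_sets guard on the size of any optimal family.
#' @return an `"opt_sequence"` with the exact optimal families.
#' @export
greedy_level2 <- function(net, max_sets = 10000) {
  prof <- classify_network(net)
  ok <- (prof$is_semibinary && prof$level <= 2L) ||
    (prof$arity <= 3L && prof$level <= 1L)
  if (!ok)
    stop("greedy_level2 requires a semibinary level-<=2 or semi-3-ary ",
         "level-<=1 network")
  skip_two_for_three <- prof$level <= 1L
  n <- length(net$leaves)
  by_size <- .masks_by_size(n)
  full <- as.integer(2^n - 1)
  size_moves <- list(c(1L, 0L), c(2L, 1L))
  if (!skip_two_for_three) size_moves <- c(size_moves, list(c(3L, 2L)))
  step <- function(m, fams, scorer) {
    cand <- integer(0)
    for (Y in fams[[m]]) {  # from Opt_{m-1}: one-step moves
      comp <- full - Y
      for (sz in size_moves) {
        As <- .subsets_of(comp, sz[1], by_size)
        Bs <- if (sz[2] == 0L) 0L else .subsets_of(Y, sz[2], by_size)
        if (length(As) == 0 || length(Bs) == 0) next
        for (B in Bs) cand <- c(cand, Y - B + As)
      }
    }
    if (m >= 2) {
      for (Y in fams[[m - 1]]) {  # from Opt_{m-2}: one leaf -> three leaves
        comp <- full - Y
        As <- .subsets_of(comp, 3L, by_size)
        Bs <- .subsets_of(Y, 1L, by_size)
        for (B in Bs) cand <- c(cand, Y - B + As)
      }
    }
    unique(cand)
  }
  .greedy_drive(net, step, "greedy_level2", max_sets)
}

#' Compute rPSD-optimal subsets with automatic algorithm routing
#'
#' Routes to the exact greedy algorithm for the network's class (trees,
#' galled trees, semibinary level-2 / semi-3-ary level-1) or falls back to
#' brute-force enumeration with a warning: on general networks the
#' optimization problem is NP-hard and no greedy algorithm is known.
#'
#' @param net a `phylo_network`.
#' @param m a single cardinality, or `"all"` for the full sequence.
#' @param method `"auto"`, `"brute"`, or `"greedy"` (errors when no greedy
#'   algorithm covers the network's class).
#' @param max_sets guard on the size of any optimal family.
#' @return an `"opt_family"` (single m) or an `"opt_sequence"` (`"all"`).
#' @export
optimize_rpsd <- function(net, m = "all", method = c("auto", "brute", "greedy"),
                          max_sets = 10000) {
  method <- match.arg(method)
  prof <- classify_network(net)
  n <- length(net$leaves)
  greedy_fn <- if (prof$is_tree) greedy_tree
    else if (prof$is_galled_tree) greedy_galled
    else if ((prof$is_semibinary && prof$level <= 2L) ||
             (prof$arity <= 3L && prof$level <= 1L)) greedy_level2
    else NULL
  use_greedy <- switch(method,
    auto = !is.null(greedy_fn),
    brute = FALSE,
    greedy = {
      if (is.null(greedy_fn))
        stop("no exact greedy algorithm is known for this network class")
      TRUE
    })
  if (!use_greedy && method == "auto")
    warning("no exact greedy algorithm is known for this class ",
            "(level ", prof$level, ", arity ", prof$arity, "); ",
            "falling back to brute force (the problem is NP-hard in general)")
  if (use_greedy) {
    seq <- greedy_fn(net, max_sets = max_sets)
    if (identical(m, "all")) return(seq)
    return(seq[[m + 1]])
  }
  values <- if (n <= 14) rpsd_table(net) else NULL
  if (identical(m, "all")) {
    fams <- lapply(0:n, function(mm) brute_force_opt(net, mm, values))
    return(.opt_sequence(fams, "brute_force"))
  }
  brute_force_opt(net, m, values)
}

#' One step of the improving-pair chain between two optimal sets
#'
#' Given a full optimal sequence Y and indices q < p, finds the smallest
#' step j (up to (d-1)k for the family) for which Y_p, Y_q admit an
#' improving pair (A, B) with |A| - |B| = j, returning the first such pair
#' in deterministic order.  The exchange property guarantees existence
#' when the family matches the network's class; `NULL` is returned
#' otherwise as a counterexample certificate.
#'
#' @param net a `phylo_network`.
#' @param Y an `"opt_sequence"` (full mode).
#' @param p,q cardinalities with `0 <= q < p`.
#' @param fam a [swap_family()].
#' @param values optional precomputed [rpsd_table()].
#' @return `list(j =, pair = list(A =, B =))` or `NULL`.
#' @export
chain_step <- function(net, Y, p, q, fam, values = NULL) {
  stopifnot(q >= 0, q < p, p <= length(net$leaves))
  if (is.null(values)) values <- rpsd_table(net)
  Yp <- Y[[p + 1]]$sets[[1]]
  Yq <- Y[[q + 1]]$sets[[1]]
  sp <- .family_size_pairs(fam)
  maxj <- max(sp[, 1] - sp[, 2])
  for (j in seq_len(maxj)) {
    hit <- .find_improving_j(net, Yp, Yq, fam, j, values)
    if (!is.null(hit)) return(list(j = j, pair = hit))
  }
  NULL
}

# first improving pair with |A| - |B| = j, deterministic order
.find_improving_j <- function(net, X, Xp, fam, j, values) {
  leaves <- net$leaves
  kv <- attr(values, "key")
  exact <- attr(values, "exact")
  tol <- if (exact) 0 else 1e-9 * max(1, max(abs(kv)))
  Xm <- .mask_of(leaves, X); Xpm <- .mask_of(leaves, Xp)
  base <- kv[Xm + 1] + kv[Xpm + 1]
  Apool <- sort(setdiff(X, Xp)); Bpool <- sort(setdiff(Xp, X))
  sp <- .family_size_pairs(fam)
  sp <- sp[sp[, 1] - sp[, 2] == j, , drop = FALSE]
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
        if (rhs >= base - tol) return(list(A = A, B = B))
      }
    }
  }
  NULL
}
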