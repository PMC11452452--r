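#' Empirical scan for failures of the greedy containment
#'
#' For network classes one step beyond those with a proven greedy
#' algorithm (semibinary level-3, semi-4-ary level-1, and further), it is
#' open whether every rPSD-optimal family Opt_m is contained in the union
#' of optimal tau-expansions of the earlier families,
#' Opt_m in U_{j=1..J} Opt-tau_{k,d,j}(Opt_{m-j}).
#' This harness tests the containment by brute force on a given network:
#' every Opt_m is recomputed by enumeration (never by the greedy under
#' test), each expansion family is enumerated in full, and any member of
#' Opt_m escaping the union is reported as a counterexample certificate.
#'
#' @param net a `phylo_network` with at most 12 leaves.
#' @param J maximal expansion step to include in the union.
#' @param k,d level and arity defining the family S_{k,d}; default to the
#'   network's own profile (level at least 1, arity at least 2).
#' @return an object of class `"gap_scan_report"`: a list with `k`, `d`,
#'   `J`, `per_m` (data frame with columns `m`, `n_opt`, `ok`) and
#'   `counterexamples` (list of `list(m =, set =)`; empty when the
#'   containment holds everywhere).
#' @export
gap_scan <- function(net, J = 3, k = NULL, d = NULL) {
  n <- length(net$leaves)
  if (n > 12) stop("gap_scan brute force supports at most 12 leaves")
  prof <- classify_network(net)
  if (is.null(k)) k <- max(prof$level, 1L)
  if (is.null(d)) d <- max(prof$arity, 2L)
  fam <- swap_family("skd", k = k, d = d)
  values <- rpsd_table(net)
  scorer <- .make_scorer(net, values)
  by_size <- .masks_by_size(n)
  opt_masks <- vector("list", n + 1)
  opt_masks[[1]] <- 0L
  for (m in seq_len(n)) {
    best <- .best_masks(scorer, by_size[[as.character(m)]])
    opt_masks[[m + 1]] <- best$masks
  }
  per_m <- data.frame(m = seq_len(n), n_opt = NA_integer_, ok = NA)
  counterexamples <- list()
  for (m in seq_len(n)) {
    reachable <- integer(0)
    for (j in seq_len(min(J, m))) {
      for (Y in opt_masks[[m - j + 1]]) {
        cand <- .tau_candidate_masks(Y, j, fam, n, by_size, expand = TRUE)
        if (length(cand) == 0) next
        reachable <- c(reachable, .best_masks(scorer, cand)$masks)
      }
    }
    reachable <- unique(reachable)
    missing <- setdiff(opt_masks[[m + 1]], reachable)
    per_m$n_opt[m] <- length(opt_masks[[m + 1]])
    per_m$ok[m] <- length(missing) == 0
    for (mk in missing) {
      counterexamples[[length(counterexamples) + 1L]] <-
        list(m = m, set = .mask_to_set(net$leaves, mk))
    }
  }
  structure(list(k = k, d = d, J = J, per_m = per_m,
                 counterexamples = counterexamples,
                 network = net),
            class = "gap_scan_report")
}

#' @export
print.gap_scan_report <- function(x, ...) {
  cat(sprintf("gap scan (family S_{%d,%d}, J = %d):\n", x$k, x$d, x$J))
  if (length(x$counterexamples) == 0) {
    cat("  containment holds for every m\n")
  } else {
    for (ce in x$counterexamples)
      cat(sprintf("  VIOLATION at m=%d: {%s}\n", ce$m,
                  paste(ce$set, collapse = ",")))
  }
  invisible(x)
}

#' Gap scan over a sample of random networks
#'
#' Generates `reps` seeded random networks of the requested class and runs
#' [gap_scan()] on each, collecting any counterexample certificates.
#'
#' @param class one of `"galled"`, `"level2-semibinary"`,
#'   `"level3-semibinary"`, `"level1-semi3ary"`, `"level1-semi4ary"`.
#' @param n_leaves leaves per network.
#' @param reps number of networks.
#' @param seed base seed; network i uses seed `seed + i`.
#' @param J maximal expansion step.
#' @return a list with `n_scanned`, `violations` (list of
#'   `list(seed =, report =)`), and `class`.
#' @export
gap_scan_sample <- function(class = c("galled", "level2-semibinary",
                                      "level3-semibinary", "level1-semi3ary",
                                      "level1-semi4ary"),
                            n_leaves = 8, reps = 200, seed = 1, J = 3) {
  class <- match.arg(class)
  par <- switch(class,
    "galled" = c(k = 1, d = 2),
    "level2-semibinary" = c(k = 2, d = 2),
    "level3-semibinary" = c(k = 3, d = 2),
    "level1-semi3ary" = c(k = 1, d = 3),
    "level1-semi4ary" = c(k = 1, d = 4))
  violations <- list()
  for (i in seq_len(reps)) {
    net <- random_level_k(n_leaves, k = par["k"], d = par["d"],
                          seed = seed + i)
    rep_i <- gap_scan(net, J = J, k = par[["k"]], d = par[["d"]])
    if (length(rep_i$counterexamples) > 0)
      violations[[length(violations) + 1L]] <-
        list(seed = seed + i, report = rep_i)
  }
  list(class = class, n_scanned = reps, violations = violations)
}
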