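# Independent rPSD oracle: reachability by boolean matrix closure, no code
# shared with the package's reverse-search implementation.
oracle_rpsd <- function(net, X) {
  nodes <- net$nodes
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_along(net$parent)) A[net$parent[i], net$child[i]] <- TRUE
  R <- diag(n) > 0
  dimnames(R) <- dimnames(A)
  repeat {
    R2 <- R | ((R %*% A) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  if (length(X) == 0) return(0)
  keep <- vapply(seq_along(net$parent),
                 function(i) any(R[net$child[i], X, drop = FALSE]),
                 logical(1))
  sum(net$weight[keep])
}

# Brute-force biconnectivity: two distinct edges share a biconnected
# component iff no single vertex removal separates their (surviving)
# endpoints.  Returns the edge partition as a vector of component ids.
oracle_bicomp <- function(net) {
  m <- length(net$parent)
  ends <- cbind(net$parent, net$child)
  nodes <- net$nodes
  adj <- lapply(nodes, function(v) {
    unique(c(net$child[net$parent == v], net$parent[net$child == v]))
  })
  names(adj) <- nodes
  connected_without <- function(v, a, b) {
    if (a == b) return(TRUE)
    seen <- a
    stack <- a
    while (length(stack)) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      for (y in adj[[x]]) {
        if (y == v || y %in% seen) next
        if (y == b) return(TRUE)
        seen <- c(seen, y)
        stack <- c(stack, y)
      }
    }
    FALSE
  }
  same <- function(i, j) {
    for (v in nodes) {
      ei <- setdiff(ends[i, ], v)
      ej <- setdiff(ends[j, ], v)
      if (length(ei) == 0 || length(ej) == 0) next
      if (!connected_without(v, ei[1], ej[1])) return(FALSE)
    }
    TRUE
  }
  comp <- seq_len(m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      if (comp[i] != comp[j] && same(i, j)) {
        comp[comp == comp[j]] <- comp[i]
      }
    }
  }
  comp
}

# canonical text key of an optimal family's sets, for equality assertions
fam_key <- function(f) {
  sort(vapply(f$sets, function(s) paste(sort(s), collapse = ","), character(1)))
}

# canonical key of a list of leaf sets
sets_key <- function(sets) {
  sort(vapply(sets, function(s) paste(sort(s), collapse = ","), character(1)))
}

# all 15 printed subset values of the worked four-leaf example
example1_table <- function() {
  list(
    list(X = "x1", v = 5), list(X = "x2", v = 6), list(X = "x3", v = 5),
    list(X = "x4", v = 4),
    list(X = c("x1", "x2"), v = 8), list(X = c("x1", "x3"), v = 9),
    list(X = c("x1", "x4"), v = 9), list(X = c("x2", "x3"), v = 8),
    list(X = c("x2", "x4"), v = 10), list(X = c("x3", "x4"), v = 9),
    list(X = c("x1", "x2", "x3"), v = 10),
    list(X = c("x1", "x2", "x4"), v = 12),
    list(X = c("x1", "x3", "x4"), v = 13),
    list(X = c("x2", "x3", "x4"), v = 12),
    list(X = c("x1", "x2", "x3", "x4"), v = 14))
}
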