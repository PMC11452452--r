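# Bitmask machinery over leaf sets.  Leaves are indexed by their position in
# the sorted label vector net$leaves; a subset is the integer whose bit i-1
# is set when leaf i belongs to it.  Limited to n <= 30 leaves.

.leaf_bits <- function(n) as.integer(2^(seq_len(n) - 1))

.mask_of <- function(leaves, X) {
  idx <- match(X, leaves)
  if (anyNA(idx)) stop("unknown leaf label(s): ",
                       paste(X[is.na(idx)], collapse = ", "))
  if (length(idx) == 0) return(0L)
  as.integer(sum(2^(idx - 1)))
}

.mask_to_set <- function(leaves, mask) {
  if (mask == 0) return(character(0))
  bits <- .leaf_bits(length(leaves))
  leaves[bitwAnd(mask, bits) > 0L]
}

# popcount of every mask in 0..2^n-1
.popcounts <- function(n) {
  masks <- 0:(2^n - 1)
  pc <- integer(2^n)
  for (b in .leaf_bits(n)) pc <- pc + (bitwAnd(masks, b) > 0L)
  pc
}

# masks grouped by popcount: element s+1 holds all masks of size s
.masks_by_size <- function(n) {
  pc <- .popcounts(n)
  split(0:(2^n - 1), pc)
}

# all subsets of pool (a mask) of cardinality s, as an integer vector,
# given the by-size grouping for the full universe
.subsets_of <- function(pool, s, by_size) {
  cand <- by_size[[as.character(s)]]
  if (is.null(cand)) return(integer(0))
  cand[bitwAnd(cand, pool) == cand]
}

# local RNG scope: runs expr with the given seed without disturbing the
# caller's random number stream; seed = NULL uses the current stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# format a leaf set for messages and TSV output
.set_label <- function(X) {
  if (length(X) == 0) "{}" else paste(sort(X), collapse = ",")
}
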