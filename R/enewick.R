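#' Read a phylogenetic network from extended Newick
#'
#' Parses a single extended-Newick statement using the hybrid-node
#' convention: a reticulation appears once in expanded form,
#' `(subtree)#LABEL:len`, and at every other attachment point as a bare
#' `#LABEL:len`.  All occurrences sharing a `#LABEL` are merged into one
#' reticulation node; the branch length on each occurrence becomes the
#' weight of that incoming arc.  Arcs without a branch length receive
#' `default_weight`.
#'
#' @param text a single eNewick string terminated by `;`.
#' @param default_weight weight assigned to arcs with no branch length.
#' @return a validated [phylo_network()].
#' @examples
#' net <- read_enewick("((a:1,b:2)v:3)r;")
#' total_weight(net)
#' @export
read_enewick <- function(text, default_weight = 1) {
  text <- trimws(paste(text, collapse = ""))
  if (!nzchar(text)) stop("empty eNewick input")
  st <- new.env(parent = emptyenv())
  st$s <- text
  st$i <- 1L
  st$n_anon <- 0L
  st$parent <- character(0)
  st$child <- character(0)
  st$weight <- numeric(0)
  st$hybrid_expanded <- character(0)  # hybrid labels whose subtree was seen

  fail <- function(msg) {
    stop(sprintf("eNewick parse error at character %d: %s", st$i, msg))
  }
  peek <- function() {
    if (st$i > nchar(st$s)) "" else substr(st$s, st$i, st$i)
  }
  advance <- function() st$i <- st$i + 1L
  read_name <- function() {
    start <- st$i
    while (st$i <= nchar(st$s) &&
           !substr(st$s, st$i, st$i) %in% c("(", ")", ",", ":", ";")) {
      advance()
    }
    substr(st$s, start, st$i - 1L)
  }
  fresh_id <- function() {
    st$n_anon <- st$n_anon + 1L
    paste0(".i", st$n_anon)
  }
  add_arc <- function(p, c, w) {
    st$parent <- c(st$parent, p)
    st$child <- c(st$child, c)
    st$weight <- c(st$weight, w)
  }

  # parses one node (with optional subtree) and returns list(id, len)
  parse_node <- function() {
    kids <- list()
    if (peek() == "(") {
      advance()
      repeat {
        kids[[length(kids) + 1L]] <- parse_node()
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        fail("expected ',' or ')'")
      }
    }
    name <- read_name()
    len <- NA_real_
    if (peek() == ":") {
      advance()
      numstr <- read_name()
      len <- suppressWarnings(as.numeric(numstr))
      if (is.na(len)) fail(paste0("bad branch length '", numstr, "'"))
    }
    hybrid <- grepl("#", name, fixed = TRUE)
    if (hybrid) {
      id <- sub("^[^#]*", "", name)  # node id is the #LABEL part
      if (length(kids) > 0) {
        if (id %in% st$hybrid_expanded)
          fail(paste0("hybrid node ", id, " expanded more than once"))
        st$hybrid_expanded <- c(st$hybrid_expanded, id)
      }
    } else {
      id <- if (nzchar(name)) name else fresh_id()
    }
    for (k in kids) {
      add_arc(id, k$id, if (is.na(k$len)) default_weight else k$len)
    }
    if (length(kids) == 0 && !hybrid && !nzchar(name))
      fail("anonymous leaf")
    list(id = id, len = len)
  }

  root <- parse_node()
  if (peek() != ";") fail("expected ';'")
  if (length(st$parent) == 0)
    stop("eNewick input describes a single node, not a network")
  phylo_network(st$parent, st$child, st$weight)
}

#' Write a phylogenetic network as extended Newick
#'
#' Serializes with the hybrid-node convention: the first (deterministic,
#' lexicographic-child-order) visit of each reticulation carries its
#' subtree, later visits emit a bare `#LABEL`.  Internal node ids are
#' written as node names so the output re-parses to an identical network.
#'
#' @param net a `phylo_network`.
#' @return a single eNewick string terminated by `;`.
#' @export
write_enewick <- function(net) {
  retic <- reticulations(net)
  hlab <- structure(paste0("#H", seq_along(retic)), names = retic)
  expanded <- structure(logical(length(retic)), names = retic)
  kids_of <- split(seq_along(net$parent), factor(net$parent, levels = net$nodes))

  render <- function(v, win) {
    # win: weight of the incoming arc (NA at root)
    suffix <- if (is.na(win)) "" else paste0(":", .fmt_weight(win))
    if (v %in% retic) {
      if (expanded[v]) return(paste0(hlab[v], suffix))
      expanded[v] <<- TRUE
      ai <- kids_of[[v]]
      inner <- render(net$child[ai], net$weight[ai])
      return(paste0("(", inner, ")", hlab[v], suffix))
    }
    ai <- kids_of[[v]]
    if (length(ai) == 0) return(paste0(v, suffix))
    ord <- order(net$child[ai])
    parts <- vapply(ai[ord], function(j) render(net$child[j], net$weight[j]),
                    character(1))
    nm <- if (startsWith(v, ".i")) "" else v
    paste0("(", paste(parts, collapse = ","), ")", nm, suffix)
  }
  paste0(render(net$root, NA_real_), ";")
}

#' Read / write a network as an edge-list TSV
#'
#' The format is a tab-separated table with header
#' `parent<TAB>child<TAB>weight`, one arc per row.  Node ids are literal
#' strings; leaves are nodes that never appear in the `parent` column and
#' their labels equal their ids.
#'
#' @param text TSV text (a single string or a character vector of lines).
#' @return [read_edgelist()]: a validated `phylo_network`.
#' @export
read_edgelist <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("no root: empty edge list")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(header) < 3 || tolower(header[1]) != "parent" ||
      tolower(header[2]) != "child" || tolower(header[3]) != "weight")
    stop("edge-list header must be 'parent\\tchild\\tweight'")
  body <- lines[-1]
  if (length(body) == 0) stop("no root: edge list has no arcs")
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3))
    stop("malformed edge-list row(s): ", paste(which(nf != 3) + 1, collapse = ", "))
  m <- do.call(rbind, fields)
  w <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(w) || any(w < 0))
    stop("weight must be a nonnegative number (rows ",
         paste(which(is.na(w) | w < 0) + 1, collapse = ", "), ")")
  phylo_network(m[, 1], m[, 2], w)
}

#' @rdname read_edgelist
#' @param net a `phylo_network`.
#' @return [write_edgelist()]: a single TSV string (rows sorted by parent,
#'   then child).
#' @export
write_edgelist <- function(net) {
  ord <- order(net$parent, net$child)
  rows <- paste(net$parent[ord], net$child[ord],
                .fmt_weight(net$weight[ord]), sep = "\t")
  paste(c("parent\tchild\tweight", rows, ""), collapse = "\n")
}
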