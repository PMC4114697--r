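# Rooted phylogeny I/O and queries.
#
# Trees are plain ape "phylo" objects carrying branch lengths (in
# amino-acid substitutions per position for the trees this package was
# designed around) and a complete set of unique node labels: unlabeled
# internal nodes are auto-named "N0001", "N0002", ... by post-order
# index at parse time, so ancestral nodes are referable across runs.

#' Parse a rooted newick tree
#'
#' Reads a newick string into an [ape::read.tree()] `phylo` object,
#' validates it (branch lengths present and non-negative, leaf labels
#' unique), and assigns deterministic post-order names (`"N0001"`, ...)
#' to unlabeled internal nodes.  A single-leaf dialect `"A:0.0;"` is
#' accepted and produced for degenerate trees.
#'
#' @param text A length-one character string containing one newick tree.
#' @return A `phylo` object with complete, unique tip and node labels.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2):0;")
#' patristic_distance(tr, "A", "A")
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) stop("parse error at character 1: empty newick string")
  .check_newick_parens(text)
  if (!grepl("(", text, fixed = TRUE)) {
    return(.parse_single_leaf(text))
  }
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tr) || inherits(tr, "multiPhylo")) {
    stop("parse error at character 1: not a valid single newick tree")
  }
  if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
    stop("branch lengths are required on every edge")
  }
  if (any(tr$edge.length < 0)) stop("negative branch length")
  dup <- tr$tip.label[duplicated(tr$tip.label)]
  if (length(dup) > 0) {
    stop("duplicate leaf label: ", paste(unique(dup), collapse = ", "))
  }
  tr <- .autoname_nodes(tr)
  .validate_phylogeny(tr)
  tr
}

#' Write a phylogeny as a newick string
#'
#' Inverse of [parse_newick()]: `parse_newick(write_newick(t))` is
#' isomorphic to `t` with identical branch lengths and labels.  The
#' single-leaf dialect is `"<label>:<length>;"`.
#'
#' @param tree A `phylo` object.
#' @return A length-one character string (with trailing `";"`).
#' @export
write_newick <- function(tree) {
  .validate_phylogeny(tree)
  if (length(tree$tip.label) == 1L) {
    len <- if (is.null(tree$edge.length)) 0 else tree$edge.length[1]
    return(paste0(tree$tip.label, ":", format(len, scientific = FALSE), ";"))
  }
  ape::write.tree(tree)
}

#' Ancestors of a leaf, youngest first
#'
#' @param tree A `phylo` object.
#' @param leaf A tip label.
#' @return Character vector of internal-node labels from the leaf's
#'   parent up to and including the root.
#' @export
ancestor_chain <- function(tree, leaf) {
  idx <- .tree_index(tree)
  i <- match(leaf, tree$tip.label)
  if (is.na(i)) stop("unknown leaf: ", leaf)
  out <- integer(0)
  v <- idx$parent[i]
  while (!is.na(v)) {
    out <- c(out, v)
    v <- idx$parent[v]
  }
  idx$labels[out]
}

#' Patristic distance from an ancestor to a leaf
#'
#' Sum of branch lengths on the path from `node` (which must be the
#' leaf itself or one of its ancestors) down to `leaf`; zero when
#' `node == leaf`.
#'
#' @param tree A `phylo` object.
#' @param node A node label (internal or the leaf itself).
#' @param leaf A tip label.
#' @return Non-negative numeric distance.
#' @export
patristic_distance <- function(tree, node, leaf) {
  idx <- .tree_index(tree)
  i <- match(leaf, tree$tip.label)
  if (is.na(i)) stop("unknown leaf: ", leaf)
  if (identical(node, leaf)) return(0)
  target <- match(node, idx$labels)
  if (is.na(target)) stop("unknown node: ", node)
  d <- 0
  v <- i
  repeat {
    p <- idx$parent[v]
    if (is.na(p)) stop("node '", node, "' is not an ancestor of leaf '", leaf, "'")
    d <- d + idx$blen[v]
    if (p == target) return(d)
    v <- p
  }
}

#' Prune a tree to a leaf set
#'
#' Retains the leaves `setdiff(keep, exclude)`, collapsing degree-2
#' internal nodes (branch lengths summed) so that all pairwise
#' patristic distances between retained leaves are preserved.
#'
#' @param tree A `phylo` object.
#' @param keep Character vector of leaf labels to keep (default: all).
#' @param exclude Character vector of leaf labels to drop, e.g. an
#'   exclusion list of endosymbionts read with [read_exclusion_list()].
#' @return A pruned `phylo` object.
#' @export
prune_to <- function(tree, keep = NULL, exclude = character()) {
  .validate_phylogeny(tree)
  if (is.null(keep)) keep <- tree$tip.label
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown) > 0) {
    stop("keep set contains unknown leaves: ", paste(unknown, collapse = ", "))
  }
  retained <- setdiff(keep, exclude)
  if (length(retained) == 0) stop("pruning would remove every leaf")
  if (length(retained) == length(tree$tip.label)) return(tree)
  if (length(retained) == 1L) {
    idx <- .tree_index(tree)
    d <- patristic_distance(tree, idx$labels[idx$root], retained)
    return(.single_leaf_tree(retained, d))
  }
  out <- ape::keep.tip(tree, retained)
  .validate_phylogeny(out)
  out
}

#' Read an exclusion list
#'
#' One leaf label per line; blank lines and lines starting with `#`
#' are ignored.
#'
#' @param path Path to a plain-text file.
#' @return Character vector of labels.
#' @export
read_exclusion_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

## ---- internal helpers -------------------------------------------------

.check_newick_parens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    if (chars[k] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop("parse error at character ", k, ": unbalanced ')'")
    }
  }
  if (depth != 0L) {
    stop("parse error at character ", nchar(text), ": unbalanced '('")
  }
  invisible(TRUE)
}

.parse_single_leaf <- function(text) {
  m <- regmatches(text, regexec("^([^():;,[:space:]]+)(:([0-9.eE+-]+))?;?$", text))[[1]]
  if (length(m) == 0) {
    stop("parse error at character 1: not a valid single-leaf newick")
  }
  len <- if (nzchar(m[4])) as.numeric(m[4]) else 0
  if (is.na(len) || len < 0) stop("invalid branch length in single-leaf newick")
  .single_leaf_tree(m[2], len)
}

.single_leaf_tree <- function(label, len) {
  structure(
    list(
      edge = matrix(c(2L, 1L), 1L, 2L),
      edge.length = len,
      tip.label = label,
      node.label = "N0001",
      Nnode = 1L
    ),
    class = "phylo", order = "cladewise"
  )
}

# Deterministic post-order names for unlabeled internal nodes.
.autoname_nodes <- function(tree) {
  n <- length(tree$tip.label)
  N <- n + tree$Nnode
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", tree$Nnode)
  lab[is.na(lab)] <- ""
  children <- .children_list(tree, N)
  po <- .postorder_nodes(children, n + 1L)
  po <- po[po > n]
  k <- 0L
  for (v in po) {
    if (!nzchar(lab[v - n])) {
      repeat {
        k <- k + 1L
        cand <- sprintf("N%04d", k)
        if (!cand %in% lab && !cand %in% tree$tip.label) break
      }
      lab[v - n] <- cand
    }
  }
  tree$node.label <- lab
  tree
}

.children_list <- function(tree, N) {
  children <- vector("list", N)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1L]
    children[[p]] <- c(children[[p]], tree$edge[k, 2L])
  }
  children
}

# Iterative post-order traversal (children before parent).
.postorder_nodes <- function(children, root) {
  out <- integer(0)
  stack <- list(list(node = root, stage = 1L))
  while (length(stack) > 0) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (top$stage == 1L) {
      stack[[length(stack) + 1L]] <- list(node = top$node, stage = 2L)
      kids <- children[[top$node]]
      for (c in rev(kids)) {
        stack[[length(stack) + 1L]] <- list(node = c, stage = 1L)
      }
    } else {
      out <- c(out, top$node)
    }
  }
  out
}

# Index structure used by every traversal: parents, branch lengths to
# parent, child lists, and a post-order node sequence.
.tree_index <- function(tree) {
  n <- length(tree$tip.label)
  N <- n + tree$Nnode
  nl <- tree$node.label
  if (is.null(nl)) stop("tree has no internal node labels; use parse_newick()")
  labels <- c(tree$tip.label, nl)
  parent <- rep(NA_integer_, N)
  blen <- rep(NA_real_, N)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  blen[tree$edge[, 2L]] <- tree$edge.length
  children <- .children_list(tree, N)
  root <- if (n == 1L) 2L else n + 1L
  list(
    n_tip = n, N = N, labels = labels, parent = parent, blen = blen,
    children = children, root = root,
    postorder = .postorder_nodes(children, root)
  )
}

.validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  n <- length(tree$tip.label)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("branch lengths are required on every edge")
  }
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label))) {
    stop("internal nodes must be labeled; use parse_newick() or .autoname_nodes()")
  }
  labels <- c(tree$tip.label, tree$node.label)
  if (anyDuplicated(labels)) {
    stop("duplicate node label: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  # every non-root node has exactly one parent; chain reaches the root
  idx_parent <- rep(NA_integer_, n + tree$Nnode)
  cnt <- tabulate(tree$edge[, 2L], nbins = n + tree$Nnode)
  if (any(cnt > 1L)) stop("a node has more than one parent")
  invisible(TRUE)
}
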