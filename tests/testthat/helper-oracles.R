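# Independent oracles: brute-force enumeration over all joint internal
# state assignments for the gain/loss model (never calls the pruning
# code), and a matrix-exponential route to the transition matrix.

# Transition matrix via eigendecomposition of Q = [[-g, g], [l, -l]].
expm_transition <- function(g, l, t) {
  Q <- matrix(c(-g, g, l, -l), 2, 2, byrow = TRUE)
  e <- eigen(Q)
  Re(e$vectors %*% diag(exp(e$values * t)) %*% solve(e$vectors))
}

# Edge list (parent label, child label, length) of a tree.
.edge_table <- function(tree) {
  labels <- c(tree$tip.label, tree$node.label)
  data.frame(parent = labels[tree$edge[, 1]],
             child = labels[tree$edge[, 2]],
             len = tree$edge.length, stringsAsFactors = FALSE)
}

# Full-enumeration log-likelihood for a single-category model.
enum_loglik <- function(tree, profile, g, l, prior = NULL) {
  if (is.null(prior)) prior <- c(l, g) / (g + l)
  P <- function(t) {
    r <- g + l
    f <- 1 - exp(-r * t)
    matrix(c(1 - g / r * f, g / r * f, l / r * f, 1 - l / r * f),
           2, 2, byrow = TRUE)
  }
  edges <- .edge_table(tree)
  internals <- c(tree$node.label)
  root <- tree$node.label[1]
  tips <- tree$tip.label
  lik <- 0
  n_int <- length(internals)
  for (code in 0:(2^n_int - 1)) {
    states <- as.integer(intToBits(code))[seq_len(n_int)]
    names(states) <- internals
    term <- prior[states[[root]] + 1]
    ok <- TRUE
    for (k in seq_len(nrow(edges))) {
      ps <- states[[edges$parent[k]]]
      ch <- edges$child[k]
      if (ch %in% tips) {
        obs <- profile[[ch]]
        if (is.null(obs) || is.na(obs)) {
          pc <- 1  # missing leaf: sum over both states
        } else {
          pc <- P(edges$len[k])[ps + 1, obs + 1]
        }
      } else {
        pc <- P(edges$len[k])[ps + 1, states[[ch]] + 1]
      }
      term <- term * pc
    }
    lik <- lik + term
  }
  log(lik)
}

# Full-enumeration marginal posteriors of presence at every node.
enum_posteriors <- function(tree, profile, g, l, prior = NULL) {
  if (is.null(prior)) prior <- c(l, g) / (g + l)
  P <- function(t) {
    r <- g + l
    f <- 1 - exp(-r * t)
    matrix(c(1 - g / r * f, g / r * f, l / r * f, 1 - l / r * f),
           2, 2, byrow = TRUE)
  }
  edges <- .edge_table(tree)
  internals <- tree$node.label
  root <- tree$node.label[1]
  tips <- tree$tip.label
  # treat unobserved tips as free variables too
  free_tips <- tips[vapply(tips, function(tp) {
    is.null(profile[[tp]]) || is.na(profile[[tp]])
  }, logical(1))]
  vars <- c(internals, free_tips)
  nodes <- c(tips, internals)
  num <- setNames(numeric(length(nodes)), nodes)
  tot <- 0
  for (code in 0:(2^length(vars) - 1)) {
    fs <- as.integer(intToBits(code))[seq_along(vars)]
    names(fs) <- vars
    state_of <- function(nd) {
      if (nd %in% vars) fs[[nd]] else profile[[nd]]
    }
    term <- prior[state_of(root) + 1]
    for (k in seq_len(nrow(edges))) {
      term <- term * P(edges$len[k])[state_of(edges$parent[k]) + 1,
                                     state_of(edges$child[k]) + 1]
    }
    tot <- tot + term
    for (nd in nodes) if (state_of(nd) == 1L) num[nd] <- num[nd] + term
  }
  num / tot
}

# Small random 0/1/NA profile over the tips of a tree.
random_profile <- function(tree, p_present = 0.5, p_missing = 0) {
  n <- length(tree$tip.label)
  x <- as.integer(runif(n) < p_present)
  x[runif(n) < p_missing] <- NA_integer_
  # ensure at least one observed leaf
  if (all(is.na(x))) x[1] <- 1L
  setNames(x, tree$tip.label)
}

# A 6-level caterpillar tree whose focal leaf F has a long ancestor
# chain with unit branch lengths.
caterpillar_tree <- function(levels = 5) {
  nwk <- "F:1"
  for (k in seq_len(levels)) {
    nwk <- sprintf("(%s,x%d:1):1", nwk, k)
  }
  parse_newick(sub(":1$", ":0;", nwk))
}
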