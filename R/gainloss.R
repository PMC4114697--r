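# Two-state (0 = absent, 1 = present) gain/loss continuous-time Markov
# model on a fixed rooted phylogeny: closed-form transition matrices,
# Felsenstein-pruning likelihood, bounded ML rate fitting, and marginal
# ancestral posteriors by an up-down (inside-outside) pass.  Branch
# lengths are never re-estimated.

.RATE_MIN <- 1e-6
.RATE_MAX <- 1e3

#' Two-state gain/loss transition matrix
#'
#' Closed form for the CTMC with generator `Q = [[-g, g], [l, -l]]`:
#' with `r = g + l` and stationary presence probability `pi1 = g / r`,
#' `P01(t) = pi1 (1 - exp(-r t))` and `P10(t) = pi0 (1 - exp(-r t))`.
#'
#' @param gain,loss Positive gain and loss rates.
#' @param t Non-negative branch length.
#' @return A 2x2 row-stochastic matrix with states ordered (0, 1).
#' @export
transition_matrix <- function(gain, loss, t) {
  if (!is.finite(gain) || !is.finite(loss) || gain <= 0 || loss <= 0) {
    stop("gain and loss rates must be positive")
  }
  if (!is.finite(t) || t < 0) stop("branch length must be non-negative")
  r <- gain + loss
  p1 <- gain / r
  p0 <- loss / r
  f <- 1 - exp(-r * t)
  matrix(c(1 - p1 * f, p1 * f, p0 * f, 1 - p0 * f),
         nrow = 2L, byrow = TRUE, dimnames = list(c("0", "1"), c("0", "1")))
}

#' Construct a gain/loss model
#'
#' One or more rate categories, each `(gain, loss, weight)`, with either
#' the per-category stationary distribution as root prior (the default)
#' or an explicit `(p0, p1)` pair.
#'
#' @param gain,loss Positive rate vectors (one entry per category).
#' @param weight Non-negative category weights (normalized to sum 1).
#' @param root_prior `"stationary"` or a numeric pair `(p0, p1)`.
#' @return An object of class `gain_loss_model`.
#' @export
gain_loss_model <- function(gain, loss, weight = NULL, root_prior = "stationary") {
  K <- length(gain)
  stopifnot(length(loss) == K, K >= 1)
  if (is.null(weight)) weight <- rep(1 / K, K)
  stopifnot(length(weight) == K, all(weight >= 0), sum(weight) > 0)
  weight <- weight / sum(weight)
  if (any(gain < .RATE_MIN) || any(gain > .RATE_MAX) ||
      any(loss < .RATE_MIN) || any(loss > .RATE_MAX)) {
    stop("rates must lie in [", .RATE_MIN, ", ", .RATE_MAX, "]")
  }
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == 2, all(root_prior >= 0),
              abs(sum(root_prior) - 1) < 1e-8)
  } else if (!identical(root_prior, "stationary")) {
    stop("root_prior must be \"stationary\" or a numeric (p0, p1) pair")
  }
  structure(
    list(gain = as.numeric(gain), loss = as.numeric(loss),
         weight = weight, root_prior = root_prior),
    class = "gain_loss_model"
  )
}

#' @export
print.gain_loss_model <- function(x, ...) {
  cat("Gain/loss model (", length(x$gain), " categor",
      if (length(x$gain) == 1) "y" else "ies", ")\n", sep = "")
  for (k in seq_along(x$gain)) {
    cat(sprintf("  [%d] gain = %.6g, loss = %.6g, weight = %.3f\n",
                k, x$gain[k], x$loss[k], x$weight[k]))
  }
  cat("  root prior:",
      if (is.character(x$root_prior)) "stationary" else
        sprintf("(%.4f, %.4f)", x$root_prior[1], x$root_prior[2]), "\n")
  if (!is.null(attr(x, "logLik"))) {
    cat(sprintf("  log-likelihood at fit: %.6f\n", attr(x, "logLik")))
  }
  invisible(x)
}

.root_prior_k <- function(model, k) {
  if (is.numeric(model$root_prior)) return(model$root_prior)
  r <- model$gain[k] + model$loss[k]
  c(model$loss[k] / r, model$gain[k] / r)
}

# Leaf partial-likelihood matrices (n_tip x n_traits) from a profile
# matrix with entries 0 / 1 / NA (missing -> (1, 1)).
.leaf_partials <- function(tree, profiles) {
  if (is.vector(profiles)) {
    profiles <- matrix(profiles, nrow = 1L,
                       dimnames = list("trait", names(profiles)))
  }
  tips <- tree$tip.label
  bad <- setdiff(colnames(profiles), tips)
  if (length(bad) > 0) {
    stop("profile references labels that are not leaves of the tree: ",
         paste(bad, collapse = ", "))
  }
  if (all(is.na(profiles))) stop("profile has no observed leaves")
  X <- matrix(NA_real_, nrow = length(tips), ncol = nrow(profiles),
              dimnames = list(tips, rownames(profiles)))
  X[colnames(profiles), ] <- t(profiles)
  X0 <- ifelse(is.na(X), 1, 1 - X)
  X1 <- ifelse(is.na(X), 1, X)
  list(X0 = X0, X1 = X1)
}

# Vectorized pruning pass over all traits for one rate category.
# Returns per-node scaled partial likelihoods and per-trait log scale.
.pruning_pass <- function(idx, X0, X1, gain, loss) {
  m <- ncol(X0)
  L0 <- matrix(NA_real_, idx$N, m)
  L1 <- matrix(NA_real_, idx$N, m)
  L0[seq_len(idx$n_tip), ] <- X0
  L1[seq_len(idx$n_tip), ] <- X1
  logscale <- numeric(m)
  internal <- idx$postorder[idx$postorder > idx$n_tip]
  for (v in internal) {
    l0 <- rep(1, m)
    l1 <- rep(1, m)
    for (ch in idx$children[[v]]) {
      P <- transition_matrix(gain, loss, idx$blen[ch])
      l0 <- l0 * (P[1, 1] * L0[ch, ] + P[1, 2] * L1[ch, ])
      l1 <- l1 * (P[2, 1] * L0[ch, ] + P[2, 2] * L1[ch, ])
    }
    s <- pmax(l0, l1)
    s[s <= 0] <- 1
    L0[v, ] <- l0 / s
    L1[v, ] <- l1 / s
    logscale <- logscale + log(s)
  }
  list(L0 = L0, L1 = L1, logscale = logscale)
}

# Per-trait log-likelihood vector for one category.
.loglik_category <- function(idx, X0, X1, model, k) {
  up <- .pruning_pass(idx, X0, X1, model$gain[k], model$loss[k])
  pr <- .root_prior_k(model, k)
  lik_root <- pr[1] * up$L0[idx$root, ] + pr[2] * up$L1[idx$root, ]
  log(lik_root) + up$logscale
}

.logsumexp_rows <- function(M) {
  mx <- apply(M, 1L, max)
  mx + log(rowSums(exp(M - mx)))
}

#' Pruning log-likelihood of phyletic profiles
#'
#' Felsenstein pruning on the fixed tree.  Missing leaves contribute the
#' partial likelihood (1, 1); mixture categories are combined on the
#' likelihood scale before the log.
#'
#' @param tree A `phylo` object from [parse_newick()].
#' @param profiles Named 0/1/NA vector (one trait) or a traits-by-genomes
#'   matrix with genome labels as column names.
#' @param model A [gain_loss_model()].
#' @return Numeric vector of log-likelihoods, one per trait.
#' @export
pruning_loglik <- function(tree, profiles, model) {
  idx <- .tree_index(tree)
  lp <- .leaf_partials(tree, profiles)
  K <- length(model$gain)
  ll_k <- vapply(seq_len(K), function(k) {
    .loglik_category(idx, lp$X0, lp$X1, model, k)
  }, numeric(ncol(lp$X0)))
  ll_k <- matrix(ll_k, ncol = K)
  if (K == 1L) return(drop(ll_k[, 1L]))
  drop(.logsumexp_rows(sweep(ll_k, 2L, log(model$weight), "+")))
}

#' Fit gain/loss rates by maximum likelihood
#'
#' Maximizes the summed pruning log-likelihood over all profiles with a
#' bounded quasi-Newton search (`L-BFGS-B` over log-rates) restarted
#' from a 3x3 grid of starting rates per category; branch lengths are
#' never touched.  A rate driven to its bound raises a warning and the
#' bound value is returned.
#'
#' @param tree A `phylo` object.
#' @param profiles Traits-by-genomes 0/1/NA matrix (or one named vector).
#' @param n_categories Number of mixture categories (default 1).
#' @param root_prior Passed to [gain_loss_model()].
#' @return A fitted `gain_loss_model` with attribute `logLik`.
#' @export
fit_rates <- function(tree, profiles, n_categories = 1L, root_prior = "stationary") {
  idx <- .tree_index(tree)
  lp <- .leaf_partials(tree, profiles)
  m <- ncol(lp$X0)
  K <- as.integer(n_categories)
  stopifnot(K >= 1L)

  negll <- function(par) {
    gains <- exp(par[seq_len(K)])
    losses <- exp(par[K + seq_len(K)])
    w <- if (K == 1L) 1 else {
      z <- c(0, par[2L * K + seq_len(K - 1L)])
      exp(z) / sum(exp(z))
    }
    mod <- structure(list(gain = gains, loss = losses, weight = w,
                          root_prior = root_prior),
                     class = "gain_loss_model")
    ll_k <- vapply(seq_len(K), function(k) {
      .loglik_category(idx, lp$X0, lp$X1, mod, k)
    }, numeric(m))
    ll_k <- matrix(ll_k, ncol = K)
    tot <- if (K == 1L) sum(ll_k) else
      sum(.logsumexp_rows(sweep(ll_k, 2L, log(w), "+")))
    if (!is.finite(tot)) 1e12 else -tot
  }

  lb <- rep(log(.RATE_MIN), 2L * K)
  ub <- rep(log(.RATE_MAX), 2L * K)
  # single category: dense 3x3 grid of restarts; mixtures: a smaller
  # grid (the category spread in par0 already diversifies the starts)
  starts1 <- if (K == 1L) {
    expand.grid(lg = log(c(0.01, 1, 100)), ll = log(c(0.01, 1, 100)))
  } else {
    expand.grid(lg = log(c(0.05, 5)), ll = log(c(0.05, 5)))
  }
  best <- NULL
  for (s in seq_len(nrow(starts1))) {
    par0 <- c(rep(starts1$lg[s], K) + seq(0, 4, length.out = K),
              rep(starts1$ll[s], K) + seq(0, 4, length.out = K))
    lo <- lb; hi <- ub
    if (K > 1L) {
      par0 <- c(par0, rep(0, K - 1L))
      lo <- c(lo, rep(-10, K - 1L))
      hi <- c(hi, rep(10, K - 1L))
    }
    fit <- tryCatch(
      stats::optim(par0, negll, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(factr = 1e4, maxit = 500)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("rate optimization failed from every start")

  gains <- exp(best$par[seq_len(K)])
  losses <- exp(best$par[K + seq_len(K)])
  w <- if (K == 1L) 1 else {
    z <- c(0, best$par[2L * K + seq_len(K - 1L)])
    exp(z) / sum(exp(z))
  }
  at_bound <- c(gains, losses) <= .RATE_MIN * (1 + 1e-6) |
    c(gains, losses) >= .RATE_MAX * (1 - 1e-6)
  if (any(at_bound)) {
    warning("fitted rate at optimization bound; profile set is degenerate ",
            "(e.g. all-present or all-absent traits)")
  }
  gains <- pmin(pmax(gains, .RATE_MIN), .RATE_MAX)
  losses <- pmin(pmax(losses, .RATE_MIN), .RATE_MAX)
  out <- gain_loss_model(gains, losses, w, root_prior)
  attr(out, "logLik") <- -best$value
  out
}

#' Marginal ancestral posteriors of presence
#'
#' Inside-outside (up-down) message passing: the up pass is Felsenstein
#' pruning, the down pass propagates the evidence outside each node's
#' subtree; the product, normalized, is the marginal posterior
#' `P(state_v = 1 | data)` at every node.  For mixtures, per-category
#' posteriors are combined with weights `P(category | data)`.
#'
#' Observed leaves keep their observed state (posterior 0 or 1); missing
#' leaves get a genuine posterior.
#'
#' @param tree A `phylo` object.
#' @param profile A single named 0/1/NA vector over (a subset of) leaves.
#' @param model A `gain_loss_model`.
#' @return Named numeric vector of presence posteriors over all nodes
#'   (tips first, then internal nodes).
#' @export
node_posteriors <- function(tree, profile, model) {
  idx <- .tree_index(tree)
  lp <- .leaf_partials(tree, profile)
  K <- length(model$gain)

  post_k <- matrix(NA_real_, idx$N, K)
  ll_k <- numeric(K)
  for (k in seq_len(K)) {
    up <- .pruning_pass(idx, lp$X0, lp$X1, model$gain[k], model$loss[k])
    pr <- .root_prior_k(model, k)
    ll_k[k] <- log(pr[1] * up$L0[idx$root, 1] + pr[2] * up$L1[idx$root, 1]) +
      up$logscale
    O0 <- rep(NA_real_, idx$N)
    O1 <- rep(NA_real_, idx$N)
    O0[idx$root] <- pr[1]
    O1[idx$root] <- pr[2]
    for (v in rev(idx$postorder)) {
      kids <- idx$children[[v]]
      if (length(kids) == 0) next
      # child messages M_c(s) = P(s -> .) %*% L_c
      M0 <- numeric(length(kids))
      M1 <- numeric(length(kids))
      Ps <- vector("list", length(kids))
      for (j in seq_along(kids)) {
        ch <- kids[j]
        P <- transition_matrix(model$gain[k], model$loss[k], idx$blen[ch])
        Ps[[j]] <- P
        M0[j] <- P[1, 1] * up$L0[ch, 1] + P[1, 2] * up$L1[ch, 1]
        M1[j] <- P[2, 1] * up$L0[ch, 1] + P[2, 2] * up$L1[ch, 1]
      }
      for (j in seq_along(kids)) {
        ch <- kids[j]
        sib0 <- prod(M0[-j])
        sib1 <- prod(M1[-j])
        a0 <- O0[v] * sib0
        a1 <- O1[v] * sib1
        P <- Ps[[j]]
        o0 <- a0 * P[1, 1] + a1 * P[2, 1]
        o1 <- a0 * P[1, 2] + a1 * P[2, 2]
        s <- o0 + o1
        if (s <= 0) s <- 1
        O0[ch] <- o0 / s
        O1[ch] <- o1 / s
      }
    }
    w0 <- O0 * up$L0[, 1]
    w1 <- O1 * up$L1[, 1]
    post_k[, k] <- w1 / (w0 + w1)
  }

  if (K == 1L) {
    post <- post_k[, 1L]
  } else {
    lw <- log(model$weight) + ll_k
    resp <- exp(lw - max(lw))
    resp <- resp / sum(resp)
    post <- drop(post_k %*% resp)
  }
  names(post) <- idx$labels
  post
}

#' Maximum-likelihood marginal states
#'
#' State 1 iff the posterior exceeds 0.5; an exact tie (0.5) is called
#' absent (documented tie-break).
#'
#' @param posteriors Named posterior vector from [node_posteriors()].
#' @return Named integer vector of 0/1 states.
#' @export
marginal_ml_states <- function(posteriors) {
  out <- as.integer(posteriors > 0.5)
  names(out) <- names(posteriors)
  out
}

#' Read a phyletic-profile matrix
#'
#' TSV with rows = traits (first column `trait`), columns = genome
#' labels, cells 0/1/NA.
#'
#' @param path Path to a TSV file.
#' @return Traits-by-genomes integer matrix with dimnames.
#' @export
read_profiles <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}

#' Write a phyletic-profile matrix
#'
#' @param profiles Traits-by-genomes matrix.
#' @param path Output TSV path.
#' @export
write_profiles <- function(profiles, path) {
  df <- data.frame(trait = rownames(profiles), profiles,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write node posteriors in long format
#'
#' TSV with columns `trait`, `node`, `posterior`.
#'
#' @param posterior_list Named list of posterior vectors (one per trait).
#' @param path Output TSV path.
#' @export
write_posteriors <- function(posterior_list, path) {
  rows <- do.call(rbind, lapply(names(posterior_list), function(tr) {
    p <- posterior_list[[tr]]
    data.frame(trait = tr, node = names(p), posterior = unname(p),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
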