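test_that("transition matrix matches the closed form and its limits", {
  expect_equal(transition_matrix(1, 1, 0), diag(2),
               ignore_attr = TRUE)
  P <- transition_matrix(1, 3, 1e6)
  expect_equal(unname(P[1, ]), c(0.75, 0.25), tolerance = 1e-12)
  expect_equal(unname(P[2, ]), c(0.75, 0.25), tolerance = 1e-12)
  # matrix-exponential oracle
  for (gl in list(c(1, 1, 1), c(0.5, 2, 0.3), c(3, 0.2, 1.7))) {
    expect_equal(unname(transition_matrix(gl[1], gl[2], gl[3])),
                 expm_transition(gl[1], gl[2], gl[3]), tolerance = 1e-12)
  }
  expect_error(transition_matrix(0, 1, 1), "positive")
  expect_error(transition_matrix(1, 1, -1), "non-negative")
})

test_that("pruning likelihood matches hand-computable cases", {
  # zero-length branches: likelihood collapses to the root prior
  tr0 <- parse_newick("(A:0,B:0):0;")
  m <- gain_loss_model(0.5, 1.5)
  expect_equal(pruning_loglik(tr0, c(A = 1L, B = 1L), m), log(0.25))

  # 2-leaf (1, 0) pattern by explicit summation over the root state
  tr <- parse_newick("(A:0.4,B:0.7):0;")
  g <- 0.8; l <- 1.3
  P <- function(t) expm_transition(g, l, t)
  prior <- c(l, g) / (g + l)
  lik <- sum(vapply(0:1, function(s) {
    prior[s + 1] * P(0.4)[s + 1, 2] * P(0.7)[s + 1, 1]
  }, numeric(1)))
  expect_equal(pruning_loglik(tr, c(A = 1L, B = 0L), gain_loss_model(g, l)),
               log(lik), tolerance = 1e-12)
})

test_that("pruning equals brute-force enumeration on small random trees", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(4:6, 1)
    tr <- simulate_tree(n, depth = runif(1, 0.3, 1.5), seed = 100 + rep)
    prof <- random_profile(tr, p_missing = ifelse(rep %% 3 == 0, 0.2, 0))
    g <- runif(1, 0.1, 2); l <- runif(1, 0.1, 2)
    m <- gain_loss_model(g, l)
    expect_equal(pruning_loglik(tr, prof, m), enum_loglik(tr, prof, g, l),
                 tolerance = 1e-10)
  }
})

test_that("node posteriors equal enumeration and honor observations", {
  set.seed(13)
  for (rep in 1:8) {
    tr <- simulate_tree(sample(4:6, 1), depth = 1, seed = 200 + rep)
    prof <- random_profile(tr, p_missing = ifelse(rep %% 2 == 0, 0.25, 0))
    g <- runif(1, 0.2, 2); l <- runif(1, 0.2, 2)
    post <- node_posteriors(tr, prof, gain_loss_model(g, l))
    oracle <- enum_posteriors(tr, prof, g, l)
    expect_equal(post[names(oracle)], oracle, tolerance = 1e-8)
    obs <- prof[!is.na(prof)]
    expect_equal(post[names(obs)], as.numeric(obs), ignore_attr = TRUE)
  }
})

test_that("root posterior is 1/2 on a symmetric half-present star", {
  tr <- parse_newick("(A:1,B:1,C:1,D:1)r;")
  post <- node_posteriors(tr, c(A = 1L, B = 1L, C = 0L, D = 0L),
                          gain_loss_model(1, 1))
  expect_equal(unname(post["r"]), 0.5, tolerance = 1e-12)
})

test_that("mixture likelihood combines categories on the likelihood scale", {
  tr <- simulate_tree(5, seed = 31)
  prof <- random_profile(tr)
  m2 <- gain_loss_model(c(0.3, 2), c(1, 0.5), weight = c(0.4, 0.6))
  ll1 <- enum_loglik(tr, prof, 0.3, 1)
  ll2 <- enum_loglik(tr, prof, 2, 0.5)
  expect_equal(pruning_loglik(tr, prof, m2),
               log(0.4 * exp(ll1) + 0.6 * exp(ll2)), tolerance = 1e-10)
  # mixture posteriors stay in [0, 1] and match observations
  post <- node_posteriors(tr, prof, m2)
  expect_true(all(post >= 0 & post <= 1))
})

test_that("rate fitting recovers symmetry and flags degenerate input", {
  # profiles closed under 0/1 swap on a symmetric tree => g ~= l
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1):0;")
  pats <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1), c(1, 0, 1, 0), c(0, 1, 0, 1))
  profs <- pats[rep(1:4, 25), ]
  colnames(profs) <- tr$tip.label
  rownames(profs) <- paste0("t", seq_len(nrow(profs)))
  fit <- suppressWarnings(fit_rates(tr, profs))
  expect_equal(fit$gain, fit$loss, tolerance = 0.02)

  allabs <- matrix(0L, 1, 4, dimnames = list("t1", tr$tip.label))
  expect_warning(fit0 <- fit_rates(tr, allabs), "bound")
  expect_equal(fit0$gain, 1e-6)
})

test_that("ML marginal states use the documented 0.5 tie-break", {
  p <- c(a = 0.51, b = 0.5, c = 1.0, d = 0.49)
  expect_equal(marginal_ml_states(p), c(a = 1L, b = 0L, c = 1L, d = 0L))
})

test_that("posterior probabilities are calibrated on simulated traits", {
  # among nodes with posterior near 0.7, about 70% are truly present
  tr <- simulate_tree(16, depth = 1, seed = 99)
  g <- 1; l <- 1
  m <- gain_loss_model(g, l)
  in_bin <- 0L; present <- 0L
  set.seed(77)
  for (i in 1:2000) {
    sim <- simulate_trait(tr, g, l)
    post <- node_posteriors(tr, sim$profile, m)
    internal <- setdiff(names(post), tr$tip.label)
    sel <- internal[post[internal] >= 0.65 & post[internal] <= 0.75]
    in_bin <- in_bin + length(sel)
    present <- present + sum(sim$states[sel] == 1L)
  }
  expect_gt(in_bin, 100)
  expect_lt(abs(present / in_bin - 0.7), 0.1)
})

test_that("profile matrices round-trip through TSV", {
  tr <- simulate_tree(6, seed = 5)
  profs <- rbind(t1 = random_profile(tr), t2 = random_profile(tr))
  profs["t2", 2] <- NA
  f <- tempfile(fileext = ".tsv")
  write_profiles(profs, f)
  back <- read_profiles(f)
  expect_equal(back, profs)
  expect_error(pruning_loglik(tr, c(ZZ = 1L), gain_loss_model(1, 1)),
               "not leaves")
})
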