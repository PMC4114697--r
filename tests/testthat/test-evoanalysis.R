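# Caterpillar fixture: focal leaf F under ancestors n1 (parent) .. n5
# (root), each branch of length 1.
cat_tree <- caterpillar_tree(5)
cat_chain <- ancestor_chain(cat_tree, "F")

post_vec <- function(chain_values, focal = 1) {
  p <- setNames(rep(1, length(cat_tree$tip.label) + cat_tree$Nnode),
                c(cat_tree$tip.label, cat_tree$node.label))
  p[cat_chain] <- chain_values
  p["F"] <- focal
  p
}

test_that("the posterior-chain rule stops at the first low ancestor", {
  # chain (parent -> root) = (0.95, 0.8, 0.71, 0.65, 0.9): the 0.65
  # breaks the chain, so the gain node is the 3rd ancestor despite the
  # confident node beyond it
  call <- gain_node_by_posterior(post_vec(c(0.95, 0.8, 0.71, 0.65, 0.9)),
                                 cat_tree, "F")
  expect_equal(call$node, cat_chain[3])
  expect_equal(call$age, 3)

  # parent below threshold: lineage-specific trait, age 0
  call0 <- gain_node_by_posterior(post_vec(c(0.69, 1, 1, 1, 1)),
                                  cat_tree, "F")
  expect_equal(call0$node, "F")
  expect_equal(call0$age, 0)

  # unbroken chain to the root
  callr <- gain_node_by_posterior(post_vec(rep(0.9, 5)), cat_tree, "F")
  expect_equal(callr$node, cat_chain[5])
  expect_equal(callr$age, 5)

  expect_error(gain_node_by_posterior(post_vec(rep(1, 5), focal = 0),
                                      cat_tree, "F"), "present")
})

test_that("the ML-state rule mirrors the chain walk on 0/1 states", {
  st <- function(v) {
    s <- setNames(rep(1L, length(cat_tree$tip.label) + cat_tree$Nnode),
                  c(cat_tree$tip.label, cat_tree$node.label))
    s[cat_chain] <- v
    s
  }
  expect_equal(gain_node_by_ml(st(c(1, 1, 0, 1, 1)), cat_tree, "F")$node,
               cat_chain[2])
  expect_equal(gain_node_by_ml(st(c(0, 1, 1, 1, 1)), cat_tree, "F")$node, "F")
  expect_equal(gain_node_by_ml(st(rep(1L, 5)), cat_tree, "F")$node,
               cat_chain[5])
})

test_that("gain calls are monotone in the posterior threshold", {
  set.seed(41)
  for (i in 1:50) {
    vals <- runif(5, 0.4, 1)
    ages <- vapply(c(0.7, 0.8, 0.9), function(th) {
      gain_node_by_posterior(post_vec(vals), cat_tree, "F", theta = th)$age
    }, numeric(1))
    expect_true(ages[3] <= ages[2] && ages[2] <= ages[1])
  }
})

test_that("evolutionary age is the patristic distance to the focal leaf", {
  call <- gain_node_by_posterior(post_vec(c(0.9, 0.9, 0.6, 0.6, 0.6)),
                                 cat_tree, "F")
  expect_equal(evolutionary_age(cat_tree, call), 2)
  expect_equal(evolutionary_age(cat_tree, call),
               patristic_distance(cat_tree, call$node, "F"))
})

test_that("scenario classification compares gain nodes on one lineage", {
  mk <- function(node) {
    structure(list(trait = "x", node = node,
                   age = patristic_distance(cat_tree, node, "F"),
                   posterior = 1, method = "posterior_chain", theta = 0.7,
                   focal_leaf = "F"),
              class = "gain_node_call")
  }
  co <- classify_scenario(mk(cat_chain[3]), mk(cat_chain[3]))
  expect_equal(co$scenario, "CO_GAINED")
  expect_equal(co$interaction_age, 3)

  pre <- classify_scenario(mk(cat_chain[2]), mk(cat_chain[4]))
  expect_equal(pre$scenario, "MBS_PRECEDES")
  expect_equal(pre$interaction_age, 2)

  suc <- classify_scenario(mk(cat_chain[4]), mk(cat_chain[1]))
  expect_equal(suc$scenario, "MBS_SUCCEEDS")
  expect_equal(suc$interaction_age, 1)

  # interaction age never exceeds either member age
  expect_true(all(c(co$interaction_age, pre$interaction_age,
                    suc$interaction_age) <=
                    c(3, 4, 4)))

  other <- mk(cat_chain[2]); other$focal_leaf <- "x1"
  expect_error(classify_scenario(mk(cat_chain[2]), other), "focal")
})

test_that("gene timing allows with/after and rejects impossible order", {
  mk <- function(node) {
    structure(list(trait = "x", node = node,
                   age = patristic_distance(cat_tree, node, "F"),
                   posterior = 1, method = "posterior_chain", theta = 0.7,
                   focal_leaf = "F"),
              class = "gain_node_call")
  }
  expect_equal(classify_gene_timing(mk(cat_chain[3]), mk(cat_chain[3])),
               "MBS_WITH_GENE")
  expect_equal(classify_gene_timing(mk(cat_chain[3]), mk(cat_chain[1])),
               "MBS_AFTER_GENE")
  expect_error(classify_gene_timing(mk(cat_chain[1]), mk(cat_chain[3])),
               "older")
})

test_that("Mann-Whitney exact enumeration matches hand-counted cases", {
  same <- mann_whitney_two_tailed(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p.value, 1.0)

  mw <- mann_whitney_two_tailed(c(1, 2), c(3, 4))
  expect_equal(mw$statistic, 4)
  expect_equal(mw$p.value, 2 / 6, tolerance = 1e-12)

  # tie-free exact p agrees with the reference implementation
  set.seed(51)
  for (i in 1:20) {
    xs <- runif(sample(3:7, 1))
    ys <- runif(sample(3:7, 1))
    ref <- stats::wilcox.test(xs, ys, exact = TRUE)$p.value
    expect_equal(mann_whitney_two_tailed(xs, ys)$p.value, ref,
                 tolerance = 1e-10, info = i)
  }
  expect_error(mann_whitney_two_tailed(numeric(0), 1), "non-empty")
})

test_that("the normal approximation tracks the exact p-value", {
  # balanced-to-moderate layouts at the exact/approximate switch point
  set.seed(52)
  for (i in 1:25) {
    n1 <- sample(6:10, 1)
    xs <- runif(n1)
    ys <- runif(16 - n1) + 0.1 * (i %% 3)
    pe <- mann_whitney_two_tailed(xs, ys, method = "exact")$p.value
    pn <- mann_whitney_two_tailed(xs, ys, method = "normal")$p.value
    expect_lt(abs(pe - pn), 0.01)
  }
})

test_that("forced gains are recovered from posteriors on fresh trees", {
  # posterior-chain recovery of loss-free forced gains, with posteriors
  # computed under the generating model (rate estimation is exercised
  # separately); residual failures come from short-branch ambiguity
  set.seed(620)
  model <- gain_loss_model(0.1, 1e-6, root_prior = c(1, 0))
  hits <- 0L
  n_rep <- 30L
  for (i in seq_len(n_rep)) {
    tr <- simulate_tree(32, depth = 1, seed = 9000 + i)
    focal <- tr$tip.label[1]
    chain <- ancestor_chain(tr, focal)
    node <- sample(chain[-length(chain)], 1)
    sim <- simulate_trait(tr, gain = 0.1, loss = 0, forced_gain = node)
    # the recoverable truth: oldest chain ancestor with an unbroken
    # presence path down to the focal leaf in the true states
    ok <- sim$states[chain] == 1L
    stop_at <- which(!ok)
    truth <- if (length(stop_at) == 0) chain[length(chain)] else
      if (stop_at[1] == 1L) focal else chain[stop_at[1] - 1L]
    post <- node_posteriors(tr, sim$profile, model)
    call <- gain_node_by_posterior(post, tr, focal, theta = 0.7)
    hits <- hits + (call$node == truth)
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("network tables summarize classified records", {
  rec <- data.frame(
    srna = c("s1", "s1", "s2"), target = c("t1", "t2", "t3"),
    srna_age = c(2, 2, 3), gene_age = c(4, 1, 3),
    interaction_age = c(2, 1, 3),
    scenario = c("CO_GAINED", "MBS_PRECEDES", "MBS_SUCCEEDS"),
    gene_timing = c("MBS_WITH_GENE", "MBS_AFTER_GENE", "MBS_WITH_GENE")
  )
  net <- build_network_table(rec)
  expect_equal(as.integer(net$scenario_counts), c(1L, 1L, 1L))
  expect_equal(sum(net$scenario_counts), nrow(rec))
  expect_equal(nrow(net$edges), 3L)

  one <- build_network_table(rec[rec$srna == "s1", ])
  expect_equal(nrow(one$nodes), 3L)  # 1 sRNA + 2 targets

  empty <- build_network_table(rec[0, ])
  expect_equal(nrow(empty$nodes), 0L)
  expect_equal(sum(empty$scenario_counts), 0L)
})
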