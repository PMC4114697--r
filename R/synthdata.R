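# Seeded generators for every input the pipeline consumes -- a random
# phylogeny, binary traits evolving under the two-state gain/loss CTMC
# with optionally forced gain nodes, and pre-aligned sequence windows
# in which a binding-site interval becomes (and stays) complementary
# to an sRNA site from a chosen ancestral node onward.  Every function
# is a pure function of its arguments and seed, so fixtures carry
# exact ground truth.

#' Simulate a pure-birth tree
#'
#' Yule (pure-birth) tree with exponential inter-speciation times,
#' rescaled so the root-to-tip depth equals `depth`.  Tips are labeled
#' `T001`, ... and internal nodes get deterministic post-order names.
#'
#' @param n_leaves Number of tips (>= 2).
#' @param depth Root-to-tip depth after rescaling (default 1).
#' @param seed Optional integer seed (fixes the output exactly).
#' @return A `phylo` object.
#' @export
simulate_tree <- function(n_leaves, depth = 1, seed = NULL) {
  stopifnot(n_leaves >= 2)
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(n_leaves, birth = 1, death = 0)
  tr$tip.label <- sprintf("T%03d", seq_len(n_leaves))
  d <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * depth / d
  tr$node.label <- NULL
  tr <- .autoname_nodes(tr)
  .validate_phylogeny(tr)
  tr
}

#' Simulate a binary trait on a tree
#'
#' The trait evolves along each branch under the two-state gain/loss
#' CTMC (rates may be zero here, unlike in the inference model: the
#' transition probabilities are taken in the appropriate limit).  With
#' `forced_gain`, the root starts absent and the state is set present
#' at the forced node, so with `loss = 0` its entire clade inherits the
#' trait and the forced node is the exact gain node.
#'
#' @param tree A `phylo` object.
#' @param gain,loss Non-negative rates.
#' @param seed Optional integer seed.
#' @param forced_gain Optional node label where the trait is forced on.
#' @return List with `profile` (named 0/1 vector over tips),
#'   `gain_node` (the forced node label or `NA`), and `states` (named
#'   0/1 vector over all nodes).
#' @export
simulate_trait <- function(tree, gain, loss, seed = NULL, forced_gain = NULL) {
  stopifnot(gain >= 0, loss >= 0)
  if (!is.null(seed)) set.seed(seed)
  idx <- .tree_index(tree)
  forced_i <- NA_integer_
  if (!is.null(forced_gain)) {
    forced_i <- match(forced_gain, idx$labels)
    if (is.na(forced_i)) stop("unknown forced gain node: ", forced_gain)
  }
  r <- gain + loss
  p01 <- function(t) if (gain == 0) 0 else (gain / r) * (1 - exp(-r * t))
  p10 <- function(t) if (loss == 0) 0 else (loss / r) * (1 - exp(-r * t))

  states <- integer(idx$N)
  root_state <- if (!is.na(forced_i) || r == 0) {
    0L
  } else {
    as.integer(stats::runif(1) < gain / r)
  }
  states[idx$root] <- if (!is.na(forced_i) && forced_i == idx$root) 1L else root_state
  for (v in rev(idx$postorder)) {  # preorder: parents before children
    for (ch in idx$children[[v]]) {
      t <- idx$blen[ch]
      p_flip <- if (states[v] == 0L) p01(t) else p10(t)
      flip <- stats::runif(1) < p_flip
      states[ch] <- if (flip) 1L - states[v] else states[v]
      if (!is.na(forced_i) && ch == forced_i) states[ch] <- 1L
    }
  }
  names(states) <- idx$labels
  list(
    profile = states[seq_len(idx$n_tip)],
    gain_node = if (is.null(forced_gain)) NA_character_ else forced_gain,
    states = states
  )
}

#' Simulate a pre-aligned set of sequence windows
#'
#' Sequences evolve down the tree by a symmetric single-nucleotide
#' (Jukes-Cantor-style) substitution process at rate `mu` per site per
#' unit branch length; no indels, so the rows are column-aligned by
#' construction.  Each entry of `sites` designates an interval that is
#' (a) optionally re-initialized to a planted sequence at a gain node
#' and (b) conserved (rate `rho * mu`) along branches whose child node
#' possesses the associated trait.  Rows without the trait carry
#' unconstrained sequence over the interval.  Optional gap injection
#' replaces a short run inside a site with `-` in randomly chosen rows,
#' to exercise gap-flag logic downstream.
#'
#' @param tree A `phylo` object.
#' @param seq_length Window length in nt.
#' @param mu Substitution rate per site per unit branch length.
#' @param sites List of site descriptors, each a list with `start`,
#'   `end` (0-based half-open), `states` (named 0/1 vector over all
#'   nodes, as from [simulate_trait()]`$states`), `rho` (conservation
#'   factor in \[0, 1\]), and optionally `plant_seq` plus `gain_node`
#'   (the interval is set to `plant_seq` when the traversal reaches
#'   `gain_node`) and `plant_mismatch` (number of random mismatches
#'   introduced into the planted copy).
#' @param rows Tip labels to output (default: all tips).
#' @param root_seq Optional root sequence (random A/C/G/U otherwise).
#' @param gap_rate Per-row probability of injecting a 3-nt gap run
#'   inside a random site interval (default 0).
#' @param seed Optional integer seed.
#' @return Named character vector of equal-length RNA rows; the full
#'   node-wise sequences are attached as attribute `node_seqs`.
#' @export
simulate_alignment <- function(tree, seq_length, mu, sites = list(),
                               rows = NULL, root_seq = NULL, gap_rate = 0,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- .tree_index(tree)
  alphabet <- c("A", "C", "G", "U")
  for (s in sites) {
    stopifnot(s$start >= 0, s$start < s$end, s$end <= seq_length)
  }
  if (is.null(root_seq)) {
    root_chars <- sample(alphabet, seq_length, replace = TRUE)
  } else {
    stopifnot(nchar(root_seq) == seq_length)
    root_chars <- strsplit(toupper(chartr("T", "U", root_seq)), "")[[1]]
  }

  site_cols <- lapply(sites, function(s) seq(s$start + 1L, s$end))
  rate_for <- function(node_lab) {
    rate <- rep(mu, seq_length)
    for (k in seq_along(sites)) {
      if (sites[[k]]$states[[node_lab]] == 1L) {
        rate[site_cols[[k]]] <- sites[[k]]$rho * mu
      }
    }
    rate
  }
  mutate <- function(chars, rate, t) {
    p_diff <- 0.75 * (1 - exp(-4 / 3 * rate * t))
    hit <- which(stats::runif(length(chars)) < p_diff)
    for (i in hit) {
      chars[i] <- sample(setdiff(alphabet, chars[i]), 1L)
    }
    chars
  }

  plant_into <- function(chars, s, k) {
    planted <- strsplit(toupper(chartr("T", "U", s$plant_seq)), "")[[1]]
    stopifnot(length(planted) == length(site_cols[[k]]))
    nm <- if (is.null(s$plant_mismatch)) 0L else s$plant_mismatch
    if (nm > 0) {
      at <- sample(seq_along(planted), nm)
      for (i in at) planted[i] <- sample(setdiff(alphabet, planted[i]), 1L)
    }
    chars[site_cols[[k]]] <- planted
    chars
  }
  root_lab <- idx$labels[idx$root]
  for (k in seq_along(sites)) {
    s <- sites[[k]]
    if (!is.null(s$plant_seq) && identical(s$gain_node, root_lab)) {
      root_chars <- plant_into(root_chars, s, k)
    }
  }
  seqs <- vector("list", idx$N)
  seqs[[idx$root]] <- root_chars
  for (v in rev(idx$postorder)) {  # preorder
    for (ch in idx$children[[v]]) {
      lab <- idx$labels[ch]
      chars <- mutate(seqs[[v]], rate_for(lab), idx$blen[ch])
      for (k in seq_along(sites)) {
        s <- sites[[k]]
        if (!is.null(s$plant_seq) && !is.null(s$gain_node) &&
            identical(lab, s$gain_node)) {
          chars <- plant_into(chars, s, k)
        }
      }
      seqs[[ch]] <- chars
    }
  }

  if (is.null(rows)) rows <- tree$tip.label
  out <- vapply(rows, function(g) {
    paste(seqs[[match(g, idx$labels)]], collapse = "")
  }, character(1))
  if (gap_rate > 0 && length(sites) > 0) {
    for (g in seq_along(out)) {
      if (stats::runif(1) < gap_rate) {
        k <- sample.int(length(sites), 1L)
        s <- sites[[k]]
        glen <- min(3L, s$end - s$start)
        cand_at <- seq(s$start + 1L, s$end - glen + 1L)
        at <- cand_at[sample.int(length(cand_at), 1L)]
        chars <- strsplit(out[g], "")[[1]]
        chars[at:(at + glen - 1L)] <- "-"
        out[g] <- paste(chars, collapse = "")
      }
    }
  }
  names(out) <- rows
  attr(out, "node_seqs") <- stats::setNames(
    vapply(seqs, paste, character(1), collapse = ""), idx$labels)
  out
}

#' Simulation configuration
#'
#' Bundles every knob of [make_fixture_dataset()].  Two presets are
#' provided: `"minimal"` (1 sRNA, 2 targets, 3 interactions, one per
#' scenario class, 16 leaves) and `"benchmark"` (15 sRNAs, 49 targets,
#' 60 interactions with scenario mix 6 co-gained / 2 site-first /
#' 52 sRNA-first and gene-timing mix 18 with-gene / 42 after-gene,
#' 64 leaves) -- the composition of the experimentally determined
#' interaction set the pipeline is designed around.
#'
#' @param preset `"minimal"`, `"benchmark"`, or `"custom"`.
#' @param seed Master seed; all sub-generators derive their seeds from
#'   it deterministically.
#' @param ... Overrides of individual fields (see the function body for
#'   the full list and defaults).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(preset = c("benchmark", "minimal", "custom"),
                       seed = 1L, ...) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset, seed = as.integer(seed),
    n_leaves = 64L, depth = 0.5,
    n_srnas = 15L, n_targets = 49L, n_interactions = 60L,
    scenario_counts = c(CO_GAINED = 6L, MBS_PRECEDES = 2L, MBS_SUCCEEDS = 52L),
    timing_after = 42L,
    n_cis = 31L, n_trans = 58L, n_other = 13L,
    srna_length = 100L, window_length = 200L, site_length = 14L,
    mu = 0.3, rho = 0.05, pad = 5L,
    family_flip_rate = 0.02, gap_rate = 0, plant_mismatch = 0L
  )
  if (preset == "minimal") {
    base[c("n_leaves", "n_srnas", "n_targets", "n_interactions")] <-
      list(16L, 1L, 2L, 3L)
    base$scenario_counts <- c(CO_GAINED = 1L, MBS_PRECEDES = 1L,
                              MBS_SUCCEEDS = 1L)
    base$timing_after <- 2L
    base[c("n_cis", "n_trans", "n_other")] <- list(3L, 3L, 2L)
    base[c("srna_length", "window_length", "site_length")] <-
      list(80L, 120L, 12L)
  }
  over <- list(...)
  bad <- setdiff(names(over), names(base))
  if (length(bad) > 0) stop("unknown sim_config field(s): ",
                            paste(bad, collapse = ", "))
  base[names(over)] <- over
  structure(base, class = "sim_config")
}

# Deterministic sub-seeds below 2^31 derived from the master seed.
.derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Generate a complete fixture dataset with ground truth
#'
#' Writes every input the pipeline reads -- tree (newick), ncRNA-family
#' and sRNA and target-gene phyletic profiles (TSV), per-sRNA and
#' per-target gapped FASTA alignments, an interaction coordinate table
#' (TSV, 1-based inclusive coordinates) -- plus `truth.tsv` holding the
#' true gain nodes, ages, scenario and gene-timing class of every
#' interaction, and a `manifest.tsv` naming the focal leaf, preset and
#' seed.  All randomness derives from `config$seed`, so the directory
#' is byte-identical across runs with the same configuration.
#'
#' The generator forces each trait's gain at a chosen ancestor of the
#' focal leaf (loss-free inheritance, so presence profiles are exact
#' clades) and plants, at each binding-site gain node, the reverse
#' complement of the focal sRNA-site sequence into the target window,
#' conserved at `rho * mu` within the trait-bearing lineages.  Family
#' profiles additionally receive a small per-leaf flip noise
#' (`family_flip_rate`) to emulate annotation error.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the tree, focal leaf, truth table and
#'   file paths.
#' @export
make_fixture_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "alignments"), showWarnings = FALSE)
  seeds <- .derive_seeds(config$seed, 12L)

  # -- tree: retry sub-seeds until the focal chain is deep enough -----
  tree <- NULL
  for (k in 0:20) {
    cand_tree <- simulate_tree(config$n_leaves, config$depth,
                               seed = (seeds[1] + k) %% .Machine$integer.max)
    chains <- lapply(cand_tree$tip.label, function(tp)
      ancestor_chain(cand_tree, tp))
    depth_k <- lengths(chains)
    if (max(depth_k) >= 6L) {
      tree <- cand_tree
      focal <- cand_tree$tip.label[which.max(depth_k)]
      chain <- chains[[which.max(depth_k)]]
      break
    }
  }
  if (is.null(tree)) stop("could not simulate a tree with a deep focal chain")
  K <- length(chain)  # chain[1] = parent (youngest) ... chain[K] = root

  .resample <- function(x, n = 1L) x[sample.int(length(x), n)]

  clade_profile <- function(node_lab) {
    simulate_trait(tree, 0, 0, forced_gain = node_lab)$profile
  }
  clade_states <- function(node_lab) {
    simulate_trait(tree, 0, 0, forced_gain = node_lab)$states
  }
  age_of <- function(node_lab) patristic_distance(tree, node_lab, focal)

  # -- interaction design: gain positions on the focal chain ----------
  set.seed(seeds[2])
  scen <- rep(names(config$scenario_counts), config$scenario_counts)
  scen <- sample(scen)
  n_int <- config$n_interactions
  stopifnot(length(scen) == n_int)
  srna_ids <- sprintf("S%02d", seq_len(config$n_srnas))
  srna_of <- rep(srna_ids, length.out = n_int)
  # deep sRNA gains: positions in the older half of the chain, keeping
  # at least one younger internal node and one older node available
  p_lo <- max(3L, ceiling(K / 2))
  p_hi <- K - 1L
  srna_pos <- stats::setNames(
    sample(seq(p_lo, p_hi), config$n_srnas, replace = TRUE), srna_ids)

  mbs_pos <- integer(n_int)
  for (i in seq_len(n_int)) {
    p <- srna_pos[[srna_of[i]]]
    mbs_pos[i] <- switch(scen[i],
      CO_GAINED = p,
      MBS_PRECEDES = .resample(seq(p + 1L, K)),
      MBS_SUCCEEDS = .resample(seq(2L, p - 1L))
    )
  }
  # gene timing: "after" needs an older node than the binding site
  timing <- character(n_int)
  gene_pos <- integer(n_int)
  quota_after <- config$timing_after
  for (i in sample(seq_len(n_int))) {
    can_after <- mbs_pos[i] < K
    if (quota_after > 0 && can_after) {
      timing[i] <- "MBS_AFTER_GENE"
      gene_pos[i] <- .resample(seq(mbs_pos[i] + 1L, K))
      quota_after <- quota_after - 1L
    } else {
      timing[i] <- "MBS_WITH_GENE"
      gene_pos[i] <- mbs_pos[i]
    }
  }

  # -- target identities: share a target between two interactions of
  # equal gene position (different sRNAs) until n_targets is reached --
  target_of <- sprintf("tg%02d", seq_len(n_int))
  n_to_share <- n_int - config$n_targets
  if (n_to_share > 0) {
    shared <- 0L
    used <- rep(FALSE, n_int)
    for (i in seq_len(n_int)) {
      if (shared >= n_to_share) break
      if (used[i]) next
      j <- which(!used & seq_len(n_int) > i & gene_pos == gene_pos[i])
      if (length(j) > 0) {
        j <- j[1]
        target_of[j] <- target_of[i]
        used[i] <- TRUE; used[j] <- TRUE
        shared <- shared + 1L
      }
    }
    target_of <- stats::setNames(
      sprintf("tg%02d", as.integer(factor(target_of, levels = unique(target_of)))),
      NULL)
  }
  targets <- unique(target_of)

  # -- site coordinates ----------------------------------------------
  sl <- config$site_length
  sbs_slots <- seq(10L, by = sl + 8L,
                   length.out = ceiling(n_int / config$n_srnas))
  sbs_start <- integer(n_int)
  for (s in srna_ids) {
    ii <- which(srna_of == s)
    sbs_start[ii] <- sbs_slots[seq_along(ii)]
  }
  mbs_slots <- seq(20L, by = sl + 26L, length.out = 4L)
  mbs_start <- integer(n_int)
  for (tg in targets) {
    ii <- which(target_of == tg)
    mbs_start[ii] <- mbs_slots[seq_along(ii)]
  }

  # -- profiles -------------------------------------------------------
  srna_profiles <- do.call(rbind, lapply(srna_ids, function(s)
    clade_profile(chain[srna_pos[[s]]])))
  rownames(srna_profiles) <- srna_ids

  gene_pos_of_target <- stats::setNames(
    gene_pos[match(targets, target_of)], targets)
  gene_profiles <- do.call(rbind, lapply(targets, function(tg)
    clade_profile(chain[gene_pos_of_target[[tg]]])))
  rownames(gene_profiles) <- targets

  # -- family profiles (cis / trans / other) with flip noise ----------
  set.seed(seeds[3])
  fam_group <- c(rep("cis", config$n_cis), rep("trans", config$n_trans),
                 rep("other", config$n_other))
  fam_ids <- sprintf("fam_%s_%02d", fam_group,
                     stats::ave(seq_along(fam_group), fam_group, FUN = seq_along))
  fam_pos <- vapply(fam_group, function(g) {
    switch(g,
      cis = .resample(seq(max(2L, ceiling(2 * K / 3)), K)),
      trans = .resample(seq(2L, max(2L, floor(K / 2)))),
      other = .resample(seq(K - 1L, K)))
  }, integer(1))
  fam_profiles <- do.call(rbind, lapply(fam_pos, function(p)
    clade_profile(chain[p])))
  rownames(fam_profiles) <- fam_ids
  if (config$family_flip_rate > 0) {
    flips <- matrix(stats::runif(length(fam_profiles)) < config$family_flip_rate,
                    nrow = nrow(fam_profiles))
    fam_profiles <- abs(fam_profiles - as.integer(flips))
    fam_profiles[, focal] <- 1L  # the focal genome is annotated by definition
  }

  # -- sRNA alignments ------------------------------------------------
  srna_states <- lapply(srna_ids, function(s) clade_states(chain[srna_pos[[s]]]))
  names(srna_states) <- srna_ids
  srna_msas <- list()
  focal_sbs <- character(n_int)
  for (si in seq_along(srna_ids)) {
    s <- srna_ids[si]
    ii <- which(srna_of == s)
    sites <- lapply(ii, function(i) list(
      start = sbs_start[i], end = sbs_start[i] + sl,
      states = srna_states[[s]], rho = config$rho
    ))
    rows <- names(which(srna_profiles[s, ] == 1L))
    msa <- simulate_alignment(tree, config$srna_length, config$mu,
                              sites = sites, rows = rows,
                              seed = seeds[4] + si)
    srna_msas[[s]] <- msa
    for (i in ii) {
      focal_sbs[i] <- substr(msa[[focal]], sbs_start[i] + 1L, sbs_start[i] + sl)
    }
  }

  # -- target alignments with planted complementary sites -------------
  mbs_states <- lapply(seq_len(n_int), function(i) clade_states(chain[mbs_pos[i]]))
  target_msas <- list()
  for (ti in seq_along(targets)) {
    tg <- targets[ti]
    ii <- which(target_of == tg)
    sites <- lapply(ii, function(i) list(
      start = mbs_start[i], end = mbs_start[i] + sl,
      states = mbs_states[[i]], rho = config$rho,
      plant_seq = revcomp(focal_sbs[i]), gain_node = chain[mbs_pos[i]],
      plant_mismatch = config$plant_mismatch
    ))
    rows <- names(which(gene_profiles[tg, ] == 1L))
    target_msas[[tg]] <- simulate_alignment(
      tree, config$window_length, config$mu, sites = sites, rows = rows,
      gap_rate = config$gap_rate, seed = seeds[5] + ti)
  }

  # -- truth table ----------------------------------------------------
  truth <- data.frame(
    interaction_id = sprintf("I%03d", seq_len(n_int)),
    srna = srna_of, target = target_of,
    scenario = scen, gene_timing = timing,
    srna_gain_node = chain[srna_pos[srna_of]],
    gene_gain_node = chain[gene_pos],
    mbs_gain_node = chain[mbs_pos],
    srna_age = vapply(chain[srna_pos[srna_of]], age_of, numeric(1)),
    gene_age = vapply(chain[gene_pos], age_of, numeric(1)),
    mbs_age = vapply(chain[mbs_pos], age_of, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  truth$interaction_age <- pmin(truth$srna_age, truth$mbs_age)

  interactions <- data.frame(
    interaction_id = truth$interaction_id,
    srna = srna_of, target = target_of,
    sbs_start = sbs_start + 1L, sbs_end = sbs_start + sl,
    mbs_start = mbs_start + 1L, mbs_end = mbs_start + sl,
    stringsAsFactors = FALSE
  )

  # -- write everything ----------------------------------------------
  paths <- list(
    tree = file.path(out_dir, "tree.nwk"),
    srna_profiles = file.path(out_dir, "srna_profiles.tsv"),
    gene_profiles = file.path(out_dir, "gene_profiles.tsv"),
    families = file.path(out_dir, "families.tsv"),
    family_groups = file.path(out_dir, "family_groups.tsv"),
    interactions = file.path(out_dir, "interactions.tsv"),
    truth = file.path(out_dir, "truth.tsv"),
    manifest = file.path(out_dir, "manifest.tsv")
  )
  writeLines(write_newick(tree), paths$tree)
  write_profiles(srna_profiles, paths$srna_profiles)
  write_profiles(gene_profiles, paths$gene_profiles)
  write_profiles(fam_profiles, paths$families)
  utils::write.table(
    data.frame(family = fam_ids, group = fam_group),
    paths$family_groups, sep = "\t", quote = FALSE, row.names = FALSE)
  con <- file(paths$interactions, "w")
  writeLines("# coordinates are 1-based inclusive on the ungapped focal row",
             con)
  utils::write.table(interactions, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(key = c("preset", "seed", "focal_leaf", "pad", "site_length"),
               value = c(config$preset, config$seed, focal, config$pad,
                         config$site_length)),
    paths$manifest, sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in names(srna_msas)) {
    write_alignment(srna_msas[[s]],
                    file.path(out_dir, "alignments", paste0("srna_", s, ".fasta")))
  }
  for (tg in names(target_msas)) {
    write_alignment(target_msas[[tg]],
                    file.path(out_dir, "alignments", paste0("target_", tg, ".fasta")))
  }

  invisible(list(tree = tree, focal = focal, chain = chain, truth = truth,
                 interactions = interactions, paths = paths,
                 out_dir = out_dir))
}
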