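# End-to-end orchestration: from a fixture-style input directory
# (tree, phyletic profiles, alignments, interaction coordinates) to
# the summary tables -- per-family gain nodes and ages with the
# cis-vs-trans age comparison, and per-interaction scenario calls with
# aggregate counts.

#' Read an interaction coordinate table
#'
#' TSV with columns `interaction_id`, `srna`, `target`, `sbs_start`,
#' `sbs_end`, `mbs_start`, `mbs_end` in 1-based inclusive coordinates
#' on the ungapped focal row; converted to the package-internal 0-based
#' half-open convention.
#'
#' @param path TSV path.
#' @return Data frame with 0-based half-open coordinates.
#' @export
read_interactions <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  for (col in c("sbs_start", "mbs_start")) df[[col]] <- df[[col]] - 1L
  df
}

#' Reconstruct family gain nodes, ages and group comparison
#'
#' Fits one gain/loss model to all family profiles, reconstructs ML
#' marginal states per family, walks the focal lineage for the gain
#' node (ML-state rule), reports per-family ages, counts families per
#' group at every direct ancestor of the focal leaf, and compares the
#' age distributions of the cis- and trans-acting groups with a
#' two-tailed Mann-Whitney test.
#'
#' @param tree A `phylo` object.
#' @param families Traits-by-genomes 0/1 matrix of family profiles.
#' @param groups Data frame with columns `family`, `group` (levels
#'   `cis`, `trans`, `other`); must cover every family.
#' @param focal_leaf Focal tip label.
#' @param n_categories Rate categories of the fitted mixture (default 2).
#' @return List with `table` (family, group, gain node, age),
#'   `ancestor_counts` (per-chain-node family counts by group),
#'   `mw` (Mann-Whitney result cis vs trans), and the fitted `model`.
#' @export
run_family_ages <- function(tree, families, groups, focal_leaf,
                            n_categories = 2L) {
  missing_fam <- setdiff(rownames(families), groups$family)
  if (length(missing_fam) > 0) {
    stop("grouping is missing families: ", paste(missing_fam, collapse = ", "))
  }
  model <- suppressWarnings(fit_rates(tree, families, n_categories = n_categories))
  chain <- ancestor_chain(tree, focal_leaf)
  states_mat <- matrix(NA_integer_, nrow(families),
                       length(tree$tip.label) + tree$Nnode)
  rows <- lapply(rownames(families), function(fam) {
    post <- node_posteriors(tree, families[fam, ], model)
    states <- marginal_ml_states(post)
    states_mat[match(fam, rownames(families)), ] <<- states
    if (states[[focal_leaf]] != 1L) {
      return(data.frame(family = fam,
                        group = groups$group[match(fam, groups$family)],
                        gain_node = NA_character_, age = NA_real_,
                        stringsAsFactors = FALSE))
    }
    call <- gain_node_by_ml(states, tree, focal_leaf, trait = fam)
    data.frame(family = fam, group = groups$group[match(fam, groups$family)],
               gain_node = call$node, age = call$age, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  colnames(states_mat) <- c(tree$tip.label, tree$node.label)
  ancestor_counts <- do.call(rbind, lapply(chain, function(nd) {
    present <- states_mat[, nd] == 1L
    data.frame(node = nd,
               cis = sum(present & tab$group == "cis", na.rm = TRUE),
               trans = sum(present & tab$group == "trans", na.rm = TRUE),
               other = sum(present & tab$group == "other", na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  cis_ages <- tab$age[tab$group == "cis" & !is.na(tab$age)]
  trans_ages <- tab$age[tab$group == "trans" & !is.na(tab$age)]
  mw <- if (length(cis_ages) > 0 && length(trans_ages) > 0) {
    mann_whitney_two_tailed(cis_ages, trans_ages)
  } else {
    NULL
  }
  list(table = tab, ancestor_counts = ancestor_counts, mw = mw, model = model)
}

#' Classify all interactions of an input directory
#'
#' For every interaction: extracts the sRNA-site and mRNA-site
#' sequences of each genome from the gapped alignments (padded by
#' `pad` nt for context and gap detection), computes the duplex energy
#' of each ortholog core-site pair against the focal-genome reference
#' pairing (energies are scored on the unpadded cores: chance pairing
#' within the unconstrained pads would otherwise inflate the reference
#' energy and starve the ratio rule), calls binding-site presence by
#' the relative-energy rule (genomes lacking the target-gene ortholog,
#' or with an alignment gap across the core site, are absent; genomes
#' lacking the sRNA contribute the clade-consensus ancestral sRNA
#' site), reconstructs sRNA / gene / binding-site posteriors under one
#' jointly fitted gain/loss model, calls gain nodes by the
#' posterior-chain rule at `theta`, and classifies the order of
#' appearance.  Near-duplicate records (closer than `merge_dist` nt on
#' both molecules) are merged first.
#'
#' @param dir Input directory as written by [make_fixture_dataset()]
#'   (tree.nwk, srna_profiles.tsv, gene_profiles.tsv, interactions.tsv,
#'   alignments/).
#' @param theta Posterior threshold for the gain chain (default 0.7).
#' @param ratio Relative-energy threshold (default 0.9).
#' @param pad Site padding in nt (default 5).
#' @param merge_dist Interaction merge distance in nt (default 10).
#' @param params Duplex parameters (default [default_duplex_params()]).
#' @param focal_leaf Focal tip; default: the `focal_leaf` entry of
#'   `manifest.tsv` in `dir`.
#' @param n_categories Rate categories of the jointly fitted gain/loss
#'   mixture (default 2: one slow category carries the phylogenetically
#'   clean profiles, one fast category absorbs noisy ones, in the
#'   spirit of GLOOME's mixture models; a single category over-smooths
#'   deep clean clades when the profile set is heterogeneous).
#' @return List with `table` (one row per interaction: gain nodes,
#'   ages, scenario, gene timing), `scenario_counts`, `timing_counts`,
#'   `mbs_profiles` (the energy-derived presence matrix), the fitted
#'   `model`, and `network` (from [build_network_table()]).
#' @export
run_interaction_scenarios <- function(dir, theta = 0.7, ratio = 0.9,
                                      pad = 5L, merge_dist = 10L,
                                      params = default_duplex_params(),
                                      focal_leaf = NULL, n_categories = 2L) {
  tree <- parse_newick(paste(readLines(file.path(dir, "tree.nwk")),
                             collapse = ""))
  srna_profiles <- read_profiles(file.path(dir, "srna_profiles.tsv"))
  gene_profiles <- read_profiles(file.path(dir, "gene_profiles.tsv"))
  interactions <- read_interactions(file.path(dir, "interactions.tsv"))
  if (is.null(focal_leaf)) {
    man <- utils::read.delim(file.path(dir, "manifest.tsv"),
                             stringsAsFactors = FALSE)
    focal_leaf <- man$value[man$key == "focal_leaf"]
  }
  interactions <- distinct_interactions(interactions, min_dist = merge_dist)
  genomes <- tree$tip.label

  # -- binding-site presence per genome from duplex energies ----------
  mbs_profiles <- matrix(0L, nrow(interactions), length(genomes),
                         dimnames = list(interactions$interaction_id, genomes))
  dg_ref_all <- numeric(nrow(interactions))
  for (i in seq_len(nrow(interactions))) {
    rec <- interactions[i, ]
    srna_msa <- read_alignment(
      file.path(dir, "alignments", paste0("srna_", rec$srna, ".fasta")))
    tgt_msa <- read_alignment(
      file.path(dir, "alignments", paste0("target_", rec$target, ".fasta")))
    sbs <- map_site_columns(srna_msa, focal_leaf, rec$sbs_start, rec$sbs_end,
                            pad = pad)
    mbs <- map_site_columns(tgt_msa, focal_leaf, rec$mbs_start, rec$mbs_end,
                            pad = pad)
    ref_sbs_seq <- sbs$core_seq[sbs$genome == focal_leaf]
    ref_mbs_seq <- mbs$core_seq[mbs$genome == focal_leaf]
    ref_dx <- duplex_energy(ref_sbs_seq, ref_mbs_seq, params)
    if (ref_dx$no_duplex || ref_dx$energy >= 0) {
      stop("reference pairing of ", rec$interaction_id, " is not stabilizing")
    }
    dg_ref_all[i] <- ref_dx$energy
    # ancestral sRNA site: consensus over the rows of genomes having the sRNA
    anc_sbs <- consensus_site(vapply(
      sbs$core_seq[sbs$genome %in%
                     names(which(srna_profiles[rec$srna, ] == 1L))],
      identity, character(1)))
    for (g in genomes) {
      ortho <- gene_profiles[rec$target, g] == 1L
      if (!ortho || !g %in% mbs$genome) next
      row_m <- mbs[mbs$genome == g, ]
      sbs_seq <- if (srna_profiles[rec$srna, g] == 1L && g %in% sbs$genome) {
        sbs$core_seq[sbs$genome == g]
      } else {
        anc_sbs
      }
      dx <- duplex_energy(sbs_seq, row_m$core_seq, params)
      mbs_profiles[i, g] <- mbs_call(
        if (dx$no_duplex) NA_real_ else dx$energy,
        dg_ref_all[i], ratio = ratio, gap_flag = row_m$gap_flag,
        ortholog_present = TRUE)
    }
  }

  # -- joint rate fit and gain calls ----------------------------------
  all_profiles <- rbind(srna_profiles, gene_profiles, mbs_profiles)
  model <- suppressWarnings(
    fit_rates(tree, all_profiles, n_categories = n_categories))

  call_of <- function(profile, trait) {
    post <- node_posteriors(tree, profile, model)
    gain_node_by_posterior(post, tree, focal_leaf, theta = theta,
                           trait = trait)
  }
  srna_calls <- lapply(rownames(srna_profiles), function(s)
    call_of(srna_profiles[s, ], s))
  names(srna_calls) <- rownames(srna_profiles)
  gene_calls <- lapply(rownames(gene_profiles), function(tg)
    call_of(gene_profiles[tg, ], tg))
  names(gene_calls) <- rownames(gene_profiles)

  rows <- lapply(seq_len(nrow(interactions)), function(i) {
    rec <- interactions[i, ]
    sbs_call <- srna_calls[[rec$srna]]
    gene_call <- gene_calls[[rec$target]]
    mbs_gain <- call_of(mbs_profiles[i, ], rec$interaction_id)
    scen <- classify_scenario(sbs_call, mbs_gain)
    timing <- classify_gene_timing(gene_call, mbs_gain)
    data.frame(
      interaction_id = rec$interaction_id, srna = rec$srna,
      target = rec$target,
      srna_gain_node = sbs_call$node, srna_age = sbs_call$age,
      gene_gain_node = gene_call$node, gene_age = gene_call$age,
      mbs_gain_node = mbs_gain$node, mbs_age = mbs_gain$age,
      dg_ref = dg_ref_all[i],
      scenario = scen$scenario, interaction_age = scen$interaction_age,
      gene_timing = timing, stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  net <- build_network_table(tab)
  list(table = tab, scenario_counts = net$scenario_counts,
       timing_counts = net$timing_counts, mbs_profiles = mbs_profiles,
       model = model, network = net)
}

#' Write the result tables of a run
#'
#' Writes the per-interaction table, the node/edge network tables and
#' the count summaries as TSVs, each carrying a comment header with a
#' manifest fingerprint (thresholds and input directory), so outputs
#' are traceable to the run that produced them.
#'
#' @param result A [run_interaction_scenarios()] result.
#' @param out_dir Output directory.
#' @param manifest Named list of run settings to fingerprint.
#' @return Invisibly, the manifest hash.
#' @export
save_run <- function(result, out_dir, manifest = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .fnv1a(paste(names(manifest), unlist(manifest),
                       collapse = ";", sep = "="))
  hdr <- sprintf("# manifest %s | %s", hash,
                 paste(names(manifest), unlist(manifest),
                       sep = "=", collapse = " "))
  wr <- function(df, name) {
    con <- file(file.path(out_dir, name), "w")
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  wr(result$table, "interactions_classified.tsv")
  wr(result$network$nodes, "network_nodes.tsv")
  wr(result$network$edges, "network_edges.tsv")
  counts <- data.frame(class = c(names(result$scenario_counts),
                                 names(result$timing_counts)),
                       count = c(as.integer(result$scenario_counts),
                                 as.integer(result$timing_counts)))
  wr(counts, "class_counts.tsv")
  invisible(hash)
}

# Simple 31-bit polynomial fingerprint of a string (keeps outputs
# traceable to a run without an external digest dependency).
.fnv1a <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
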