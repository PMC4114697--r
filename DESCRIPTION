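Package: srnaevo
Title: Evolutionary Reconstruction of Bacterial Small RNAs and Their
    mRNA Binding Sites
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs the evolutionary history of bacterial small
    regulatory RNAs (sRNAs) and of their binding sites on target mRNAs
    on a fixed rooted phylogeny.  Implements a two-state (absent/present)
    gain/loss continuous-time Markov model with maximum-likelihood rate
    fitting and marginal ancestral posteriors (Felsenstein pruning with
    an up-down pass), gain-node calling along the focal lineage with
    posterior-chain and ML-state rules, evolutionary ages as patristic
    distances, an intermolecular RNA-RNA duplex free-energy model
    (nearest-neighbor stacks with affine loops) used to call mRNA
    binding-site presence by a relative-energy rule, classification of
    the order of appearance of sRNA, target gene, and binding site, and
    a fully seeded synthetic-data generator so the whole pipeline is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
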