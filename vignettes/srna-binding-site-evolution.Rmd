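---
title: "Reconstructing the evolution of bacterial sRNAs and their mRNA binding sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing the evolution of bacterial sRNAs and their mRNA binding sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnaevo)
```

## The question

Bacterial small regulatory RNAs (sRNAs) act by base-pairing with
target mRNAs: a short region of the sRNA (its binding site, here
*sBS*) pairs with a site on the mRNA (the *mBS*), usually near the
translation start.  A regulatory interaction can only exist once both
sites exist, so for each experimentally known sRNA–mRNA pair one can
ask: in which ancestor did the sRNA appear, in which ancestor did the
target gene appear, and in which ancestor did the mRNA binding site
appear?  Ordering these three events across many interactions
distinguishes interactions whose binding site was co-gained with the
sRNA, predated it, or evolved later to meet an existing sRNA — and
thereby tests the model that an sRNA is retained because an early
interaction put it under selection, after which additional targets
accumulate binding sites that fit it.

This package implements that analysis as a reproducible pipeline on a
fixed rooted species phylogeny, together with a fully seeded synthetic
data generator so every stage is testable without access to the
original annotation databases.

## The gain/loss model

Presence/absence of a trait (an ncRNA family, a target gene, or a
binding site) across the genomes at the tips of the tree is a
*phyletic profile*.  Each trait evolves independently along the tree
under a two-state continuous-time Markov chain with gain rate $g$
(0→1) and loss rate $l$ (1→0); for a branch of length $t$ (branch
lengths are in amino-acid substitutions per position, inherited from
the protein-based species tree, and are never re-estimated),

$$P_{01}(t) = \pi_1\,(1 - e^{-rt}), \qquad
  P_{10}(t) = \pi_0\,(1 - e^{-rt}),$$

with $r = g + l$, $\pi_1 = g/r$, $\pi_0 = l/r$.  `pruning_loglik()`
computes trait likelihoods by Felsenstein pruning (missing genomes
enter as partial likelihood $(1,1)$), `fit_rates()` maximizes the
summed log-likelihood over all profiles by bounded quasi-Newton search
over log-rates from a grid of restarts (rates bounded to
$[10^{-6}, 10^{3}]$; a fit at a bound warns), and `node_posteriors()`
returns the marginal posterior probability that each ancestral node
possessed the trait, via an inside–outside (up–down) pass.  All three
are checked against brute-force enumeration over all joint internal
state assignments on small trees.

**Rate categories.** `fit_rates(n_categories = K)` fits a $K$-component
rate mixture (weights and per-category $(g_k, l_k)$ jointly by ML;
posteriors combine categories by their data responsibility).  The
single-category model is the identifiable core and the default of
`fit_rates()`; the *pipeline* functions default to `n_categories = 2`
because their profile collections are heterogeneous — phylogenetically
clean clade-like profiles (sRNAs, genes) mixed with noisy
energy-derived binding-site profiles.  A single category fitted to
such a mixture lands on intermediate rates that over-smooth the clean
profiles: posteriors along deep clean clades sag below the calling
threshold and gain nodes are called one or two nodes too young.  With
two categories the fit separates a slow "signal" component from a
fast noise-absorbing one and the calls sharpen; this mirrors the use
of mixture models in standard gain/loss reconstruction software.

**Root prior.** Defaults to the per-category stationary distribution;
an explicit $(p_0, p_1)$ prior can be supplied.  Stationarity couples
the root state to the fitted rates, which is questionable for trait
sets ascertained in one focal genome (they are mostly young, so the
root was mostly absent); the explicit-prior override exists for
exactly that situation and is used in the gain-node recovery
experiments.

## Gain nodes and ages

For a focal genome (typically *E. coli*), the *gain
node* of a trait is found by walking the focal leaf's ancestor chain
upward: the gain node is the oldest ancestor $A$ such that **every**
node on the path from $A$ down to the leaf has posterior $\ge
\theta$ (default 0.7).  The unbroken-chain requirement deliberately
refuses to jump across a low-posterior gap, which would otherwise
conflate a loss followed by a regain with a single ancient gain.  If
the leaf's own parent is already below $\theta$ the trait is
lineage-specific (gain node = leaf, age 0); if the chain never breaks
the gain node is the root.  `gain_node_by_ml()` applies the same walk
to maximum-likelihood marginal states (state 1 iff posterior > 0.5;
an exact 0.5 tie is called absent), which is the convention used for
the broad ncRNA-family age survey where per-node confidence is less
critical.  The *evolutionary age* of a trait is the patristic distance
from its gain node to the focal leaf.

Two properties of the walk are worth noting.  It is monotone in
$\theta$: raising the threshold can only produce younger (or equal)
gain nodes, which is what the robustness checks at $\theta \in \{0.7,
0.8, 0.9\}$ exploit.  And its failure modes are geometric: when the
branch into the true gain node is very short, or the sister clade
just above it is a single leaf, "one gain at the node" and "two gains
just below it" (or "presence above plus one loss") have comparable
likelihoods and the call lands one node off.  In seeded experiments
with forced loss-free gains on 64-leaf trees, the posterior-chain rule
recovers the exact true gain node in over 90% of replicates when
posteriors are computed under the generating model; the residual
errors are these short-branch ambiguities.  With rates *re-fitted*
from clade-like profiles under the stationary root prior, recovery
degrades because pure-gain data cannot separate the loss rate from
the root prior — an identifiability limit of the model class, not of
the calling rule, and the reason the recovery experiments fix the
generating model.

## Binding-site presence from duplex energies

A genome is annotated with an mBS for a given interaction if the
orthologous site still base-pairs with the (orthologous or ancestral)
sRNA site strongly enough.  `duplex_energy()` computes the minimum
free energy of an intermolecular, antiparallel, non-crossing duplex by
dynamic programming over admissible base pairs (Watson–Crick plus
G:U): consecutive pairs are scored by a bundled nearest-neighbor
stack table (`inst/extdata/nn_stacks.tsv`, Turner-style values,
symmetric under strand swap), non-contiguous pairs by an affine
interior/bulge penalty $a + b\,(n_1 + n_2)$ up to 30 unpaired bases,
plus one duplex initiation penalty.  Intramolecular structure,
dangling ends, terminal AU penalties and partition functions are out
of scope; a brute-force enumerator over the same scoring
(`brute_force_duplex_energy()`) is the exact oracle on short inputs.
Because the analysis only ever uses energy *ratios*, the absolute
calibration of the parameter set matters less than its ordering of
duplexes.

The presence rule (`mbs_call()`) marks an ortholog as having the site
iff (i) the target-gene ortholog exists in that genome, (ii) the
aligned site has no gap in its core columns, and (iii)
$\Delta G_{\text{orth}} \le \rho \cdot \Delta G_{\text{ref}}$ with
$\rho = 0.9$ — at least 90% of the stability of the focal-genome
reference pairing, boundary inclusive.  Both energies are negative, so
*larger* $\rho$ is *stricter*; the robustness checks at
$\rho \in \{0.8, 0.95\}$ bracket the default from both sides.  When a
genome has the target but not the sRNA, the sRNA side of the duplex is
the majority-rule consensus (`consensus_site()`; gaps do not vote,
ties break alphabetically and are reported) over the genomes that do
have the sRNA — a deliberate, documented stand-in for a full ancestral
sequence reconstruction.

**Padded vs core energies.**  Sites are mapped through the gapped
alignment with 5-nt pads on each side (`map_site_columns()`); the pads
serve alignment context and only the unpadded core columns set the
gap flag.  Energies, however, are scored on the unpadded cores.  In
synthetic data we found that scoring the padded sequences lets the
focal-vs-focal reference pick up several kcal/mol of *chance* pairing
in the pads; orthologs cannot reproduce that luck (their pads are
unconstrained), so the 0.9-ratio rule rejected perfectly conserved
cores wholesale.  Restricting the energy to the core removes this
bias while keeping the pads where they help.

## Scenario classification

The sRNA's gain node is taken as the gain node of its sBS (the
empirical justification: reconstructed ancestral sBS sequences are
nearly always identical to the focal ones).  For each interaction the
sBS and mBS gain calls lie on the same focal ancestor chain and are
therefore comparable: the same node is `CO_GAINED`, an older mBS is
`MBS_PRECEDES`, a younger one `MBS_SUCCEEDS`; the *interaction age*
is the younger of the two ages.  Relative to its host gene a binding
site can only be `MBS_WITH_GENE` or `MBS_AFTER_GENE` — an older
binding site than its gene is reported as an error, since it can only
arise from inconsistent upstream calls.  Records of the same
sRNA–target pair whose sites lie within 10 nt of each other
(edge-to-edge, overlap = 0; the anchor is configurable) describe the
same interaction and are merged transitively before classification;
at exactly 10 nt they stay distinct.

Age distributions between groups (cis- vs trans-acting families) are
compared with a two-tailed Mann–Whitney test:
$U = \#\{x < y\} + \tfrac12\#\text{ties}$, exact by full enumeration
of labelings for $n_1 + n_2 \le 16$, otherwise a normal approximation
with tie-corrected variance, continuity correction, and an Edgeworth
kurtosis term using the exact excess kurtosis of tie-free $U$,
$\gamma_2 = -1.2\,(n_1^2 + n_2^2 + n_1 n_2 + n)/(n_1 n_2 (n+1))$.
The kurtosis term matters near the switch point: with it the
approximation stays within 0.01 of the exact value on balanced
layouts at $n_1 + n_2 = 16$, which the plain corrected normal does
not achieve;
for very unbalanced layouts ($\min(n_1,n_2) \lesssim 3$) the exact
distribution is so coarse that no continuous approximation is
adequate — there the exact route is always used anyway.

## The synthetic-data generator

`make_fixture_dataset()` writes a complete, self-consistent input set
with known truth: a Yule tree rescaled to a chosen depth (default 0.5
amino-acid substitutions per position root-to-tip, a scale comparable
to a proteobacterial subtree), presence profiles that are exact
clades of chosen gain nodes on the focal lineage (the loss-free limit
of the trait CTMC), and pre-aligned sequence windows evolving under a
Jukes–Cantor process at rate $\mu = 0.3$ per site per unit branch
length, in which each binding-site interval is initialized at its
gain node to the reverse complement of the focal sRNA site and
conserved at $\rho_{\text{cons}}\mu$ ($\rho_{\text{cons}} = 0.05$)
within trait-bearing lineages.  The `benchmark` preset emulates a
realistic experimentally curated interaction set: 64 genomes, 15
sRNAs, 49 targets, 60 interactions (6 co-gained, 2 site-first, 52
sRNA-first; 18 with-gene, 42 after-gene) and 102 ncRNA families (31
cis, 58 trans, 13 other; cis gains placed deep, trans shallow; family
profiles get 2% per-leaf flip noise to emulate annotation error).
The `minimal` preset (16 genomes, 1 sRNA, 2 targets, 3 interactions)
covers all three scenario classes in seconds and drives the unit
tests.

Choices worth flagging:

* $\mu = 0.3$ keeps conserved sites essentially complementary over
  the tree (the generator's contract) while background sequence is
  unrelated to the sRNA site.  At $\mu = 1$ conserved sites lose
  complementarity over deep clades: a single core substitution costs
  ~9–10 kcal/mol in this energy model — more than the 10% stability
  margin the 0.9 rule allows — so every in-clade substitution becomes
  a presence flip, and substitutions on internal branches produce
  phylogenetically *clustered* flips that imitate genuine site loss.
  Residual in-clade flips (a few percent) remain at $\mu = 0.3$ and
  are absorbed by the reconstruction.
* No indels by default; gap injection is a separate knob
  (`gap_rate`) used to exercise the gap-flag logic.
* All randomness derives from the master seed, so a fixture directory
  is byte-identical across runs.

What passing on these fixtures does *not* show: real alignments have
indels and alignment error (the generator emits gapless alignments
unless asked); real binding sites pair imperfectly, with bulges, so
real reference energies are weaker and the ratio rule behaves more
leniently; horizontal transfer (which would leave a double-gain
signature on the tree) is not modeled; and real annotation
error is not independent per leaf.

## Problem sizes and numerics

The shipped tests run the enumeration oracles on trees of up to 6
leaves (exact to $10^{-8}$), transition-matrix properties on $10^4$
random rate/branch tuples ($10^{-10}$), rate recovery from 500 traits
on a 32-leaf depth-2 tree (within 20%), gain-node recovery on 100
fresh 64-leaf trees, duplex DP vs brute force on 500 random pairs of
length ≤ 8 (exact), and the full pipeline on the benchmark preset
(≥ 95% scenario agreement with truth).  Likelihood evaluations are
vectorized across traits with per-node rescaling; the optimizer uses
L-BFGS-B on log-rates with 9 restarts (4 for mixtures).  Ratio-rule
boundaries are compared with a $10^{-9}$ absolute tolerance so that
"exactly 90% of the reference" is inclusive under floating-point
arithmetic.  Zero-length branches give identity transition matrices;
age ties between distinct nodes on one chain can then occur and are
classified as co-gained with a warning.

## Limitations

Losses of the focal genome's own elements are invisible by
construction (traits are ascertained in the focal genome), so ages
are ages of the *current* trait, not of its first origin.  Gain-node
calls are one-node-fuzzy around very short branches.  The duplex
model is intermolecular-only with a reduced parameter set; absolute
energies should not be interpreted, only ratios.  The consensus
stand-in for ancestral sRNA sites is majority-rule, not a
likelihood-based reconstruction.
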