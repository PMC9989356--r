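---
title: "Reconstructing ancestral voltage-gated K+ channel sets from gene phylogenies"
author: "kvancestry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing ancestral voltage-gated K+ channel sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kvancestry)
ka_log_level("warn")
```

## The inference problem

Voltage-gated K⁺ channels comprise three anciently diverged gene families
(Kv, EAG, KCNQ), each with conserved subfamilies (Shaker, Shab, Shaw, Shal;
Eag, Erg, Elk; KCNQ). Within-family sequence identity over the
transmembrane core (S1–S6) is far higher than between families, and each
family carries a diagnostic cytoplasmic domain — the N-terminal T1
tetramerization domain in Kv, the C-linker plus cyclic-nucleotide-binding
homology domain (CNBHD) in EAG, and a C-terminal coiled-coil in KCNQ — so
family membership of a candidate protein is decidable from sequence alone.

Given the channel complements of extant species spanning a deep split
(here the cnidarian lineages Anthozoa and Medusozoa), the gene set of
their last common ancestor is estimated from per-family gene phylogenies:
each *minimal* clade that contains at least one gene from each side of the
split, with adequate statistical support, witnesses one ancestral gene.
This vignette describes the model and procedure behind each stage, the
parameters that matter, and the design decisions taken where the design
was genuinely open.

## Minimal dual-lineage clade counting

`find_ancestral_groups()` evaluates every clade `v` of a rooted gene tree
(polytomy nodes included) on two axes: lineage coverage (tips from both
focal lineages, via the species→lineage map) and support `s(v) ≥ θ`. The
returned groups are the minimal admissible clades under containment; since
clades of one tree form a laminar family, the groups are pairwise
disjoint, and the count is non-increasing in θ.

Numerical and policy choices:

* **Threshold comparison is inclusive (`≥ 0.95`) by default.** Bayesian
  consensus-tree practice reports "support ≥ 0.95", and clades at exactly
  0.95 are conventionally accepted; a strict `>` mode is retained as a
  flag for sensitivity analysis.
* **Unannotated internal nodes fail the threshold** (configurable). In a
  majority-rule consensus tree an absent support is an unresolved or
  weakly supported node, not a certain one. A tree with *no* supports
  anywhere is an error unless `assume_support = TRUE`, which treats it as
  fully resolved (used for simulator truth runs).
* **The root counts as a clade with support 1.0**, otherwise a family
  with a single ancestral gene could never be counted.
* **Per-clade overrides** attach a local θ to a clade identified by its
  tip set. This reproduces documented manual exceptions (a clade accepted
  at posterior probability 0.93, say) without loosening the genome-wide
  rule; every override is logged.
* **Merge directives** dissolve all candidates strictly below the joint
  ancestor of a named tip set, forcing evaluation there. This expresses
  the judgement that a large clade with weakly supported internal
  structure should be treated as a single ancestral group. (When the
  internal supports are genuinely weak the same result emerges from the
  threshold alone; the directive makes the decision explicit and
  auditable.)
* **Rooting** (`root_by_outgroup()`) treats node supports as annotations
  of bipartitions and reattaches them to the same bipartitions after
  rerooting, so the ancestral count is invariant to rerooting along any
  branch that keeps the focal bipartitions intact.

An independent brute-force implementation (`brute_force_groups()`:
explicit tip-set enumeration and pairwise containment tests, ≤16 tips) is
kept in the package and compared against the recursive implementation on
hundreds of random trees in every test run.

## Classification by reciprocal best hit

`reciprocal_classify()` mirrors standard reciprocal-best-BLAST practice
with a built-in Smith–Waterman scorer (Biostrings), so no external search
binary is required at desk scale. Scoring defaults are BLOSUM62 with
affine gaps, open 11 / extend 1, under the convention that a run of `g`
gap characters costs `open + extend·(g−1)`; the scorer reproduces the
classic textbook local-alignment example (BLOSUM50, open = extend = 8,
score 28) used as a hand-check in the tests. E-values use the
Karlin–Altschul form `E = K·m·n·e^(−λS)` with published ungapped BLOSUM62
constants — approximate as absolute probabilities, but strictly monotone
in the score, which is all the acceptance rule (`E < 0.01`, strict, per
the search protocol this emulates) consumes.

The reciprocal test runs in **cohort mode** by default: the best
reference hit of query `q` proposes a family/subfamily call; the back-hit
from that reference into the query set must itself carry the same
proposed call. Strict mode (back-hit must be `q` exactly) is available.
Cohort mode matches the intent of "best reciprocal match to the
family/subfamily of the original query" and is robust to near-duplicate
queries outcompeting each other. Ties (equal raw score) break to the
lexicographically first target id and are logged.

Diagnostic domains are detected by local alignment against a profile
consensus; **presence thresholds are calibrated from a seeded
shuffled-sequence null** (999th permille of 1,000 shuffle scores by
default) rather than hard-coded, since no principled universal cutoff
exists for blocks of differing length and composition. Completeness then
follows the per-family rule: Kv needs core + T1, KCNQ needs core +
coiled-coil, EAG needs core + CNBHD/C-linker with the N-terminal PAS
(eag) domain explicitly optional, because Erg-subfamily genes have lost
it repeatedly. Alignment rows missing more than 10% of aligned columns
(gaps or X) are removed — the boundary itself survives — and every
removal is logged.

## Gate-degeneration scoring

Kv α-subunits share a strongly conserved S6 activation-gate sequence
(consensus of the PVPVIV type); "regulatory" R-subunits, which only
function in heteromers, accumulate nonconservative gate substitutions.
`build_consensus()` takes the designated α-subunit rows of a trimmed
alignment and a **user-supplied gate column window** (1-based inclusive;
auto-detecting the window would amount to inventing data) and records the
plurality residue plus the set of chemical classes observed per column.
`classify_gate()` flags a position nonconservative when the observed
residue's class is outside that set, **or** when the consensus residue is
structurally critical (P or G, which set gate backbone geometry) and the
observed residue differs at all. One nonconservative position makes the
sequence `degenerate`; an entirely missing gate yields `missing_data`
and is excluded from group-level calls rather than counted as evidence.

The default conservation scheme partitions the amino acids into
hydrophobic {A,V,L,I,M,F,W,Y,C}, polar {S,T,N,Q}, basic {K,R,H}, acidic
{D,E}, and the two special singletons P and G. "Nonconservative" has no
unique definition; this standard chemical partition with P/G specialness
approximates conservation *in terms of gate structure* and is fully
configurable, so scheme sensitivity can (and should) be reported
alongside any gate-degeneration claim.

Group-level calls are monotone by construction: `ancestral_degenerate`
needs a degenerate member in *each* focal lineage, so adding α-like
members can never demote a call.

## The duplication–loss simulator

The generator exists so that every stage above can be tested against known
ancestral truth. Gene lineages evolve independently along an ultrametric
species tree: within a branch, a lineage waits `Exp(λ+μ)`; a duplication
(probability `λ/(λ+μ)`) splits it, a loss terminates it, and a speciation
node copies every surviving lineage into both daughters (exact
Gillespie-style sampling — not per-branch Poisson thinning — because it
makes truth bookkeeping trivial and sampling exact). The simulator
records the gene count at every species-tree node and, per root gene,
whether surviving tips exist in both focal lineages
(`dual_survivors`) — exactly the quantity the clade counter estimates.
Unifurcations left by losses are spliced out; root-gene subtrees join at
a root polytomy. With perfect supports, each dual-surviving root gene
surfaces as exactly one minimal dual-lineage clade, because every clade
strictly below a gene's focal-split node is single-lineage. (One
theoretical edge case: if *no* root gene survives in both lineages but
the family as a whole does, the gene-tree root itself forms one minimal
dual-lineage clade — a topology from which any observer would infer one
ancestral gene, though the bookkept truth is 0. Under the rate grids used
in the tests this configuration is vanishingly rare and has not occurred
at the fixed seeds.)

Default study conditions (chosen once, as the conditions the package is
meant to emulate, and not tuned thereafter):

* **Species tree**: the 8-species cnidarian phylogeny — Anthozoa
  (Acropora, Stylophora, Exaiptasia, Nematostella; Renilla) vs Medusozoa
  (Rhopilema, Sanderia; Hydra) — with unit depth and equal internal
  timings, since published divergence times for these nodes are poorly
  constrained; the root is the focal split.
* **n0 = 28** genes at the focal split: the ancestral voltage-gated K⁺
  channel count reconstructed for stem cnidarians.
* **λ = 0.55, μ = 0.1** per gene per unit time: with unit depth this puts
  the expected per-species count `n0·e^{λ−μ}` in the mid-40s, matching
  the observed mean (~44) across cnidarian genomes while allowing both
  lineage-specific expansions and losses.
* **Supports** ~ Beta(mean 0.985, concentration 80), i.e. concentrated
  near 1 as in well-converged Bayesian consensus trees, with a 5% "weak
  node" fraction forced uniformly into [0.5, 0.94] to emulate the
  occasional poorly resolved node.
* **Sequences**: per-subfamily templates assembled from the family's
  diagnostic blocks (T1 + core + PVPVIV-type gate for Kv; [PAS] + core +
  CNBHD for EAG, PAS omitted in Erg; core + coiled-coil for KCNQ), with
  subfamily cores differing at 15% of sites. Substitutions accumulate at
  a per-site, per-branch probability (default 0.02); indels are not
  simulated, so the emitted set doubles as a gap-free alignment and
  alignment-consuming operations are testable without running an aligner.
* **R-subunits**: 60% of root genes (the approximate R fraction among
  ancestral cnidarian Kv groups), flagged per root gene — R status is a
  property of an ancestral gene lineage, inherited by all its tips — with
  at least one forced cross-class gate substitution per R tip.

What the generator does *not* emulate: site-heterogeneous substitution
processes, rate variation across branches, indels, alignment error, or
Bayesian-inference behaviour beyond the Beta support model. Passing the
recovery tests therefore demonstrates the correctness of the counting,
classification and scoring logic under the stated model — not robustness
to alignment artefacts or to systematically misleading tree inference on
real data.

## Problem sizes used in the test and acceptance runs

The randomized suites use 500 trees of ≤16 tips for the brute-force
equivalence, 100 trees for θ-monotonicity, 200 simulated families across a
λ ∈ {0, 0.1, 0.3} × μ ∈ {0, 0.1} grid for exact truth recovery, 2,000
replicates for the birth–death mean-tip-count check (within 3 Monte Carlo
standard errors of `n0·e^{(λ−μ)T}`), and ~300 emitted sequences for
classification recovery. These sizes give the randomized checks enough
power to catch systematic errors while keeping a full test run in the
low tens of seconds on one core.

## Known limitations

* E-values are calibrated for ranking, not for cross-tool comparability;
  the acceptance rule only uses their order and a fixed cutoff.
* The NEXUS reader targets consensus files whose node comments carry
  `prob=`/`posterior=` fields (MrBayes `.con.tre` style); exotic
  annotation dialects may need conversion.
* Gate calls are sequence-level only. A degenerate gate marks relaxed
  selection compatible with the R-subunit phenotype; it is neither
  necessary nor sufficient for it, and functional confirmation requires
  electrophysiology.
* Ancestral counting assumes the deep split is correctly placed in each
  gene tree; genes lost (or unsequenced) in one entire lineage are
  invisible to the method and make the ancestral count a lower bound.
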