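---
title: "Experiment-level curation analytics: models, nulls and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Experiment-level curation analytics: models, nulls and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtrinet)
```

## The problem

Low-throughput experiments — TF perturbation followed by target
expression readout, TF–DNA binding assays (ChIP, EMSA), and TF-reporter
assays — are the community's de facto gold standard for direct
transcriptional regulatory interactions (DTRIs), interactions in which a
transcription factor modulates a target through a cis-regulatory element.
A literature-curation effort that records evidence at the level of the
*individual experiment*, rather than the interaction, lets users weigh
each claim by the number and kinds of experiments behind it, the cellular
context they were performed in, and the position of the binding site.
This package implements the data model and every analysis such a
curation project needs: validation and aggregation of experiment
records, corpus-bias statistics, network connectivity against a
degree-preserving null, benchmarking against high-throughput
TF-perturbation screens, and a synthetic-data generator that produces
every input with known ground truth.

## The record model and its invariants

One row of the experiment table is one experiment supporting one
TF→target pair. All categorical attributes come from closed
vocabularies (`default_vocabulary()`); values outside them are rejected,
never coerced. Three detail blocks exist — perturbation (direction,
timing, zygosity), binding (ChIP vs EMSA, EMSA protein source), reporter
(element mutated, mutation effect verified by binding) — and exactly one
must be present, matching the experiment type. Two rules encode assay
semantics: the `in_vitro` context is reserved for EMSA (a binding
reaction in a tube has no cellular context), and mutation–binding
verification is only meaningful when the element was in fact mutated.

Genes are Entrez ids with explicit species (human or mouse, recorded
separately for TF and target since cross-species designs occur in
overexpression and EMSA work). For reporting, every gene is mapped to
its human ortholog through a supplied homology table; a mouse gene
without an ortholog keeps its own id and is flagged, a deliberate
pass-through rather than an error so that mouse-specific genes are not
silently dropped.

Binding-site positions are classified by `classify_tfbs()`: promoters
are proximal by definition; otherwise an element within 2 kb of the
target TSS (either direction) is proximal, beyond it distal. The 2 kb
boundary is treated as inclusive — the threshold is a convention
(ENCODE's promoter-proximal window) and the boundary case is not
specified by it, so the more permissive reading was fixed once. When
only one end of an element was recorded, that signed offset is the
classification input.

## Aggregation to unique interactions

A DTRI is a unique combination of human-ortholog TF and target.
Evidence types are unioned over the supporting experiments; the other
summaries resolve as follows:

* **Species support** — an experiment counts toward a species only when
  TF and target are from the same species; a pair supported only by
  cross-species experiments is `mixed_only`.
* **Mode** — unreported experiments are ignored as long as any
  experiment reports a direction; conflicting directions give `both`.
* **Binding-site class** — union semantics, `both` when proximal and
  distal elements co-occur.
* **Context** — "tested directly in the CNS" requires at least one
  experiment in *primary* tissue or cells annotated with the CNS root
  (UBERON:0001017) or a descendant; CNS-derived cell lines never
  qualify. CNS takes precedence over eye (UBERON:0000970) so the
  categories partition the interactions. Embryonic-stage detection uses
  a configurable label grammar (defaults: `E<digits>`, `embryonic`,
  `fetal`) since curated stage strings are free text.

Free-text context terms are stored verbatim and never matched by
ontology queries; ontology-style terms missing from the DAG warn and are
treated as non-matching rather than failing the run, since a curation
snapshot and an ontology release can legitimately disagree.

The remaining-literature projection is deliberately plain arithmetic:
the positive rate among examined candidate papers is applied to the
unexamined remainder and scaled by the mean number of interactions per
positive paper (computed only over papers that yielded at least one
interaction); evidence-depth and context fractions scale it further.
Projections are reported unrounded; printed claims of the form
"more than N" are checked as lower bounds.

## Network connectivity and the rewiring null

The interaction network is a simple directed graph (self-loops retained
for autoregulation). Three connectivity statistics are computed with
igraph: the number of ordered gene pairs joined by a directed path
(self-loops never make a gene reachable from itself), the number of
complete subgraphs of three or more genes in the undirected projection
(all cliques, not only maximal ones; self-loops removed, reciprocal
edges merged), and the number of weakly connected components.

The null model rewires edges while preserving every node's in- and
out-degree, with swaps rejected if they would create self-loops or
duplicate edges; the swap budget is ten attempts per edge. Degree
preservation is asserted on every rewire, not sampled. One implementation
note: each successful swap transposes two edge heads, so on very small
graphs where no swap is ever rejected a fixed trial count would freeze
the permutation parity and make half of the configuration space
unreachable; a random extra trial restores ergodicity. Empirical
p-values use the add-one rule (r+1)/(n+1) with ties counted as extreme,
so no p-value is ever zero; the connectivity hypotheses are directional
(more reachable pairs and cliques, fewer components than the null).

## Benchmarking against perturbation screens

A screen is a per-gene table of log2 fold change, nominal p-value and
Benjamini–Hochberg q-value (derived when absent). Two complementary
enrichment readouts are provided. The hit-list route thresholds the
q-values at FDR 0.1 and asks whether curated targets are
overrepresented among hits (upper-tail hypergeometric, with the screen's
own gene table as the universe). The threshold-free route ranks genes by
ascending nominal p-value with midranks for ties and computes the AUROC
— the probability that a curated target outranks a non-target — from the
Mann–Whitney rank-sum statistic, with an exact two-sided p-value when
the comparison count is at most 10,000 and there are no ties, and the
tie- and continuity-corrected normal approximation otherwise.

Uncertainty comes from a percentile bootstrap that resamples the target
set (not the ranking), matching the way curated target lists, not
screens, are the scarce quantity. Each target's win fraction against the
fixed non-target set is precomputed, and a resample's AUROC is the mean
of the resampled win fractions — algebraically identical to the rank-sum
statistic for distinct targets and well defined when a target is drawn
twice. The default interval is the central 95% (2.5th–97.5th
percentiles); the narrower 5th–95th reading is available through the
`level` parameter.

When several screens exist for one TF, a consensus ranking is built:
restrict to the genes measured in every screen, recompute the midranks
within that shared universe, and average them per gene (ties broken by
gene id). Recomputing ranks after restriction keeps ranks comparable
across screens with different universe sizes, which is why that order of
operations was fixed. Target sets with fewer than 10 genes in the
evaluation universe are reported as skipped rather than tested.

## The synthetic-data generator

The generator produces every input the pipeline consumes under a single
seeded configuration (`sim_config()`), and its defaults are the study
conditions the analyses are exercised at: 250 TFs, 800 targets
(about half of the TFs also appearing as targets), 1,500 unique
interactions supported by roughly 3,600 experiments; an evidence-type
mixture with 27% triple-evidence and 64% multi-evidence interactions;
60/27/13% cell-line/primary/in-vitro experiments, with 26% of primary
experiments in the CNS and three quarters of those embryonic; 24%
repressive interactions among those with a known mode; 91% proximal
binding sites among the ~44% of interactions with an annotated
position; one third human-only, half mouse-only and 14% dual-species
support; and a mean of 1.9 interactions per positive paper (the paper
pool is sized by inverting the expected number of distinct papers drawn
under uniform assignment). Contexts are drawn per interaction and then
per experiment within it, because the experiments behind one interaction
tend to share labs and tissues; this keeps the experiment-level primary
share at its configured value while the share of interactions with any
primary evidence lands near 40%, as in real curation. Every generated
table passes the package validators, and each generator draws from its
own seed-derived stream, so artifacts are byte-identical under a fixed
seed.

Candidate-paper corpora use a Zipf-like per-TF paper count (34% of TFs
with no papers at all), a shared paper pool so that papers attach to
several TFs, and popularity counts equal to the candidate counts under
multiplicative log-normal noise — so zero noise gives a rank correlation
of exactly 1. The per-TF ceiling of 2,000 papers yields a corpus of a
few thousand distinct papers in which the top ~10% of TFs cover 90% of
the corpus and the popularity correlation is ~0.9, the regime a real
literature shows. At small corpus scales the many single-paper TFs tie,
and tie-breaking noise attenuates the rank correlation — a scale
artifact worth knowing when interpreting small simulations.

Planted differential-expression screens give each responsive gene a
Beta(a, 1) p-value (sub-uniform; a = 0.1 by default) and every other
gene a uniform one; responsive sets are drawn per target category with
configurable fractions (defaults 0.72/0.32/0.12 for CNS/eye/other,
mirroring a developing-brain screen where context-matched targets
respond most) and shared across screens, which resample p-values
independently with a per-screen log-normal jitter of the shape. The
expected AUROC of a target set with responsive fraction rho is
rho/(1+a) + (1−rho)/2, a closed form the tests verify against both a
Monte-Carlo oracle and the estimator.

### The biased network generator

The network generator grows a directed graph under a single bias dial
beta; beta = 0 is uniform random target choice with a skewed out-degree
sequence, which a degree-preserving rewiring null reproduces — measured
over replicate simulations its permutation p-values are approximately
uniform. For beta > 0 the design question was which wiring behaviour
actually produces connectivity that rewiring cannot explain, since any
*node-level* preference (for example "choose popular targets in
proportion to their degree") is absorbed into the degree sequence the
null preserves; mechanisms of that form were measured to be invisible to
the null. Three behaviours, each a genuine edge-level correlation and
each a recognisable research bias, are therefore combined under the one
dial:

* **cascade backbone** — a beta/(1+beta) share of the repeatedly studied
  TFs are chained as targets of other such TFs, the way developmental
  cascades are followed downstream; directed depth inflates reachable
  pairs far beyond a rewired graph, whose chains scatter;
* **famous-target attachment** — a TF entering the literature is first
  tested against an already-curated gene (probability beta/(0.1+beta),
  degree-weighted), so peripheral TFs never form isolated TF–target
  islands; the rewired null, pairing single out-edges with single
  in-edges at random, fragments into many more components;
* **triadic closure** — established TFs direct a share of further
  experiments at genes within undirected distance two, weighted by the
  number of shared partners, yielding locally complete modules and a
  clique excess.

At the default beta = 8 and the default network scale, all three
connectivity metrics are flagged at p ≤ 0.05 against 199-permutation
nulls in ≥ 90% of replicate simulations, while beta = 0 stays
calibrated. This three-facet mechanism is the package's own design for
realising the biased-curation hypothesis in a form a degree-preserving
null can actually detect.

## Problem sizes used by the tests and analyses

The test suite exercises the generators at reduced scales (tens of TFs,
60–500 interactions) where brute-force oracles — transitive closure by
boolean squaring, exhaustive clique enumeration, exhaustive
hypergeometric draws, literal step-up FDR selection, pairwise AUROC
counting — are feasible, and runs the bias-detection calibration at the
full default scale with 199-permutation nulls over 10 replicates. The
analysis scripts use the full defaults with 1,000 permutations and 1,000
bootstrap replicates. These sizes were chosen so each check carries
enough Monte-Carlo resolution for its assertion; all are ordinary
single-core workloads.

## Known limitations

* The generator emulates marginal and a few joint distributions of real
  curation (context repetition within an interaction, cascade/closure
  wiring); it does not emulate curator disagreement, symbol-resolution
  errors, within-paper correlation of experiment types, or realistic
  microarray noise, so green tests certify the statistical machinery and
  not robustness to those artifacts.
* Binding-only interactions cannot carry a perturbation-style mode, so
  the realised mode-unreported fraction sits slightly above the
  configured marginal; binding records are allowed to report a mode
  about half the time to mirror curation practice.
* The mode-known denominator excludes only `unreported` interactions;
  whether mixed-species records should also be excluded is a judgment
  call on which the summary simply reports both numerator and
  denominator.
* Reproducing the published curation counts requires the deposited
  supplementary tables (see `inst/extdata/README.md`); without them the
  corresponding acceptance tests report the data as missing, while all
  property-based checks are self-contained.
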