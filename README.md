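# dtrinet

Analytics for **experiment-level literature curation of direct
transcriptional regulatory interactions (DTRIs)** — TF→target pairs in
which a transcription factor controls a target gene through a
cis-regulatory element, supported by low-throughput evidence: TF
perturbation assays, TF–DNA binding assays (ChIP, EMSA) and TF-reporter
assays.

The package is written for curation teams and network biologists who
record evidence one *experiment* at a time and need, on top of that
record model:

* validated TSV I/O with controlled vocabularies, type-specific detail
  blocks, human-ortholog mapping and binding-site proximity
  classification (promoter or within 2 kb of the TSS ⇒ proximal);
* aggregation of experiments into unique human-ortholog TF→target
  interactions, with evidence-type, species, mode-of-regulation,
  binding-site and cellular-context summaries driven by an `is_a`
  ontology DAG (primary CNS tissue = UBERON:0001017 or a descendant);
* candidate-paper **corpus bias** statistics: top-*k* coverage, Jaccard
  of top-TF sets, asymmetric pairwise overlaps, Spearman correlation of
  corpus size with gene popularity;
* **network connectivity** of the directed interaction graph — reachable
  ordered pairs, cliques of ≥ 3 genes (undirected), weak components —
  tested against a degree-preserving edge-rewiring null with add-one
  empirical p-values, p = (r + 1)/(n + 1);
* **benchmarking** of curated target sets against TF-perturbation
  differential-expression screens: BH hit lists at FDR 0.1 with
  upper-tail hypergeometric overrepresentation, threshold-free AUROC
  from the Mann–Whitney rank-sum statistic
  (AUROC = U/(m·n′), the probability a curated target outranks a
  non-target in the ascending p-value ranking), percentile-bootstrap
  confidence intervals over the target set, and consensus rank
  aggregation across screens;
* a remaining-literature **projection** from the examined fraction of
  the candidate corpus; and
* a seeded **synthetic-data generator** for every input — experiment
  tables, corpora, ontology/homology fixtures, bias-grown networks and
  screens with planted signal — with known ground truth.

## Worked example

Simulate a curation-scale data set, aggregate it, and benchmark the
most-curated TF's targets against three perturbation screens whose
responsive genes were planted preferentially among CNS-validated
targets:

```r
library(dtrinet)

cfg     <- sim_config(seed = 20210)          # default study conditions
fx      <- generate_fixtures(cfg)            # homology table + ontology DAG
records <- generate_experiments(cfg, fx)     # 3,630 validated experiments
dtris   <- aggregate_dtris(records, fx$dag)  # 1,500 unique interactions
summarize_curation(dtris, records)
#> curation_summary: 1500 DTRIs | 221 TFs | 704 targets | 3630 experiments
#>   evidence: 965 with >=2 types, 405 with all three (223 triple in primary, 60 triple in CNS)
#>   TFBS: 542 annotated, 482 proximal, 65 distal
#>   mode: 294/1211 repressive
#>   papers: 788 with >=1 DTRI, mean 1.90 DTRIs/positive paper

tf   <- as.integer(names(which.max(table(dtris$tf_entrez))))
sets <- subset_targets(dtris, tf, "context")[-1]
sc   <- generate_de_screens(cfg, sets)
benchmark_tf(dtris, sc$screens, tf, min_targets = 5, n_boot = 500, seed = 2)
#> benchmark_report: TF 1193 | 3 screen(s) (consensus) | universe 10000 genes
#>   all              n=226 AUROC 0.582 (95% CI 0.541-0.623) p = 2.72e-05
#>   CNS              n=22 AUROC 0.867 (95% CI 0.766-0.949) p = 2.53e-09
#>   eye              n=11 AUROC 0.767 (95% CI 0.577-0.921) p = 0.00219
#>   other            n=193 AUROC 0.537 (95% CI 0.495-0.578) p = 0.0775
#>   multi_evidence   n=133 AUROC 0.596 (95% CI 0.537-0.656) p = 0.000146
#>   single_evidence  n=93 AUROC 0.559 (95% CI 0.497-0.619) p = 0.0494
```

Reading the report: each row is one curated target subset, `n` its size
inside the evaluation universe (the consensus ranking over genes shared
by all three screens). Targets validated in the screen-matched context
(CNS) are by far the most enriched — AUROC 0.87 with a bootstrap
confidence interval clear of the "other" subset — and multi-evidence
targets beat single-evidence ones, exactly the ground truth the
simulation planted. The analysis scripts under `analysis/`
(`01_simulate.R` … `06_literature_projection.R`) run the same pipeline
stage by stage, narrate what they find, and leave their tables and JSON
reports under `results/`.

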