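#!/usr/bin/env Rscript
# Coverage skew of the TF-to-candidate-paper corpus: how few TFs hold 90%
# of the papers, and how strongly corpus size tracks gene popularity.
suppressMessages(library(dtrinet))

corpus <- read_corpus_table("results/sim_bundle/corpus.tsv",
                            "results/sim_bundle/popularity.tsv")
cov <- coverage_topk(corpus, 0.9)
rho <- popularity_correlation(corpus)
cat(sprintf("%d of %d TFs with papers cover 90%% of the %d corpus papers\n",
            cov$k, length(corpus$papers), length(corpus_papers(corpus))))
cat(sprintf("Spearman correlation of corpus size with popularity: %.2f\n",
            rho))
jsonlite::write_json(
  list(n_tfs = length(corpus$papers),
       n_papers = length(corpus_papers(corpus)),
       top_tfs_for_90pct = cov$k, top_tf_ids = cov$top_tfs,
       popularity_spearman = rho),
  "results/corpus_stats.json", auto_unbox = TRUE, digits = NA)
cat("Corpus statistics -> results/corpus_stats.json\n")
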