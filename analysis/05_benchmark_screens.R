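#!/usr/bin/env Rscript
# Benchmark the most-curated TF's targets against the perturbation
# screens: hit-list overrepresentation and threshold-free AUROC with
# bootstrap confidence intervals, on the consensus p-value ranking.
suppressMessages(library(dtrinet))

dtris <- read_dtri_table("results/dtris.tsv")
man <- read.delim("results/sim_bundle/screen_manifest.tsv")
tf <- as.integer(man$tf_entrez[1])
screens <- lapply(seq_len(nrow(man)), function(i) {
  read_de_table(file.path("results/sim_bundle", man$path[i]),
                dataset = man$dataset_id[i], tf = tf)
})
rep <- benchmark_tf(dtris, screens, tf, min_targets = 5, n_boot = 1000,
                    seed = 20212)
print(rep)
write_benchmark_report(rep, "results/benchmark_report.json")
cat("\nTargets curated in the screen-matched context (CNS) rank highest,",
    "\nas planted by the simulation design.",
    "\nReport -> results/benchmark_report.json\n")
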