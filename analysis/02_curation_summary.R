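#!/usr/bin/env Rscript
# Validate the experiment table, collapse it to unique TF-target
# interactions and tabulate the evidence, species, context, mode and
# binding-site-position strata.
suppressMessages(library(dtrinet))

hom <- read_homology_table("results/sim_bundle/homology.tsv")
dag <- read_ontology_edges("results/sim_bundle/ontology_edges.tsv")
records <- read_experiment_table("results/sim_bundle/experiments.tsv",
                                 homology = hom)
dtris <- aggregate_dtris(records, dag)
s <- summarize_curation(dtris, records)
print(s)

write_dtri_table(dtris, "results/dtris.tsv")
write_summary_json(s, "results/curation_summary.json")
cat("\nInteraction table -> results/dtris.tsv",
    "\nStratified summary -> results/curation_summary.json\n")
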