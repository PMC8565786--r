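# External data drop-in

The acceptance checks against the published curation counts look here for
the deposited supplementary tables, converted to the package's TSV dialect:

- `deposited_experiments.tsv` — experiment-level curation records
  (columns of `experiment_table_columns()`)
- `deposited_homology.tsv` — species, entrez_id, human_entrez_id
- `deposited_ontology_edges.tsv` — child_curie, parent_curie is_a edges
  covering the CNS (UBERON:0001017) and eye (UBERON:0000970) branches
- `deposited_edge_list.tsv` — tf_entrez, target_entrez for the curated
  network

These files are distributed with the original publication, not with this
package; without them the corresponding acceptance tests report the data
as missing. All other tests and analyses are self-contained.
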