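#' Controlled vocabularies for experiment-level curation records
#'
#' Every categorical attribute of an experiment record is constrained to a
#' closed vocabulary; values outside the vocabulary are rejected during
#' validation rather than coerced. The accepted ontology namespaces cover
#' anatomy (UBERON), cell types (CL), cell lines (CLO), tissues (BTO) and
#' experimental factors (EFO); `freetext` marks verbatim context names that
#' could not be matched to any ontology and are never matched by ontology
#' queries.
#'
#' @return A named list of character vectors, one per controlled field, with
#'   an `ontology_namespaces` entry listing accepted CURIE prefixes.
#' @export
default_vocabulary <- function() {
  list(
    species = c("human", "mouse"),
    experiment_type = c("perturbation", "binding", "reporter"),
    context_type = c("cell_line", "primary", "in_vitro"),
    mode = c("activation", "repression", "unreported"),
    perturbation_direction = c("overexpression", "knockdown", "knockout"),
    perturbation_timing = c("constitutive", "induced"),
    zygosity = c("heterozygous", "homozygous", "not_applicable"),
    binding_method = c("chip", "emsa"),
    emsa_protein_source = c("transfected_cell_line", "primary_extract",
                            "recombinant", "other"),
    tfbs_class = c("proximal", "distal", "unreported"),
    ontology_namespaces = c("UBERON", "CL", "CLO", "BTO", "EFO", "freetext")
  )
}

#' Column dialect of the experiment-level table
#'
#' Order is canonical for writing; readers only require presence.
#'
#' @return Character vector of the 22 dialect column names.
#' @export
experiment_table_columns <- function() {
  c("experiment_id", "pubmed_id",
    "tf_symbol", "tf_entrez", "tf_species",
    "target_symbol", "target_entrez", "target_species",
    "experiment_type", "context_type", "context_term",
    "developmental_stage", "mode", "tfbs_offset_bp", "is_promoter",
    "perturbation_direction", "perturbation_timing", "zygosity",
    "binding_method", "emsa_protein_source",
    "reporter_cre_mutated", "mutation_binding_verified")
}

# Namespace of a context term: the CURIE prefix before ":", or "freetext"
# when the term does not look like a CURIE.
context_namespace <- function(term) {
  ns <- rep(NA_character_, length(term))
  has <- !is.na(term)
  curie <- has & grepl("^[A-Za-z]+:", term)
  ns[curie] <- sub(":.*$", "", term[curie])
  ns[has & !curie] <- "freetext"
  ns
}
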