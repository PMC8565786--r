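#' Resolve species support for one TF-target pair
#'
#' An experiment counts toward a species only when its TF and target genes
#' come from the same species; experiments mixing a TF from one species with
#' a target from the other (possible in overexpression and EMSA designs)
#' count toward neither. A pair supported only by such mixed experiments is
#' `mixed_only`.
#'
#' @param tf_species,target_species Character vectors, one entry per
#'   experiment supporting the pair.
#' @return One of `"human_only"`, `"mouse_only"`, `"both"`, `"mixed_only"`.
#' @export
resolve_species_support <- function(tf_species, target_species) {
  stopifnot(length(tf_species) > 0,
            length(tf_species) == length(target_species))
  same <- tf_species == target_species
  has_h <- any(same & tf_species == "human")
  has_m <- any(same & tf_species == "mouse")
  if (has_h && has_m) "both"
  else if (has_h) "human_only"
  else if (has_m) "mouse_only"
  else "mixed_only"
}

#' Resolve the mode of regulation for one TF-target pair
#'
#' Experiments that did not report a direction are ignored as long as any
#' experiment did; a pair with both activating and repressive reports is
#' `both`.
#'
#' @param modes Character vector over
#'   `{"activation", "repression", "unreported"}`.
#' @return One of `"activation"`, `"repression"`, `"both"`, `"unreported"`.
#' @export
resolve_mode <- function(modes) {
  stopifnot(length(modes) > 0)
  act <- any(modes == "activation", na.rm = TRUE)
  rep_ <- any(modes == "repression", na.rm = TRUE)
  if (act && rep_) "both" else if (act) "activation"
  else if (rep_) "repression" else "unreported"
}

#' Resolve the binding-site proximity class for one TF-target pair
#'
#' Union semantics over per-experiment [classify_tfbs()] results: pairs with
#' both proximal and distal elements are `both`; pairs where no experiment
#' recorded a position are `unreported`.
#'
#' @param classes Character vector over
#'   `{"proximal", "distal", "unreported"}`.
#' @return One of `"proximal"`, `"distal"`, `"both"`, `"unreported"`.
#' @export
resolve_tfbs_class <- function(classes) {
  stopifnot(length(classes) > 0)
  prox <- any(classes == "proximal")
  dist <- any(classes == "distal")
  if (prox && dist) "both" else if (prox) "proximal"
  else if (dist) "distal" else "unreported"
}

#' Resolve the cellular-context summary for one TF-target pair
#'
#' A pair was "tested directly" in an anatomical system only when at least
#' one supporting experiment used primary tissue or cells annotated with the
#' system's root term or one of its descendants; cell lines derived from the
#' system do not qualify. Pairs with both CNS and eye evidence are placed
#' only in the CNS category so that the categories are mutually exclusive.
#' Free-text context terms never match ontology queries; ontology-style
#' terms absent from the DAG are treated as non-matching.
#'
#' @param context_type,context_term,developmental_stage Per-experiment
#'   vectors.
#' @param dag An `ontology_dag`.
#' @param cns_root,eye_root Root CURIEs of the two categories of interest.
#' @param embryonic_patterns Regular expressions recognising embryonic or
#'   fetal developmental-stage labels.
#' @return List with `context_category` (`"CNS"`, `"eye"` or `"other"`),
#'   `any_primary`, `any_cns`, `any_embryonic_cns`.
#' @export
resolve_context <- function(context_type, context_term,
                            developmental_stage = NULL, dag,
                            cns_root = "UBERON:0001017",
                            eye_root = "UBERON:0000970",
                            embryonic_patterns = c("^E[0-9]", "embryonic",
                                                   "fetal")) {
  n <- length(context_type)
  stopifnot(n > 0, length(context_term) == n)
  if (is.null(developmental_stage)) developmental_stage <- rep(NA, n)
  cns_terms <- dag_descendants(dag, cns_root)
  eye_terms <- dag_descendants(dag, eye_root)

  ns <- context_namespace(context_term)
  queryable <- !is.na(context_term) & ns != "freetext"
  primary <- context_type == "primary"
  unknown <- primary & queryable & !(context_term %in% dag$terms)
  if (any(unknown)) {
    warning("ontology term(s) not in DAG treated as non-matching: ",
            paste(unique(context_term[unknown]), collapse = ", "),
            call. = FALSE)
  }
  in_cns <- primary & queryable & context_term %in% cns_terms
  in_eye <- primary & queryable & context_term %in% eye_terms

  stage <- as.character(developmental_stage)
  embry <- !is.na(stage) &
    Reduce(`|`, lapply(embryonic_patterns, grepl, x = stage,
                       ignore.case = TRUE))

  any_cns <- any(in_cns)
  any_eye <- any(in_eye)
  list(
    context_category = if (any_cns) "CNS" else if (any_eye) "eye" else
      "other",
    any_primary = any(primary),
    any_cns = any_cns,
    any_embryonic_cns = any(in_cns & embry)
  )
}

#' Aggregate experiment records into unique DTRIs
#'
#' Collapses experiment-level records into one row per unique combination of
#' human-ortholog TF and target gene, the unit at which independent
#' regulatory interactions are counted. Evidence types are unioned across
#' the supporting experiments and the species, mode, binding-site proximity
#' and cellular-context summaries are resolved by the `resolve_*`
#' operations.
#'
#' @param records Validated experiment frame carrying `tf_human_entrez` and
#'   `target_human_entrez` (see [read_experiment_table()]).
#' @param dag An `ontology_dag` used for context categorisation.
#' @param threshold_bp Proximity threshold passed to [classify_tfbs()].
#' @param ... Passed to [resolve_context()] (roots, embryonic patterns).
#' @return A `data.frame` with one row per DTRI, sorted by (TF, target):
#'   `tf_entrez`, `target_entrez`, `evidence_types` (semicolon-joined,
#'   sorted), `n_evidence_types`, `n_experiments`, `species_support`,
#'   `mode`, `tfbs_class`, `context_category`, `any_primary`, `any_cns`,
#'   `any_embryonic_cns`, `pubmed_ids` (semicolon-joined, sorted).
#' @export
aggregate_dtris <- function(records, dag, threshold_bp = 2000, ...) {
  if (is.null(records$tf_human_entrez) ||
      is.null(records$target_human_entrez)) {
    stop("records must carry human ortholog ids; ",
         "read them with a homology table")
  }
  if (nrow(records) == 0) {
    return(data.frame(
      tf_entrez = integer(), target_entrez = integer(),
      evidence_types = character(), n_evidence_types = integer(),
      n_experiments = integer(), species_support = character(),
      mode = character(), tfbs_class = character(),
      context_category = character(), any_primary = logical(),
      any_cns = logical(), any_embryonic_cns = logical(),
      pubmed_ids = character(), stringsAsFactors = FALSE))
  }
  records$.tfbs <- classify_tfbs(records$tfbs_offset_bp,
                                 records$is_promoter, threshold_bp)
  key <- paste(records$tf_human_entrez, records$target_human_entrez)
  groups <- split(seq_len(nrow(records)), key)

  rows <- lapply(groups, function(idx) {
    r <- records[idx, , drop = FALSE]
    types <- sort(unique(r$experiment_type))
    ctx <- resolve_context(r$context_type, r$context_term,
                           r$developmental_stage, dag, ...)
    data.frame(
      tf_entrez = r$tf_human_entrez[1],
      target_entrez = r$target_human_entrez[1],
      evidence_types = paste(types, collapse = ";"),
      n_evidence_types = length(types),
      n_experiments = nrow(r),
      species_support = resolve_species_support(r$tf_species,
                                                r$target_species),
      mode = resolve_mode(r$mode),
      tfbs_class = resolve_tfbs_class(r$.tfbs),
      context_category = ctx$context_category,
      any_primary = ctx$any_primary,
      any_cns = ctx$any_cns,
      any_embryonic_cns = ctx$any_embryonic_cns,
      pubmed_ids = paste(sort(unique(r$pubmed_id)), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$tf_entrez, out$target_entrez), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a DTRI-level table
#'
#' @param dtris DTRI frame from [aggregate_dtris()].
#' @param path TSV path.
#' @return `path` invisibly (write); a DTRI frame (read).
#' @export
write_dtri_table <- function(dtris, path) {
  utils::write.table(dtris, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_dtri_table
#' @export
read_dtri_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "NA",
                    fileEncoding = "UTF-8",
                    colClasses = c(evidence_types = "character",
                                   pubmed_ids = "character"))
}
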