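#' Read an experiment-level curation table
#'
#' Reads a tab-separated table of low-throughput experiment records (one row
#' per experiment supporting one TF-target interaction), validates every row
#' against the controlled vocabularies and the type-specific detail-block
#' rules, and maps TF and target genes to human orthologs for reporting.
#'
#' Tables are UTF-8, tab-separated, with "NA" for absent values. Column order
#' is free but all dialect columns must be present (see
#' [experiment_table_columns()]).
#'
#' @param source Path or connection to a TSV file.
#' @param vocab Controlled vocabulary, as from [default_vocabulary()].
#' @param homology Homology table from [read_homology_table()], or `NULL` to
#'   skip ortholog mapping.
#' @param column_map Optional named character vector mapping dialect column
#'   names to the names actually used in `source` (an adapter for deposited
#'   supplementary tables whose headers differ).
#' @return A `data.frame` with one validated row per experiment, in file
#'   order, with typed columns plus `tf_human_entrez`, `target_human_entrez`,
#'   `tf_unmapped` and `target_unmapped` when a homology table is supplied.
#' @export
read_experiment_table <- function(source, vocab = default_vocabulary(),
                                  homology = NULL, column_map = NULL) {
  raw <- utils::read.delim(source, sep = "\t", header = TRUE,
                           na.strings = "NA", colClasses = "character",
                           check.names = FALSE, fileEncoding = "UTF-8")
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      idx <- match(column_map[[std]], names(raw))
      if (!is.na(idx)) names(raw)[idx] <- std
    }
  }
  missing <- setdiff(experiment_table_columns(), names(raw))
  if (length(missing) > 0) {
    stop("experiment table is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  records <- type_experiment_table(raw[experiment_table_columns()])

  dup <- records$experiment_id[duplicated(records$experiment_id)]
  if (length(dup) > 0) {
    stop("duplicate experiment_id values: ",
         paste(unique(dup), collapse = ", "))
  }

  viol <- validate_experiment_table(records, vocab)
  if (nrow(viol) > 0) {
    stop("experiment table failed validation:\n",
         paste(sprintf("  row %d [%s]: %s", viol$row, viol$field,
                       viol$message), collapse = "\n"))
  }

  if (!is.null(homology)) {
    tf <- map_to_human(records$tf_entrez, records$tf_species, homology)
    tg <- map_to_human(records$target_entrez, records$target_species, homology)
    records$tf_human_entrez <- tf$human_entrez_id
    records$tf_unmapped <- tf$unmapped
    records$target_human_entrez <- tg$human_entrez_id
    records$target_unmapped <- tg$unmapped
  }
  records
}

# Convert an all-character frame into the typed record frame.
type_experiment_table <- function(raw) {
  to_int <- function(x, col) {
    out <- suppressWarnings(as.integer(x))
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      stop("non-integer value in column '", col, "' at row ",
           paste(bad, collapse = ", "))
    }
    out
  }
  to_lgl <- function(x, col) {
    lx <- toupper(trimws(x))
    out <- rep(NA, length(x))
    out[lx %in% c("TRUE", "T", "1")] <- TRUE
    out[lx %in% c("FALSE", "F", "0")] <- FALSE
    bad <- which(!is.na(x) & is.na(out))
    if (length(bad) > 0) {
      stop("non-logical value in column '", col, "' at row ",
           paste(bad, collapse = ", "))
    }
    out
  }
  raw$pubmed_id <- to_int(raw$pubmed_id, "pubmed_id")
  raw$tf_entrez <- to_int(raw$tf_entrez, "tf_entrez")
  raw$target_entrez <- to_int(raw$target_entrez, "target_entrez")
  raw$tfbs_offset_bp <- to_int(raw$tfbs_offset_bp, "tfbs_offset_bp")
  raw$is_promoter <- to_lgl(raw$is_promoter, "is_promoter")
  raw$reporter_cre_mutated <- to_lgl(raw$reporter_cre_mutated,
                                     "reporter_cre_mutated")
  raw$mutation_binding_verified <- to_lgl(raw$mutation_binding_verified,
                                          "mutation_binding_verified")
  rownames(raw) <- NULL
  raw
}

#' Write an experiment-level curation table
#'
#' Inverse of [read_experiment_table()]: writes the dialect columns as
#' UTF-8 TSV with "NA" for absent values, so that read and write round-trip
#' field-for-field.
#'
#' @param records Experiment record frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_experiment_table <- function(records, path) {
  out <- records[experiment_table_columns()]
  for (col in names(out)) {
    if (is.logical(out[[col]])) {
      out[[col]] <- ifelse(is.na(out[[col]]), NA_character_,
                           ifelse(out[[col]], "TRUE", "FALSE"))
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate every row of an experiment table
#'
#' Checks the controlled vocabularies, identifier sanity, and the
#' detail-block invariants: exactly one of the perturbation / binding /
#' reporter detail blocks is filled and it matches `experiment_type`; the
#' `in_vitro` context is reserved for EMSA binding experiments; the EMSA
#' protein source is only recorded for EMSA; and reporter mutation-binding
#' verification is only recorded when the cis-regulatory element was mutated.
#'
#' @param records Typed experiment record frame.
#' @param vocab Controlled vocabulary.
#' @return A `data.frame` with columns `row`, `field`, `message`; zero rows
#'   when every record is valid. Violations are data, not exceptions.
#' @export
validate_experiment_table <- function(records, vocab = default_vocabulary()) {
  viol <- list()
  add <- function(rows, field, message) {
    if (length(rows) > 0) {
      viol[[length(viol) + 1L]] <<- data.frame(
        row = rows, field = field, message = message,
        stringsAsFactors = FALSE)
    }
  }
  n <- nrow(records)
  if (n == 0) {
    return(data.frame(row = integer(), field = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  rows <- seq_len(n)

  req <- function(col) add(rows[is.na(records[[col]])], col, "value required")
  req("experiment_id"); req("pubmed_id")
  req("tf_entrez"); req("tf_species")
  req("target_entrez"); req("target_species")
  req("experiment_type"); req("context_type")

  add(rows[!is.na(records$pubmed_id) & records$pubmed_id <= 0],
      "pubmed_id", "must be a positive integer")
  add(rows[!is.na(records$tf_entrez) & records$tf_entrez <= 0],
      "tf_entrez", "must be a positive integer")
  add(rows[!is.na(records$target_entrez) & records$target_entrez <= 0],
      "target_entrez", "must be a positive integer")

  enum <- function(col, allowed, optional = FALSE) {
    x <- records[[col]]
    bad <- !is.na(x) & !(x %in% allowed)
    if (!optional) bad <- bad  # required-ness handled separately
    add(rows[bad], col,
        paste0("value outside vocabulary {",
               paste(allowed, collapse = ", "), "}"))
  }
  enum("tf_species", vocab$species)
  enum("target_species", vocab$species)
  enum("experiment_type", vocab$experiment_type)
  enum("context_type", vocab$context_type)
  enum("perturbation_direction", vocab$perturbation_direction)
  enum("perturbation_timing", vocab$perturbation_timing)
  enum("zygosity", vocab$zygosity)
  enum("binding_method", vocab$binding_method)
  enum("emsa_protein_source", vocab$emsa_protein_source)

  mode_missing <- is.na(records$mode)
  add(rows[mode_missing], "mode", "value required (use 'unreported')")
  enum("mode", vocab$mode)

  ns <- context_namespace(records$context_term)
  add(rows[!is.na(ns) & !(ns %in% vocab$ontology_namespaces)],
      "context_term",
      paste0("namespace outside accepted set {",
             paste(vocab$ontology_namespaces, collapse = ", "), "}"))

  # Detail blocks: presence indicator per block.
  has_pert <- !is.na(records$perturbation_direction) |
    !is.na(records$perturbation_timing) | !is.na(records$zygosity)
  has_bind <- !is.na(records$binding_method) |
    !is.na(records$emsa_protein_source)
  has_rep <- !is.na(records$reporter_cre_mutated) |
    !is.na(records$mutation_binding_verified)
  et <- records$experiment_type

  add(rows[!is.na(et) & et == "perturbation" & !has_pert],
      "perturbation_direction", "perturbation record lacks its detail block")
  add(rows[!is.na(et) & et == "binding" & !has_bind],
      "binding_method", "binding record lacks its detail block")
  add(rows[!is.na(et) & et == "reporter" & !has_rep],
      "reporter_cre_mutated", "reporter record lacks its detail block")
  add(rows[!is.na(et) & et != "perturbation" & has_pert],
      "perturbation_direction",
      "perturbation details present on a non-perturbation record")
  add(rows[!is.na(et) & et != "binding" & has_bind],
      "binding_method", "binding details present on a non-binding record")
  add(rows[!is.na(et) & et != "reporter" & has_rep],
      "reporter_cre_mutated",
      "reporter details present on a non-reporter record")

  is_emsa <- !is.na(records$binding_method) & records$binding_method == "emsa"
  add(rows[!is.na(records$context_type) &
             records$context_type == "in_vitro" & !is_emsa],
      "context_type", "in_vitro context is only valid for EMSA binding")
  add(rows[!is.na(records$emsa_protein_source) & !is_emsa],
      "emsa_protein_source", "protein source is only recorded for EMSA")
  cre_mut <- records$reporter_cre_mutated
  add(rows[!is.na(records$mutation_binding_verified) &
             (is.na(cre_mut) | !cre_mut)],
      "mutation_binding_verified",
      "only recorded when the cis-regulatory element was mutated")

  if (length(viol) == 0) {
    return(data.frame(row = integer(), field = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, viol)
  out[order(out$row), , drop = FALSE]
}

#' Validate a single experiment record
#'
#' @param record A one-row experiment frame or a named list with the dialect
#'   fields (missing fields are treated as absent).
#' @param vocab Controlled vocabulary.
#' @return Character vector of violation messages; empty iff the record is
#'   valid.
#' @export
validate_record <- function(record, vocab = default_vocabulary()) {
  cols <- experiment_table_columns()
  row <- as.list(record)[cols]
  names(row) <- cols
  row <- lapply(row, function(x) if (is.null(x) || length(x) == 0) NA else x)
  df <- type_experiment_table(
    as.data.frame(lapply(row, as.character), stringsAsFactors = FALSE))
  v <- validate_experiment_table(df, vocab)
  if (nrow(v) == 0) character(0) else sprintf("[%s] %s", v$field, v$message)
}

#' Classify a TF binding site as proximal or distal to the target TSS
#'
#' A cis-regulatory element counts as proximal when it is a promoter or lies
#' within `threshold_bp` base pairs (inclusive) of the target's transcription
#' start site, in either direction; beyond the threshold it is distal; with
#' neither a coordinate nor a promoter flag the position is unreported. When
#' only one end of the element was recorded, its signed offset is the
#' classification input.
#'
#' @param offset_bp Signed integer offset(s) from the TSS in bp, `NA` when
#'   absent.
#' @param is_promoter Logical flag(s), `NA` when absent.
#' @param threshold_bp Positive proximity threshold in bp (default 2000, the
#'   ENCODE promoter-proximal convention).
#' @return Character vector over `{"proximal", "distal", "unreported"}`.
#' @export
classify_tfbs <- function(offset_bp, is_promoter = NA, threshold_bp = 2000) {
  stopifnot(length(threshold_bp) == 1, threshold_bp > 0)
  n <- max(length(offset_bp), length(is_promoter))
  offset_bp <- rep_len(offset_bp, n)
  is_promoter <- rep_len(is_promoter, n)
  out <- rep("unreported", n)
  has_off <- !is.na(offset_bp)
  out[has_off & abs(offset_bp) <= threshold_bp] <- "proximal"
  out[has_off & abs(offset_bp) > threshold_bp] <- "distal"
  out[!is.na(is_promoter) & is_promoter] <- "proximal"
  out
}
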