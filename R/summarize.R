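#' Stratified summary of a DTRI collection
#'
#' Produces the count tables used to describe a curation effort: totals,
#' evidence-type-combination by context-category cross-tabulation, species
#' support, mode by binding-site proximity, per-TF target counts, per-target
#' regulator counts, and per-paper DTRI counts (over papers contributing at
#' least one DTRI). Papers examined without yielding a DTRI are carried as a
#' separate count when the number of examined papers is supplied.
#'
#' @param dtris DTRI frame from [aggregate_dtris()].
#' @param records The underlying experiment frame (used for per-experiment
#'   context and paper statistics).
#' @param n_papers_examined Optional total number of papers examined, used
#'   to report the count of negative (DTRI-free) papers.
#' @return A list of class `curation_summary`.
#' @export
summarize_curation <- function(dtris, records, n_papers_examined = NULL) {
  pair_papers <- strsplit(dtris$pubmed_ids, ";", fixed = TRUE)
  papers_with_dtri <- unique(unlist(pair_papers))
  per_paper <- table(unlist(pair_papers))
  per_paper_dtris <- as.integer(per_paper)
  names(per_paper_dtris) <- names(per_paper)

  multi <- dtris$n_evidence_types >= 2
  triple <- dtris$n_evidence_types == 3
  annotated <- dtris$tfbs_class != "unreported"
  mode_known <- dtris$mode != "unreported"

  out <- list(
    totals = list(
      n_dtris = nrow(dtris),
      n_tfs = length(unique(dtris$tf_entrez)),
      n_targets = length(unique(dtris$target_entrez)),
      n_experiments = nrow(records),
      n_papers_with_dtri = length(papers_with_dtri),
      n_papers_negative = if (is.null(n_papers_examined)) NA_integer_ else
        n_papers_examined - length(papers_with_dtri)
    ),
    evidence_by_context = table(evidence_types = dtris$evidence_types,
                                context_category = dtris$context_category),
    species_support = table(species_support = dtris$species_support),
    mode_by_tfbs = table(mode = dtris$mode, tfbs_class = dtris$tfbs_class),
    evidence_depth = list(
      n_multi_evidence = sum(multi),
      n_triple_evidence = sum(triple),
      n_single_evidence = sum(!multi),
      n_triple_primary = sum(triple & dtris$any_primary),
      n_triple_cns = sum(triple & dtris$any_cns)
    ),
    tfbs = list(
      n_annotated = sum(annotated),
      n_proximal_any = sum(dtris$tfbs_class %in% c("proximal", "both")),
      n_distal_any = sum(dtris$tfbs_class %in% c("distal", "both"))
    ),
    mode = list(
      n_mode_known = sum(mode_known),
      n_repressive = sum(dtris$mode %in% c("repression", "both")),
      n_activating = sum(dtris$mode %in% c("activation", "both"))
    ),
    context = list(
      n_any_primary = sum(dtris$any_primary),
      n_cns = sum(dtris$any_cns),
      n_eye = sum(dtris$context_category == "eye"),
      n_embryonic_cns = sum(dtris$any_embryonic_cns)
    ),
    per_tf_targets = table(tf_entrez = dtris$tf_entrez),
    per_target_regulators = table(target_entrez = dtris$target_entrez),
    per_paper_dtris = per_paper_dtris,
    mean_dtris_per_positive_paper =
      if (length(per_paper_dtris) > 0) mean(per_paper_dtris) else NA_real_
  )
  class(out) <- "curation_summary"
  out
}

#' @export
print.curation_summary <- function(x, ...) {
  t <- x$totals
  cat(sprintf("curation_summary: %d DTRIs | %d TFs | %d targets | %d experiments\n",
              t$n_dtris, t$n_tfs, t$n_targets, t$n_experiments))
  cat(sprintf("  evidence: %d with >=2 types, %d with all three (%d triple in primary, %d triple in CNS)\n",
              x$evidence_depth$n_multi_evidence,
              x$evidence_depth$n_triple_evidence,
              x$evidence_depth$n_triple_primary,
              x$evidence_depth$n_triple_cns))
  cat(sprintf("  TFBS: %d annotated, %d proximal, %d distal\n",
              x$tfbs$n_annotated, x$tfbs$n_proximal_any,
              x$tfbs$n_distal_any))
  cat(sprintf("  mode: %d/%d repressive\n", x$mode$n_repressive,
              x$mode$n_mode_known))
  cat(sprintf("  papers: %d with >=1 DTRI, mean %.2f DTRIs/positive paper\n",
              t$n_papers_with_dtri, x$mean_dtris_per_positive_paper))
  invisible(x)
}

#' Serialise a curation summary to JSON
#'
#' @param summary A `curation_summary`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  to_df <- function(tab) as.data.frame(tab, stringsAsFactors = FALSE)
  payload <- list(
    totals = summary$totals,
    evidence_by_context = to_df(summary$evidence_by_context),
    species_support = to_df(summary$species_support),
    mode_by_tfbs = to_df(summary$mode_by_tfbs),
    evidence_depth = summary$evidence_depth,
    tfbs = summary$tfbs,
    mode = summary$mode,
    context = summary$context,
    per_tf_targets = to_df(summary$per_tf_targets),
    per_target_regulators = to_df(summary$per_target_regulators),
    per_paper_dtris = as.list(summary$per_paper_dtris),
    mean_dtris_per_positive_paper = summary$mean_dtris_per_positive_paper
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Project the number of DTRIs remaining in the unexamined literature
#'
#' Extrapolates from the examined fraction of the candidate-paper corpus:
#' the positive rate (papers containing at least one DTRI) is applied to the
#' remaining candidate papers, then scaled by the mean number of DTRIs per
#' positive paper; fractions of high-evidence and CNS-tested DTRIs scale the
#' projection further. The captured-fraction estimate compares an observed
#' count of CNS-verified DTRIs with its projection.
#'
#' @param n_examined Number of candidate papers examined.
#' @param n_positive Number of examined papers containing at least one DTRI.
#' @param n_candidates_remaining Number of candidate papers not yet
#'   examined.
#' @param mean_dtris_per_positive_paper Mean DTRIs reported per positive
#'   paper.
#' @param frac_triple Fraction of DTRIs supported by all three evidence
#'   types.
#' @param frac_cns Fraction of DTRIs tested directly in primary CNS tissue.
#' @param n_cns_observed Observed count of triple-evidence CNS DTRIs, used
#'   for the captured-fraction estimate (optional).
#' @return A list of class `literature_estimate` with unrounded projections.
#' @export
estimate_remaining <- function(n_examined, n_positive,
                               n_candidates_remaining,
                               mean_dtris_per_positive_paper,
                               frac_triple = NA_real_, frac_cns = NA_real_,
                               n_cns_observed = NA_integer_) {
  if (n_examined <= 0) stop("positive rate undefined: n_examined must be > 0")
  stopifnot(n_positive <= n_examined, n_positive >= 0,
            n_candidates_remaining >= 0,
            mean_dtris_per_positive_paper >= 0)
  for (f in c(frac_triple, frac_cns)) {
    if (!is.na(f) && (f < 0 || f > 1)) stop("fractions must lie in [0, 1]")
  }
  positive_rate <- n_positive / n_examined
  projected_positive <- positive_rate * n_candidates_remaining
  projected_dtris <- projected_positive * mean_dtris_per_positive_paper
  out <- list(
    positive_rate = positive_rate,
    mean_dtris_per_positive_paper = mean_dtris_per_positive_paper,
    projected_positive_papers = projected_positive,
    projected_dtris = projected_dtris,
    projected_triple_evidence_dtris = projected_dtris * frac_triple,
    projected_cns_dtris = projected_dtris * frac_cns,
    captured_fraction_cns =
      if (is.na(n_cns_observed)) NA_real_ else
        n_cns_observed / (projected_dtris * frac_cns + n_cns_observed)
  )
  class(out) <- "literature_estimate"
  out
}

#' @export
print.literature_estimate <- function(x, ...) {
  cat(sprintf("literature_estimate: positive rate %.3f\n", x$positive_rate))
  cat(sprintf("  projected positive papers: %.1f\n",
              x$projected_positive_papers))
  cat(sprintf("  projected DTRIs: %.1f (triple-evidence %.1f, CNS %.1f)\n",
              x$projected_dtris, x$projected_triple_evidence_dtris,
              x$projected_cns_dtris))
  invisible(x)
}
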