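#' Construct a TF-to-candidate-paper corpus
#'
#' A corpus maps each TF (human Entrez id) to the set of candidate papers
#' (PubMed ids) assigned to it; a paper may be assigned to many TFs.
#' Optional per-TF popularity counts record the total PubMed hits for the
#' TF's symbol, irrespective of topical filters.
#'
#' @param papers Named list: TF entrez id (as name) to integer vector of
#'   paper ids.
#' @param source Free-text source label.
#' @param popularity Optional named numeric vector of per-TF popularity
#'   counts.
#' @return Object of class `candidate_corpus`.
#' @export
candidate_corpus <- function(papers, source = "unnamed",
                             popularity = NULL) {
  papers <- lapply(papers, function(p) {
    p <- as.integer(unique(p))
    if (any(p <= 0)) stop("paper ids must be positive integers")
    sort(p)
  })
  structure(list(source = source, papers = papers,
                 popularity = popularity),
            class = "candidate_corpus")
}

#' Read a corpus table (and optional popularity table)
#'
#' @param path TSV with columns `tf_entrez`, `pubmed_id` and optionally
#'   `source`.
#' @param popularity_path Optional TSV with columns `tf_entrez`,
#'   `popularity_count`.
#' @param source Source label override.
#' @return A `candidate_corpus`.
#' @export
read_corpus_table <- function(path, popularity_path = NULL,
                              source = NULL) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           na.strings = "NA", fileEncoding = "UTF-8")
  stopifnot(all(c("tf_entrez", "pubmed_id") %in% names(tab)))
  papers <- split(as.integer(tab$pubmed_id), as.character(tab$tf_entrez))
  pop <- NULL
  if (!is.null(popularity_path)) {
    pt <- utils::read.delim(popularity_path, sep = "\t", header = TRUE,
                            na.strings = "NA", fileEncoding = "UTF-8")
    pop <- stats::setNames(as.numeric(pt$popularity_count),
                           as.character(pt$tf_entrez))
  }
  if (is.null(source)) {
    source <- if ("source" %in% names(tab) && nrow(tab) > 0)
      as.character(tab$source[1]) else basename(path)
  }
  candidate_corpus(papers, source = source, popularity = pop)
}

#' Distinct papers in a corpus
#' @param corpus A `candidate_corpus`.
#' @return Sorted integer vector of distinct paper ids.
#' @export
corpus_papers <- function(corpus) {
  sort(unique(unlist(corpus$papers, use.names = FALSE)))
}

#' Smallest top-TF prefix covering a fraction of the corpus
#'
#' TFs are ordered by descending candidate-paper count (ties broken by
#' ascending Entrez id); `k` is the length of the smallest prefix whose
#' union of paper sets covers at least `fraction` of the corpus's distinct
#' papers. Coverage counts distinct papers via prefix unions, not summed
#' TF-paper assignments.
#'
#' @param corpus A `candidate_corpus`.
#' @param fraction Coverage fraction in (0, 1].
#' @return List with `k` and `top_tfs` (the ordered prefix of TF ids).
#' @export
coverage_topk <- function(corpus, fraction = 0.9) {
  stopifnot(fraction > 0, fraction <= 1)
  sizes <- vapply(corpus$papers, length, integer(1))
  if (length(sizes) == 0 || sum(sizes) == 0) stop("corpus is empty")
  ord <- order(-sizes, as.integer(names(sizes)))
  tfs <- names(sizes)[ord]
  total <- length(corpus_papers(corpus))
  seen <- integer(0)
  for (k in seq_along(tfs)) {
    seen <- union(seen, corpus$papers[[tfs[k]]])
    if (length(seen) >= fraction * total) {
      return(list(k = k, top_tfs = tfs[seq_len(k)]))
    }
  }
  list(k = length(tfs), top_tfs = tfs)
}

#' Jaccard index of two sets
#'
#' @param set_a,set_b Vectors treated as sets.
#' @return |A intersect B| / |A union B|; 0 when both sets are empty.
#' @export
jaccard <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0) return(0)
  length(intersect(set_a, set_b)) / u
}

#' Asymmetric pairwise overlap fraction of two corpora
#'
#' The fraction of the target corpus's distinct papers that also occur in
#' the source corpus. Asymmetric by construction: a large corpus can
#' contain most of a small one while the converse fraction is tiny.
#'
#' @param source,target `candidate_corpus` objects.
#' @return Proportion in [0, 1].
#' @export
pairwise_overlap_fraction <- function(source, target) {
  ps <- corpus_papers(source); pt <- corpus_papers(target)
  stopifnot(length(ps) > 0, length(pt) > 0)
  length(intersect(ps, pt)) / length(pt)
}

#' Rank correlation between candidate-paper counts and TF popularity
#'
#' Spearman correlation (midranks for ties) between the number of candidate
#' papers per TF and the TF's overall popularity count, over TFs with a
#' popularity entry.
#'
#' @param corpus A `candidate_corpus` with popularity counts.
#' @return Spearman's rank correlation coefficient.
#' @export
popularity_correlation <- function(corpus) {
  if (is.null(corpus$popularity)) stop("corpus has no popularity counts")
  tfs <- intersect(names(corpus$papers), names(corpus$popularity))
  if (length(tfs) < 3) {
    stop("popularity correlation needs >= 3 paired observations, got ",
         length(tfs))
  }
  counts <- vapply(corpus$papers[tfs], length, integer(1))
  stats::cor(counts, corpus$popularity[tfs], method = "spearman")
}

#' @export
print.candidate_corpus <- function(x, ...) {
  cat(sprintf("candidate_corpus '%s': %d TFs, %d distinct papers\n",
              x$source, length(x$papers), length(corpus_papers(x))))
  invisible(x)
}
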