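#' Read a gene-level differential-expression table
#'
#' One row per gene with the log2 fold change, nominal p-value and (if
#' absent, Benjamini-Hochberg-derived) q-value of a TF-perturbation screen.
#'
#' @param path TSV with columns `gene_entrez`, `log2fc`, `pvalue` and
#'   optionally `qvalue`.
#' @param dataset Dataset label.
#' @param tf Entrez id of the perturbed TF.
#' @return A `data.frame` of class `de_result` with attributes `dataset`
#'   and `tf`.
#' @export
read_de_table <- function(path, dataset = basename(path), tf = NA) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           na.strings = "NA", fileEncoding = "UTF-8")
  stopifnot(all(c("gene_entrez", "log2fc", "pvalue") %in% names(tab)))
  de_result(tab, dataset = dataset, tf = tf)
}

#' Construct a DE result from a data frame
#'
#' @param tab Data frame with `gene_entrez`, `log2fc`, `pvalue`, optional
#'   `qvalue`.
#' @param dataset Dataset label.
#' @param tf Perturbed TF id.
#' @return A `de_result` data frame.
#' @export
de_result <- function(tab, dataset = "unnamed", tf = NA) {
  if (anyDuplicated(tab$gene_entrez)) stop("one row per gene required")
  if (any(tab$pvalue < 0 | tab$pvalue > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  if (is.null(tab$qvalue)) {
    tab$qvalue <- stats::p.adjust(tab$pvalue, method = "BH")
  }
  attr(tab, "dataset") <- dataset
  attr(tab, "tf") <- tf
  class(tab) <- c("de_result", "data.frame")
  tab
}

#' Hit list of differentially expressed genes at an FDR cut-off
#'
#' @param de A `de_result`.
#' @param fdr FDR threshold on the Benjamini-Hochberg q-values
#'   (default 0.1).
#' @return Vector of gene ids with q-value at or below `fdr`.
#' @export
hit_list <- function(de, fdr = 0.1) {
  de$gene_entrez[!is.na(de$qvalue) & de$qvalue <= fdr]
}

#' Hypergeometric overrepresentation of curated targets in a hit list
#'
#' Upper-tail probability of drawing at least the observed number of
#' curated targets when sampling the hit list at random from the screen's
#' gene universe. Genes outside the universe are dropped with a message.
#'
#' @param hits Hit-list gene set.
#' @param targets Curated target gene set.
#' @param universe All genes measured by the screen (nonempty).
#' @return List of class `enrichment_result` with `kind = "hypergeometric"`
#'   and fields `k` (hits intersect targets), `K` (targets in universe),
#'   `n` (hits), `N` (universe size), `p_value`.
#' @export
hypergeom_overrep <- function(hits, targets, universe) {
  if (length(universe) == 0) stop("universe is empty")
  universe <- unique(universe)
  dropped <- length(setdiff(targets, universe)) +
    length(setdiff(hits, universe))
  if (dropped > 0) {
    message(dropped, " gene(s) outside the universe dropped")
  }
  hits <- intersect(unique(hits), universe)
  targets <- intersect(unique(targets), universe)
  k <- length(intersect(hits, targets))
  K <- length(targets); n <- length(hits); N <- length(universe)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  structure(list(kind = "hypergeometric", k = k, K = K, n = n, N = N,
                 p_value = p),
            class = "enrichment_result")
}

#' Build a p-value ranking from a DE result
#'
#' Genes are ranked by ascending nominal p-value with midranks for ties, so
#' rank 1 is the most significant gene.
#'
#' @param de A `de_result`.
#' @return List of class `ranking`: `gene`, `pvalue`, `rank`, `n`.
#' @export
make_ranking <- function(de) {
  structure(list(gene = de$gene_entrez, pvalue = de$pvalue,
                 rank = rank(de$pvalue, ties.method = "average"),
                 n = nrow(de)),
            class = "ranking",
            dataset = attr(de, "dataset"), tf = attr(de, "tf"))
}

# AUROC from the ranks of the positives (1 = best/smallest p).
# Duplicated ranks are allowed (bootstrap resamples).
auroc_from_ranks <- function(target_ranks, n_universe) {
  m <- length(target_ranks)
  nn <- n_universe - m
  u <- m * nn + m * (m + 1) / 2 - sum(target_ranks)
  u / (m * nn)
}

#' Threshold-free enrichment of a target set in a p-value ranking
#'
#' The AUROC is the probability that a curated target outranks (has a
#' smaller nominal p-value than) a non-target, computed from the
#' Mann-Whitney rank-sum statistic with midranks for ties; 1.0 means all
#' targets sit at the smallest p-values. The two-sided p-value comes from
#' the rank-sum test: exact when the comparison count m*n' is at most
#' `exact_limit` and there are no ties, otherwise the normal approximation
#' with continuity and tie corrections.
#'
#' @param ranking A `ranking` (from [make_ranking()] or
#'   [consensus_ranking()]).
#' @param targets Target gene set; genes absent from the ranking's universe
#'   are dropped with a message.
#' @param exact_limit Threshold on m*n' for the exact test (default 10000).
#' @return List of class `enrichment_result` with `kind = "auroc"`,
#'   `statistic`, `p_value`, `n_targets_in_universe`.
#' @export
auroc <- function(ranking, targets, exact_limit = 10000) {
  is_t <- ranking$gene %in% targets
  m <- sum(is_t); nn <- ranking$n - m
  dropped <- length(setdiff(unique(targets), ranking$gene))
  if (dropped > 0) message(dropped, " target(s) not in universe dropped")
  if (m == 0) stop("no targets in the ranking universe (0 of ",
                   length(unique(targets)), ")")
  if (nn == 0) stop("no non-targets in the ranking universe")
  stat <- auroc_from_ranks(ranking$rank[is_t], ranking$n)
  has_ties <- anyDuplicated(ranking$rank) > 0
  p <- if (!is.null(ranking$pvalue)) {
    suppressWarnings(stats::wilcox.test(
      ranking$pvalue[is_t], ranking$pvalue[!is_t],
      alternative = "two.sided",
      exact = (m * nn <= exact_limit) && !has_ties,
      correct = TRUE))$p.value
  } else {
    suppressWarnings(stats::wilcox.test(
      ranking$rank[is_t], ranking$rank[!is_t],
      alternative = "two.sided",
      exact = (m * nn <= exact_limit) && !has_ties,
      correct = TRUE))$p.value
  }
  structure(list(kind = "auroc", statistic = stat, p_value = p,
                 n_targets_in_universe = m),
            class = "enrichment_result")
}

#' Percentile bootstrap confidence interval for the AUROC
#'
#' Resamples the target set with replacement (same size), recomputes the
#' AUROC per replicate against the fixed ranking, and returns the central
#' empirical percentile interval.
#'
#' @param ranking A `ranking`.
#' @param targets Target gene set with at least 2 genes in the universe.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param level Central coverage level (default 0.95, i.e. the 2.5th to
#'   97.5th percentiles).
#' @param seed Optional RNG seed.
#' @return Numeric `c(low, high)`.
#' @export
bootstrap_auroc_ci <- function(ranking, targets, n_boot = 1000,
                               level = 0.95, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  is_t <- ranking$gene %in% targets
  m <- sum(is_t)
  if (m < 2) stop("bootstrap needs >= 2 targets in the universe")
  rt <- ranking$rank[is_t]
  rn <- sort(ranking$rank[!is_t])
  nn <- length(rn)
  # per-target win fraction against the fixed non-target set; the AUROC of
  # any resampled target multiset is the mean of these, which keeps the
  # statistic in [0, 1] even when a target is drawn more than once
  below <- findInterval(rt, rn, left.open = TRUE)   # rn strictly smaller
  ties <- findInterval(rt, rn) - below
  wins <- (nn - below - ties + 0.5 * ties) / nn
  reps <- vapply(seq_len(n_boot), function(i) {
    mean(sample(wins, m, replace = TRUE))
  }, numeric(1))
  alpha <- (1 - level) / 2
  unname(stats::quantile(reps, c(alpha, 1 - alpha)))
}

#' Consensus ranking across differential-expression screens
#'
#' Restricts to the genes measured in every member screen, recomputes the
#' within-screen midranks on that shared universe, averages them per gene,
#' and re-ranks by the mean (ties broken by gene id). Averaging within-
#' screen ranks controls for screen-specific conditions before enrichment
#' is assessed once per TF.
#'
#' @param rankings Nonempty list of `ranking` objects.
#' @return List of class `c("consensus_ranking", "ranking")` with `gene`
#'   (ordered by consensus), `mean_rank`, `rank` (midranks of the mean),
#'   `n`, `members`.
#' @export
consensus_ranking <- function(rankings) {
  stopifnot(length(rankings) >= 1)
  shared <- Reduce(intersect, lapply(rankings, `[[`, "gene"))
  if (length(shared) == 0) stop("no genes shared across all rankings")
  mat <- vapply(rankings, function(rk) {
    idx <- match(shared, rk$gene)
    rank(rk$pvalue[idx], ties.method = "average")
  }, numeric(length(shared)))
  if (length(shared) == 1L) mat <- matrix(mat, nrow = 1L)
  mean_rank <- rowMeans(as.matrix(mat))
  ord <- order(mean_rank, shared)
  structure(list(gene = shared[ord], pvalue = NULL,
                 mean_rank = mean_rank[ord],
                 rank = rank(mean_rank[ord], ties.method = "average"),
                 n = length(shared),
                 members = vapply(rankings, function(rk) {
                   ds <- attr(rk, "dataset")
                   if (is.null(ds)) NA_character_ else as.character(ds)
                 }, character(1))),
            class = c("consensus_ranking", "ranking"))
}

#' Partition a TF's curated targets by context or evidence depth
#'
#' The context scheme splits targets into CNS, eye and "other" using the
#' mutually exclusive DTRI context categories (CNS takes precedence over
#' eye). The evidence-depth scheme splits into targets supported by
#' multiple experiment types versus a single type. Both schemes partition
#' the full target set.
#'
#' @param dtris DTRI frame.
#' @param tf Entrez id of the TF (must occur among the DTRIs).
#' @param scheme `"context"` or `"evidence_depth"`.
#' @return Named list of target-id vectors, plus an `"all"` entry.
#' @export
subset_targets <- function(dtris, tf,
                           scheme = c("context", "evidence_depth")) {
  scheme <- match.arg(scheme)
  d <- dtris[dtris$tf_entrez == tf, , drop = FALSE]
  if (nrow(d) == 0) stop("TF ", tf, " has no curated targets")
  sets <- if (scheme == "context") {
    list(CNS = d$target_entrez[d$context_category == "CNS"],
         eye = d$target_entrez[d$context_category == "eye"],
         other = d$target_entrez[d$context_category == "other"])
  } else {
    list(multi_evidence = d$target_entrez[d$n_evidence_types >= 2],
         single_evidence = d$target_entrez[d$n_evidence_types == 1])
  }
  c(list(all = d$target_entrez), sets)
}

#' Benchmark a TF's curated targets against perturbation screens
#'
#' For each target subset (all targets plus the context and evidence-depth
#' partitions) with at least `min_targets` genes in the evaluation
#' universe, computes the threshold-free AUROC with a bootstrap confidence
#' interval on the evaluation ranking, and hypergeometric
#' overrepresentation in each screen's FDR hit list. With more than one
#' screen the evaluation ranking is the consensus ranking over the shared
#' gene universe; subsets below the threshold are reported as skipped.
#'
#' @param dtris DTRI frame.
#' @param screens Nonempty list of `de_result` objects for the TF.
#' @param tf TF Entrez id.
#' @param min_targets Minimum targets in the universe (default 10).
#' @param fdr Hit-list FDR threshold (default 0.1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Optional RNG seed.
#' @return List of class `benchmark_report`.
#' @export
benchmark_tf <- function(dtris, screens, tf, min_targets = 10, fdr = 0.1,
                         n_boot = 1000, seed = NULL) {
  stopifnot(length(screens) >= 1)
  if (!is.null(seed)) set.seed(seed)
  rankings <- lapply(screens, make_ranking)
  eval_ranking <- if (length(rankings) > 1) consensus_ranking(rankings)
                  else rankings[[1]]
  universe <- eval_ranking$gene
  hitsets <- lapply(screens, hit_list, fdr = fdr)

  sets <- c(subset_targets(dtris, tf, "context")[-1],
            subset_targets(dtris, tf, "evidence_depth"))
  sets <- sets[c("all", "CNS", "eye", "other", "multi_evidence",
                 "single_evidence")]

  entries <- lapply(names(sets), function(nm) {
    tg <- intersect(sets[[nm]], universe)
    if (length(tg) < min_targets) {
      return(list(category = nm, n_in_universe = length(tg),
                  skipped = TRUE))
    }
    a <- auroc(eval_ranking, tg)
    ci <- bootstrap_auroc_ci(eval_ranking, tg, n_boot = n_boot)
    hg <- lapply(seq_along(screens), function(i) {
      suppressMessages(
        hypergeom_overrep(intersect(hitsets[[i]], universe), tg, universe))
    })
    names(hg) <- vapply(screens, function(s) {
      ds <- attr(s, "dataset")
      if (is.null(ds)) "screen" else as.character(ds)
    }, character(1))
    list(category = nm, n_in_universe = length(tg), skipped = FALSE,
         auroc = a$statistic, auroc_p = a$p_value,
         ci = list(low = ci[1], high = ci[2]), hypergeom = hg)
  })
  names(entries) <- names(sets)
  structure(list(tf = tf, n_screens = length(screens),
                 consensus = length(screens) > 1,
                 universe_size = length(universe), min_targets = min_targets,
                 fdr = fdr, n_boot = n_boot, results = entries),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat(sprintf("benchmark_report: TF %s | %d screen(s)%s | universe %d genes\n",
              x$tf, x$n_screens, if (x$consensus) " (consensus)" else "",
              x$universe_size))
  for (e in x$results) {
    if (isTRUE(e$skipped)) {
      cat(sprintf("  %-16s skipped (%d targets in universe < %d)\n",
                  e$category, e$n_in_universe, x$min_targets))
    } else {
      cat(sprintf("  %-16s n=%d AUROC %.3f (95%% CI %.3f-%.3f) p = %.3g\n",
                  e$category, e$n_in_universe, e$auroc, e$ci$low, e$ci$high,
                  e$auroc_p))
    }
  }
  invisible(x)
}

#' Write a benchmark report as JSON
#'
#' @param report A `benchmark_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_benchmark_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", force = TRUE)
  invisible(path)
}
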