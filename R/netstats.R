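#' Build the directed DTRI network
#'
#' Nodes are all genes appearing as TF or target; each DTRI contributes one
#' directed edge. The network is simple by construction of the DTRI table
#' (one row per unique pair); autoregulatory self-loops are retained.
#'
#' @param dtris DTRI frame (or any data frame whose first two columns are
#'   `tf_entrez` and `target_entrez`).
#' @return An [igraph::igraph] directed graph with vertex name order
#'   deterministic (sorted ids).
#' @export
build_network <- function(dtris) {
  edges <- data.frame(from = as.character(dtris$tf_entrez),
                      to = as.character(dtris$target_entrez),
                      stringsAsFactors = FALSE)
  nodes <- sort(unique(c(edges$from, edges$to)))
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

#' Read / write a network edge list
#'
#' @param path TSV with columns `tf_entrez`, `target_entrez`.
#' @param net An igraph directed graph.
#' @return A directed igraph (read); `path` invisibly (write).
#' @export
read_edge_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           na.strings = "NA", fileEncoding = "UTF-8")
  stopifnot(all(c("tf_entrez", "target_entrez") %in% names(tab)))
  build_network(tab)
}

#' @rdname read_edge_table
#' @export
write_edge_table <- function(net, path) {
  el <- igraph::as_edgelist(net, names = TRUE)
  utils::write.table(
    data.frame(tf_entrez = el[, 1], target_entrez = el[, 2]),
    path, sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8")
  invisible(path)
}

#' Number of reachable ordered gene pairs
#'
#' Counts ordered pairs (u, v), u != v, such that v can be reached from u
#' along at least one directed path. Self-loops never make a node reachable
#' from itself for this count.
#'
#' @param net Directed igraph.
#' @return Integer count, at most n(n-1).
#' @export
reachable_pairs <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0) return(0L)
  d <- igraph::distances(net, mode = "out")
  as.integer(sum(is.finite(d)) - n)
}

#' Number of cliques of a minimum size, ignoring directionality
#'
#' Complete subgraphs (all cliques, not only maximal ones) of at least
#' `min_size` nodes in the undirected projection, after removing self-loops
#' and merging reciprocal edges.
#'
#' @param net Directed igraph.
#' @param min_size Minimum clique size (default 3).
#' @return Integer count.
#' @export
count_cliques <- function(net, min_size = 3) {
  stopifnot(min_size >= 2)
  u <- igraph::as_undirected(igraph::simplify(net, remove.loops = TRUE),
                             mode = "collapse")
  length(igraph::cliques(u, min = min_size))
}

#' Number of weakly connected components
#'
#' @param net Directed igraph; must be nonempty.
#' @return Integer count of connected components of the undirected
#'   projection.
#' @export
weak_components <- function(net) {
  if (igraph::vcount(net) == 0) stop("network is empty")
  igraph::components(net, mode = "weak")$no
}

#' All three connectivity metrics at once
#'
#' @param net Directed igraph.
#' @return Named list: `reachable_pairs`, `n_cliques`, `n_components`.
#' @export
connectivity_metrics <- function(net) {
  list(reachable_pairs = reachable_pairs(net),
       n_cliques = count_cliques(net),
       n_components = weak_components(net))
}

#' Degree-preserving rewiring of a directed network
#'
#' Randomises the wiring by repeated edge swaps that keep every node's in-
#' and out-degree fixed; swaps that would create duplicate edges or
#' self-loops are rejected. The swap budget is `swap_multiplier` times the
#' edge count. Degree preservation is asserted on every call.
#'
#' @param net Directed igraph with at least 2 edges.
#' @param swap_multiplier Swap attempts per edge (default 10).
#' @return A rewired directed igraph over the same vertex set.
#' @export
rewire_degree_preserving <- function(net, swap_multiplier = 10) {
  m <- igraph::ecount(net)
  if (m < 2) stop("rewiring needs at least 2 edges")
  # Each successful swap is a transposition of edge heads; on small graphs
  # where no swap is ever rejected, a fixed trial count would freeze the
  # permutation parity and make half the configuration space unreachable.
  # A random extra trial restores ergodicity.
  niter <- swap_multiplier * m + stats::rbinom(1, 1, 0.5)
  out <- igraph::rewire(
    net, igraph::keeping_degseq(loops = FALSE, niter = niter))
  stopifnot(
    identical(igraph::degree(out, mode = "in"),
              igraph::degree(net, mode = "in")),
    identical(igraph::degree(out, mode = "out"),
              igraph::degree(net, mode = "out")))
  out
}

#' Connectivity null ensemble from degree-preserving permutations
#'
#' Generates `n_perm` independent degree-preserving rewirings of the
#' observed network and scores each with the three connectivity metrics,
#' yielding empirical null distributions.
#'
#' @param net Directed igraph.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Optional RNG seed for reproducibility.
#' @param swap_multiplier Swap attempts per edge per rewiring.
#' @return List of class `null_ensemble` with a per-permutation metric
#'   `data.frame` and the generation parameters.
#' @export
permutation_null <- function(net, n_perm = 1000, seed = NULL,
                             swap_multiplier = 10) {
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", n_perm)
  for (i in seq_len(n_perm)) {
    r <- rewire_degree_preserving(net, swap_multiplier)
    rows[[i]] <- as.data.frame(connectivity_metrics(r))
  }
  structure(list(metrics = do.call(rbind, rows), n_perm = n_perm,
                 seed = seed, swap_multiplier = swap_multiplier),
            class = "null_ensemble")
}

#' One-tailed empirical p-value against a permutation null
#'
#' Uses the add-one correction (r + 1) / (n + 1), where r counts null
#' values as or more extreme than the observed value in the stated tail, so
#' the p-value is never zero; ties count as as-extreme.
#'
#' @param observed Observed statistic.
#' @param null_values Numeric vector of null statistics (nonempty).
#' @param tail `"greater"` (observed unusually large) or `"less"`.
#' @return Empirical p-value in (0, 1].
#' @export
empirical_pvalue <- function(observed, null_values,
                             tail = c("greater", "less")) {
  tail <- match.arg(tail)
  stopifnot(length(null_values) > 0)
  r <- if (tail == "greater") sum(null_values >= observed)
       else sum(null_values <= observed)
  (r + 1) / (length(null_values) + 1)
}

#' Connectivity report: observed metrics against the rewiring null
#'
#' Scores the observed network, builds the permutation null, and reports
#' per-metric observed value, null mean and SD, and one-tailed empirical
#' p-values (greater tail for reachable pairs and cliques, less tail for
#' components, matching the directional hypotheses of excess connectivity).
#'
#' @inheritParams permutation_null
#' @return List of class `network_report`.
#' @export
network_report <- function(net, n_perm = 1000, seed = NULL,
                           swap_multiplier = 10) {
  observed <- connectivity_metrics(net)
  ens <- permutation_null(net, n_perm = n_perm, seed = seed,
                          swap_multiplier = swap_multiplier)
  tails <- c(reachable_pairs = "greater", n_cliques = "greater",
             n_components = "less")
  metrics <- lapply(names(tails), function(m) {
    nulls <- ens$metrics[[m]]
    list(observed = observed[[m]], null_mean = mean(nulls),
         null_sd = stats::sd(nulls), tail = unname(tails[m]),
         p_value = empirical_pvalue(observed[[m]], nulls, tails[m]))
  })
  names(metrics) <- names(tails)
  structure(list(n_nodes = igraph::vcount(net),
                 n_edges = igraph::ecount(net),
                 n_perm = n_perm, seed = seed,
                 swap_multiplier = swap_multiplier, metrics = metrics),
            class = "network_report")
}

#' @export
print.network_report <- function(x, ...) {
  cat(sprintf("network_report: %d nodes, %d edges, %d permutations\n",
              x$n_nodes, x$n_edges, x$n_perm))
  for (m in names(x$metrics)) {
    s <- x$metrics[[m]]
    cat(sprintf("  %-16s observed %g | null %.1f +/- %.1f | one-tailed (%s) p = %.4g\n",
                m, s$observed, s$null_mean, s$null_sd, s$tail, s$p_value))
  }
  invisible(x)
}

#' Write a connectivity report as JSON
#'
#' @param report A `network_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
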