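# Shared fixtures and independent brute-force oracles for the test suite.

# --- record fixtures --------------------------------------------------------

# A fully specified experiment record; override any field.
make_record <- function(...) {
  base <- list(
    experiment_id = "EXP000001", pubmed_id = 12345L,
    tf_symbol = "PAX6", tf_entrez = 5080L, tf_species = "human",
    target_symbol = "NEUROG2", target_entrez = 63973L,
    target_species = "human",
    experiment_type = "perturbation", context_type = "cell_line",
    context_term = "CLO:0000031", developmental_stage = NA,
    mode = "activation", tfbs_offset_bp = NA, is_promoter = NA,
    perturbation_direction = "knockout", perturbation_timing = "induced",
    zygosity = "homozygous",
    binding_method = NA, emsa_protein_source = NA,
    reporter_cre_mutated = NA, mutation_binding_verified = NA)
  mods <- list(...)
  base[names(mods)] <- mods
  base
}

record_frame <- function(records) {
  cols <- dtrinet::experiment_table_columns()
  do.call(rbind, lapply(records, function(r) {
    df <- as.data.frame(lapply(r[cols], function(x) {
      if (is.null(x)) NA else x
    }), stringsAsFactors = FALSE)
    names(df) <- cols
    df
  }))
}

# Write records to a temp TSV and read them back through the validator.
read_records <- function(records, homology = NULL) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  df <- record_frame(records)
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  read_experiment_table(path, homology = homology)
}

# Binding and reporter record shorthands.
binding_record <- function(...) {
  make_record(experiment_type = "binding", binding_method = "chip",
              mode = "unreported",
              perturbation_direction = NA, perturbation_timing = NA,
              zygosity = NA, ...)
}
reporter_record <- function(...) {
  make_record(experiment_type = "reporter", reporter_cre_mutated = FALSE,
              perturbation_direction = NA, perturbation_timing = NA,
              zygosity = NA, ...)
}

# --- toy ontology and homology ---------------------------------------------

toy_dag <- function() {
  ontology_dag(data.frame(
    child_curie = c("UBERON:0001017", "UBERON:0000970", "UBERON:0002107",
                    "UBERON:0000955", "UBERON:0002240", "CL:0000540",
                    "UBERON:0000966"),
    parent_curie = c("UBERON:0000000", "UBERON:0000000", "UBERON:0000000",
                     "UBERON:0001017", "UBERON:0001017", "UBERON:0000955",
                     "UBERON:0000970"),
    stringsAsFactors = FALSE))
}

toy_homology <- function() {
  homology_table(data.frame(
    species = c("human", "human", "mouse", "mouse"),
    entrez_id = c(5080L, 63973L, 18508L, 11924L),
    human_entrez_id = c(5080L, 63973L, 5080L, 63973L),
    stringsAsFactors = FALSE), provenance = "toy")
}

# --- graph oracles ----------------------------------------------------------

# Random simple digraph as an edge frame (no self-loops).
random_digraph <- function(n_nodes, n_edges, seed) {
  set.seed(seed)
  all_pairs <- expand.grid(from = seq_len(n_nodes), to = seq_len(n_nodes))
  all_pairs <- all_pairs[all_pairs$from != all_pairs$to, ]
  idx <- sample(nrow(all_pairs), min(n_edges, nrow(all_pairs)))
  data.frame(tf_entrez = all_pairs$from[idx],
             target_entrez = all_pairs$to[idx])
}

graph_adjacency <- function(net) {
  el <- igraph::as_edgelist(net, names = TRUE)
  nodes <- igraph::V(net)$name
  adj <- matrix(FALSE, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  adj[el] <- TRUE
  adj
}

# Transitive closure by repeated boolean squaring.
oracle_reachable_pairs <- function(net) {
  adj <- graph_adjacency(net)
  diag(adj) <- FALSE
  reach <- adj
  repeat {
    nxt <- reach | ((reach %*% reach) > 0)
    diag(nxt) <- FALSE
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  sum(reach)
}

# Exhaustive clique enumeration over all node subsets.
oracle_count_cliques <- function(net, min_size = 3) {
  adj <- graph_adjacency(net)
  und <- adj | t(adj)
  diag(und) <- FALSE
  n <- nrow(und)
  total <- 0L
  for (k in min_size:n) {
    if (k > n) break
    combs <- utils::combn(n, k)
    for (j in seq_len(ncol(combs))) {
      sub <- und[combs[, j], combs[, j], drop = FALSE]
      if (all(sub[upper.tri(sub)])) total <- total + 1L
    }
  }
  total
}

# Connected components of the undirected projection by BFS.
oracle_weak_components <- function(net) {
  adj <- graph_adjacency(net)
  und <- adj | t(adj)
  n <- nrow(und)
  seen <- rep(FALSE, n)
  comps <- 0L
  for (i in seq_len(n)) {
    if (seen[i]) next
    comps <- comps + 1L
    frontier <- i
    while (length(frontier) > 0) {
      seen[frontier] <- TRUE
      nxt <- unique(unlist(lapply(frontier, function(v) which(und[v, ]))))
      frontier <- nxt[!seen[nxt]]
    }
  }
  comps
}

# --- statistics oracles -----------------------------------------------------

# AUROC as the fraction of (target, non-target) pairs where the target has
# the smaller p-value (ties count one half).
oracle_auroc <- function(pvals, is_target) {
  pt <- pvals[is_target]
  pn <- pvals[!is_target]
  tot <- 0
  for (a in pt) tot <- tot + sum(a < pn) + 0.5 * sum(a == pn)
  tot / (length(pt) * length(pn))
}

# Upper-tail hypergeometric probability by exhaustive enumeration of draws.
oracle_hypergeom <- function(k, K, n, N) {
  stopifnot(N <= 12)
  draws <- utils::combn(N, n)
  in_targets <- seq_len(K)   # first K elements are the targets
  hits <- vapply(seq_len(ncol(draws)), function(j) {
    sum(draws[, j] %in% in_targets)
  }, numeric(1))
  mean(hits >= k)
}

# Benjamini-Hochberg step-up selection done literally.
oracle_bh_hits <- function(pvals, q) {
  m <- length(pvals)
  ord <- order(pvals)
  keep_up_to <- 0L
  for (i in seq_len(m)) {
    if (pvals[ord[i]] <= i / m * q) keep_up_to <- i
  }
  if (keep_up_to == 0) integer(0) else sort(ord[seq_len(keep_up_to)])
}

# Spearman correlation computed as Pearson on midranks.
oracle_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# Minimal DE screen from a p-value vector.
de_from_p <- function(p, genes = seq_along(p), dataset = "d1") {
  de_result(data.frame(gene_entrez = genes, log2fc = 0, pvalue = p),
            dataset = dataset)
}
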