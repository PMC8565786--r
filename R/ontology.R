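#' Construct an is_a ontology DAG from an edge list
#'
#' A minimal projection of a tissue/cell ontology: terms are CURIEs and
#' edges are child-to-parent `is_a` links. Cycles are rejected. Descendant
#' queries are used to decide whether an experimental context falls under an
#' anatomical root such as the central nervous system (UBERON:0001017) or
#' the eye (UBERON:0000970).
#'
#' @param edges Data frame with columns `child_curie`, `parent_curie`.
#' @param extra_terms Terms to include even if they occur in no edge.
#' @return An object of class `ontology_dag`.
#' @export
ontology_dag <- function(edges, extra_terms = character(0)) {
  stopifnot(all(c("child_curie", "parent_curie") %in% names(edges)))
  edges$child_curie <- as.character(edges$child_curie)
  edges$parent_curie <- as.character(edges$parent_curie)
  terms <- sort(unique(c(edges$child_curie, edges$parent_curie, extra_terms)))
  if (nrow(edges) > 0) {
    g <- igraph::graph_from_data_frame(
      edges[, c("child_curie", "parent_curie")], directed = TRUE,
      vertices = terms)
    if (!igraph::is_dag(g)) stop("ontology edge list contains a cycle")
  }
  children <- split(edges$child_curie, edges$parent_curie)
  structure(list(terms = terms, edges = edges, children = children),
            class = "ontology_dag")
}

#' Read an ontology edge-list TSV
#'
#' @param path TSV with columns `child_curie`, `parent_curie`.
#' @return An `ontology_dag`.
#' @export
read_ontology_edges <- function(path) {
  edges <- utils::read.delim(path, sep = "\t", header = TRUE,
                             na.strings = "NA", fileEncoding = "UTF-8",
                             colClasses = "character")
  ontology_dag(edges)
}

#' All descendants of a term, including the term itself
#'
#' @param dag An `ontology_dag`.
#' @param root Term CURIE.
#' @return Character vector: the root plus all transitive children.
#' @export
dag_descendants <- function(dag, root) {
  stopifnot(inherits(dag, "ontology_dag"))
  if (!(root %in% dag$terms)) {
    stop("term '", root, "' is not in the ontology")
  }
  seen <- character(0)
  frontier <- root
  while (length(frontier) > 0) {
    seen <- c(seen, frontier)
    kids <- unlist(dag$children[frontier], use.names = FALSE)
    frontier <- setdiff(unique(kids), seen)
  }
  sort(unique(seen))
}

#' @export
print.ontology_dag <- function(x, ...) {
  cat("ontology_dag:", length(x$terms), "terms,", nrow(x$edges),
      "is_a links\n")
  invisible(x)
}
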