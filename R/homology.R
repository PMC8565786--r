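#' Read a homology table
#'
#' The table maps (species, native Entrez id) to the human Entrez id used for
#' reporting, in the style of an NCBI HomoloGene projection. Human genes map
#' to themselves; rows saying otherwise are rejected. The mapping must be a
#' function: each (species, entrez) key maps to at most one human id.
#'
#' @param path TSV with columns `species`, `entrez_id`, `human_entrez_id`.
#' @param provenance Free-text provenance label stored on the result.
#' @return A `data.frame` of class `homology_table`.
#' @export
read_homology_table <- function(path, provenance = basename(path)) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           na.strings = "NA", fileEncoding = "UTF-8")
  missing <- setdiff(c("species", "entrez_id", "human_entrez_id"), names(tab))
  if (length(missing) > 0) {
    stop("homology table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  homology_table(tab, provenance = provenance)
}

#' Construct a homology table from a data frame
#'
#' @param tab Data frame with `species`, `entrez_id`, `human_entrez_id`.
#' @param provenance Provenance label.
#' @return A `data.frame` of class `homology_table`.
#' @export
homology_table <- function(tab, provenance = "constructed") {
  tab$entrez_id <- as.integer(tab$entrez_id)
  tab$human_entrez_id <- as.integer(tab$human_entrez_id)
  key <- paste(tab$species, tab$entrez_id)
  if (anyDuplicated(key)) {
    amb <- unique(key[duplicated(key)])
    stop("homology mapping is not a function; ambiguous key(s): ",
         paste(amb, collapse = ", "))
  }
  hum <- tab$species == "human"
  if (any(hum & tab$entrez_id != tab$human_entrez_id)) {
    stop("human keys must map to themselves")
  }
  attr(tab, "provenance") <- provenance
  class(tab) <- c("homology_table", "data.frame")
  tab
}

#' Map genes to human orthologs
#'
#' Human genes pass through unchanged. Mouse genes are mapped through the
#' homology table; a mouse gene with no ortholog entry keeps its own Entrez
#' id as the reporting identifier and is flagged unmapped (a flagged
#' pass-through, not an error). The operation is idempotent: a human id is a
#' fixed point.
#'
#' @param entrez_id Integer vector of native Entrez ids.
#' @param species Character vector over `{"human", "mouse"}` (recycled).
#' @param homology A `homology_table`.
#' @return A list with integer `human_entrez_id` and logical `unmapped`.
#' @export
map_to_human <- function(entrez_id, species, homology) {
  n <- max(length(entrez_id), length(species))
  entrez_id <- as.integer(rep_len(entrez_id, n))
  species <- rep_len(species, n)
  bad <- !(species %in% c("human", "mouse"))
  if (any(bad)) stop("unknown species: ", paste(unique(species[bad]),
                                                collapse = ", "))
  out <- entrez_id
  unmapped <- rep(FALSE, n)
  is_mouse <- species == "mouse"
  if (any(is_mouse)) {
    idx <- match(paste("mouse", entrez_id[is_mouse]),
                 paste(homology$species, homology$entrez_id))
    hit <- !is.na(idx)
    out[is_mouse][hit] <- homology$human_entrez_id[idx[hit]]
    unmapped[is_mouse][!hit] <- TRUE
  }
  list(human_entrez_id = out, unmapped = unmapped)
}

#' Map a single gene reference to its human ortholog
#'
#' @param gene Named list with `entrez_id`, `species` and optionally
#'   `symbol`.
#' @param homology A `homology_table`.
#' @return The gene list with `human_entrez_id` and `unmapped` filled in.
#' @export
to_human_ortholog <- function(gene, homology) {
  stopifnot(is.list(gene), !is.null(gene$entrez_id), !is.null(gene$species))
  m <- map_to_human(gene$entrez_id, gene$species, homology)
  gene$human_entrez_id <- m$human_entrez_id
  gene$unmapped <- m$unmapped
  gene
}
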