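#' Read a flat key = value run configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored. Numeric-looking values are converted.
#'
#' @param path Config file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  out <- list()
  for (m in kv) {
    if (length(m) != 3) next
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Default run configuration
#'
#' Analysis defaults: 2 kb binding-site proximity threshold, FDR 0.1 hit
#' lists, 1000 network permutations with a 10x swap budget, 1000 bootstrap
#' replicates, and a minimum of 10 targets per benchmarked set.
#'
#' @param input_dir Directory holding the input bundle (as written by
#'   [generate_bundle()]).
#' @param output_dir Directory for pipeline artifacts.
#' @param seed Global seed; stages derive deterministic sub-seeds from it.
#' @param ... Overrides for any default parameter.
#' @return Named list.
#' @export
run_config <- function(input_dir, output_dir, seed = 1, ...) {
  cfg <- list(
    input_dir = input_dir, output_dir = output_dir, seed = seed,
    threshold_bp = 2000, fdr = 0.1, n_perm = 1000, n_boot = 1000,
    min_targets = 10, swap_multiplier = 10,
    experiments = file.path(input_dir, "experiments.tsv"),
    homology = file.path(input_dir, "homology.tsv"),
    ontology = file.path(input_dir, "ontology_edges.tsv"),
    edges = file.path(input_dir, "edge_list.tsv"),
    screen_manifest = file.path(input_dir, "screen_manifest.tsv"))
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

#' Run the curation analysis pipeline
#'
#' Executes the requested stages in dependency order: `validate` (read and
#' validate the experiment table), `aggregate` (collapse to DTRIs),
#' `summarize` (stratified count tables), `netstats` (connectivity against
#' the rewiring null) and `benchmark` (curated targets against the
#' perturbation screens listed in the manifest). Each stage writes TSV or
#' JSON artifacts into the output directory; a manifest of artifacts with
#' content hashes and the resolved configuration are written alongside.
#'
#' @param config List from [run_config()] or [read_run_config()].
#' @param stages Subset of
#'   `c("validate", "aggregate", "summarize", "netstats", "benchmark")`.
#' @return List with `artifacts` (paths), `manifest` (path/hash frame) and
#'   the stage results, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("validate", "aggregate", "summarize",
                                    "netstats", "benchmark")) {
  order_all <- c("validate", "aggregate", "summarize", "netstats",
                 "benchmark")
  stages <- order_all[order_all %in% match.arg(stages, order_all,
                                               several.ok = TRUE)]
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  need <- function(path, stage) {
    if (is.null(path) || !file.exists(path)) {
      stop("stage '", stage, "' needs missing input: ",
           if (is.null(path)) "(unset path)" else path)
    }
  }
  artifacts <- list()
  results <- list()
  records <- dtris <- dag <- NULL

  load_records <- function() {
    need(config$experiments, "validate")
    need(config$homology, "validate")
    hom <- read_homology_table(config$homology)
    read_experiment_table(config$experiments, homology = hom)
  }

  if (any(c("validate", "aggregate", "summarize", "benchmark") %in%
            stages)) {
    records <- load_records()
    results$validate <- list(n_records = nrow(records))
  }
  if (any(c("aggregate", "summarize", "benchmark") %in% stages)) {
    need(config$ontology, "aggregate")
    dag <- read_ontology_edges(config$ontology)
    dtris <- aggregate_dtris(records, dag,
                             threshold_bp = config$threshold_bp)
    p <- file.path(config$output_dir, "dtris.tsv")
    write_dtri_table(dtris, p)
    artifacts$dtris <- p
    results$aggregate <- list(n_dtris = nrow(dtris))
  }
  if ("summarize" %in% stages) {
    s <- summarize_curation(dtris, records)
    p <- file.path(config$output_dir, "curation_summary.json")
    write_summary_json(s, p)
    artifacts$summary <- p
    results$summarize <- s
  }
  if ("netstats" %in% stages) {
    need(config$edges, "netstats")
    net <- read_edge_table(config$edges)
    rep <- network_report(net, n_perm = config$n_perm,
                          seed = config$seed + 1L,
                          swap_multiplier = config$swap_multiplier)
    p <- file.path(config$output_dir, "network_report.json")
    write_network_report(rep, p)
    artifacts$netstats <- p
    results$netstats <- rep
  }
  if ("benchmark" %in% stages) {
    need(config$screen_manifest, "benchmark")
    man <- utils::read.delim(config$screen_manifest, sep = "\t",
                             header = TRUE, fileEncoding = "UTF-8")
    tf <- as.integer(man$tf_entrez[1])
    screens <- lapply(seq_len(nrow(man)), function(i) {
      read_de_table(file.path(dirname(config$screen_manifest),
                              man$path[i]),
                    dataset = man$dataset_id[i], tf = tf)
    })
    rep <- benchmark_tf(dtris, screens, tf,
                        min_targets = config$min_targets,
                        fdr = config$fdr, n_boot = config$n_boot,
                        seed = config$seed + 2L)
    p <- file.path(config$output_dir, "benchmark_report.json")
    write_benchmark_report(rep, p)
    artifacts$benchmark <- p
    results$benchmark <- rep
  }

  cfg_path <- file.path(config$output_dir, "resolved_config.json")
  jsonlite::write_json(config, cfg_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  artifacts$config <- cfg_path
  files <- unlist(artifacts, use.names = FALSE)
  manifest <- data.frame(artifact = names(artifacts), path = files,
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  man_path <- file.path(config$output_dir, "artifact_manifest.tsv")
  utils::write.table(manifest, man_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(artifacts = artifacts, manifest = manifest,
                 results = results))
}
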