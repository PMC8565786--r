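#' Simulation configuration for the synthetic curation pipeline
#'
#' Bundles every parameter of the synthetic-data generators. The defaults
#' emulate the marginal composition of a literature-curation effort of the
#' scale this package targets: ~250 TFs, ~800 targets and ~1,500 unique
#' interactions supported by ~3,600 experiments; an evidence mixture with
#' 27% of interactions supported by all three experiment types and 64% by
#' two or more; roughly a quarter of experiments in primary tissue (26% of
#' primary experiments in the CNS, three quarters of those embryonic); 24%
#' repressive interactions among those with a reported mode; 91% proximal
#' binding sites among the ~44% of interactions with an annotated position;
#' and a species split of roughly one third human-only, half mouse-only and
#' 14% supported in both species.
#'
#' @param seed Integer seed; every generator derives its RNG stream from it
#'   and records it in its output.
#' @param n_tfs,n_targets,n_dtris Gene-pool and interaction counts.
#' @param shared_tf_fraction Fraction of TFs that also occur as targets.
#' @param dtri_zipf Skew exponent of the per-TF target-count distribution.
#' @param evidence_mix Probabilities of the 7 nonempty evidence-type
#'   combinations (names are sorted semicolon-joined types).
#' @param extra_experiment_rate Poisson rate of extra experiments per
#'   (interaction, evidence type) beyond the first.
#' @param context_mix Experiment-level proportions of cell-line, primary
#'   and in-vitro contexts (in-vitro arises only from EMSA).
#' @param primary_context_mix Split of primary-context experiments across
#'   CNS, eye and other tissue branches.
#' @param embryonic_fraction_cns Fraction of primary CNS experiments with
#'   an embryonic stage label.
#' @param mode_reported_fraction,repressive_fraction,both_mode_fraction
#'   Mode-of-regulation marginals at the interaction level (repressive and
#'   both fractions are conditional on a reported mode).
#' @param tfbs_annotated_fraction,proximal_fraction,both_tfbs_fraction
#'   Binding-site position marginals (proximal and both fractions are
#'   conditional on annotation).
#' @param species_mix Interaction-level species support proportions over
#'   human_only / mouse_only / both / mixed_only.
#' @param emsa_fraction Fraction of binding experiments using EMSA.
#' @param mutated_reporter_fraction Fraction of reporter assays testing a
#'   mutated element.
#' @param unmapped_fraction Fraction of mouse genes absent from the
#'   homology fixture.
#' @param zipf_exponent,zero_paper_fraction,max_papers_per_tf,
#'   popularity_scale,popularity_noise Candidate-corpus parameters.
#' @param target_bias Preferential-attachment strength beta (>= 0) of the
#'   biased network generator; 0 gives unbiased uniform target choice.
#' @param universe_size,n_screens,rho,signal_shape,screen_noise
#'   Differential-expression screen parameters: gene universe size, number
#'   of screens, per-category responsive fractions, Beta(a, 1) signal shape
#'   for responsive p-values, and per-screen log-normal jitter of the
#'   shape.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_tfs = 250, n_targets = 800, n_dtris = 1500,
                       shared_tf_fraction = 0.48,
                       dtri_zipf = 1.0,
                       evidence_mix = c(
                         "binding" = 0.18,
                         "perturbation" = 0.12,
                         "reporter" = 0.06,
                         "binding;perturbation" = 0.15,
                         "binding;reporter" = 0.15,
                         "perturbation;reporter" = 0.07,
                         "binding;perturbation;reporter" = 0.27),
                       extra_experiment_rate = 0.25,
                       context_mix = c(cell_line = 0.60, primary = 0.27,
                                       in_vitro = 0.13),
                       primary_context_mix = c(CNS = 0.26, eye = 0.10,
                                               other = 0.64),
                       embryonic_fraction_cns = 0.74,
                       mode_reported_fraction = 0.88,
                       repressive_fraction = 0.24,
                       both_mode_fraction = 0.017,
                       tfbs_annotated_fraction = 0.44,
                       proximal_fraction = 0.91,
                       both_tfbs_fraction = 0.023,
                       species_mix = c(human_only = 0.33, mouse_only = 0.53,
                                       both = 0.14, mixed_only = 0.00),
                       emsa_fraction = 0.32,
                       mutated_reporter_fraction = 0.44,
                       unmapped_fraction = 0.05,
                       mean_dtris_per_paper = 1.9,
                       zipf_exponent = 1.5,
                       zero_paper_fraction = 0.34,
                       max_papers_per_tf = 2000,
                       popularity_scale = 20,
                       popularity_noise = 0.2,
                       target_bias = 8,
                       universe_size = 10000,
                       n_screens = 3,
                       rho = c(CNS = 0.72, eye = 0.32, other = 0.12),
                       signal_shape = 0.1,
                       screen_noise = 0.2) {
  cfg <- as.list(environment())
  for (v in list(cfg$evidence_mix, cfg$context_mix,
                 cfg$primary_context_mix, cfg$species_mix)) {
    if (abs(sum(v) - 1) > 1e-8) stop("probability vector must sum to 1")
  }
  stopifnot(cfg$target_bias >= 0, cfg$zipf_exponent > 0,
            all(cfg$rho >= 0 & cfg$rho <= 1), cfg$signal_shape > 0)
  class(cfg) <- "sim_config"
  cfg
}

# Gene pools shared by the generators: TF ids, target ids (some TFs also
# occur as targets), and the mouse id convention (human id + 100000).
sim_gene_pools <- function(config) {
  tf_pool <- 1000L + seq_len(config$n_tfs)
  n_shared <- min(round(config$shared_tf_fraction * config$n_tfs),
                  config$n_tfs, config$n_targets)
  shared <- tf_pool[seq_len(n_shared)]
  extra <- 5000L + seq_len(config$n_targets - n_shared)
  list(tf_pool = tf_pool,
       target_pool = c(shared, extra),
       all_genes = sort(unique(c(tf_pool, shared, extra))))
}

mouse_id <- function(human_id) as.integer(human_id + 100000L)

#' Generate the homology and ontology fixtures
#'
#' The toy homology table pairs each mouse gene (human id + 100000) with
#' its human counterpart, with a configurable fraction left unmapped. The
#' toy ontology has a tissue root, a CNS branch rooted at UBERON:0001017,
#' a disjoint eye branch rooted at UBERON:0000970, and unrelated tissue
#' branches.
#'
#' @param config A `sim_config`.
#' @return List with `homology` (a `homology_table`), `dag` (an
#'   `ontology_dag`) and `unmapped` (mouse ids left out of the table).
#' @export
generate_fixtures <- function(config = sim_config()) {
  set.seed(config$seed + 101L)
  pools <- sim_gene_pools(config)
  genes <- pools$all_genes
  n_unmapped <- round(config$unmapped_fraction * length(genes))
  unmapped_h <- if (n_unmapped > 0) sample(genes, n_unmapped) else integer(0)
  mapped_h <- setdiff(genes, unmapped_h)
  tab <- data.frame(species = "human", entrez_id = genes,
                    human_entrez_id = genes)
  if (length(mapped_h) > 0) {
    tab <- rbind(tab, data.frame(species = "mouse",
                                 entrez_id = mouse_id(mapped_h),
                                 human_entrez_id = mapped_h))
  }
  hom <- homology_table(tab, provenance = "synthetic toy homology")

  edges <- rbind(
    data.frame(child_curie = c("UBERON:0001017", "UBERON:0000970",
                               "UBERON:0002107", "UBERON:0002113",
                               "UBERON:0000948"),
               parent_curie = "UBERON:0000000"),
    data.frame(child_curie = c("UBERON:0000955", "UBERON:0002240",
                               "UBERON:0001893"),
               parent_curie = "UBERON:0001017"),
    data.frame(child_curie = c("CL:0000540", "CL:0000047"),
               parent_curie = "UBERON:0000955"),
    data.frame(child_curie = c("UBERON:0000966", "CL:0000604"),
               parent_curie = "UBERON:0000970"),
    data.frame(child_curie = "CL:0000182", parent_curie = "UBERON:0002107"))
  dag <- ontology_dag(edges)
  list(homology = hom, dag = dag, unmapped = mouse_id(unmapped_h))
}

#' Generate a popularity-skewed TF-to-candidate-paper corpus
#'
#' Per-TF candidate-paper counts follow a Zipf-like law with a configurable
#' fraction of TFs holding no papers at all; papers are drawn from a shared
#' pool so that some papers are assigned to several TFs; popularity counts
#' are the candidate counts scaled with multiplicative log-normal noise.
#'
#' @param config A `sim_config`.
#' @return A `candidate_corpus` with popularity counts.
#' @export
generate_corpus <- function(config = sim_config()) {
  set.seed(config$seed + 202L)
  pools <- sim_gene_pools(config)
  tfs <- pools$tf_pool
  n <- length(tfs)
  n_zero <- round(config$zero_paper_fraction * n)
  sizes <- round(config$max_papers_per_tf *
                   seq_len(n)^(-config$zipf_exponent))
  sizes <- pmax(sizes, 1L)
  sizes <- sample(sizes)           # detach skew from id order
  zero_idx <- if (n_zero > 0) sample(n, n_zero) else integer(0)
  sizes[zero_idx] <- 0L
  pool_size <- max(10L, round(0.9 * sum(sizes)))
  papers <- lapply(sizes, function(s) {
    if (s == 0) integer(0) else
      100000L + sample.int(pool_size, s, replace = FALSE)
  })
  names(papers) <- tfs
  popularity <- sizes * config$popularity_scale *
    exp(stats::rnorm(n, sd = config$popularity_noise))
  names(popularity) <- tfs
  candidate_corpus(papers[sizes > 0], source = "synthetic",
                   popularity = round(popularity, 3))
}

# Draw the per-DTRI categorical summaries implied by the config.
sim_dtri_plan <- function(config, pairs) {
  n <- nrow(pairs)
  combos <- sample(names(config$evidence_mix), n, replace = TRUE,
                   prob = config$evidence_mix)
  species <- sample(names(config$species_mix), n, replace = TRUE,
                    prob = config$species_mix)
  rep_frac <- config$repressive_fraction
  both_frac <- config$both_mode_fraction
  mode_probs <- c(
    activation = config$mode_reported_fraction * (1 - rep_frac - both_frac),
    repression = config$mode_reported_fraction * rep_frac,
    both = config$mode_reported_fraction * both_frac,
    unreported = 1 - config$mode_reported_fraction)
  modes <- sample(names(mode_probs), n, replace = TRUE, prob = mode_probs)
  tf_probs <- c(
    proximal = config$tfbs_annotated_fraction *
      (config$proximal_fraction - config$both_tfbs_fraction),
    distal = config$tfbs_annotated_fraction * (1 - config$proximal_fraction),
    both = config$tfbs_annotated_fraction * config$both_tfbs_fraction,
    unreported = 1 - config$tfbs_annotated_fraction)
  tfbs <- sample(names(tf_probs), n, replace = TRUE, prob = tf_probs)
  data.frame(pairs, combo = combos, species = species, mode = modes,
             tfbs = tfbs, stringsAsFactors = FALSE)
}

#' Generate experiment-level curation records with known ground truth
#'
#' Draws unique TF-target pairs (TFs skewed by popularity), assigns each an
#' evidence-type combination, species support, mode and binding-site class
#' from the configured mixtures, and expands it into one or more
#' experiment records per evidence type with type-appropriate detail
#' blocks, cellular contexts drawn from the ontology fixture, and papers
#' assigned so that the mean number of interactions per positive paper is
#' about 1.9. Every record passes [validate_experiment_table()]; the
#' interaction-level aggregation of the records reproduces the configured
#' mixtures up to multinomial sampling error.
#'
#' @param config A `sim_config`.
#' @param fixtures Output of [generate_fixtures()] (regenerated when
#'   omitted).
#' @return Typed experiment frame (dialect columns plus human ortholog
#'   columns), with the per-interaction plan in attribute `plan`.
#' @export
generate_experiments <- function(config = sim_config(),
                                 fixtures = generate_fixtures(config)) {
  force(fixtures)   # resolve before seeding this generator's RNG stream
  set.seed(config$seed + 303L)
  pools <- sim_gene_pools(config)
  hom <- fixtures$homology
  mapped_mouse <- hom$entrez_id[hom$species == "mouse"]

  # unique pairs, TF skewed
  tf_w <- seq_along(pools$tf_pool)^(-config$dtri_zipf)
  tf_w <- sample(tf_w)
  pairs <- unique(data.frame(
    tf = sample(pools$tf_pool, config$n_dtris * 3, replace = TRUE,
                prob = tf_w),
    target = sample(pools$target_pool, config$n_dtris * 3, replace = TRUE)))
  pairs <- pairs[pairs$tf != pairs$target, , drop = FALSE]
  if (nrow(pairs) < config$n_dtris) stop("gene pools too small")
  pairs <- pairs[seq_len(config$n_dtris), ]
  plan <- sim_dtri_plan(config, pairs)

  # species support needs mapped mouse genes for the 'both' category
  mappable <- function(g) mouse_id(g) %in% mapped_mouse
  cns_terms <- dag_descendants(fixtures$dag, "UBERON:0001017")
  cns_terms <- setdiff(cns_terms, "UBERON:0001017")
  eye_terms <- setdiff(dag_descendants(fixtures$dag, "UBERON:0000970"),
                       "UBERON:0000970")
  other_terms <- c("UBERON:0002107", "UBERON:0002113", "UBERON:0000948",
                   "CL:0000182")
  cell_lines <- c("CLO:0000031", "CLO:0000019", "CLO:0000511",
                  "freetext:immortalized line")
  # Context correlation within an interaction: contexts repeat across the
  # experiments of one interaction (same labs, same tissues), so primary
  # usage is drawn per interaction and then per experiment within it. This
  # keeps the experiment-level primary share at the configured value while
  # holding the share of interactions with any primary evidence close to
  # the curation-scale pattern (~40% of interactions vs ~26% of
  # experiments).
  p_primary_marg <- config$context_mix[["primary"]] /
    (config$context_mix[["primary"]] + config$context_mix[["cell_line"]])
  p_within <- 0.55
  p_dtri_primary <- min(1, p_primary_marg / p_within)
  dtri_primary <- stats::runif(config$n_dtris) < p_dtri_primary
  dtri_branch <- sample(names(config$primary_context_mix), config$n_dtris,
                        replace = TRUE, prob = config$primary_context_mix)

  # Paper pool sized so that the expected number of interactions per
  # positive paper hits the configured mean under uniform assignment
  # (distinct papers ~ B * (1 - exp(-D/B)) for D interactions, B papers).
  D <- config$n_dtris
  target_mean <- config$mean_dtris_per_paper
  n_papers <- if (target_mean <= 1) 10L * D else {
    f <- function(B) D / (B * (1 - exp(-D / B))) - target_mean
    max(1L, round(stats::uniroot(f, c(D / (2 * target_mean), 50 * D),
                                 tol = 1)$root))
  }
  paper_of_dtri <- 900000L + sample.int(n_papers, config$n_dtris,
                                        replace = TRUE)

  rows <- vector("list", config$n_dtris)
  for (i in seq_len(config$n_dtris)) {
    p <- plan[i, ]
    types <- strsplit(p$combo, ";", fixed = TRUE)[[1]]
    n_per_type <- 1L + stats::rpois(length(types),
                                    config$extra_experiment_rate)
    if (p$species == "both" && sum(n_per_type) < 2) n_per_type[1] <- 2L
    et <- rep(types, n_per_type)
    k <- length(et)

    # per-experiment species assignment honouring the pair's support class
    sp_tf <- sp_tg <- character(k)
    if (p$species == "human_only") {
      sp_tf[] <- sp_tg[] <- "human"
    } else if (p$species == "mouse_only") {
      sp_tf[] <- sp_tg[] <- "mouse"
    } else if (p$species == "both") {
      # both-species support needs mapped mouse orthologs so that all
      # experiments collapse onto the same human pair
      if (mappable(p$tf) && mappable(p$target)) {
        half <- sample(c("human", "mouse"), k, replace = TRUE)
        half[1] <- "human"; half[2] <- "mouse"
        sp_tf <- sp_tg <- half
      } else sp_tf[] <- sp_tg[] <- "human"
    } else {                       # mixed_only: TF and target species differ
      sp_tf[] <- "mouse"; sp_tg[] <- "human"
    }

    # mode per experiment: perturbation and reporter assays always report
    # a direction; binding papers state one only about half the time
    carries_mode <- et %in% c("perturbation", "reporter") |
      (et == "binding" & stats::runif(k) < 0.5)
    mode <- rep("unreported", k)
    if (p$mode %in% c("activation", "repression") && any(carries_mode)) {
      mode[carries_mode] <- p$mode
    } else if (p$mode == "both" && sum(carries_mode) >= 1) {
      idx <- which(carries_mode)
      if (length(idx) == 1) { et <- c(et, "perturbation")
        carries_mode <- c(carries_mode, TRUE)
        sp_tf <- c(sp_tf, sp_tf[idx]); sp_tg <- c(sp_tg, sp_tg[idx])
        mode <- c(mode, "unreported"); idx <- which(carries_mode)
        k <- k + 1L }
      mode[idx] <- "activation"; mode[idx[length(idx)]] <- "repression"
    }

    # binding method / context type
    method <- rep(NA_character_, k)
    is_bind <- et == "binding"
    method[is_bind] <- sample(c("emsa", "chip"), sum(is_bind),
                              replace = TRUE,
                              prob = c(config$emsa_fraction,
                                       1 - config$emsa_fraction))
    p_prim_i <- if (dtri_primary[i]) p_within else 0
    ctx_type <- ifelse(!is.na(method) & method == "emsa", "in_vitro",
                       ifelse(stats::runif(k) < p_prim_i, "primary",
                              "cell_line"))
    branch <- dtri_branch[i]
    term <- character(k); stage <- rep(NA_character_, k)
    for (j in seq_len(k)) {
      if (ctx_type[j] == "in_vitro") {
        term[j] <- "freetext:in vitro binding reaction"
      } else if (ctx_type[j] == "primary") {
        term[j] <- switch(branch,
                          CNS = sample(cns_terms, 1),
                          eye = sample(eye_terms, 1),
                          other = sample(other_terms, 1))
        embry <- if (branch == "CNS")
          stats::runif(1) < config$embryonic_fraction_cns
          else stats::runif(1) < 0.4
        stage[j] <- if (embry)
          sample(c("E12.5", "E14.5", "embryonic day 10", "fetal week 9"), 1)
          else sample(c("adult", "P21", "8 weeks"), 1)
      } else term[j] <- sample(cell_lines, 1)
    }

    # binding-site positions on binding/reporter experiments
    carries_pos <- et %in% c("binding", "reporter")
    offset <- rep(NA_integer_, k); promoter <- rep(NA, k)
    tfbs_class_i <- p$tfbs
    if (!any(carries_pos)) tfbs_class_i <- "unreported"
    if (tfbs_class_i == "both" && sum(carries_pos) < 2) {
      tfbs_class_i <- "proximal"
    }
    if (tfbs_class_i != "unreported") {
      idx <- which(carries_pos)
      ann <- idx[stats::runif(length(idx)) < 0.8]
      if (length(ann) == 0) ann <- idx[1]
      draw_prox <- function(n) {
        prom <- stats::runif(n) < 0.3
        off <- ifelse(prom, NA_integer_,
                      as.integer(sample(-2000:2000, n, replace = TRUE)))
        list(off = off, prom = ifelse(prom, TRUE, NA))
      }
      draw_dist <- function(n) {
        s <- sample(c(-1L, 1L), n, replace = TRUE)
        list(off = s * as.integer(sample(2001:20000, n, replace = TRUE)),
             prom = rep(NA, n))
      }
      if (tfbs_class_i == "proximal") {
        d <- draw_prox(length(ann))
      } else if (tfbs_class_i == "distal") {
        d <- draw_dist(length(ann))
      } else {                     # both
        n1 <- max(1L, length(ann) %/% 2L)
        d1 <- draw_prox(n1); d2 <- draw_dist(length(ann) - n1)
        d <- list(off = c(d1$off, d2$off), prom = c(d1$prom, d2$prom))
      }
      offset[ann] <- d$off; promoter[ann] <- d$prom
    }

    # detail blocks
    pert_dir <- pert_tim <- zyg <- rep(NA_character_, k)
    is_pert <- et == "perturbation"
    if (any(is_pert)) {
      pert_dir[is_pert] <- sample(c("knockdown", "knockout",
                                    "overexpression"),
                                  sum(is_pert), replace = TRUE,
                                  prob = c(0.35, 0.35, 0.30))
      pert_tim[is_pert] <- sample(c("constitutive", "induced"),
                                  sum(is_pert), replace = TRUE,
                                  prob = c(0.68, 0.32))
      zyg[is_pert] <- ifelse(pert_dir[is_pert] == "knockout",
                             sample(c("heterozygous", "homozygous"),
                                    sum(is_pert), replace = TRUE),
                             "not_applicable")
    }
    emsa_src <- rep(NA_character_, k)
    is_emsa <- !is.na(method) & method == "emsa"
    if (any(is_emsa)) {
      emsa_src[is_emsa] <- sample(c("transfected_cell_line",
                                    "primary_extract", "recombinant",
                                    "other"),
                                  sum(is_emsa), replace = TRUE,
                                  prob = c(0.62, 0.10, 0.20, 0.08))
    }
    cre_mut <- verified <- rep(NA, k)
    is_rep <- et == "reporter"
    if (any(is_rep)) {
      cre_mut[is_rep] <- stats::runif(sum(is_rep)) <
        config$mutated_reporter_fraction
      vv <- is_rep & !is.na(cre_mut) & cre_mut
      verified[vv] <- stats::runif(sum(vv)) < 0.5
    }

    pmid <- rep(paper_of_dtri[i], k)
    rows[[i]] <- data.frame(
      experiment_id = NA_character_,
      pubmed_id = pmid,
      tf_symbol = paste0("TF", p$tf),
      tf_entrez = ifelse(sp_tf == "mouse", mouse_id(p$tf), p$tf),
      tf_species = sp_tf,
      target_symbol = paste0("TG", p$target),
      target_entrez = ifelse(sp_tg == "mouse", mouse_id(p$target),
                             p$target),
      target_species = sp_tg,
      experiment_type = et,
      context_type = ctx_type,
      context_term = term,
      developmental_stage = stage,
      mode = mode,
      tfbs_offset_bp = offset,
      is_promoter = promoter,
      perturbation_direction = pert_dir,
      perturbation_timing = pert_tim,
      zygosity = zyg,
      binding_method = method,
      emsa_protein_source = emsa_src,
      reporter_cre_mutated = cre_mut,
      mutation_binding_verified = verified,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rows)
  records$experiment_id <- sprintf("EXP%06d", seq_len(nrow(records)))
  rownames(records) <- NULL

  tf_m <- map_to_human(records$tf_entrez, records$tf_species, hom)
  tg_m <- map_to_human(records$target_entrez, records$target_species, hom)
  records$tf_human_entrez <- tf_m$human_entrez_id
  records$tf_unmapped <- tf_m$unmapped
  records$target_human_entrez <- tg_m$human_entrez_id
  records$target_unmapped <- tg_m$unmapped
  attr(records, "plan") <- plan
  records
}

#' Generate a directed network with tunable target-selection bias
#'
#' Emulates how literature curation grows a regulatory network when
#' investigators prefer to study genes suspected to be related, with a
#' single bias dial beta. Edges are added with sources drawn from a skewed
#' out-degree distribution; at beta = 0 every target is drawn uniformly
#' from the target pool, which a degree-preserving rewiring null
#' reproduces. At beta > 0 three facets of research bias act together,
#' each a form of wiring structure that edge rewiring cannot explain by
#' the degree sequence alone:
#'
#' * a regulatory-cascade backbone: a fraction beta/(1+beta) of the
#'   repeatedly studied TFs are chained as targets of other such TFs
#'   (developmental cascades are followed downstream), creating directed
#'   depth that inflates the number of reachable gene pairs;
#' * famous-target attachment: a TF entering the literature is first
#'   tested against an already-curated gene (probability beta/(0.1+beta),
#'   weight 1 + beta * degree), so peripheral TFs never form isolated
#'   islands the way rewired graphs do — observed component counts fall
#'   well below the null;
#' * triadic closure: established TFs direct a share of their further
#'   experiments at genes within undirected distance 2, weighted by the
#'   number of shared partners, yielding locally complete modules (clique
#'   excess).
#'
#' @param config A `sim_config`; `target_bias` is beta.
#' @return List with `network` (directed igraph) and `ground_truth`
#'   (beta, seed, edge count).
#' @export
generate_biased_network <- function(config = sim_config()) {
  set.seed(config$seed + 404L)
  beta <- config$target_bias
  pools <- sim_gene_pools(config)
  tf_w <- sample(seq_along(pools$tf_pool)^(-config$dtri_zipf))
  sources <- sample(pools$tf_pool, config$n_dtris, replace = TRUE,
                    prob = tf_w)
  tpool <- as.character(pools$target_pool)
  all_ids <- as.character(pools$all_genes)
  deg <- stats::setNames(integer(length(all_ids)), all_ids)
  nbrs <- new.env(parent = emptyenv())    # undirected adjacency
  edges <- new.env(parent = emptyenv())
  seen <- character(0)
  from <- integer(0); to <- integer(0)
  p_bias <- if (beta > 0) beta / (1 + beta) else 0
  p_first <- if (beta > 0) beta / (0.1 + beta) else 0
  closure_share <- 0.55
  get_nbrs <- function(v) {
    x <- nbrs[[v]]
    if (is.null(x)) character(0) else x
  }
  add_edge <- function(sc, t) {
    from <<- c(from, as.integer(sc)); to <<- c(to, as.integer(t))
    edges[[paste(sc, t)]] <- TRUE
    deg[sc] <<- deg[sc] + 1L; deg[t] <<- deg[t] + 1L
    nbrs[[sc]] <- union(get_nbrs(sc), t)
    nbrs[[t]] <- union(get_nbrs(t), sc)
    seen <<- union(seen, c(sc, t))
  }

  # cascade backbone over the repeatedly studied TFs
  tf_use <- table(as.character(sources))
  cascade_tfs <- names(tf_use)[tf_use >= 2]
  n_backbone <- if (beta > 0) round(p_bias * length(cascade_tfs)) else 0
  if (n_backbone > 1) {
    bb <- sample(cascade_tfs, n_backbone)
    for (i in 2:length(bb)) {
      parent <- bb[max(1, i - 1 - stats::rgeom(1, 0.5))]
      if (parent != bb[i] && is.null(edges[[paste(parent, bb[i])]])) {
        add_edge(parent, bb[i])
      }
      if (i > 3 && stats::runif(1) < 0.25) {
        p2 <- bb[sample.int(i - 1, 1)]
        if (p2 != bb[i] && is.null(edges[[paste(p2, bb[i])]])) {
          add_edge(p2, bb[i])
        }
      }
    }
  }

  budget <- config$n_dtris - length(from)
  for (s in sources[seq_len(max(0, budget))]) {
    sc <- as.character(s)
    picked <- NA_character_
    for (attempt in 1:50) {
      w <- NULL; cand <- NULL
      if (deg[sc] == 0L && length(seen) > 0 &&
          stats::runif(1) < p_first) {
        # a newly studied TF is tested against curated genes first
        cand <- intersect(seen, tpool)
        if (length(cand) > 0) w <- 1 + beta * deg[cand]
      } else if (length(seen) > 0 &&
                 stats::runif(1) < p_bias * closure_share) {
        # triadic closure among the source's extended neighbourhood
        near <- get_nbrs(sc)
        nn <- unlist(lapply(near, get_nbrs), use.names = FALSE)
        cnt <- table(c(near, nn))
        cand <- intersect(setdiff(names(cnt), sc), tpool)
        if (length(cand) > 0) w <- 1 + beta * as.numeric(cnt[cand])
      }
      if (is.null(cand) || length(cand) == 0) { cand <- tpool; w <- NULL }
      t <- if (length(cand) == 1) cand else sample(cand, 1, prob = w)
      if (t == sc) next
      if (!is.null(edges[[paste(sc, t)]])) next
      picked <- t
      break
    }
    if (!is.na(picked)) add_edge(sc, picked)
  }
  net <- build_network(data.frame(tf_entrez = from, target_entrez = to))
  list(network = net,
       ground_truth = list(beta = beta, seed = config$seed,
                           n_edges = igraph::ecount(net)))
}

#' Generate differential-expression screens with planted curated targets
#'
#' A fraction rho of the targets in each category is designated responsive
#' (shared across screens); responsive genes receive sub-uniform p-values
#' from a Beta(a, 1) distribution while every other gene in the universe is
#' uniform. Each screen resamples p-values independently with a per-screen
#' log-normal jitter of the signal shape; q-values are Benjamini-Hochberg;
#' log2 fold changes carry random signs with magnitudes scaled by -log10 p.
#'
#' @param config A `sim_config`.
#' @param target_sets Named list of target-id vectors per category; names
#'   must appear in `config$rho`.
#' @return List with `screens` (list of `de_result`) and `ground_truth`
#'   (responsive genes per category, rho, shape).
#' @export
generate_de_screens <- function(config = sim_config(), target_sets) {
  set.seed(config$seed + 505L)
  stopifnot(all(names(target_sets) %in% names(config$rho)))
  targets_all <- unique(unlist(target_sets, use.names = FALSE))
  n_fill <- config$universe_size - length(targets_all)
  if (n_fill < 0) stop("universe smaller than the target sets")
  universe <- c(targets_all, 700000L + seq_len(n_fill))
  responsive <- lapply(names(target_sets), function(cat) {
    tg <- setdiff(target_sets[[cat]], NA)
    n_resp <- round(config$rho[[cat]] * length(tg))
    if (n_resp == 0) integer(0) else sample(tg, n_resp)
  })
  names(responsive) <- names(target_sets)
  resp_all <- unique(unlist(responsive, use.names = FALSE))

  screens <- lapply(seq_len(config$n_screens), function(sidx) {
    a <- config$signal_shape *
      exp(stats::rnorm(1, sd = config$screen_noise))
    p <- stats::runif(length(universe))
    is_resp <- universe %in% resp_all
    p[is_resp] <- stats::rbeta(sum(is_resp), a, 1)
    lfc <- sample(c(-1, 1), length(universe), replace = TRUE) *
      (-log10(pmax(p, 1e-300)) / 2)
    de_result(data.frame(gene_entrez = universe, log2fc = lfc,
                         pvalue = p, stringsAsFactors = FALSE),
              dataset = sprintf("synthetic_screen_%02d", sidx),
              tf = NA)
  })
  list(screens = screens,
       ground_truth = list(responsive = responsive, rho = config$rho,
                           signal_shape = config$signal_shape,
                           universe_size = length(universe)))
}

#' Write a complete synthetic input bundle to a directory
#'
#' Emits every input the pipeline consumes: the homology and ontology
#' fixtures, the experiment table, the candidate corpus and popularity
#' tables, the biased network edge list, the differential-expression
#' screens with a dataset manifest, a ground-truth JSON and the resolved
#' configuration.
#'
#' @param config A `sim_config`.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
generate_bundle <- function(config = sim_config(), dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- generate_fixtures(config)
  records <- generate_experiments(config, fx)
  corpus <- generate_corpus(config)
  net <- generate_biased_network(config)

  dtris <- aggregate_dtris(records, fx$dag)
  pax_like <- names(which.max(table(dtris$tf_entrez)))
  sets <- subset_targets(dtris, as.integer(pax_like), "context")[-1]
  de <- generate_de_screens(config, sets)

  paths <- list(
    homology = file.path(dir, "homology.tsv"),
    ontology = file.path(dir, "ontology_edges.tsv"),
    experiments = file.path(dir, "experiments.tsv"),
    corpus = file.path(dir, "corpus.tsv"),
    popularity = file.path(dir, "popularity.tsv"),
    edges = file.path(dir, "edge_list.tsv"),
    manifest = file.path(dir, "screen_manifest.tsv"),
    ground_truth = file.path(dir, "ground_truth.json"),
    config = file.path(dir, "sim_config.json"))

  hm <- fx$homology
  utils::write.table(as.data.frame(hm), paths$homology, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  utils::write.table(fx$dag$edges, paths$ontology, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  write_experiment_table(records, paths$experiments)
  corpus_df <- do.call(rbind, lapply(names(corpus$papers), function(tf) {
    if (length(corpus$papers[[tf]]) == 0) return(NULL)
    data.frame(tf_entrez = tf, pubmed_id = corpus$papers[[tf]],
               source = corpus$source)
  }))
  utils::write.table(corpus_df, paths$corpus, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  utils::write.table(
    data.frame(tf_entrez = names(corpus$popularity),
               popularity_count = unname(corpus$popularity)),
    paths$popularity, sep = "\t", quote = FALSE, row.names = FALSE,
    na = "NA")
  write_edge_table(net$network, paths$edges)

  screen_paths <- character(length(de$screens))
  for (i in seq_along(de$screens)) {
    screen_paths[i] <- file.path(dir, sprintf("screen_%02d.tsv", i))
    utils::write.table(as.data.frame(de$screens[[i]]), screen_paths[i],
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  }
  utils::write.table(
    data.frame(dataset_id = vapply(de$screens, attr, "", "dataset"),
               tf_entrez = pax_like, label = "synthetic perturbation",
               path = basename(screen_paths)),
    paths$manifest, sep = "\t", quote = FALSE, row.names = FALSE,
    na = "NA")
  jsonlite::write_json(
    list(seed = config$seed,
         network = net$ground_truth,
         benchmark_tf = as.integer(pax_like),
         target_sets = sets,
         de = de$ground_truth),
    paths$ground_truth, auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE,
                       digits = NA, na = "null")
  paths$screens <- screen_paths
  invisible(paths)
}
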