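# Synthetic-data generators: fixtures, corpora, experiment records, biased
# networks, planted differential-expression screens, and the bundle writer.

test_that("fixture DAG keeps CNS and eye branches disjoint; homology honours the unmapped fraction", {
  fx <- generate_fixtures(sim_config(seed = 2))
  cns <- dag_descendants(fx$dag, "UBERON:0001017")
  eye <- dag_descendants(fx$dag, "UBERON:0000970")
  expect_length(intersect(cns, eye), 0)
  expect_gte(length(setdiff(cns, "UBERON:0001017")), 3)

  none <- generate_fixtures(sim_config(seed = 2, unmapped_fraction = 0))
  expect_length(none$unmapped, 0)
  allm <- generate_fixtures(sim_config(seed = 2, unmapped_fraction = 1))
  expect_equal(nrow(allm$homology[allm$homology$species == "mouse", ]), 0)
  m <- map_to_human(allm$unmapped[1], "mouse", allm$homology)
  expect_true(m$unmapped)
  expect_equal(m$human_entrez_id, allm$unmapped[1])
})

test_that("generated records validate and reproduce the configured mixtures", {
  cfg <- sim_config(seed = 19, n_tfs = 80, n_targets = 260, n_dtris = 500)
  fx <- generate_fixtures(cfg)
  recs <- generate_experiments(cfg, fx)
  expect_equal(nrow(validate_experiment_table(recs)), 0)

  d <- aggregate_dtris(recs, fx$dag)
  expect_equal(nrow(d), 500)

  # evidence-combination mixture within 3 multinomial SEs of the config
  obs <- table(factor(d$evidence_types, names(cfg$evidence_mix))) / nrow(d)
  se <- sqrt(cfg$evidence_mix * (1 - cfg$evidence_mix) / nrow(d))
  expect_true(all(abs(obs - cfg$evidence_mix) <= 3 * se + 0.02))

  # species support close to its configured split
  sp <- table(factor(d$species_support,
                     c("human_only", "mouse_only", "both", "mixed_only")))
  expect_true(all(abs(sp / nrow(d) - cfg$species_mix[
    c("human_only", "mouse_only", "both", "mixed_only")]) < 0.06))

  # proximal share among annotated interactions
  ann <- d$tfbs_class != "unreported"
  expect_lt(abs(mean(d$tfbs_class[ann] %in% c("proximal", "both")) -
                  cfg$proximal_fraction), 0.06)

  # primary-context experiment share
  expect_lt(abs(mean(recs$context_type == "primary") -
                  cfg$context_mix[["primary"]]), 0.05)

  # papers average about the configured number of interactions each
  s <- summarize_curation(d, recs)
  expect_lt(abs(s$mean_dtris_per_positive_paper -
                  cfg$mean_dtris_per_paper), 0.25)
})

test_that("degenerate mixtures force the corresponding record structure", {
  mix <- c("binding" = 0, "perturbation" = 0, "reporter" = 0,
           "binding;perturbation" = 0, "binding;reporter" = 0,
           "perturbation;reporter" = 0,
           "binding;perturbation;reporter" = 1)
  cfg <- sim_config(seed = 4, n_tfs = 10, n_targets = 40, n_dtris = 50,
                    evidence_mix = mix)
  fx <- generate_fixtures(cfg)
  d <- aggregate_dtris(generate_experiments(cfg, fx), fx$dag)
  expect_true(all(d$n_evidence_types == 3))

  cfg0 <- sim_config(seed = 4, n_tfs = 10, n_targets = 40, n_dtris = 50,
                     repressive_fraction = 0, both_mode_fraction = 0)
  fx0 <- generate_fixtures(cfg0)
  d0 <- aggregate_dtris(generate_experiments(cfg0, fx0), fx0$dag)
  expect_false(any(d0$mode %in% c("repression", "both")))
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 77, n_tfs = 20, n_targets = 50, n_dtris = 80,
                    universe_size = 400)
  expect_identical(generate_fixtures(cfg), generate_fixtures(cfg))
  fx <- generate_fixtures(cfg)
  expect_identical(generate_experiments(cfg, fx),
                   generate_experiments(cfg, fx))
  expect_identical(generate_corpus(cfg), generate_corpus(cfg))
  g1 <- generate_biased_network(cfg)
  g2 <- generate_biased_network(cfg)
  expect_identical(igraph::as_edgelist(g1$network),
                   igraph::as_edgelist(g2$network))
  sets <- list(CNS = 1:10, other = 11:30)
  expect_identical(generate_de_screens(cfg, sets),
                   generate_de_screens(cfg, sets))
})

test_that("a single-target pool yields a star with no cliques", {
  cfg <- sim_config(seed = 6, n_tfs = 10, n_targets = 1, n_dtris = 12,
                    shared_tf_fraction = 0, target_bias = 0)
  g <- generate_biased_network(cfg)$network
  el <- igraph::as_edgelist(g)
  expect_equal(length(unique(el[, 2])), 1)
  expect_equal(count_cliques(g), 0)
})

test_that("planted screens recover the configured signal structure", {
  # null case: no responsive targets
  cfg0 <- sim_config(seed = 23, universe_size = 3000,
                     rho = c(CNS = 0, eye = 0, other = 0), n_screens = 4)
  sets <- list(CNS = 1:25, other = 26:60)
  sc0 <- generate_de_screens(cfg0, sets)
  aucs <- vapply(sc0$screens, function(s) {
    auroc(make_ranking(s), sets$CNS)$statistic
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.08)

  # saturated case: everything responsive with a hard signal
  cfg1 <- sim_config(seed = 23, universe_size = 3000,
                     rho = c(CNS = 1, eye = 1, other = 1),
                     signal_shape = 0.01, n_screens = 2, screen_noise = 0)
  sc1 <- generate_de_screens(cfg1, sets)
  a1 <- auroc(make_ranking(sc1$screens[[1]]), sets$CNS)$statistic
  expect_gt(a1, 0.97)

  # the analytic mean: rho / (1 + a) + (1 - rho) / 2, cross-checked by a
  # Monte-Carlo oracle over independent replicates
  rho <- 0.7; a <- 0.1
  set.seed(91)
  mc <- replicate(3000, {
    resp <- runif(1) < rho
    pt <- if (resp) rbeta(1, a, 1) else runif(1)
    pb <- runif(1)
    (pt < pb) + 0.5 * (pt == pb)
  })
  expect_lt(abs(mean(mc) - (rho / (1 + a) + (1 - rho) / 2)), 0.03)

  cfg2 <- sim_config(seed = 29, universe_size = 5000,
                     rho = c(CNS = rho, eye = 0, other = 0),
                     signal_shape = a, n_screens = 3, screen_noise = 0)
  sets2 <- list(CNS = 1:18, other = 200:220)
  sc2 <- generate_de_screens(cfg2, sets2)
  a2 <- mean(vapply(sc2$screens, function(s) {
    auroc(make_ranking(s), sets2$CNS)$statistic
  }, numeric(1)))
  expect_lt(abs(a2 - mean(mc)), 0.05)
})

test_that("the bundle writer emits a complete, reloadable input set", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 37, n_tfs = 20, n_targets = 60, n_dtris = 90,
                    universe_size = 800, n_screens = 2)
  paths <- generate_bundle(cfg, dir)
  for (p in paths[c("homology", "ontology", "experiments", "corpus",
                    "popularity", "edges", "manifest", "ground_truth")]) {
    expect_true(file.exists(p))
  }
  hom <- read_homology_table(paths$homology)
  recs <- read_experiment_table(paths$experiments, homology = hom)
  dag <- read_ontology_edges(paths$ontology)
  d <- aggregate_dtris(recs, dag)
  expect_equal(nrow(d), 90)
  gt <- jsonlite::read_json(paths$ground_truth, simplifyVector = TRUE)
  expect_equal(gt$seed, 37)
  expect_true(gt$benchmark_tf %in% d$tf_entrez)
})
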