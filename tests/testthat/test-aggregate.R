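# Aggregation of experiment records into unique interactions, resolver
# semantics, summaries and the remaining-literature projection.

dag <- toy_dag()

test_that("three records on one pair collapse to a single triple-evidence DTRI", {
  recs <- list(
    make_record(experiment_id = "E1"),
    binding_record(experiment_id = "E2"),
    reporter_record(experiment_id = "E3", pubmed_id = 777L))
  tab <- read_records(recs, homology = toy_homology())
  d <- aggregate_dtris(tab, dag)
  expect_equal(nrow(d), 1)
  expect_equal(d$evidence_types, "binding;perturbation;reporter")
  expect_equal(d$n_evidence_types, 3)
  expect_equal(d$n_experiments, 3)
  expect_equal(d$pubmed_ids, "777;12345")
  expect_equal(nrow(aggregate_dtris(tab[0, ], dag)), 0)
})

test_that("mouse and human records of the same orthologous pair merge", {
  recs <- list(
    make_record(experiment_id = "E1"),
    make_record(experiment_id = "E2", tf_entrez = 18508L,
                tf_species = "mouse", target_entrez = 11924L,
                target_species = "mouse"))
  tab <- read_records(recs, homology = toy_homology())
  d <- aggregate_dtris(tab, dag)
  expect_equal(nrow(d), 1)
  expect_equal(d$tf_entrez, 5080)
  expect_equal(d$species_support, "both")
})

test_that("species support distinguishes same-species from mixed evidence", {
  expect_equal(resolve_species_support("human", "human"), "human_only")
  expect_equal(resolve_species_support(c("human", "mouse"),
                                       c("human", "mouse")), "both")
  expect_equal(resolve_species_support("mouse", "human"), "mixed_only")
  expect_equal(resolve_species_support(c("mouse", "mouse"),
                                       c("human", "mouse")), "mouse_only")
})

test_that("mode resolution ignores unreported unless nothing is reported", {
  expect_equal(resolve_mode(c("activation", "unreported")), "activation")
  expect_equal(resolve_mode(c("activation", "repression")), "both")
  expect_equal(resolve_mode(c("unreported", "unreported")), "unreported")
  expect_equal(resolve_mode("repression"), "repression")
})

test_that("binding-site class uses union semantics over experiments", {
  expect_equal(resolve_tfbs_class(c("proximal", "unreported")), "proximal")
  expect_equal(resolve_tfbs_class(c("proximal", "distal")), "both")
  expect_equal(resolve_tfbs_class(c("unreported", "unreported")),
               "unreported")
})

test_that("context requires primary tissue, CNS beats eye, cell lines never count", {
  r <- resolve_context("primary", "UBERON:0000955", "E12.5", dag)
  expect_equal(r$context_category, "CNS")
  expect_true(r$any_cns && r$any_primary && r$any_embryonic_cns)

  r <- resolve_context(c("primary", "primary"),
                       c("UBERON:0000966", "CL:0000540"),
                       c("adult", "adult"), dag)
  expect_equal(r$context_category, "CNS")   # CNS takes precedence over eye

  # a neural cell line is not primary CNS evidence
  r <- resolve_context("cell_line", "CL:0000540", NA, dag)
  expect_equal(r$context_category, "other")
  expect_false(r$any_cns || r$any_primary)

  # unknown ontology-style terms warn and do not match
  expect_warning(
    r <- resolve_context("primary", "UBERON:9999999", NA, dag),
    "non-matching")
  expect_equal(r$context_category, "other")

  # embryonic stage grammar
  r <- resolve_context("primary", "UBERON:0002240", "fetal week 9", dag)
  expect_true(r$any_embryonic_cns)
  r <- resolve_context("primary", "UBERON:0002240", "P21", dag)
  expect_false(r$any_embryonic_cns)
})

test_that("aggregation is invariant to record order and monotone in records", {
  cfg <- sim_config(seed = 42, n_tfs = 15, n_targets = 40, n_dtris = 60)
  fx <- generate_fixtures(cfg)
  recs <- generate_experiments(cfg, fx)
  d1 <- aggregate_dtris(recs, fx$dag)
  set.seed(1)
  d2 <- aggregate_dtris(recs[sample(nrow(recs)), ], fx$dag)
  rownames(d2) <- NULL
  expect_equal(d1, d2)

  # dropping records never adds interactions or evidence types
  sub <- aggregate_dtris(recs[seq_len(nrow(recs) - 25), ], fx$dag)
  expect_lte(nrow(sub), nrow(d1))
  merged <- merge(sub, d1, by = c("tf_entrez", "target_entrez"))
  expect_equal(nrow(merged), nrow(sub))
  expect_true(all(mapply(function(a, b) {
    all(strsplit(a, ";")[[1]] %in% strsplit(b, ";")[[1]])
  }, merged$evidence_types.x, merged$evidence_types.y)))
})

test_that("summary cells match naive filtering on synthetic records", {
  cfg <- sim_config(seed = 7, n_tfs = 20, n_targets = 60, n_dtris = 120)
  fx <- generate_fixtures(cfg)
  recs <- generate_experiments(cfg, fx)
  d <- aggregate_dtris(recs, fx$dag)
  s <- summarize_curation(d, recs)

  expect_equal(s$totals$n_dtris, nrow(d))
  expect_equal(s$totals$n_tfs, length(unique(d$tf_entrez)))
  expect_equal(sum(s$evidence_by_context), nrow(d))
  expect_equal(sum(s$species_support), nrow(d))
  expect_equal(sum(s$mode_by_tfbs), nrow(d))
  expect_equal(sum(s$per_tf_targets), nrow(d))
  expect_equal(s$evidence_depth$n_triple_evidence,
               sum(d$n_evidence_types == 3))
  expect_equal(s$evidence_depth$n_triple_cns,
               sum(d$n_evidence_types == 3 & d$any_cns))
  expect_equal(s$tfbs$n_proximal_any,
               sum(d$tfbs_class %in% c("proximal", "both")))
  expect_equal(s$mode$n_repressive,
               sum(d$mode %in% c("repression", "both")))

  papers <- unlist(strsplit(d$pubmed_ids, ";"))
  expect_equal(unname(s$mean_dtris_per_positive_paper),
               mean(table(papers)))
})

test_that("per-paper statistics follow the worked arithmetic", {
  recs <- list(
    make_record(experiment_id = "A", pubmed_id = 1L),
    make_record(experiment_id = "B", pubmed_id = 2L,
                target_entrez = 11L, target_symbol = "T1"),
    make_record(experiment_id = "C", pubmed_id = 2L,
                target_entrez = 12L, target_symbol = "T2"),
    make_record(experiment_id = "D", pubmed_id = 2L,
                target_entrez = 13L, target_symbol = "T3"))
  tab <- read_records(recs, homology = toy_homology())
  d <- aggregate_dtris(tab, dag)
  s <- summarize_curation(d, tab, n_papers_examined = 5)
  expect_equal(unname(s$mean_dtris_per_positive_paper), 2.0)
  expect_equal(s$totals$n_papers_negative, 3)
})

test_that("literature projection reproduces the published extrapolation arithmetic", {
  est <- estimate_remaining(1310, 828, 20043, 1.9,
                            frac_triple = 0.27, frac_cns = 0.03)
  expect_equal(est$positive_rate, 828 / 1310)
  expect_equal(est$projected_positive_papers, 828 / 1310 * 20043)
  expect_gt(est$projected_positive_papers, 12000)
  expect_gt(est$projected_dtris, 22000)
  expect_equal(est$projected_dtris,
               est$projected_positive_papers * 1.9)
  expect_gt(est$projected_triple_evidence_dtris, 6000)
  expect_gt(est$projected_cns_dtris, 600)

  zero <- estimate_remaining(100, 50, 0, 2.0)
  expect_equal(zero$projected_dtris, 0)
  small <- estimate_remaining(100, 50, 200, 2.0)
  expect_equal(small$projected_positive_papers, 100)
  expect_equal(small$projected_dtris, 200)
  expect_error(estimate_remaining(0, 0, 10, 1), "n_examined")
  expect_error(estimate_remaining(10, 5, 10, 1, frac_triple = 1.2),
               "fractions")
})
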