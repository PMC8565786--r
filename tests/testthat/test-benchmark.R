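# Enrichment statistics: BH hit lists, hypergeometric overrepresentation,
# rank-based AUROC with bootstrap, consensus rankings, target subsetting.

test_that("hit lists follow the Benjamini-Hochberg step-up rule", {
  de <- de_from_p(c(0.001, 0.01, 0.02, 0.8))
  # adjusted q-values are 0.004, 0.02, 0.0267, 0.8
  expect_equal(de$qvalue, c(0.004, 0.02, 0.08 / 3, 0.8))
  expect_equal(hit_list(de, 0.1), 1:3)
  expect_equal(hit_list(de_from_p(rep(1, 5))), integer(0))
  expect_equal(hit_list(de, fdr = 1), 1:4)
})

test_that("hit lists equal a literal step-up procedure on random p-vectors", {
  set.seed(8)
  for (i in 1:30) {
    m <- sample(3:20, 1)
    p <- round(runif(m)^sample(1:3, 1), 3)
    q <- runif(1, 0.02, 0.3)
    expect_equal(hit_list(de_from_p(p), q), oracle_bh_hits(p, q),
                 info = paste("case", i))
  }
})

test_that("hypergeometric overrepresentation matches exhaustive enumeration", {
  r <- hypergeom_overrep(hits = 1:5, targets = 1:5, universe = 1:10)
  expect_equal(r$p_value, 1 / choose(10, 5))
  expect_equal(unlist(r[c("k", "K", "n", "N")]),
               c(k = 5, K = 5, n = 5, N = 10))

  full <- hypergeom_overrep(1:10, 1:10, 1:10)
  expect_equal(full$p_value, 1)

  set.seed(12)
  for (i in 1:25) {
    N <- sample(5:12, 1)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    hits <- sample(N, n)
    r <- hypergeom_overrep(hits, seq_len(K), seq_len(N))
    expect_equal(r$p_value, oracle_hypergeom(r$k, K, n, N),
                 info = paste("case", i))
  }

  # upper-tail monotonicity: k = 0 is the least surprising outcome
  r0 <- hypergeom_overrep(6:8, 1:3, 1:10)
  expect_equal(r0$k, 0)
  expect_equal(r0$p_value, 1)
  expect_error(hypergeom_overrep(1, 1, integer(0)), "empty")
})

test_that("AUROC is the probability a target outranks a non-target", {
  rk <- make_ranking(de_from_p(seq(0.01, 1, length.out = 10)))
  top <- auroc(rk, targets = 1:2)
  expect_equal(top$statistic, 1.0)
  expect_lt(top$p_value, 0.05)

  split <- auroc(rk, targets = c(1, 10))
  expect_equal(split$statistic, 0.5)   # (8 + 0) / 16 by pairwise count

  expect_error(auroc(rk, targets = 100:110), "no targets")
  expect_message(auroc(rk, targets = c(1, 2, 99)), "not in universe")
})

test_that("AUROC equals the brute-force pairwise comparison on tied rankings", {
  set.seed(21)
  for (i in 1:25) {
    n <- sample(8:50, 1)
    p <- round(runif(n), sample(1:2, 1))  # rounding forces ties
    m <- sample(2:(n - 2), 1)
    targets <- sample(n, m)
    rk <- make_ranking(de_from_p(p))
    got <- auroc(rk, targets)
    expect_equal(got$statistic,
                 oracle_auroc(p, seq_len(n) %in% targets),
                 info = paste("case", i))
  }
})

test_that("random target sets score near 0.5 on average", {
  set.seed(33)
  p <- runif(2000)
  rk <- make_ranking(de_from_p(p))
  aucs <- replicate(60, auroc(rk, sample(2000, 40))$statistic)
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
})

test_that("bootstrap intervals behave at the degenerate extremes", {
  rk <- make_ranking(de_from_p(seq(0.001, 1, length.out = 20)))
  ci <- bootstrap_auroc_ci(rk, targets = 1:2, n_boot = 50, seed = 1)
  expect_equal(unname(ci), c(1, 1))   # every resample is perfect

  mid <- bootstrap_auroc_ci(rk, targets = c(7, 7, 7, 12), n_boot = 40,
                            seed = 2)
  expect_lte(mid[1], mid[2])
  expect_error(bootstrap_auroc_ci(rk, targets = 3), ">= 2")

  # reproducible under a fixed seed
  a <- bootstrap_auroc_ci(rk, 1:5, n_boot = 30, seed = 9)
  b <- bootstrap_auroc_ci(rk, 1:5, n_boot = 30, seed = 9)
  expect_identical(a, b)
})

test_that("bootstrap intervals usually cover the point AUROC of a planted screen", {
  set.seed(50)
  hits <- 0
  for (rep in 1:25) {
    p <- runif(600)
    targets <- sample(600, 25)
    resp <- sample(targets, 18)
    p[resp] <- rbeta(length(resp), 0.15, 1)
    rk <- make_ranking(de_from_p(p))
    a <- auroc(rk, targets)$statistic
    ci <- bootstrap_auroc_ci(rk, targets, n_boot = 200)
    if (a >= ci[1] && a <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 22)   # ~90% of outer replicates
})

test_that("consensus ranking restricts, re-ranks and averages midranks", {
  single <- consensus_ranking(list(make_ranking(de_from_p(c(0.2, 0.1, 0.9)))))
  expect_equal(single$gene, c(2, 1, 3))

  # two exactly reversed rankings tie every gene at mean rank 2.5
  f <- make_ranking(de_from_p(c(0.1, 0.2, 0.3, 0.4), genes = 1:4,
                              dataset = "f"))
  r <- make_ranking(de_from_p(c(0.4, 0.3, 0.2, 0.1), genes = 1:4,
                              dataset = "r"))
  cons <- consensus_ranking(list(f, r))
  expect_true(all(cons$mean_rank == 2.5))
  expect_equal(cons$gene, 1:4)   # deterministic tie-break by gene id
  expect_equal(cons$members, c("f", "r"))

  # restriction to the shared universe with recomputed ranks
  a <- make_ranking(de_from_p(c(0.01, 0.5, 0.9), genes = c(1, 2, 3)))
  b <- make_ranking(de_from_p(c(0.6, 0.2), genes = c(2, 3)))
  cons <- consensus_ranking(list(a, b))
  expect_setequal(cons$gene, c(2, 3))
  # within {2,3}: a ranks 2 first, b ranks 3 first -> tie at 1.5
  expect_true(all(cons$mean_rank == 1.5))

  expect_error(consensus_ranking(list(a, make_ranking(
    de_from_p(0.5, genes = 99)))), "shared")
})

test_that("consensus of noisy replicate screens beats the median screen", {
  set.seed(61)
  wins <- 0
  for (rep in 1:15) {
    n <- 800
    targets <- sample(n, 30)
    resp <- sample(targets, 21)
    screens <- lapply(1:3, function(i) {
      p <- runif(n)
      p[resp] <- rbeta(length(resp), 0.25, 1)
      de_from_p(p, dataset = paste0("s", i))
    })
    rks <- lapply(screens, make_ranking)
    each <- vapply(rks, function(rk) auroc(rk, targets)$statistic,
                   numeric(1))
    cons <- auroc(consensus_ranking(rks), targets)$statistic
    if (cons >= stats::median(each)) wins <- wins + 1
  }
  expect_gte(wins, 12)
})

test_that("target subsetting partitions by context and by evidence depth", {
  cfg <- sim_config(seed = 13, n_tfs = 10, n_targets = 40, n_dtris = 60)
  fx <- generate_fixtures(cfg)
  d <- aggregate_dtris(generate_experiments(cfg, fx), fx$dag)
  tf <- as.integer(names(which.max(table(d$tf_entrez))))

  ctx <- subset_targets(d, tf, "context")
  expect_setequal(ctx$all, c(ctx$CNS, ctx$eye, ctx$other))
  expect_length(intersect(ctx$CNS, ctx$eye), 0)

  ev <- subset_targets(d, tf, "evidence_depth")
  expect_setequal(ev$all, c(ev$multi_evidence, ev$single_evidence))
  expect_error(subset_targets(d, 424242, "context"), "no curated targets")

  # a CNS-and-eye target lands only in the CNS bin
  recs <- list(
    make_record(experiment_id = "E1", context_type = "primary",
                context_term = "UBERON:0000955"),
    make_record(experiment_id = "E2", context_type = "primary",
                context_term = "UBERON:0000966"))
  tab <- read_records(recs, homology = toy_homology())
  dd <- aggregate_dtris(tab, toy_dag())
  s <- subset_targets(dd, 5080, "context")
  expect_equal(s$CNS, dd$target_entrez)
  expect_length(s$eye, 0)
})

test_that("the per-TF benchmark report handles consensus, skips and enrichment", {
  cfg <- sim_config(seed = 29, n_tfs = 12, n_targets = 60, n_dtris = 90,
                    universe_size = 1500, n_screens = 3)
  fx <- generate_fixtures(cfg)
  d <- aggregate_dtris(generate_experiments(cfg, fx), fx$dag)
  tf <- as.integer(names(which.max(table(d$tf_entrez))))
  sets <- subset_targets(d, tf, "context")[-1]
  sc <- generate_de_screens(cfg, sets)

  rep <- benchmark_tf(d, sc$screens, tf, min_targets = 5, n_boot = 100,
                      seed = 3)
  expect_true(rep$consensus)
  all_entry <- rep$results$all
  expect_false(all_entry$skipped)
  expect_gt(all_entry$auroc, 0.5)
  expect_length(all_entry$hypergeom, 3)
  expect_true(all(vapply(all_entry$hypergeom,
                         function(h) h$k <= min(h$K, h$n), logical(1))))

  # a tight threshold marks small sets as skipped, without dropping them
  rep2 <- benchmark_tf(d, sc$screens[1], tf, min_targets = 1e4)
  expect_false(rep2$consensus)
  expect_true(all(vapply(rep2$results, `[[`, logical(1), "skipped")))
  expect_named(rep2$results, c("all", "CNS", "eye", "other",
                               "multi_evidence", "single_evidence"))
})
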