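test_that("simulation_config validates its fields", {
  expect_s3_class(simulation_config(), "SimulationConfig")
  expect_error(simulation_config(reversal_noise = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(n_compounds = 2, n_planted_reversers = 3),
               "more planted")
  expect_error(simulation_config(n_genes = -1), "non-negative")
})

test_that("identical seeds give byte-identical worlds", {
  cfg <- simulation_config(n_genes = 100, n_compounds = 15, seed = 42)
  a <- suppressMessages(simulate_world(cfg))
  b <- suppressMessages(simulate_world(cfg))
  expect_identical(a$tissue$values, b$tissue$values)
  expect_identical(a$cellline$values, b$cellline$values)
  expect_identical(a$bank$ranks, b$bank$ranks)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$genesets$sets, b$genesets$sets)
  c2 <- suppressMessages(
    simulate_world(simulation_config(n_genes = 100, n_compounds = 15,
                                     seed = 43)))
  expect_false(identical(a$tissue$values, c2$tissue$values))
})

test_that("large effects put every planted DE gene in the extreme windows", {
  cfg <- simulation_config(n_genes = 300, n_normal = 5, n_disease = 5,
                           de_fraction = 0.1, effect_size = 10, seed = 2)
  tissue <- simulate_tissue(cfg)
  truth <- attr(tissue, "de_truth")
  rl <- rank_disease(tissue)
  n_up <- sum(truth$direction > 0)
  n_dn <- sum(truth$direction < 0)
  s <- slice_ranked(rl, max(n_up, n_dn))
  expect_true(all(truth$gene[truth$direction > 0] %in% s$top))
  expect_true(all(truth$gene[truth$direction < 0] %in% s$bottom))
})

test_that("zero effect leaves DE labels unrecoverable by rank extremes", {
  cfg <- simulation_config(n_genes = 500, effect_size = 0, seed = 9,
                           incompatible_fraction = 0)
  tissue <- simulate_tissue(cfg)
  rl <- rank_disease(tissue)
  truth <- attr(tissue, "de_truth")
  top <- slice_ranked(rl, 50)$top
  # planted labels should hit the top window at roughly chance rate
  expect_lt(sum(truth$gene[truth$de] %in% top), 20)
})

test_that("noise-free planted reversers mirror the disease list exactly", {
  cfg <- simulation_config(n_genes = 200, n_compounds = 10,
                           n_planted_reversers = 2, reversal_noise = 0,
                           seed = 13)
  d <- rank_disease(simulate_tissue(cfg))
  bank <- simulate_compound_bank(cfg, d)
  truth <- attr(bank, "truth")
  expect_equal(sum(truth$planted), 2L)
  lists <- rank_compound_bank(bank, "SYN", d$gene_ids)
  for (cp in truth$compound[truth$planted]) {
    for (k in c(10, 40, 100)) {
      expect_equal(
        sum(slice_ranked(d, k)$top %in% slice_ranked(lists[[cp]], k)$bottom),
        k)
    }
  }
})

test_that("planted overlap concentrates near (1-noise)*k", {
  noise <- 0.1
  k <- 100
  overlaps <- vapply(1:10, function(r) {
    cfg <- simulation_config(n_genes = 2000, n_compounds = 1,
                             n_planted_reversers = 1,
                             reversal_noise = noise, seed = 100 + r)
    d <- rank_disease(simulate_tissue(cfg))
    bank <- simulate_compound_bank(cfg, d)
    cl <- rank_compound_bank(bank, "SYN", d$gene_ids)[[1]]
    sum(slice_ranked(d, k)$top %in% slice_ranked(cl, k)$bottom)
  }, numeric(1))
  expect_gt(mean(overlaps), (1 - noise) * k - 10)
  expect_lt(mean(overlaps), (1 - noise) * k + 5)
})

test_that("fully shuffled planted lists are indistinguishable from random", {
  ps <- vapply(1:20, function(r) {
    cfg <- simulation_config(n_genes = 400, n_compounds = 1,
                             n_planted_reversers = 1, reversal_noise = 1,
                             seed = 300 + r)
    d <- rank_disease(simulate_tissue(cfg))
    bank <- simulate_compound_bank(cfg, d)
    cl <- rank_compound_bank(bank, "SYN", d$gene_ids)[[1]]
    x <- sum(slice_ranked(d, 40)$top %in% slice_ranked(cl, 40)$bottom)
    overlap_pvalue(x, 40, 400)
  }, numeric(1))
  # discrete p-values, but none should be extreme and the spread wide
  expect_gt(min(ps), 1e-4)
  expect_gt(diff(range(ps)), 0.2)
})

test_that("synthetic annotations wire positives, negatives and gene sets", {
  cfg <- simulation_config(n_genes = 200, n_compounds = 20,
                           n_failed_negatives = 3, seed = 21)
  w <- suppressMessages(simulate_world(cfg))
  pos <- annotation_positives(w$annotations, w$target_disease)
  neg <- annotation_negatives(w$annotations, w$target_disease)
  expect_equal(pos, "compound_001")
  expect_length(neg, 3L)
  expect_false(any(neg %in% w$truth$compounds$compound[
    w$truth$compounds$planted]))
  expect_true("PLANTED" %in% names(w$genesets$sets))
  de <- w$truth$de$gene[w$truth$de$de]
  expect_true(all(w$genesets$sets$PLANTED %in% de))
  # positives present -> evaluate_k runs without error
  d <- rank_disease(w$tissue)
  lists <- rank_compound_bank(w$bank, "SYN", d$gene_ids)
  expect_no_error(evaluate_k(d, lists, 20, w$annotations,
                             w$target_disease))
})

test_that("decoy enrichment p-values match the exact null; planted does not", {
  set.seed(1)
  pooled <- c()
  hit <- 0
  for (r in 1:5) {
    cfg <- simulation_config(n_genes = 500, n_compounds = 5,
                             effect_size = 3, seed = 400 + r)
    w <- suppressMessages(simulate_world(cfg))
    d <- rank_disease(w$tissue)
    query <- slice_ranked(d, 50)$top
    res <- enrich(query, w$genesets, d$gene_ids, mode = "pathway",
                  filter = FALSE)
    pooled <- c(pooled, res$p_value[grepl("DECOY", res$set_id)])
    hit <- hit + (res$p_value[res$set_id == "PLANTED"] < 0.05)
  }
  expect_gte(hit, 4)  # planted pathway enriched nearly always

  # the exact null p distribution is discrete (atoms at the achievable
  # overlaps), so compare moments against the closed-form null rather
  # than a continuous-uniform KS
  universe_n <- 500
  x <- 0:50
  atom_pr <- dhyper(x, 50, universe_n - 50, 50)
  atom_p <- phyper(x - 1, 50, universe_n - 50, 50, lower.tail = FALSE)
  mu <- sum(atom_pr * atom_p)
  sdv <- sqrt(sum(atom_pr * (atom_p - mu)^2))
  n <- length(pooled)
  expect_lt(abs(mean(pooled) - mu), 4 * sdv / sqrt(n))
  frac05 <- sum(atom_pr[atom_p <= 0.05])
  expect_lt(abs(mean(pooled <= 0.05) - frac05),
            4 * sqrt(frac05 * (1 - frac05) / n) + 0.01)
})
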