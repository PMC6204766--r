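test_that("log pmf matches exhaustive subset enumeration on tiny universes", {
  # F=4, S=2, R=2: of the 6 possible 2-subsets exactly one contains both
  # marked genes, so P(x = 2) = 1/6
  c1 <- overlap_counts(2, 2, 2, 4)
  enum <- oracle_tail_enum(2, 2, 2, 4)
  expect_equal(enum$pmf, 1 / 6)
  expect_equal(log_hypergeom_pmf(2, c1), log(1 / 6))

  # only possible outcome has probability one
  expect_equal(log_hypergeom_pmf(0, overlap_counts(0, 5, 0, 10)), 0)

  # normalisation over the whole support
  c2 <- overlap_counts(0, 7, 5, 20)
  expect_equal(sum(exp(log_hypergeom_pmf(0:5, c2))), 1, tolerance = 1e-12)

  # impossible outcomes carry zero probability
  expect_identical(log_hypergeom_pmf(0, overlap_counts(3, 5, 4, 6)), -Inf)

  expect_error(overlap_counts(3, 2, 5, 10), "min\\(S, R\\)")
  expect_error(overlap_counts(1, 2, 11, 10), "universe")
  expect_error(overlap_counts(-1, 2, 5, 10), "non-negative")
  expect_error(log_hypergeom_pmf(7, c2), "x must be")
})

test_that("tail p-values match enumeration and an independent library", {
  for (F in c(6, 9, 12)) {
    for (S in 0:F) for (R in c(0L, 2L, F %/% 2, F)) {
      for (T in 0:min(S, R)) {
        enum <- oracle_tail_enum(T, R, S, F)
        c <- overlap_counts(T, R, S, F)
        expect_equal(p_enrichment(c), enum$upper, tolerance = 1e-12)
        expect_equal(p_depletion(c), enum$lower, tolerance = 1e-12)
      }
    }
  }
  # cross-check against stats::phyper at genome scale
  set.seed(5)
  for (i in 1:50) {
    F <- sample(100:8000, 1)
    S <- sample(0:F, 1); R <- sample(0:F, 1)
    T <- sample(0:min(S, R), 1)
    c <- overlap_counts(T, R, S, F)
    expect_equal(p_enrichment(c),
                 stats::phyper(T - 1, S, F - S, R, lower.tail = FALSE),
                 tolerance = 1e-10)
    expect_equal(p_depletion(c),
                 stats::phyper(T, S, F - S, R, lower.tail = TRUE),
                 tolerance = 1e-10)
  }
})

test_that("tail identity and edge tails hold", {
  # whole-support tails
  expect_equal(p_enrichment(overlap_counts(0, 7, 5, 20)), 1, tolerance = 1e-12)
  expect_equal(p_depletion(overlap_counts(5, 7, 5, 20)), 1, tolerance = 1e-12)
  # p_enr + p_dep = 1 + pmf(T)
  c <- overlap_counts(3, 7, 5, 20)
  expect_equal(p_enrichment(c) + p_depletion(c),
               1 + exp(log_hypergeom_pmf(3, c)), tolerance = 1e-12)
})

test_that("enrichment p decreases and depletion p increases with T", {
  for (T in 1:10) {
    lo <- overlap_counts(T - 1, 10, 30, 100)
    hi <- overlap_counts(T, 10, 30, 100)
    expect_lt(p_enrichment(hi), p_enrichment(lo))
    expect_gt(p_depletion(hi), p_depletion(lo))
  }
})

test_that("multiple-testing corrections obey their contracts", {
  expect_identical(correct_pvalues(0.004, "bonferroni"), 0.004)
  expect_identical(correct_pvalues(0.004, "fdr"), 0.004)
  expect_equal(correct_pvalues(c(0.004, 0.2), "bonferroni"), c(0.008, 0.4))
  # Benjamini-Hochberg step-up, hand-evaluated
  expect_equal(correct_pvalues(c(0.01, 0.02, 0.03, 0.04), "fdr"),
               rep(0.04, 4))
  expect_identical(correct_pvalues(c(0.5, 0.1), "none"), c(0.5, 0.1))

  set.seed(8)
  p <- stats::runif(40)
  bonf <- correct_pvalues(p, "bonferroni")
  bh <- correct_pvalues(p, "fdr")
  expect_true(all(bonf >= p) && all(bh >= p))
  expect_true(all(bonf >= bh))
  expect_true(all(bonf <= 1) && all(bh <= 1))
  # output order matches input order: corrected values are monotone
  # transformations of the raw ranks
  expect_identical(order(p), order(bh, p))
  expect_error(correct_pvalues(c(0.1, 1.2), "fdr"), "\\[0, 1\\]")
  expect_error(correct_pvalues(numeric(0), "fdr"), "at least one")
})

test_that("fold and ratio arithmetic handles zero overlaps and empty sets", {
  r0 <- enrichment_from_counts("m", overlap_counts(0, 10, 5, 100))
  expect_identical(r0$fold_enrichment, 0)
  expect_identical(r0$observed_ratio, 0)
  expect_false(r0$untestable)
  expect_equal(r0$p_enrich_raw, 1, tolerance = 1e-12)

  rS0 <- enrichment_from_counts("m", overlap_counts(0, 10, 0, 100))
  expect_true(rS0$untestable)
  expect_true(is.na(rS0$fold_enrichment))

  r <- enrichment_from_counts("m", overlap_counts(8, 10, 20, 100))
  expect_equal(r$fold_enrichment, (8 / 10) / (20 / 100))
  expect_equal(r$observed_ratio, 0.8)
  expect_equal(r$expected_ratio, 0.2)
})

test_that("analyze calls planted enrichment and nothing else", {
  n <- 1000L
  ann <- toy_universe(n)
  ids <- ann$genes$gene_id
  set.seed(21)
  planted <- sort(sample(ids, 200L))
  null_sets <- lapply(sprintf("null%d", 1:4), function(nm) {
    gene_set(sample(ids, 200L), nm, "promoter", provenance = 1)
  })
  mark_sets <- c(list(gene_set(planted, "planted", "promoter",
                               provenance = 1)), null_sets)
  input <- sample(planted, 50L)
  res <- analyze(input, mark_sets, NULL, ann, "bonferroni", 0.01)
  expect_identical(res$trend[res$label == "planted"], "enriched")
  expect_true(all(res$trend[res$label != "planted"] == "none"))
  # raw and corrected p both reported, corrected never smaller
  expect_true(all(res$p_corrected >= res$p_raw))
})

test_that("analyze on the whole universe finds fold 1 and no calls", {
  ann <- toy_universe(200L)
  ids <- ann$genes$gene_id
  sets <- list(gene_set(ids[1:80], "m1", "promoter", provenance = 1),
               gene_set(ids[5:60], "m2", "coding", provenance = 1))
  res <- analyze(ids, sets, NULL, ann, "bonferroni", 0.01)
  expect_equal(res$fold_enrichment, c(1, 1))
  expect_equal(res$observed_ratio, res$expected_ratio)
  expect_true(all(res$trend == "none"))
})

test_that("a regulator's own target list is fully enriched", {
  ann <- toy_universe(300L)
  targets <- ann$genes$gene_id[1:30]
  regs <- list(gene_set(targets, "RegZ", "promoter", condition = "25C",
                        provenance = "curated"))
  res <- analyze(targets, list(), regs, ann, "bonferroni", 0.01)
  expect_identical(res$trend, "enriched")
  expect_identical(res$observed_ratio, 1)
  expect_equal(res$expected_ratio, 0.1)
  expect_identical(res$family, "regulators")
})

test_that("analyze is order-independent within a correction family", {
  ann <- toy_universe(400L)
  ids <- ann$genes$gene_id
  set.seed(33)
  sets <- lapply(sprintf("m%d", 1:6), function(nm) {
    gene_set(sample(ids, sample(50:150, 1)), nm, "promoter", provenance = 1)
  })
  input <- sample(ids, 40L)
  res1 <- analyze(input, sets, NULL, ann, "fdr", 0.05)
  res2 <- analyze(input, rev(sets), NULL, ann, "fdr", 0.05)
  res2 <- res2[match(res1$label, res2$label), ]
  for (col in c("p_enrich_raw", "p_deplete_raw", "p_enrich_corrected",
                "p_deplete_corrected", "trend", "fold_enrichment")) {
    expect_equal(unname(res1[[col]]), unname(res2[[col]]))
  }
})

test_that("analyze validates its inputs", {
  ann <- toy_universe(50L)
  sets <- list(gene_set(ann$genes$gene_id[1:10], "m", "promoter",
                        provenance = 1))
  expect_error(analyze(character(0), sets, NULL, ann), "empty gene list")
  expect_error(analyze("not_a_gene", sets, NULL, ann), "absent from the universe")
  expect_error(analyze(ann$genes$gene_id[1:5], sets, NULL, ann, alpha = 0),
               "alpha")
})

test_that("display formatting follows the table conventions", {
  expect_identical(format_pvalue(c(1.25e-41, 0, NA)), c("1.25e-41", "0", "NA"))
  expect_identical(format_pvalue(0.01), "1.00e-02")
  expect_identical(format_percent(c(0.954023, 1)), c("95.40%", "100.00%"))
  expect_identical(format_fold(c(12.216, 0.1896)), c("12.22", "0.19"))
})
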