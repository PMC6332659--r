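test_that("enrichment statistic matches its closed form on forced cases", {
  # 10 set p-values all below the background 10% quantile, grid {0.1}, k=1
  bg <- seq(0.001, 1, length.out = 1000)
  set_p <- rep(0.0001, 10)
  par1 <- msea_params(quantile_grid = 0.1, n_permutations = 100)
  expect_equal(enrichment_statistic(set_p, bg, par1), 9 / sqrt(2))
  # all set p-values at 1 with a sub-unit grid: every O_j = 0, S < 0
  par <- msea_params(n_permutations = 100)
  expect_lt(enrichment_statistic(rep(1, 20), bg, par), 0)
  expect_error(enrichment_statistic(numeric(), bg, par),
               class = "msekda_value_error")
})

test_that("enrichment statistic is centered near zero under the null", {
  withr::with_seed(31, {
    par <- msea_params(n_permutations = 100)
    s <- vapply(1:1000, function(i)
      enrichment_statistic(runif(50), runif(2000), par), 0)
    expect_lt(abs(mean(s)), 3 * stats::sd(s) / sqrt(length(s)))
  })
})

test_that("enrichment statistic agrees with the brute-force oracle", {
  withr::with_seed(17, {
    for (i in 1:100) {
      grid <- sort(runif(sample(1:6, 1), 0.01, 0.6))
      kappa <- runif(1, 0, 2)
      par <- msea_params(quantile_grid = grid, stabilizer_kappa = kappa,
                         n_permutations = 100)
      set_p <- runif(sample(3:40, 1))^sample(1:3, 1)
      bg <- runif(500)
      expect_equal(enrichment_statistic(set_p, bg, par),
                   oracle_enrichment_stat(set_p, bg, grid, kappa),
                   tolerance = 1e-12)
    }
  })
})

test_that("msea skips out-of-bounds sets, errors on disjoint inputs", {
  cfg <- sim_config(seed = 6, n_genes = 120, n_gene_sets = 10,
                    set_size_range = c(5, 15), planted_set_size = 10,
                    network_nodes = 20, signal_fraction = 0)
  ann <- simulate_annotation(cfg)
  gs <- simulate_gene_sets(cfg, ann)
  map <- map_by_distance(ann$genes, ann$markers)
  assoc <- simulate_association_study(cfg, ann$markers, map, gs$truth,
                                      "gwas")
  sets <- gs$sets
  sets$too_small <- sets[[1]][1:2]
  sets$unmapped <- c("NOPE1", "NOPE2")
  par <- msea_params(n_permutations = 199, min_genes = 5)
  res <- msea(sets, map, assoc, par, seed = 2)
  skipped <- attr(res, "skipped")
  expect_false(any(c("too_small", "unmapped") %in% res$set_id))
  expect_setequal(skipped$set_id, c("too_small", "unmapped"))
  expect_true(all(res$p_empirical >= 1 / 200))
  expect_error(msea(sets, map,
                    data.frame(marker = "other", pvalue = 0.5), par),
               class = "msekda_consistency_error")
})

test_that("msea is reproducible and invariant to marker relabeling", {
  cfg <- sim_config(seed = 13, n_genes = 150, n_gene_sets = 12,
                    set_size_range = c(8, 20), planted_set_size = 15,
                    network_nodes = 20)
  ann <- simulate_annotation(cfg)
  gs <- simulate_gene_sets(cfg, ann)
  map <- map_by_distance(ann$genes, ann$markers)
  assoc <- simulate_association_study(cfg, ann$markers, map, gs$truth,
                                      "gwas")
  par <- msea_params(n_permutations = 199)
  r1 <- msea(gs$sets, map, assoc, par, seed = 5)
  expect_identical(r1, msea(gs$sets, map, assoc, par, seed = 5))
  # bijective marker renaming leaves every statistic unchanged
  relabel <- stats::setNames(sprintf("X%04d", seq_len(nrow(assoc))),
                             assoc$marker)
  assoc2 <- transform(assoc, marker = unname(relabel[marker]))
  map2 <- transform(map, marker = unname(relabel[marker]))
  r2 <- msea(gs$sets, map2, assoc2, par, seed = 5)
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_empirical, r2$p_empirical)
})

test_that("duplicate markers within a set are counted once", {
  # two genes sharing one strong marker; the set statistic must not double
  # count it
  assoc <- data.frame(marker = c("m1", sprintf("b%02d", 1:40)),
                      pvalue = c(1e-6, seq(0.025, 1, length.out = 40)))
  map <- rbind(data.frame(marker = "m1", gene = c("g1", "g2"),
                          scheme = "distance", source_scheme = "distance"),
               data.frame(marker = sprintf("b%02d", 1:40),
                          gene = sprintf("h%02d", 1:40),
                          scheme = "distance", source_scheme = "distance"))
  par <- msea_params(n_permutations = 100, min_genes = 2)
  res <- msea(list(dup = c("g1", "g2")), map, assoc, par, seed = 1)
  expect_equal(res$n_markers, 1L)
  expect_equal(res$statistic,
               enrichment_statistic(1e-6, assoc$pvalue, par))
})

test_that("bh_fdr reproduces hand-computed step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  withr::with_seed(2, {
    p <- runif(50)
    expect_equal(bh_fdr(p), oracle_bh(p))
  })
})

test_that("meta-analysis follows the unweighted Stouffer rule", {
  mk <- function(study, sets, p)
    data.frame(set_id = sets, statistic = 0, p_empirical = p, fdr = p,
               n_genes_mapped = 10L, n_markers = 10L, study_id = study)
  two <- meta_msea(list(mk("s1", "A", 0.05), mk("s2", "A", 0.05)))
  expect_equal(two$statistic[1], 2 * qnorm(0.95) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(two$p_empirical[1],
               pnorm(2 * qnorm(0.95) / sqrt(2), lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(round(two$p_empirical[1], 3), 0.010)
  # identical studies at p = 0.5 are a fixed point
  three <- meta_msea(list(mk("s1", "A", 0.5), mk("s2", "A", 0.5),
                          mk("s3", "A", 0.5)))
  expect_equal(three$p_empirical[1], 0.5, tolerance = 1e-12)
  # one study at the permutation floor, one at 1: combined strictly between
  floor_p <- 1 / 2000
  mixed <- meta_msea(list(mk("s1", "A", floor_p), mk("s2", "A", 1)))
  expect_gt(mixed$p_empirical[1], floor_p)
  expect_lt(mixed$p_empirical[1], 1)
  # a set present in one study only is passed through, flagged
  lop <- meta_msea(list(mk("s1", c("A", "B"), c(0.5, 0.01)),
                        mk("s2", "A", 0.5)))
  expect_false(lop$meta_combined[lop$set_id == "B"])
  expect_equal(sum(lop$meta_combined), 1)
})

test_that("significance selection applies the two-study-or-meta rule", {
  mk <- function(study, set, fdr)
    data.frame(set_id = set, statistic = 0, p_empirical = fdr, fdr = fdr,
               n_genes_mapped = 10L, n_markers = 10L, study_id = study)
  res <- rbind(mk("s1", "in_two", 0.01), mk("s2", "in_two", 0.01),
               mk("s1", "in_one", 0.01), mk("s2", "in_one", 0.9),
               mk("meta", "meta_only", 0.01),
               mk("s1", "meta_only", 0.9), mk("s2", "meta_only", 0.9))
  expect_setequal(select_significant(res, min_studies = 2),
                  c("in_two", "meta_only"))
  expect_true("in_one" %in% select_significant(res, min_studies = 1))
})
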