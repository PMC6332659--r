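test_that("annotation places markers inside their own genes, deterministically", {
  cfg <- sim_config(seed = 3, n_genes = 10, markers_per_gene = 5,
                    network_nodes = 10)
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$genes), 10)
  expect_equal(nrow(ann$markers), 50)
  expect_true(all(ann$genes$start >= 0 & ann$genes$end > ann$genes$start))
  # genes are spaced > 100 kb apart, so each marker falls within +-50 kb of
  # exactly its own gene
  map <- map_by_distance(ann$genes, ann$markers, window_bp = 50000)
  expect_equal(nrow(map), 50)
  expect_equal(sub("^M(\\d+)_.*$", "G\\1", map$marker), map$gene)
  expect_identical(ann, simulate_annotation(cfg))
  empty <- simulate_annotation(sim_config(n_genes = 0, network_nodes = 1,
                                          planted_hub_count = 0))
  expect_equal(nrow(empty$genes), 0)
  expect_equal(nrow(empty$markers), 0)
})

test_that("config validation names the offending field", {
  expect_error(sim_config(signal_fraction = 1.5), "signal_fraction",
               class = "msekda_config_error")
  expect_error(sim_config(set_size_range = c(1, 5)), "set_size_range",
               class = "msekda_config_error")
  expect_error(sim_config(n_samples_per_group = 2), "n_samples_per_group",
               class = "msekda_config_error")
  cfg <- sim_config(seed = 1, n_genes = 20, network_nodes = 10)
  ann <- simulate_annotation(cfg)
  bad_map <- data.frame(marker = "nope", gene = "G0001",
                        scheme = "distance", source_scheme = "distance")
  expect_error(
    simulate_association_study(cfg, ann$markers, bad_map,
                               list(planted_genes = character()), "gwas"),
    class = "msekda_consistency_error")
})

test_that("association p-values are null-uniform without signal", {
  cfg <- sim_config(n_genes = 200, network_nodes = 50, signal_fraction = 0)
  ann <- simulate_annotation(cfg)
  gs <- simulate_gene_sets(cfg, ann)
  map <- map_by_distance(ann$genes, ann$markers)
  pass <- vapply(1:60, function(s) {
    cfg$seed <- s
    a <- simulate_association_study(cfg, ann$markers, map, gs$truth, "gwas")
    suppressWarnings(stats::ks.test(a$pvalue, "punif"))$p.value > 0.01
  }, TRUE)
  expect_gte(mean(pass), 0.9)
})

test_that("planted markers are left-skewed and strength 1 is the null", {
  cfg <- sim_config(seed = 5, n_genes = 400, network_nodes = 50,
                    signal_fraction = 0.5, signal_strength = 0.2,
                    n_planted_sets = 2, planted_set_size = 100)
  ann <- simulate_annotation(cfg)
  gs <- simulate_gene_sets(cfg, ann)
  map <- map_by_distance(ann$genes, ann$markers)
  a <- simulate_association_study(cfg, ann$markers, map, gs$truth, "gwas")
  planted_m <- map$marker[map$gene %in% gs$truth$planted_genes]
  expect_lt(median(a$pvalue[a$marker %in% planted_m]),
            median(a$pvalue[!a$marker %in% planted_m]))
  # Beta(1, 1) = Uniform: planted and background indistinguishable
  cfg$signal_strength <- 1
  cfg$signal_fraction <- 1
  a2 <- simulate_association_study(cfg, ann$markers, map, gs$truth, "gwas")
  ks <- suppressWarnings(
    stats::ks.test(a2$pvalue[a2$marker %in% planted_m],
                   a2$pvalue[!a2$marker %in% planted_m]))
  expect_gt(ks$p.value, 0.01)
  # EWAS replicates from one truth differ but are individually reproducible
  e1 <- simulate_association_study(cfg, ann$markers, map, gs$truth, "ewas",
                                   study_index = 1)
  e2 <- simulate_association_study(cfg, ann$markers, map, gs$truth, "ewas",
                                   study_index = 2)
  expect_false(identical(e1$pvalue, e2$pvalue))
  expect_identical(e1, simulate_association_study(cfg, ann$markers, map,
                                                  gs$truth, "ewas",
                                                  study_index = 1))
})

test_that("LD tables contain exactly the within-block pairs", {
  cfg <- sim_config(seed = 2, n_genes = 3, markers_per_gene = 3,
                    ld_block_size = 3, ld_r2 = 0.9, network_nodes = 2,
                    planted_hub_count = 0, n_chromosomes = 1)
  ann <- simulate_annotation(cfg)   # 9 markers on one chromosome
  ld <- simulate_ld(cfg, ann$markers)
  expect_equal(nrow(ld), 9)         # 3 blocks x choose(3, 2)
  expect_true(all(ld$r2 == 0.9))
  cfg$ld_block_size <- 1L
  expect_equal(nrow(simulate_ld(cfg, ann$markers)), 0)
})

test_that("planted hubs have enriched neighborhoods; full enrichment nests them", {
  cfg <- sim_config(seed = 11, n_genes = 300, network_nodes = 150,
                    planted_hub_count = 3, hub_degree = 20,
                    hub_neighborhood_enrichment = 1.0,
                    n_planted_sets = 1, planted_set_size = 30)
  ann <- simulate_annotation(cfg)
  gs <- simulate_gene_sets(cfg, ann)
  nt <- simulate_network(cfg, gs$truth, ann$genes$gene)
  expect_length(nt$truth$planted_hubs, 3)
  for (h in nt$truth$planted_hubs) {
    nb <- names(neighborhood(nt$network, h))
    expect_true(all(nb %in% gs$truth$planted_genes))
    expect_gte(length(nb), 20)
  }
  expect_true(all(nt$network$weight > 0 & nt$network$weight <= 1))
  expect_identical(nt$network,
                   simulate_network(cfg, gs$truth, ann$genes$gene)$network)
})

test_that("expression planting yields detectable DE and module correlation", {
  cfg <- sim_config(seed = 9, n_genes = 300, network_nodes = 50,
                    n_samples_per_group = 50, de_effect_size = 2,
                    n_modules = 4, module_size = 25, module_loading = 0.9)
  ann <- simulate_annotation(cfg)
  truth <- list(de_genes = sprintf("G%04d", 1:30))
  ex <- simulate_expression(cfg, truth, ann$genes$gene)
  de <- de_genes(ex$expr, ex$labels)
  hits <- de$gene[de$fdr < 0.05]
  expect_gte(mean(truth$de_genes %in% hits), 0.95)
  # module genes correlate through the shared latent factor
  mods <- ex$truth$module_assignments
  m1 <- names(mods)[mods == "MOD_01"]
  m2 <- names(mods)[mods == "MOD_02"]
  within <- mean(cor(t(ex$expr[m1, ]))[upper.tri(diag(length(m1)))])
  between <- mean(cor(t(ex$expr[m1, ]), t(ex$expr[m2, ])))
  expect_gt(within, between)
  # zero effect: planted "DE" genes behave like null genes
  cfg$de_effect_size <- 0
  ex0 <- simulate_expression(cfg, truth, ann$genes$gene)
  de0 <- de_genes(ex0$expr, ex0$labels)
  t_de <- de0$statistic[de0$gene %in% truth$de_genes]
  t_null <- de0$statistic[!de0$gene %in% truth$de_genes]
  expect_gt(suppressWarnings(stats::ks.test(t_de, t_null))$p.value, 0.01)
})

test_that("a written study round-trips through the plain-text formats", {
  cfg <- sim_config(seed = 4, n_genes = 60, network_nodes = 40,
                    n_gene_sets = 10, set_size_range = c(5, 10),
                    planted_set_size = 20, n_planted_sets = 1,
                    n_samples_per_group = 4,
                    planted_hub_count = 1, hub_degree = 10,
                    n_modules = 2, module_size = 5)
  st <- simulate_study(cfg, n_ewas = 1)
  d <- withr::local_tempdir()
  write_study(st, d)
  expect_equal(read_association(file.path(d, "gwas.tsv")), st$gwas)
  expect_equal(read_gmt(file.path(d, "gene_sets.gmt")),
               st$sets, ignore_attr = TRUE)
  expect_equal(read_network(file.path(d, "network.tsv")),
               st$network, ignore_attr = TRUE)
  ex <- read_expression(file.path(d, "expression.tsv"),
                        file.path(d, "sample_labels.tsv"))
  expect_equal(ex$expr, st$expr, tolerance = 1e-12)
  expect_equal(as.character(ex$labels), as.character(st$labels))
  expect_equal(levels(ex$labels), levels(st$labels))
})
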