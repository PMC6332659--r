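star_net <- function(center, spokes, w) {
  validate_network(data.frame(tail = center, head = spokes, weight = w))
}

test_that("neighborhood follows the max-product rule", {
  # isolated node: a network it does not appear in
  net <- star_net("hub", c("a", "b", "c"), c(0.9, 0.5, 0.2))
  expect_length(neighborhood(net, "zzz"), 0)
  # star center at depth 1: the spokes with their edge weights
  nb <- neighborhood(net, "hub", depth = 1)
  expect_equal(nb[c("a", "b", "c")], c(a = 0.9, b = 0.5, c = 0.2))
  # path a-b-c with weights 0.5, 0.5 at depth 2 from a
  path <- validate_network(data.frame(tail = c("a", "b"),
                                      head = c("b", "c"),
                                      weight = c(0.5, 0.5)))
  nb2 <- neighborhood(path, "a", depth = 2)
  expect_equal(nb2[c("b", "c")], c(b = 0.5, c = 0.25))
  expect_length(neighborhood(path, "a", depth = 1), 1)
  # two routes to the same node: the better product wins
  tri <- validate_network(data.frame(
    tail = c("a", "a", "b"), head = c("b", "c", "c"),
    weight = c(0.9, 0.1, 0.9)))
  expect_equal(neighborhood(tri, "a", depth = 2)[["c"]], 0.9 * 0.9)
})

test_that("a superset covering every node forces null statistics", {
  withr::with_seed(12, {
    cfg <- sim_config(n_genes = 200, network_nodes = 100, mean_degree = 8,
                      planted_hub_count = 2, n_planted_sets = 1,
                      planted_set_size = 30)
    ann <- simulate_annotation(cfg)
    gs <- simulate_gene_sets(cfg, ann)
    nt <- simulate_network(cfg, gs$truth, ann$genes$gene)
    nodes <- unique(c(nt$network$tail, nt$network$head))
    res <- wkda(nt$network, nodes, n_permutations = 199,
                min_neighborhood = 3, seed = 1)
    expect_true(all(abs(res$statistic) < 1e-12))
    expect_false(any(res$fdr < 0.05))
  })
})

test_that("uniform-weight wKDA matches the unweighted counting oracle", {
  withr::with_seed(23, {
    for (i in 1:5) {
      n <- 60
      pr <- t(utils::combn(sprintf("n%02d", 1:n), 2))
      pick <- sample(nrow(pr), 240)
      net <- validate_network(data.frame(tail = pr[pick, 1],
                                         head = pr[pick, 2], weight = 1))
      superset <- sample(sprintf("n%02d", 1:n), 15)
      res <- wkda(net, superset, n_permutations = 100,
                  min_neighborhood = 5, seed = i)
      orc <- oracle_unweighted_kda(net, superset, min_neighborhood = 5)
      expect_setequal(res$gene_id, names(orc))
      expect_equal(res$statistic, unname(orc[res$gene_id]),
                   tolerance = 1e-12)
      # identical ranking under the shared deterministic tie-break
      ord_pkg <- res$gene_id[order(-res$statistic, res$gene_id)]
      ord_orc <- names(orc)[order(-orc, names(orc))]
      expect_equal(ord_pkg, ord_orc)
    }
  })
})

test_that("wkda recovers planted hubs and is seed-stable", {
  cfg <- sim_config(seed = 31, n_genes = 600, network_nodes = 300,
                    planted_hub_count = 3, hub_degree = 30,
                    hub_neighborhood_enrichment = 0.8,
                    n_planted_sets = 1, planted_set_size = 50)
  ann <- simulate_annotation(cfg)
  gs <- simulate_gene_sets(cfg, ann)
  nt <- simulate_network(cfg, gs$truth, ann$genes$gene)
  res <- wkda(nt$network, gs$truth$planted_genes, n_permutations = 499,
              seed = 7)
  expect_true(all(nt$truth$planted_hubs %in% head(res$gene_id, 10)))
  expect_identical(res, wkda(nt$network, gs$truth$planted_genes,
                             n_permutations = 499, seed = 7))
  expect_error(wkda(nt$network, c("absent1", "absent2")),
               class = "msekda_consistency_error")
  expect_warning(wkda(nt$network, gs$truth$planted_genes,
                      n_permutations = 100, min_neighborhood = 10000),
                 "neighborhood")
})

test_that("removing a hub's disease edges lowers its statistic", {
  cfg <- sim_config(seed = 44, n_genes = 400, network_nodes = 200,
                    planted_hub_count = 1, hub_degree = 25,
                    hub_neighborhood_enrichment = 0.8,
                    n_planted_sets = 1, planted_set_size = 40)
  ann <- simulate_annotation(cfg)
  gs <- simulate_gene_sets(cfg, ann)
  nt <- simulate_network(cfg, gs$truth, ann$genes$gene)
  hub <- nt$truth$planted_hubs
  full <- wkda(nt$network, gs$truth$planted_genes, n_permutations = 100,
               seed = 2)
  cut <- nt$network[!((nt$network$tail == hub &
                         nt$network$head %in% gs$truth$planted_genes) |
                        (nt$network$head == hub &
                           nt$network$tail %in% gs$truth$planted_genes)), ]
  reduced <- wkda(validate_network(cut), gs$truth$planted_genes,
                  n_permutations = 100, seed = 2)
  s_full <- full$statistic[full$gene_id == hub]
  s_cut <- reduced$statistic[reduced$gene_id == hub]
  expect_true(length(s_cut) == 0 || s_cut < s_full)
})

test_that("shared key drivers require two significant combinations", {
  mk <- function(gene, ss, net, fdr)
    data.frame(gene_id = gene, superset_id = ss, network_id = net,
               statistic = 1, p_empirical = fdr, fdr = fdr,
               neighborhood_size = 10L, n_hits = 5L, in_superset = FALSE)
  res <- rbind(mk("g1", "S1", "skin", 0.01), mk("g1", "S1", "blood", 0.01),
               mk("g2", "S1", "skin", 0.01), mk("g2", "S2", "skin", 0.2),
               mk("g3", "S1", "skin", 0.5))
  sh <- shared_kds(res)
  expect_equal(sh$gene_id, "g1")
  expect_equal(sh$n_combinations, 2L)
  expect_identical(sh, shared_kds(res[sample(nrow(res)), ]))
})

test_that("subnetwork extraction annotates and round-trips through files", {
  net <- star_net("kd", c("a", "b", "c", "d"), c(0.9, 0.8, 0.7, 0.6))
  sn <- extract_subnetwork(net, "kd", superset = c("a", "b"),
                           marker_flags = c(a = TRUE, b = FALSE, c = FALSE,
                                            d = TRUE, kd = FALSE))
  expect_equal(nrow(sn$edges), 4)
  expect_equal(sum(sn$nodes$in_superset), 2)
  expect_true(sn$nodes$is_kd[sn$nodes$gene_id == "kd"])
  d <- withr::local_tempdir()
  write_subnetwork(sn, file.path(d, "sub"))
  back <- read_subnetwork(file.path(d, "sub"))
  expect_equal(back$nodes, sn$nodes)
  expect_equal(back$edges, sn$edges, ignore_attr = TRUE)
  # a KD with no superset genes nearby still yields a subnetwork
  sn0 <- extract_subnetwork(net, "kd", superset = "elsewhere")
  expect_equal(sum(sn0$nodes$in_superset), 0)
  expect_equal(nrow(sn0$edges), 4)
})
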