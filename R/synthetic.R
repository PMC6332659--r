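#' Configuration for the synthetic multi-omics study generator
#'
#' Collects every tunable of the generator in one validated object.  The
#' defaults define a desk-scale study with planted disease pathways, an LD
#' block structure, a hub-enriched gene network, and an expression matrix
#' with planted differential expression and coexpression modules, so that
#' every downstream stage (mapping, MSEA, superset merging, wKDA, GSEA
#' validation) has a known ground truth to recover.
#'
#' @param seed Integer seed; every generated artifact derives its own RNG
#'   stream from `seed` plus a fixed per-artifact offset, so artifacts are
#'   individually reproducible.
#' @param n_genes Number of genes in the universe.
#' @param markers_per_gene Markers placed inside each gene body.
#' @param n_gene_sets Number of gene sets in the collection.
#' @param set_size_range Length-2 integer vector, min/max genes per set
#'   (min must be >= 2).
#' @param n_planted_sets Number of sets carrying planted association signal.
#' @param planted_set_ids Optional explicit ids of planted sets (must be a
#'   subset of the generated names `SET_001`, ...); overrides
#'   `n_planted_sets`.
#' @param planted_set_size Optional fixed size for planted sets; `NULL`
#'   draws them like any other set.
#' @param signal_fraction Fraction of markers mapped to planted-set genes
#'   that carry signal, in \[0, 1\].
#' @param signal_strength Shape parameter `a` of the Beta(a, 1) signal
#'   p-value law; `a < 1` is left-skewed, `a = 1` is the uniform null.
#' @param ld_block_size Consecutive markers per LD block.
#' @param ld_r2 Within-block squared correlation, in \[0, 1\].
#' @param network_nodes Number of network nodes (drawn from the universe).
#' @param planted_hub_count Number of planted hub genes.
#' @param hub_degree Neighbors attached to each planted hub (>= 20 in the
#'   default study conditions).
#' @param hub_neighborhood_enrichment Fraction of each hub's neighbors
#'   drawn from the disease gene set (the union of planted sets).
#' @param mean_degree Mean degree of the random background topology.
#' @param n_modules,module_size Planted coexpression modules in the
#'   expression matrix.
#' @param module_loading Loading of module genes on their shared latent
#'   factor, in \[0, 1\).
#' @param n_samples_per_group Samples per phenotype group (>= 3).
#' @param de_effect_size Standardized mean difference planted in
#'   differentially expressed genes.
#' @param gene_spacing,gene_length Base-pair layout of the synthetic
#'   chromosomes; the default spacing exceeds twice the 50 kb mapping
#'   window, so distance mapping is unambiguous.
#' @param n_chromosomes Number of synthetic chromosomes.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 1000L,
                       markers_per_gene = 5L,
                       n_gene_sets = 100L,
                       set_size_range = c(10L, 50L),
                       n_planted_sets = 3L,
                       planted_set_ids = NULL,
                       planted_set_size = 50L,
                       signal_fraction = 0.5,
                       signal_strength = 0.2,
                       ld_block_size = 5L,
                       ld_r2 = 0.9,
                       network_nodes = 500L,
                       planted_hub_count = 5L,
                       hub_degree = 30L,
                       hub_neighborhood_enrichment = 0.8,
                       mean_degree = 6,
                       n_modules = 8L,
                       module_size = 30L,
                       module_loading = 0.7,
                       n_samples_per_group = 50L,
                       de_effect_size = 2,
                       gene_spacing = 150000L,
                       gene_length = 20000L,
                       n_chromosomes = 5L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              markers_per_gene = as.integer(markers_per_gene),
              n_gene_sets = as.integer(n_gene_sets),
              set_size_range = as.integer(set_size_range),
              n_planted_sets = as.integer(n_planted_sets),
              planted_set_ids = planted_set_ids,
              planted_set_size =
                if (is.null(planted_set_size)) NULL
                else as.integer(planted_set_size),
              signal_fraction = signal_fraction,
              signal_strength = signal_strength,
              ld_block_size = as.integer(ld_block_size), ld_r2 = ld_r2,
              network_nodes = as.integer(network_nodes),
              planted_hub_count = as.integer(planted_hub_count),
              hub_degree = as.integer(hub_degree),
              hub_neighborhood_enrichment = hub_neighborhood_enrichment,
              mean_degree = mean_degree, n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              module_loading = module_loading,
              n_samples_per_group = as.integer(n_samples_per_group),
              de_effect_size = de_effect_size,
              gene_spacing = as.integer(gene_spacing),
              gene_length = as.integer(gene_length),
              n_chromosomes = as.integer(n_chromosomes))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why)
    msekda_stop(sprintf("invalid config field '%s': %s", field, why),
                "msekda_config_error")
  counts <- c("markers_per_gene", "n_gene_sets", "ld_block_size",
              "network_nodes", "hub_degree", "n_modules", "module_size",
              "gene_spacing", "gene_length", "n_chromosomes")
  for (f in counts) if (cfg[[f]] < 1L) bad(f, "must be a positive count")
  if (cfg$n_genes < 0L) bad("n_genes", "must be non-negative")
  if (cfg$n_planted_sets < 0L) bad("n_planted_sets", "must be non-negative")
  if (cfg$planted_hub_count < 0L)
    bad("planted_hub_count", "must be non-negative")
  if (cfg$n_samples_per_group < 3L)
    bad("n_samples_per_group", "must be at least 3")
  fracs <- c("signal_fraction", "ld_r2", "hub_neighborhood_enrichment",
             "module_loading")
  for (f in fracs)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) bad(f, "must lie in [0, 1]")
  if (cfg$signal_strength <= 0) bad("signal_strength", "must be positive")
  if (length(cfg$set_size_range) != 2L || cfg$set_size_range[1] < 2L ||
      cfg$set_size_range[2] < cfg$set_size_range[1])
    bad("set_size_range", "must be (min, max) with min >= 2 and max >= min")
  if (cfg$planted_hub_count > cfg$network_nodes)
    bad("planted_hub_count", "cannot exceed network_nodes")
  if (cfg$network_nodes > max(cfg$n_genes, 1L))
    bad("network_nodes", "cannot exceed n_genes")
  cfg
}

sim_seed <- function(cfg, offset) (cfg$seed %% 1000000L) * 1000L + offset

#' Simulate a gene/marker annotation
#'
#' Places genes on synthetic chromosomes at regular spacing (so intervals
#' are strictly ordered and non-overlapping) and drops `markers_per_gene`
#' markers evenly through each gene body, giving every gene a known marker
#' complement under any mapping window.  Coordinates are 0-based half-open.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"sim_annotation"` with `genes` (data.frame
#'   `gene`, `chrom`, `start`, `end`) and `markers` (data.frame `marker`,
#'   `chrom`, `pos`), both position-sorted within chromosome.
#' @export
simulate_annotation <- function(config) {
  config <- validate_sim_config(config)
  ng <- config$n_genes
  if (ng == 0L) {
    out <- list(genes = data.frame(gene = character(), chrom = character(),
                                   start = integer(), end = integer()),
                markers = data.frame(marker = character(),
                                     chrom = character(), pos = integer()))
    class(out) <- "sim_annotation"
    return(out)
  }
  chrom_idx <- rep(seq_len(config$n_chromosomes), length.out = ng)
  within <- stats::ave(seq_len(ng), chrom_idx, FUN = seq_along)
  start <- (within - 1L) * config$gene_spacing
  genes <- data.frame(gene = sprintf("G%04d", seq_len(ng)),
                      chrom = paste0("chr", chrom_idx),
                      start = start, end = start + config$gene_length)
  m <- config$markers_per_gene
  offs <- round(config$gene_length * seq_len(m) / (m + 1L))
  markers <- data.frame(
    marker = sprintf("M%04d_%02d", rep(seq_len(ng), each = m),
                     rep(seq_len(m), ng)),
    chrom = rep(genes$chrom, each = m),
    pos = rep(genes$start, each = m) + rep(offs, ng))
  ord <- order(genes$chrom, genes$start)
  mord <- order(markers$chrom, markers$pos)
  out <- list(genes = genes[ord, , drop = FALSE],
              markers = markers[mord, , drop = FALSE])
  rownames(out$genes) <- rownames(out$markers) <- NULL
  class(out) <- "sim_annotation"
  out
}

#' Simulate a gene-set collection with planted disease sets
#'
#' Draws `n_gene_sets` sets of sizes uniform in `set_size_range` from the
#' gene universe (without replacement within a set, so pairwise overlaps
#' follow the hypergeometric law) and designates planted sets whose genes
#' will carry association signal downstream.
#'
#' @param config A [sim_config()] object.
#' @param annotation A [simulate_annotation()] result.
#' @return A list with `sets` (named list of gene id vectors) and `truth`
#'   (list with `planted_sets` and `planted_genes`).
#' @export
simulate_gene_sets <- function(config, annotation) {
  config <- validate_sim_config(config)
  universe <- annotation$genes$gene
  withr::with_seed(sim_seed(config, 2L), {
    sizes <- sample(seq(config$set_size_range[1], config$set_size_range[2]),
                    config$n_gene_sets, replace = TRUE)
    ids <- sprintf("SET_%03d", seq_len(config$n_gene_sets))
    planted <- config$planted_set_ids %||%
      ids[seq_len(min(config$n_planted_sets, length(ids)))]
    if (!all(planted %in% ids))
      msekda_stop("invalid config field 'planted_set_ids': not a subset of generated set names",
                  "msekda_config_error")
    if (!is.null(config$planted_set_size))
      sizes[match(planted, ids)] <- config$planted_set_size
    sizes <- pmin(sizes, length(universe))
    sets <- lapply(sizes, function(k) sort(sample(universe, k)))
    names(sets) <- ids
  })
  list(sets = sets,
       truth = list(planted_sets = planted,
                    planted_set_genes = sets[planted],
                    planted_genes = sort(unique(unlist(sets[planted],
                                                       use.names = FALSE)))))
}

#' Simulate GWAS/EWAS summary statistics with planted pathway signal
#'
#' Markers mapped to genes outside the planted sets receive p ~
#' Uniform(0, 1).  Among markers mapped to planted-set genes, a
#' `signal_fraction` receive p ~ Beta(`signal_strength`, 1), which is
#' left-skewed for `signal_strength` < 1 and reduces to the uniform null at
#' `signal_strength` = 1.  For EWAS, independent replicate studies from the
#' same ground truth are obtained by varying `study_index`.
#'
#' @param config A [sim_config()] object.
#' @param markers Marker position data.frame (`marker`, `chrom`, `pos`),
#'   e.g. `simulate_annotation(config)$markers`.
#' @param map A marker-gene map covering (a subset of) `markers`.
#' @param truth Ground-truth list with `planted_genes` (see
#'   [simulate_gene_sets()]).
#' @param study_kind `"gwas"` or `"ewas"` (affects only the RNG stream).
#' @param study_index Replicate index (1, 2, ... for multi-study EWAS).
#' @return An association data.frame (`marker`, `pvalue`).
#' @export
simulate_association_study <- function(config, markers, map, truth,
                                       study_kind = c("gwas", "ewas"),
                                       study_index = 1L) {
  config <- validate_sim_config(config)
  study_kind <- match.arg(study_kind)
  if (!all(map$marker %in% markers$marker))
    msekda_stop("marker-gene map references markers absent from the annotation",
                "msekda_consistency_error")
  planted_markers <- unique(map$marker[map$gene %in% truth$planted_genes])
  offset <- 10L + 7L * as.integer(study_index) +
    if (study_kind == "ewas") 1000L else 0L
  withr::with_seed(sim_seed(config, offset), {
    p <- runif(nrow(markers))
    if (length(planted_markers) && config$signal_fraction > 0) {
      n_sig <- round(config$signal_fraction * length(planted_markers))
      sig <- sample(planted_markers, n_sig)
      idx <- match(sig, markers$marker)
      p[idx] <- rbeta(length(idx), config$signal_strength, 1)
    }
  })
  validate_association(data.frame(marker = markers$marker,
                                  pvalue = pmax(p, 1e-300)))
}

#' Simulate a block LD table
#'
#' Groups consecutive markers (within chromosome, by position) into blocks
#' of `ld_block_size`; every within-block pair carries r2 = `ld_r2` and
#' cross-block pairs carry r2 = 0 (omitted from the table).  This is the
#' minimal structure needed to exercise LD pruning; realistic LD decay is
#' out of scope.
#'
#' @param config A [sim_config()] object.
#' @param markers Marker position data.frame, position-sorted.
#' @return An LD data.frame (`marker_a`, `marker_b`, `r2`).
#' @export
simulate_ld <- function(config, markers) {
  config <- validate_sim_config(config)
  empty <- data.frame(marker_a = character(), marker_b = character(),
                      r2 = numeric())
  if (nrow(markers) == 0L || config$ld_block_size < 2L)
    return(validate_ld(empty))
  ord <- order(markers$chrom, markers$pos)
  pieces <- lapply(split(markers$marker[ord], markers$chrom[ord]),
                   function(ids) {
    block <- ceiling(seq_along(ids) / config$ld_block_size)
    do.call(rbind, lapply(split(ids, block), function(b) {
      if (length(b) < 2L) return(NULL)
      pr <- utils::combn(b, 2L)
      data.frame(marker_a = pr[1, ], marker_b = pr[2, ], r2 = config$ld_r2)
    }))
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) out <- empty
  rownames(out) <- NULL
  validate_ld(out)
}

#' Simulate an edge-weighted gene network with planted hubs
#'
#' Background topology is an Erdos-Renyi graph with mean degree
#' `mean_degree` over `network_nodes` genes sampled from the universe
#' (disease genes are always included).  Each planted hub is assigned a
#' designated disease gene set -- the planted sets in `truth`, cycled --
#' and receives `hub_degree` neighbors of which a
#' `hub_neighborhood_enrichment` fraction are drawn from that set, so each
#' hub's neighborhood is enriched for one planted pathway, the way a
#' regulator drives one process.  Edge weights are uniform on (0, 1].
#'
#' As a side effect of hub placement, the ground truth gains `planted_hubs`
#' and `de_genes` (the hubs plus their disease-gene neighbors), which
#' [simulate_expression()] uses to plant differential expression in hub
#' neighborhoods.
#'
#' @param config A [sim_config()] object.
#' @param truth Ground-truth list with `planted_genes`.
#' @param universe Character vector of all gene ids.
#' @return A list with `network` (edge data.frame `tail`, `head`, `weight`,
#'   undirected) and the augmented `truth`.
#' @export
simulate_network <- function(config, truth, universe) {
  config <- validate_sim_config(config)
  n <- config$network_nodes
  withr::with_seed(sim_seed(config, 4L), {
    disease <- utils::head(intersect(truth$planted_genes, universe), n)
    nodes <- c(disease, sample(setdiff(universe, disease),
                               max(0L, n - length(disease))))
    non_disease <- setdiff(nodes, disease)
    if (config$planted_hub_count > length(non_disease))
      msekda_stop("not enough non-disease nodes to place planted hubs",
                  "msekda_sampling_error")
    hubs <- if (config$planted_hub_count > 0L)
      sample(non_disease, config$planted_hub_count) else character()

    # background topology avoids the hubs so a hub's neighborhood is
    # exactly its planted draw (full enrichment nests it in the disease set)
    bg_nodes <- setdiff(nodes, hubs)
    n_edges <- round(config$mean_degree * length(bg_nodes) / 2)
    a <- sample(bg_nodes, n_edges, replace = TRUE)
    b <- sample(bg_nodes, n_edges, replace = TRUE)
    keep <- a != b
    edges <- data.frame(tail = pmin(a[keep], b[keep]),
                        head = pmax(a[keep], b[keep]))

    n_dis <- round(config$hub_neighborhood_enrichment * config$hub_degree)
    designated <- truth$planted_set_genes %||% list(truth$planted_genes)
    hub_edges <- lapply(seq_along(hubs), function(i) {
      h <- hubs[i]
      dset <- designated[[(i - 1L) %% length(designated) + 1L]]
      pool <- setdiff(intersect(dset, nodes), h)
      if (length(pool) < n_dis)
        msekda_stop("disease gene set smaller than required hub neighbor draw",
                    "msekda_sampling_error")
      nb <- c(sample(pool, n_dis),
              sample(setdiff(nodes, c(h, disease)),
                     config$hub_degree - n_dis))
      data.frame(tail = pmin(h, nb), head = pmax(h, nb))
    })
    edges <- rbind(edges, do.call(rbind, hub_edges))
    edges <- edges[!duplicated(edges[, c("tail", "head")]), , drop = FALSE]
    edges$weight <- runif(nrow(edges), min = 1e-6)
    edges <- edges[order(edges$tail, edges$head), , drop = FALSE]
  })
  rownames(edges) <- NULL
  hub_nb <- unique(c(edges$head[edges$tail %in% hubs],
                     edges$tail[edges$head %in% hubs]))
  truth$planted_hubs <- sort(hubs)
  truth$de_genes <- sort(unique(c(hubs, intersect(hub_nb, disease))))
  list(network = validate_network(edges, directed = FALSE), truth = truth)
}

#' Simulate an expression matrix with planted DE genes and modules
#'
#' Entries are unit-variance Gaussian noise; genes sharing a module label
#' load on a per-module latent factor (loading `module_loading`, noise
#' scaled so marginal variance stays 1); genes in `truth$de_genes` are
#' shifted by `de_effect_size` standard deviations in the case group
#' (up-regulated in cases).
#'
#' @param config A [sim_config()] object.
#' @param truth Ground-truth list; `de_genes` (optional) receive the mean
#'   shift.  The returned truth gains `module_assignments`.
#' @param universe Character vector of gene ids to simulate.
#' @return A list with `expr` (genes x samples matrix), `labels` (factor
#'   `control`/`case`), and the augmented `truth`.
#' @export
simulate_expression <- function(config, truth, universe) {
  config <- validate_sim_config(config)
  ns <- config$n_samples_per_group
  labels <- factor(rep(c("control", "case"), each = ns),
                   levels = c("control", "case"))
  withr::with_seed(sim_seed(config, 5L), {
    expr <- matrix(rnorm(length(universe) * 2L * ns), nrow = length(universe),
                   dimnames = list(universe,
                                   sprintf("S%03d", seq_len(2L * ns))))
    n_mod_genes <- min(config$n_modules * config$module_size,
                       length(universe))
    mod_genes <- if (n_mod_genes > 0L) sample(universe, n_mod_genes)
                 else character()
    assignments <- stats::setNames(
      sprintf("MOD_%02d", rep(seq_len(config$n_modules),
                              each = config$module_size))[seq_along(mod_genes)],
      mod_genes)
    lam <- config$module_loading
    for (m in unique(assignments)) {
      g <- names(assignments)[assignments == m]
      f <- rnorm(ncol(expr))
      expr[g, ] <- lam * matrix(f, nrow = length(g), ncol = ncol(expr),
                                byrow = TRUE) +
        sqrt(1 - lam^2) * expr[g, , drop = FALSE]
    }
    de <- intersect(truth$de_genes %||% character(), universe)
    if (length(de))
      expr[de, labels == "case"] <- expr[de, labels == "case"] +
        config$de_effect_size
  })
  truth$module_assignments <- assignments
  list(expr = expr, labels = labels, truth = truth)
}

#' Simulate a complete synthetic multi-omics study
#'
#' Convenience orchestrator running every generator stage with one config:
#' annotation, gene sets, distance-based marker-gene map, one GWAS plus
#' `n_ewas` EWAS association studies, block LD, hub-planted network, and a
#' labeled expression matrix.  All ground truth (planted sets, planted
#' genes, planted hubs, DE genes, module assignments) is collected in
#' `$truth`.
#'
#' @param config A [sim_config()] object.
#' @param n_ewas Number of EWAS replicate studies.
#' @param window_bp Mapping window passed to [map_by_distance()].
#' @return A list of class `"sim_study"` with elements `annotation`,
#'   `sets`, `map`, `gwas`, `ewas` (list), `ld`, `network`, `expr`,
#'   `labels`, `truth`, and `config`.
#' @export
simulate_study <- function(config, n_ewas = 3L, window_bp = 50000L) {
  config <- validate_sim_config(config)
  ann <- simulate_annotation(config)
  gs <- simulate_gene_sets(config, ann)
  map <- map_by_distance(ann$genes, ann$markers, window_bp = window_bp)
  gwas <- simulate_association_study(config, ann$markers, map, gs$truth,
                                     study_kind = "gwas")
  ewas <- lapply(seq_len(n_ewas), function(i)
    simulate_association_study(config, ann$markers, map, gs$truth,
                               study_kind = "ewas", study_index = i))
  names(ewas) <- sprintf("ewas%d", seq_len(n_ewas))
  ld <- simulate_ld(config, ann$markers)
  net <- simulate_network(config, gs$truth, ann$genes$gene)
  ex <- simulate_expression(config, net$truth, ann$genes$gene)
  out <- list(annotation = ann, sets = gs$sets, map = map, gwas = gwas,
              ewas = ewas, ld = ld, network = net$network, expr = ex$expr,
              labels = ex$labels, truth = ex$truth, config = config)
  class(out) <- "sim_study"
  out
}

#' Write a simulated study to a directory of plain-text files
#'
#' Emits the standard interchange formats: BED-like annotation, marker
#' positions, 2-column association TSVs, LD TSV, GMT gene sets, edge-list
#' network TSV, expression and label TSVs, and the ground truth as YAML.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_annotation(study$annotation$genes, fp("genes.bed.tsv"))
  write_marker_positions(study$annotation$markers, fp("markers.tsv"))
  write_gmt(study$sets, fp("gene_sets.gmt"))
  write_map(study$map, fp("marker_gene_map.tsv"))
  write_association(study$gwas, fp("gwas.tsv"))
  for (nm in names(study$ewas))
    write_association(study$ewas[[nm]], fp(paste0(nm, ".tsv")))
  write_ld(study$ld, fp("ld.tsv"))
  write_network(study$network, fp("network.tsv"))
  write_expression(study$expr, study$labels, fp("expression.tsv"),
                   fp("sample_labels.tsv"))
  truth <- study$truth
  truth$module_assignments <- as.list(truth$module_assignments)
  yaml::write_yaml(truth, fp("ground_truth.yaml"))
  invisible(dir)
}
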