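#' Three-way intersection of significant set ids
#'
#' Exact partition of two significant-set lists by set id, used to find
#' the gene sets on which genetic (GWAS) and epigenetic (EWAS) evidence
#' converges.
#'
#' @param gwas_sets,ewas_sets Character vectors of set ids.
#' @return A list with `common`, `gwas_only`, `ewas_only` (sorted).
#' @export
intersect_significant <- function(gwas_sets, ewas_sets) {
  list(common = sort(intersect(gwas_sets, ewas_sets)),
       gwas_only = sort(setdiff(gwas_sets, ewas_sets)),
       ewas_only = sort(setdiff(ewas_sets, gwas_sets)))
}

#' Pipeline configuration
#'
#' Collects input paths and per-stage parameters for [run_pipeline()].
#' All paths must exist at run start.  Either supply a YAML file with the
#' same field names or build the config in R.
#'
#' @param gwas Path to the GWAS association TSV.
#' @param ewas Character vector of EWAS association TSV paths (named by
#'   study id; defaults to file stems).
#' @param annotation Path to the BED-like gene annotation.
#' @param markers Path to the marker-position TSV.
#' @param gene_sets Path to the gene-set GMT.
#' @param ld Path to the LD TSV (optional; empty string disables pruning).
#' @param network Paths to network edge-list TSVs, named by tissue.
#' @param expression,sample_labels Paths for the validation expression
#'   matrix and labels (optional).
#' @param out_dir Output directory.
#' @param seed Global integer seed.
#' @param window_bp Distance-mapping window (default 50 kb).
#' @param ld_r2 LD pruning threshold (default 0.7).
#' @param msea An [msea_params()] object.
#' @param merge_r,merge_fdr,merge_max_size Superset merging thresholds.
#' @param exclude_genes Character vector removed from supersets before
#'   revalidation (e.g. HLA genes).
#' @param kda_min_neighborhood,kda_permutations wKDA parameters.
#' @param gsea_permutations GSEA label permutations.
#' @param fdr_threshold Stage-level significance threshold.
#' @param gwas_min_studies,ewas_min_studies Study-count rules for
#'   [select_significant()] (defaults: 1 for the single GWAS, 2 for EWAS).
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(gwas, ewas, annotation, markers, gene_sets,
                            ld = "", network, expression = "",
                            sample_labels = "", out_dir, seed = 1L,
                            window_bp = 50000L, ld_r2 = 0.7,
                            msea = msea_params(), merge_r = 0.2,
                            merge_fdr = 0.05, merge_max_size = 500L,
                            exclude_genes = character(),
                            kda_min_neighborhood = 10L,
                            kda_permutations = 1999L,
                            gsea_permutations = 199L,
                            fdr_threshold = 0.05,
                            gwas_min_studies = 1L, ewas_min_studies = 2L) {
  if (is.null(names(ewas)))
    names(ewas) <- sub("\\.tsv$", "", basename(ewas))
  if (is.null(names(network)))
    names(network) <- sub("\\.tsv$", "", basename(network))
  cfg <- list(gwas = gwas, ewas = ewas, annotation = annotation,
              markers = markers, gene_sets = gene_sets, ld = ld,
              network = network, expression = expression,
              sample_labels = sample_labels, out_dir = out_dir,
              seed = as.integer(seed), window_bp = window_bp,
              ld_r2 = ld_r2, msea = msea, merge_r = merge_r,
              merge_fdr = merge_fdr, merge_max_size = merge_max_size,
              exclude_genes = exclude_genes,
              kda_min_neighborhood = kda_min_neighborhood,
              kda_permutations = kda_permutations,
              gsea_permutations = gsea_permutations,
              fdr_threshold = fdr_threshold,
              gwas_min_studies = gwas_min_studies,
              ewas_min_studies = ewas_min_studies)
  required <- c(cfg$gwas, cfg$ewas, cfg$annotation, cfg$markers,
                cfg$gene_sets,
                if (nzchar(cfg$ld)) cfg$ld, cfg$network,
                if (nzchar(cfg$expression)) c(cfg$expression,
                                              cfg$sample_labels))
  missing <- required[!file.exists(required)]
  if (length(missing))
    msekda_stop(paste("missing input file(s):",
                      paste(missing, collapse = ", ")),
                "msekda_config_error")
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the [pipeline_config()]
#'   arguments (stage parameter blocks `msea` given as a named list).
#' @return A `"pipeline_config"` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$msea)) y$msea <- do.call(msea_params, y$msea)
  y$ewas <- unlist(y$ewas)
  y$network <- unlist(y$network)
  do.call(pipeline_config, y)
}

stage_done <- function(manifest, stage, files) {
  if (is.null(manifest)) return(FALSE)
  rec <- manifest$stages[[stage]]
  if (is.null(rec)) return(FALSE)
  all(file.exists(files)) &&
    identical(unname(unlist(rec$outputs)),
              unname(tools::md5sum(files)))
}

#' Run the integrated multi-omics pipeline
#'
#' Executes the full analysis on file inputs: distance mapping, LD
#' pruning, MSEA per study, EWAS meta-analysis, significant-set selection
#' per arm, GWAS/EWAS intersection, superset merging, superset
#' revalidation, wKDA per (superset, network), key driver subnetwork
#' export, and (when expression data is configured) GSEA validation of the
#' KD subnetworks.  Every stage writes its outputs under
#' `config$out_dir` and records their MD5 checksums in
#' `manifest.json`, written last.  On re-runs, stages whose recorded
#' outputs still exist with matching checksums are skipped, so deleting
#' one stage's outputs re-executes only that stage and those after it.
#'
#' @param config A [pipeline_config()] object (or a YAML path).
#' @return The run manifest (named list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out, ...)
  prev <- if (file.exists(fp("manifest.json")))
    jsonlite::read_json(fp("manifest.json")) else NULL
  if (!is.null(prev) && !identical(prev$config_hash, digest_config(config)))
    prev <- NULL
  manifest <- list(tool = "msekda",
                   version = as.character(utils::packageVersion("msekda")),
                   seed = config$seed, stages = list())
  failed_marker <- fp("FAILED")
  if (file.exists(failed_marker)) unlink(failed_marker)

  record <- function(stage, files) {
    manifest$stages[[stage]] <<- list(outputs = as.list(
      stats::setNames(unname(tools::md5sum(files)), basename(files))))
  }
  dirty <- FALSE
  run_stage <- function(stage, files, fun) {
    if (!dirty && stage_done(prev, stage, files)) {
      manifest$stages[[stage]] <<- prev$stages[[stage]]
      return(invisible(FALSE))
    }
    dirty <<- TRUE
    ok <- tryCatch({ fun(); TRUE }, error = function(e) {
      writeLines(paste("failed stage:", stage, "-", conditionMessage(e)),
                 failed_marker)
      msekda_stop(sprintf("pipeline stage '%s' failed: %s", stage,
                          conditionMessage(e)), "msekda_stage_error")
    })
    record(stage, files)
    invisible(TRUE)
  }

  annotation <- read_annotation(config$annotation)
  markers <- read_marker_positions(config$markers)
  sets <- read_gmt(config$gene_sets)

  # --- mapping -------------------------------------------------------
  map_file <- fp("marker_gene_map.tsv")
  run_stage("map", map_file, function() {
    map <- map_by_distance(annotation, markers,
                           window_bp = config$window_bp)
    write_map(map, map_file)
  })
  map <- read_map(map_file)

  # --- LD pruning + per-study MSEA -----------------------------------
  studies <- c(list(gwas = config$gwas), as.list(config$ewas))
  kinds <- c("gwas", rep("ewas", length(config$ewas)))
  ld <- if (nzchar(config$ld)) read_ld(config$ld) else NULL
  msea_files <- fp(sprintf("msea_%s.tsv", names(studies)))
  pruned <- list()
  for (i in seq_along(studies)) {
    st <- names(studies)[i]
    assoc <- read_association(studies[[i]])
    if (!is.null(ld)) assoc <- ld_prune(assoc, ld, config$ld_r2)
    pruned[[st]] <- assoc
    run_stage(paste0("msea_", st), msea_files[i], local({
      stf <- st; fi <- msea_files[i]; assoc_i <- assoc
      function() {
        res <- msea(sets, map, assoc_i, params = config$msea,
                    seed = config$seed + i, study_id = stf)
        data.table::fwrite(res, fi, sep = "\t")
      }
    }))
  }
  msea_res <- lapply(stats::setNames(msea_files, names(studies)),
                     function(f) data.table::fread(f, data.table = FALSE))

  # --- EWAS meta + selection + intersection --------------------------
  sel_file <- fp("significant_sets.tsv")
  run_stage("select", sel_file, function() {
    ewas_res <- msea_res[kinds == "ewas"]
    ewas_all <- if (length(ewas_res) >= 2L)
      rbind(do.call(rbind, ewas_res),
            meta_msea(ewas_res)[, names(ewas_res[[1]])])
    else do.call(rbind, ewas_res)
    gwas_sig <- select_significant(msea_res$gwas,
                                   fdr_threshold = config$fdr_threshold,
                                   min_studies = config$gwas_min_studies)
    ewas_sig <- select_significant(ewas_all,
                                   fdr_threshold = config$fdr_threshold,
                                   min_studies = config$ewas_min_studies)
    parts <- intersect_significant(gwas_sig, ewas_sig)
    tab <- data.frame(
      SET_ID = c(parts$common, parts$gwas_only, parts$ewas_only),
      EVIDENCE = rep(c("common", "gwas_only", "ewas_only"),
                     lengths(parts)))
    data.table::fwrite(tab, sel_file, sep = "\t")
  })
  sel <- data.table::fread(sel_file, data.table = FALSE)
  common_ids <- sel$SET_ID[sel$EVIDENCE == "common"]

  # --- superset merging ----------------------------------------------
  ss_gmt <- fp("supersets.gmt")
  ss_members <- fp("superset_members.tsv")
  universe_size <- nrow(annotation)
  run_stage("merge", c(ss_gmt, ss_members), function() {
    if (length(common_ids) == 0L)
      msekda_stop("no common significant sets to merge",
                  "msekda_value_error")
    ss <- merge_gene_sets(sets[common_ids], universe_size,
                          r_cutoff = config$merge_r,
                          fdr_cutoff = config$merge_fdr,
                          max_size = config$merge_max_size)
    write_gmt(ss$genes, ss_gmt)
    data.table::fwrite(
      data.frame(SUPERSET_ID = rep(names(ss$members),
                                   lengths(ss$members)),
                 MEMBER_SET_ID = unlist(ss$members, use.names = FALSE)),
      ss_members, sep = "\t")
  })
  supersets <- read_gmt(ss_gmt)

  # --- superset revalidation -----------------------------------------
  reval_file <- fp("superset_revalidation.tsv")
  run_stage("revalidate", reval_file, function() {
    study_inputs <- lapply(pruned, function(a) list(map = map, assoc = a))
    res <- revalidate_supersets(supersets, study_inputs,
                                params = config$msea, seed = config$seed,
                                exclude_genes = config$exclude_genes)
    data.table::fwrite(res, reval_file, sep = "\t")
  })

  # --- wKDA -----------------------------------------------------------
  kd_file <- fp("key_drivers.tsv")
  run_stage("wkda", kd_file, function() {
    res <- list()
    for (tis in names(config$network)) {
      net <- read_network(config$network[[tis]])
      for (sid in names(supersets)) {
        if (!length(intersect(supersets[[sid]],
                              unique(c(net$tail, net$head))))) next
        res[[paste(tis, sid)]] <- wkda(
          net, supersets[[sid]], superset_id = sid, network_id = tis,
          n_permutations = config$kda_permutations,
          min_neighborhood = config$kda_min_neighborhood,
          seed = config$seed)
      }
    }
    data.table::fwrite(do.call(rbind, res), kd_file, sep = "\t")
  })
  kd <- data.table::fread(kd_file, data.table = FALSE)

  # --- subnetwork export ---------------------------------------------
  subnet_gmt <- fp("kd_subnetworks.gmt")
  run_stage("subnetworks", subnet_gmt, function() {
    sig <- kd[kd$fdr < config$fdr_threshold, , drop = FALSE]
    kds <- unique(sig$gene_id)
    nets <- lapply(config$network, read_network)
    subnets <- list()
    for (g in kds) {
      tis <- sig$network_id[sig$gene_id == g][1L]
      sid <- sig$superset_id[sig$gene_id == g][1L]
      sn <- extract_subnetwork(nets[[tis]], g, supersets[[sid]])
      subnets[[g]] <- unique(c(g, sn$nodes$gene_id))
    }
    if (length(subnets) == 0L)
      msekda_stop("no FDR-significant key drivers", "msekda_value_error")
    write_gmt(subnets, subnet_gmt)
  })

  # --- GSEA validation ------------------------------------------------
  if (nzchar(config$expression)) {
    gsea_file <- fp("gsea_validation.tsv")
    run_stage("gsea", gsea_file, function() {
      ex <- read_expression(config$expression, config$sample_labels)
      subnets <- read_gmt(subnet_gmt)
      subnets <- lapply(subnets, intersect, rownames(ex$expr))
      subnets <- subnets[lengths(subnets) >= 2L]
      res <- gsea_significance(ex$expr, ex$labels, subnets,
                               n_permutations = config$gsea_permutations,
                               seed = config$seed)
      data.table::fwrite(res, gsea_file, sep = "\t")
    })
  }

  manifest$config_hash <- digest_config(config)
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

digest_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- unclass(config)
  cfg$msea <- unclass(cfg$msea)
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}
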