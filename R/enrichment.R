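#' Parameters for marker set enrichment analysis
#'
#' @param quantile_grid Strictly increasing probabilities in (0, 1) at
#'   which the background p-value distribution is cut.  The default grid
#'   spans the tail from the median down to 5e-4.
#' @param n_permutations Number of random same-size gene sets drawn to form
#'   the empirical null (>= 100).
#' @param stabilizer_kappa Non-negative variance stabilizer added under the
#'   square root of each grid term.
#' @param min_genes,max_genes Mapped-gene size bounds; sets outside the
#'   bounds are skipped and reported.
#' @param fdr_threshold Benjamini-Hochberg significance threshold.
#' @return A list of class `"msea_params"`.
#' @export
msea_params <- function(quantile_grid = c(0.0005, 0.001, 0.0025, 0.005,
                                          0.01, 0.025, 0.05, 0.1, 0.25, 0.5),
                        n_permutations = 1999L,
                        stabilizer_kappa = 1,
                        min_genes = 10L,
                        max_genes = 500L,
                        fdr_threshold = 0.05) {
  grid <- sort(as.numeric(quantile_grid))
  if (any(grid <= 0 | grid >= 1) || anyDuplicated(grid))
    msekda_stop("quantile_grid must be strictly increasing within (0, 1)",
                "msekda_config_error")
  if (n_permutations < 100L)
    msekda_stop("n_permutations must be at least 100",
                "msekda_config_error")
  if (stabilizer_kappa < 0)
    msekda_stop("stabilizer_kappa must be non-negative",
                "msekda_config_error")
  structure(list(quantile_grid = grid,
                 n_permutations = as.integer(n_permutations),
                 stabilizer_kappa = stabilizer_kappa,
                 min_genes = as.integer(min_genes),
                 max_genes = as.integer(max_genes),
                 fdr_threshold = fdr_threshold),
            class = "msea_params")
}

#' Chi-squared-like marker set enrichment statistic
#'
#' For each grid probability `q_j`, let `c_j` be the `q_j`-quantile of the
#' background p-values, `O_j` the number of set p-values at or below `c_j`,
#' and `E_j = n_set * q_j` the expected count under no enrichment.  The
#' statistic is
#' \deqn{S = \sum_j (O_j - E_j) / \sqrt{E_j + \kappa}}
#' where the stabilizer \eqn{\kappa} damps the contribution of extreme-tail
#' grid points.  Larger `S` means the set's markers are coordinately more
#' associated than background.
#'
#' @param set_pvalues Non-empty numeric vector of the set's marker
#'   p-values.
#' @param background_pvalues Non-empty numeric vector of background marker
#'   p-values (typically all mapped markers in the study).
#' @param params An [msea_params()] object.
#' @return The statistic, a finite scalar.
#' @export
enrichment_statistic <- function(set_pvalues, background_pvalues,
                                 params = msea_params()) {
  if (length(set_pvalues) == 0L || length(background_pvalues) == 0L)
    msekda_stop("p-value vectors must be non-empty", "msekda_value_error")
  cuts <- stats::quantile(background_pvalues, probs = params$quantile_grid,
                          names = FALSE)
  O <- vapply(cuts, function(cj) sum(set_pvalues <= cj), 0)
  E <- length(set_pvalues) * params$quantile_grid
  sum((O - E) / sqrt(E + params$stabilizer_kappa))
}

# Precompute, per marker, how many (ascending) cutoffs its p-value is <=.
# O_j for any marker subset is then a reverse cumulative tabulation of
# these levels: O_j = #{lev >= J - j + 1}.
marker_levels <- function(pvalues, cuts) {
  length(cuts) - findInterval(pvalues, cuts, left.open = TRUE)
}

stat_from_levels <- function(lev, n_set, E_over, denom) {
  J <- length(denom)
  cnt <- tabulate(lev, nbins = J)
  O <- rev(cumsum(rev(cnt)))
  sum((O - n_set * E_over) / denom)
}

#' Marker set enrichment analysis (MSEA)
#'
#' For each gene set, member genes are mapped to markers via `map`, the
#' disease-association p-values of those markers are extracted from
#' `assoc` (a marker mapped to several member genes is counted once per
#' set), and the [enrichment_statistic()] is computed against the
#' background of all mapped markers.  Significance comes from comparing
#' each set with random gene sets of matching mapped-gene size drawn
#' uniformly from the mapped-gene universe:
#' `p = (1 + #\{S* >= S_obs\}) / (n_permutations + 1)`.  Because this null
#' depends only on the mapped-gene count, same-size sets share one cache of
#' permutation draws.  Benjamini-Hochberg FDR is computed across all
#' retained sets within the study.
#'
#' The association table should already be LD-pruned (see [ld_prune()]);
#' this is recorded in the result's `"provenance"` attribute but not
#' enforced.
#'
#' @param collection Named list of gene sets (character vectors).
#' @param map Marker-gene map data.frame.
#' @param assoc Association data.frame (`marker`, `pvalue`).
#' @param params An [msea_params()] object.
#' @param seed Integer seed for the permutation draws.
#' @param study_id Study label recorded in the results.
#' @return A data.frame with columns `set_id`, `statistic`, `p_empirical`,
#'   `fdr`, `n_genes_mapped`, `n_markers`, `study_id`, sorted by
#'   `p_empirical`.  Sets skipped (size bounds, zero mapped markers) are
#'   reported in the `"skipped"` attribute (data.frame `set_id`, `reason`).
#' @export
msea <- function(collection, map, assoc, params = msea_params(), seed = 1L,
                 study_id = "study") {
  stopifnot(is.list(collection), !is.null(names(collection)))
  assoc <- validate_association(assoc)
  map <- map[map$marker %in% assoc$marker, , drop = FALSE]
  if (nrow(map) == 0L)
    msekda_stop("no overlap between marker-gene map and association table",
                "msekda_consistency_error")

  # per-gene marker index lists over the mapped universe
  midx <- match(map$marker, assoc$marker)
  gene_markers <- split(midx, map$gene)
  gene_markers <- lapply(gene_markers, unique)
  genes <- names(gene_markers)
  bg_idx <- sort(unique(unlist(gene_markers, use.names = FALSE)))
  bg_p <- assoc$pvalue[bg_idx]

  cuts <- stats::quantile(bg_p, probs = params$quantile_grid, names = FALSE)
  lev <- marker_levels(assoc$pvalue, cuts)   # indexed like assoc
  J <- length(cuts)
  E_over <- params$quantile_grid
  denom <- NULL  # per-set: sqrt(n_set * q + kappa)

  # injective fast path: if no marker maps to >1 gene, unique() per random
  # set is unnecessary and per-gene level tabulations can be pre-summed
  injective <- !anyDuplicated(unlist(gene_markers, use.names = FALSE))
  if (injective) {
    lev_counts <- matrix(vapply(gene_markers, function(ix)
      tabulate(lev[ix], nbins = J), integer(J)), nrow = J)  # J x n_genes
    gene_nm <- lengths(gene_markers)
  }

  skip <- list()
  rows <- list()
  null_cache <- new.env(parent = emptyenv())
  withr::with_seed(as.integer(seed), {
    for (sid in names(collection)) {
      gg <- intersect(collection[[sid]], genes)
      k <- length(gg)
      if (k < params$min_genes || k > params$max_genes) {
        skip[[sid]] <- sprintf("mapped gene count %d outside [%d, %d]", k,
                               params$min_genes, params$max_genes)
        next
      }
      set_idx <- unique(unlist(gene_markers[gg], use.names = FALSE))
      if (length(set_idx) == 0L) {
        skip[[sid]] <- "zero mapped markers"
        next
      }
      n_set <- length(set_idx)
      denom_set <- sqrt(n_set * E_over + params$stabilizer_kappa)
      s_obs <- stat_from_levels(lev[set_idx], n_set, E_over, denom_set)

      ck <- as.character(k)
      if (is.null(null_cache[[ck]])) {
        null_cache[[ck]] <- if (injective) {
          perm_idx <- replicate(params$n_permutations,
                                sample.int(length(genes), k))
          cnts <- lev_counts[, as.vector(perm_idx), drop = FALSE]
          dim(cnts) <- c(J, k, params$n_permutations)
          csum <- colSums(aperm(cnts, c(2, 1, 3)))        # J x nperm
          nm <- colSums(matrix(gene_nm[as.vector(perm_idx)], nrow = k))
          csum <- matrix(csum, nrow = J)
          O <- matrix(apply(csum, 2L, function(x) rev(cumsum(rev(x)))),
                      nrow = J)
          colSums((O - outer(E_over, nm)) /
                    sqrt(outer(E_over, nm) + params$stabilizer_kappa))
        } else {
          vapply(seq_len(params$n_permutations), function(i) {
            ix <- unique(unlist(
              gene_markers[sample.int(length(genes), k)], use.names = FALSE))
            nm <- length(ix)
            stat_from_levels(lev[ix], nm, E_over,
                             sqrt(nm * E_over + params$stabilizer_kappa))
          }, 0)
        }
      }
      p_emp <- (1 + sum(null_cache[[ck]] >= s_obs)) /
        (params$n_permutations + 1)
      rows[[sid]] <- data.frame(set_id = sid, statistic = s_obs,
                                p_empirical = p_emp,
                                n_genes_mapped = k, n_markers = n_set)
    }
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set_id = character(), statistic = numeric(),
               p_empirical = numeric(), n_genes_mapped = integer(),
               n_markers = integer())
  out$fdr <- bh_fdr(out$p_empirical)
  out$study_id <- study_id
  out <- out[order(out$p_empirical, out$set_id),
             c("set_id", "statistic", "p_empirical", "fdr",
               "n_genes_mapped", "n_markers", "study_id")]
  rownames(out) <- NULL
  attr(out, "skipped") <- data.frame(set_id = names(skip),
                                     reason = unlist(skip, use.names = FALSE))
  attr(out, "provenance") <- list(seed = as.integer(seed),
                                  n_permutations = params$n_permutations,
                                  ld_pruned = "caller responsibility")
  out
}

#' Meta-analysis of MSEA results across studies (meta-MSEA)
#'
#' Sets tested in at least two studies are combined with the unweighted
#' Stouffer rule: `z_i = qnorm(1 - p_i)`, `z = sum(z_i) / sqrt(k)`,
#' `p = 1 - pnorm(z)`; Benjamini-Hochberg FDR is recomputed over the
#' combined results and `study_id` is set to `"meta"`.  Sets present in a
#' single study are passed through unchanged with `meta_combined = FALSE`.
#' Study p-values are clamped to `[1e-12, 1 - 1e-12]` so degenerate
#' empirical p-values of exactly 1 contribute a finite z.
#'
#' @param per_study List of per-study MSEA result data.frames (each with a
#'   distinct `study_id`).
#' @return A data.frame in the MSEA result layout plus `n_studies` and
#'   `meta_combined`.
#' @export
meta_msea <- function(per_study) {
  stopifnot(length(per_study) >= 2L)
  all <- do.call(rbind, lapply(per_study, function(x)
    x[, c("set_id", "statistic", "p_empirical", "n_genes_mapped",
          "n_markers", "study_id")]))
  counts <- table(all$set_id)
  shared <- names(counts)[counts >= 2L]
  if (length(shared) == 0L)
    msekda_stop("no set is tested in two or more studies",
                "msekda_consistency_error")
  meta_rows <- do.call(rbind, lapply(shared, function(sid) {
    sub <- all[all$set_id == sid, , drop = FALSE]
    p <- pmin(pmax(sub$p_empirical, 1e-12), 1 - 1e-12)
    z <- sum(qnorm(1 - p)) / sqrt(length(p))
    data.frame(set_id = sid, statistic = z,
               p_empirical = pnorm(z, lower.tail = FALSE),
               n_genes_mapped = max(sub$n_genes_mapped),
               n_markers = max(sub$n_markers),
               study_id = "meta", n_studies = length(p),
               meta_combined = TRUE)
  }))
  meta_rows$fdr <- bh_fdr(meta_rows$p_empirical)
  single <- all[!(all$set_id %in% shared), , drop = FALSE]
  if (nrow(single)) {
    single$n_studies <- 1L
    single$meta_combined <- FALSE
    single$fdr <- NA_real_
  }
  out <- rbind(meta_rows[, c("set_id", "statistic", "p_empirical", "fdr",
                             "n_genes_mapped", "n_markers", "study_id",
                             "n_studies", "meta_combined")],
               if (nrow(single))
                 single[, c("set_id", "statistic", "p_empirical", "fdr",
                            "n_genes_mapped", "n_markers", "study_id",
                            "n_studies", "meta_combined")])
  out <- out[order(!out$meta_combined, out$p_empirical, out$set_id), ]
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg q-values
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")`, kept as a named
#' entry point so every stage corrects multiplicity the same way.
#'
#' @param pvalues Numeric vector of p-values.
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvalues) stats::p.adjust(pvalues, method = "BH")

#' Select significant gene sets across studies
#'
#' A set is selected when it passes the FDR threshold in at least
#' `min_studies` individual studies, or in the meta-analysis row
#' (`study_id == "meta"`).
#'
#' @param results Data.frame combining per-study and (optionally) meta
#'   MSEA rows.
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param min_studies Minimum number of individual studies (default 2; use
#'   1 for a single-study arm).
#' @return Character vector of selected `set_id`s.
#' @export
select_significant <- function(results, fdr_threshold = 0.05,
                               min_studies = 2L) {
  ind <- results[results$study_id != "meta" & !is.na(results$fdr) &
                   results$fdr < fdr_threshold, , drop = FALSE]
  n_sig <- table(ind$set_id)
  by_studies <- names(n_sig)[n_sig >= min_studies]
  meta <- results[results$study_id == "meta" & !is.na(results$fdr) &
                    results$fdr < fdr_threshold, , drop = FALSE]
  sort(union(by_studies, meta$set_id))
}
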