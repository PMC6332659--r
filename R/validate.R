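group_summaries <- function(expr, labels) {
  labels <- factor(labels)
  if (nlevels(labels) != 2L)
    msekda_stop("expression labels must have exactly two groups",
                "msekda_value_error")
  g1 <- labels == levels(labels)[1L]
  g2 <- labels == levels(labels)[2L]
  n1 <- sum(g1); n2 <- sum(g2)
  m1 <- rowMeans(expr[, g1, drop = FALSE])
  m2 <- rowMeans(expr[, g2, drop = FALSE])
  v1 <- rowSums((expr[, g1, drop = FALSE] - m1)^2) / (n1 - 1L)
  v2 <- rowSums((expr[, g2, drop = FALSE] - m2)^2) / (n2 - 1L)
  list(m1 = m1, m2 = m2, v1 = v1, v2 = v2, n1 = n1, n2 = n2,
       levels = levels(labels))
}

#' Differential expression by Welch two-sample t-test
#'
#' Per-gene Welch t statistic (second group level minus first), two-sided
#' p-value with Welch-Satterthwaite degrees of freedom, and
#' Benjamini-Hochberg FDR.  Genes with zero variance in both groups are
#' untestable and are excluded, with their ids recorded in the
#' `"untestable"` attribute.
#'
#' @param expr Numeric matrix, genes x samples.
#' @param labels Two-level factor of group labels (first level is the
#'   reference, e.g. control).
#' @return A data.frame (`gene`, `statistic`, `p`, `fdr`) sorted by p.
#' @export
de_genes <- function(expr, labels) {
  gs <- group_summaries(expr, labels)
  if (gs$n1 < 2L || gs$n2 < 2L)
    msekda_stop("each group needs at least two samples",
                "msekda_value_error")
  se2 <- gs$v1 / gs$n1 + gs$v2 / gs$n2
  testable <- se2 > 0
  t_stat <- (gs$m2[testable] - gs$m1[testable]) / sqrt(se2[testable])
  df <- se2[testable]^2 /
    ((gs$v1[testable] / gs$n1)^2 / (gs$n1 - 1L) +
       (gs$v2[testable] / gs$n2)^2 / (gs$n2 - 1L))
  p <- 2 * pt(-abs(t_stat), df)
  out <- data.frame(gene = rownames(expr)[testable], statistic = t_stat,
                    p = p, fdr = bh_fdr(p))
  out <- out[order(out$p, out$gene), ]
  rownames(out) <- NULL
  attr(out, "untestable") <- rownames(expr)[!testable]
  out
}

#' Rank genes by signal-to-noise ratio
#'
#' Score = (mean in second group - mean in first group) / (sd1 + sd2),
#' the classic two-class GSEA ranking metric; genes are returned in
#' descending score order with ties broken by gene id.  Zero-variance
#' genes (sd1 + sd2 = 0) are excluded and counted in the `"n_excluded"`
#' attribute.
#'
#' @inheritParams de_genes
#' @return A named numeric vector of scores, ordered for [gsea_es()].
#' @export
rank_genes <- function(expr, labels) {
  gs <- group_summaries(expr, labels)
  denom <- sqrt(gs$v1) + sqrt(gs$v2)
  ok <- denom > 0
  score <- (gs$m2[ok] - gs$m1[ok]) / denom[ok]
  names(score) <- rownames(expr)[ok]
  score <- score[order(-score, names(score))]
  attr(score, "n_excluded") <- sum(!ok)
  score
}

#' Weighted Kolmogorov-Smirnov running-sum enrichment score
#'
#' Walks down the ranked list; genes in the set increment the running sum
#' by `|score|^weight_exponent` normalized by the set's total, genes
#' outside decrement it by `1 / (N - n_set)`.  The enrichment score (ES)
#' is the maximum-magnitude deviation of the running sum, signed: positive
#' ES means the set concentrates at the top of the ranking
#' (up-regulated), negative at the bottom.
#'
#' @param ranked Named numeric vector of ranking scores, ordered
#'   descending (see [rank_genes()]).
#' @param gene_set Character vector of gene ids; must intersect the
#'   ranked list.
#' @param weight_exponent Weighting of the ranking scores (0 = classic
#'   unweighted KS; default 1).
#' @return A list with `es` (scalar in \[-1, 1\]) and `running` (the full
#'   running-sum profile).
#' @export
gsea_es <- function(ranked, gene_set, weight_exponent = 1) {
  hit <- names(ranked) %in% gene_set
  if (!any(hit))
    msekda_stop("gene set shares no genes with the ranked list",
                "msekda_value_error")
  if (all(hit))
    msekda_stop("gene set covers the entire ranked list",
                "msekda_value_error")
  w <- abs(ranked)^weight_exponent
  inc <- numeric(length(ranked))
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / sum(!hit)
  running <- cumsum(inc)
  # signed maximum-magnitude deviation; an exact magnitude tie between the
  # positive and negative extremes resolves to the positive side
  mx <- max(running)
  mn <- min(running)
  es <- if (mx + mn >= -1e-12) mx else mn
  list(es = es, running = running)
}

#' GSEA significance by phenotype permutation
#'
#' Observed enrichment scores come from the signal-to-noise ranking of the
#' true labels; the null re-ranks under shuffled group labels.  For each
#' set, the empirical p-value is one-sided on the side of the observed ES
#' sign (with the add-one estimator), the normalized enrichment score
#' (NES) divides the ES by the mean magnitude of same-sign permuted ES,
#' and Benjamini-Hochberg FDR is computed across sets.
#'
#' @inheritParams de_genes
#' @param gene_sets Named list of gene id vectors.
#' @param n_permutations Label permutations (>= 100).
#' @param weight_exponent Passed to [gsea_es()].
#' @param seed Integer seed.
#' @return A data.frame (`set_id`, `es`, `nes`, `p_empirical`, `fdr`,
#'   `direction`) sorted by p.
#' @export
gsea_significance <- function(expr, labels, gene_sets,
                              n_permutations = 999L, weight_exponent = 1,
                              seed = 1L) {
  if (n_permutations < 100L)
    msekda_stop("n_permutations must be at least 100",
                "msekda_config_error")
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  ranked <- rank_genes(expr, labels)
  es_obs <- vapply(gene_sets, function(s)
    gsea_es(ranked, s, weight_exponent)$es, 0)
  withr::with_seed(as.integer(seed), {
    es_null <- matrix(NA_real_, nrow = length(gene_sets),
                      ncol = n_permutations,
                      dimnames = list(names(gene_sets), NULL))
    for (b in seq_len(n_permutations)) {
      perm <- sample(labels)
      rb <- rank_genes(expr, perm)
      es_null[, b] <- vapply(gene_sets, function(s)
        gsea_es(rb, s, weight_exponent)$es, 0)
    }
  })
  # one-sided within the same-sign permutation mass, as in the standard
  # phenotype-permutation GSEA; the add-one estimator avoids zero p
  p <- vapply(seq_along(gene_sets), function(i) {
    if (es_obs[i] >= 0)
      (1 + sum(es_null[i, ] >= es_obs[i])) / (1 + sum(es_null[i, ] >= 0))
    else
      (1 + sum(es_null[i, ] <= es_obs[i])) / (1 + sum(es_null[i, ] < 0))
  }, 0)
  nes <- vapply(seq_along(gene_sets), function(i) {
    same <- if (es_obs[i] >= 0) es_null[i, es_null[i, ] >= 0]
            else es_null[i, es_null[i, ] < 0]
    if (length(same) == 0L) return(NA_real_)
    es_obs[i] / mean(abs(same))
  }, 0)
  out <- data.frame(set_id = names(gene_sets), es = unname(es_obs),
                    nes = nes, p_empirical = p, fdr = bh_fdr(p),
                    direction = ifelse(es_obs >= 0, "up", "down"))
  out <- out[order(out$p_empirical, out$set_id), ]
  rownames(out) <- NULL
  attr(out, "fdr_method") <- "BH over set-level permutation p-values"
  out
}
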