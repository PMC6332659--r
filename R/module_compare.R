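#' One-sided Fisher overlap test between two gene sets
#'
#' Enrichment (upper-tail hypergeometric) p-value for the observed overlap
#' of two gene sets within a shared universe, plus the sample odds ratio of
#' the 2x2 table.
#'
#' @param a,b Character vectors of gene ids (duplicates ignored).
#' @param universe_size Size of the shared gene universe (>= the union of
#'   both sets).
#' @return A list with `odds_ratio` and `p_value`.
#' @export
fisher_overlap <- function(a, b, universe_size) {
  a <- unique(a); b <- unique(b)
  if (universe_size < 1L)
    msekda_stop("universe_size must be positive", "msekda_value_error")
  if (length(a) > universe_size || length(b) > universe_size)
    msekda_stop("set larger than the declared universe",
                "msekda_value_error")
  k <- length(intersect(a, b))
  p <- phyper(k - 1L, length(a), universe_size - length(a), length(b),
              lower.tail = FALSE)
  d <- universe_size - length(a) - length(b) + k
  or <- (k * d) / ((length(a) - k) * (length(b) - k))
  list(odds_ratio = or, p_value = p)
}

# Vectorized upper-tail hypergeometric p for all pairs of two set lists.
# Returns a list(p = matrix, k = intersection-count matrix).
overlap_p_matrix <- function(sets_a, sets_b, universe_size) {
  genes <- unique(c(unlist(sets_a, use.names = FALSE),
                    unlist(sets_b, use.names = FALSE)))
  ma <- vapply(sets_a, function(s) genes %in% s, logical(length(genes)))
  mb <- vapply(sets_b, function(s) genes %in% s, logical(length(genes)))
  ma <- matrix(ma, nrow = length(genes))
  mb <- matrix(mb, nrow = length(genes))
  k <- crossprod(ma, mb)                      # |a_i n b_j|
  na <- colSums(ma); nb <- colSums(mb)
  p <- matrix(phyper(as.vector(k) - 1L, rep(na, times = length(nb)),
                     universe_size - rep(na, times = length(nb)),
                     rep(nb, each = length(na)), lower.tail = FALSE),
              nrow = length(na),
              dimnames = list(names(sets_a), names(sets_b)))
  list(p = p, k = k)
}

# deterministic best hit: smallest p, ties by larger overlap, then
# lexicographic partner id
best_hit_idx <- function(p_row, k_row, partner_ids) {
  order(p_row, -k_row, partner_ids)[1L]
}

#' Module preservation by reciprocal best hits
#'
#' Scores every cross-network module pair with the one-sided Fisher
#' overlap test, applies Benjamini-Hochberg correction over all pairs, and
#' calls a module *preserved* when its best hit in the other network
#' (smallest p, ties broken by larger overlap then lexicographic id) has
#' it as its own best hit and that pair's FDR is below `fdr_threshold`.
#' All other modules are *differential*.
#'
#' @param net_a,net_b Named lists of gene id vectors, one entry per module
#'   (modules may overlap).
#' @param universe_size Shared gene universe size.
#' @param fdr_threshold Pair-level FDR cutoff (default 0.05).
#' @return A data.frame with `network_id`, `module_id`, `status`
#'   (`"preserved"`/`"differential"`), `best_hit`, `fisher_p`, `fdr`.
#' @export
rbh_preservation <- function(net_a, net_b, universe_size,
                             fdr_threshold = 0.05) {
  stopifnot(length(net_a) >= 1L, length(net_b) >= 1L,
            !is.null(names(net_a)), !is.null(names(net_b)))
  om <- overlap_p_matrix(net_a, net_b, universe_size)
  q <- matrix(bh_fdr(as.vector(om$p)), nrow = nrow(om$p),
              dimnames = dimnames(om$p))
  ids_a <- names(net_a); ids_b <- names(net_b)
  best_a <- vapply(seq_along(ids_a), function(i)
    best_hit_idx(om$p[i, ], om$k[i, ], ids_b), 0L)
  best_b <- vapply(seq_along(ids_b), function(j)
    best_hit_idx(om$p[, j], om$k[, j], ids_a), 0L)
  row_a <- lapply(seq_along(ids_a), function(i) {
    j <- best_a[i]
    reciprocal <- best_b[j] == i
    preserved <- reciprocal && q[i, j] < fdr_threshold
    data.frame(network_id = "A", module_id = ids_a[i],
               status = if (preserved) "preserved" else "differential",
               best_hit = ids_b[j], fisher_p = om$p[i, j], fdr = q[i, j])
  })
  row_b <- lapply(seq_along(ids_b), function(j) {
    i <- best_b[j]
    reciprocal <- best_a[i] == j
    preserved <- reciprocal && q[i, j] < fdr_threshold
    data.frame(network_id = "B", module_id = ids_b[j],
               status = if (preserved) "preserved" else "differential",
               best_hit = ids_a[i], fisher_p = om$p[i, j], fdr = q[i, j])
  })
  out <- do.call(rbind, c(row_a, row_b))
  rownames(out) <- NULL
  out
}

#' Annotate modules with known pathways
#'
#' Scores every (module, pathway) pair with the one-sided Fisher overlap
#' test and corrects per module across pathways (Benjamini-Hochberg).
#'
#' @param modules Named list of module gene vectors.
#' @param pathways Named list of pathway gene vectors.
#' @param universe_size Shared gene universe size.
#' @param fdr_threshold Significance cutoff for the `significant` flag.
#' @return A data.frame (`module_id`, `pathway_id`, `n_overlap`,
#'   `fisher_p`, `fdr`, `significant`) sorted by module then p-value.
#' @export
annotate_modules <- function(modules, pathways, universe_size,
                             fdr_threshold = 0.05) {
  om <- overlap_p_matrix(modules, pathways, universe_size)
  rows <- lapply(seq_along(modules), function(i) {
    q <- bh_fdr(om$p[i, ])
    ord <- order(om$p[i, ], names(pathways))
    data.frame(module_id = names(modules)[i],
               pathway_id = names(pathways)[ord],
               n_overlap = om$k[i, ord], fisher_p = om$p[i, ord],
               fdr = q[ord], significant = q[ord] < fdr_threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
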