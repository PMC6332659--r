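#' Geometric-mean overlap ratio between two gene sets
#'
#' `r = sqrt(r_AB * r_BA)` where `r_AB` is the proportion of genes in A
#' also in B and `r_BA` the converse; `r` lies in \[0, 1\], equals 1 for
#' identical sets and 0 for disjoint ones.
#'
#' @param a,b Non-empty character vectors of gene ids.
#' @return The overlap ratio, a scalar in \[0, 1\].
#' @export
overlap_ratio <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0L || length(b) == 0L)
    msekda_stop("overlap_ratio requires non-empty sets",
                "msekda_value_error")
  k <- length(intersect(a, b))
  sqrt((k / length(a)) * (k / length(b)))
}

#' Merge overlapping gene sets into independent supersets
#'
#' Builds a graph over the input sets with an edge whenever the
#' [overlap_ratio()] is at least `r_cutoff` *and* the pair's Fisher
#' overlap test passes FDR < `fdr_cutoff` (Benjamini-Hochberg over all
#' within-list pairs).  Supersets are the connected components; each
#' superset's genes are the union of its members.  A union larger than
#' `max_size` is trimmed to the core genes shared by at least two member
#' sets; if that core is empty or still oversized, genes are ranked by
#' membership multiplicity (ties lexicographic) and truncated at
#' `max_size`.  Singleton components pass through unchanged.
#'
#' @param sets Named list of gene id vectors.
#' @param universe_size Shared gene universe size for the Fisher tests.
#' @param r_cutoff Minimum overlap ratio for an edge (default 0.2).
#' @param fdr_cutoff Fisher FDR gate for an edge (default 0.05).
#' @param max_size Trimming threshold (default 500 genes).
#' @return A list of class `"superset_collection"`: `genes` (named list of
#'   gene vectors), `members` (named list of member set ids), `trimmed`
#'   (named logical).
#' @export
merge_gene_sets <- function(sets, universe_size, r_cutoff = 0.2,
                            fdr_cutoff = 0.05, max_size = 500L) {
  stopifnot(length(sets) >= 1L, !is.null(names(sets)))
  sets <- lapply(sets, unique)
  n <- length(sets)
  ids <- names(sets)
  if (n == 1L) {
    edges <- matrix(integer(), ncol = 2L)
  } else {
    om <- overlap_p_matrix(sets, sets, universe_size)
    pair <- which(upper.tri(om$p), arr.ind = TRUE)
    q <- bh_fdr(om$p[pair])
    r <- vapply(seq_len(nrow(pair)), function(e)
      overlap_ratio(sets[[pair[e, 1]]], sets[[pair[e, 2]]]), 0)
    keep <- r >= r_cutoff & q < fdr_cutoff
    edges <- pair[keep, , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(
    matrix(ids[edges], ncol = 2L), directed = FALSE)
  g <- g + igraph::vertices(setdiff(ids, igraph::V(g)$name))
  comp <- igraph::components(g)$membership[ids]
  out <- list(genes = list(), members = list(), trimmed = logical())
  for (cmp in unique(comp)) {
    members <- sort(ids[comp == cmp])
    union_genes <- sort(unique(unlist(sets[members], use.names = FALSE)))
    mult <- table(unlist(lapply(sets[members], unique), use.names = FALSE))
    trimmed <- FALSE
    genes <- union_genes
    if (length(members) > 1L && length(union_genes) > max_size) {
      core <- sort(names(mult)[mult >= 2L])
      genes <- if (length(core) > 0L && length(core) <= max_size) core
      else {
        nm <- names(mult)
        nm[order(-as.integer(mult), nm)][seq_len(max_size)]
      }
      genes <- sort(genes)
      trimmed <- TRUE
    }
    sid <- sprintf("SS_%s", members[1L])
    out$genes[[sid]] <- genes
    out$members[[sid]] <- members
    out$trimmed[[sid]] <- trimmed
  }
  ord <- order(names(out$genes))
  out <- list(genes = out$genes[ord], members = out$members[ord],
              trimmed = out$trimmed[ord])
  class(out) <- "superset_collection"
  out
}

#' @export
print.superset_collection <- function(x, ...) {
  cat(sprintf("superset_collection: %d supersets (%d trimmed)\n",
              length(x$genes), sum(x$trimmed)))
  invisible(x)
}

#' Flag supersets unique to one evidence stream
#'
#' A superset in `list_x` is *unique* when none of its Fisher overlap
#' tests against supersets from the other lists reaches FDR <
#' `fdr_cutoff`; the Benjamini-Hochberg family is all cross-list pairs.
#'
#' @param list_x Named list of superset gene vectors to flag.
#' @param other_lists A list of named lists of superset gene vectors (the
#'   other evidence streams).
#' @param universe_size Shared gene universe size.
#' @param fdr_cutoff FDR cutoff (default 0.05).
#' @return Named logical vector over `list_x`: `TRUE` = unique.
#' @export
superset_uniqueness <- function(list_x, other_lists, universe_size,
                                fdr_cutoff = 0.05) {
  others <- do.call(c, unname(other_lists))
  if (length(others) == 0L)
    return(stats::setNames(rep(TRUE, length(list_x)), names(list_x)))
  om <- overlap_p_matrix(list_x, others, universe_size)
  q <- matrix(bh_fdr(as.vector(om$p)), nrow = nrow(om$p))
  stats::setNames(apply(q >= fdr_cutoff, 1L, all), names(list_x))
}

#' Re-test supersets for enrichment in the underlying studies
#'
#' Treats each superset as a gene set and re-runs [msea()] on every study
#' (and [meta_msea()] across them when two or more studies are supplied),
#' optionally removing an exclusion gene list (e.g. HLA genes, whose tight
#' physical clustering can inflate enrichment) from superset membership
#' first.  Supersets emptied by the exclusion are skipped with a reason.
#'
#' @param supersets A [merge_gene_sets()] result or named list of gene
#'   vectors.
#' @param studies Named list; each element is a list with `map` and
#'   `assoc` for one study.
#' @param params An [msea_params()] object.
#' @param seed Integer seed.
#' @param exclude_genes Character vector of genes removed from every
#'   superset before testing (default none).
#' @return A data.frame of per-study rows plus `"meta"` rows when
#'   applicable, in the [meta_msea()] layout.
#' @export
revalidate_supersets <- function(supersets, studies, params = msea_params(),
                                 seed = 1L, exclude_genes = character()) {
  sets <- if (inherits(supersets, "superset_collection")) supersets$genes
          else supersets
  sets <- lapply(sets, function(g) setdiff(g, exclude_genes))
  empty <- lengths(sets) == 0L
  sets <- sets[!empty]
  if (length(sets) == 0L)
    msekda_stop("all supersets empty after exclusion", "msekda_value_error")
  per_study <- lapply(names(studies), function(st)
    msea(sets, studies[[st]]$map, studies[[st]]$assoc, params = params,
         seed = seed, study_id = st))
  out <- if (length(per_study) >= 2L) meta_msea(per_study)
         else cbind(per_study[[1]], n_studies = 1L, meta_combined = FALSE)
  full <- rbind(do.call(rbind, lapply(per_study, function(x)
    cbind(x, n_studies = 1L, meta_combined = FALSE))),
    out[out$study_id == "meta", , drop = FALSE])
  attr(full, "excluded_empty") <- names(empty)[empty]
  rownames(full) <- NULL
  full
}
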