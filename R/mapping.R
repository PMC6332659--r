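MAP_SCHEMES <- c("distance", "eqtl_skin", "eqtl_blood", "eqtl_all",
                 "functional", "combined", "cpg_distance")

new_map <- function(marker, gene, scheme, source_scheme = scheme) {
  out <- data.frame(marker = as.character(marker), gene = as.character(gene),
                    scheme = rep_len(as.character(scheme), length(marker)),
                    source_scheme = rep_len(as.character(source_scheme),
                                            length(marker)))
  out[!duplicated(out[, c("marker", "gene", "scheme")]), , drop = FALSE]
}

#' Map markers to genes by chromosomal distance
#'
#' A marker maps to a gene when its position falls in the gene interval
#' extended symmetrically by `window_bp` on both sides, i.e. in
#' `[start - window_bp, end + window_bp)` on the gene's chromosome
#' (0-based half-open coordinates; strand is ignored).  A marker may map
#' to several genes and a gene to several markers.
#'
#' @param annotation Gene annotation data.frame (`gene`, `chrom`, `start`,
#'   `end`).
#' @param markers Marker position data.frame (`marker`, `chrom`, `pos`).
#' @param window_bp Non-negative window in base pairs (default 50 kb, the
#'   standard distance-based SNP-gene window).
#' @param scheme Scheme label recorded in the output (`"distance"` for
#'   SNPs; [map_cpg()] uses `"cpg_distance"`).
#' @return A marker-gene map data.frame (`marker`, `gene`, `scheme`,
#'   `source_scheme`).  Markers on chromosomes absent from the annotation
#'   yield zero rows and a warning.
#' @export
map_by_distance <- function(annotation, markers, window_bp = 50000L,
                            scheme = "distance") {
  stopifnot(window_bp >= 0, scheme %in% MAP_SCHEMES)
  annotation <- validate_annotation(annotation)
  unknown <- setdiff(unique(markers$chrom), unique(annotation$chrom))
  if (length(unknown))
    warning("markers on chromosome(s) absent from annotation: ",
            paste(unknown, collapse = ", "))
  pieces <- lapply(intersect(unique(markers$chrom), unique(annotation$chrom)),
                   function(ch) {
    g <- annotation[annotation$chrom == ch, , drop = FALSE]
    m <- markers[markers$chrom == ch, , drop = FALSE]
    if (!nrow(g) || !nrow(m)) return(NULL)
    # 0-based half-open [start-w, end+w) -> 1-based closed [start-w+1, end+w]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(start = m$pos + 1L, width = 1L),
      IRanges::IRanges(start = g$start - window_bp + 1L,
                       end = g$end + window_bp))
    data.frame(marker = m$marker[S4Vectors::queryHits(hits)],
               gene = g$gene[S4Vectors::subjectHits(hits)])
  })
  hits <- do.call(rbind, pieces)
  if (is.null(hits)) hits <- data.frame(marker = character(),
                                        gene = character())
  new_map(hits$marker, hits$gene, scheme)
}

#' Map CpG sites to adjacent genes
#'
#' Distance mapping with the CpG convention: a 5 kb window on either side
#' of the gene body, scheme recorded as `"cpg_distance"`.
#'
#' @inheritParams map_by_distance
#' @param cpgs CpG position data.frame (`marker`, `chrom`, `pos`).
#' @export
map_cpg <- function(annotation, cpgs, window_bp = 5000L) {
  map_by_distance(annotation, cpgs, window_bp = window_bp,
                  scheme = "cpg_distance")
}

#' Build a marker-gene map from a precomputed evidence table
#'
#' Pass-through (with de-duplication) for externally supplied marker-gene
#' evidence such as skin/blood eQTL tables or ENCODE-based functional
#' assignments.
#'
#' @param eqtl_table Data.frame whose first two columns are marker id and
#'   gene id.
#' @param scheme_label One of `"eqtl_skin"`, `"eqtl_blood"`, `"eqtl_all"`,
#'   `"functional"`.
#' @return A marker-gene map data.frame.
#' @export
map_by_table <- function(eqtl_table, scheme_label) {
  stopifnot(scheme_label %in% MAP_SCHEMES)
  if (nrow(eqtl_table) == 0L) {
    warning("empty evidence table for scheme ", scheme_label)
    return(new_map(character(), character(), character()))
  }
  new_map(eqtl_table[[1]], eqtl_table[[2]], scheme_label)
}

#' Combine marker-gene maps across mapping schemes
#'
#' Set union over (marker, gene) pairs; the combined scheme is recorded as
#' `"combined"` while the contributing schemes are preserved in the
#' `source_scheme` provenance column (comma-joined when a pair arises from
#' several schemes).
#'
#' @param maps List of marker-gene map data.frames.
#' @return A marker-gene map data.frame with scheme `"combined"`.
#' @export
combine_maps <- function(maps) {
  stopifnot(length(maps) >= 1L)
  all <- do.call(rbind, maps)
  key <- paste(all$marker, all$gene, sep = "\r")
  src <- vapply(split(all$source_scheme, key), function(s)
    paste(sort(unique(s)), collapse = ","), "")
  first <- all[!duplicated(key), , drop = FALSE]
  out <- new_map(first$marker, first$gene, "combined",
                 source_scheme = src[paste(first$marker, first$gene,
                                           sep = "\r")])
  out <- out[order(out$marker, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prune markers in linkage disequilibrium
#'
#' Builds the graph whose edges are marker pairs with r2 strictly above
#' `r2_threshold`, and keeps exactly one representative per connected
#' component: the member with the smallest association p-value, ties broken
#' by lexicographic marker id.  Markers absent from the LD table are always
#' retained.  LD rows naming markers absent from the association table are
#' ignored with a warning.
#'
#' @param markers Association data.frame (`marker`, `pvalue`).
#' @param ld LD data.frame (`marker_a`, `marker_b`, `r2`).
#' @param r2_threshold Pairs with r2 strictly greater than this are pruned
#'   (default 0.7).
#' @return The pruned association data.frame (a subset of the input rows).
#' @export
ld_prune <- function(markers, ld, r2_threshold = 0.7) {
  stopifnot(r2_threshold >= 0, r2_threshold <= 1)
  markers <- validate_association(markers)
  ld <- validate_ld(ld)
  ld <- ld[ld$r2 > r2_threshold, , drop = FALSE]
  known <- ld$marker_a %in% markers$marker & ld$marker_b %in% markers$marker
  if (any(!known)) {
    warning(sum(!known), " LD pair(s) reference markers absent from the ",
            "association table; ignored")
    ld <- ld[known, , drop = FALSE]
  }
  if (nrow(ld) == 0L) return(markers)
  g <- igraph::graph_from_data_frame(
    ld[, c("marker_a", "marker_b")], directed = FALSE,
    vertices = unique(c(ld$marker_a, ld$marker_b)))
  comp <- igraph::components(g)$membership
  in_ld <- match(markers$marker, names(comp))
  keep <- rep(TRUE, nrow(markers))
  for (members in split(which(!is.na(in_ld)), comp[in_ld[!is.na(in_ld)]])) {
    sub <- markers[members, , drop = FALSE]
    best <- members[order(sub$pvalue, sub$marker)[1L]]
    keep[setdiff(members, best)] <- FALSE
  }
  out <- markers[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read and write marker-gene maps
#'
#' Tab-delimited with columns `MARKER`, `GENE`, `SCHEME`, `SOURCE_SCHEME`.
#'
#' @param path File path.
#' @export
read_map <- function(path) {
  x <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  names(x) <- tolower(names(x))
  new_map(x$marker, x$gene, x$scheme,
          source_scheme = x$source_scheme %||% x$scheme)
}

#' @param map Marker-gene map data.frame.
#' @rdname read_map
#' @export
write_map <- function(map, path) {
  out <- data.frame(MARKER = map$marker, GENE = map$gene,
                    SCHEME = map$scheme, SOURCE_SCHEME = map$source_scheme)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}
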