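#' Read and write GMT gene-set files
#'
#' GMT is the tab-delimited gene-set format: one set per line with the set
#' name, a free-text description, and then the member genes.
#'
#' @param path File path.
#' @return `read_gmt()` returns a named list of character vectors (one per
#'   set), with the description column kept in the `"descriptions"`
#'   attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1L)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(parts, `[`, "", 2L), names(sets))
  sets
}

#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to the set names).
#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read and write marker association tables
#'
#' Two-column tab-delimited tables (`MARKER`, `PVALUE`) carrying per-marker
#' disease-association p-values from one GWAS or EWAS study.
#'
#' @param path File path.
#' @return A data.frame with columns `marker`, `pvalue`.
#' @export
read_association <- function(path) {
  x <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  names(x)[1:2] <- c("marker", "pvalue")
  validate_association(x[, 1:2])
}

#' @param assoc Association data.frame (`marker`, `pvalue`).
#' @rdname read_association
#' @export
write_association <- function(assoc, path) {
  out <- data.frame(MARKER = assoc$marker, PVALUE = assoc$pvalue)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

validate_association <- function(assoc) {
  stopifnot(is.data.frame(assoc), all(c("marker", "pvalue") %in% names(assoc)))
  if (anyDuplicated(assoc$marker))
    msekda_stop("duplicate marker ids in association table",
                "msekda_consistency_error")
  if (any(assoc$pvalue <= 0 | assoc$pvalue > 1))
    msekda_stop("association p-values must lie in (0, 1]",
                "msekda_consistency_error")
  assoc
}

#' Read and write BED-like gene annotations
#'
#' Four tab-delimited columns (`CHROM`, `START`, `END`, `GENE`), 0-based
#' half-open coordinates as in BED.
#'
#' @param path File path.
#' @return A data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_annotation <- function(path) {
  x <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  names(x)[1:4] <- c("chrom", "start", "end", "gene")
  validate_annotation(x[, c("gene", "chrom", "start", "end")])
}

#' @param annotation Annotation data.frame.
#' @rdname read_annotation
#' @export
write_annotation <- function(annotation, path) {
  out <- data.frame(CHROM = annotation$chrom, START = annotation$start,
                    END = annotation$end, GENE = annotation$gene)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

validate_annotation <- function(annotation) {
  stopifnot(is.data.frame(annotation),
            all(c("gene", "chrom", "start", "end") %in% names(annotation)))
  if (anyDuplicated(annotation$gene))
    msekda_stop("duplicate gene ids in annotation", "msekda_consistency_error")
  if (nrow(annotation) &&
      (any(annotation$start < 0) || any(annotation$end <= annotation$start)))
    msekda_stop("annotation intervals must satisfy 0 <= start < end",
                "msekda_consistency_error")
  annotation
}

#' Read and write marker position tables
#'
#' Three tab-delimited columns (`MARKER`, `CHROM`, `POS`); positions are
#' 0-based, matching the annotation convention.
#'
#' @param path File path.
#' @return A data.frame with columns `marker`, `chrom`, `pos`.
#' @export
read_marker_positions <- function(path) {
  x <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  names(x)[1:3] <- c("marker", "chrom", "pos")
  x[, 1:3]
}

#' @param markers Marker position data.frame.
#' @rdname read_marker_positions
#' @export
write_marker_positions <- function(markers, path) {
  out <- data.frame(MARKER = markers$marker, CHROM = markers$chrom,
                    POS = markers$pos)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read and write pairwise LD tables
#'
#' Three tab-delimited columns (`MARKER_A`, `MARKER_B`, `R2`); pairs are
#' unordered and self-pairs are rejected.
#'
#' @param path File path.
#' @return A data.frame with columns `marker_a`, `marker_b`, `r2`.
#' @export
read_ld <- function(path) {
  x <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  names(x)[1:3] <- c("marker_a", "marker_b", "r2")
  validate_ld(x[, 1:3])
}

#' @param ld LD data.frame.
#' @rdname read_ld
#' @export
write_ld <- function(ld, path) {
  out <- data.frame(MARKER_A = ld$marker_a, MARKER_B = ld$marker_b, R2 = ld$r2)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

validate_ld <- function(ld) {
  stopifnot(is.data.frame(ld),
            all(c("marker_a", "marker_b", "r2") %in% names(ld)))
  if (nrow(ld)) {
    if (any(ld$marker_a == ld$marker_b))
      msekda_stop("LD table contains self-pairs", "msekda_consistency_error")
    if (any(ld$r2 < 0 | ld$r2 > 1))
      msekda_stop("LD r2 values must lie in [0, 1]",
                  "msekda_consistency_error")
  }
  ld
}

#' Read and write edge-weighted networks
#'
#' Three tab-delimited columns (`TAIL`, `HEAD`, `WEIGHT`), weights in (0, 1].
#'
#' @param path File path.
#' @param directed Whether edges are directed (default `FALSE`; functional
#'   tissue networks are treated as undirected).
#' @return A data.frame with columns `tail`, `head`, `weight` and a
#'   `"directed"` attribute.
#' @export
read_network <- function(path, directed = FALSE) {
  x <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  names(x)[1:3] <- c("tail", "head", "weight")
  validate_network(x[, 1:3], directed = directed)
}

#' @param net Network edge data.frame.
#' @rdname read_network
#' @export
write_network <- function(net, path) {
  out <- data.frame(TAIL = net$tail, HEAD = net$head, WEIGHT = net$weight)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Validate a network edge table
#'
#' Checks the edge-list contract (no self-loops, weights in (0, 1]) and
#' stamps the `"directed"` attribute.
#'
#' @param net Edge data.frame (`tail`, `head`, `weight`).
#' @param directed Whether edges are directed.
#' @return The validated data.frame.
#' @export
validate_network <- function(net, directed = FALSE) {
  stopifnot(is.data.frame(net),
            all(c("tail", "head", "weight") %in% names(net)))
  if (nrow(net)) {
    if (any(net$tail == net$head))
      msekda_stop("network contains self-loops", "msekda_consistency_error")
    if (any(net$weight <= 0 | net$weight > 1))
      msekda_stop("edge weights must lie in (0, 1]",
                  "msekda_consistency_error")
  }
  attr(net, "directed") <- directed
  net
}

#' Read and write expression matrices with sample labels
#'
#' The expression file is a genes x samples TSV whose first column holds
#' gene ids; the label file has two columns (`SAMPLE`, `GROUP`) with exactly
#' two group levels.
#'
#' @param expr_path,label_path File paths.
#' @return A list with `expr` (numeric matrix, genes x samples) and
#'   `labels` (factor of group labels, named by sample).
#' @export
read_expression <- function(expr_path, label_path) {
  x <- data.table::fread(expr_path, header = TRUE, sep = "\t",
                         data.table = FALSE)
  expr <- as.matrix(x[, -1, drop = FALSE])
  rownames(expr) <- x[[1]]
  lab <- data.table::fread(label_path, header = TRUE, sep = "\t",
                           data.table = FALSE)
  # group levels in order of first appearance: the first-listed group is
  # the reference for DE statistics and GSEA direction
  labels <- factor(lab[[2]], levels = unique(lab[[2]]))
  names(labels) <- lab[[1]]
  labels <- labels[colnames(expr)]
  if (anyNA(labels))
    msekda_stop("samples in expression matrix missing from label file",
                "msekda_consistency_error")
  list(expr = expr, labels = labels)
}

#' @param expr Numeric matrix, genes x samples.
#' @param labels Factor of group labels, one per column of `expr`.
#' @rdname read_expression
#' @export
write_expression <- function(expr, labels, expr_path, label_path) {
  out <- data.frame(GENE = rownames(expr), expr, check.names = FALSE)
  data.table::fwrite(out, expr_path, sep = "\t")
  data.table::fwrite(data.frame(SAMPLE = colnames(expr),
                                GROUP = as.character(labels)),
                     label_path, sep = "\t")
  invisible(expr_path)
}
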