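# internal: node index and sparse symmetric weight matrix for a network
network_matrix <- function(net, directed = attr(net, "directed") %||% FALSE) {
  nodes <- sort(unique(c(net$tail, net$head)))
  i <- match(net$tail, nodes)
  j <- match(net$head, nodes)
  if (directed) {
    A <- Matrix::sparseMatrix(i = i, j = j, x = net$weight,
                              dims = c(length(nodes), length(nodes)))
  } else {
    A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                              x = rep(net$weight, 2L),
                              dims = c(length(nodes), length(nodes)),
                              use.last.ij = TRUE)
  }
  dimnames(A) <- list(nodes, nodes)
  list(nodes = nodes, A = A)
}

#' Weighted neighborhood of a network node
#'
#' All nodes reachable from `node` within `depth` edges (direction ignored
#' for undirected networks), each carrying the maximum product of edge
#' weights over admissible paths; the focal node is excluded.
#'
#' @param net Network edge data.frame (`tail`, `head`, `weight`).
#' @param node Focal gene id.
#' @param depth Maximum path length (default 1, the "first level"
#'   neighborhood).
#' @return Named numeric vector of neighbor weights (empty for isolated
#'   nodes).
#' @export
neighborhood <- function(net, node, depth = 1L) {
  directed <- attr(net, "directed") %||% FALSE
  nodes <- sort(unique(c(net$tail, net$head)))
  if (!node %in% nodes) return(stats::setNames(numeric(), character()))
  agg_max <- function(vals, keys) vapply(split(vals, keys), max, 0)
  best <- stats::setNames(numeric(length(nodes)), nodes)
  best[node] <- 1
  # relax edges depth times: round d settles the best product over paths
  # of <= d hops (weights <= 1, so cycles never improve the product)
  for (d in seq_len(depth)) {
    nb <- best
    fwd <- agg_max(best[net$tail] * net$weight, net$head)
    nb[names(fwd)] <- pmax(nb[names(fwd)], fwd)
    if (!directed) {
      bwd <- agg_max(best[net$head] * net$weight, net$tail)
      nb[names(bwd)] <- pmax(nb[names(bwd)], bwd)
    }
    if (identical(nb, best)) break
    best <- nb
  }
  best[names(best) != node & best > 0]
}

#' Weighted key driver analysis (wKDA)
#'
#' Ranks network genes by enrichment of their edge-weighted neighborhoods
#' for a disease gene set.  For each candidate node (neighborhood size >=
#' `min_neighborhood`), the statistic is
#' `T = (O_w - E_w) / sqrt(E_w + kappa)` with `O_w` the summed neighbor
#' weights of superset members, `E_w = W_tot * rho` where `W_tot` is the
#' node's total neighborhood weight and `rho` the fraction of network
#' nodes in the superset.  The null permutes superset membership labels
#' uniformly over network nodes (size-preserving), giving
#' `p = (1 + #\{T* >= T\}) / (n_permutations + 1)`; Benjamini-Hochberg FDR
#' is applied across candidates.
#'
#' @param net Network edge data.frame (`tail`, `head`, `weight`), treated
#'   as undirected.
#' @param superset Character vector of disease gene ids (must intersect
#'   the network nodes).
#' @param superset_id Label recorded in the results.
#' @param network_id Tissue/network label recorded in the results.
#' @param depth Neighborhood depth (default 1).
#' @param n_permutations Membership permutations (default 1999).
#' @param min_neighborhood Minimum neighborhood size for a candidate
#'   (default 10).
#' @param kappa Variance stabilizer (default 1, matching MSEA).
#' @param seed Integer seed.
#' @return A data.frame (`gene_id`, `superset_id`, `network_id`,
#'   `statistic`, `p_empirical`, `fdr`, `neighborhood_size`, `n_hits`,
#'   `in_superset`) sorted by FDR then statistic.  Empty, with a warning,
#'   when no node qualifies.
#' @export
wkda <- function(net, superset, superset_id = "superset",
                 network_id = "network", depth = 1L,
                 n_permutations = 1999L, min_neighborhood = 10L,
                 kappa = 1, seed = 1L) {
  net <- validate_network(net, directed = attr(net, "directed") %||% FALSE)
  nm <- network_matrix(net, directed = FALSE)
  n <- length(nm$nodes)
  member <- nm$nodes %in% superset
  if (!any(member))
    msekda_stop("superset does not intersect the network nodes",
                "msekda_consistency_error")
  W <- if (depth == 1L) nm$A else {
    # depth-d max-product neighborhoods, assembled row-wise
    rows <- lapply(nm$nodes, function(v) neighborhood(net, v, depth))
    i <- rep(seq_len(n), lengths(rows))
    j <- match(unlist(lapply(rows, names), use.names = FALSE), nm$nodes)
    Matrix::sparseMatrix(i = i, j = j, x = unlist(rows, use.names = FALSE),
                         dims = c(n, n), dimnames = list(nm$nodes, nm$nodes))
  }
  nb_size <- Matrix::rowSums(W > 0)
  cand <- which(nb_size >= min_neighborhood)
  if (length(cand) == 0L) {
    warning("no node has a neighborhood of at least ", min_neighborhood,
            " genes")
    return(data.frame(gene_id = character(), superset_id = character(),
                      network_id = character(), statistic = numeric(),
                      p_empirical = numeric(), fdr = numeric(),
                      neighborhood_size = integer(), n_hits = integer(),
                      in_superset = logical()))
  }
  Wc <- W[cand, , drop = FALSE]
  tot_w <- Matrix::rowSums(Wc)
  rho <- sum(member) / n
  E_w <- tot_w * rho
  denom <- sqrt(E_w + kappa)
  O_w <- as.vector(Wc %*% member)
  T_obs <- (O_w - E_w) / denom
  n_hits <- as.vector((Wc > 0) %*% member)

  withr::with_seed(as.integer(seed), {
    exceed <- integer(length(cand))
    chunk <- 250L
    done <- 0L
    while (done < n_permutations) {
      m <- min(chunk, n_permutations - done)
      P <- vapply(seq_len(m), function(i) {
        x <- logical(n); x[sample.int(n, sum(member))] <- TRUE; x
      }, logical(n))
      Tp <- (as.matrix(Wc %*% P) - E_w) / denom
      exceed <- exceed + rowSums(Tp >= T_obs)
      done <- done + m
    }
  })
  p_emp <- (1 + exceed) / (n_permutations + 1)
  out <- data.frame(gene_id = nm$nodes[cand], superset_id = superset_id,
                    network_id = network_id, statistic = T_obs,
                    p_empirical = p_emp, fdr = bh_fdr(p_emp),
                    neighborhood_size = as.integer(nb_size[cand]),
                    n_hits = as.integer(n_hits),
                    in_superset = member[cand])
  out <- out[order(out$fdr, -out$statistic, out$gene_id), ]
  rownames(out) <- NULL
  out
}

#' Key drivers shared across supersets and networks
#'
#' Genes FDR-significant for at least `min_combinations` distinct
#' (superset, network) combinations, with the combinations listed.
#'
#' @param results Data.frame of combined [wkda()] results (rows from
#'   several supersets/networks).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param min_combinations Minimum number of significant combinations
#'   (default 2).
#' @return A data.frame (`gene_id`, `n_combinations`, `combinations`)
#'   sorted by gene id.
#' @export
shared_kds <- function(results, fdr_threshold = 0.05,
                       min_combinations = 2L) {
  sig <- results[results$fdr < fdr_threshold, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(data.frame(gene_id = character(), n_combinations = integer(),
                      combinations = character()))
  combo <- paste(sig$superset_id, sig$network_id, sep = "/")
  by_gene <- split(combo, sig$gene_id)
  by_gene <- lapply(by_gene, function(x) sort(unique(x)))
  keep <- lengths(by_gene) >= min_combinations
  data.frame(gene_id = names(by_gene)[keep],
             n_combinations = lengths(by_gene)[keep],
             combinations = vapply(by_gene[keep], paste, "",
                                   collapse = ";"),
             row.names = NULL)
}

#' Extract a key driver subnetwork
#'
#' Induced edges among the key driver and its depth-neighborhood, with
#' node annotations: superset membership and, optionally, per-gene marker
#' significance flags.
#'
#' @param net Network edge data.frame.
#' @param kd_gene Key driver gene id.
#' @param superset Character vector of superset gene ids.
#' @param depth Neighborhood depth (default 1).
#' @param marker_flags Optional named logical vector of per-gene
#'   GWAS/EWAS significance flags.
#' @return A list of class `"kd_subnetwork"`: `edges` (edge data.frame)
#'   and `nodes` (data.frame `gene_id`, `is_kd`, `in_superset`,
#'   `marker_significant`).
#' @export
extract_subnetwork <- function(net, kd_gene, superset, depth = 1L,
                               marker_flags = NULL) {
  nb <- neighborhood(net, kd_gene, depth)
  keep_nodes <- c(kd_gene, names(nb))
  edges <- net[net$tail %in% keep_nodes & net$head %in% keep_nodes, ,
               drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(gene_id = keep_nodes,
                      is_kd = keep_nodes == kd_gene,
                      in_superset = keep_nodes %in% superset,
                      marker_significant =
                        if (is.null(marker_flags)) NA
                        else unname(marker_flags[keep_nodes]))
  structure(list(edges = edges, nodes = nodes), class = "kd_subnetwork")
}

#' Write and read a key driver subnetwork
#'
#' Serialized as two TSVs: `<prefix>_edges.tsv` (TAIL, HEAD, WEIGHT) and
#' `<prefix>_nodes.tsv` (GENE, IS_KD, IN_SUPERSET, MARKER_SIGNIFICANT).
#'
#' @param subnet A [extract_subnetwork()] result.
#' @param prefix Output path prefix.
#' @export
write_subnetwork <- function(subnet, prefix) {
  write_network(subnet$edges, paste0(prefix, "_edges.tsv"))
  data.table::fwrite(
    data.frame(GENE = subnet$nodes$gene_id, IS_KD = subnet$nodes$is_kd,
               IN_SUPERSET = subnet$nodes$in_superset,
               MARKER_SIGNIFICANT = subnet$nodes$marker_significant),
    paste0(prefix, "_nodes.tsv"), sep = "\t")
  invisible(prefix)
}

#' @rdname write_subnetwork
#' @export
read_subnetwork <- function(prefix) {
  edges <- read_network(paste0(prefix, "_edges.tsv"))
  nd <- data.table::fread(paste0(prefix, "_nodes.tsv"), sep = "\t",
                          data.table = FALSE)
  nodes <- data.frame(gene_id = as.character(nd$GENE),
                      is_kd = as.logical(nd$IS_KD),
                      in_superset = as.logical(nd$IN_SUPERSET),
                      marker_significant = as.logical(nd$MARKER_SIGNIFICANT))
  structure(list(edges = edges, nodes = nodes), class = "kd_subnetwork")
}
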