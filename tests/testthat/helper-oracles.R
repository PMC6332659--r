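# Independent brute-force oracles: explicit loops, no shared code with the
# package internals.  These deliberately re-derive each statistic from its
# definition so the implementation and the check cannot share a bug.

oracle_enrichment_stat <- function(set_p, bg_p, grid, kappa) {
  s <- 0
  for (q in grid) {
    cj <- stats::quantile(bg_p, q, names = FALSE)
    O <- 0
    for (p in set_p) if (p <= cj) O <- O + 1
    E <- length(set_p) * q
    s <- s + (O - E) / sqrt(E + kappa)
  }
  s
}

oracle_gsea_es <- function(ranked, set, w) {
  N <- length(ranked)
  in_set <- names(ranked) %in% set
  ranked <- unname(ranked)
  total_hit <- 0
  for (i in seq_len(N)) if (in_set[i]) total_hit <- total_hit + abs(ranked[i])^w
  run <- 0
  hi <- -Inf
  lo <- Inf
  profile <- numeric(N)
  for (i in seq_len(N)) {
    if (in_set[i]) run <- run + abs(ranked[i])^w / total_hit
    else run <- run - 1 / (N - sum(in_set))
    profile[i] <- run
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  best <- if (hi + lo >= -1e-12) hi else lo   # magnitude ties go positive
  list(es = best, running = profile)
}

# upper-tail hypergeometric by explicit summation over the support
oracle_hyper_tail <- function(k, na, nb, U) {
  lo <- max(0L, na + nb - U)
  hi <- min(na, nb)
  if (k > hi) return(0)
  terms <- vapply(max(k, lo):hi, function(i)
    exp(lchoose(na, i) + lchoose(U - na, nb - i) - lchoose(U, nb)), 0)
  sum(terms)
}

# own step-up BH, written from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running_min <- 1
  for (r in m:1) {
    i <- ord[r]
    running_min <- min(running_min, p[i] * m / r)
    q[i] <- running_min
  }
  q
}

# union-find over explicit pairwise edge enumeration; edge rule replicated
# from the definitions (geometric-mean overlap ratio + own hypergeometric
# tail + own BH)
oracle_merge_components <- function(sets, U, r_cutoff, fdr_cutoff) {
  n <- length(sets)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  pairs <- if (n > 1) t(utils::combn(n, 2)) else matrix(integer(), ncol = 2)
  pvals <- numeric(nrow(pairs))
  ratios <- numeric(nrow(pairs))
  for (e in seq_len(nrow(pairs))) {
    a <- unique(sets[[pairs[e, 1]]]); b <- unique(sets[[pairs[e, 2]]])
    k <- length(intersect(a, b))
    pvals[e] <- oracle_hyper_tail(k, length(a), length(b), U)
    ratios[e] <- sqrt((k / length(a)) * (k / length(b)))
  }
  qvals <- oracle_bh(pvals)
  for (e in seq_len(nrow(pairs))) {
    if (ratios[e] >= r_cutoff && qvals[e] < fdr_cutoff) {
      ra <- find(pairs[e, 1]); rb <- find(pairs[e, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  comp <- vapply(seq_len(n), find, 0L)
  split(names(sets), comp)
}

# all-pairs reciprocal-best-hit enumeration with fisher.test as the
# p-value engine (independent of phyper-based package code)
oracle_rbh_status <- function(net_a, net_b, U, fdr_cutoff = 0.05) {
  na <- length(net_a); nb <- length(net_b)
  p <- matrix(NA_real_, na, nb)
  k <- matrix(NA_integer_, na, nb)
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    a <- unique(net_a[[i]]); b <- unique(net_b[[j]])
    ov <- length(intersect(a, b))
    tab <- matrix(c(ov, length(a) - ov, length(b) - ov,
                    U - length(a) - length(b) + ov), 2)
    p[i, j] <- stats::fisher.test(tab, alternative = "greater")$p.value
    k[i, j] <- ov
  }
  q <- matrix(oracle_bh(as.vector(p)), na, nb)
  best_a <- integer(na); best_b <- integer(nb)
  for (i in seq_len(na))
    best_a[i] <- order(p[i, ], -k[i, ], names(net_b))[1]
  for (j in seq_len(nb))
    best_b[j] <- order(p[, j], -k[, j], names(net_a))[1]
  status_a <- vapply(seq_len(na), function(i) {
    j <- best_a[i]
    if (best_b[j] == i && q[i, j] < fdr_cutoff) "preserved" else "differential"
  }, "")
  status_b <- vapply(seq_len(nb), function(j) {
    i <- best_b[j]
    if (best_a[i] == j && q[i, j] < fdr_cutoff) "preserved" else "differential"
  }, "")
  list(a = stats::setNames(status_a, names(net_a)),
       b = stats::setNames(status_b, names(net_b)))
}

# unweighted key driver statistic by explicit neighbor counting
oracle_unweighted_kda <- function(net, superset, kappa = 1,
                                  min_neighborhood = 10) {
  nodes <- sort(unique(c(net$tail, net$head)))
  nbrs <- lapply(nodes, function(v)
    unique(c(net$head[net$tail == v], net$tail[net$head == v])))
  names(nbrs) <- nodes
  rho <- length(intersect(superset, nodes)) / length(nodes)
  stats <- numeric(0)
  for (v in nodes) {
    nb <- nbrs[[v]]
    if (length(nb) < min_neighborhood) next
    O <- length(intersect(nb, superset))
    E <- length(nb) * rho
    stats[v] <- (O - E) / sqrt(E + kappa)
  }
  stats
}

# connected components of the thresholded LD graph by repeated expansion
oracle_ld_components <- function(ld, threshold) {
  ld <- ld[ld$r2 > threshold, , drop = FALSE]
  ids <- unique(c(ld$marker_a, ld$marker_b))
  comps <- list()
  left <- ids
  while (length(left)) {
    comp <- left[1]
    repeat {
      grow <- unique(c(ld$marker_b[ld$marker_a %in% comp],
                       ld$marker_a[ld$marker_b %in% comp]))
      new <- union(comp, grow)
      if (length(new) == length(comp)) break
      comp <- new
    }
    comps[[length(comps) + 1]] <- sort(comp)
    left <- setdiff(left, comp)
  }
  comps
}

# small random gene-set collection used across merge tests
random_set_collection <- function(n_sets, universe, size_range) {
  sets <- lapply(seq_len(n_sets), function(i)
    sample(universe, sample(size_range[1]:size_range[2], 1)))
  names(sets) <- sprintf("S%02d", seq_len(n_sets))
  sets
}
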