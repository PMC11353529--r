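# independent flood-fill component labelling (no igraph)
oracle_components <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$source[i]; b <- edges$target[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- character(0)
  comps <- list()
  for (v in nodes) {
    if (v %in% seen) next
    queue <- v
    comp <- character(0)
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      if (u %in% comp) next
      comp <- c(comp, u)
      queue <- c(queue, setdiff(adj[[u]], comp))
    }
    comps[[length(comps) + 1]] <- sort(comp)
    seen <- c(seen, comp)
  }
  comps
}

# brute-force BFS distances from one source (own queue, no igraph)
oracle_bfs_dist <- function(nodes, edges, src) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$source[i]; b <- edges$target[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  d <- stats::setNames(rep(Inf, length(nodes)), nodes)
  d[src] <- 0
  frontier <- src
  while (length(frontier)) {
    nxt <- character(0)
    for (u in frontier) {
      for (w in adj[[u]]) {
        if (is.infinite(d[w])) {
          d[w] <- d[u] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- unique(nxt)
  }
  d
}

# O(n^3) triple loop over all class-filtered node combinations
oracle_triples <- function(net, module,
                           ncrna_classes = c("lncRNA", "pseudogene")) {
  cls <- stats::setNames(network_nodes(net)$gene_class,
                         network_nodes(net)$id)
  ed <- network_edges(net)
  inside <- ed$source %in% module & ed$target %in% module
  key <- c(paste(ed$source[inside], ed$target[inside]),
           paste(ed$target[inside], ed$source[inside]))
  has_edge <- function(a, b) paste(a, b) %in% key
  module <- intersect(module, names(cls))
  ncs <- module[cls[module] %in% ncrna_classes]
  mis <- module[cls[module] == "miRNA"]
  mrs <- module[cls[module] == "mRNA"]
  out <- list()
  for (n in ncs) for (mi in mis) for (m in mrs) {
    if (has_edge(n, mi) && has_edge(mi, m)) {
      out[[length(out) + 1]] <- c(n, mi, m)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(ncrna = character(0), mirna = character(0),
                          mrna = character(0)))
  }
  mt <- do.call(rbind, out)
  res <- tibble::tibble(ncrna = mt[, 1], mirna = mt[, 2], mrna = mt[, 3])
  res[order(res$ncrna, res$mirna, res$mrna), ]
}

# exhaustive hypergeometric tail: probability that a random module of size
# k from background 1..N overlaps the first m genes at least obs times
oracle_ora_p <- function(N, m, k, obs) {
  draws <- utils::combn(N, k)
  mean(apply(draws, 2, function(d) sum(d <= m)) >= obs)
}

# full enumeration rank-sum oracle on the rank-sum (not U) statistic
oracle_ranksum_p <- function(x, y, alternative) {
  n <- length(x); N <- n + length(y)
  r <- rank(c(x, y))
  s_obs <- sum(r[seq_len(n)])
  sums <- apply(utils::combn(N, n), 2, function(idx) sum(r[idx]))
  p_le <- mean(sums <= s_obs + 1e-9)
  p_ge <- mean(sums >= s_obs - 1e-9)
  switch(alternative,
         less = p_le, greater = p_ge,
         two.sided = min(1, 2 * min(p_le, p_ge)))
}
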