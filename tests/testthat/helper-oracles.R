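# Independent oracles and fixture builders. These deliberately avoid the
# package's own code paths so the tests are dual-route checks.

# All set partitions of n elements as restricted-growth strings.
all_set_partitions <- function(n) {
  out <- list()
  recurse <- function(assign, k) {
    i <- length(assign) + 1
    if (i > n) {
      out[[length(out) + 1]] <<- assign
      return(invisible())
    }
    for (g in seq_len(k + 1)) recurse(c(assign, g), max(k, g))
  }
  recurse(integer(0), 0L)
  out
}

# Modularity via the adjacency-matrix double sum
# (1/2m) sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j) -- a different route
# from the package's within-module edge-fraction formula.
modularity_adjacency_oracle <- function(adj, membership) {
  m <- sum(adj) / 2
  if (m == 0) return(0)
  k <- unname(rowSums(adj))
  adj <- unname(adj)
  q <- 0
  n <- nrow(adj)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (membership[i] == membership[j]) {
      q <- q + adj[i, j] - k[i] * k[j] / (2 * m)
    }
  }
  q / (2 * m)
}

# Hand-written BH step-up (the package wraps stats::p.adjust).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Explicit mid-rank Spearman: average ranks for ties, then the Pearson
# product-moment formula written out by hand.
spearman_midrank_oracle <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Build a co_network from an integer edge matrix/list on nodes named n1..nk.
make_net <- function(edges, n_nodes = NULL) {
  edges <- matrix(as.integer(edges), ncol = 2)
  ids <- function(i) paste0("n", i)
  n_nodes <- if (is.null(n_nodes)) max(edges) else n_nodes
  co_network(
    tibble::tibble(from = ids(edges[, 1]), to = ids(edges[, 2])),
    nodes = tibble::tibble(otu_id = ids(seq_len(n_nodes)))
  )
}

# Adjacency matrix of a make_net() network, node order n1..nk.
net_adjacency <- function(net) {
  ids <- net$nodes$otu_id
  adj <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (e in seq_len(nrow(net$edges))) {
    adj[net$edges$from[e], net$edges$to[e]] <- 1
    adj[net$edges$to[e], net$edges$from[e]] <- 1
  }
  adj
}

# Random Erdos-Renyi edge list on n nodes (at least one edge).
random_edges <- function(n, p = 0.4) {
  repeat {
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < p
    if (any(keep)) return(pairs[keep, , drop = FALSE])
  }
}

# Tiny OTU table fixture.
tiny_table <- function() {
  m <- matrix(c(10L, 5L, 0L, 2L, 8L, 1L), nrow = 3, byrow = TRUE,
              dimnames = list(c("OTU1", "OTU2", "OTU3"), c("s1", "s2")))
  otu_table(m, c("Bacteria;Proteobacteria", "Bacteria", ""))
}

# Metadata for constructed tables: habitats/treatments per the 4-group
# design, recycled over the sample ids.
make_meta <- function(sample_id, group) {
  hab <- ifelse(grepl("e$", group), "gut", "soil")
  trt <- sub("[se]$", "", group)
  sample_metadata(sample_id, hab, trt)
}
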