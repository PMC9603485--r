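#' Prevalence filter
#'
#' Keeps OTUs present (count > 0) in strictly more than `min_fraction` of the
#' samples, the usual pre-filter before co-occurrence analysis ("found in
#' more than two-thirds of the samples").
#'
#' @param x an OTU table tibble.
#' @param min_fraction fraction in (0, 1]; default 2/3. The inequality is
#'   strict: with 12 samples an OTU present in exactly 8 (= 2/3) is dropped.
#' @return the filtered OTU table tibble.
#' @export
prevalence_filter <- function(x, min_fraction = 2 / 3) {
  if (!is.numeric(min_fraction) || min_fraction <= 0 || min_fraction > 1) {
    abort("min_fraction must be in (0, 1]")
  }
  x <- validate_otu_table(x)
  m <- otu_counts(x)
  keep <- rowSums(m > 0) > min_fraction * ncol(m)
  if (!any(keep)) warn("prevalence_filter() removed every OTU")
  x[keep, , drop = FALSE]
}

#' Relative abundances
#'
#' @param x an OTU table tibble.
#' @return a tibble of the same shape with counts replaced by per-sample
#'   proportions.
#' @export
relative_abundance <- function(x) {
  m <- otu_counts(validate_otu_table(x))
  p <- sweep(m, 2, colSums(m), "/")
  out <- x
  out[, sample_ids(x)] <- as_tibble(p, .name_repair = "minimal")
  out
}

# Scalar Spearman correlation with the t-approximation p-value used
# throughout the package: rho is the Pearson correlation of mid-ranks
# (average ranks for ties); p comes from t = rho sqrt((n-2)/(1-rho^2)) with
# n-2 df, two-sided. Constant vectors give rho = 0, p = 1; |rho| = 1 gives
# p = 0.
spearman_test <- function(x, y) {
  n <- length(x)
  if (sd(x) == 0 || sd(y) == 0) return(c(rho = 0, p = 1))
  rho <- cor(rank(x), rank(y))
  c(rho = rho, p = spearman_p(rho, n))
}

spearman_p <- function(rho, n) {
  p <- rep(1, length(rho))
  one <- abs(rho) >= 1 - 1e-12
  p[one] <- 0
  mid <- !one & abs(rho) > 0
  if (any(mid)) {
    tval <- abs(rho[mid]) * sqrt((n - 2) / (1 - rho[mid]^2))
    p[mid] <- 2 * pt(tval, df = n - 2, lower.tail = FALSE)
  }
  p
}

#' All-pairs Spearman correlation matrix
#'
#' Computes Spearman's rho for every OTU pair on relative abundances, with
#' two-sided p-values from the t-distribution approximation. Constant
#' abundance vectors are recorded as rho = 0, p = 1 rather than NaN;
#' p-values for |rho| = 1 are 0.
#'
#' @param x an OTU table tibble with at least 4 samples.
#' @return a list with elements `rho` and `p` (symmetric matrices with OTU
#'   ids as dimnames, unit/zero diagonal) and `n` (sample count).
#' @export
spearman_all_pairs <- function(x) {
  x <- validate_otu_table(x)
  m <- otu_counts(relative_abundance(x))
  n <- ncol(m)
  if (n < 4) abort("spearman_all_pairs() needs at least 4 samples")
  rk <- t(apply(m, 1, rank))
  const <- apply(m, 1, sd) == 0
  rho <- suppressWarnings(cor(t(rk)))
  rho[const, ] <- 0
  rho[, const] <- 0
  diag(rho) <- 1
  p <- matrix(spearman_p(rho, n), nrow(rho), dimnames = dimnames(rho))
  p[const, ] <- 1
  p[, const] <- 1
  diag(p) <- 0
  list(rho = rho, p = p, n = n)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: on sorted p-values,
#' `q_(i) = min_(j >= i) p_(j) m / j`, mapped back to input order and capped
#' at 1. Wraps [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return vector of adjusted q-values.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04)) # all 0.04
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Construct a co-occurrence network from node and edge tables
#'
#' Low-level constructor used by [build_network()] and handy for building
#' fixture graphs. Nodes absent from the edge list are kept and flagged
#' `isolated`.
#'
#' @param edges tibble (or data frame) with columns `from` and `to` (node
#'   ids); optional columns `rho`, `p`, `q` are preserved.
#' @param nodes optional tibble with a `otu_id` column (plus any annotation
#'   columns); defaults to the nodes appearing in `edges`.
#' @param params optional list of the thresholds used.
#' @return an object of class `co_network`: a list with tibbles `nodes` and
#'   `edges` plus `params`.
#' @export
co_network <- function(edges, nodes = NULL, params = list()) {
  edges <- as_tibble(edges)
  if (nrow(edges) && !all(c("from", "to") %in% names(edges))) {
    abort("edges need 'from' and 'to' columns")
  }
  if (nrow(edges) == 0 && !all(c("from", "to") %in% names(edges))) {
    edges <- tibble(from = character(), to = character())
  }
  edges <- mutate(edges, from = as.character(.data$from), to = as.character(.data$to))
  if (any(edges$from == edges$to)) abort("self-edges are not allowed")
  # canonical unordered representation, each pair at most once
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]
  edges$from[swap] <- edges$to[swap]
  edges$to[swap] <- tmp
  if (anyDuplicated(paste(edges$from, edges$to))) {
    abort("duplicate edges for the same unordered pair")
  }
  if (!"rho" %in% names(edges)) edges$rho <- rep(1, nrow(edges))
  if (!"sign" %in% names(edges)) {
    edges$sign <- ifelse(edges$rho >= 0, "+", "-")
  }
  if (is.null(nodes)) {
    nodes <- tibble(otu_id = sort(unique(c(edges$from, edges$to))))
  } else {
    nodes <- as_tibble(nodes)
    if (!"otu_id" %in% names(nodes)) abort("nodes need an 'otu_id' column")
    missing <- setdiff(unique(c(edges$from, edges$to)), nodes$otu_id)
    if (length(missing)) {
      abort(sprintf("edge endpoints missing from node table: %s",
                    paste(head(missing, 5), collapse = ", ")))
    }
  }
  deg <- table(factor(c(edges$from, edges$to), levels = nodes$otu_id))
  nodes$degree <- as.integer(deg[nodes$otu_id])
  nodes$isolated <- nodes$degree == 0L
  structure(list(nodes = nodes, edges = edges, params = params),
            class = "co_network")
}

#' Build the thresholded Spearman co-occurrence network
#'
#' Computes all-pairs Spearman correlations on relative abundances, adjusts
#' the p-values with Benjamini-Hochberg across all pairs, and keeps an edge
#' if and only if `|rho| > r_threshold` (strict) and the adjusted
#' `q < q_threshold`. Nodes that end up with no retained edge stay in the
#' node set, flagged `isolated`. The input should already be
#' prevalence-filtered.
#'
#' @param x an OTU table tibble.
#' @param r_threshold correlation magnitude threshold (default 0.8).
#' @param q_threshold BH-adjusted significance threshold (default 0.01).
#' @return a `co_network` whose nodes carry `prevalence` and
#'   `mean_rel_abund`, and whose edges carry `rho`, `p`, `q`, and `sign`.
#' @export
build_network <- function(x, r_threshold = 0.8, q_threshold = 0.01) {
  if (r_threshold < 0 || r_threshold > 1) abort("r_threshold must be in [0, 1]")
  if (q_threshold <= 0 || q_threshold > 1) abort("q_threshold must be in (0, 1]")
  x <- validate_otu_table(x)
  sp <- spearman_all_pairs(x)
  ids <- rownames(sp$rho)
  ut <- which(upper.tri(sp$rho), arr.ind = TRUE)
  pairs <- tibble(
    from = ids[ut[, 1]], to = ids[ut[, 2]],
    rho = sp$rho[ut], p = sp$p[ut]
  )
  pairs$q <- bh_adjust(pairs$p)
  kept <- filter(pairs, abs(.data$rho) > r_threshold, .data$q < q_threshold)
  m <- otu_counts(x)
  ra <- sweep(m, 2, colSums(m), "/")
  nodes <- tibble(
    otu_id = x$otu_id,
    taxonomy = x$taxonomy,
    prevalence = rowMeans(m > 0),
    mean_rel_abund = rowMeans(ra)
  )
  co_network(kept, nodes,
             params = list(r_threshold = r_threshold,
                           q_threshold = q_threshold,
                           n_samples = sp$n))
}

#' @export
print.co_network <- function(x, ...) {
  cat(sprintf(
    "co_network: %d nodes (%d isolated), %d edges (%d positive / %d negative)\n",
    nrow(x$nodes), sum(x$nodes$isolated), nrow(x$edges),
    sum(x$edges$sign == "+"), sum(x$edges$sign == "-")
  ))
  invisible(x)
}

#' Convert a co-occurrence network to an igraph object
#'
#' @param net a `co_network`.
#' @return an undirected [igraph::igraph] graph including isolated nodes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "co_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

# Drop nodes (and incident edges) from a network.
subnetwork <- function(net, drop) {
  keep <- !(net$nodes$otu_id %in% drop)
  edges <- filter(net$edges, !(.data$from %in% drop), !(.data$to %in% drop))
  co_network(edges, net$nodes[keep, setdiff(names(net$nodes), c("degree", "isolated"))],
             params = net$params)
}

#' Export a network edge list as CSV
#'
#' Columns: source, target, rho, p, q, sign.
#'
#' @param net a `co_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  out <- net$edges %>%
    rename(source = "from", target = "to")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Export a network as GraphML with node attributes
#'
#' @param net a `co_network`.
#' @param path output file path.
#' @param topology optional node topology tibble from [zi_pi()] (adds
#'   `module`, `zi`, `pi`, `role` vertex attributes).
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path, topology = NULL) {
  g <- as_igraph(net)
  if (!is.null(topology)) {
    idx <- match(igraph::V(g)$name, topology$otu_id)
    igraph::V(g)$module <- topology$module[idx]
    igraph::V(g)$zi <- topology$zi[idx]
    igraph::V(g)$pi <- topology$pi[idx]
    igraph::V(g)$role <- topology$role[idx]
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
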