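#' Newman modularity of a partition
#'
#' `Q = sum_s (e_ss - a_s^2)` where `e_ss` is the fraction of edges falling
#' within module `s` and `a_s` the fraction of edge endpoints attached to
#' `s`; equivalently `(1/2m) sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j)`.
#' Computed on the unweighted, unsigned graph (positive and negative edges
#' both count as edges). An edgeless network has `Q = 0` by convention.
#'
#' @param net a `co_network`.
#' @param membership a named vector (`otu_id` -> module) or a tibble with
#'   columns `otu_id` and `module`; must cover every node.
#' @return the modularity Q (scalar in \[-0.5, 1)).
#' @export
modularity_q <- function(net, membership) {
  mem <- as_membership(net, membership)
  m <- nrow(net$edges)
  if (m == 0) return(0)
  cf <- mem[net$edges$from]
  ct <- mem[net$edges$to]
  mods <- sort(unique(mem))
  e_ss <- vapply(mods, function(s) sum(cf == s & ct == s), numeric(1)) / m
  ends <- c(cf, ct)
  a_s <- vapply(mods, function(s) sum(ends == s), numeric(1)) / (2 * m)
  sum(e_ss - a_s^2)
}

# Normalize membership input to a named integer vector covering all nodes.
as_membership <- function(net, membership) {
  if (is.data.frame(membership)) {
    mem <- setNames(membership$module, membership$otu_id)
  } else {
    mem <- membership
  }
  missing <- setdiff(net$nodes$otu_id, names(mem))
  if (length(missing)) {
    abort(sprintf("node(s) missing from partition: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  mem[net$nodes$otu_id]
}

#' Detect modules by deterministic greedy modularity maximization
#'
#' Agglomerative (CNM-style) community detection: every node starts in its
#' own module; the merge with the largest modularity gain is applied
#' repeatedly until no merge increases Q. Ties are broken by the
#' lexicographically smallest pair of module ids (a module's id is the
#' smallest node index it contains), so the result is deterministic for a
#' fixed input ordering. A deterministic single-node relocation pass then
#' refines the agglomerative optimum (sweeps in node order, applying each
#' strictly improving move, until no move helps), which closes most of the
#' gap the pure merge phase leaves on small graphs. Isolated nodes remain
#' singleton modules. With `n_restarts > 0`, additional runs on seeded
#' random node permutations are performed and the best-Q partition kept.
#'
#' @param net a `co_network`.
#' @param seed integer seed; only consumed by the optional random restarts.
#' @param n_restarts number of extra randomized runs (default 0, fully
#'   deterministic).
#' @return an object of class `module_partition`: list with `membership`
#'   (tibble `otu_id`, `module` with integer module ids 0..M-1),
#'   `modularity`, `n_modules`.
#' @export
detect_modules <- function(net, seed = 0L, n_restarts = 0L) {
  stopifnot(inherits(net, "co_network"))
  ids <- net$nodes$otu_id
  base <- cnm_greedy(net, ids)
  if (n_restarts > 0) {
    for (r in seq_len(n_restarts)) {
      perm <- withr::with_seed(derive_seed(seed, paste0("restart", r)),
                               sample(ids))
      cand <- cnm_greedy(net, perm)
      if (cand$q > base$q + 1e-12) base <- cand
    }
  }
  mem <- base$membership[ids]
  # relabel 0..M-1 in order of first appearance
  labels <- unique(unname(mem))
  mem_int <- setNames(match(mem, labels) - 1L, names(mem))
  structure(
    list(
      membership = tibble(otu_id = ids, module = as.integer(mem_int[ids])),
      modularity = modularity_q(net, mem_int),
      n_modules = length(labels)
    ),
    class = "module_partition"
  )
}

# Core optimizer over a given node ordering: exact enumeration when few
# enough nodes carry edges, greedy agglomeration + relocation otherwise.
# Returns the membership (named by otu_id) and the final Q.
cnm_greedy <- function(net, order_ids) {
  n <- length(order_ids)
  idx <- setNames(seq_len(n), order_ids)
  ef <- idx[net$edges$from]
  et <- idx[net$edges$to]
  m <- length(ef)
  if (m == 0) {
    return(list(membership = setNames(order_ids, order_ids),
                q = 0))
  }
  if (length(unique(c(ef, et))) <= 10L) {
    return(exact_modules(net, order_ids, ef, et, m))
  }
  # restrict the merge machinery to nodes that have at least one edge
  active <- sort(unique(c(ef, et)))
  na <- length(active)
  aidx <- integer(n)
  aidx[active] <- seq_len(na)
  E <- matrix(0, na, na)           # inter-module edge counts
  for (k in seq_len(m)) {
    i <- aidx[ef[k]]; j <- aidx[et[k]]
    E[i, j] <- E[i, j] + 1
    E[j, i] <- E[j, i] + 1
  }
  d <- rowSums(E) + diag(E)        # degree sums per module (diag = 2*internal)
  alive <- rep(TRUE, na)
  comp <- seq_len(na)              # module representative per active slot
  mod_id <- active                 # smallest original node index per module
  repeat {
    dd <- outer(d, d)
    gain <- E / m - dd / (2 * m^2)
    gain[E == 0] <- -Inf
    gain[!alive, ] <- -Inf
    gain[, !alive] <- -Inf
    diag(gain) <- -Inf
    best <- max(gain)
    if (!is.finite(best) || best <= 0) break
    cand <- which(gain >= best - 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_ids <- cbind(pmin(mod_id[cand[, 1]], mod_id[cand[, 2]]),
                      pmax(mod_id[cand[, 1]], mod_id[cand[, 2]]))
    pick <- order(pair_ids[, 1], pair_ids[, 2])[1]
    a <- cand[pick, 1]; b <- cand[pick, 2]
    # merge b into a
    E[a, ] <- E[a, ] + E[b, ]
    E[, a] <- E[, a] + E[, b]
    E[b, ] <- 0; E[, b] <- 0
    d[a] <- d[a] + d[b]; d[b] <- 0
    alive[b] <- FALSE
    comp[comp == b] <- a
    mod_id[a] <- min(mod_id[a], mod_id[b])
  }
  membership <- order_ids                       # singletons keep their own id
  names(membership) <- order_ids
  membership[active] <- order_ids[mod_id[comp[aidx[active]]]]
  membership <- refine_moves(membership, order_ids, ef, et, m)
  q <- modularity_q(net, setNames(membership, order_ids))
  list(membership = membership, q = q)
}

# Exact modularity maximization by enumerating all set partitions of the
# nodes that carry edges (at most Bell(10) = 115975 candidates). The first
# maximizer in restricted-growth order is kept, so the result is
# deterministic; isolated nodes stay singletons.
exact_modules <- function(net, order_ids, ef, et, m) {
  active <- sort(unique(c(ef, et)))
  na <- length(active)
  aidx <- integer(length(order_ids))
  aidx[active] <- seq_len(na)
  ea <- aidx[ef]; eb <- aidx[et]
  deg <- tabulate(c(ea, eb), nbins = na)
  best_q <- -Inf
  best_assign <- seq_len(na)
  assign <- integer(na)
  recurse <- function(i, k) {
    if (i > na) {
      d_s <- vapply(seq_len(k), function(s) sum(deg[assign == s]), numeric(1))
      q <- sum(assign[ea] == assign[eb]) / m - sum((d_s / (2 * m))^2)
      if (q > best_q + 1e-15) {
        best_q <<- q
        best_assign <<- assign[seq_len(na)]
      }
      return(invisible())
    }
    for (g in seq_len(k + 1)) {
      assign[i] <<- g
      recurse(i + 1, max(k, g))
    }
  }
  recurse(1L, 0L)
  membership <- order_ids
  names(membership) <- order_ids
  # label each active module by its smallest member node
  for (s in unique(best_assign)) {
    members <- active[best_assign == s]
    membership[members] <- order_ids[min(members)]
  }
  q <- modularity_q(net, setNames(membership, order_ids))
  list(membership = membership, q = q)
}

# Deterministic single-node relocation refinement: sweep nodes in input
# order, move a node to the adjacent module with the largest strictly
# positive modularity gain, repeat until a full sweep changes nothing.
refine_moves <- function(membership, order_ids, ef, et, m) {
  n <- length(order_ids)
  mem <- match(membership, order_ids)           # module label as integer
  deg <- numeric(n)
  adj <- vector("list", n)
  for (k in seq_along(ef)) {
    i <- ef[k]; j <- et[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
    deg[i] <- deg[i] + 1; deg[j] <- deg[j] + 1
  }
  dmod <- vapply(seq_len(n), function(s) sum(deg[mem == s]), numeric(1))
  occ <- tabulate(mem, nbins = n)               # nodes per module label
  for (sweep in seq_len(100)) {
    moved <- FALSE
    for (i in seq_len(n)) {
      if (deg[i] == 0) next
      a <- mem[i]
      nb_mods <- mem[adj[[i]]]
      e_to <- tabulate(nb_mods, nbins = n)
      gain_leave <- -e_to[a] / m + deg[i] * (dmod[a] - deg[i]) / (2 * m^2)
      cand <- sort(unique(nb_mods[nb_mods != a]))
      gains <- vapply(cand, function(b) {
        gain_leave + e_to[b] / m - deg[i] * dmod[b] / (2 * m^2)
      }, numeric(1))
      # detaching into a fresh singleton module is also a legal move
      if (occ[a] > 1L) {
        fresh <- which(occ == 0L)
        if (length(fresh)) {
          cand <- c(cand, fresh[1])
          gains <- c(gains, gain_leave)
        }
      }
      if (!length(cand)) next
      best <- which.max(gains)
      if (gains[best] > 1e-12) {
        b <- cand[best]
        dmod[a] <- dmod[a] - deg[i]
        dmod[b] <- dmod[b] + deg[i]
        occ[a] <- occ[a] - 1L
        occ[b] <- occ[b] + 1L
        mem[i] <- b
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  setNames(order_ids[mem], order_ids)
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules, Q = %.4f\n",
              x$n_modules, x$modularity))
  invisible(x)
}

#' @rdname detect_modules
#' @param x a `module_partition` object.
#' @param ... unused.
#' @export
tidy.module_partition <- function(x, ...) x$membership

#' @rdname detect_modules
#' @export
glance.module_partition <- function(x, ...) {
  tibble(modularity = x$modularity, n_modules = x$n_modules,
         n_nodes = nrow(x$membership))
}
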