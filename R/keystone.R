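#' Within-module degree (Zi) and participation coefficient (Pi)
#'
#' For every node: `kappa_i` is its number of links to nodes of its own
#' module, and `Zi = (kappa_i - mean kappa) / sd kappa`, standardized over
#' the node's module with the population standard deviation (`Zi = 0` when
#' the module's kappa has no variance). `Pi = 1 - sum_s (k_is / k_i)^2` over
#' modules `s`, with `Pi = 0` for isolated nodes; Pi is 0 whenever all of a
#' node's edges stay within its own module. Roles are assigned with
#' [classify_role()].
#'
#' @param net a `co_network`.
#' @param partition a `module_partition` (or membership tibble/named vector)
#'   covering all nodes.
#' @param z_threshold,p_threshold role thresholds, passed to
#'   [classify_role()].
#' @return a tibble with columns `otu_id`, `module`, `degree`,
#'   `within_module_degree`, `zi`, `pi`, `role`.
#' @export
zi_pi <- function(net, partition, z_threshold = 2.5, p_threshold = 0.62) {
  if (inherits(partition, "module_partition")) partition <- partition$membership
  mem <- as_membership(net, partition)
  ids <- net$nodes$otu_id
  k <- setNames(numeric(length(ids)), ids)
  kappa <- setNames(numeric(length(ids)), ids)
  # per-node edge counts into each module
  kin <- list()
  if (nrow(net$edges)) {
    long <- tibble(
      node = c(net$edges$from, net$edges$to),
      other = c(net$edges$to, net$edges$from)
    )
    long$other_mod <- mem[long$other]
    tab <- long %>% count(.data$node, .data$other_mod)
    kt <- tapply(tab$n, tab$node, sum)
    k[names(kt)] <- kt
    own <- tab[tab$other_mod == mem[tab$node], ]
    kappa[own$node] <- own$n
    pi_sum <- tapply((tab$n)^2, tab$node, sum)
    pi <- setNames(rep(0, length(ids)), ids)
    nz <- names(pi_sum)
    pi[nz] <- 1 - pi_sum[nz] / (k[nz]^2)
  } else {
    pi <- setNames(rep(0, length(ids)), ids)
  }
  zi <- setNames(rep(0, length(ids)), ids)
  for (s in unique(mem)) {
    members <- ids[mem == s]
    mu <- mean(kappa[members])
    sdev <- pop_sd(kappa[members])
    if (sdev > 0) zi[members] <- (kappa[members] - mu) / sdev
  }
  zi_out <- unname(zi[ids])
  pi_out <- unname(pi[ids])
  tibble(
    otu_id = ids,
    module = unname(mem),
    degree = as.integer(unname(k[ids])),
    within_module_degree = as.integer(unname(kappa[ids])),
    zi = zi_out,
    pi = pi_out,
    role = classify_role(zi_out, pi_out, z_threshold, p_threshold)
  )
}

#' Classify node roles from Zi and Pi
#'
#' Threshold semantics follow the standard Zi-Pi taxonomy: module hubs have
#' `Zi > 2.5` and `Pi <= 0.62` (key to their own module), connectors have
#' `Zi <= 2.5` and `Pi > 0.62` (key to network connection), network hubs
#' have both `Zi > 2.5` and `Pi > 0.62`; everything else is peripheral.
#' Values exactly at a threshold fall on the non-keystone-favoring side, so
#' the keystone call is conservative. Module hubs, connectors, and network
#' hubs together form the potential keystone set.
#'
#' @param zi,pi numeric vectors (recycled to common length).
#' @param z_threshold Zi cutoff (default 2.5).
#' @param p_threshold Pi cutoff (default 0.62).
#' @return character vector: `module_hub`, `connector`, `network_hub`, or
#'   `peripheral`.
#' @examples
#' classify_role(3.0, 0.30) # module_hub
#' classify_role(1.0, 0.70) # connector
#' @export
classify_role <- function(zi, pi, z_threshold = 2.5, p_threshold = 0.62) {
  n <- max(length(zi), length(pi))
  zi <- rep_len(zi, n)
  pi <- rep_len(pi, n)
  dplyr::case_when(
    zi > z_threshold & pi > p_threshold ~ "network_hub",
    zi > z_threshold ~ "module_hub",
    pi > p_threshold ~ "connector",
    TRUE ~ "peripheral"
  )
}

#' Is a role a keystone role?
#'
#' @param role character vector of roles from [classify_role()].
#' @return logical vector; `TRUE` for module hubs, connectors, and network
#'   hubs.
#' @export
is_keystone <- function(role) role %in% c("module_hub", "connector", "network_hub")

#' Per-sample summed relative abundance of a taxon set
#'
#' @param x an OTU table tibble.
#' @param otu_ids character vector of OTU ids (e.g. a keystone set).
#' @return tibble with `sample_id` and `abundance` (summed relative
#'   abundance, 0 when the set is empty).
#' @export
taxon_set_abundance <- function(x, otu_ids) {
  m <- otu_counts(relative_abundance(x))
  sel <- m[rownames(m) %in% otu_ids, , drop = FALSE]
  tibble(sample_id = colnames(m), abundance = unname(colSums(sel)))
}

#' Keystone report across group networks
#'
#' Combines per-group node topologies into a keystone table with lineages
#' and mean relative abundances, the cross-group shared keystone set
#' (intersection of keystone OTU ids over all groups), and per-network and
#' pooled keystone counts.
#'
#' @param topologies named list of [zi_pi()] tibbles, one per group network.
#' @param x the OTU table the networks were built from.
#' @param meta metadata tibble.
#' @param group_col metadata column defining the groups (default
#'   `group_label`).
#' @return an object of class `keystone_report`: list with `taxa` (tibble),
#'   `shared` (character vector), `counts` (tibble of per-network keystone
#'   counts), `pooled_n` (size of the union), and `abundance` (per sample,
#'   summed relative abundance of the pooled keystone set).
#' @export
keystone_report <- function(topologies, x, meta, group_col = "group_label") {
  stopifnot(is.list(topologies), length(topologies) >= 1, !is.null(names(topologies)))
  x <- validate_otu_table(x)
  tax <- setNames(x$taxonomy, x$otu_id)
  ra <- otu_counts(relative_abundance(x))
  taxa <- purrr::imap_dfr(topologies, function(tp, g) {
    key <- filter(tp, is_keystone(.data$role))
    if (nrow(key) == 0) return(tibble())
    key %>%
      mutate(
        group = g,
        taxonomy = unname(tax[.data$otu_id]),
        mean_relative_abundance =
          rowMeans(ra[.data$otu_id, , drop = FALSE])
      ) %>%
      select("group", "otu_id", "taxonomy", "degree", "zi", "pi", "role",
             "mean_relative_abundance")
  })
  sets <- purrr::map(topologies, ~ .x$otu_id[is_keystone(.x$role)])
  shared <- purrr::reduce(sets, intersect)
  pooled <- unique(unlist(sets))
  counts <- tibble(group = names(sets),
                   n_keystone = unname(lengths(sets)))
  structure(
    list(taxa = taxa, shared = shared, counts = counts,
         pooled_n = length(pooled),
         pooled = pooled,
         abundance = taxon_set_abundance(x, pooled)),
    class = "keystone_report"
  )
}

#' @export
print.keystone_report <- function(x, ...) {
  cat(sprintf("keystone_report: %d pooled keystone taxa, %d shared across %d networks\n",
              x$pooled_n, length(x$shared), nrow(x$counts)))
  print(x$counts)
  invisible(x)
}

#' @rdname keystone_report
#' @param x a `keystone_report` object.
#' @param ... unused.
#' @export
tidy.keystone_report <- function(x, ...) x$taxa

#' Keystone-removal network stability test
#'
#' Deletes the keystone nodes (and incident edges), re-detects modules on
#' the remnant, and records the modularity drop. The null reference removes
#' `n_null` uniformly random node sets of the same size (sampled without
#' replacement within each draw, seeded). The empirical one-sided p-value
#' for the observed post-removal modularity being lower than the null is
#' `(1 + #\{null <= observed\}) / (1 + n_null)`.
#'
#' @param net a `co_network`.
#' @param keystones character vector of node ids to remove (subset of the
#'   node set, not all of it).
#' @param n_null number of null removals (at least 99).
#' @param seed integer seed.
#' @param detect_fn partition function applied to each remnant network
#'   (default [detect_modules()]).
#' @return an object of class `removal_stability`: list with `q_before`,
#'   `q_after`, `null_q`, `p_value`, `n_null`, `n_removed`, `seed`.
#' @export
removal_stability <- function(net, keystones, n_null = 199, seed = 1L,
                              detect_fn = detect_modules) {
  stopifnot(inherits(net, "co_network"))
  if (n_null < 99) abort("n_null must be at least 99")
  ids <- net$nodes$otu_id
  extra <- setdiff(keystones, ids)
  if (length(extra)) {
    abort(sprintf("keystone id(s) not in the network: %s",
                  paste(head(extra, 5), collapse = ", ")))
  }
  if (length(keystones) >= length(ids)) {
    abort("cannot remove the entire node set")
  }
  q_before <- detect_fn(net)$modularity
  if (length(keystones) == 0) {
    null_q <- rep(q_before, n_null)
    return(structure(
      list(q_before = q_before, q_after = q_before, null_q = null_q,
           p_value = 1, n_null = n_null, n_removed = 0L,
           seed = as.integer(seed)),
      class = "removal_stability"
    ))
  }
  q_after <- detect_fn(subnetwork(net, keystones))$modularity
  k <- length(keystones)
  null_q <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_null), function(i) {
      drop <- sample(ids, k)
      detect_fn(subnetwork(net, drop))$modularity
    }, numeric(1))
  })
  p <- (1 + sum(null_q <= q_after)) / (1 + n_null)
  structure(
    list(q_before = q_before, q_after = q_after, null_q = null_q,
         p_value = p, n_null = as.integer(n_null),
         n_removed = as.integer(k), seed = as.integer(seed)),
    class = "removal_stability"
  )
}

#' @export
print.removal_stability <- function(x, ...) {
  cat(sprintf(
    "removal_stability: Q %.4f -> %.4f after removing %d nodes; empirical p = %.4f (n_null = %d)\n",
    x$q_before, x$q_after, x$n_removed, x$p_value, x$n_null
  ))
  invisible(x)
}

#' @rdname removal_stability
#' @param x a `removal_stability` object.
#' @param ... unused.
#' @export
glance.removal_stability <- function(x, ...) {
  tibble(
    q_before = x$q_before, q_after = x$q_after,
    null_mean = mean(x$null_q), null_sd = sd(x$null_q),
    p_value = x$p_value, n_null = x$n_null, n_removed = x$n_removed
  )
}

#' Write a removal-stability result as JSON
#'
#' @param x a `removal_stability` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_removal_json <- function(x, path) {
  qs <- stats::quantile(x$null_q, c(0.025, 0.25, 0.5, 0.75, 0.975))
  jsonlite::write_json(
    list(
      q_before = x$q_before, q_after = x$q_after,
      null = list(mean = mean(x$null_q), sd = sd(x$null_q),
                  quantiles = as.list(setNames(unname(qs), names(qs)))),
      p_value = x$p_value, n_null = x$n_null, n_removed = x$n_removed,
      seed = x$seed
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Correlate keystone abundance with environmental covariates (and AWCD)
#'
#' Spearman correlation (same estimator and t-approximation p-value as the
#' network stage) between the per-sample keystone relative abundance and
#' each environmental covariate, plus -- when provided -- each carbon-source
#' category's reference-time AWCD. All p-values are BH-adjusted together.
#' Constant covariates are flagged and reported as rho = 0, p = 1.
#'
#' @param abundance tibble with `sample_id` and `abundance` (e.g. from
#'   [taxon_set_abundance()]), or a `keystone_report`.
#' @param meta metadata tibble carrying the covariates.
#' @param env_vars covariate columns to test (default pH, OM, TN, TP, TK,
#'   MC; silently restricted to those present).
#' @param awcd optional `awcd_result` from [awcd_curve()]; adds one test per
#'   carbon-source category at the reference time.
#' @return tibble with `variable`, `type` (`env` or `awcd`), `rho`,
#'   `p.value`, `q.value`, `constant`.
#' @export
keystone_env_correlation <- function(abundance, meta,
                                     env_vars = c("pH", "OM", "TN", "TP", "TK", "MC"),
                                     awcd = NULL) {
  if (inherits(abundance, "keystone_report")) abundance <- abundance$abundance
  stopifnot(all(c("sample_id", "abundance") %in% names(abundance)))
  env_vars <- intersect(env_vars, names(meta))
  meta <- meta[match(abundance$sample_id, meta$sample_id), , drop = FALSE]
  rows <- purrr::map_dfr(env_vars, function(v) {
    ok <- complete.cases(abundance$abundance, meta[[v]])
    if (sum(ok) < 4) abort(sprintf("fewer than 4 complete observations for '%s'", v))
    st <- spearman_test(abundance$abundance[ok], meta[[v]][ok])
    tibble(variable = v, type = "env", rho = st[["rho"]], p.value = st[["p"]],
           constant = sd(meta[[v]][ok]) == 0)
  })
  if (!is.null(awcd)) {
    stopifnot(inherits(awcd, "awcd_result"))
    ref_time <- awcd$reference_time
    ref <- filter(awcd$curve, .data$time_h == ref_time,
                  .data$category != "overall")
    rows_a <- ref %>%
      group_by(.data$category) %>%
      dplyr::group_modify(function(d, key) {
        d <- d[match(abundance$sample_id, d$sample_id), ]
        st <- spearman_test(abundance$abundance, d$awcd)
        tibble(type = "awcd", rho = st[["rho"]], p.value = st[["p"]],
               constant = sd(d$awcd) == 0)
      }) %>%
      ungroup() %>%
      rename(variable = "category") %>%
      select("variable", "type", "rho", "p.value", "constant")
    rows <- bind_rows(rows, rows_a)
  }
  rows$q.value <- bh_adjust(rows$p.value)
  select(rows, "variable", "type", "rho", "p.value", "q.value", "constant")
}
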