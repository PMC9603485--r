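test_that("prevalence filter applies the strict more-than rule", {
  n <- 12
  m <- rbind(
    o_all = rep(1L, n),
    o_nine = c(rep(1L, 9), rep(0L, 3)),
    o_eight = c(rep(1L, 8), rep(0L, 4))
  )
  colnames(m) <- paste0("s", 1:n)
  tab <- otu_table(m)
  kept <- prevalence_filter(tab, 2 / 3)$otu_id
  expect_true("o_nine" %in% kept)       # 9/12 > 2/3
  expect_false("o_eight" %in% kept)     # exactly 2/3 is dropped
  expect_true("o_all" %in% kept)
  expect_true("o_all" %in% prevalence_filter(tab, 0.99)$otu_id)

  expect_warning(prevalence_filter(tab[3, ], 0.9), "removed every OTU")
  expect_error(prevalence_filter(tab, 0), "min_fraction")
})

test_that("Spearman all-pairs matches hand computation, handles ties and constants", {
  # a large constant "background" row keeps the compositional closure from
  # distorting the ranks of the pair under test
  mk <- function(...) {
    rows <- c(list(...), list(rep(100000L, length(..1))))
    m <- do.call(rbind, rows)
    rownames(m) <- paste0("o", seq_len(nrow(m)))
    colnames(m) <- paste0("s", seq_len(ncol(m)))
    otu_table(m)
  }
  sp <- spearman_all_pairs(mk(c(1L, 2L, 3L, 4L), c(10L, 20L, 30L, 40L)))
  expect_equal(sp$rho["o1", "o2"], 1)
  expect_equal(sp$p["o1", "o2"], 0)

  sp2 <- spearman_all_pairs(mk(c(1L, 2L, 3L, 4L), c(4L, 3L, 2L, 1L)))
  expect_equal(sp2$rho["o1", "o2"], -1)
  expect_equal(sp2$p["o1", "o2"], 0)

  # tied data vs the explicit mid-rank oracle (on relative abundances)
  x <- c(1L, 1L, 2L, 3L); y <- c(2L, 3L, 3L, 5L)
  tab <- mk(x, y, c(5L, 1L, 1L, 1L))
  ra <- otu_counts(relative_abundance(tab))
  sp3 <- spearman_all_pairs(tab)
  expect_equal(sp3$rho["o1", "o2"],
               spearman_midrank_oracle(ra["o1", ], ra["o2", ]),
               tolerance = 1e-12)

  # symmetry and unit diagonal
  expect_equal(sp3$rho, t(sp3$rho))
  expect_equal(unname(diag(sp3$rho)), rep(1, nrow(sp3$rho)))

  # proportional rows are constant after closure: rho 0, p 1, no NaN
  m <- rbind(o1 = c(1L, 2L, 3L, 4L), o2 = c(2L, 4L, 6L, 8L), o3 = c(1L, 2L, 3L, 4L))
  colnames(m) <- paste0("s", 1:4)
  spc <- spearman_all_pairs(otu_table(m))
  expect_equal(spc$rho["o1", "o2"], 0)
  expect_equal(unname(spc$p[upper.tri(spc$p)]), rep(1, 3))

  expect_error(spearman_all_pairs(mk(c(1L, 2L, 3L), c(3L, 2L, 1L))),
               "at least 4")
})

test_that("BH adjustment matches the step-up oracle and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0, 5)), rep(0, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  withr::with_seed(5, {
    for (i in 1:25) {
      p <- runif(sample(1:40, 1))
      q <- bh_adjust(p)
      expect_equal(q, bh_oracle(p), tolerance = 1e-14)
      expect_true(all(q >= p - 1e-15))            # never decreases a p-value
      expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in sorted order
    }
    # reapplication can only inflate further, and a fully tied adjusted
    # vector is a fixed point
    p <- sort(runif(20))
    expect_true(all(bh_adjust(bh_adjust(p)) >= bh_adjust(p) - 1e-15))
    tied <- rep(0.37, 6)
    expect_equal(bh_adjust(tied), tied)
  })
})

test_that("network edges obey the strict rho and q thresholds", {
  # o1/o2: identical ranks -> rho = 1, q = 0 -> edge
  # o3 vs o1: ranks (2,1,3,5,4) vs (1,2,3,4,5): rho = 0.8 exactly -> no edge
  # o4 is a heavy stable background so closure keeps the planted ranks
  m <- rbind(
    o1 = c(10L, 20L, 30L, 40L, 50L),
    o2 = c(11L, 22L, 33L, 44L, 55L),
    o3 = c(20L, 10L, 30L, 50L, 40L),
    o4 = rep(100000L, 5)
  )
  colnames(m) <- paste0("s", 1:5)
  net <- build_network(otu_table(m), r_threshold = 0.8, q_threshold = 0.05)
  sp <- spearman_all_pairs(otu_table(m))
  expect_equal(sp$rho["o1", "o3"], 0.8)
  pairs <- paste(net$edges$from, net$edges$to)
  expect_true("o1 o2" %in% pairs)
  expect_false(any(grepl("o3", pairs)))
  expect_equal(net$edges$sign[pairs == "o1 o2"], "+")
  # isolated node retained and flagged
  expect_true(net$nodes$isolated[net$nodes$otu_id == "o3"])

  # negative correlation keeps a "-" edge
  m2 <- rbind(o1 = c(1L, 2L, 3L, 4L, 5L), o2 = c(5L, 4L, 3L, 2L, 1L),
              o3 = c(7L, 8L, 9L, 10L, 11L))
  colnames(m2) <- paste0("s", 1:5)
  net2 <- build_network(otu_table(m2), q_threshold = 0.05)
  e12 <- net2$edges[net2$edges$from == "o1" & net2$edges$to == "o2", ]
  expect_equal(e12$sign, "-")
})

test_that("an independent community yields almost no edges under BH control", {
  # full-null simulation: any rejection at q < 0.01 has probability <= 0.01
  # per seed under BH, so seeds with edges are Binomial(50, <=0.01)
  seeds_with_edges <- sum(vapply(1:50, function(s) {
    m <- withr::with_seed(s, matrix(rpois(30 * 24, 50), nrow = 30))
    rownames(m) <- paste0("o", 1:30); colnames(m) <- paste0("s", 1:24)
    nrow(build_network(otu_table(m))$edges) > 0
  }, logical(1)))
  expect_lte(seeds_with_edges, qbinom(0.999, 50, 0.01) + 1)
})

test_that("network construction is invariant to row and column order", {
  withr::with_seed(21, {
    m <- matrix(rpois(8 * 12, 60), nrow = 8)
    # plant one strong pair
    m[2, ] <- m[1, ] + rpois(12, 2)
    rownames(m) <- paste0("o", 1:8); colnames(m) <- paste0("s", 1:12)
    net <- build_network(otu_table(m), r_threshold = 0.7, q_threshold = 0.1)
    perm_r <- sample(nrow(m)); perm_c <- sample(ncol(m))
    net2 <- build_network(otu_table(m[perm_r, perm_c]),
                          r_threshold = 0.7, q_threshold = 0.1)
    key <- function(nw) {
      e <- nw$edges
      sort(paste(pmin(e$from, e$to), pmax(e$from, e$to), round(e$rho, 10)))
    }
    expect_equal(key(net2), key(net))
  })
})

test_that("modularity matches closed forms and the exhaustive oracle", {
  # any connected graph, one module -> Q = 0
  tri2 <- make_net(rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
  one <- stats::setNames(rep(1, 6), paste0("n", 1:6))
  expect_equal(modularity_q(tri2, one), 0)

  # two disjoint triangles, natural split -> Q = 1/2
  nat <- stats::setNames(c(1, 1, 1, 2, 2, 2), paste0("n", 1:6))
  expect_equal(modularity_q(tri2, nat), 0.5)

  # random graphs <= 7 nodes: every partition agrees with the adjacency
  # oracle to 1e-12, and with igraph
  withr::with_seed(7, {
    for (rep in 1:10) {
      n <- sample(4:7, 1)
      net <- make_net(random_edges(n), n_nodes = n)
      adj <- net_adjacency(net)
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      parts <- all_set_partitions(n)
      for (p in parts[seq(1, length(parts), by = 7)]) {
        mem <- stats::setNames(p, paste0("n", seq_len(n)))
        q <- modularity_q(net, mem)
        expect_equal(q, modularity_adjacency_oracle(adj, p), tolerance = 1e-12)
        expect_equal(q, igraph::modularity(g, p), tolerance = 1e-12)
      }
    }
  })

  expect_error(modularity_q(tri2, stats::setNames(1, "n1")), "missing from partition")
})

test_that("greedy module detection recovers planted structure deterministically", {
  tri2 <- make_net(rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6)))
  part <- detect_modules(tri2)
  expect_equal(part$modularity, 0.5)
  expect_equal(part$n_modules, 2L)
  mem <- part$membership
  expect_equal(length(unique(mem$module[1:3])), 1L)
  expect_equal(length(unique(mem$module[4:6])), 1L)
  expect_false(mem$module[1] == mem$module[4])
  expect_equal(sort(unique(mem$module)), c(0L, 1L))

  # edgeless network: every node a singleton, Q = 0
  lonely <- co_network(tibble::tibble(from = character(), to = character()),
                       nodes = tibble::tibble(otu_id = paste0("n", 1:4)))
  p0 <- detect_modules(lonely)
  expect_equal(p0$n_modules, 4L)
  expect_equal(p0$modularity, 0)

  # determinism
  expect_identical(detect_modules(tri2), detect_modules(tri2))
})

test_that("detected modularity is near the exhaustive maximum on small graphs", {
  withr::with_seed(13, {
    for (rep in 1:8) {
      n <- sample(5:8, 1)
      net <- make_net(random_edges(n, p = 0.35), n_nodes = n)
      parts <- all_set_partitions(n)
      best <- max(vapply(parts, function(p) {
        modularity_q(net, stats::setNames(p, paste0("n", seq_len(n))))
      }, numeric(1)))
      got <- detect_modules(net)$modularity
      expect_gte(got, 0.95 * best - 1e-12)
    }
  })
})

test_that("modularity of random partitions of a random graph concentrates near zero", {
  withr::with_seed(31, {
    g <- igraph::sample_gnp(200, 0.03)
    el <- igraph::as_edgelist(g)
    net <- make_net(el, n_nodes = 200)
    mem <- stats::setNames(sample(1:4, 200, TRUE), paste0("n", 1:200))
    q <- modularity_q(net, mem)
    expect_lt(abs(q), 0.1)
    expect_gte(q, -0.5)
    expect_lt(q, 1)
  })
})

test_that("graph exports round-trip through igraph", {
  tri2 <- make_net(rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5)))
  part <- detect_modules(tri2)
  tp <- zi_pi(tri2, part)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(tri2, gml, topology = tp)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), 5)
  expect_equal(igraph::gsize(g), 4)
  expect_true("module" %in% igraph::vertex_attr_names(g))

  csvp <- withr::local_tempfile(fileext = ".csv")
  write_edge_list(tri2, csvp)
  el <- readr::read_csv(csvp, show_col_types = FALSE)
  expect_equal(nrow(el), 4)
  expect_true(all(c("source", "target", "rho", "sign") %in% names(el)))
})
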