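# 9-node fixture: module A = n1..n5, module B = n6..n9.
# Edges: 1-2 1-3 1-4 1-5 2-3 | 6-7 6-8 7-8 8-9 | bridges 5-6 1-6.
zipi_fixture <- function() {
  net <- make_net(rbind(
    c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(2, 3),
    c(6, 7), c(6, 8), c(7, 8), c(8, 9),
    c(5, 6), c(1, 6)
  ))
  mem <- tibble::tibble(otu_id = paste0("n", 1:9),
                        module = c(rep(0L, 5), rep(1L, 4)))
  list(net = net, mem = mem)
}

test_that("Zi and Pi reproduce the hand-tabulated 9-node fixture", {
  fx <- zipi_fixture()
  tp <- zi_pi(fx$net, fx$mem)

  # hand arithmetic: module A kappa = (4,2,2,1,1), mean 2, pop sd sqrt(1.2);
  # module B kappa = (2,2,3,1), mean 2, pop sd sqrt(0.5)
  sA <- sqrt(1.2); sB <- sqrt(0.5)
  expected_zi <- c(2 / sA, 0, 0, -1 / sA, -1 / sA, 0, 0, 1 / sB, -1 / sB)
  expected_pi <- c(1 - (16 + 1) / 25, 0, 0, 0, 0.5, 0.5, 0, 0, 0)
  expected_k <- c(5L, 2L, 2L, 1L, 2L, 4L, 2L, 3L, 1L)

  expect_equal(tp$zi, expected_zi, tolerance = 1e-12)
  expect_equal(tp$pi, expected_pi, tolerance = 1e-12)
  expect_equal(tp$degree, expected_k)
  expect_equal(tp$within_module_degree, c(4L, 2L, 2L, 1L, 1L, 2L, 2L, 3L, 1L))
  expect_equal(unique(tp$role), "peripheral")

  # within-module mean of Zi is 0 wherever sd > 0
  expect_equal(mean(tp$zi[1:5]), 0, tolerance = 1e-12)
  expect_equal(mean(tp$zi[6:9]), 0, tolerance = 1e-12)
})

test_that("Pi respects the degree-partition identity and closed forms", {
  # node with all edges inside its own module -> Pi = 0
  star <- make_net(rbind(c(1, 2), c(1, 3), c(1, 4)))
  mem1 <- tibble::tibble(otu_id = paste0("n", 1:4), module = 0L)
  expect_equal(zi_pi(star, mem1)$pi, rep(0, 4))

  # degree 4 split 2/2 across two modules -> Pi = 1 - 2 (1/2)^2 = 0.5
  cross <- make_net(rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))
  mem2 <- tibble::tibble(otu_id = paste0("n", 1:5),
                         module = c(0L, 0L, 0L, 1L, 1L))
  expect_equal(zi_pi(cross, mem2)$pi[1], 0.5)

  # partition of degree: Pi <= 1 - 1/M for any node
  fx <- zipi_fixture()
  tp <- zi_pi(fx$net, fx$mem)
  expect_true(all(tp$pi <= 1 - 1 / 2 + 1e-12))
  expect_true(all(tp$pi >= 0))
})

test_that("role classification covers the plane with the stated boundaries", {
  expect_equal(classify_role(3.0, 0.30), "module_hub")
  expect_equal(classify_role(1.0, 0.70), "connector")
  expect_equal(classify_role(1.0, 0.30), "peripheral")
  expect_equal(classify_role(3.0, 0.70), "network_hub")
  # boundary values fall on the non-keystone side
  expect_equal(classify_role(2.5, 0.30), "peripheral")
  expect_equal(classify_role(1.0, 0.62), "peripheral")
  expect_equal(classify_role(2.5, 0.62), "peripheral")
  # exactly one role for any (zi, pi)
  withr::with_seed(3, {
    zi <- runif(200, -4, 4); pi <- runif(200, 0, 1)
    roles <- classify_role(zi, pi)
    expect_true(all(roles %in% c("module_hub", "connector", "network_hub",
                                 "peripheral")))
    # keystone set is the union of the three hub-ish roles
    expect_equal(is_keystone(roles),
                 (zi > 2.5 & pi <= 0.62) | (zi <= 2.5 & pi > 0.62) |
                   (zi > 2.5 & pi > 0.62))
  })
})

test_that("keystone report intersects keystone sets across groups", {
  tp1 <- tibble::tibble(otu_id = c("a", "b", "c"), module = 0L,
                        degree = 3L, within_module_degree = 3L,
                        zi = c(3, 3, 0), pi = c(0.2, 0.2, 0.2),
                        role = c("module_hub", "module_hub", "peripheral"))
  tp2 <- dplyr::mutate(tp1, role = c("module_hub", "peripheral", "peripheral"))
  m <- matrix(c(4L, 6L, 2L, 8L, 6L, 4L), nrow = 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  tab <- otu_table(m)
  meta <- make_meta(c("s1", "s2"), c("HMs", "HMe"))

  # identical sets -> shared equals either; disjoint -> empty
  r_same <- keystone_report(list(g1 = tp1, g2 = tp1), tab, meta)
  expect_setequal(r_same$shared, c("a", "b"))
  expect_equal(r_same$pooled_n, 2L)

  tp3 <- dplyr::mutate(tp1, role = c("peripheral", "peripheral", "connector"))
  r_disj <- keystone_report(list(g1 = tp2, g2 = tp3), tab, meta)
  expect_equal(length(r_disj$shared), 0L)
  expect_equal(r_disj$pooled_n, 2L)
  expect_equal(sort(r_disj$counts$n_keystone), c(1L, 1L))

  # abundance of the pooled set is the summed relative abundance per sample
  expect_equal(r_disj$abundance$abundance,
               c((4 + 2) / 12, (8 + 4) / 18))
})

test_that("removal stability contracts: empty set, determinism, connector removal", {
  # two triangles joined through one connector node n7
  net <- make_net(rbind(
    c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6),
    c(7, 1), c(7, 4)
  ))
  rs0 <- removal_stability(net, character(0), n_null = 99, seed = 5)
  expect_equal(rs0$q_after, rs0$q_before)
  expect_equal(rs0$p_value, 1)

  rs1 <- removal_stability(net, "n7", n_null = 99, seed = 5)
  rs2 <- removal_stability(net, "n7", n_null = 99, seed = 5)
  expect_identical(rs1$null_q, rs2$null_q)      # bit-identical null
  expect_false(identical(rs1$null_q,
                         removal_stability(net, "n7", n_null = 99, seed = 6)$null_q))

  # after removing the connector the remnant is two disjoint triangles whose
  # exhaustive-maximum modularity is 1/2; the detected Q must equal it
  remnant_best <- 0.5
  expect_equal(rs1$q_after, remnant_best, tolerance = 1e-12)

  expect_error(removal_stability(net, paste0("n", 1:7), n_null = 99, seed = 1),
               "entire node set")
  expect_error(removal_stability(net, "n7", n_null = 10, seed = 1),
               "at least 99")
  expect_error(removal_stability(net, "nope", n_null = 99, seed = 1),
               "not in the network")
})

test_that("random removals give approximately uniform empirical p-values", {
  # under the null hypothesis (keystones chosen at random) the empirical p
  # of the removal test is approximately uniform; KS test at alpha = 0.01.
  # A 24-node random graph keeps post-removal Q values effectively
  # continuous, so ties do not distort the uniformity.
  net <- withr::with_seed(8, make_net(random_edges(24, p = 0.18), n_nodes = 24))
  ids <- net$nodes$otu_id
  ps <- withr::with_seed(17, {
    vapply(1:200, function(i) {
      removal_stability(net, sample(ids, 3), n_null = 99,
                        seed = sample.int(1e6, 1))$p_value
    }, numeric(1))
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("keystone-environment correlations reuse the Spearman machinery", {
  ab <- tibble::tibble(sample_id = paste0("s", 1:8),
                       abundance = c(0.1, 0.3, 0.2, 0.5, 0.4, 0.6, 0.8, 0.7))
  meta <- make_meta(ab$sample_id, rep("HMs", 8))
  meta$pH <- ab$abundance            # identical -> rho 1
  meta$OM <- -rank(ab$abundance)     # negated ranks -> rho -1
  meta$TN <- rep(3, 8)               # constant -> flagged
  res <- keystone_env_correlation(ab, meta, env_vars = c("pH", "OM", "TN"))
  expect_equal(res$rho[res$variable == "pH"], 1)
  expect_equal(res$rho[res$variable == "OM"], -1)
  expect_equal(res$rho[res$variable == "TN"], 0)
  expect_equal(res$p.value[res$variable == "TN"], 1)
  expect_true(res$constant[res$variable == "TN"])
  expect_equal(res$q.value, bh_oracle(res$p.value))
})

test_that("planted environmental coupling is recovered with high power", {
  # strong-signal generator defaults couple OM positively (and pH
  # negatively) to the hub abundance; q < 0.05 for OM in >= 90% of seeds
  hits <- vapply(1:50, function(s) {
    cfg <- sim_config(seed = s, n_taxa = 120, taxa_per_module = 10)
    b <- generate_community(cfg)
    ab <- taxon_set_abundance(b$table, b$truth$hubs$otu_id)
    res <- keystone_env_correlation(ab, b$metadata)
    om <- res[res$variable == "OM", ]
    om$rho > 0 && om$q.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
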