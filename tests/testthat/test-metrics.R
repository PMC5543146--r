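test_that("assortativity matches hand calculations and degenerate cases", {
  expect_equal(assortativity_degree_total(star_exporter(3)), -1)
  expect_true(is.na(assortativity_degree_total(directed_cycle(4)))) # zero variance
  expect_true(is.na(assortativity_degree_total(net_with_edges(3, list(c(1, 2))))))

  # two-community 6-node graph, hand-computed over symmetrized endpoint pairs
  net <- net_with_edges(6, list(c(2, 1), c(3, 1), c(2, 3), c(5, 4), c(6, 4)))
  d <- total_degree(net) # 2,2,2,2,1,1
  ed <- net$edges
  x <- c(d[ed[, 1]], d[ed[, 2]])
  y <- c(d[ed[, 2]], d[ed[, 1]])
  expect_equal(assortativity_degree_total(net), stats::cor(x, y))
  expect_equal(assortativity_degree_total(net), -0.25) # hand value
})

test_that("average path length averages finite directed distances only", {
  expect_equal(average_path_length(directed_cycle(2)), 1)
  expect_equal(average_path_length(net_with_edges(3, list(c(2, 1), c(3, 2)))), 4 / 3)
  expect_equal(average_path_length(complete_directed(4)), 1)
  expect_true(is.na(average_path_length(trade_network(3))))
})

test_that("average clustering is the mean local coefficient on the projection", {
  triangle <- net_with_edges(3, list(c(2, 1), c(3, 2), c(1, 3)))
  expect_equal(average_clustering(triangle), 1)
  expect_equal(average_clustering(star_exporter(3)), 0)
  # triangle plus pendant: locals 1/3, 1, 1 over the three eligible nodes
  tp <- net_with_edges(4, list(c(2, 1), c(3, 2), c(1, 3), c(4, 1)))
  expect_equal(average_clustering(tp), 7 / 9)
})

test_that("giant component sizes follow the standard SCC/WCC definitions", {
  expect_equal(giant_components(directed_cycle(3)), c(gsc = 3, gwc = 3))
  path3 <- net_with_edges(3, list(c(2, 1), c(3, 2)))
  expect_equal(giant_components(path3), c(gsc = 1, gwc = 3))
  two_cycles <- net_with_edges(4, list(c(1, 2), c(2, 1), c(3, 4), c(4, 3)))
  expect_equal(giant_components(two_cycles), c(gsc = 2, gwc = 2))
  expect_equal(giant_components(trade_network(5)), c(gsc = 0, gwc = 0))
})

test_that("density uses active nodes in the denominator", {
  expect_equal(network_density(complete_directed(4)), 1)
  expect_equal(network_density(net_with_edges(10, list(c(1, 2)))), 1 / 2)
  expect_true(is.na(network_density(trade_network(10))))
  # at the empirical 2013 scale: 363 edges over 108 active countries
  set.seed(20)
  net <- trade_network(244)
  # ring over 108 nodes guarantees exactly 108 active, then random fill to 363
  for (i in 1:108) add_edge(net, i %% 108 + 1, i)
  while (net$m < 363) {
    i <- sample.int(108, 2)
    if (!net$adj[i[1], i[2]]) add_edge(net, i[1], i[2])
  }
  expect_equal(network_density(net), 363 / (108 * 107))
})

test_that("symmetry correlates in- with out-degree across active nodes", {
  expect_equal(degree_symmetry(reciprocal_star(3)), 1)
  expect_true(is.na(degree_symmetry(directed_cycle(4)))) # constant vectors
  # exporters-only -> importers-only bipartite graph with varying degrees
  bip <- net_with_edges(6, list(c(4, 1), c(5, 1), c(6, 1), c(4, 2), c(5, 2), c(4, 3)))
  expect_lt(degree_symmetry(bip), 0)
  act <- active_nodes(bip)
  expect_equal(degree_symmetry(bip), stats::cor(bip$in_deg[act], bip$out_deg[act]))
})

test_that("heterogeneity is the degree coefficient of variation, scale-invariant", {
  expect_equal(degree_heterogeneity(directed_cycle(5)), c(cv_in = 0, cv_out = 0))
  st <- star_exporter(3) # out-degrees 3,0,0,0 over 4 active nodes
  outs <- c(3, 0, 0, 0)
  expect_equal(degree_heterogeneity(st)[["cv_out"]],
               sqrt(mean((outs - 0.75)^2)) / 0.75)
  # disjoint copies leave the CV unchanged
  one <- net_with_edges(8, list(c(2, 1), c(3, 1), c(2, 3)))
  two <- net_with_edges(8, list(c(2, 1), c(3, 1), c(2, 3), c(6, 5), c(7, 5), c(6, 7)))
  expect_equal(degree_heterogeneity(one), degree_heterogeneity(two))
})

test_that("degree-fit testing is gated on network size", {
  small <- complete_directed(5)
  res <- degree_distribution_fit(small)
  expect_true(res$gated)
  expect_equal(res$n, 5)
})

test_that("the exponential-decay test keeps its level under the matching null", {
  set.seed(21)
  kbar <- 6
  p_geom <- 1 - exp(-1 / kbar) # the discretised-exponential null itself
  rejections <- vapply(1:20, function(r) {
    d <- 1 + stats::rgeom(500, p_geom)
    wheatnet:::fit_exponential_ks(d, n_boot = 100)$p < 0.05
  }, TRUE)
  expect_gte(mean(!rejections), 0.9)
})

test_that("the exponential-decay test rejects heavy-tailed Zipf degrees", {
  set.seed(22)
  zipf <- function(n) sample(1:2000, n, replace = TRUE, prob = (1:2000)^-2.2)
  rejections <- vapply(1:10, function(r) {
    wheatnet:::fit_exponential_ks(zipf(500), n_boot = 100)$p < 0.05
  }, TRUE)
  expect_gt(mean(rejections), 0.5)
  # and the power-law bootstrap does not reject its own null here
  set.seed(23)
  pl <- wheatnet:::fit_powerlaw_ks(zipf(500), n_boot = 60)
  expect_gt(pl$p, 0.05)
})

test_that("metric ranges and component ordering hold over random networks", {
  set.seed(24)
  for (rep in 1:15) {
    net <- random_net(sample(5:30, 1), sample(4:60, 1))
    rec <- network_metrics(net, year = 2000)
    expect_lte(rec$gsc_size, rec$gwc_size)
    expect_lte(rec$gwc_size, rec$n_nodes)
    for (cl in c("reciprocity", "acc", "density")) {
      if (!is.na(rec[[cl]])) {
        expect_gte(rec[[cl]], 0); expect_lte(rec[[cl]], 1)
      }
    }
    for (cl in c("assortativity", "symmetry")) {
      if (!is.na(rec[[cl]])) {
        expect_gte(rec[[cl]], -1); expect_lte(rec[[cl]], 1)
      }
    }
    if (!is.na(rec$apl)) expect_gte(rec$apl, 1)
  }
})

test_that("metrics are invariant under node relabelling", {
  set.seed(25)
  net <- random_net(12, 25)
  perm <- sample.int(12)
  relab <- trade_network(12)
  for (k in seq_len(net$m)) add_edge(relab, perm[net$edges[k, 1]], perm[net$edges[k, 2]])
  a <- network_metrics(net, 2000)
  b <- network_metrics(relab, 2000)
  expect_equal(a, b, tolerance = 1e-12)
})
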