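test_that("trade probability follows the saturating fitness-product form", {
  p <- growth_params(0.5, 1, 0.01)
  expect_equal(trade_probability(0, 0, p), 0.01) # zero-fitness limit is epsilon
  expect_equal(trade_probability(0.2, 0.3, p), 0.04 / 1.06)
  p0 <- growth_params(0.5, 0, 0)
  expect_equal(trade_probability(0.4, 0.5, p0), 0.5 * 0.4 * 0.5) # beta = 0 linearises
})

test_that("parameter validity is enforced at construction", {
  expect_error(growth_params(2, 0, 0.5), "P_t")   # alpha + eps > 1 at z = 1
  expect_error(growth_params(0.5, 1, 1.5), "epsilon")
  expect_error(growth_params(0.5, 1, -0.1), "epsilon")
  expect_error(growth_params(-1, 1, 0.1))
  expect_silent(growth_params(2, 1.5, 0.5))       # (2 + 0.5)/(1 + 1.5) = 1 is allowed
})

test_that("candidate events fail legally on saturated, banned or zero-probability pairs", {
  p0 <- growth_params(0.5, 1, 0) # epsilon = 0
  net <- trade_network(4)
  set.seed(1)
  for (k in 1:50) expect_null(attempt_edge_event(net, p0)) # all-zero fitness, P = 0
  expect_equal(net$m, 0L)

  # banned exporters never export
  p <- growth_params(0.5, 1, 0.5)
  net <- trade_network(3)
  set.seed(2)
  for (k in 1:200) attempt_edge_event(net, p, banned = 3L)
  expect_equal(net$out_deg[3], 0L)
  expect_gt(net$m, 0L)
})

test_that("growing one edge stalls with a diagnostic when nothing is acceptable", {
  p0 <- growth_params(0.5, 1, 0)
  net <- trade_network(4)
  set.seed(1)
  expect_error(grow_one_edge(net, p0, max_attempts = 2000), "stalled")

  # a single admissible pair is eventually found
  net <- complete_directed(3)
  wheatnet:::remove_out_edges(net, 3) # absent: (1,3) and (2,3)
  add_edge(net, 1, 3)
  p <- growth_params(0.1, 1, 0.01)
  set.seed(3)
  e <- grow_one_edge(net, p)
  expect_equal(unname(e), c(2L, 3L))
})

test_that("first-edge distribution matches brute-force enumeration on a 5-node pool", {
  base <- net_with_edges(5, list(c(1, 2), c(2, 1), c(1, 3)))
  p <- growth_params(0.5, 1, 0.01)
  probs <- enumerate_first_edge_probs(base, p)
  n_draw <- 20000
  set.seed(11)
  counts <- matrix(0, 5, 5)
  for (k in seq_len(n_draw)) {
    net <- net_copy(base)
    e <- grow_one_edge(net, p)
    counts[e[1], e[2]] <- counts[e[1], e[2]] + 1
  }
  keep <- probs > 0
  expect_equal(sum(counts[!keep]), 0)
  chi <- stats::chisq.test(counts[keep], p = probs[keep])
  expect_gt(chi$p.value, 0.01)
})

test_that("rewiring budget decays exponentially with stochastic rounding", {
  p <- growth_params(0.1, 1, 0.01, C = 100, lam = 0.01)
  expect_equal(rewiring_budget(0, p), 100L) # integer expectation, no rounding
  set.seed(4)
  draws <- replicate(4000, rewiring_budget(100, p))
  expect_true(all(draws %in% c(36L, 37L)))
  expect_equal(mean(draws), 100 * exp(-1), tolerance = 0.005)
  p_flat <- growth_params(0.1, 1, 0.01, C = 5, lam = 0)
  expect_true(all(replicate(50, rewiring_budget(1e4, p_flat)) == 5L))
})

test_that("Maslov-Sneppen attempts preserve every in- and out-degree bit-identically", {
  # hand case: disjoint endpoints always swap
  net <- net_with_edges(4, list(c(1, 2), c(3, 4)))
  set.seed(5)
  expect_true(ms_rewire_attempt(net))
  expect_true(has_edge(net, 1, 4) && has_edge(net, 3, 2))

  # reciprocal pair: the only swap proposals create self-loops
  net <- net_with_edges(2, list(c(1, 2), c(2, 1)))
  expect_false(ms_rewire_attempt(net))
  expect_true(has_edge(net, 1, 2) && has_edge(net, 2, 1))

  expect_false(ms_rewire_attempt(net_with_edges(3, list(c(1, 2))))) # m < 2 no-op

  set.seed(6)
  for (rep in 1:10) {
    net <- random_net(15, 40)
    ind <- net$in_deg; outd <- net$out_deg
    for (k in 1:200) ms_rewire_attempt(net)
    expect_identical(net$in_deg, ind)
    expect_identical(net$out_deg, outd)
    expect_equal(sum(net$adj), 40) # edges stay unique, none lost
    expect_true(all(!diag(net$adj)))
  }
})

test_that("growth hits every yearly edge target exactly and is reproducible", {
  p <- growth_params(20, 30, 0.01, C = 10, lam = 0.05)
  sch <- growth_schedule(2001:2005, c(5, 10, 20, 35, 50))
  r1 <- run_growth(p, sch, pool = 40, seed = 7)
  expect_equal(r1$metrics$m, sch$edges)
  expect_equal(r1$metrics$year, sch$year)
  r2 <- run_growth(p, sch, pool = 40, seed = 7)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$network$adj, r2$network$adj)

  # constant schedule: nothing grows, metrics constant
  sch_const <- growth_schedule(2001:2003, c(8, 8, 8))
  rc <- run_growth(p, sch_const, pool = 40, seed = 8)
  expect_equal(rc$metrics$m, rep(8L, 3))
  expect_equal(rc$metrics$n_nodes, rep(rc$metrics$n_nodes[1], 3))
})

test_that("with epsilon = 0 inactive nodes can never activate", {
  p <- growth_params(50, 100, 0) # P = 0 whenever either fitness is 0
  net <- net_with_edges(10, list(c(1, 2), c(2, 1), c(1, 3), c(3, 2)))
  sch <- growth_schedule(2001:2002, c(5, 6)) # 6 = saturation of the active triangle
  set.seed(9)
  r <- run_growth(p, sch, pool = 244, net = net, record = "fitting")
  expect_equal(r$metrics$n_nodes[2], 3) # only nodes 1..3 ever trade
})

test_that("rewiring vanishes once the expected budget decays away", {
  p <- growth_params(100, 200, 0.01, C = 20, lam = 0.5) # decays within ~30 edges
  sch <- growth_schedule(2001:2002, c(40, 80))
  r <- run_growth(p, sch, pool = 60, seed = 10, instrument = TRUE, record = "none")
  # expected total attempts beyond m = 40: sum C e^(-lam m) < 20 * e^-20 / lam, ~ 0
  expect_equal(unname(r$rewires["2002"]), 0L)
  expect_gt(unname(r$rewires["2001"]), 0L)
})

test_that("more baseline probability activates more countries on average", {
  sch <- growth_schedule(2001:2003, c(30, 60, 90))
  n_active <- vapply(c(0.001, 0.05), function(eps) {
    p <- growth_params(20, 30, eps)
    mean(vapply(1:8, function(r) {
      run_growth(p, sch, pool = 100, seed = 100 + r, record = "fitting")$metrics$n_nodes[3]
    }, 0))
  }, 0)
  expect_lt(n_active[1], n_active[2])
})
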