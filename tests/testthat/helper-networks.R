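# Small constructed networks used across tests.

net_with_edges <- function(n, edges) {
  net <- trade_network(n)
  for (e in edges) add_edge(net, e[1], e[2])
  net
}

# hub exports to k leaves
star_exporter <- function(k = 3) {
  net_with_edges(k + 1, lapply(seq_len(k) + 1L, function(leaf) c(leaf, 1L)))
}

# hub <-> leaves in both directions
reciprocal_star <- function(k = 3) {
  net <- trade_network(k + 1)
  for (leaf in seq_len(k) + 1L) {
    add_edge(net, leaf, 1L)
    add_edge(net, 1L, leaf)
  }
  net
}

directed_cycle <- function(k) {
  net_with_edges(k, lapply(seq_len(k), function(i) c(i %% k + 1L, i)))
}

complete_directed <- function(k) {
  net <- trade_network(k)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) add_edge(net, i, j)
  net
}

# uniformly random directed graph with m edges on n nodes
random_net <- function(n, m) {
  net <- trade_network(n)
  all_pairs <- which(diag(n) == 0)
  picks <- sample(all_pairs, min(m, length(all_pairs)))
  for (k in picks) {
    add_edge(net, (k - 1L) %% n + 1L, (k - 1L) %/% n + 1L)
  }
  net
}

# exact distribution of the first accepted edge over admissible ordered pairs
# (uniform pair draw times acceptance probability, renormalised) -- the
# brute-force oracle for grow_one_edge
enumerate_first_edge_probs <- function(net, params) {
  x <- fitness(net)
  probs <- matrix(0, net$n, net$n)
  for (i in seq_len(net$n)) {
    for (j in seq_len(net$n)) {
      if (i != j && !net$adj[i, j]) {
        probs[i, j] <- trade_probability(x[i], x[j], params)
      }
    }
  }
  probs / sum(probs)
}

toy_table_path <- function() {
  system.file("extdata", "toy-trade-synthetic.csv", package = "wheatnet")
}
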