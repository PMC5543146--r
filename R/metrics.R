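#' Degree assortativity
#'
#' Pearson degree-degree correlation over edges, computed on total degree
#' (the model's fitness currency) with each directed edge contributing its
#' endpoint pair in both orientations (Newman's formulation). Negative values
#' indicate a disassortative network in which hubs attach to low-degree
#' nodes.
#'
#' @param net A [trade_network()].
#' @return Correlation in [-1, 1]; `NA` when fewer than 2 edges or the
#'   endpoint degrees have zero variance (e.g. a directed cycle).
#' @export
assortativity_degree_total <- function(net) {
  if (net$m < 2L) return(NA_real_)
  d <- total_degree(net)
  a <- d[net$edges[, 1L]]
  b <- d[net$edges[, 2L]]
  x <- c(a, b)
  y <- c(b, a)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Average directed shortest-path length
#'
#' Mean of the directed shortest-path lengths over all ordered pairs of
#' active nodes with a finite distance; unreachable pairs are dropped rather
#' than imputed, the only convention that stays finite on the fragmented
#' networks of early growth.
#'
#' @param net A [trade_network()].
#' @return Mean hops (>= 1); `NA` if no finite pair exists.
#' @export
average_path_length <- function(net) {
  if (net$m == 0L) return(NA_real_)
  v <- igraph::mean_distance(as_igraph(net), directed = TRUE, unconnected = TRUE)
  if (is.nan(v)) NA_real_ else v
}

#' Average local clustering coefficient
#'
#' Local clustering is computed on the undirected projection of the network
#' and averaged over nodes with projected degree >= 2 (nodes with fewer
#' neighbours have no defined local coefficient).
#'
#' @param net A [trade_network()].
#' @return Mean local clustering in [0, 1]; `NA` when no eligible node.
#' @export
average_clustering <- function(net) {
  if (net$m == 0L) return(NA_real_)
  g <- igraph::as_undirected(as_igraph(net), mode = "collapse")
  deg <- igraph::degree(g)
  if (!any(deg >= 2)) return(NA_real_)
  loc <- igraph::transitivity(g, type = "local")
  mean(loc[deg >= 2])
}

#' Giant strongly and weakly connected component sizes
#'
#' In a directed network the largest strongly connected component (GSC, all
#' nodes mutually reachable) and the largest weakly connected component (GWC,
#' connected ignoring direction) bound from below and above the maximum reach
#' of a shock starting inside the giant component.
#'
#' @param net A [trade_network()].
#' @return Named numeric vector `c(gsc = ..., gwc = ...)` of node counts;
#'   `c(0, 0)` for an empty network.
#' @export
giant_components <- function(net) {
  if (net$m == 0L) return(c(gsc = 0, gwc = 0))
  g <- as_igraph(net)
  c(
    gsc = max(igraph::components(g, mode = "strong")$csize),
    gwc = max(igraph::components(g, mode = "weak")$csize)
  )
}

#' Network density over active nodes
#'
#' Fraction of the maximum possible number of directed links among the
#' currently active nodes: m / (n_active * (n_active - 1)). The isolated
#' members of the fixed 244-country pool are excluded from the denominator.
#'
#' @param net A [trade_network()].
#' @return Fraction in [0, 1]; `NA` with fewer than 2 active nodes.
#' @export
network_density <- function(net) {
  na <- length(active_nodes(net))
  if (na < 2L) return(NA_real_)
  net$m / (na * (na - 1))
}

#' In/out-degree symmetry
#'
#' Pearson correlation between in-degree and out-degree across active nodes:
#' the extent to which big importers are also big exporters.
#'
#' @param net A [trade_network()].
#' @return Correlation in [-1, 1]; `NA` when either degree vector has zero
#'   variance over the active nodes.
#' @export
degree_symmetry <- function(net) {
  act <- active_nodes(net)
  if (length(act) < 2L) return(NA_real_)
  ind <- net$in_deg[act]
  outd <- net$out_deg[act]
  if (stats::sd(ind) == 0 || stats::sd(outd) == 0) return(NA_real_)
  stats::cor(ind, outd)
}

#' In/out-degree heterogeneity
#'
#' Coefficient of variation (population standard deviation / mean) of the
#' in- and out-degree distributions over active nodes. Zero for
#' degree-regular networks; large for skewed, hub-dominated networks. The
#' population moment makes the measure exactly invariant under disjoint
#' replication of the network.
#'
#' @param net A [trade_network()].
#' @return Named vector `c(cv_in = ..., cv_out = ...)`; `NA` entries when the
#'   corresponding mean degree is zero or fewer than 2 nodes are active.
#' @export
degree_heterogeneity <- function(net) {
  act <- active_nodes(net)
  if (length(act) < 2L) return(c(cv_in = NA_real_, cv_out = NA_real_))
  cv <- function(v) {
    if (mean(v) == 0) return(NA_real_)
    sqrt(mean((v - mean(v))^2)) / mean(v)
  }
  c(cv_in = cv(net$in_deg[act]), cv_out = cv(net$out_deg[act]))
}

#' Degree-distribution shape tests
#'
#' Tests whether the total-degree distribution of the active nodes is
#' consistent with (a) a power law and (b) an exponential decay law with rate
#' fixed to the reciprocal of the mean degree. Both tests use the
#' Kolmogorov-Smirnov distance with Monte-Carlo p-values, since degrees are
#' discrete: the power-law fit is by maximum likelihood with xmin selection
#' and a semi-parametric bootstrap (resample below xmin, simulate the fitted
#' tail above); the exponential null is the discretised exponential
#' distribution P(k) proportional to exp(-k/mean_k) on k >= 1 with a
#' parametric bootstrap. The KS machinery is unreliable below roughly 100
#' nodes, so smaller networks return a gated empty result.
#'
#' @param net A [trade_network()].
#' @param n_boot Bootstrap replicates per test (default 200).
#' @param min_nodes Gate on active-node count (default 100, exclusive).
#' @return A list with `n`, `gated`, and when not gated: `ks_powerlaw`,
#'   `powerlaw_p`, `powerlaw_rejected`, `fitted_exponent`, `ks_exponential`,
#'   `exponential_p`, `exponential_rejected`, `fitted_rate` (all at the 5%
#'   level).
#' @export
degree_distribution_fit <- function(net, n_boot = 200L, min_nodes = 100L) {
  act <- active_nodes(net)
  n <- length(act)
  if (n <= min_nodes) {
    return(list(n = n, gated = TRUE,
                reason = sprintf("KS-based fits are unreliable at <= %d nodes", min_nodes)))
  }
  d <- total_degree(net)[act]
  if (stats::sd(d) == 0) return(list(n = n, gated = TRUE, reason = "degenerate degree vector"))
  pl <- fit_powerlaw_ks(d, n_boot = n_boot)
  ex <- fit_exponential_ks(d, n_boot = n_boot)
  list(
    n = n, gated = FALSE,
    ks_powerlaw = pl$ks, powerlaw_p = pl$p, powerlaw_rejected = pl$p < 0.05,
    fitted_exponent = pl$alpha, fitted_xmin = pl$xmin,
    ks_exponential = ex$ks, exponential_p = ex$p,
    exponential_rejected = ex$p < 0.05, fitted_rate = ex$rate
  )
}

# Clauset-style power-law fit: MLE + xmin by KS via igraph's plfit, p-value
# by semi-parametric bootstrap.
fit_powerlaw_ks <- function(d, n_boot = 200L) {
  fit <- igraph::fit_power_law(d, implementation = "plfit")
  n <- length(d)
  body <- d[d < fit$xmin]
  n_tail <- n - length(body)
  ks_boot <- replicate(n_boot, {
    take_tail <- stats::rbinom(1L, n, n_tail / n)
    synth <- c(
      if (n - take_tail > 0L && length(body)) sample(body, n - take_tail, replace = TRUE) else integer(0),
      rzeta_tail(take_tail, fit$alpha, fit$xmin)
    )
    if (length(unique(synth)) < 2L) return(NA_real_)
    igraph::fit_power_law(synth, implementation = "plfit")$KS.stat
  })
  p <- mean(ks_boot >= fit$KS.stat, na.rm = TRUE)
  list(ks = fit$KS.stat, p = p, alpha = fit$alpha, xmin = fit$xmin)
}

# Discrete power-law sampler on k >= xmin via inverse CDF on a truncated
# support (tail mass beyond the cap is negligible for alpha > 1.5).
rzeta_tail <- function(n, alpha, xmin, cap = 1e5) {
  if (n == 0L) return(integer(0))
  k <- seq.int(xmin, max(xmin + 1, cap))
  w <- k^(-alpha)
  sample(k, n, replace = TRUE, prob = w / sum(w))
}

# Exponential-decay null with rate fixed at 1/mean(d): discretised to
# P(k) proportional to exp(-k/mean_k) on k = 1, 2, ...; KS distance against
# the null CDF, p-value by parametric bootstrap.
fit_exponential_ks <- function(d, n_boot = 200L) {
  rate <- 1 / mean(d)
  kmax <- max(max(d), ceiling(40 / rate))
  k <- seq_len(kmax)
  pmf <- exp(-rate * k)
  pmf <- pmf / sum(pmf)
  cdf <- cumsum(pmf)
  ks_stat <- function(v) {
    f_n <- cumsum(tabulate(v, nbins = kmax)) / length(v)
    max(abs(f_n - cdf))
  }
  obs <- ks_stat(pmin(d, kmax))
  boot <- replicate(n_boot, ks_stat(sample.int(kmax, length(d), replace = TRUE, prob = pmf)))
  list(ks = obs, p = mean(boot >= obs), rate = rate)
}

#' Full per-year metric record
#'
#' Computes the tracked metric suite on a network and returns it as a single
#' data.frame row. Metrics that are undefined on the current network (empty,
#' degenerate variance, no finite paths) are typed missing values, never
#' silent zeros.
#'
#' @param net A [trade_network()].
#' @param year Calendar year attached to the record.
#' @param suite `"all"` for the full suite or `"fitting"` for the cheap
#'   calibration subset (n_nodes, reciprocity, assortativity).
#' @return A one-row data.frame.
#' @export
network_metrics <- function(net, year = NA_integer_, suite = c("all", "fitting")) {
  suite <- match.arg(suite)
  base <- data.frame(
    year = as.integer(year),
    m = net$m,
    n_nodes = length(active_nodes(net)),
    reciprocity = reciprocity(net),
    assortativity = assortativity_degree_total(net)
  )
  if (suite == "fitting") return(base)
  gc_ <- giant_components(net)
  het <- degree_heterogeneity(net)
  cbind(base, data.frame(
    apl = average_path_length(net),
    acc = average_clustering(net),
    gsc_size = gc_[["gsc"]],
    gwc_size = gc_[["gwc"]],
    density = network_density(net),
    symmetry = degree_symmetry(net),
    heterogeneity_in = het[["cv_in"]],
    heterogeneity_out = het[["cv_out"]]
  ))
}

# Names of the per-year metric columns (excluding bookkeeping columns).
metric_columns <- function(suite = c("all", "fitting")) {
  suite <- match.arg(suite)
  fit_cols <- c("n_nodes", "reciprocity", "assortativity")
  if (suite == "fitting") return(fit_cols)
  c(fit_cols, "apl", "acc", "gsc_size", "gwc_size", "density",
    "symmetry", "heterogeneity_in", "heterogeneity_out")
}
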