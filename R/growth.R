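#' Growth-model parameters
#'
#' The five scalars of the preferential-attachment growth process. The
#' probability that a sampled candidate pair (i, j) becomes a trade edge is
#'
#'   P_t(x_i, x_j) = (alpha * x_i * x_j + epsilon) / (1 + beta * x_i * x_j)
#'
#' where x is fitness (total degree / m). `alpha` scales the overall
#' connection probability, `beta` damps how strongly it grows with the
#' fitness product, and `epsilon` (<< 1) is the baseline probability that
#' lets countries with zero fitness bootstrap into the network. After every
#' added edge, R(m) = C * exp(-lam * m) Maslov-Sneppen rewiring attempts are
#' made, so random reshuffling of partnerships dominates early growth and
#' preferential attachment dominates late growth.
#'
#' Validity requires P_t in [0, 1] for all fitness products z = x_i * x_j in
#' [0, 1]. As a ratio of two linear functions of z, P_t attains its extrema
#' at the endpoints, so the constraint is checked at z = 0 and z = 1.
#'
#' @param alpha Nonnegative scaling of the fitness product.
#' @param beta Nonnegative saturation coefficient.
#' @param epsilon Baseline connection probability in [0, 1].
#' @param C Nonnegative rewiring amplitude (attempts at m = 0).
#' @param lam Nonnegative rewiring decay rate, per directed edge.
#' @return A `growth_params` list.
#' @export
growth_params <- function(alpha, beta, epsilon, C = 0, lam = 0) {
  stopifnot(
    is.numeric(alpha), length(alpha) == 1L, alpha >= 0,
    is.numeric(beta), length(beta) == 1L, beta >= 0,
    is.numeric(epsilon), length(epsilon) == 1L,
    is.numeric(C), length(C) == 1L, C >= 0,
    is.numeric(lam), length(lam) == 1L, lam >= 0
  )
  if (epsilon < 0 || epsilon > 1) stop("epsilon must lie in [0, 1]")
  for (z in c(0, 1)) {
    p <- (alpha * z + epsilon) / (1 + beta * z)
    if (p > 1 + 1e-12) {
      stop(sprintf(
        "invalid growth parameters: P_t = %.4f > 1 at fitness product z = %g; need (alpha*z + epsilon) <= (1 + beta*z)",
        p, z
      ))
    }
  }
  structure(
    list(alpha = alpha, beta = beta, epsilon = epsilon, C = C, lam = lam),
    class = "growth_params"
  )
}

#' Reference parameter set
#'
#' A documented single parameter set used as the package default wherever one
#' concrete parametrisation is needed (examples, shock presets, qualitative
#' trend checks). It was chosen by running the package's own grid calibration
#' against the empirical anchors of the continuous wheat trade network
#' (roughly 108 active countries and 363 partnerships by 2013, negative
#' assortativity rising towards zero) and is fixed thereafter; it is not a
#' fitted quantity carried over from elsewhere.
#'
#' @return A [growth_params()] object.
#' @export
reference_params <- function() {
  growth_params(alpha = 100, beta = 200, epsilon = 0.001, C = 50, lam = 0.02)
}

#' Year-indexed cumulative edge schedule
#'
#' Calendar years are realised purely as cumulative-edge checkpoints: the
#' growth loop adds edges until m reaches E(year), then records metrics.
#'
#' @param years Strictly increasing integer calendar years.
#' @param edges Nondecreasing nonnegative integer cumulative edge counts.
#' @return A `growth_schedule` data frame with columns `year`, `edges`.
#' @export
growth_schedule <- function(years, edges) {
  years <- as.integer(years)
  edges <- as.integer(round(edges))
  stopifnot(length(years) == length(edges), length(years) >= 1L)
  if (any(diff(years) <= 0L)) stop("schedule years must be strictly increasing")
  if (any(edges < 0L)) stop("schedule edge counts must be nonnegative")
  if (any(diff(edges) < 0L)) stop("schedule edge counts must be nondecreasing")
  structure(
    data.frame(year = years, edges = edges),
    class = c("growth_schedule", "data.frame")
  )
}

#' Reference linear growth schedule, 1986-2050
#'
#' Linear extrapolation of the continuous wheat trade network's cumulative
#' edge count, anchored at roughly 30 sustained partnerships in 1986 and the
#' 363 observed by 2013 (slope ~12.3 edges/year), extended to `horizon`.
#'
#' @param years Calendar years covered (default 1986:2050).
#' @return A [growth_schedule()].
#' @export
reference_schedule <- function(years = 1986:2050) {
  slope <- (363 - 30) / (2013 - 1986)
  growth_schedule(years, pmax(0, round(30 + slope * (years - 1986))))
}

#' Pairwise trade probability
#'
#' @param x_i,x_j Fitness values in [0, 1] (vectorised).
#' @param params A [growth_params()].
#' @return Probability vector in [0, 1].
#' @export
trade_probability <- function(x_i, x_j, params) {
  z <- x_i * x_j
  (params$alpha * z + params$epsilon) / (1 + params$beta * z)
}

#' One candidate-pair event
#'
#' Samples one ordered pair (importer, exporter) uniformly from all non-self
#' pairs of the pool. The event fails when the edge already exists or the
#' exporter is banned; otherwise the edge is added with probability
#' [trade_probability()] of the endpoint fitnesses. Failure is a legal
#' outcome, not an error.
#'
#' @param net A [trade_network()]; modified in place on success.
#' @param params A [growth_params()].
#' @param banned Integer indices of countries currently barred from exporting.
#' @return The added edge as `c(importer, exporter)`, or `NULL`.
#' @export
attempt_edge_event <- function(net, params, banned = integer(0)) {
  n <- net$n
  if (n < 2L) stop("pool must contain at least 2 countries")
  k <- sample.int(n * (n - 1L), 1L) - 1L
  i <- k %/% (n - 1L) + 1L
  j <- k %% (n - 1L) + 1L
  if (j >= i) j <- j + 1L
  if (net$adj[i, j] || (length(banned) && j %in% banned)) return(NULL)
  x <- fitness(net)
  if (stats::runif(1L) < trade_probability(x[i], x[j], params)) {
    add_edge(net, i, j)
    return(c(importer = i, exporter = j))
  }
  NULL
}

#' Add exactly one edge by repeated candidate events
#'
#' Repeats the candidate-pair event until an edge is accepted. Because
#' fitness and the admissible-pair set only change when an edge is actually
#' added, the rejection loop is run in vectorised batches; the accepted pair
#' has exactly the distribution of sequential single events (uniform ordered
#' pair draw times the acceptance probability, renormalised over admissible
#' pairs).
#'
#' @inheritParams attempt_edge_event
#' @param max_attempts Stall guard on the number of candidate draws.
#' @param batch Number of candidate pairs drawn per vectorised round.
#' @return The added edge as `c(importer, exporter)`.
#' @export
grow_one_edge <- function(net, params, banned = integer(0),
                          max_attempts = 1e6, batch = 256L) {
  n <- net$n
  if (n < 2L) stop("pool must contain at least 2 countries")
  x <- fitness(net)
  is_banned <- logical(n)
  if (length(banned)) is_banned[resolve_country(net, banned)] <- TRUE
  attempts <- 0
  while (attempts < max_attempts) {
    b <- as.integer(min(batch, max_attempts - attempts))
    i <- sample.int(n, b, replace = TRUE)
    j <- sample.int(n, b, replace = TRUE)
    u <- stats::runif(b)
    ok <- i != j & !is_banned[j] & !net$adj[cbind(i, j)] &
      u < trade_probability(x[i], x[j], params)
    hit <- which(ok)
    if (length(hit)) {
      add_edge(net, i[hit[1L]], j[hit[1L]])
      return(c(importer = i[hit[1L]], exporter = j[hit[1L]]))
    }
    attempts <- attempts + b
  }
  stop(
    "grow_one_edge stalled after ", format(max_attempts, scientific = FALSE),
    " candidate draws: no admissible pair was accepted. Likely causes: ",
    "epsilon = 0 on a network where all sampled pairs have zero fitness, ",
    "or all absent pairs are banned/saturated."
  )
}

#' Rewiring attempt budget after an edge addition
#'
#' Expected number of Maslov-Sneppen attempts is C * exp(-lam * m). The
#' realised integer budget uses stochastic rounding (floor plus a Bernoulli
#' draw on the fractional part) so the exponential decay continues to act
#' below one expected attempt per edge.
#'
#' @param m Current directed edge count.
#' @param params A [growth_params()].
#' @return Nonnegative integer number of attempts.
#' @export
rewiring_budget <- function(m, params) {
  mu <- params$C * exp(-params$lam * m)
  base <- floor(mu)
  as.integer(base + (stats::runif(1L) < (mu - base)))
}

#' One Maslov-Sneppen rewiring attempt
#'
#' Draws two distinct directed edges (i1 <- j1) and (i2 <- j2) uniformly and
#' proposes swapping their exporters: (i1 <- j2), (i2 <- j1). The swap is
#' applied only if it creates no self-loop and no duplicate edge. Every
#' node's in- and out-degree is unchanged whether or not the swap is applied,
#' and edges remain uniquely defined.
#'
#' @param net A [trade_network()]; modified in place on success.
#' @return `TRUE` if the swap was applied, `FALSE` otherwise.
#' @export
ms_rewire_attempt <- function(net) {
  if (net$m < 2L) return(FALSE)
  k <- sample.int(net$m, 2L)
  i1 <- net$edges[k[1L], 1L]; j1 <- net$edges[k[1L], 2L]
  i2 <- net$edges[k[2L], 1L]; j2 <- net$edges[k[2L], 2L]
  if (i1 == j2 || i2 == j1) return(FALSE)            # would create self-loops
  if (i1 == i2 && j1 == j2) return(FALSE)            # cannot happen (unique edges)
  # proposed new edges; duplicates checked against the network minus the two
  # removed edges
  new_dup <- (i1 == i2 && j2 == j1)                  # the two proposals coincide
  net$adj[i1, j1] <- FALSE
  net$adj[i2, j2] <- FALSE
  if (new_dup || net$adj[i1, j2] || net$adj[i2, j1]) {
    net$adj[i1, j1] <- TRUE
    net$adj[i2, j2] <- TRUE
    return(FALSE)
  }
  net$adj[i1, j2] <- TRUE
  net$adj[i2, j1] <- TRUE
  net$edges[k[1L], 2L] <- j2
  net$edges[k[2L], 2L] <- j1
  TRUE
}

#' Grow a network along a year schedule, with optional shocks
#'
#' For each scheduled year, in order: (1) any shock starting that year is
#' applied (out-edges of its targets removed, exporters banned for the shock
#' duration); (2) edges are added one at a time until m reaches E(year), with
#' [rewiring_budget()] Maslov-Sneppen attempts executed after every added
#' edge; (3) the year's network metrics are recorded. Growth never pauses
#' during a ban: non-banned exporters keep forming edges.
#'
#' @param params A [growth_params()].
#' @param schedule A [growth_schedule()].
#' @param pool Pool size or label vector (default 244).
#' @param shocks Optional [shock_schedule()] (or a single [shock_spec()]).
#' @param seed Optional integer seed set before the run.
#' @param record Which metrics to record each year: `"all"` (full suite),
#'   `"fitting"` (n_nodes, reciprocity, assortativity only -- cheap, used by
#'   calibration), or `"none"`.
#' @param net Optional starting network (e.g. an empirical snapshot); by
#'   default growth starts from an empty pool and bootstraps through epsilon.
#' @param max_attempts Stall guard per added edge.
#' @param instrument If `TRUE`, every added edge is checked against the ban
#'   registry and counts of accepted rewirings are kept (slower; used by
#'   tests).
#' @return A list with `metrics` (one data.frame row per scheduled year),
#'   `network` (final [trade_network()]), `removed` (named per-year count of
#'   shock-removed edges) and, when instrumented, `rewires` (accepted swaps
#'   per year).
#' @export
run_growth <- function(params, schedule, pool = 244, shocks = NULL, seed = NULL,
                       record = c("all", "fitting", "none"), net = NULL,
                       max_attempts = 1e6, instrument = FALSE) {
  record <- match.arg(record)
  stopifnot(inherits(params, "growth_params"), inherits(schedule, "growth_schedule"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(net)) net <- trade_network(pool)
  if (!is.null(shocks)) {
    shocks <- as_shock_schedule(shocks)
    bad <- setdiff(vapply(shocks$shocks, `[[`, 0L, "start_year"), schedule$year)
    if (length(bad)) {
      stop("shock start year(s) outside the growth schedule: ", paste(bad, collapse = ", "))
    }
  }
  registry <- new_ban_registry(net$n)
  rows <- vector("list", nrow(schedule))
  removed <- stats::setNames(integer(nrow(schedule)), schedule$year)
  rewires <- stats::setNames(integer(nrow(schedule)), schedule$year)
  for (t in seq_len(nrow(schedule))) {
    y <- schedule$year[t]
    if (!is.null(shocks)) {
      for (sp in shocks$shocks) {
        if (sp$start_year == y) {
          targets <- select_shock_targets(net, sp)
          removed[t] <- removed[t] + apply_export_ban(net, targets, sp$duration, y, registry)
        }
      }
    }
    banned <- banned_exporters(registry, y)
    while (net$m < schedule$edges[t]) {
      grow_one_edge(net, params, banned = banned, max_attempts = max_attempts)
      if (instrument) {
        e <- net$edges[net$m, ]
        if (length(banned) && e[2L] %in% banned) {
          stop("internal error: banned exporter formed an edge")
        }
      }
      n_rw <- rewiring_budget(net$m, params)
      for (r in seq_len(n_rw)) {
        if (ms_rewire_attempt(net) && instrument) rewires[t] <- rewires[t] + 1L
      }
    }
    if (record != "none") {
      rows[[t]] <- network_metrics(net, year = y, suite = record)
    }
  }
  out <- list(
    metrics = if (record == "none") NULL else do.call(rbind, rows),
    network = net,
    removed = removed
  )
  if (instrument) out$rewires <- rewires
  out
}
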