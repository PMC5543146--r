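#' Specify a single shock
#'
#' A shock makes a set of countries cease exporting: their outgoing (export)
#' edges are removed at the start of the shock year and they are barred from
#' forming new export links for the shock duration (they keep importing).
#' Errors pick targets uniformly at random among exporters; attacks pick the
#' most-connected countries by total- or out-degree centrality, either
#' simultaneously (centrality ranked once) or sequentially (re-ranked after
#' each target's exports are removed).
#'
#' Default severities follow the low/high convention (3 or 15 countries) and
#' durations the short/long convention (1 or 5 years).
#'
#' @param type `"error"` or `"attack"`.
#' @param severity Number of countries that cease exports (default 3 = low;
#'   15 = high).
#' @param duration Ban length in years (default 1 = short; 5 = long).
#' @param start_year Calendar year at whose start the shock hits.
#' @param targeting Attack centrality: `"total_degree"` or `"out_degree"`.
#' @param mode Attack mode: `"simultaneous"` or `"sequential"`.
#' @return A `shock_spec` list.
#' @export
shock_spec <- function(type = c("error", "attack"), severity = 3L, duration = 1L,
                       start_year, targeting = c("total_degree", "out_degree"),
                       mode = c("simultaneous", "sequential")) {
  type <- match.arg(type)
  targeting <- match.arg(targeting)
  mode <- match.arg(mode)
  stopifnot(severity >= 1, duration >= 1, severity == round(severity),
            duration == round(duration), length(start_year) == 1L)
  structure(
    list(type = type, severity = as.integer(severity),
         duration = as.integer(duration), start_year = as.integer(start_year),
         targeting = targeting, mode = mode),
    class = "shock_spec"
  )
}

#' Shock sequence with a minimum gap
#'
#' Validates that shocks do not overlap and that consecutive shocks are
#' separated by at least `gap` calendar years between the end of one ban and
#' the start of the next.
#'
#' @param ... [shock_spec()] objects (or a single list of them).
#' @param gap Minimum clear years between shocks (default 2).
#' @return A `shock_schedule` list.
#' @export
shock_schedule <- function(..., gap = 2L) {
  shocks <- list(...)
  if (length(shocks) == 1L && !inherits(shocks[[1L]], "shock_spec")) shocks <- shocks[[1L]]
  stopifnot(all(vapply(shocks, inherits, TRUE, "shock_spec")))
  ord <- order(vapply(shocks, `[[`, 0L, "start_year"))
  shocks <- shocks[ord]
  if (length(shocks) >= 2L) {
    for (k in seq_len(length(shocks) - 1L)) {
      end_k <- shocks[[k]]$start_year + shocks[[k]]$duration - 1L
      if (shocks[[k + 1L]]$start_year - end_k - 1L < gap) {
        stop(sprintf(
          "shocks must be separated by at least %d clear year(s): shock ending %d vs shock starting %d",
          gap, end_k, shocks[[k + 1L]]$start_year
        ))
      }
    }
  }
  structure(list(shocks = shocks, gap = as.integer(gap)), class = "shock_schedule")
}

as_shock_schedule <- function(x) {
  if (inherits(x, "shock_schedule")) return(x)
  if (inherits(x, "shock_spec")) return(shock_schedule(x))
  stop("expected a shock_spec or shock_schedule")
}

#' Shock presets
#'
#' Shortcut for the standard severity x duration grid, named
#' `"<type>-<low|high>-<short|long>-<start year>"`, e.g.
#' `"attack-low-short-2017"` (3 countries, 1 year, starting 2017).
#'
#' @param name Preset name.
#' @param targeting,mode Passed to [shock_spec()] for attacks.
#' @return A [shock_spec()].
#' @export
shock_preset <- function(name, targeting = "total_degree", mode = "simultaneous") {
  parts <- strsplit(name, "-", fixed = TRUE)[[1L]]
  if (length(parts) != 4L) stop("preset name must be <type>-<low|high>-<short|long>-<year>")
  sev <- switch(parts[2L], low = 3L, high = 15L, stop("severity must be low or high"))
  dur <- switch(parts[3L], short = 1L, long = 5L, stop("duration must be short or long"))
  shock_spec(parts[1L], severity = sev, duration = dur,
             start_year = as.integer(parts[4L]), targeting = targeting, mode = mode)
}

# Ban registry: per-country last banned year (0 = never banned).
new_ban_registry <- function(n) {
  reg <- new.env(parent = emptyenv())
  reg$until <- integer(n)
  reg
}

banned_exporters <- function(registry, year) which(registry$until >= year)

#' Random error targets
#'
#' Draws `k` distinct countries uniformly without replacement from the
#' eligible set: by default the current exporters (out-degree >= 1), since an
#' export ban on a non-exporter removes nothing.
#'
#' @param net A [trade_network()].
#' @param k Number of countries.
#' @param eligible `"exporters"` (default) or `"active"`.
#' @return Integer vector of k country indices.
#' @export
select_targets_error <- function(net, k, eligible = c("exporters", "active")) {
  eligible <- match.arg(eligible)
  pool <- if (eligible == "exporters") which(net$out_deg >= 1L) else active_nodes(net)
  if (length(pool) < k) {
    stop(sprintf("error shock needs %d eligible countries but only %d exist", k, length(pool)))
  }
  pool[sample.int(length(pool), k)]
}

#' Targeted attack selection
#'
#' Simultaneous mode ranks all active countries once by the chosen centrality
#' and takes the top k (the centrality is not recalculated between removals);
#' sequential mode picks the top country, removes its export edges from a
#' working copy of the degree bookkeeping, re-ranks, and repeats. Ties are
#' broken uniformly at random.
#'
#' @param net A [trade_network()].
#' @param k Number of countries.
#' @param targeting `"total_degree"` or `"out_degree"`.
#' @param mode `"simultaneous"` or `"sequential"`.
#' @return Ordered integer vector of k country indices.
#' @export
select_targets_attack <- function(net, k, targeting = c("total_degree", "out_degree"),
                                  mode = c("simultaneous", "sequential")) {
  targeting <- match.arg(targeting)
  mode <- match.arg(mode)
  act <- active_nodes(net)
  if (length(act) < k) {
    stop(sprintf("attack needs %d active countries but only %d exist", k, length(act)))
  }
  if (mode == "simultaneous") {
    score <- switch(targeting,
      total_degree = total_degree(net)[act],
      out_degree = net$out_deg[act]
    )
    ord <- order(-score, sample.int(length(act)))
    return(act[ord[seq_len(k)]])
  }
  # sequential: work on degree copies, re-ranking after each removal
  in_deg <- net$in_deg
  out_deg <- net$out_deg
  edges <- net$edges
  picked <- integer(0)
  for (step in seq_len(k)) {
    tot <- in_deg + out_deg
    cand <- setdiff(which(tot >= 1L), picked)
    if (!length(cand)) stop("sequential attack ran out of active targets")
    score <- switch(targeting, total_degree = tot[cand], out_degree = out_deg[cand])
    v <- cand[order(-score, sample.int(length(cand)))[1L]]
    picked <- c(picked, v)
    gone <- edges[, 2L] == v
    if (any(gone)) {
      lost <- tabulate(edges[gone, 1L], nbins = net$n)
      in_deg <- in_deg - lost
      out_deg[v] <- 0L
      edges <- edges[!gone, , drop = FALSE]
    }
  }
  picked
}

select_shock_targets <- function(net, sp) {
  if (sp$type == "error") {
    select_targets_error(net, sp$severity)
  } else {
    select_targets_attack(net, sp$severity, sp$targeting, sp$mode)
  }
}

#' Apply an export ban
#'
#' Deletes every outgoing edge of the target countries (their imports are
#' unaffected) and records the ban in the registry until `year + duration - 1`.
#' Removed edges are not restored when the ban lifts: recovery happens only
#' through subsequent growth.
#'
#' @param net A [trade_network()]; modified in place.
#' @param targets Country indices.
#' @param duration Ban duration in years.
#' @param year Ban start year.
#' @param registry A ban registry from within [run_growth()] (created
#'   automatically there).
#' @return Number of edges removed.
#' @export
apply_export_ban <- function(net, targets, duration, year, registry = NULL) {
  stopifnot(length(targets) >= 1L)
  removed <- remove_out_edges(net, targets)
  if (!is.null(registry)) {
    expiry <- as.integer(year + duration - 1L)
    registry$until[targets] <- pmax(registry$until[targets], expiry)
  }
  removed
}

#' Per-shock metric changes
#'
#' For each shock year, the difference between the metric record at the end
#' of that year and the record at the end of the preceding year. Changes in
#' unshocked years are not reported.
#'
#' @param metrics A per-year metric data.frame (as returned by [run_growth()]).
#' @param shock_years Integer vector of shock start years.
#' @return A data.frame with one row per shock year and one column per metric
#'   (differences), plus `year`.
#' @export
shock_delta <- function(metrics, shock_years) {
  cols <- setdiff(names(metrics), "year")
  rows <- lapply(sort(unique(as.integer(shock_years))), function(y) {
    at <- match(y, metrics$year)
    before <- match(y - 1L, metrics$year)
    if (is.na(at) || is.na(before)) {
      stop("metric series must cover the shock year and the year before: ", y)
    }
    cbind(data.frame(year = y), metrics[at, cols, drop = FALSE] - metrics[before, cols, drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Shocked-vs-unshocked ensemble experiment
#'
#' For each supplied parameter set, runs one shocked and one unshocked growth
#' realisation from a paired seed (identical randomness up to the first
#' shock), then aggregates per-year means and standard deviations across
#' parameter sets for both arms, plus the average per-shock metric deltas of
#' the shocked arm.
#'
#' @param param_sets A data.frame with columns alpha, beta, epsilon, C, lam
#'   (one row per parameter set), or a list of [growth_params()].
#' @param scenario A [shock_schedule()] (or single [shock_spec()]), or `NULL`
#'   for no shocks in either arm.
#' @param schedule A [growth_schedule()].
#' @param pool Pool size or labels.
#' @param seed Base integer seed; run s uses a derived stream.
#' @param record Metric suite to record.
#' @return A list with `series` (long data.frame: year, arm, metric, mean,
#'   sd), `deltas` (mean per-shock-year metric changes across sets, shocked
#'   arm) and `removed` (mean edges removed per shock year).
#' @export
run_shock_experiment <- function(param_sets, scenario, schedule, pool = 244,
                                 seed = 1L, record = "all") {
  sets <- as_param_list(param_sets)
  shocked <- vector("list", length(sets))
  unshocked <- vector("list", length(sets))
  deltas <- vector("list", length(sets))
  removed <- NULL
  shock_years <- if (is.null(scenario)) integer(0) else {
    vapply(as_shock_schedule(scenario)$shocks, `[[`, 0L, "start_year")
  }
  for (s in seq_along(sets)) {
    rs <- derive_seed(seed, s, 1L)
    sh <- run_growth(sets[[s]], schedule, pool = pool,
                     shocks = scenario, seed = rs, record = record)
    un <- run_growth(sets[[s]], schedule, pool = pool,
                     shocks = NULL, seed = rs, record = record)
    shocked[[s]] <- sh$metrics
    unshocked[[s]] <- un$metrics
    if (length(shock_years)) {
      deltas[[s]] <- shock_delta(sh$metrics, shock_years)
      removed <- rbind(removed, sh$removed[as.character(shock_years)])
    }
  }
  series <- rbind(
    aggregate_metric_series(shocked, arm = "shocked"),
    aggregate_metric_series(unshocked, arm = "unshocked")
  )
  mean_deltas <- NULL
  if (length(shock_years)) {
    all_d <- do.call(rbind, deltas)
    mean_deltas <- stats::aggregate(. ~ year, data = all_d, FUN = mean, na.action = stats::na.pass)
  }
  list(
    series = series,
    deltas = mean_deltas,
    removed = if (length(shock_years)) colMeans(removed) else NULL
  )
}

# Long-format per-year mean/sd across a list of metric data.frames.
aggregate_metric_series <- function(dfs, arm) {
  cols <- setdiff(names(dfs[[1L]]), "year")
  years <- dfs[[1L]]$year
  rows <- lapply(cols, function(cl) {
    vals <- vapply(dfs, function(d) d[[cl]], numeric(length(years)))
    vals <- matrix(vals, nrow = length(years))
    data.frame(
      year = years, arm = arm, metric = cl,
      mean = rowMeans(vals, na.rm = TRUE),
      sd = apply(vals, 1L, stats::sd, na.rm = TRUE)
    )
  })
  do.call(rbind, rows)
}
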