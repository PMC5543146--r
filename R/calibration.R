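#' Parameter grid for the calibration sweep
#'
#' Builds the cross product of per-parameter axis values and drops
#' combinations that violate the probability-validity constraint of
#' [growth_params()]. Default axes are log-spaced and sized to a few thousand
#' combinations, mirroring a coarse global sweep; all axes are caller-
#' configurable.
#'
#' @param alpha,beta,epsilon,C,lam Numeric axis values per parameter.
#' @return A data.frame with one valid parameter set per row and an `id`
#'   column giving grid order.
#' @export
parameter_grid <- function(alpha = exp(seq(log(5), log(500), length.out = 8)),
                           beta = exp(seq(log(5), log(500), length.out = 8)),
                           epsilon = c(0.002, 0.005, 0.01, 0.02),
                           C = c(0, 25, 50, 100),
                           lam = c(0.005, 0.02, 0.05)) {
  grid <- expand.grid(alpha = alpha, beta = beta, epsilon = epsilon,
                      C = C, lam = lam, KEEP.OUT.ATTRS = FALSE)
  ok <- vapply(seq_len(nrow(grid)), function(k) {
    !inherits(try(growth_params(grid$alpha[k], grid$beta[k], grid$epsilon[k],
                                grid$C[k], grid$lam[k]), silent = TRUE), "try-error")
  }, TRUE)
  grid <- grid[ok, , drop = FALSE]
  grid$id <- seq_len(nrow(grid))
  rownames(grid) <- NULL
  grid
}

#' Replicate-averaged model metric series
#'
#' Runs the growth model `n_rep` times (no shocks) under one parameter set
#' and returns the per-year mean of each recorded metric. Averaging over
#' replicates (default 25) damps the run-to-run stochasticity before the
#' series is compared to an empirical target.
#'
#' @param params A [growth_params()].
#' @param schedule A [growth_schedule()].
#' @param n_rep Number of replicates (default 25).
#' @param pool Pool size or labels.
#' @param seed Base seed; replicate r uses a derived stream.
#' @param record Metric suite (default the cheap `"fitting"` subset).
#' @param set_id Identifier mixed into the derived seeds so different grid
#'   rows get different streams.
#' @return A data.frame of per-year replicate means.
#' @export
simulate_replicates <- function(params, schedule, n_rep = 25L, pool = 244,
                                seed = 1L, record = "fitting", set_id = 1L) {
  stopifnot(n_rep >= 1L)
  runs <- lapply(seq_len(n_rep), function(r) {
    run_growth(params, schedule, pool = pool, seed = derive_seed(seed, set_id, r),
               record = record)$metrics
  })
  out <- runs[[1L]]["year"]
  for (cl in setdiff(names(runs[[1L]]), "year")) {
    vals <- vapply(runs, function(d) d[[cl]], numeric(nrow(out)))
    out[[cl]] <- rowMeans(matrix(vals, nrow = nrow(out)), na.rm = TRUE)
  }
  out
}

#' Mean squared error between model and target metric series
#'
#' @param model_series,empirical_series Data frames with a `year` column and
#'   the metric column.
#' @param metric Metric column name.
#' @param window Integer years over which to compare (default 1986:2011).
#' @return Nonnegative scalar MSE.
#' @export
metric_mse <- function(model_series, empirical_series, metric, window = 1986:2011) {
  im <- match(window, model_series$year)
  ie <- match(window, empirical_series$year)
  if (anyNA(im) || anyNA(ie)) {
    stop("both series must cover every year of the comparison window")
  }
  mean((model_series[[metric]][im] - empirical_series[[metric]][ie])^2)
}

#' Normalize per-metric MSE columns and combine
#'
#' Each metric's MSE column is divided by its maximum across parameter sets
#' (so the worst set scores 1 on that metric); the combined score is the sum
#' of the normalized columns. An all-zero column contributes 0 for every set.
#' The result is invariant to rescaling any raw column by a positive
#' constant.
#'
#' @param mse_table Data frame of raw MSEs, one row per parameter set, one
#'   column per metric.
#' @param method `"max"` (default), `"minmax"` or `"zscore"`.
#' @return List with `normalized` (data.frame) and `combined` (numeric).
#' @export
normalize_and_combine <- function(mse_table, method = c("max", "minmax", "zscore")) {
  method <- match.arg(method)
  stopifnot(nrow(mse_table) >= 2L)
  norm <- as.data.frame(lapply(mse_table, function(v) {
    switch(method,
      max = if (max(v) == 0) rep(0, length(v)) else v / max(v),
      minmax = if (max(v) == min(v)) rep(0, length(v)) else (v - min(v)) / (max(v) - min(v)),
      zscore = if (stats::sd(v) == 0) rep(0, length(v)) else (v - mean(v)) / stats::sd(v)
    )
  }))
  list(normalized = norm, combined = rowSums(norm))
}

#' Rank parameter sets and select the best k
#'
#' Ascending sort on the combined score with a stable tie-break by grid
#' order.
#'
#' @param combined Numeric combined scores.
#' @param k Number of sets to select.
#' @return List with `rank` (1 = best, a permutation) and `selected`
#'   (indices of the k best, in score order).
#' @export
rank_and_select <- function(combined, k) {
  if (k > length(combined)) stop("k exceeds the number of parameter sets")
  ord <- order(combined) # stable: ties keep grid order
  rank <- integer(length(combined))
  rank[ord] <- seq_along(combined)
  list(rank = rank, selected = ord[seq_len(k)])
}

#' Grid-sweep calibration against a target metric series
#'
#' For every parameter set in the grid, simulates `n_rep` replicate networks,
#' averages the fitted metrics per year, computes the per-metric MSE against
#' the target over the comparison window, normalizes each metric's MSE column
#' across the grid, sums them into a combined score, and ranks the sets.
#'
#' @param grid A [parameter_grid()]-style data.frame.
#' @param target Target metric series (empirical or pseudo-empirical), with
#'   `year` and the fitted metric columns.
#' @param schedule A [growth_schedule()].
#' @param metrics Fitting metrics (default assortativity, node count,
#'   reciprocity; pass `"assortativity"` alone for the assortativity-only
#'   variant).
#' @param n_rep Replicates per set (default 25).
#' @param window Comparison years.
#' @param pool Pool size or labels.
#' @param seed Base seed.
#' @param top_k Number of best sets to flag (default 100).
#' @return A data.frame: the grid plus raw MSE columns (`mse_<metric>`),
#'   normalized columns (`nmse_<metric>`), `combined`, `rank`, `selected`.
#' @export
calibrate <- function(grid, target, schedule,
                      metrics = c("assortativity", "n_nodes", "reciprocity"),
                      n_rep = 25L, window = 1986:2011, pool = 244, seed = 1L,
                      top_k = 100L) {
  top_k <- min(top_k, nrow(grid))
  mse <- matrix(NA_real_, nrow(grid), length(metrics),
                dimnames = list(NULL, metrics))
  for (k in seq_len(nrow(grid))) {
    p <- growth_params(grid$alpha[k], grid$beta[k], grid$epsilon[k], grid$C[k], grid$lam[k])
    sim <- simulate_replicates(p, schedule, n_rep = n_rep, pool = pool,
                               seed = seed, set_id = grid$id[k])
    for (mt in metrics) mse[k, mt] <- metric_mse(sim, target, mt, window)
  }
  nc <- normalize_and_combine(as.data.frame(mse))
  rs <- rank_and_select(nc$combined, top_k)
  out <- grid
  for (mt in metrics) out[[paste0("mse_", mt)]] <- mse[, mt]
  for (mt in metrics) out[[paste0("nmse_", mt)]] <- nc$normalized[[mt]]
  out$combined <- nc$combined
  out$rank <- rs$rank
  out$selected <- seq_len(nrow(grid)) %in% rs$selected
  out
}
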