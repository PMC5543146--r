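#' Generate a synthetic annual bilateral trade table
#'
#' Produces a trade table with the qualitative structure the continuous-
#' network extraction assumes: persistent partnerships (two-state Markov
#' dynamics per ordered country pair), growing participation, and heavy-
#' tailed annual volumes (log-normal). Each dormant ordered pair starts
#' trading with probability `initiation_rate` per year; an active pair trades
#' again the next year with probability `persistence`, else goes dormant.
#' Output is byte-identical under a fixed seed.
#'
#' @param n_countries Pool size (labels `S01`, `S02`, ...).
#' @param years Calendar years covered.
#' @param initiation_rate Per-year activation probability of a dormant pair.
#' @param persistence Per-year survival probability of an active pair.
#' @param vol_meanlog,vol_sdlog Log-normal volume parameters (log tonnes).
#' @param seed Optional integer seed.
#' @return A `trade_table` data.frame (importer, exporter, year, quantity).
#' @export
generate_trade_table <- function(n_countries = 25L, years = 1986:2013,
                                 initiation_rate = 0.02, persistence = 0.9,
                                 vol_meanlog = 8, vol_sdlog = 2, seed = NULL) {
  stopifnot(n_countries >= 2L, initiation_rate >= 0, initiation_rate <= 1,
            persistence >= 0, persistence <= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  labels <- sprintf("S%02d", seq_len(n_countries))
  pairs <- expand.grid(importer = seq_len(n_countries),
                       exporter = seq_len(n_countries))
  pairs <- pairs[pairs$importer != pairs$exporter, ]
  np <- nrow(pairs)
  active <- logical(np)
  rows <- list()
  for (y in years) {
    u <- stats::runif(np)
    active <- ifelse(active, u < persistence, u < initiation_rate)
    idx <- which(active)
    if (length(idx)) {
      rows[[as.character(y)]] <- data.frame(
        importer = labels[pairs$importer[idx]],
        exporter = labels[pairs$exporter[idx]],
        year = y,
        quantity = stats::rlnorm(length(idx), vol_meanlog, vol_sdlog)
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(importer = character(0), exporter = character(0),
                      year = integer(0), quantity = numeric(0))
  }
  rownames(out) <- NULL
  class(out) <- c("trade_table", "data.frame")
  out
}

#' Pseudo-empirical calibration targets from a known parameter set
#'
#' Runs the growth model under a known "true" parameter set and returns the
#' replicate-averaged fitted-metric series, tagged with the generating
#' parameters. Feeding this series to [calibrate()] with a grid containing
#' the true set provides a parameter-recovery check of the whole calibration
#' machinery.
#'
#' @param true_params The generating [growth_params()].
#' @param schedule A [growth_schedule()].
#' @param n_rep Replicates averaged (default 25; `n_rep = 1` is supported).
#' @param pool Pool size or labels.
#' @param seed Base seed.
#' @return A data.frame metric series with attribute `true_params`.
#' @export
generate_pseudo_empirical <- function(true_params, schedule, n_rep = 25L,
                                      pool = 244, seed = 1L) {
  series <- simulate_replicates(true_params, schedule, n_rep = n_rep,
                                pool = pool, seed = seed, set_id = 0L)
  attr(series, "true_params") <- true_params
  series
}
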