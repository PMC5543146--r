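#' Read an annual bilateral trade table
#'
#' Reads a CSV of annual bilateral trade records into the canonical table
#' used by the continuous-network extraction: one row per (importer,
#' exporter, year) with the traded quantity, duplicates aggregated by
#' summation. Two dialects are supported: the generic four-column dialect
#' (`reporter, partner, year, quantity`, with `direction` saying whether the
#' reporter imports from or exports to the partner) and the FAOSTAT detailed
#' trade matrix export dialect (`Reporter Countries`, `Partner Countries`,
#' `Element`, `Year`, `Value`), from which import-reported quantities are
#' preferred, mirror export rows being less reliable.
#'
#' @param path CSV file path.
#' @param dialect `"generic"` or `"faostat"`.
#' @param direction For the generic dialect: `"import"` (reporter imports
#'   from partner, default) or `"export"`.
#' @param columns Optional named character vector remapping the generic
#'   column names, e.g. `c(reporter = "rep", partner = "par", year = "yr",
#'   quantity = "tonnes")`.
#' @return A `trade_table` data.frame with columns `importer`, `exporter`,
#'   `year`, `quantity`.
#' @export
read_trade_table <- function(path, dialect = c("generic", "faostat"),
                             direction = c("import", "export"), columns = NULL) {
  dialect <- match.arg(dialect)
  direction <- match.arg(direction)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (dialect == "faostat") {
    need <- c("Reporter Countries", "Partner Countries", "Element", "Year", "Value")
    missing_cols <- setdiff(need, names(raw))
    if (length(missing_cols)) stop("FAOSTAT file lacks column(s): ", paste(missing_cols, collapse = ", "))
    raw <- raw[grepl("Import Quantity", raw$Element, fixed = TRUE), ]
    df <- data.frame(
      reporter = raw[["Reporter Countries"]], partner = raw[["Partner Countries"]],
      year = raw[["Year"]], quantity = raw[["Value"]], stringsAsFactors = FALSE
    )
    direction <- "import"
  } else {
    nm <- c(reporter = "reporter", partner = "partner", year = "year", quantity = "quantity")
    if (!is.null(columns)) nm[names(columns)] <- columns
    missing_cols <- setdiff(unname(nm), names(raw))
    if (length(missing_cols)) stop("trade table lacks column(s): ", paste(missing_cols, collapse = ", "))
    df <- data.frame(
      reporter = raw[[nm[["reporter"]]]], partner = raw[[nm[["partner"]]]],
      year = raw[[nm[["year"]]]], quantity = raw[[nm[["quantity"]]]],
      stringsAsFactors = FALSE
    )
  }
  df$year <- suppressWarnings(as.integer(df$year))
  df$quantity <- suppressWarnings(as.numeric(df$quantity))
  bad <- which(is.na(df$year) | is.na(df$quantity) | df$quantity < 0)
  if (length(bad)) {
    stop("invalid year or negative/unparseable quantity at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  if (direction == "import") {
    df$importer <- df$reporter; df$exporter <- df$partner
  } else {
    df$importer <- df$partner; df$exporter <- df$reporter
  }
  out <- stats::aggregate(quantity ~ importer + exporter + year,
                          data = df, FUN = sum)
  out <- out[order(out$year, out$importer, out$exporter),
             c("importer", "exporter", "year", "quantity")]
  rownames(out) <- NULL
  class(out) <- c("trade_table", "data.frame")
  out
}

#' Extract the continuous trade network
#'
#' The continuous network keeps only directed trade links sustained over at
#' least `min_run` consecutive years (default 3). An edge enters the yearly
#' snapshot at the year its qualifying run completes (`entry = "run_end"`,
#' default) or back-filled to the run's first year (`entry = "run_start"`).
#' With `persist = TRUE` (default, matching the growth model's no-deletion
#' dynamics) an edge remains in all later snapshots; with `persist = FALSE`
#' membership is a sliding trailing window requiring trade in each of the
#' last `min_run` years.
#'
#' @param table A `trade_table` from [read_trade_table()] (or any data.frame
#'   with importer, exporter, year, quantity > 0 meaning trade occurred).
#' @param min_run Minimum sustained run length in years.
#' @param persist Keep edges once entered.
#' @param entry `"run_end"` or `"run_start"`.
#' @param pool Country pool for the snapshots (default: all labels in the
#'   table).
#' @param years Years to emit snapshots for (default: the table's full span).
#' @return A `continuous_series` list: `years`, `networks` (named list of
#'   [trade_network()] snapshots), `edge_counts` (data.frame year, edges),
#'   `pool`.
#' @export
extract_continuous <- function(table, min_run = 3L, persist = TRUE,
                               entry = c("run_end", "run_start"),
                               pool = NULL, years = NULL) {
  entry <- match.arg(entry)
  stopifnot(min_run >= 1L)
  tab <- table[table$quantity > 0, , drop = FALSE]
  if (is.null(pool)) pool <- sort(unique(c(table$importer, table$exporter)))
  if (is.null(years)) {
    years <- if (nrow(tab)) seq(min(tab$year), max(tab$year)) else integer(0)
  }
  # membership years per directed pair
  key <- paste(tab$importer, tab$exporter, sep = "\r")
  pair_years <- split(tab$year, key)
  pair_member_years <- lapply(pair_years, function(ys) {
    ys <- sort(unique(ys))
    if (!length(ys)) return(integer(0))
    run_id <- cumsum(c(1L, diff(ys) != 1L))
    member <- integer(0)
    for (rid in unique(run_id)) {
      run <- ys[run_id == rid]
      if (length(run) < min_run) next
      enter <- if (entry == "run_end") run[min_run] else run[1L]
      member <- c(member, if (persist) enter else {
        # trailing-window membership within this run
        run[run >= run[min_run]]
      })
    }
    member
  })
  if (persist) {
    # entry year per pair = earliest membership year
    entry_year <- vapply(pair_member_years, function(v) {
      if (length(v)) min(v) else NA_integer_
    }, 0L)
  }
  pairs <- do.call(rbind, strsplit(names(pair_years), "\r", fixed = TRUE))
  networks <- list()
  edge_counts <- integer(length(years))
  for (t in seq_along(years)) {
    y <- years[t]
    present <- if (persist) {
      !is.na(entry_year) & entry_year <= y
    } else {
      vapply(pair_member_years, function(v) y %in% v, TRUE)
    }
    net <- trade_network(pool)
    idx <- which(present)
    for (k in idx) add_edge(net, pairs[k, 1L], pairs[k, 2L])
    networks[[as.character(y)]] <- net
    edge_counts[t] <- net$m
  }
  structure(
    list(years = years, networks = networks,
         edge_counts = data.frame(year = years, edges = edge_counts),
         pool = pool, persist = persist, entry = entry, min_run = min_run),
    class = "continuous_series"
  )
}

#' Coverage of the continuous network
#'
#' Per-year share of total trade volume and of distinct trading pairs carried
#' by edges of the continuous network, plus window means. Years with zero
#' total volume get `NA` shares.
#'
#' @param table The trade table the series was extracted from.
#' @param series A `continuous_series` from [extract_continuous()].
#' @return A list with `per_year` (data.frame year, volume_share,
#'   count_share) and `mean_volume_share`, `mean_count_share`.
#' @export
coverage_stats <- function(table, series) {
  per_year <- lapply(series$years, function(y) {
    rows <- table[table$year == y & table$quantity > 0, , drop = FALSE]
    total_vol <- sum(rows$quantity)
    net <- series$networks[[as.character(y)]]
    if (total_vol == 0 || nrow(rows) == 0L) {
      return(data.frame(year = y, volume_share = NA_real_, count_share = NA_real_))
    }
    in_cont <- mapply(function(i, e) has_edge(net, i, e), rows$importer, rows$exporter)
    data.frame(
      year = y,
      volume_share = sum(rows$quantity[in_cont]) / total_vol,
      count_share = sum(in_cont) / nrow(rows)
    )
  })
  per_year <- do.call(rbind, per_year)
  list(
    per_year = per_year,
    mean_volume_share = mean(per_year$volume_share, na.rm = TRUE),
    mean_count_share = mean(per_year$count_share, na.rm = TRUE)
  )
}

#' Fit and extrapolate a growth schedule from a continuous series
#'
#' Fits the yearly cumulative continuous-edge counts over a window (ordinary
#' least squares on count vs year by default; exponential via a log-linear
#' fit optional) and extrapolates integer, nondecreasing targets to the
#' horizon.
#'
#' @param series A `continuous_series`, or a data.frame with `year`, `edges`.
#' @param window Years used for fitting (default: all available).
#' @param horizon Last extrapolated year (default 2050).
#' @param form `"linear"` or `"exponential"`.
#' @return A [growth_schedule()] covering window start through horizon.
#' @export
fit_growth_schedule <- function(series, window = NULL, horizon = 2050L,
                                form = c("linear", "exponential")) {
  form <- match.arg(form)
  counts <- if (inherits(series, "continuous_series")) series$edge_counts else series
  if (!is.null(window)) counts <- counts[counts$year %in% window, , drop = FALSE]
  if (nrow(counts) < 3L) stop("need at least 3 years of edge counts to fit a schedule")
  years_out <- seq(min(counts$year), horizon)
  if (stats::sd(counts$edges) == 0) {
    warning("edge counts are constant; returning a constant schedule")
    return(growth_schedule(years_out, rep(counts$edges[1L], length(years_out))))
  }
  pred <- if (form == "linear") {
    fit <- stats::lm(edges ~ year, data = counts)
    stats::predict(fit, newdata = data.frame(year = years_out))
  } else {
    fit <- stats::lm(log(pmax(edges, 1)) ~ year, data = counts)
    exp(stats::predict(fit, newdata = data.frame(year = years_out)))
  }
  growth_schedule(years_out, cummax(pmax(0, round(pred))))
}

#' Metric series of a continuous network
#'
#' Applies the metric suite to every yearly snapshot.
#'
#' @param series A `continuous_series`.
#' @param suite `"all"` or `"fitting"`.
#' @return A data.frame with one row per year.
#' @export
empirical_metric_series <- function(series, suite = "all") {
  do.call(rbind, lapply(seq_along(series$years), function(t) {
    network_metrics(series$networks[[t]], year = series$years[t], suite = suite)
  }))
}
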