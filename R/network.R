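#' Directed, unweighted trade network over a fixed country pool
#'
#' A `trade_network` holds the state of a directed, unweighted, self-loop-free
#' trade graph over a fixed pool of countries. An edge (i, j) means "country i
#' imports from country j"; reciprocal trade between two countries is
#' represented by two separate directed edges. The object is an environment
#' (reference semantics) so that the growth loop can update degree bookkeeping
#' in place; use [net_copy()] when an independent copy is needed.
#'
#' @param pool Either a positive integer (pool size; countries get synthetic
#'   labels `C001`, `C002`, ...) or a character vector of unique country
#'   labels (e.g. ISO 3166-1 alpha-3 codes). Defaults to the 244 countries of
#'   the world trade system.
#' @return An object of class `trade_network` with fields `labels`, `n`,
#'   `adj` (n x n logical adjacency, `adj[i, j]` = i imports from j),
#'   `edges` (m x 2 integer matrix of importer, exporter indices),
#'   `in_deg`, `out_deg` (integer vectors) and `m` (edge count).
#' @examples
#' net <- trade_network(5)
#' add_edge(net, 1, 2)
#' net$m
#' @export
trade_network <- function(pool = 244) {
  if (is.numeric(pool) && length(pool) == 1L) {
    stopifnot(pool >= 1, pool == as.integer(pool))
    labels <- sprintf("C%03d", seq_len(pool))
  } else {
    labels <- as.character(pool)
  }
  if (anyDuplicated(labels)) {
    stop("country pool labels must be unique")
  }
  n <- length(labels)
  net <- new.env(parent = emptyenv())
  net$labels <- labels
  net$n <- n
  net$adj <- matrix(FALSE, n, n, dimnames = NULL)
  net$edges <- matrix(integer(0), ncol = 2L)
  net$in_deg <- integer(n)
  net$out_deg <- integer(n)
  net$m <- 0L
  class(net) <- "trade_network"
  net
}

#' @export
print.trade_network <- function(x, ...) {
  cat(sprintf(
    "<trade_network> pool=%d countries, m=%d directed edges, %d active nodes\n",
    x$n, x$m, length(active_nodes(x))
  ))
  invisible(x)
}

#' Deep copy of a trade network
#'
#' @param net A [trade_network()].
#' @return An independent copy sharing no state with `net`.
#' @export
net_copy <- function(net) {
  out <- new.env(parent = emptyenv())
  for (f in ls(net)) assign(f, get(f, envir = net), envir = out)
  class(out) <- "trade_network"
  out
}

resolve_country <- function(net, x) {
  if (is.character(x)) {
    idx <- match(x, net$labels)
    if (anyNA(idx)) stop("unknown country label: ", paste(x[is.na(idx)], collapse = ", "))
    return(idx)
  }
  x <- as.integer(x)
  if (any(x < 1L | x > net$n)) stop("country index out of range 1..", net$n)
  x
}

#' Add a directed trade edge
#'
#' Adds the edge "importer imports from exporter" and updates the degree
#' bookkeeping of the two endpoints. Self-loops and duplicate edges are
#' rejected with an error.
#'
#' @param net A [trade_network()]; modified in place.
#' @param importer,exporter Country index (1-based) or label.
#' @return `net`, invisibly.
#' @export
add_edge <- function(net, importer, exporter) {
  i <- resolve_country(net, importer)
  j <- resolve_country(net, exporter)
  stopifnot(length(i) == 1L, length(j) == 1L)
  if (i == j) stop("self-loops are excluded: a country cannot trade with itself")
  if (net$adj[i, j]) stop("duplicate edge: ", net$labels[i], " already imports from ", net$labels[j])
  net$adj[i, j] <- TRUE
  net$edges <- rbind(net$edges, c(i, j))
  net$in_deg[i] <- net$in_deg[i] + 1L
  net$out_deg[j] <- net$out_deg[j] + 1L
  net$m <- net$m + 1L
  invisible(net)
}

#' @rdname add_edge
#' @export
has_edge <- function(net, importer, exporter) {
  net$adj[resolve_country(net, importer), resolve_country(net, exporter)]
}

#' Total degree of every country
#'
#' @param net A [trade_network()].
#' @return Integer vector of in-degree + out-degree, length `net$n`.
#' @export
total_degree <- function(net) net$in_deg + net$out_deg

#' Preferential-attachment fitness
#'
#' A country's fitness when the network holds m directed edges is its total
#' degree divided by m: the fraction of all trades it is involved in. For the
#' empty network (m = 0) fitness is defined as 0, so the connection
#' probability reduces to the baseline epsilon for the very first edges.
#'
#' @param net A [trade_network()].
#' @param i Optional country index/label vector; default all countries.
#' @return Numeric vector of fitness values in [0, 1].
#' @export
fitness <- function(net, i = NULL) {
  d <- total_degree(net)
  x <- if (net$m == 0L) rep(0, net$n) else d / net$m
  if (is.null(i)) x else x[resolve_country(net, i)]
}

#' Countries currently engaged in trade
#'
#' @param net A [trade_network()].
#' @return Integer vector of indices of nodes with total degree >= 1.
#' @export
active_nodes <- function(net) which(total_degree(net) >= 1L)

#' Edge-wise reciprocity
#'
#' Fraction of directed edges whose reverse edge is also present.
#'
#' @param net A [trade_network()].
#' @return A fraction in [0, 1]; `NA` for the empty network.
#' @export
reciprocity <- function(net) {
  if (net$m == 0L) return(NA_real_)
  ed <- net$edges
  sum(net$adj[cbind(ed[, 2L], ed[, 1L])]) / net$m
}

# Remove all outgoing (export) edges of the given countries.
# Returns the number of edges removed. Importer-side edges are untouched.
remove_out_edges <- function(net, targets) {
  targets <- resolve_country(net, targets)
  if (net$m == 0L || length(targets) == 0L) return(0L)
  drop <- net$edges[, 2L] %in% targets
  n_drop <- sum(drop)
  if (n_drop == 0L) return(0L)
  dropped <- net$edges[drop, , drop = FALSE]
  net$adj[dropped] <- FALSE
  lost_in <- tabulate(dropped[, 1L], nbins = net$n)
  net$in_deg <- net$in_deg - lost_in
  net$out_deg[targets] <- 0L
  net$edges <- net$edges[!drop, , drop = FALSE]
  net$m <- net$m - n_drop
  n_drop
}

#' Convert to an igraph graph
#'
#' Edges point in the direction of commodity flow (exporter to importer).
#'
#' @param net A [trade_network()].
#' @param active_only Keep only nodes with total degree >= 1 (default). The
#'   full 244-country pool mostly contains isolated nodes, which standard
#'   path/component routines should not see.
#' @return An `igraph` directed graph.
#' @export
as_igraph <- function(net, active_only = TRUE) {
  keep <- if (active_only) active_nodes(net) else seq_len(net$n)
  if (net$m == 0L) {
    g <- igraph::make_empty_graph(n = length(keep), directed = TRUE)
  } else {
    el <- cbind(net$edges[, 2L], net$edges[, 1L]) # exporter -> importer
    g <- igraph::graph_from_edgelist(matrix(match(el, keep), ncol = 2L), directed = TRUE)
    g <- igraph::add_vertices(g, max(0L, length(keep) - igraph::vcount(g)))
  }
  igraph::V(g)$name <- net$labels[keep]
  g
}

#' Export and import edge lists as CSV
#'
#' One row per directed edge, columns `importer,exporter`, using pool labels.
#'
#' @param net A [trade_network()].
#' @param path File path.
#' @return `write_edgelist()`: the path, invisibly. `read_edgelist()`: a
#'   [trade_network()] over `pool`.
#' @export
write_edgelist <- function(net, path) {
  df <- data.frame(
    importer = net$labels[net$edges[, 1L]],
    exporter = net$labels[net$edges[, 2L]]
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edgelist
#' @param pool Pool for the reconstructed network (size or labels). Defaults
#'   to the labels found in the file.
#' @export
read_edgelist <- function(path, pool = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("importer", "exporter") %in% names(df))) {
    stop("edge-list CSV must have columns importer, exporter")
  }
  if (is.null(pool)) pool <- sort(unique(c(df$importer, df$exporter)))
  net <- trade_network(pool)
  for (k in seq_len(nrow(df))) add_edge(net, df$importer[k], df$exporter[k])
  net
}
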