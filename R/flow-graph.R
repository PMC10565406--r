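#' Directed mobility flow graph
#'
#' A `flow_graph` holds the inter-tile weighted adjacency matrix `A`
#' (zero diagonal) restricted to the largest strongly connected component
#' (LSCC) of the flow network, plus the intra-tile (self-loop) flow vector
#' kept separately. Node order is fixed lexicographically over tile IDs so
#' matrices are reproducible across runs.
#'
#' @param A square non-negative matrix of inter-tile flows (diagonal must be
#'   zero or is moved to `intra`). Row/column names are the tile IDs.
#' @param intra non-negative vector of intra-tile flows, one per node
#'   (default 0).
#' @param check_connected if `TRUE` (default) require strong connectivity;
#'   use [build_baseline_graph()] to restrict arbitrary flow tables to the
#'   LSCC.
#' @return An object of class `flow_graph`: a list with elements `nodes`,
#'   `A` (dense base matrix), `intra`, `d_out` (out-strengths `A %*% 1`),
#'   and `n_dropped` (nodes outside the LSCC removed during construction).
#' @seealso [build_baseline_graph()], [random_walk_model()]
#' @export
flow_graph <- function(A, intra = NULL, check_connected = TRUE) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("A must be square")
  if (is.null(rownames(A))) {
    rownames(A) <- colnames(A) <- as.character(seq_len(nrow(A)))
  }
  if (!identical(rownames(A), colnames(A))) stop("row/column names of A differ")
  if (any(A < 0)) stop("negative flows in A")
  if (is.null(intra)) intra <- stats::setNames(rep(0, nrow(A)), rownames(A))
  if (is.null(names(intra))) names(intra) <- rownames(A)
  if (any(intra < 0)) stop("negative intra-tile flows")
  # self-loops live in `intra`, never on the diagonal of A
  dg <- diag(A)
  if (any(dg > 0)) {
    intra <- intra + dg
    diag(A) <- 0
  }
  ord <- order(rownames(A))
  A <- A[ord, ord, drop = FALSE]
  intra <- intra[rownames(A)]
  g <- structure(list(nodes = rownames(A), A = A, intra = intra,
                      d_out = rowSums(A), n_dropped = 0L),
                 class = "flow_graph")
  if (check_connected && !is_strongly_connected(A))
    stop("graph is not strongly connected; use build_baseline_graph() to restrict to the LSCC")
  if (check_connected && any(g$d_out <= 0))
    stop("zero out-strength node in a supposedly strongly connected graph")
  g
}

#' @export
print.flow_graph <- function(x, ...) {
  cat(sprintf("flow_graph: %d nodes, %d directed edges\n",
              length(x$nodes), sum(x$A > 0)))
  cat(sprintf("  total inter-tile flow %.6g, intra-tile flow %.6g\n",
              sum(x$A), sum(x$intra)))
  if (x$n_dropped > 0)
    cat(sprintf("  %d nodes outside the LSCC were dropped\n", x$n_dropped))
  invisible(x)
}

is_strongly_connected <- function(A) {
  g <- igraph::graph_from_adjacency_matrix((A > 0) * 1, mode = "directed")
  igraph::is_connected(g, mode = "strong")
}

# index of LSCC membership; ties between equally large components broken by
# total edge weight
lscc_members <- function(A) {
  g <- igraph::graph_from_adjacency_matrix((A > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    wt <- vapply(best, function(k) {
      idx <- which(comp$membership == k)
      sum(A[idx, idx])
    }, numeric(1))
    best <- best[which.max(wt)]
  }
  which(comp$membership == best)
}

#' Build the baseline mobility graph from origin-destination records
#'
#' Averages daily trip counts per ordered tile pair over a date window,
#' separates self-loops into the intra-tile vector, and restricts the graph
#' to its largest strongly connected component (LSCC). Days of the window
#' with no record for a pair contribute zero trips to that pair's average.
#'
#' @param flow_records data frame with columns `origin`, `destination`,
#'   `trips`, and optionally `date`. Without a `date` column the table is
#'   treated as a single day's (or already-averaged) flows.
#' @param date_window optional vector of dates (anything coercible by
#'   [as.Date()]) defining the averaging window; defaults to all dates
#'   present. The denominator of the average is the window length.
#' @return a [flow_graph()] whose `n_dropped` records how many nodes fell
#'   outside the LSCC.
#' @examples
#' od <- data.frame(origin = c("a", "b", "c"),
#'                  destination = c("b", "c", "a"), trips = 1)
#' g <- build_baseline_graph(od)
#' g$d_out
#' @export
build_baseline_graph <- function(flow_records, date_window = NULL) {
  flow_records <- validate_od_table(flow_records)
  if (!is.null(flow_records$date)) {
    dates <- as.Date(flow_records$date)
    if (is.null(date_window)) date_window <- sort(unique(dates))
    date_window <- as.Date(date_window)
    if (length(date_window) == 0) stop("empty date window")
    keep <- dates %in% date_window
    flow_records <- flow_records[keep, , drop = FALSE]
    n_days <- length(date_window)
  } else {
    n_days <- 1L
  }
  if (nrow(flow_records) == 0) stop("no records in the date window")
  nodes <- sort(unique(c(flow_records$origin, flow_records$destination)))
  oi <- match(flow_records$origin, nodes)
  di <- match(flow_records$destination, nodes)
  N <- length(nodes)
  A <- matrix(0, N, N, dimnames = list(nodes, nodes))
  # accumulate then divide once: mean over the window with absent days as 0
  lin <- oi + N * (di - 1L)
  acc <- rowsum(flow_records$trips, lin)
  A[as.integer(rownames(acc))] <- acc[, 1]
  A <- A / n_days
  intra <- diag(A)
  diag(A) <- 0
  keep <- lscc_members(A)
  if (sum(A[keep, keep, drop = FALSE]) == 0)
    stop("empty LSCC: no inter-tile edges survive")
  g <- flow_graph(A[keep, keep, drop = FALSE], intra[keep])
  g$n_dropped <- N - length(keep)
  g
}

validate_od_table <- function(x) {
  x <- as.data.frame(x)
  need <- c("origin", "destination", "trips")
  if (!all(need %in% names(x)))
    stop("flow table must have columns origin, destination, trips")
  x$origin <- as.character(x$origin)
  x$destination <- as.character(x$destination)
  bad <- which(!is.finite(x$trips) | x$trips < 0)
  if (length(bad))
    stop("malformed trips values at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  x
}

#' Read / write origin-destination flow tables
#'
#' The OD-flow CSV dialect has columns `date,origin,destination,trips`
#' (ISO dates; rows with `origin == destination` are intra-tile flows).
#' `date` may be absent for baseline (already averaged) tables.
#'
#' @param path CSV file path.
#' @return `read_od_csv`: a data frame of validated records.
#' @export
read_od_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(origin = "character",
                                      destination = "character"))
  validate_od_table(x)
}

#' @rdname read_od_csv
#' @param flow_records data frame of OD records.
#' @export
write_od_csv <- function(flow_records, path) {
  utils::write.csv(validate_od_table(flow_records), path, row.names = FALSE)
  invisible(path)
}

#' Write a flow graph as edge-list plus node-index CSV files
#'
#' @param graph a [flow_graph()].
#' @param dir output directory (created if needed); writes `edges.csv`
#'   (`origin,destination,trips`) and `nodes.csv` (`node,index,intra`).
#' @return `dir`, invisibly.
#' @export
write_flow_graph <- function(graph, dir) {
  stopifnot(inherits(graph, "flow_graph"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nz <- which(graph$A > 0, arr.ind = TRUE)
  edges <- data.frame(origin = graph$nodes[nz[, 1]],
                      destination = graph$nodes[nz[, 2]],
                      trips = graph$A[nz])
  utils::write.csv(edges[order(edges$origin, edges$destination), ],
                   file.path(dir, "edges.csv"), row.names = FALSE)
  utils::write.csv(data.frame(node = graph$nodes,
                              index = seq_along(graph$nodes),
                              intra = unname(graph$intra)),
                   file.path(dir, "nodes.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read reference partitions from a `node,community` CSV
#'
#' @param path CSV with columns `node` and `community`.
#' @return a [partition()].
#' @export
read_partition_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(node = "character"))
  if (!all(c("node", "community") %in% names(x)))
    stop("partition CSV must have columns node, community")
  partition(x$community, x$node)
}

#' @rdname read_partition_csv
#' @param p a [partition()].
#' @export
write_partition_csv <- function(p, path) {
  p <- as_partition(p)
  utils::write.csv(data.frame(node = names(p), community = unclass(p)),
                   path, row.names = FALSE)
  invisible(path)
}
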