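#' Flow coverage and nodal containment of a partition
#'
#' Quantifies how well a partition contains the mobility flows. With
#' `Atilde = A + diag(intra)` the flow matrix including intra-tile trips
#' and `H` the partition indicator, `F = H^T Atilde H` is the lumped
#' community-level flow matrix. The coverage of community `k` is
#' `C_k = F_kk / d_hat_k` with `d_hat = F 1` the lumped out-strengths:
#' the probability that the lumped Markov process stays in state `k`. The
#' partition coverage `C` is the `d_hat`-weighted average of the `C_k`,
#' i.e. the ratio of flow contained within communities to total flow. The
#' nodal containment `NC_i = (A H)_{i, c(i)} / d_i` uses the inter-tile
#' out-strength `d_i = (A 1)_i` only (self-loops excluded), and `NC` is
#' its plain average over nodes.
#'
#' @param graph a [flow_graph()].
#' @param p a [partition()] covering all graph nodes.
#' @return An object of class `containment_report`: list with `F`,
#'   `d_hat`, `community_coverage` (C_k), `coverage` (C),
#'   `nodal_containment` (NC_i), `avg_nodal_containment` (NC), and
#'   `n_communities`.
#' @examples
#' g <- build_baseline_graph(data.frame(origin = c("a","b","c"),
#'   destination = c("b","c","a"), trips = 1))
#' containment(g, partition(c(a = 1, b = 1, c = 2)))
#' @export
containment <- function(graph, p) {
  stopifnot(inherits(graph, "flow_graph"))
  p <- subset_partition(as_partition(p), graph$nodes)
  H <- indicator_matrix(p)
  Atilde <- graph$A + diag(graph$intra, nrow = length(graph$intra))
  F_lump <- crossprod(H, Atilde %*% H)
  d_hat <- rowSums(F_lump)
  C_k <- ifelse(d_hat > 0, diag(F_lump) / d_hat, 0)
  C <- sum(d_hat * C_k) / sum(d_hat)
  d_i <- graph$d_out
  own <- (graph$A %*% H)[cbind(seq_along(p), unclass(p))]
  usable <- d_i > 0
  if (!all(usable))
    warning(sum(!usable), " nodes with zero inter-tile out-strength excluded from NC")
  NC_i <- rep(NA_real_, length(p))
  NC_i[usable] <- own[usable] / d_i[usable]
  names(NC_i) <- graph$nodes
  structure(list(F = F_lump, d_hat = d_hat,
                 community_coverage = C_k, coverage = C,
                 nodal_containment = NC_i,
                 avg_nodal_containment = mean(NC_i[usable]),
                 n_communities = attr(p, "n_communities")),
            class = "containment_report")
}

#' @export
print.containment_report <- function(x, ...) {
  cat(sprintf("containment_report: %d communities\n", x$n_communities))
  cat(sprintf("  coverage C = %.4f, avg nodal containment NC = %.4f\n",
              x$coverage, x$avg_nodal_containment))
  invisible(x)
}

#' Compare a scale scan against a reference partition
#'
#' Computes the NVI between a reference partition (e.g. an administrative
#' geography) and the best partition at every scale of a scan, and
#' reports the best-matching scale (argmin of the curve). Nodes absent
#' from the reference are dropped from both partitions before the
#' comparison, with a count.
#'
#' @param scan a [scale_scan()].
#' @param ref a [partition()]; may cover only part of the scan's nodes.
#' @return list with `nvi_curve`, `scales`, `best_index`, `best_scale`,
#'   `n_dropped`.
#' @export
compare_to_reference <- function(scan, ref) {
  stopifnot(inherits(scan, "scale_scan"))
  ref <- as_partition(ref)
  common <- intersect(scan$nodes, names(ref))
  if (length(common) == 0) stop("no overlap between scan nodes and reference")
  n_dropped <- length(scan$nodes) - length(common)
  ref_c <- subset_partition(ref, common)
  curve <- vapply(scan$partitions, function(p)
    nvi(subset_partition(p, common), ref_c), numeric(1))
  best <- which.min(curve)
  list(nvi_curve = curve, scales = scan$scales, best_index = best,
       best_scale = scan$scales[best], n_dropped = n_dropped)
}

#' Two-sided Mann-Whitney rank-sum comparison
#'
#' Compares two samples of per-community or per-node statistics (e.g.
#' community coverages under two partitions). Uses the exact distribution
#' for small untied samples and the normal approximation with tie
#' correction otherwise. If every value in both samples is identical the
#' test is degenerate and `p = 1` is returned with a flag.
#'
#' @param x,y numeric samples.
#' @return list with `p_value`, `statistic` (U for `x`), `degenerate`.
#' @export
rank_sum_compare <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1L)
    return(list(p_value = 1, statistic = length(x) * length(y) / 2,
                degenerate = TRUE))
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       degenerate = FALSE)
}
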