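#' Node partitions
#'
#' A `partition` is an assignment of every node of a graph to exactly one
#' community. Internally it is stored as an integer label vector named by
#' node ID, with labels normalised to the contiguous range `1..c`. It is
#' equivalent to the N x c indicator matrix H with `H[i, j] = 1` iff node i
#' belongs to community j.
#'
#' @param labels community labels: an integer, factor or character vector,
#'   one entry per node.
#' @param nodes node IDs; defaults to `names(labels)` and must be unique.
#' @return An object of class `partition`: a named integer vector with
#'   attribute `n_communities`.
#' @examples
#' p <- partition(c(a = 1, b = 1, c = 2))
#' n_communities(p)
#' @export
partition <- function(labels, nodes = names(labels)) {
  if (length(labels) == 0L) stop("partition needs at least one node")
  if (is.null(nodes)) nodes <- as.character(seq_along(labels))
  nodes <- as.character(nodes)
  if (length(nodes) != length(labels)) stop("`nodes` and `labels` lengths differ")
  if (anyDuplicated(nodes)) stop("duplicated node IDs in partition")
  if (anyNA(labels)) stop("NA labels are not allowed")
  lab <- as.integer(factor(labels, levels = unique(labels)))
  # renumber to contiguous 1..c in order of first appearance
  structure(stats::setNames(lab, nodes),
            n_communities = max(lab), class = "partition")
}

#' @rdname partition
#' @param x object to coerce or query.
#' @export
as_partition <- function(x) {
  if (inherits(x, "partition")) return(x)
  partition(x)
}

#' @rdname partition
#' @export
n_communities <- function(x) {
  x <- as_partition(x)
  attr(x, "n_communities")
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("partition: %d nodes, %d communities\n",
              length(x), attr(x, "n_communities")))
  sizes <- tabulate(unclass(x))
  cat("community sizes:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

#' Indicator matrix of a partition
#'
#' @param p a [partition()].
#' @return N x c binary matrix H with one 1 per row.
#' @export
indicator_matrix <- function(p) {
  p <- as_partition(p)
  c <- attr(p, "n_communities")
  H <- matrix(0, length(p), c, dimnames = list(names(p), NULL))
  H[cbind(seq_along(p), unclass(p))] <- 1
  H
}

#' Restrict a partition to a node subset
#'
#' @param p a [partition()].
#' @param nodes character vector of node IDs to keep (order respected).
#' @return a [partition()] on `nodes`; labels renumbered contiguously.
#' @export
subset_partition <- function(p, nodes) {
  p <- as_partition(p)
  missing <- setdiff(nodes, names(p))
  if (length(missing))
    stop("partition is missing nodes: ", paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ...")
  partition(unclass(p)[nodes], nodes)
}

# joint contingency counts of two aligned label vectors (same node order)
joint_counts <- function(a, b) {
  ca <- max(a); cb <- max(b)
  tab <- tabulate(a + ca * (b - 1L), nbins = ca * cb)
  matrix(tab, ca, cb)
}

#' Normalised variation of information between two partitions
#'
#' NVI(p, q) = VI(p, q) / H(p, q), where VI is the variation of information
#' and H(p, q) the joint entropy of the empirical joint label distribution
#' (uniform weight per node, natural logarithms; the ratio is base
#' invariant). NVI is a universal metric on partitions with values in
#' \[0, 1\]: 0 means identical partitions, 1 maximally dissimilar. When both
#' partitions are trivial (joint entropy 0) the NVI is defined as 0.
#'
#' @param p,q partitions over the same node set (order may differ; matched
#'   by node ID when named).
#' @return scalar in \[0, 1\].
#' @examples
#' p <- partition(c(a = 1, b = 1, c = 2, d = 2))
#' q <- partition(c(a = 1, b = 2, c = 1, d = 2))
#' nvi(p, q)  # 1: maximally dissimilar pair on 4 nodes
#' @export
nvi <- function(p, q) {
  p <- as_partition(p); q <- as_partition(q)
  if (length(p) != length(q) || !setequal(names(p), names(q)))
    stop("partitions are over different node sets")
  q <- subset_partition(q, names(p))
  nvi_labels(unclass(p), unclass(q))
}

# core NVI on aligned integer label vectors (1-based, contiguous)
nvi_labels <- function(a, b) {
  n <- length(a)
  tab <- joint_counts(a, b)
  pj <- tab[tab > 0] / n
  h_joint <- -sum(pj * log(pj))
  if (h_joint <= 0) return(0)
  pa <- rowSums(tab) / n; pa <- pa[pa > 0]
  pb <- colSums(tab) / n; pb <- pb[pb > 0]
  ha <- -sum(pa * log(pa))
  hb <- -sum(pb * log(pb))
  vi <- 2 * h_joint - ha - hb
  max(0, min(1, vi / h_joint))
}
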