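# Independent oracles and small fixtures used across the suite.
# Everything here is deliberately written by a different route than the
# package implementation (double loops, enumeration, dense eigensolvers).

# all partitions of n elements as label vectors (restricted growth strings)
enumerate_partitions <- function(n) {
  out <- list()
  grow <- function(lab) {
    i <- length(lab) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- lab; return(invisible()) }
    for (v in seq_len(max(lab, 0L) + 1L)) grow(c(lab, v))
  }
  grow(integer(0))
  out
}

# quality Tr[H^T Q H] by explicit double loop
quality_by_loop <- function(Q, lab) {
  s <- 0
  for (i in seq_along(lab)) for (j in seq_along(lab))
    if (lab[i] == lab[j]) s <- s + Q[i, j]
  s
}

# NVI by explicit probability table (natural log)
nvi_by_table <- function(a, b) {
  n <- length(a)
  tab <- table(a, b) / n
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hj <- h(as.vector(tab))
  if (hj == 0) return(0)
  vi <- 2 * hj - h(rowSums(tab)) - h(colSums(tab))
  vi / hj
}

# containment statistics by explicit double-loop summation
containment_by_loop <- function(A, intra, lab) {
  N <- nrow(A)
  c <- max(lab)
  Atil <- A
  for (i in seq_len(N)) Atil[i, i] <- Atil[i, i] + intra[i]
  F_ <- matrix(0, c, c)
  for (i in seq_len(N)) for (j in seq_len(N))
    F_[lab[i], lab[j]] <- F_[lab[i], lab[j]] + Atil[i, j]
  d_hat <- rowSums(F_)
  C_k <- diag(F_) / d_hat
  C <- sum(d_hat * C_k) / sum(d_hat)
  NC_i <- numeric(N)
  for (i in seq_len(N)) {
    own <- 0; tot <- 0
    for (j in seq_len(N)) if (j != i) {
      tot <- tot + A[i, j]
      if (lab[j] == lab[i]) own <- own + A[i, j]
    }
    NC_i[i] <- own / tot
  }
  list(F = F_, d_hat = d_hat, C_k = C_k, C = C, NC_i = NC_i,
       NC = mean(NC_i))
}

# stationary distribution by dense left eigendecomposition
stationary_by_eigen <- function(A) {
  M <- A / rowSums(A)
  e <- eigen(t(M))
  k <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, k])
  v <- v / sum(v)
  if (any(v < -1e-10)) v <- -v
  v / sum(v)
}

# random strongly connected directed graph with log-normal weights
random_sc_graph <- function(n, density = 0.5, seed = 1) {
  set.seed(seed)
  repeat {
    A <- matrix(0, n, n)
    off <- which(row(A) != col(A))
    pick <- off[stats::runif(length(off)) < density]
    A[pick] <- stats::rlnorm(length(pick))
    g <- igraph::graph_from_adjacency_matrix((A > 0) * 1, mode = "directed")
    if (igraph::is_connected(g, mode = "strong") && all(rowSums(A) > 0)) break
  }
  rownames(A) <- colnames(A) <- sprintf("n%02d", seq_len(n))
  A
}

# flow_graph from a raw adjacency without LSCC machinery
fg <- function(A, intra = NULL) flowscales::flow_graph(A, intra)

# OD table from an adjacency matrix plus intra vector
od_from_matrix <- function(A, intra = NULL) {
  nodes <- rownames(A)
  nz <- which(A > 0, arr.ind = TRUE)
  tab <- data.frame(origin = nodes[nz[, 1]], destination = nodes[nz[, 2]],
                    trips = A[nz])
  if (!is.null(intra))
    tab <- rbind(tab, data.frame(origin = nodes, destination = nodes,
                                 trips = intra))
  tab
}

# standard two-level planted fixture used by several tests
planted_fixture <- function(seed, levels = c(4, 4), leaf_size = 4,
                            decay = 0.1, asymmetry = 0.1) {
  plan <- hierarchy_plan(levels = levels, leaf_size = leaf_size,
                         decay = decay, asymmetry = asymmetry)
  tab <- generate_hierarchical_flows(plan, seed = seed)
  g <- build_baseline_graph(tab)
  list(plan = plan, table = tab, graph = g,
       model = random_walk_model(g), planted = attr(tab, "planted"))
}

random_partition_labels <- function(n, c) {
  lab <- sample.int(c, n, replace = TRUE)
  match(lab, unique(lab))
}
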