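#' Random-walk model of a flow graph
#'
#' From a strongly connected [flow_graph()] derives the discrete-time
#' transition matrix `M = D_out^+ A`, its stationary distribution `pi`
#' (the unique probability vector with `pi M = pi`, equivalent to PageRank
#' without teleportation), and the random-walk Laplacian
#' `L = I - D_out^+ A` governing the continuous-time diffusion used by
#' Markov stability.
#'
#' The stationary distribution is computed by solving the dense linear
#' system with an appended normalisation row rather than by power
#' iteration, which fails on periodic chains (e.g. 2-cycles).
#'
#' @param graph a [flow_graph()].
#' @param tol condition-number threshold above which the linear solve is
#'   considered unreliable.
#' @return An object of class `random_walk_model`: list with `M`, `pi`,
#'   `Pi` (diag(pi)), `L`, and `nodes`.
#' @examples
#' g <- build_baseline_graph(data.frame(origin = c("a","b"),
#'   destination = c("b","a"), trips = c(2, 1)))
#' m <- random_walk_model(g)
#' m$pi  # (1/2, 1/2): two-state chains are always reversible
#' @export
random_walk_model <- function(graph, tol = 1e12) {
  stopifnot(inherits(graph, "flow_graph"))
  A <- graph$A
  M <- A / graph$d_out           # rows scaled by out-strength
  pi <- stationary_distribution(graph, tol = tol)
  L <- diag(nrow(A)) - M
  structure(list(M = M, pi = pi, Pi = diag(pi, nrow = length(pi)),
                 L = L, nodes = graph$nodes),
            class = "random_walk_model")
}

#' @export
print.random_walk_model <- function(x, ...) {
  cat(sprintf("random_walk_model: %d states\n", length(x$pi)))
  cat(sprintf("  detailed-balance deviation %.4g\n",
              detailed_balance_deviation(x)))
  invisible(x)
}

#' Stationary distribution of the mobility random walk
#'
#' Solves `pi M = pi`, `sum(pi) = 1` as a dense linear system (the
#' normalisation condition replaces the redundancy of the singular
#' balance equations). For symmetric `A` this reduces to the reversible
#' closed form `pi_i = d_out_i / sum(d_out)`.
#'
#' @inheritParams random_walk_model
#' @return named probability vector `pi`.
#' @export
stationary_distribution <- function(graph, tol = 1e12) {
  stopifnot(inherits(graph, "flow_graph"))
  A <- graph$A
  N <- nrow(A)
  M <- A / graph$d_out
  # (M^T - I) pi^T = 0 with one balance row traded for the normalisation
  S <- t(M) - diag(N)
  S[N, ] <- 1
  b <- c(rep(0, N - 1), 1)
  kap <- kappa(S, exact = FALSE)
  if (!is.finite(kap) || kap > tol)
    stop(sprintf("stationary-distribution system ill-conditioned (condition estimate %.3g)", kap))
  pi <- solve(S, b)
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  stats::setNames(pi, graph$nodes)
}

#' Pairwise relative asymmetry of tile pairs
#'
#' `PRA_ij = |A_ij - A_ji| / (A_ij + A_ji)` for unordered pairs with
#' positive total flow: 0 for perfectly symmetric pairs, 1 for one-way
#' connections. Invariant to global rescaling of the flows.
#'
#' @param graph a [flow_graph()].
#' @param probs quantiles to report (default quartiles).
#' @return list with `pairs` (data frame `i, j, pra`), `quantiles`, and
#'   `n_one_way` (count of pairs with PRA = 1).
#' @export
pairwise_relative_asymmetry <- function(graph, probs = c(0.25, 0.5, 0.75)) {
  stopifnot(inherits(graph, "flow_graph"))
  A <- graph$A
  up <- which(upper.tri(A) & (A + t(A)) > 0, arr.ind = TRUE)
  tot <- A[up] + t(A)[up]
  pra <- abs(A[up] - t(A)[up]) / tot
  pairs <- data.frame(i = graph$nodes[up[, 1]], j = graph$nodes[up[, 2]],
                      pra = pra)
  list(pairs = pairs,
       quantiles = stats::quantile(pra, probs = probs, names = TRUE),
       n_one_way = sum(pra == 1))
}

#' Detailed-balance deviation of the stationary random walk
#'
#' Relative Frobenius deviation `||Pi M - (Pi M)^T||_F / ||Pi M||_F`,
#' quantifying the irreversibility of the chain at equilibrium: 0 iff the
#' chain satisfies detailed balance (reversible), e.g. whenever `A` is
#' symmetric or the graph has only two nodes.
#'
#' @param model a [random_walk_model()].
#' @return non-negative scalar.
#' @export
detailed_balance_deviation <- function(model) {
  stopifnot(inherits(model, "random_walk_model"))
  PM <- model$Pi %*% model$M
  norm(PM - t(PM), "F") / norm(PM, "F")
}

#' Centrality diagnostics: stationary distribution vs strength measures
#'
#' Coefficients of determination (R^2 of simple linear regression) between
#' the stationary distribution and (i) the out-strengths and (ii) the
#' intra-tile flows. In empirical mobility networks both are strongly
#' correlated with `pi`, reflecting concentration of mobility in urban
#' areas.
#'
#' @param graph a [flow_graph()].
#' @param model the matching [random_walk_model()].
#' @return list with `r2_out_strength` and `r2_intra`.
#' @export
centrality_diagnostics <- function(graph, model) {
  stopifnot(inherits(graph, "flow_graph"), inherits(model, "random_walk_model"))
  if (length(graph$nodes) < 3) stop("need at least 3 nodes")
  r2 <- function(y, x) {
    if (stats::var(x) == 0)
      stop("undefined R^2: zero-variance regressor")
    stats::cor(y, x)^2
  }
  list(r2_out_strength = r2(model$pi, graph$d_out),
       r2_intra = r2(model$pi, graph$intra))
}
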