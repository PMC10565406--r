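#' Markov stability quality matrix
#'
#' Computes `Q(r) = Pi exp(-L r) - pi^T pi` for a Markov scale `r >= 0`.
#' The Markov stability of a partition with indicator matrix H is
#' `Tr[H^T Q(r) H]`: the probability that a random walker started at
#' stationarity is found in its starting community after time `r`, minus
#' the same probability for independent walkers. At `r = 0` the analytic
#' limit `Q = Pi - pi^T pi` is returned. The matrix exponential uses
#' scaling-and-squaring (via [Matrix::expm()]).
#'
#' The entries of `Q(r)` sum to 0 for every `r`, so the one-community
#' partition always has quality 0.
#'
#' @param model a [random_walk_model()].
#' @param r Markov scale (time of the continuous diffusion), `r >= 0`.
#' @return dense N x N matrix.
#' @export
quality_matrix <- function(model, r) {
  stopifnot(inherits(model, "random_walk_model"))
  if (!is.numeric(r) || length(r) != 1 || is.na(r) || r < 0)
    stop("Markov scale r must be a single non-negative number")
  pi <- model$pi
  P <- if (r == 0) diag(length(pi)) else
    as.matrix(Matrix::expm(-model$L * r))
  Q <- model$Pi %*% P - tcrossprod(pi)
  if (!all(is.finite(Q))) stop("non-finite entries in quality matrix")
  dimnames(Q) <- list(model$nodes, model$nodes)
  Q
}

#' Markov stability of a partition
#'
#' @param Q quality matrix from [quality_matrix()].
#' @param p a [partition()] of the same nodes (or an integer label vector
#'   aligned with the rows of `Q`).
#' @return the quality value `Tr[H^T Q H]`.
#' @export
partition_quality <- function(Q, p) {
  lab <- if (inherits(p, "partition")) unclass(subset_partition(p, rownames(Q))) else as.integer(p)
  sum(Q[outer(lab, lab, "==")])
}

#' Generalised Louvain optimisation of a quality matrix
#'
#' Greedy two-phase maximisation of `Tr[H^T Q H]` over partitions: nodes
#' are swept in random order and moved to the community with the largest
#' positive gain, then communities are aggregated by summing the
#' corresponding blocks of `Q`, and the two phases repeat until no gain
#' remains. Gains are evaluated on the symmetrised matrix `(Q + Q^T)/2`,
#' to which the trace objective is invariant; directionality enters
#' through the Laplacian and stationary distribution inside `Q`. Ties in
#' gain are broken toward the incumbent community so the sweep terminates.
#'
#' @param Q square finite quality matrix.
#' @param seed integer seed making the node sweep order reproducible.
#' @param gain_tol smallest gain counted as an improvement.
#' @return list with `partition` (a [partition()], labels in order of
#'   first appearance over the row order of `Q`) and `quality`.
#' @examples
#' g <- build_baseline_graph(data.frame(
#'   origin      = c("a","b","b","c","c","d","d","a"),
#'   destination = c("b","a","c","b","d","c","a","d"),
#'   trips       = c(5, 5, 0.1, 0.1, 5, 5, 0.1, 0.1)))
#' Q <- quality_matrix(random_walk_model(g), r = 1)
#' louvain_partition(Q, seed = 1)$partition
#' @export
louvain_partition <- function(Q, seed = 1L, gain_tol = 1e-12) {
  Q <- as.matrix(Q)
  if (nrow(Q) != ncol(Q)) stop("Q must be square")
  if (!all(is.finite(Q))) stop("NaN/Inf in quality matrix")
  nodes <- rownames(Q)
  N <- nrow(Q)
  if (N > 2000)
    stop("dense quality matrices above 2000 nodes are not supported")
  set.seed(as.integer(seed %% .Machine$integer.max))
  B <- (Q + t(Q)) / 2

  labels <- seq_len(N)           # node -> community of original nodes
  Bc <- B                        # aggregated matrix at current level
  repeat {
    n <- nrow(Bc)
    comm <- seq_len(n)
    # S[i, k] = sum of B over (i, members of community k)
    S <- Bc
    improved_level <- FALSE
    repeat {
      moved <- FALSE
      for (i in sample.int(n)) {
        a <- comm[i]
        self <- Bc[i, i]
        # gain of moving i from a to k: 2*S[i,k] - 2*(S[i,a] - self-term)
        gains <- 2 * (S[i, ] - (S[i, a] - self))
        gains[a] <- 0
        k <- which.max(gains)
        if (gains[k] > gain_tol && k != a) {
          comm[i] <- k
          S[, a] <- S[, a] - Bc[, i]
          S[, k] <- S[, k] + Bc[, i]
          moved <- TRUE
          improved_level <- TRUE
        }
      }
      if (!moved) break
    }
    # drop empty communities, renumber
    keep <- sort(unique(comm))
    comm <- match(comm, keep)
    labels <- comm[labels]
    if (!improved_level || length(keep) == n) break
    # aggregate: sum Q blocks
    H <- matrix(0, n, length(keep))
    H[cbind(seq_len(n), comm)] <- 1
    Bc <- crossprod(H, Bc %*% H)
  }
  lab <- match(labels, unique(labels))
  qual <- sum(B[outer(lab, lab, "==")])
  p <- partition(lab, nodes %||% as.character(seq_len(N)))
  list(partition = p, quality = qual)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scan Markov scales with repeated Louvain optimisation
#'
#' For each scale `s = log10(r)` of a strictly increasing grid, runs
#' [louvain_partition()] `n_repeats` times with distinct sub-seeds on
#' `Q(10^s)`, keeps the best-quality partition, and records two
#' robustness statistics: `nvi_within[s]`, the average pairwise NVI over
#' the ensemble of optimised partitions at `s` (low values mean the
#' non-convex optimisation is reproducible there), and the symmetric
#' cross-scale matrix `nvi_cross[s, s']` between the best partitions of
#' each pair of scales (blocks of low values mean persistence across
#' scales).
#'
#' For `n_repeats <= 50` all ensemble pairs enter `nvi_within`; beyond
#' that a fixed seeded subsample of 1225 pairs is used.
#'
#' @param model a [random_walk_model()].
#' @param scales strictly increasing vector of Markov scales `s`
#'   (log10 of the diffusion time); see [markov_scales()].
#' @param n_repeats Louvain repetitions per scale (>= 2).
#' @param seed master seed; sub-seeds are derived deterministically.
#' @return An object of class `scale_scan`: list with `scales`,
#'   `partitions` (best [partition()] per scale), `qualities`,
#'   `n_communities`, `nvi_within`, `nvi_cross`, `n_repeats`, `seed`,
#'   and `nodes`.
#' @export
scale_scan <- function(model, scales = markov_scales(), n_repeats = 50L,
                       seed = 1L) {
  stopifnot(inherits(model, "random_walk_model"))
  if (any(diff(scales) <= 0)) stop("scales must be strictly increasing")
  if (n_repeats < 2) stop("n_repeats must be >= 2")
  m <- length(scales)
  set.seed(as.integer(seed %% .Machine$integer.max))
  sub_seeds <- matrix(sample.int(.Machine$integer.max - 1L, m * n_repeats),
                      m, n_repeats)
  pair_seed <- sample.int(.Machine$integer.max - 1L, 1)

  best <- vector("list", m)
  qualities <- numeric(m)
  nvi_within <- numeric(m)
  label_mats <- vector("list", m)
  for (si in seq_len(m)) {
    Q <- quality_matrix(model, 10^scales[si])
    ens_labels <- matrix(0L, length(model$nodes), n_repeats)
    ens_qual <- numeric(n_repeats)
    for (rep in seq_len(n_repeats)) {
      fit <- louvain_partition(Q, seed = sub_seeds[si, rep])
      ens_labels[, rep] <- unclass(fit$partition)
      ens_qual[rep] <- fit$quality
    }
    ibest <- which.max(ens_qual)
    best[[si]] <- partition(ens_labels[, ibest], model$nodes)
    qualities[si] <- ens_qual[ibest]
    nvi_within[si] <- ensemble_mean_nvi(ens_labels, pair_seed)
    label_mats[[si]] <- ens_labels[, ibest]
  }
  nvi_cross <- matrix(0, m, m)
  for (u in seq_len(m - 1)) for (v in seq(u + 1, m)) {
    nvi_cross[u, v] <- nvi_cross[v, u] <-
      nvi_labels(label_mats[[u]], label_mats[[v]])
  }
  structure(list(scales = scales, partitions = best, qualities = qualities,
                 n_communities = vapply(best, n_communities, integer(1)),
                 nvi_within = nvi_within, nvi_cross = nvi_cross,
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 nodes = model$nodes),
            class = "scale_scan")
}

# mean pairwise NVI over an ensemble of label columns; all pairs when the
# ensemble is small, a fixed seeded subsample of pairs otherwise
ensemble_mean_nvi <- function(lab, pair_seed, max_all = 50L, n_sub = 1225L) {
  R <- ncol(lab)
  if (R <= max_all) {
    prs <- utils::combn(R, 2)
  } else {
    set.seed(as.integer(pair_seed))
    prs <- replicate(n_sub, sort(sample.int(R, 2)))
  }
  mean(vapply(seq_len(ncol(prs)), function(k)
    nvi_labels(lab[, prs[1, k]], lab[, prs[2, k]]), numeric(1)))
}

#' Default Markov scale grid
#'
#' Log-spaced diffusion times, described by `s = log10(r)`.
#'
#' @param min_s,max_s grid endpoints in `s`.
#' @param n number of scales.
#' @return numeric vector of `s` values.
#' @export
markov_scales <- function(min_s = -1.5, max_s = 1.5, n = 60L) {
  seq(min_s, max_s, length.out = n)
}

#' @export
print.scale_scan <- function(x, ...) {
  cat(sprintf("scale_scan: %d scales in [%.3g, %.3g], %d repeats, %d nodes\n",
              length(x$scales), min(x$scales), max(x$scales),
              x$n_repeats, length(x$nodes)))
  cat("communities per scale:",
      paste(x$n_communities, collapse = " "), "\n")
  invisible(x)
}

#' @export
plot.scale_scan <- function(x, k = NULL, ...) {
  sel <- NULL
  if (!is.null(k)) sel <- select_robust_scales(x, kernel = k)
  bn <- block_nvi(x, kernel = if (is.null(k)) default_kernel(length(x$scales)) else k)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$scales, x$n_communities, log = "y", type = "s",
                 xlab = "Markov scale s", ylab = "communities")
  graphics::matplot(x$scales, cbind(x$nvi_within, bn), type = "l",
                    lty = c(1, 2), col = c(1, 2),
                    xlab = "Markov scale s", ylab = "NVI")
  graphics::legend("topright", c("NVI(s)", "Block NVI"), lty = c(1, 2),
                   col = c(1, 2), bty = "n")
  if (!is.null(sel))
    graphics::abline(v = x$scales[sel$selected], col = "grey", lty = 3)
  invisible(x)
}

#' Serialise / load a scale scan
#'
#' Writes `scales.csv`, `partitions.csv` (node x scale labels),
#' `nvi_within.csv`, `nvi_cross.csv` and `meta.json` into a directory.
#'
#' @param scan a [scale_scan()].
#' @param dir directory path.
#' @return `dir` (write) or a `scale_scan` (read), invisibly for write.
#' @export
write_scale_scan <- function(scan, dir) {
  stopifnot(inherits(scan, "scale_scan"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(index = seq_along(scan$scales), s = scan$scales,
                              quality = scan$qualities,
                              n_communities = scan$n_communities,
                              nvi_within = scan$nvi_within),
                   file.path(dir, "scales.csv"), row.names = FALSE)
  lab <- sapply(scan$partitions, unclass)
  colnames(lab) <- sprintf("s_%03d", seq_along(scan$scales))
  utils::write.csv(cbind(data.frame(node = scan$nodes), lab),
                   file.path(dir, "partitions.csv"), row.names = FALSE)
  utils::write.csv(scan$nvi_within, file.path(dir, "nvi_within.csv"),
                   row.names = FALSE)
  utils::write.csv(scan$nvi_cross, file.path(dir, "nvi_cross.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(seed = scan$seed, n_repeats = scan$n_repeats,
                            scales = scan$scales),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_scale_scan
#' @export
read_scale_scan <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  sc <- utils::read.csv(file.path(dir, "scales.csv"))
  part <- utils::read.csv(file.path(dir, "partitions.csv"),
                          colClasses = c(node = "character"))
  nodes <- part$node
  parts <- lapply(seq_along(sc$s), function(si)
    partition(part[[sprintf("s_%03d", si)]], nodes))
  structure(list(scales = sc$s, partitions = parts, qualities = sc$quality,
                 n_communities = sc$n_communities,
                 nvi_within = sc$nvi_within,
                 nvi_cross = as.matrix(utils::read.csv(file.path(dir, "nvi_cross.csv"))),
                 n_repeats = meta$n_repeats, seed = meta$seed, nodes = nodes),
            class = "scale_scan")
}
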