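#' Weekly flow graphs on a fixed node set
#'
#' Builds one [flow_graph()] per weekly flow table, restricted to the
#' baseline node set without re-extracting the LSCC: tiles absent from a
#' week's records stay in the graph with zero out-flow (flagged), and
#' absent edges are zero. Self-loops are separated into the intra vector
#' as in the baseline.
#'
#' @param weekly_tables list of OD flow tables (as produced by
#'   [apply_lockdown_scenario()] or read from weekly CSVs).
#' @param node_set character vector of baseline LSCC node IDs.
#' @return list of `flow_graph` objects (built with
#'   `check_connected = FALSE`; each carries attribute `n_silent`, the
#'   number of nodes with zero out-flow that week).
#' @export
weekly_graphs <- function(weekly_tables, node_set) {
  node_set <- sort(as.character(node_set))
  lapply(weekly_tables, function(tab) {
    tab <- validate_od_table(tab)
    tab <- tab[tab$origin %in% node_set & tab$destination %in% node_set, ,
               drop = FALSE]
    if (nrow(tab) == 0 || sum(tab$trips) <= 0)
      stop("week with zero total flow on the baseline node set")
    N <- length(node_set)
    A <- matrix(0, N, N, dimnames = list(node_set, node_set))
    oi <- match(tab$origin, node_set)
    di <- match(tab$destination, node_set)
    acc <- rowsum(tab$trips, oi + N * (di - 1L))
    A[as.integer(rownames(acc))] <- acc[, 1]
    intra <- diag(A); diag(A) <- 0
    g <- structure(list(nodes = node_set, A = A, intra = intra,
                        d_out = rowSums(A), n_dropped = 0L),
                   class = "flow_graph")
    n_silent <- sum(g$d_out == 0 & intra == 0)
    if (n_silent > 0)
      warning(n_silent, " nodes with no recorded flow this week kept with zero out-flow")
    attr(g, "n_silent") <- n_silent
    g
  })
}

#' Relative coverage-change series
#'
#' For a sequence of weekly graphs and a fixed partition, computes
#' `Delta C(t) = (C(t) - C(t0)) / C(t0)` relative to a baseline week,
#' where `C` is the partition coverage from [containment()]. Optionally
#' also returns the per-community relative coverage changes
#' `Delta C_k(t)`.
#'
#' @param graphs list of [flow_graph()] objects (weekly).
#' @param p a [partition()].
#' @param baseline_index index of the reference week `t0` (default 1).
#' @param per_community also compute per-community series.
#' @return An object of class `response_series`: list with `times`
#'   (weeks since series start), `values` (Delta C), `baseline_index`,
#'   `coverage` (raw C(t)), and optionally `community_values` (weeks x
#'   communities matrix).
#' @export
delta_coverage_series <- function(graphs, p, baseline_index = 1L,
                                  per_community = FALSE) {
  stopifnot(length(graphs) >= 1)
  reports <- lapply(graphs, containment, p = p)
  C <- unname(vapply(reports, `[[`, numeric(1), "coverage"))
  C0 <- C[baseline_index]
  if (C0 <= 0) stop("baseline coverage is zero; Delta C undefined")
  out <- structure(list(times = seq_along(graphs) - 1,
                        values = (C - C0) / C0,
                        baseline_index = as.integer(baseline_index),
                        coverage = C),
                   class = "response_series")
  if (per_community) {
    Ck <- t(vapply(reports, `[[`, numeric(reports[[1]]$n_communities),
                   "community_coverage"))
    Ck0 <- Ck[baseline_index, ]
    out$community_values <- sweep(Ck, 2, Ck0, "-") /
      rep(Ck0, each = nrow(Ck))
  }
  out
}

#' Activation-response function
#'
#' Solution of the linear shock model `dx/dt = -beta x + alpha e^(-lam t)`
#' with `x(0) = 0`:
#' `x(t) = alpha / (beta - lam) * (exp(-lam t) - exp(-beta t))`,
#' which is symmetric under exchanging `beta` and `lam`. At `beta = lam`
#' (within relative tolerance 1e-9) the analytic limit
#' `alpha * t * exp(-lam t)` is used. `1/beta` is the characteristic
#' recovery time and `1/lam` the characteristic stimulus time, in weeks.
#'
#' @param t time (weeks), `t >= 0`; vectorised.
#' @param alpha stimulus amplitude (any sign accepted for fitting).
#' @param beta relaxation rate (> 0).
#' @param lam stimulus decay rate (> 0).
#' @return numeric vector, `x(0) = 0` and the peak at
#'   `t* = log(beta/lam) / (beta - lam)`.
#' @export
response_function <- function(t, alpha, beta, lam) {
  if (any(t < 0)) stop("t must be non-negative")
  if (beta <= 0 || lam <= 0) stop("rates beta and lam must be positive")
  if (abs(beta - lam) <= 1e-9 * max(beta, lam)) {
    alpha * t * exp(-lam * t)
  } else {
    alpha / (beta - lam) * (exp(-lam * t) - exp(-beta * t))
  }
}

#' Fit the shock-response model to a coverage-change series
#'
#' Nonlinear least squares for `(alpha, beta, lam)` minimising the sum of
#' squared residuals between [response_function()] and the observed
#' `Delta C(t)`, using Levenberg-Marquardt (via [minpack.lm::nls.lm()])
#' from a deterministic grid of initialisations (best final fit kept),
#' with bounds `alpha >= 0`, `beta, lam > 0`. The closed form is
#' invariant under exchanging `beta` and `lam`; the fit reports the
#' labelling with `lam >= beta` (stimulus faster than recovery). 95%
#' confidence intervals are computed by profiling each parameter against
#' the F(1, n-3) threshold, re-optimising the other two parameters at
#' each profiled value.
#'
#' @param series a [delta_coverage_series()] result, or a list with
#'   `times` and `values`.
#' @param init optional named list overriding the initial grid with a
#'   single start `(alpha, beta, lam)`.
#' @param conf confidence level for the profile intervals.
#' @return An object of class `shock_fit`: list with `alpha`, `beta`,
#'   `lam`, `inv_beta`, `inv_lam`, `chi2`, `ci` (3 x 2 matrix of
#'   parameter bounds), `n`, `fitted`.
#' @export
fit_shock <- function(series, init = NULL, conf = 0.95) {
  t <- series$times
  y <- series$values
  if (length(t) < 4) stop("need at least 4 points to fit the shock model")
  n <- length(t)

  resid_fn <- function(par) response_function(t, par[1], par[2], par[3]) - y
  chi2_of <- function(par) sum(resid_fn(par)^2)
  lower <- c(0, 1e-8, 1e-8)
  upper <- c(Inf, 52, 52)   # rates bounded by one-week resolution scales

  run_lm <- function(start) {
    fit <- try(suppressWarnings(minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 200))), silent = TRUE)
    if (inherits(fit, "try-error")) return(NULL)
    list(par = fit$par, chi2 = sum(fit$fvec^2))
  }

  starts <- if (!is.null(init)) {
    list(c(init$alpha, init$beta, init$lam))
  } else {
    shock_start_grid(t, y)
  }
  best <- NULL
  for (st in starts) {
    res <- run_lm(st)
    if (!is.null(res) && (is.null(best) || res$chi2 < best$chi2)) best <- res
  }
  if (is.null(best)) stop("shock fit failed to converge from every start")
  par <- best$par
  # labelling convention: lam >= beta (fast stimulus, slow recovery)
  if (par[3] < par[2]) par <- c(par[1], par[3], par[2])
  chi2 <- chi2_of(par)

  ci <- profile_f_ci(par, t, y, chi2, lower, upper, conf = conf)
  structure(list(alpha = par[1], beta = par[2], lam = par[3],
                 inv_beta = 1 / par[2], inv_lam = 1 / par[3],
                 chi2 = chi2, ci = ci, n = n,
                 fitted = response_function(t, par[1], par[2], par[3]),
                 times = t, values = y),
            class = "shock_fit")
}

# deterministic multi-start grid: amplitude from the observed peak scaled
# through the unit-amplitude response peak; time scales bracketing typical
# stimulus (1-4 weeks) and recovery (8-32 weeks)
shock_start_grid <- function(t, y) {
  peak <- max(abs(y))
  if (peak == 0) peak <- 1e-6
  starts <- list()
  for (inv_lam in c(1, 2, 4)) for (inv_beta in c(8, 16, 32)) {
    beta <- 1 / inv_beta; lam <- 1 / inv_lam
    unit_peak <- max(response_function(seq(0, max(t), length.out = 200),
                                       1, beta, lam))
    for (f in c(0.5, 1, 2))
      starts[[length(starts) + 1]] <- c(f * peak / unit_peak, beta, lam)
  }
  starts
}

# per-parameter profile CIs against the F(1, n-p) threshold: bound where
# chi2_profile(theta) = chi2_min * (1 + qf(conf, 1, n-p)/(n-p))
profile_f_ci <- function(par, t, y, chi2_min, lower, upper, conf = 0.95) {
  n <- length(t); p <- 3
  fcrit <- stats::qf(conf, 1, n - p)
  thresh <- max(chi2_min, 1e-20) * (1 + fcrit / (n - p))

  prof_chi2 <- function(j, val) {
    fixed <- par; fixed[j] <- val
    free <- setdiff(1:3, j)
    rf <- function(pp) {
      full <- fixed; full[free] <- pp
      response_function(t, full[1], full[2], full[3]) - y
    }
    fit <- try(suppressWarnings(minpack.lm::nls.lm(
      par = par[free], lower = lower[free], upper = upper[free], fn = rf,
      control = minpack.lm::nls.lm.control(maxiter = 100))), silent = TRUE)
    if (inherits(fit, "try-error")) return(Inf)
    sum(fit$fvec^2)
  }

  one_bound <- function(j, dir) {
    # expand multiplicatively (additively for alpha near 0) until the
    # profile crosses the threshold, then bisect
    base <- par[j]
    step0 <- if (base > 0) abs(base) * 0.1 else 0.01
    lo <- base; hi <- base
    for (i in 1:40) {
      cand <- base + dir * step0 * 2^(i - 1)
      cand <- min(max(cand, lower[j]), upper[j])
      if (prof_chi2(j, cand) > thresh) { hi <- cand; break }
      lo <- cand
      if (cand == lower[j] || cand == upper[j]) return(cand)
    }
    if (hi == base) return(lo)  # never crossed: bound at expansion limit
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      if (prof_chi2(j, mid) > thresh) hi <- mid else lo <- mid
      if (abs(hi - lo) < 1e-8 * (abs(base) + 1e-8)) break
    }
    lo
  }

  ci <- matrix(NA_real_, 3, 2,
               dimnames = list(c("alpha", "beta", "lam"), c("lower", "upper")))
  for (j in 1:3) {
    ci[j, 1] <- one_bound(j, -1)
    ci[j, 2] <- one_bound(j, +1)
  }
  ci
}

#' @export
print.shock_fit <- function(x, ...) {
  cat("shock_fit (Delta C activation-response model)\n")
  cat(sprintf("  alpha = %.4g  (95%% CI %.4g-%.4g)\n",
              x$alpha, x$ci["alpha", 1], x$ci["alpha", 2]))
  cat(sprintf("  1/beta = %.3g weeks (CI %.3g-%.3g), 1/lam = %.3g weeks (CI %.3g-%.3g)\n",
              x$inv_beta, 1 / x$ci["beta", 2], 1 / x$ci["beta", 1],
              x$inv_lam, 1 / x$ci["lam", 2], 1 / x$ci["lam", 1]))
  cat(sprintf("  chi2 = %.4g over %d points\n", x$chi2, x$n))
  invisible(x)
}
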