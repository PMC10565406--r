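test_that("a directed cycle is kept whole and one-way pendants are dropped", {
  cyc <- data.frame(origin = c("1", "2", "3"), destination = c("2", "3", "1"),
                    trips = 1)
  g <- build_baseline_graph(cyc)
  expect_equal(length(g$nodes), 3)
  expect_equal(sum(g$A > 0), 3)
  expect_equal(g$n_dropped, 0)

  pend <- rbind(cyc, data.frame(origin = "3", destination = "4", trips = 2))
  g2 <- build_baseline_graph(pend)
  expect_equal(sort(g2$nodes), c("1", "2", "3"))
  expect_equal(g2$n_dropped, 1)
})

test_that("window averaging matches a direct per-day reference loop", {
  set.seed(21)
  days <- as.Date("2020-02-01") + 0:4
  recs <- do.call(rbind, lapply(seq_along(days), function(d) {
    # each day records a random subset of a 4-node cycle plus extras
    base <- data.frame(origin = c("a", "b", "c", "d", "a"),
                       destination = c("b", "c", "d", "a", "c"),
                       trips = round(stats::runif(5, 1, 10), 2))
    base[stats::runif(5) < 0.8, , drop = FALSE] |>
      transform(date = days[d])
  }))
  g <- build_baseline_graph(recs, date_window = days)
  # oracle: loop over days; absent records contribute 0
  pairs <- unique(recs[recs$origin %in% g$nodes &
                         recs$destination %in% g$nodes,
                       c("origin", "destination")])
  for (r in seq_len(nrow(pairs))) {
    tot <- 0
    for (d in seq_along(days)) {
      hit <- recs$date == days[d] & recs$origin == pairs$origin[r] &
        recs$destination == pairs$destination[r]
      tot <- tot + sum(recs$trips[hit])
    }
    expect_equal(g$A[pairs$origin[r], pairs$destination[r]],
                 tot / length(days), tolerance = 1e-12)
  }
})

test_that("self-loops are separated into the intra vector", {
  tab <- data.frame(origin = c("a", "b", "a"), destination = c("b", "a", "a"),
                    trips = c(1, 2, 7))
  g <- build_baseline_graph(tab)
  expect_equal(unname(diag(g$A)), c(0, 0))
  expect_equal(unname(g$intra), c(7, 0))
})

test_that("malformed rows and empty inputs raise informative errors", {
  expect_error(build_baseline_graph(data.frame(origin = "a", trips = 1)),
               "columns")
  expect_error(build_baseline_graph(
    data.frame(origin = "a", destination = "b", trips = -3)), "rows")
  expect_error(build_baseline_graph(
    data.frame(origin = "a", destination = "a", trips = 5)), "LSCC")
})

test_that("stationary distribution solves pi M = pi on every model", {
  for (s in 1:5) {
    A <- random_sc_graph(8, seed = s)
    m <- random_walk_model(fg(A))
    expect_equal(unname(rowSums(m$M)), rep(1, 8), tolerance = 1e-12)
    expect_lt(max(abs(m$pi %*% m$M - m$pi)), 1e-10)
    expect_lt(max(abs(m$pi %*% m$L)), 1e-10)
    expect_true(all(m$pi >= 0))
    expect_equal(sum(m$pi), 1, tolerance = 1e-12)
  }
})

test_that("symmetric graphs give the reversible closed form for pi", {
  set.seed(5)
  A <- matrix(stats::runif(36), 6, 6); A <- A + t(A); diag(A) <- 0
  rownames(A) <- colnames(A) <- letters[1:6]
  g <- fg(A)
  pi <- stationary_distribution(g)
  expect_equal(unname(pi), unname(g$d_out / sum(g$d_out)), tolerance = 1e-12)
})

test_that("two-node chains are forced symmetric with pi = (1/2, 1/2)", {
  g <- fg(matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b"))))
  m <- random_walk_model(g)
  expect_equal(unname(m$pi), c(0.5, 0.5), tolerance = 1e-12)
  expect_lt(detailed_balance_deviation(m), 1e-12)
})

test_that("pi matches a dense left-eigendecomposition oracle", {
  for (s in 1:5) {
    A <- random_sc_graph(5, seed = 100 + s)
    pi <- stationary_distribution(fg(A))
    expect_lt(max(abs(unname(pi) - stationary_by_eigen(A))), 1e-10)
  }
})

test_that("PRA boundary values and scale invariance", {
  A <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  A["a", "b"] <- 3; A["b", "a"] <- 1     # PRA 0.5
  A["b", "c"] <- 2; A["c", "b"] <- 2     # PRA 0
  A["c", "a"] <- 4                       # one-way, PRA 1
  g <- flow_graph(A, check_connected = FALSE)
  pra <- pairwise_relative_asymmetry(g)
  vals <- with(pra$pairs, stats::setNames(pra, paste(i, j)))
  expect_equal(unname(vals["a b"]), 0.5)
  expect_equal(unname(vals["b c"]), 0)
  expect_equal(unname(vals["a c"]), 1)
  expect_equal(pra$n_one_way, 1)
  g10 <- flow_graph(A * 10, check_connected = FALSE)
  expect_equal(pairwise_relative_asymmetry(g10)$pairs$pra, pra$pairs$pra)
})

test_that("detailed-balance deviation is sqrt(2) on the 3-cycle and 0 when reversible", {
  cyc <- fg(matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, 3,
                   dimnames = list(1:3, 1:3)))
  expect_equal(detailed_balance_deviation(random_walk_model(cyc)), sqrt(2),
               tolerance = 1e-10)
  set.seed(8)
  A <- matrix(stats::runif(16), 4, 4); A <- A + t(A); diag(A) <- 0
  rownames(A) <- colnames(A) <- letters[1:4]
  expect_lt(detailed_balance_deviation(random_walk_model(fg(A))), 1e-12)
})

test_that("centrality diagnostics match a closed-form regression and flag degeneracy", {
  fx <- planted_fixture(seed = 6, levels = 2, leaf_size = 5)
  d <- centrality_diagnostics(fx$graph, fx$model)
  # reference least-squares computation
  y <- fx$model$pi; x <- fx$graph$d_out
  bet <- cov(y, x) / var(x); a <- mean(y) - bet * mean(x)
  r2_ref <- 1 - sum((y - a - bet * x)^2) / sum((y - mean(y))^2)
  expect_equal(d$r2_out_strength, r2_ref, tolerance = 1e-10)
  # symmetric graph: pi proportional to d_out, R^2 = 1
  set.seed(9)
  A <- matrix(stats::runif(25), 5, 5); A <- A + t(A); diag(A) <- 0
  rownames(A) <- colnames(A) <- letters[1:5]
  gs <- fg(A, intra = stats::runif(5))
  expect_equal(centrality_diagnostics(gs, random_walk_model(gs))$r2_out_strength,
               1, tolerance = 1e-10)
  gz <- fg(A, intra = rep(2, 5))
  expect_error(centrality_diagnostics(gz, random_walk_model(gz)),
               "zero-variance")
})

test_that("flow graphs round-trip through the edge-list CSV layout", {
  fx <- planted_fixture(seed = 2, levels = 2, leaf_size = 4)
  dir <- withr::local_tempdir()
  write_flow_graph(fx$graph, dir)
  edges <- utils::read.csv(file.path(dir, "edges.csv"),
                           colClasses = c(origin = "character",
                                          destination = "character"))
  nodes <- utils::read.csv(file.path(dir, "nodes.csv"),
                           colClasses = c(node = "character"))
  expect_equal(nodes$node, fx$graph$nodes)
  expect_equal(nodes$intra, unname(fx$graph$intra))
  A2 <- matrix(0, length(nodes$node), length(nodes$node),
               dimnames = list(nodes$node, nodes$node))
  A2[cbind(edges$origin, edges$destination)] <- edges$trips
  expect_equal(A2, fx$graph$A)
})
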