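test_that("generator validates its parameters", {
  expect_error(hierarchy_plan(levels = integer(0), leaf_size = 4), "level")
  expect_error(hierarchy_plan(c(2), 4, within_rate = -1), "positive")
  expect_error(hierarchy_plan(c(2), 4, decay = 1.2), "decay")
  expect_error(hierarchy_plan(c(2), 4, sparsity = 2), "sparsity")
  expect_error(shock_scenario(alpha = -1, beta = 0.1, lam = 0.5), "alpha")
  expect_error(shock_scenario(alpha = 1, beta = 0, lam = 0.5), "positive")
})

test_that("complete one-block plan yields the full edge and self-loop count", {
  plan <- hierarchy_plan(levels = 1, leaf_size = 4, sparsity = 1)
  tab <- generate_hierarchical_flows(plan, seed = 1)
  loops <- tab$origin == tab$destination
  expect_equal(sum(!loops), 12)  # complete directed graph on 4 tiles
  expect_equal(sum(loops), 4)
})

test_that("asymmetry = 0 forces exactly symmetric flows", {
  plan <- hierarchy_plan(levels = c(2, 2), leaf_size = 3, asymmetry = 0)
  tab <- generate_hierarchical_flows(plan, seed = 7)
  inter <- tab[tab$origin != tab$destination, ]
  key_fwd <- paste(inter$origin, inter$destination)
  key_rev <- paste(inter$destination, inter$origin)
  expect_setequal(key_fwd, key_rev)
  expect_equal(inter$trips, inter$trips[match(key_fwd, key_rev)])
})

test_that("identical seed reproduces identical tables", {
  plan <- hierarchy_plan(levels = c(2, 2), leaf_size = 3)
  expect_identical(generate_hierarchical_flows(plan, seed = 42),
                   generate_hierarchical_flows(plan, seed = 42))
  t1 <- generate_hierarchical_flows(plan, seed = 42)
  t2 <- generate_hierarchical_flows(plan, seed = 43)
  expect_false(identical(t1$trips, t2$trips))
})

test_that("within/between rate ratio matches 1/decay by Monte-Carlo averaging", {
  # direct averaging over 20 seeds, oracle from the generative definition
  plan <- hierarchy_plan(levels = 4, leaf_size = 8, decay = 0.05,
                         asymmetry = 0, sigma = 0.5)
  p1 <- planted_partitions(plan)$level_1
  within <- c(); between <- c()
  for (s in 1:20) {
    tab <- generate_hierarchical_flows(plan, seed = s)
    inter <- tab[tab$origin != tab$destination, ]
    same <- unclass(p1)[inter$origin] == unclass(p1)[inter$destination]
    within <- c(within, inter$trips[same])
    between <- c(between, inter$trips[!same])
  }
  ratio <- mean(within) / mean(between)
  expect_gt(ratio, 1 / 0.05 * 0.8)
  expect_lt(ratio, 1 / 0.05 * 1.2)
})

test_that("generated baseline is strongly connected with heavy-tailed weights", {
  for (s in 1:3) {
    fx <- planted_fixture(seed = s)
    expect_equal(length(fx$graph$nodes), 64)   # nothing dropped by the LSCC
    expect_equal(fx$graph$n_dropped, 0)
    w <- fx$graph$A[fx$graph$A > 0]
    expect_gt(stats::sd(w) / mean(w), 2)       # CV >= 2 as in tile-level data
  }
})

test_that("sparse plans remain strongly connected via ring repair", {
  plan <- hierarchy_plan(levels = c(3, 3), leaf_size = 3, sparsity = 0.15)
  for (s in 1:5) {
    tab <- generate_hierarchical_flows(plan, seed = s)
    g <- build_baseline_graph(tab)
    expect_equal(g$n_dropped, 0)
  }
})

test_that("detailed-balance deviation grows with the asymmetry parameter", {
  mean_dev <- function(asym) {
    devs <- sapply(1:5, function(s) {
      plan <- hierarchy_plan(levels = 2, leaf_size = 6, asymmetry = asym)
      tab <- generate_hierarchical_flows(plan, seed = s)
      detailed_balance_deviation(random_walk_model(build_baseline_graph(tab)))
    })
    mean(devs)
  }
  devs <- vapply(c(0, 0.2, 0.6), mean_dev, numeric(1))
  expect_equal(devs[1], 0, tolerance = 1e-12)
  expect_true(all(diff(devs) > 0))
})

test_that("lockdown scenario conserves weekly totals and follows g(t)", {
  fx <- planted_fixture(seed = 3)
  sc <- shock_scenario(alpha = 0.8 * abs(1 / 16 - 1 / 2), beta = 1 / 16,
                       lam = 1 / 2, n_weeks = 18)
  weekly <- apply_lockdown_scenario(fx$table, sc, fx$planted$level_1)
  expect_length(weekly, 18)
  base_total <- sum(fx$table$trips)
  lab <- unclass(fx$planted$level_1)
  base_inter_mask <- with(fx$table, origin != destination &
                            lab[origin] != lab[destination])
  base_inter <- sum(fx$table$trips[base_inter_mask])
  g_analytic <- response_function(0:17, sc$alpha, sc$beta, sc$lam)
  for (w in seq_along(weekly)) {
    tab <- weekly[[w]]
    # conservation: per-week totals equal baseline exactly
    expect_equal(sum(tab$trips), base_total, tolerance = 1e-9)
    inter_mask <- with(tab, origin != destination &
                         lab[origin] != lab[destination])
    frac <- sum(tab$trips[inter_mask]) / base_inter
    expect_equal(frac, 1 - g_analytic[w], tolerance = 1e-9)
  }
  # dip then monotone recovery after the peak
  frac_series <- vapply(weekly, function(tab) {
    m <- with(tab, origin != destination & lab[origin] != lab[destination])
    sum(tab$trips[m])
  }, numeric(1)) / base_inter
  peak <- which.min(frac_series)
  expect_gt(peak, 1)
  expect_true(all(diff(frac_series[peak:18]) >= -1e-12))
})

test_that("zero stimulus leaves every weekly table at baseline", {
  fx <- planted_fixture(seed = 4, levels = 2, leaf_size = 4)
  sc <- shock_scenario(alpha = 0, beta = 1 / 16, lam = 1 / 2, n_weeks = 4)
  weekly <- apply_lockdown_scenario(fx$table, sc, fx$planted$level_1)
  for (tab in weekly)
    expect_equal(tab$trips, fx$table$trips)
})

test_that("scenario application requires a complete target partition", {
  fx <- planted_fixture(seed = 4, levels = 2, leaf_size = 4)
  p_bad <- partition(rep(1, 3), fx$graph$nodes[1:3])
  sc <- shock_scenario(alpha = 0.1, beta = 1 / 16, lam = 1 / 2, n_weeks = 2)
  expect_error(apply_lockdown_scenario(fx$table, sc, p_bad), "missing nodes")
})

test_that("simulate_mobility_dataset writes the documented file layout", {
  dir <- withr::local_tempdir()
  plan <- hierarchy_plan(levels = c(2, 2), leaf_size = 3)
  sc <- shock_scenario(alpha = 0.2, beta = 1 / 16, lam = 1 / 2, n_weeks = 3)
  simulate_mobility_dataset(plan, sc, dir = dir, seed = 9)
  expect_true(file.exists(file.path(dir, "baseline.csv")))
  expect_true(file.exists(file.path(dir, "partition_level_1.csv")))
  expect_true(file.exists(file.path(dir, "partition_level_2.csv")))
  expect_true(all(file.exists(file.path(dir, sprintf("week_%02d.csv", 1:3)))))
  meta <- jsonlite::read_json(file.path(dir, "scenario.json"))
  expect_equal(meta$n_weeks, 3)
  # round-trip: baseline re-read equals generated table
  back <- read_od_csv(file.path(dir, "baseline.csv"))
  gen <- generate_hierarchical_flows(plan, seed = 9)
  expect_equal(back$trips, gen$trips)
})
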