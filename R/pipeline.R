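#' Pipeline configuration
#'
#' Assembles and validates the configuration for the two end-to-end
#' workflows. A fully resolved config round-trips through JSON
#' serialisation unchanged.
#'
#' @param od_table path to the baseline OD CSV (or a data frame).
#' @param weekly_tables character vector of weekly OD CSV paths (or list
#'   of data frames) for the temporal workflow.
#' @param reference_partitions named character vector of `node,community`
#'   CSV paths (or named list of partitions) to compare against.
#' @param scales Markov scale grid (`s = log10(r)` values).
#' @param n_repeats Louvain repetitions per scale.
#' @param kernel Block-NVI pooling half-width (`NULL` = default rule).
#' @param seed master seed.
#' @param baseline_window optional date vector for baseline averaging.
#' @param output_dir directory for all artifacts.
#' @return object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(od_table, weekly_tables = NULL,
                            reference_partitions = NULL,
                            scales = markov_scales(), n_repeats = 50L,
                            kernel = NULL, seed = 1L,
                            baseline_window = NULL, output_dir = "flowscales-out") {
  cfg <- list(od_table = od_table, weekly_tables = weekly_tables,
              reference_partitions = reference_partitions,
              scales = scales, n_repeats = as.integer(n_repeats),
              kernel = kernel, seed = as.integer(seed),
              baseline_window = baseline_window, output_dir = output_dir)
  if (any(diff(cfg$scales) <= 0)) stop("config error: scales must increase")
  if (cfg$n_repeats < 2) stop("config error: n_repeats must be >= 2")
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x[!vapply(x, is.null, logical(1))])
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config)[!vapply(config, is.null, logical(1))],
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

resolve_od <- function(x) if (is.character(x)) read_od_csv(x) else validate_od_table(x)
resolve_ref <- function(x) if (is.character(x)) read_partition_csv(x) else as_partition(x)

#' Run the baseline multiscale workflow
#'
#' Executes: OD table -> baseline graph (LSCC) -> random-walk model ->
#' Markov-stability scale scan -> Block-NVI scale selection ->
#' containment reports for the selected partitions -> NVI comparison
#' against any reference partitions. All artifacts and a run manifest
#' (seed, stage timings) are written under `output_dir`.
#'
#' @param config a [pipeline_config()].
#' @return list with `graph`, `model`, `scan`, `selection`,
#'   `containment` (per selected scale), `reference_comparison`,
#'   `manifest` (also written as `manifest.json`).
#' @export
run_baseline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, stages = list())
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    val
  }

  graph <- tick("mobility_graph", {
    g <- build_baseline_graph(resolve_od(config$od_table), config$baseline_window)
    write_flow_graph(g, file.path(config$output_dir, "baseline_graph"))
    g
  })
  model <- tick("random_walk_model", random_walk_model(graph))
  scan <- tick("markov_stability", {
    sc <- scale_scan(model, scales = config$scales,
                     n_repeats = config$n_repeats, seed = config$seed)
    write_scale_scan(sc, file.path(config$output_dir, "scale_scan"))
    sc
  })
  kernel <- config$kernel %||% default_kernel(length(config$scales))
  selection <- tick("scale_selection", {
    sel <- select_robust_scales(scan, kernel = kernel)
    write_scale_selection(sel, scan, file.path(config$output_dir, "selection.json"))
    sel
  })
  cont <- tick("containment", {
    reports <- lapply(selection$selected, function(si)
      containment(graph, scan$partitions[[si]]))
    names(reports) <- sprintf("s_%03d", selection$selected)
    summ <- data.frame(
      scale_index = selection$selected,
      s = scan$scales[selection$selected],
      n_communities = scan$n_communities[selection$selected],
      coverage = vapply(reports, `[[`, numeric(1), "coverage"),
      avg_nodal_containment = vapply(reports, `[[`, numeric(1),
                                     "avg_nodal_containment"))
    utils::write.csv(summ, file.path(config$output_dir, "containment.csv"),
                     row.names = FALSE)
    reports
  })
  refcmp <- NULL
  if (!is.null(config$reference_partitions)) {
    refcmp <- tick("reference_comparison", {
      refs <- lapply(config$reference_partitions, resolve_ref)
      cmp <- lapply(refs, compare_to_reference, scan = scan)
      long <- do.call(rbind, lapply(names(cmp), function(nm)
        data.frame(reference = nm, s = scan$scales,
                   nvi = cmp[[nm]]$nvi_curve)))
      utils::write.csv(long, file.path(config$output_dir, "reference_nvi.csv"),
                       row.names = FALSE)
      cmp
    })
  }
  manifest$completed <- TRUE
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(graph = graph, model = model, scan = scan, selection = selection,
       containment = cont, reference_comparison = refcmp, manifest = manifest)
}

#' Run the temporal shock workflow
#'
#' For each selected partition, computes weekly flow graphs on the
#' baseline node set, the relative coverage-change series Delta C(t),
#' and the shock-response fit; writes a summary CSV (one row per
#' partition: `alpha, alpha_lo, alpha_hi, inv_beta, ..., chi2`) and,
#' optionally, per-community fits for the first partition.
#'
#' @param config a [pipeline_config()] with `weekly_tables` set.
#' @param baseline a [run_baseline()] result (or a list with `graph`,
#'   `scan`, `selection`).
#' @param partitions optional named list of partitions to analyse,
#'   overriding the selected scan partitions.
#' @param per_community also fit each community of the first partition.
#' @return list with `graphs`, `series` (per partition), `fits`,
#'   `table` (the summary data frame), `community_fits`.
#' @export
run_temporal <- function(config, baseline, partitions = NULL,
                         per_community = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$weekly_tables)) stop("config error: no weekly tables")
  if (is.null(partitions)) {
    idx <- baseline$selection$selected
    partitions <- baseline$scan$partitions[idx]
    names(partitions) <- sprintf("s_%03d", idx)
  }
  tabs <- lapply(config$weekly_tables, resolve_od)
  graphs <- weekly_graphs(tabs, baseline$graph$nodes)
  series <- lapply(partitions, function(p)
    delta_coverage_series(graphs, p, baseline_index = 1L))
  fits <- lapply(series, fit_shock)
  table <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(partition = nm,
               alpha = f$alpha, alpha_lo = f$ci["alpha", 1],
               alpha_hi = f$ci["alpha", 2],
               inv_beta = f$inv_beta,
               inv_beta_lo = 1 / f$ci["beta", 2],
               inv_beta_hi = 1 / f$ci["beta", 1],
               inv_lam = f$inv_lam,
               inv_lam_lo = 1 / f$ci["lam", 2],
               inv_lam_hi = 1 / f$ci["lam", 1],
               chi2 = f$chi2)
  }))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(table, file.path(config$output_dir, "shock_fits.csv"),
                   row.names = FALSE)
  community_fits <- NULL
  if (per_community && length(partitions)) {
    p1 <- partitions[[1]]
    ser <- delta_coverage_series(graphs, p1, per_community = TRUE)
    community_fits <- lapply(seq_len(ncol(ser$community_values)), function(k) {
      s <- list(times = ser$times, values = ser$community_values[, k])
      tryCatch(fit_shock(s), error = function(e) NULL)
    })
    ok <- !vapply(community_fits, is.null, logical(1))
    ctab <- do.call(rbind, lapply(which(ok), function(k) {
      f <- community_fits[[k]]
      data.frame(community = k, alpha = f$alpha, inv_beta = f$inv_beta,
                 inv_lam = f$inv_lam, chi2 = f$chi2)
    }))
    utils::write.csv(ctab, file.path(config$output_dir, "community_fits.csv"),
                     row.names = FALSE)
  }
  list(graphs = graphs, series = series, fits = fits, table = table,
       community_fits = community_fits)
}

#' Daily trip summary relative to the first day
#'
#' Per-table totals of intra-tile, inter-tile and all trips, as
#' proportions of the first table (the classic lockdown trip-volume
#' summary).
#'
#' @param tables list of OD flow tables.
#' @return data frame with columns `index`, `intra`, `inter`, `total`
#'   (proportions, first row = 1).
#' @export
trip_volume_summary <- function(tables) {
  rows <- lapply(tables, function(tab) {
    tab <- validate_od_table(tab)
    loop <- tab$origin == tab$destination
    c(intra = sum(tab$trips[loop]), inter = sum(tab$trips[!loop]))
  })
  m <- do.call(rbind, rows)
  data.frame(index = seq_len(nrow(m)),
             intra = m[, "intra"] / m[1, "intra"],
             inter = m[, "inter"] / m[1, "inter"],
             total = (m[, "intra"] + m[, "inter"]) /
               (m[1, "intra"] + m[1, "inter"]))
}
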