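#' Block NVI curve of a scale scan
#'
#' Average-pools the cross-scale NVI matrix around its diagonal: the
#' pooled value at scale index `s` is the mean of `NVI(u, v)` over all
#' pairs `u, v` in the neighbourhood `B_k(s) = {u : |u - s| <= k}`
#' (truncated at the grid edges), then smooths the pooled curve with a
#' centred moving average of width `2k + 1` (also truncated at the
#' edges). Blocks of low cross-scale NVI appear as basins of the Block
#' NVI curve.
#'
#' @param scan a [scale_scan()].
#' @param kernel pooling half-width `k`, `1 <= k < m`.
#' @return numeric vector of length `m`.
#' @export
block_nvi <- function(scan, kernel = default_kernel(length(scan$scales))) {
  stopifnot(inherits(scan, "scale_scan"))
  m <- length(scan$scales)
  k <- as.integer(kernel)
  if (k < 1 || k >= m) stop("kernel must satisfy 1 <= k < m")
  NV <- scan$nvi_cross
  pooled <- vapply(seq_len(m), function(s) {
    w <- max(1, s - k):min(m, s + k)
    mean(NV[w, w, drop = FALSE])
  }, numeric(1))
  # centred moving average, truncated at the edges
  vapply(seq_len(m), function(s) {
    w <- max(1, s - k):min(m, s + k)
    mean(pooled[w])
  }, numeric(1))
}

default_kernel <- function(m) max(1L, as.integer(ceiling(m / 20)))

#' Select robust Markov scales from a scan
#'
#' Implements basin-based scale selection: local minima of the Block NVI
#' curve (strict neighbour comparison, plateau minima collapsed to their
#' central index) define basins, delimited by the interior local maxima
#' between adjacent minima (watershed) and by the grid ends. Within each
#' basin the selected robust scale is the argmin of the within-scale
#' ensemble NVI, with ties broken toward the basin's Block-NVI minimum.
#' A constant Block NVI curve yields a single basin spanning the grid.
#'
#' @param scan a [scale_scan()].
#' @param kernel pooling half-width passed to [block_nvi()].
#' @param max_basins optional cap: basins are ranked by depth (basin
#'   boundary level minus basin minimum) and only the deepest kept.
#' @return An object of class `scale_selection`: list with `block_nvi`,
#'   `basins` (list of index ranges), `selected` (scale indices),
#'   `selected_scales` (s values), `kernel`.
#' @export
select_robust_scales <- function(scan, kernel = default_kernel(length(scan$scales)),
                                 max_basins = NULL) {
  stopifnot(inherits(scan, "scale_scan"))
  bn <- block_nvi(scan, kernel)
  m <- length(bn)
  minima <- plateau_extrema(bn, sign = -1)
  if (length(minima) == 0) minima <- which.min(bn)   # constant or monotone curve
  # watershed boundaries: argmax of bn strictly between adjacent minima
  bounds <- integer(0)
  if (length(minima) > 1) {
    for (i in seq_len(length(minima) - 1)) {
      span <- (minima[i] + 1):(minima[i + 1] - 1)
      if (length(span) == 0) span <- minima[i]
      bounds <- c(bounds, span[which.max(bn[span])])
    }
  }
  starts <- c(1L, bounds + 1L)
  ends <- c(bounds, m)
  basins <- Map(function(a, b) a:b, starts, ends)
  depth <- vapply(seq_along(basins), function(i) {
    idx <- basins[[i]]
    edge <- max(bn[c(idx[1], idx[length(idx)])])
    edge - min(bn[idx])
  }, numeric(1))
  if (!is.null(max_basins) && length(basins) > max_basins) {
    keep <- sort(order(depth, decreasing = TRUE)[seq_len(max_basins)])
    basins <- basins[keep]
    depth <- depth[keep]
  }
  selected <- vapply(basins, function(idx) {
    nv <- scan$nvi_within[idx]
    cand <- idx[nv == min(nv)]
    if (length(cand) > 1) {
      anchor <- idx[which.min(bn[idx])]          # tie toward Block-NVI minimum
      cand <- cand[which.min(abs(cand - anchor))]
    }
    cand[1]
  }, integer(1))
  structure(list(block_nvi = bn, basins = basins, basin_depth = depth,
                 selected = selected,
                 selected_scales = scan$scales[selected],
                 kernel = as.integer(kernel)),
            class = "scale_selection")
}

# indices of local extrema with strict neighbour comparison; plateaus
# collapse to their central index. sign = -1 for minima, +1 for maxima.
plateau_extrema <- function(x, sign = -1) {
  y <- sign * x
  m <- length(y)
  # run-length encode so plateaus are single candidates
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer(0)
  for (j in seq_along(r$values)) {
    left <- if (j == 1) -Inf else r$values[j - 1]
    right <- if (j == length(r$values)) -Inf else r$values[j + 1]
    if (r$values[j] > left && r$values[j] > right) {
      # interior plateau maxima only; runs touching the boundary count too
      out <- c(out, as.integer(floor((starts[j] + ends[j]) / 2)))
    }
  }
  out
}

#' @export
print.scale_selection <- function(x, ...) {
  cat(sprintf("scale_selection: %d basins, kernel %d\n",
              length(x$basins), x$kernel))
  for (i in seq_along(x$basins)) {
    idx <- x$basins[[i]]
    cat(sprintf("  basin %d: indices %d..%d, selected index %d (s = %.3f)\n",
                i, idx[1], idx[length(idx)], x$selected[i],
                x$selected_scales[i]))
  }
  invisible(x)
}

#' Write a scale selection to JSON
#'
#' @param selection a [select_robust_scales()] result.
#' @param scan the originating [scale_scan()] (for community counts).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_scale_selection <- function(selection, scan, path) {
  jsonlite::write_json(list(
    kernel = selection$kernel,
    basins = lapply(seq_along(selection$basins), function(i) {
      idx <- selection$basins[[i]]
      list(index_range = c(idx[1], idx[length(idx)]),
           s_range = c(scan$scales[idx[1]], scan$scales[idx[length(idx)]]))
    }),
    selected = lapply(seq_along(selection$selected), function(i) {
      si <- selection$selected[i]
      list(index = si, s = scan$scales[si],
           n_communities = scan$n_communities[si])
    })), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
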