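#' Lowest sustained MAP over k minutes
#'
#' The lowest pressure ceiling under which the MAP stayed for a contiguous
#' span of `k` minutes: the minimum, over all windows of exactly
#' `k * 60 / step_s + 1` grid points (inclusive endpoints spanning exactly
#' `k` minutes), of the window maximum. Scanning longer windows cannot
#' lower a window maximum, so restricting to exact-length windows is
#' equivalent to scanning all windows of length at least `k`.
#'
#' @param grid A [map_grid].
#' @param k Window length in minutes.
#' @return The lowest sustained MAP in mmHg, or `NA` when the grid is
#'   shorter than `k` minutes.
#' @export
lowest_sustained_map <- function(grid, k) {
  stopifnot(inherits(grid, "map_grid"), k > 0)
  m <- as.integer(round(k * 60 / grid$step_s)) + 1L
  v <- grid$values
  if (m > length(v)) return(NA_real_)
  if (m == 1L) return(min(v))
  min(zoo::rollmax(v, m))
}

#' Lowest cumulative MAP over k minutes
#'
#' The smallest observed MAP value `v` such that the total (possibly
#' non-contiguous) time spent at or below `v` is at least `k` minutes:
#' the `m`-th smallest grid value with `m = ceiling(k * 60 / step_s)`.
#'
#' @inheritParams lowest_sustained_map
#' @return The lowest cumulative MAP in mmHg, or `NA` when the grid is
#'   shorter than `k` minutes.
#' @export
lowest_cumulative_map <- function(grid, k) {
  stopifnot(inherits(grid, "map_grid"), k > 0)
  m <- as.integer(ceiling(k * 60 / grid$step_s))
  v <- grid$values
  if (m > length(v)) return(NA_real_)
  sort(v, partial = m)[m]
}

#' Time with MAP under a threshold
#'
#' Number of grid points with MAP strictly below `threshold`, converted to
#' minutes (`count * step_s / 60`).
#'
#' @inheritParams lowest_sustained_map
#' @param threshold Threshold in mmHg.
#' @return Minutes under the threshold.
#' @export
time_under <- function(grid, threshold) {
  stopifnot(inherits(grid, "map_grid"))
  sum(grid$values < threshold) * grid$step_s / 60
}

#' Fraction of anesthesia time with MAP under a threshold
#'
#' [time_under] divided by the gridded record duration; always in
#' \[0, 1\].
#'
#' @inheritParams time_under
#' @return Unitless fraction.
#' @export
fraction_under <- function(grid, threshold) {
  stopifnot(inherits(grid, "map_grid"))
  time_under(grid, threshold) / grid_duration_min(grid)
}

#' Evaluate one characterization on one grid
#'
#' @param grid A [map_grid].
#' @param spec An [ioh_spec].
#' @return A single numeric exposure value (`NA` if undefined, i.e. the
#'   grid is shorter than the window the spec requires).
#' @export
compute_exposure <- function(grid, spec) {
  stopifnot(inherits(spec, "ioh_spec"))
  switch(spec$family,
         sustained_lowest  = lowest_sustained_map(grid, spec$param),
         cumulative_lowest = lowest_cumulative_map(grid, spec$param),
         time_under        = time_under(grid, spec$param),
         fraction_under    = fraction_under(grid, spec$param))
}

#' Exposure table for a cohort
#'
#' Evaluates each characterization on each surgery's MAP grid.
#'
#' @param grids A list of [map_grid] objects.
#' @param specs A list of [ioh_spec] objects (default: all 24).
#' @return A data.frame with `case_id` and one column per characterization
#'   label; undefined exposures are `NA`.
#' @export
compute_feature_table <- function(grids, specs = default_characterizations()) {
  if (length(specs) == 0L) stop("'specs' must be non-empty", call. = FALSE)
  labels <- vapply(specs, `[[`, "", "label")
  out <- data.frame(
    case_id = vapply(grids, function(g) as.character(g$case_id), ""),
    stringsAsFactors = FALSE)
  for (j in seq_along(specs)) {
    out[[labels[j]]] <- vapply(grids, compute_exposure, 0, spec = specs[[j]])
  }
  rownames(out) <- NULL
  out
}

#' Quartile summary of a feature table
#'
#' Median and quartiles per characterization, overall and (when a binary
#' outcome is supplied) by outcome group — the usual cohort-description
#' layout for IOH exposure tables.
#'
#' @param features A feature table from [compute_feature_table].
#' @param ponv Optional binary outcome vector aligned to rows.
#' @return A data.frame with one row per characterization.
#' @export
feature_summary <- function(features, ponv = NULL) {
  labs <- setdiff(names(features), "case_id")
  qline <- function(x) {
    q <- stats::quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE, names = FALSE)
    c(median = q[1], q1 = q[2], q3 = q[3])
  }
  out <- data.frame(characterization = labs, stringsAsFactors = FALSE)
  all_q <- t(vapply(labs, function(l) qline(features[[l]]), numeric(3)))
  out$median <- all_q[, 1]; out$q1 <- all_q[, 2]; out$q3 <- all_q[, 3]
  out$n_undefined <- vapply(labs, function(l) sum(is.na(features[[l]])), 0L)
  if (!is.null(ponv)) {
    for (grp in c(0, 1)) {
      gq <- t(vapply(labs, function(l) qline(features[[l]][ponv == grp]),
                     numeric(3)))
      tag <- if (grp == 1) "ponv" else "no_ponv"
      out[[paste0("median_", tag)]] <- gq[, 1]
      out[[paste0("q1_", tag)]] <- gq[, 2]
      out[[paste0("q3_", tag)]] <- gq[, 3]
    }
  }
  rownames(out) <- NULL
  out
}
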