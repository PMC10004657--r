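#' Uniform MAP grid for one surgery
#'
#' A `map_grid` holds mean arterial pressure sampled on a uniform grid
#' (15 s by default) from anesthesia start. Each grid point stands for the
#' half-open interval `[t, t + step_s)`, so total-time accounting is
#' `length(values) * step_s / 60` minutes.
#'
#' @param case_id Case identifier.
#' @param values Numeric MAP values (mmHg), one per grid point, no missing.
#' @param step_s Grid step in seconds (default 15).
#' @return An object of class `map_grid`.
#' @export
map_grid <- function(case_id, values, step_s = 15) {
  values <- as.numeric(values)
  if (length(values) == 0L)
    stop("'values' must be non-empty", call. = FALSE)
  if (anyNA(values))
    stop("grid values must not contain missing values", call. = FALSE)
  if (any(values <= 0))
    stop("grid MAP values must be positive", call. = FALSE)
  structure(list(case_id = case_id, step_s = step_s, values = values),
            class = "map_grid")
}

#' @rdname map_grid
#' @param x A `map_grid`.
#' @export
grid_duration_min <- function(x) {
  length(x$values) * x$step_s / 60
}

#' @export
print.map_grid <- function(x, ...) {
  cat(sprintf("MAP grid [%s]: %d points at %gs (%.1f min), range %.1f-%.1f mmHg\n",
              as.character(x$case_id), length(x$values), x$step_s,
              grid_duration_min(x), min(x$values), max(x$values)))
  invisible(x)
}
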