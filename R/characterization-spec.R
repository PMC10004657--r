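#' IOH characterization specifications
#'
#' A characterization is a scalar summary of a surgery's MAP time course.
#' Four families are supported:
#' \describe{
#'   \item{`sustained_lowest`}{lowest MAP ceiling held for `k` contiguous
#'     minutes (k in 1, 3, 5, 10, 15); units mmHg.}
#'   \item{`cumulative_lowest`}{lowest MAP ceiling accumulated over `k`
#'     total, possibly non-contiguous, minutes; units mmHg.}
#'   \item{`time_under`}{absolute minutes with MAP strictly below a
#'     threshold (50, 55, 60, 65, 70, 75, 80 mmHg).}
#'   \item{`fraction_under`}{time under a threshold divided by the gridded
#'     record duration; unitless, in \[0, 1\].}
#' }
#'
#' @param family One of `"sustained_lowest"`, `"cumulative_lowest"`,
#'   `"time_under"`, `"fraction_under"`.
#' @param param Window length in minutes (lowest families, one of
#'   1, 3, 5, 10, 15) or threshold in mmHg (under families, one of
#'   50, 55, 60, 65, 70, 75, 80). Values outside the canonical sets are
#'   accepted when `strict = FALSE` (used by tests with toy windows).
#' @param strict Enforce the canonical parameter sets.
#' @return An object of class `ioh_spec` with elements `family`, `param`
#'   and `label`.
#' @examples
#' ioh_spec("time_under", 50)
#' parse_spec_label("cumulative_lowest_3")
#' @export
ioh_spec <- function(family = c("sustained_lowest", "cumulative_lowest",
                                "time_under", "fraction_under"),
                     param, strict = TRUE) {
  family <- match.arg(family)
  if (!is.numeric(param) || length(param) != 1L || !is.finite(param))
    stop("'param' must be a single finite number", call. = FALSE)
  allowed <- spec_param_set(family)
  if (strict && !param %in% allowed)
    stop(sprintf("param %g not in the allowed set {%s} for family '%s'",
                 param, paste(allowed, collapse = ", "), family),
         call. = FALSE)
  structure(list(family = family, param = param,
                 label = paste0(family, "_", format(param, trim = TRUE))),
            class = "ioh_spec")
}

spec_param_set <- function(family) {
  switch(family,
         sustained_lowest  = c(1, 3, 5, 10, 15),
         cumulative_lowest = c(1, 3, 5, 10, 15),
         time_under        = c(50, 55, 60, 65, 70, 75, 80),
         fraction_under    = c(50, 55, 60, 65, 70, 75, 80))
}

#' @rdname ioh_spec
#' @param label A label such as `"time_under_50"`.
#' @export
parse_spec_label <- function(label) {
  m <- regmatches(label, regexec("^(sustained_lowest|cumulative_lowest|time_under|fraction_under)_([0-9.]+)$", label))[[1]]
  if (length(m) != 3L)
    stop(sprintf("cannot parse characterization label '%s'", label),
         call. = FALSE)
  ioh_spec(m[2], as.numeric(m[3]), strict = FALSE)
}

#' @rdname ioh_spec
#' @export
print.ioh_spec <- function(x, ...) {
  cat("IOH characterization:", x$label, "\n")
  invisible(x)
}

#' All 24 standard IOH characterizations
#'
#' The full set: five sustained-lowest and five cumulative-lowest window
#' lengths (1, 3, 5, 10, 15 min) plus seven absolute and seven relative
#' time-under thresholds (50--80 mmHg).
#'
#' @return A list of [ioh_spec] objects.
#' @export
default_characterizations <- function() {
  c(lapply(c(1, 3, 5, 10, 15), function(k) ioh_spec("sustained_lowest", k)),
    lapply(c(1, 3, 5, 10, 15), function(k) ioh_spec("cumulative_lowest", k)),
    lapply(seq(50, 80, by = 5), function(t) ioh_spec("time_under", t)),
    lapply(seq(50, 80, by = 5), function(t) ioh_spec("fraction_under", t)))
}

#' Does a characterization family have a point mass at zero?
#'
#' Time-under and fraction-under exposures are exactly zero for every
#' surgery whose MAP never crossed the threshold, so their regression
#' models carry an extra zero-exposure indicator.
#'
#' @param spec An [ioh_spec].
#' @return Logical.
#' @export
is_zero_inflated <- function(spec) {
  spec$family %in% c("time_under", "fraction_under")
}
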