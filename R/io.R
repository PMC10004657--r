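#' Write and read the long-format time-series CSV
#'
#' Columns: `case_id`, `t_s` (integer-valued seconds), `sbp`, `dbp`,
#' `map`, `source`; empty cells denote a missing channel. One file holds
#' many surgeries.
#'
#' @param series_list Named list of [bp_series].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    data.frame(case_id = as.character(s$case_id), t_s = s$samples$t,
               sbp = s$samples$sbp, dbp = s$samples$dbp,
               map = s$samples$map, source = s$samples$source,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_timeseries_csv
#' @param end_s Optional named vector of anesthesia end times per case;
#'   default: each case's last sample.
#' @export
read_timeseries_csv <- function(path, end_s = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "t_s", "sbp", "dbp", "map", "source")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("time-series CSV lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("sbp", "dbp", "map")) d[[col]] <- as.numeric(d[[col]])
  out <- lapply(split(d, d$case_id), function(s) {
    s <- s[order(s$t_s), , drop = FALSE]
    bp_series(s$case_id[1],
              data.frame(t = s$t_s, sbp = s$sbp, dbp = s$dbp, map = s$map,
                         source = s$source, stringsAsFactors = FALSE),
              anesthesia_end_s = if (!is.null(end_s))
                end_s[[s$case_id[1]]] else NULL)
  })
  out[order(names(out))]
}

#' Write and read the case/covariate CSV
#'
#' The on-disk format carries the raw PONV documentation (`ponv_raw`,
#' one of `None`, `Nausea`, `Need_to_vomit`, `Vomiting`; a case may span
#' several rows when multiple entries were documented). The reader
#' dichotomizes: a case is PONV-positive when any of its entries is
#' `Nausea`, `Need_to_vomit` or `Vomiting` (the most severe entry wins;
#' `None` is ignored in the presence of a positive entry).
#'
#' @param cases Case data.frame (binary `ponv`; the writer maps 1 to a
#'   `Nausea` entry and 0 to `None`).
#' @param path CSV path.
#' @return `path` invisibly (writer); case data.frame with binary `ponv`
#'   (reader).
#' @export
write_cases_csv <- function(cases, path) {
  d <- cases
  d$ponv_raw <- ifelse(d$ponv == 1, "Nausea", "None")
  d$ponv <- NULL
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

ponv_severity <- c(None = 0L, Nausea = 1L, Need_to_vomit = 2L,
                   Vomiting = 3L)

#' @rdname write_cases_csv
#' @export
read_cases_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"ponv_raw" %in% names(d))
    stop("case CSV lacks 'ponv_raw'", call. = FALSE)
  bad <- setdiff(unique(d$ponv_raw), names(ponv_severity))
  if (length(bad))
    stop("unknown ponv_raw value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  sev <- ponv_severity[d$ponv_raw]
  agg <- tapply(sev, d$case_id, max)
  first <- d[!duplicated(d$case_id), , drop = FALSE]
  first$ponv <- as.integer(agg[as.character(first$case_id)] > 0)
  first$ponv_raw <- NULL
  rownames(first) <- NULL
  first
}

#' Serialize a fitted characterization model to JSON
#'
#' Persists everything needed to rebuild the design on new data:
#' coefficients, robust covariance, working correlation, winsorization
#' cap and spline knots.
#'
#' @param model An `ioh_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  basis_js <- function(b) list(knots = b$knots, boundary = b$boundary,
                               degenerate = b$degenerate)
  obj <- list(
    spec = list(family = model$spec$family, param = model$spec$param),
    coefficients = as.list(model$fit$coefficients),
    vcov = model$fit$vcov,
    alpha = model$fit$alpha,
    n_cases = model$fit$n_cases,
    n_clusters = model$fit$n_clusters,
    converged = model$fit$converged,
    winsor_cap = model$cap,
    zero_col = isTRUE(model$bases$zero_col),
    bases = lapply(model$bases[c("exposure", "age", "duration")],
                   basis_js))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- ioh_spec(obj$spec$family, obj$spec$param, strict = FALSE)
  mk_basis <- function(b) structure(list(knots = b$knots,
                                         boundary = b$boundary,
                                         degenerate = b$degenerate),
                                    class = "ns_basis")
  beta <- unlist(obj$coefficients)
  vc <- as.matrix(obj$vcov)
  dimnames(vc) <- list(names(beta), names(beta))
  fit <- structure(list(coefficients = beta, vcov = vc,
                        vcov_model = NULL, alpha = obj$alpha,
                        n_cases = obj$n_cases,
                        n_clusters = obj$n_clusters,
                        converged = obj$converged,
                        iterations = NA_integer_,
                        column_names = names(beta)),
                   class = "gee_fit")
  bases <- lapply(obj$bases, mk_basis)
  bases$zero_col <- isTRUE(obj$zero_col)
  structure(list(fit = fit, spec = spec, cap = obj$winsor_cap,
                 bases = bases, omit = NULL,
                 n_dropped = NA_integer_),
            class = "ioh_model")
}

#' Write a synthetic cohort to the pipeline's CSV formats
#'
#' Emits the two input tables the pipeline reads (time-series and case
#' CSVs) plus `truth.csv` (`case_id`, `true_exposure`, `true_prob`,
#' `artifact_count`).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_timeseries_csv(cohort$series, file.path(dir, "timeseries.csv"))
  write_cases_csv(cohort$cases, file.path(dir, "cases.csv"))
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
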