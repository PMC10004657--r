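#' Winsorize at the 99th percentile
#'
#' Caps values above the empirical 99th percentile (linear-interpolation
#' order-statistic definition, `stats::quantile` type 7). The cap is
#' learned on the data being fit and must be reused, via the `cap`
#' argument, on held-out data to avoid leakage.
#'
#' @param x Numeric vector with at least 2 finite values (when `cap` is
#'   not supplied).
#' @param cap Optional pre-computed cap (from a fitting split).
#' @return list with `x` (capped values) and `cap`.
#' @export
winsorize_99 <- function(x, cap = NULL) {
  if (is.null(cap)) {
    if (sum(is.finite(x)) < 2L)
      stop("need >= 2 finite values to estimate the 99th percentile",
           call. = FALSE)
    cap <- stats::quantile(x, 0.99, na.rm = TRUE, names = FALSE, type = 7)
  }
  list(x = pmin(x, cap), cap = cap)
}

#' Natural cubic spline basis with 3 degrees of freedom
#'
#' Wraps `splines::ns`: boundary knots at the observed min/max, two
#' interior knots at the 33.3rd and 66.7th percentiles (for zero-inflated
#' exposures, percentiles of the nonzero values — the zero point mass is
#' absorbed by the separate zero indicator). The basis is linear beyond
#' the boundary knots. When fewer than four distinct values (or collapsed
#' knots) make a cubic basis unidentifiable, the transform degrades to a
#' single linear term with a warning.
#'
#' @param x Numeric values the knots are derived from.
#' @param knots,boundary Optional explicit interior/boundary knots (used
#'   to rebuild a stored basis for held-out data).
#' @param from_nonzero Derive knot percentiles from the positive values
#'   only.
#' @return An object of class `ns_basis` with elements `knots`,
#'   `boundary`, `degenerate`.
#' @export
natural_spline_basis <- function(x, knots = NULL, boundary = NULL,
                                 from_nonzero = FALSE) {
  if (is.null(boundary)) {
    xf <- x[is.finite(x)]
    boundary <- range(xf)
    ref <- if (from_nonzero && any(xf > 0)) xf[xf > 0] else xf
    knots <- stats::quantile(ref, c(1, 2) / 3, names = FALSE, type = 7)
  }
  degenerate <- length(unique(c(boundary, knots))) < 4 ||
    any(knots <= boundary[1]) || any(knots >= boundary[2])
  if (degenerate)
    warning("too few distinct values for a cubic basis; using a linear term",
            call. = FALSE)
  structure(list(knots = knots, boundary = boundary,
                 degenerate = degenerate),
            class = "ns_basis")
}

#' Evaluate a stored natural spline basis
#'
#' @param basis An `ns_basis`.
#' @param x Values to transform.
#' @return Matrix with 3 columns (1 when the basis is degenerate).
#' @export
eval_spline_basis <- function(basis, x) {
  stopifnot(inherits(basis, "ns_basis"))
  if (basis$degenerate) return(matrix(x, ncol = 1))
  unclass(splines::ns(x, knots = basis$knots,
                      Boundary.knots = basis$boundary))[, , drop = FALSE]
}

# confounder main-effect columns shared by every model
confounder_cols <- c("female", "smoker", "volatile", "ondansetron_ppx",
                     "dexamethasone_ppx", "comorbidity_pos", "risk_surgery")

#' Build the multivariable design matrix for one characterization
#'
#' Column layout (stable order): intercept; exposure spline (3 columns,
#' winsorized values); for zero-inflated families a zero-exposure
#' indicator (`1` when the exposure equals zero; included only when the
#' fitting data contain zero exposures, and the decision is stored with
#' the bases); confounder mains
#' (female, smoker, volatile, ondansetron, dexamethasone, Charlson > 0,
#' risk surgery); ASA dummies (levels 2-4 vs ASA 1); age spline (3);
#' duration spline (3); and the age-spline columns multiplied by `female`
#' (the age-by-sex interaction, 3 columns).
#'
#' @param cases data.frame of surgery cases (see [simulate_cohort] for
#'   the column contract).
#' @param exposure Numeric exposure column aligned to `cases`, already
#'   winsorized.
#' @param spec The [ioh_spec] the exposure came from (controls the zero
#'   indicator).
#' @param bases Optional list of stored bases (`exposure`, `age`,
#'   `duration`) from a fitting split; when `NULL`, knots are derived
#'   from this data.
#' @param omit Optional variable group to drop, one of `"exposure"`,
#'   `"sex"`, `"age"` (both drop the age-sex interaction too),
#'   `"smoker"`, `"volatile"`, `"ondansetron"`, `"dexamethasone"`,
#'   `"asa"`, `"comorbidity"`, `"risk_surgery"`, `"duration"`. Used for
#'   variable-contribution analyses.
#' @return A numeric matrix with an attribute `bases` (the spline bases
#'   used) for reuse on held-out data.
#' @export
build_design <- function(cases, exposure, spec, bases = NULL, omit = NULL) {
  stopifnot(nrow(cases) == length(exposure))
  if (is.null(bases)) {
    bases <- list(
      exposure = natural_spline_basis(exposure,
                                      from_nonzero = is_zero_inflated(spec)),
      age = natural_spline_basis(cases$age),
      duration = natural_spline_basis(cases$duration_h),
      # the zero indicator enters only when the fitting data carry the
      # point mass it is meant to absorb (an all-zero column is
      # unidentifiable); the decision travels with the bases
      zero_col = is_zero_inflated(spec) && any(exposure == 0))
  }
  exp_b <- eval_spline_basis(bases$exposure, exposure)
  colnames(exp_b) <- paste0("exp_ns", seq_len(ncol(exp_b)))
  age_b <- eval_spline_basis(bases$age, cases$age)
  colnames(age_b) <- paste0("age_ns", seq_len(ncol(age_b)))
  dur_b <- eval_spline_basis(bases$duration, cases$duration_h)
  colnames(dur_b) <- paste0("dur_ns", seq_len(ncol(dur_b)))
  agefem <- age_b * cases$female
  colnames(agefem) <- paste0("agefem_ns", seq_len(ncol(agefem)))

  parts <- list("(Intercept)" = matrix(1, nrow(cases), 1,
                                       dimnames = list(NULL, "(Intercept)")))
  if (!identical(omit, "exposure")) {
    parts$exposure <- exp_b
    if (isTRUE(bases$zero_col)) {
      zi <- matrix(as.numeric(exposure == 0), ncol = 1,
                   dimnames = list(NULL, "exp_zero"))
      parts$exp_zero <- zi
    }
  }
  mains <- as.matrix(cases[confounder_cols])
  drop_main <- switch(as.character(omit %||% ""),
                      sex = "female", smoker = "smoker",
                      volatile = "volatile", ondansetron = "ondansetron_ppx",
                      dexamethasone = "dexamethasone_ppx",
                      comorbidity = "comorbidity_pos",
                      risk_surgery = "risk_surgery", NULL)
  if (!is.null(drop_main))
    mains <- mains[, setdiff(colnames(mains), drop_main), drop = FALSE]
  parts$mains <- mains
  if (!identical(omit, "asa")) {
    asa <- vapply(2:4, function(l) as.numeric(cases$asa == l),
                  numeric(nrow(cases)))
    colnames(asa) <- paste0("asa", 2:4)
    parts$asa <- asa
  }
  if (!identical(omit, "age")) parts$age <- age_b
  if (!identical(omit, "duration")) parts$duration <- dur_b
  if (!identical(omit, "age") && !identical(omit, "sex"))
    parts$agefem <- agefem
  X <- do.call(cbind, parts)
  colnames(X) <- unlist(lapply(parts, colnames), use.names = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    warning("design matrix is rank deficient; offending column(s): ",
            paste(bad, collapse = ", "), call. = FALSE)
  }
  attr(X, "bases") <- bases
  attr(X, "spec_label") <- spec$label
  X
}

`%||%` <- function(a, b) if (is.null(a)) b else a
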