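#' Brier score
#'
#' Mean squared difference between predicted probability and the binary
#' outcome; lower is better (0 = perfect, 0.25 = uninformative constant
#' 0.5).
#'
#' @param p Predicted probabilities.
#' @param y Binary outcomes (0/1), aligned to `p`.
#' @return The Brier score.
#' @export
brier_score <- function(p, y) {
  stopifnot(length(p) == length(y), length(p) > 0)
  mean((p - y)^2)
}

#' c-statistic (concordance)
#'
#' Probability that a randomly chosen event carries a higher prediction
#' than a randomly chosen non-event, ties counted one half. Computed via
#' mid-ranks (equivalent to the Wilcoxon/AUC formulation).
#'
#' @inheritParams brier_score
#' @return Concordance in \[0, 1\]; `NA` with a warning if only one
#'   outcome class is present.
#' @export
c_statistic <- function(p, y) {
  stopifnot(length(p) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    warning("c-statistic undefined: single outcome class", call. = FALSE)
    return(NA_real_)
  }
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Discrimination slope
#'
#' Difference in mean predicted probability between events and
#' non-events.
#'
#' @inheritParams brier_score
#' @return Slope in \[-1, 1\]; `NA` with a warning on single-class input.
#' @export
discrimination_slope <- function(p, y) {
  stopifnot(length(p) == length(y))
  if (length(unique(y)) < 2L) {
    warning("discrimination slope undefined: single outcome class",
            call. = FALSE)
    return(NA_real_)
  }
  mean(p[y == 1]) - mean(p[y == 0])
}

#' Calibration slope
#'
#' Slope of a univariate logistic regression of the outcome on the logit
#' of the predictions: 1 indicates well-calibrated spread, below 1
#' overfitting (predictions too extreme).
#'
#' @inheritParams brier_score
#' @return The slope; `NA` with a warning on degenerate input.
#' @export
calibration_slope <- function(p, y) {
  stopifnot(length(p) == length(y))
  if (length(unique(y)) < 2L) {
    warning("calibration slope undefined: single outcome class",
            call. = FALSE)
    return(NA_real_)
  }
  lp <- stats::qlogis(pmin(pmax(p, 1e-12), 1 - 1e-12))
  fit <- tryCatch(
    suppressWarnings(stats::glm(y ~ lp, family = stats::binomial())),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) {
    warning("calibration slope fit did not converge", call. = FALSE)
    return(NA_real_)
  }
  unname(stats::coef(fit)[2])
}
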