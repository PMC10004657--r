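#' Patient-level shaping/estimation split
#'
#' Randomly allocates each patient — with all their surgical procedures —
#' to either the shaping arm (model selection) or the estimation arm
#' (effect estimation), targeting equal procedure counts: patients are
#' visited in random order and greedily assigned to the currently smaller
#' arm, so arm sizes differ by at most the largest single patient's
#' procedure count.
#'
#' @param cases Case data.frame with `case_id` and `patient_id`.
#' @param seed Integer seed.
#' @return Object of class `split_plan`: data.frame `patients`
#'   (`patient_id`, `arm`), plus per-arm case counts.
#' @export
split_cohort <- function(cases, seed = 1L) {
  counts <- table(as.character(cases$patient_id))
  patients <- names(counts)
  if (length(patients) < 2L)
    stop("need at least 2 patients to split", call. = FALSE)
  set.seed(seed)
  ord <- sample.int(length(patients))
  arm <- character(length(patients))
  tot <- c(shaping = 0, estimation = 0)
  for (i in ord) {
    a <- if (tot[["shaping"]] <= tot[["estimation"]]) "shaping" else "estimation"
    arm[i] <- a
    tot[[a]] <- tot[[a]] + counts[[i]]
  }
  structure(list(patients = data.frame(patient_id = patients, arm = arm,
                                       stringsAsFactors = FALSE),
                 n_cases = tot, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("Split plan: shaping %d cases, estimation %d cases\n",
              x$n_cases[["shaping"]], x$n_cases[["estimation"]]))
  invisible(x)
}

#' Cases of one split arm
#'
#' @param cases Case data.frame.
#' @param plan A `split_plan`.
#' @param arm `"shaping"` or `"estimation"`.
#' @return The subset of `cases` in the arm.
#' @export
split_arm <- function(cases, plan, arm = c("shaping", "estimation")) {
  arm <- match.arg(arm)
  ids <- plan$patients$patient_id[plan$patients$arm == arm]
  cases[as.character(cases$patient_id) %in% ids, , drop = FALSE]
}

#' Adjusted odds ratio for an exposure contrast
#'
#' Contrasts exposure value `x` against the zero-exposure reference (MAP
#' consistently above the threshold, for time/fraction families) on a
#' fitted characterization model. The log-OR is the spline-basis
#' difference `[s(x) - s(0)]` (and, for zero-inflated families, the drop
#' of the zero indicator) pushed through the coefficients; its variance
#' comes from the delta method on the robust covariance (the contrast is
#' linear in the coefficients, so the delta method is exact on the
#' log-odds scale). Values beyond the winsorization cap are evaluated at
#' the cap with a note.
#'
#' @param model An `ioh_model` from [fit_characterization_model].
#' @param x Exposure value to contrast against 0 (`x >= 0`).
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `or_contrast`: `x`, `x_evaluated`,
#'   `odds_ratio`, `ci_low`, `ci_high`, `log_or`, `se`, `capped`.
#' @export
estimate_adjusted_or <- function(model, x, conf_level = 0.95) {
  stopifnot(inherits(model, "ioh_model"), x >= 0)
  if (!model$fit$converged)
    stop("model did not converge; no contrast reported", call. = FALSE)
  capped <- x > model$cap
  if (capped)
    message(sprintf("x = %g beyond the winsorization cap %.4g; evaluated at the cap",
                    x, model$cap))
  xe <- min(x, model$cap)
  cv <- contrast_vector(model, xe)
  beta <- model$fit$coefficients
  lor <- sum(cv * beta)
  se <- sqrt(drop(t(cv) %*% model$fit$vcov %*% cv))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(x = x, x_evaluated = xe,
                 odds_ratio = exp(lor),
                 ci_low = exp(lor - zq * se),
                 ci_high = exp(lor + zq * se),
                 log_or = lor, se = se, capped = capped,
                 spec = model$spec),
            class = "or_contrast")
}

contrast_vector <- function(model, x) {
  cols <- model$fit$column_names
  cv <- stats::setNames(numeric(length(cols)), cols)
  sx <- eval_spline_basis(model$bases$exposure, c(x, 0))
  dcols <- paste0("exp_ns", seq_len(ncol(sx)))
  cv[dcols] <- sx[1, ] - sx[2, ]
  if ("exp_zero" %in% cols)
    cv["exp_zero"] <- (x == 0) - 1   # reference (x = 0) carries the indicator
  cv
}

#' @export
print.or_contrast <- function(x, ...) {
  cat(sprintf(
    "Adjusted OR [%s = %g%s vs 0]: %.3f (95%% CI %.3f-%.3f)\n",
    x$spec$label, x$x, if (x$capped) sprintf(" capped to %.3g", x$x_evaluated) else "",
    x$odds_ratio, x$ci_low, x$ci_high))
  invisible(x)
}

#' Log-odds curve over exposure values and its plateau point
#'
#' Evaluates the exposure contrast over a grid and reports the first
#' exposure value at which the numerical derivative of the spline
#' log-odds falls below a tolerance — the point where the fitted
#' dose-response flattens.
#'
#' @param model An `ioh_model`.
#' @param xs Exposure grid (default: 200 points from 0 to the cap).
#' @param deriv_tol Flatness tolerance on the log-odds derivative per
#'   exposure unit.
#' @return list with `curve` (data.frame `x`, `log_or`) and
#'   `plateau_x` (`NA` when the curve never flattens).
#' @export
or_curve <- function(model, xs = NULL, deriv_tol = 0.01) {
  if (is.null(xs))
    xs <- seq(0, model$cap, length.out = 200)
  lor <- vapply(xs, function(x) sum(contrast_vector(model, x) *
                                      model$fit$coefficients), 0)
  d <- diff(lor) / diff(xs)
  # ignore the jump off zero (the zero-indicator step) when locating the
  # plateau of the continuous part
  idx <- which(xs[-1] > 0 & abs(d) < deriv_tol)
  list(curve = data.frame(x = xs, log_or = lor),
       plateau_x = if (length(idx)) xs[idx[1] + 1] else NA_real_)
}

#' Apfel PONV risk score
#'
#' Count of the four classical risk factors: female sex, non-smoking
#' status, history of PONV or motion sickness, and postoperative opioid
#' use. Reporting-only — not a model covariate (postoperative opioid use
#' is a post-exposure variable).
#'
#' @param female,smoker,history_ponv,postop_opioids Binary vectors.
#' @return Integer score 0-4 per case (`NA` where any input is missing).
#' @examples
#' apfel_score(0, 1, 0, 0)  # male smoker, no history, no opioids -> 0
#' apfel_score(1, 0, 1, 1)  # -> 4
#' @export
apfel_score <- function(female, smoker, history_ponv, postop_opioids) {
  as.integer(female + (1 - smoker) + history_ponv + postop_opioids)
}
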