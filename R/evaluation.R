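#' Cluster-respecting repeated k-fold plan
#'
#' Assigns patients (not surgeries) to folds so that all of a patient's
#' procedures share a fold, for each of `reps` independent repetitions.
#' Folds are balanced to within one patient.
#'
#' @param patient_ids Patient id per case (duplicates allowed) or a
#'   vector of unique patients.
#' @param k Folds per repetition (default 10).
#' @param reps Repetitions (default 40).
#' @param seed Integer seed.
#' @return Object of class `fold_plan`: `patients` (unique ids),
#'   `assignment` (matrix patients x reps of fold numbers), `k`, `reps`.
#' @export
make_fold_plan <- function(patient_ids, k = 10L, reps = 40L, seed = 1L) {
  patients <- sort(unique(as.character(patient_ids)))
  np <- length(patients)
  if (np < k)
    stop(sprintf("need at least k = %d patients, got %d", k, np),
         call. = FALSE)
  set.seed(seed)
  assignment <- vapply(seq_len(reps), function(r) {
    fold <- rep_len(seq_len(k), np)           # balanced to within 1
    fold[sample.int(np)] <- fold
    fold
  }, integer(np))
  rownames(assignment) <- patients
  structure(list(patients = patients, assignment = assignment,
                 k = as.integer(k), reps = as.integer(reps), seed = seed),
            class = "fold_plan")
}

#' Fold membership of cases in one repetition
#'
#' @param plan A `fold_plan`.
#' @param patient_ids Patient id per case.
#' @param rep Repetition index.
#' @return Integer fold per case.
#' @export
case_folds <- function(plan, patient_ids, rep) {
  unname(plan$assignment[as.character(patient_ids), rep])
}

#' Cross-validated performance of one characterization's model
#'
#' For each repetition and fold: the winsorization cap and all spline
#' knots are derived from the training folds only, the GEE is fit on the
#' training folds, and held-out cases are scored with the training-fold
#' design. Held-out predictions are pooled within a repetition, the four
#' metrics (Brier score, c-statistic, discrimination slope, calibration
#' slope) computed on the pooled set, and means and SDs taken across
#' repetitions. Folds whose model fails (non-convergence, single-class
#' training outcome) are dropped from their repetition with accounting.
#'
#' @param spec An [ioh_spec].
#' @param cases Case data.frame.
#' @param features Feature table from [compute_feature_table], aligned to
#'   `cases` by `case_id`.
#' @param plan A [make_fold_plan] plan covering `cases`' patients.
#' @param omit Optional variable group to exclude (contribution runs).
#' @return Object of class `cv_metrics`: per-metric `mean` and `sd`,
#'   `per_rep` data.frame, `n_failed_folds`.
#' @export
cross_validate <- function(spec, cases, features, plan, omit = NULL) {
  expo_all <- features[[spec$label]][match(cases$case_id, features$case_id)]
  keep <- !is.na(expo_all)
  cases <- cases[keep, , drop = FALSE]
  expo_all <- expo_all[keep]
  metrics <- c("brier", "c_stat", "discrimination_slope",
               "calibration_slope")
  per_rep <- matrix(NA_real_, plan$reps, length(metrics),
                    dimnames = list(NULL, metrics))
  n_failed <- 0L
  for (r in seq_len(plan$reps)) {
    fold <- case_folds(plan, cases$patient_id, r)
    p_pool <- rep(NA_real_, nrow(cases))
    for (f in seq_len(plan$k)) {
      tr <- fold != f
      if (length(unique(cases$ponv[tr])) < 2L ||
          length(unique(cases$patient_id[tr])) < 2L) {
        n_failed <- n_failed + 1L
        next
      }
      res <- tryCatch(suppressWarnings({
        wz <- winsorize_99(expo_all[tr])
        Xtr <- build_design(cases[tr, , drop = FALSE], wz$x, spec,
                            omit = omit)
        fit <- fit_gee_logistic(Xtr, cases$ponv[tr], cases$patient_id[tr])
        if (!fit$converged) stop("non-convergent fold model")
        xte <- winsorize_99(expo_all[!tr], cap = wz$cap)$x
        Xte <- build_design(cases[!tr, , drop = FALSE], xte, spec,
                            bases = attr(Xtr, "bases"), omit = omit)
        predict_prob(fit, Xte)
      }), error = function(e) NULL)
      if (is.null(res)) {
        n_failed <- n_failed + 1L
      } else {
        p_pool[!tr] <- res
      }
    }
    ok <- !is.na(p_pool)
    if (any(ok) && length(unique(cases$ponv[ok])) == 2L) {
      per_rep[r, ] <- suppressWarnings(c(
        brier_score(p_pool[ok], cases$ponv[ok]),
        c_statistic(p_pool[ok], cases$ponv[ok]),
        discrimination_slope(p_pool[ok], cases$ponv[ok]),
        calibration_slope(p_pool[ok], cases$ponv[ok])))
    }
  }
  means <- colMeans(per_rep, na.rm = TRUE)
  sds <- apply(per_rep, 2, stats::sd, na.rm = TRUE)
  sds[is.na(sds)] <- 0   # single repetition: SD reported as 0 by convention
  structure(list(spec = spec, mean = means, sd = sds,
                 per_rep = as.data.frame(per_rep),
                 n_failed_folds = n_failed),
            class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat("Cross-validated metrics for", x$spec$label, "\n")
  print(data.frame(mean = x$mean, sd = x$sd))
  invisible(x)
}

#' Rank characterizations by cross-validated Brier score
#'
#' Runs [cross_validate] for every candidate on the identical fold plan
#' and ranks ascending by mean Brier score. Ties are broken by higher
#' c-statistic, then by label order (recorded in the result).
#'
#' @param specs List of [ioh_spec] candidates (>= 2).
#' @param cases Case data.frame.
#' @param features Feature table.
#' @param plan Shared [make_fold_plan] plan.
#' @return Object of class `ioh_comparison`: `table` (one row per spec,
#'   ranked), `best` (the selected [ioh_spec]), `metrics` (named list of
#'   `cv_metrics`), `tie_broken` flag.
#' @export
rank_characterizations <- function(specs, cases, features, plan) {
  if (length(specs) < 2L) stop("need >= 2 candidate specs", call. = FALSE)
  labels <- vapply(specs, `[[`, "", "label")
  cvs <- lapply(specs, cross_validate, cases = cases, features = features,
                plan = plan)
  names(cvs) <- labels
  tab <- data.frame(
    characterization = labels,
    brier = vapply(cvs, function(m) m$mean[["brier"]], 0),
    brier_sd = vapply(cvs, function(m) m$sd[["brier"]], 0),
    c_stat = vapply(cvs, function(m) m$mean[["c_stat"]], 0),
    discrimination_slope =
      vapply(cvs, function(m) m$mean[["discrimination_slope"]], 0),
    calibration_slope =
      vapply(cvs, function(m) m$mean[["calibration_slope"]], 0),
    n_failed_folds = vapply(cvs, function(m) m$n_failed_folds, 0L),
    stringsAsFactors = FALSE)
  if (all(is.na(tab$brier)))
    stop("no characterization model converged", call. = FALSE)
  ord <- order(tab$brier, -tab$c_stat, tab$characterization)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tie <- sum(tab$brier == tab$brier[1], na.rm = TRUE) > 1
  best <- specs[[match(tab$characterization[1], labels)]]
  structure(list(table = tab, best = best, metrics = cvs,
                 tie_broken = tie),
            class = "ioh_comparison")
}

#' @export
print.ioh_comparison <- function(x, ...) {
  cat("Characterization comparison (ascending cross-validated Brier):\n")
  print(x$table[, c("rank", "characterization", "brier", "c_stat")],
        digits = 4)
  cat("Selected:", x$best$label,
      if (x$tie_broken) "(tie broken by c-statistic/label)" else "", "\n")
  invisible(x)
}

# variable groups for contribution analysis; sex and age also drop the
# age-sex interaction
contribution_groups <- c("exposure", "sex", "age", "smoker", "volatile",
                         "ondansetron", "dexamethasone", "asa",
                         "comorbidity", "risk_surgery", "duration")

#' Brier-score contribution of each model variable
#'
#' Refits and cross-validates the model with one variable group omitted
#' at a time (on the identical fold plan) and reports the increase in
#' cross-validated Brier score relative to the full model. When sex or
#' age is omitted, the age-sex interaction is omitted with it.
#'
#' @param spec The (best) [ioh_spec].
#' @param cases Case data.frame.
#' @param features Feature table.
#' @param plan Shared fold plan.
#' @param full Optional pre-computed `cv_metrics` of the full model.
#' @return Object of class `contribution_result`: data.frame `table`
#'   (`variable`, `brier_without`, `delta`), plus `full_brier`.
#' @export
variable_contribution <- function(spec, cases, features, plan, full = NULL) {
  if (is.null(full))
    full <- cross_validate(spec, cases, features, plan)
  deltas <- vapply(contribution_groups, function(g) {
    cv <- cross_validate(spec, cases, features, plan, omit = g)
    cv$mean[["brier"]]
  }, 0)
  tab <- data.frame(variable = contribution_groups,
                    brier_without = deltas,
                    delta = deltas - full$mean[["brier"]],
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, full_brier = full$mean[["brier"]]),
            class = "contribution_result")
}

#' @export
print.contribution_result <- function(x, ...) {
  cat(sprintf("Variable contributions (full-model CV Brier %.4f):\n",
              x$full_brier))
  print(x$table[order(-x$table$delta), ], digits = 4)
  invisible(x)
}
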