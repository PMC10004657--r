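test_that("fold plans are balanced, cluster-respecting and seeded", {
  plan <- make_fold_plan(sprintf("p%03d", 1:100), k = 10, reps = 5,
                         seed = 1)
  for (r in 1:5)
    expect_equal(as.integer(table(plan$assignment[, r])), rep(10L, 10))

  pid <- c(rep("a", 3), "b", "c", sprintf("p%02d", 1:20))
  plan2 <- make_fold_plan(pid, k = 5, reps = 3, seed = 2)
  f <- case_folds(plan2, c("a", "a", "a"), rep = 2)
  expect_equal(length(unique(f)), 1L)          # shared fold for one patient

  expect_identical(make_fold_plan(pid, 5, 3, seed = 9)$assignment,
                   make_fold_plan(pid, 5, 3, seed = 9)$assignment)
  expect_false(identical(make_fold_plan(pid, 5, 3, seed = 9)$assignment,
                         make_fold_plan(pid, 5, 3, seed = 10)$assignment))
  expect_error(make_fold_plan(c("a", "b"), k = 10), "at least k")
})

test_that("Brier score matches its definition", {
  expect_equal(brier_score(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier_score(rep(0.5, 10), rbinom(10, 1, 0.5)), 0.25)
  set.seed(3)
  p <- runif(50); y <- rbinom(50, 1, 0.5)
  expect_equal(brier_score(p, y), sum((p - y)^2) / 50)
})

test_that("c-statistic equals pair enumeration and handles ties", {
  expect_equal(c_statistic(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(c_statistic(rep(0.4, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  set.seed(4)
  for (i in 1:20) {
    p <- round(runif(60), 2)                   # rounding forces ties
    y <- rbinom(60, 1, 0.4)
    if (length(unique(y)) < 2) next
    expect_equal(c_statistic(p, y), oracle_cstat(p, y))
  }
  expect_warning(out <- c_statistic(runif(5), rep(1, 5)), "single")
  expect_true(is.na(out))
})

test_that("discrimination slope is the two-group mean difference", {
  expect_equal(discrimination_slope(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(discrimination_slope(rep(0.3, 8), rep(c(0, 1), 4)), 0)
  set.seed(5)
  p <- runif(40); y <- rbinom(40, 1, 0.5)
  expect_equal(discrimination_slope(p, y),
               mean(p[y == 1]) - mean(p[y == 0]))
})

test_that("calibration slope detects calibrated, overfit and null models", {
  set.seed(6)
  lp <- rnorm(4000, -1, 1.2)
  y <- rbinom(4000, 1, plogis(lp))
  expect_equal(calibration_slope(plogis(lp), y), 1, tolerance = 0.15)
  # doubling the logits halves the slope
  expect_equal(calibration_slope(plogis(2 * lp), y), 0.5, tolerance = 0.1)
  # predictions independent of the outcome
  expect_equal(calibration_slope(plogis(sample(lp)), y), 0,
               tolerance = 0.1)
})

test_that("cross-validation matches a manual two-fold computation", {
  set.seed(7)
  d <- make_cases(60, cases_per_patient = 4, beta_exposure = 0.4)
  spec <- ioh_spec("time_under", 50)
  feats <- features_from(d, spec$label)
  plan <- make_fold_plan(d$patient_id, k = 2, reps = 1, seed = 8)
  cv <- cross_validate(spec, d, feats, plan)

  # manual: same folds, same protocol
  fold <- case_folds(plan, d$patient_id, 1)
  p_pool <- rep(NA_real_, nrow(d))
  for (f in 1:2) {
    tr <- fold != f
    wz <- winsorize_99(d$exposure[tr])
    Xtr <- build_design(d[tr, ], wz$x, spec)
    fit <- fit_gee_logistic(Xtr, d$ponv[tr], d$patient_id[tr])
    xte <- winsorize_99(d$exposure[!tr], cap = wz$cap)$x
    Xte <- build_design(d[!tr, ], xte, spec, bases = attr(Xtr, "bases"))
    p_pool[!tr] <- predict_prob(fit, Xte)
  }
  expect_equal(cv$mean[["brier"]], brier_score(p_pool, d$ponv))
  expect_equal(cv$mean[["c_stat"]], c_statistic(p_pool, d$ponv))
  expect_equal(unname(cv$sd), rep(0, 4))       # single repetition: SD 0
})

test_that("winsorization caps respond only to their own training folds", {
  set.seed(9)
  d <- make_cases(40, cases_per_patient = 1)
  d$exposure[1] <- 500                          # one extreme case
  plan <- make_fold_plan(d$patient_id, k = 4, reps = 1, seed = 10)
  fold <- case_folds(plan, d$patient_id, 1)
  hot <- fold[1]                                # fold holding the extreme
  caps <- vapply(1:4, function(f)
    winsorize_99(d$exposure[fold != f])$cap, 0)
  expect_gt(min(caps[-hot]), caps[hot])         # cap drops only when held out
})

test_that("ranking is deterministic and selects the smallest Brier", {
  set.seed(11)
  d <- make_cases(120, cases_per_patient = 2, beta_exposure = 0.5,
                  beta_nonzero = 0.4)
  spec <- ioh_spec("time_under", 50)
  feats <- features_from(d, spec$label)
  feats$time_under_60 <- feats$time_under_50    # duplicate under a new label
  feats$fraction_under_50 <- pmin(d$exposure / 10, 1)
  plan <- make_fold_plan(d$patient_id, k = 3, reps = 2, seed = 12)
  specs <- list(spec, ioh_spec("time_under", 60),
                ioh_spec("fraction_under", 50))
  cmp <- rank_characterizations(specs, d, feats, plan)
  tab <- cmp$table
  # duplicated exposure column gives identical metrics
  expect_equal(tab$brier[tab$characterization == "time_under_50"],
               tab$brier[tab$characterization == "time_under_60"])
  expect_equal(tab$brier, sort(tab$brier))
  expect_equal(cmp$best$label, tab$characterization[1])
  cmp2 <- rank_characterizations(specs, d, feats, plan)
  expect_identical(cmp$table, cmp2$table)
})

test_that("variable contributions cover every group and flag the signal", {
  set.seed(13)
  d <- make_cases(150, cases_per_patient = 2, beta_exposure = 0.8,
                  beta_nonzero = 0.8)
  spec <- ioh_spec("time_under", 50)
  feats <- features_from(d, spec$label)
  plan <- make_fold_plan(d$patient_id, k = 3, reps = 2, seed = 14)
  ctr <- variable_contribution(spec, d, feats, plan)
  expect_equal(nrow(ctr$table), 11L)
  expect_setequal(ctr$table$variable,
                  c("exposure", "sex", "age", "smoker", "volatile",
                    "ondansetron", "dexamethasone", "asa", "comorbidity",
                    "risk_surgery", "duration"))
  # dropping the generating exposure must cost Brier score here
  expect_gt(ctr$table$delta[ctr$table$variable == "exposure"], 0)
})
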