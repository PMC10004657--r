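test_that("invasive traces sample every 15 s", {
  tr <- simulate_map_trace(60, "invasive", seed = 1)
  expect_equal(nrow(tr$samples), 241L)          # floor(60*60/15) + 1
  expect_equal(tr$samples$t, seq(0, 3600, 15))
  expect_error(simulate_map_trace(0, "invasive"), "duration_min")
})

test_that("non-invasive traces sample at 3-5 minute gaps", {
  tr <- simulate_map_trace(120, "non_invasive", seed = 2)
  gaps <- diff(tr$samples$t)
  expect_true(all(gaps >= 180 & gaps <= 300))
  expect_equal(tr$samples$t[1], 0)
})

test_that("a degenerate process yields a constant trace", {
  proc <- list(baseline = 80, dip_depth = 0, dip_tau_min = 3,
               reversion_rate = 0.3, noise_sd = 0)
  tr <- simulate_map_trace(30, "invasive", proc, seed = 3)
  expect_true(all(tr$samples$map == 80))
  # SBP/DBP consistent with MAP = DBP + (SBP - DBP)/3
  expect_equal(derive_map(tr$samples$sbp, tr$samples$dbp),
               tr$samples$map)
})

test_that("trace mean matches the stationary moments of the process", {
  proc <- list(baseline = 80, dip_depth = 0, dip_tau_min = 3,
               reversion_rate = 0.3, noise_sd = 9.5)
  tr <- simulate_map_trace(120, "invasive", proc, seed = 4)
  st <- map_process_stationary(proc)
  n <- nrow(tr$samples)
  rho <- exp(-proc$reversion_rate * 15 / 60)
  n_eff <- n * (1 - rho) / (1 + rho)    # AR(1) effective sample size
  se <- st$sd / sqrt(n_eff)
  expect_lt(abs(mean(tr$samples$map) - st$mean), 3 * se)
})

test_that("artifact injection honours rate, labels and rule templates", {
  tr <- simulate_map_trace(60, "invasive", seed = 5)
  none <- inject_artifacts(tr, rate = 0)
  expect_identical(none$series$samples, tr$samples)
  expect_equal(nrow(none$truth), 0L)

  counts <- vapply(1:300, function(s) {
    nrow(inject_artifacts(tr, rate = 6, seed = s)$truth)
  }, 0)
  expect_lt(abs(mean(counts) - 6), 3 * sqrt(6 / 300))   # Poisson mean 6

  inj <- inject_artifacts(tr, rate = 30, seed = 6)
  r1 <- inj$truth$t[inj$truth$rule == 1]
  s <- inj$series$samples
  expect_true(all(s$sbp[s$t %in% r1] >= 300))
  r5 <- inj$truth$t[inj$truth$rule == 5]
  expect_true(all(s$sbp[s$t %in% r5] <= s$dbp[s$t %in% r5] + 5))
  expect_true(!is.unsorted(s$t, strictly = TRUE))
})

test_that("null generative model yields a 50% event rate", {
  cfg <- sim_config(n_patients = 1500, surgeries_per_patient_rate = 1.37,
                    artifact_rate = 0, intercept = 0, patient_sd = 0,
                    confounder_betas = c(female = 0, age = 0, smoker = 0,
                                         volatile = 0, ondansetron_ppx = 0,
                                         dexamethasone_ppx = 0,
                                         risk_surgery = 0, duration = 0,
                                         comorbidity_pos = 0, asa2 = 0,
                                         asa3 = 0, asa4 = 0),
                    true_effect = list(spec = ioh_spec("time_under", 50),
                                       beta_per_unit = 0, beta_nonzero = 0),
                    seed = 31)
  co <- simulate_cohort(cfg)
  n <- nrow(co$cases)
  expect_gt(n, 2000)
  expect_lt(abs(mean(co$cases$ponv) - 0.5), 3 * sqrt(0.25 / n))
  expect_true(all(co$truth$true_prob == 0.5))
})

test_that("one surgery per patient when the rate is exactly 1", {
  co <- simulate_cohort(sim_config(n_patients = 80,
                                   surgeries_per_patient_rate = 1,
                                   seed = 8))
  expect_equal(nrow(co$cases), 80L)
  expect_equal(anyDuplicated(co$cases$patient_id), 0L)
})

test_that("cohorts are deterministic given the config seed", {
  cfg <- sim_config(n_patients = 60, seed = 12)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$cases, b$cases)
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$series, `[[`, "samples"),
                   lapply(b$series, `[[`, "samples"))
  c2 <- simulate_cohort(sim_config(n_patients = 60, seed = 13))
  expect_false(identical(a$cases$ponv, c2$cases$ponv))
})

test_that("stored truth is exactly reproducible from the clean grids", {
  co <- simulate_cohort(sim_config(n_patients = 50, seed = 14))
  spec <- co$config$true_effect$spec
  redone <- vapply(co$clean_grids[co$truth$case_id], compute_exposure, 0,
                   spec = spec)
  expect_identical(unname(redone), co$truth$true_exposure)
})

test_that("mean of the truth probabilities calibrates the event rate", {
  co <- simulate_cohort(sim_config(n_patients = 1500, seed = 15))
  n <- nrow(co$cases)
  expect_gt(n, 2000)
  p <- mean(co$truth$true_prob)
  expect_lt(abs(mean(co$cases$ponv) - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("ordinary logistic regression recovers the generating effect
           when clustering is absent", {
  cfg <- sim_config(n_patients = 2000, surgeries_per_patient_rate = 1,
                    patient_sd = 0, artifact_rate = 0, seed = 16)
  co <- simulate_cohort(cfg)
  d <- co$cases
  d$expo <- co$truth$true_exposure
  fit <- glm(ponv ~ female + I(age - 53) + smoker + volatile +
               ondansetron_ppx + dexamethasone_ppx + risk_surgery +
               I(duration_h - 1.7) + comorbidity_pos + factor(asa) +
               I(expo > 0) + expo,
             family = binomial(), data = d)
  est <- coef(fit)[["expo"]]
  se <- sqrt(diag(vcov(fit)))[["expo"]]
  expect_lt(abs(est - cfg$true_effect$beta_per_unit), 2 * se)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(monitoring_mix = 1.5))
  expect_error(sim_config(patient_sd = -1))
  expect_error(sim_config(surgeries_per_patient_rate = 0.5))
})
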