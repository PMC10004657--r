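#' Simulation configuration for synthetic perioperative cohorts
#'
#' Bundles every knob of the generator. Defaults emulate a general
#' non-cardiothoracic surgical population under general anesthesia:
#' roughly 1.37 surgeries per patient, 20% invasive monitoring (15-s
#' sampling) vs 80% oscillometric cuffs (3-5 min intervals), log-normal
#' surgery durations with median ~1.7 h, a mean-reverting MAP process
#' around 80 mmHg with a post-induction dip, and a PONV outcome whose
#' log-odds combine a hypotension exposure, standard confounders and a
#' patient-level random intercept.
#'
#' @param n_patients Number of patients.
#' @param surgeries_per_patient_rate Mean surgeries per patient; counts
#'   are drawn as `1 + Poisson(rate - 1)`.
#' @param monitoring_mix Fraction of cases with invasive monitoring.
#' @param duration_meanlog,duration_sdlog Log-normal parameters of surgery
#'   duration in hours.
#' @param map_process List: `baseline` (mmHg), `dip_depth` (mmHg),
#'   `dip_tau_min` (min, decay constant of the induction dip),
#'   `reversion_rate` (1/min), `noise_sd` (mmHg, stationary SD of the
#'   fluctuation process).
#' @param artifact_rate Artifacts injected per hour of record.
#' @param true_effect List: `spec` (an [ioh_spec] driving the outcome),
#'   `beta_per_unit` (log-odds per exposure unit), `beta_nonzero`
#'   (log-odds jump for any positive exposure).
#' @param confounder_betas Named log-odds coefficients: `female`, `age`
#'   (per year, centred at 53), `smoker`, `volatile`, `ondansetron_ppx`,
#'   `dexamethasone_ppx`, `risk_surgery`, `duration` (per hour, centred
#'   at 1.7), `comorbidity_pos`, `asa2`, `asa3`, `asa4`.
#' @param intercept Log-odds intercept.
#' @param patient_sd SD of the patient-level normal random intercept.
#' @param seed Integer seed; a fixed seed makes the cohort reproducible.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 500,
                       surgeries_per_patient_rate = 1.37,
                       monitoring_mix = 0.2,
                       duration_meanlog = log(1.7),
                       duration_sdlog = 0.45,
                       map_process = list(baseline = 79, dip_depth = 13,
                                          dip_tau_min = 3,
                                          reversion_rate = 0.3,
                                          noise_sd = 9.5),
                       artifact_rate = 2,
                       true_effect = list(spec = ioh_spec("time_under", 50),
                                          beta_per_unit = 0.02,
                                          beta_nonzero = 0.25),
                       confounder_betas = c(female = 0.9, age = -0.012,
                                            smoker = -0.35, volatile = 0.35,
                                            ondansetron_ppx = -0.35,
                                            dexamethasone_ppx = -0.35,
                                            risk_surgery = 0.7,
                                            duration = 0.25,
                                            comorbidity_pos = 0.1,
                                            asa2 = 0.05, asa3 = -0.15,
                                            asa4 = -0.1),
                       intercept = -2.9,
                       patient_sd = 0.5,
                       seed = 1L) {
  cfg <- list(n_patients = n_patients,
              surgeries_per_patient_rate = surgeries_per_patient_rate,
              monitoring_mix = monitoring_mix,
              duration_meanlog = duration_meanlog,
              duration_sdlog = duration_sdlog,
              map_process = map_process,
              artifact_rate = artifact_rate,
              true_effect = true_effect,
              confounder_betas = confounder_betas,
              intercept = intercept,
              patient_sd = patient_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1,
            cfg$surgeries_per_patient_rate >= 1,
            cfg$monitoring_mix >= 0, cfg$monitoring_mix <= 1,
            cfg$artifact_rate >= 0,
            cfg$patient_sd >= 0,
            cfg$map_process$noise_sd >= 0,
            cfg$map_process$reversion_rate > 0,
            inherits(cfg$true_effect$spec, "ioh_spec"))
  invisible(cfg)
}

#' Simulate one artifact-free MAP trace
#'
#' MAP fluctuations follow a discretised mean-reverting (Ornstein-
#' Uhlenbeck / AR(1)) process with exact transition over arbitrary time
#' gaps: `x[i] = rho * x[i-1] + s * sqrt(1 - rho^2) * eps`, with
#' `rho = exp(-reversion_rate * dt_min)` and stationary SD `s = noise_sd`.
#' The process mean carries an induction dip,
#' `baseline - dip_depth * exp(-t / dip_tau)`, acting over roughly the
#' first ten minutes. Invasive monitoring samples every 15 s; the
#' non-invasive cuff samples at uniformly random 3-5 min intervals. Pulse
#' pressure is log-normal (median 45 mmHg), and systolic/diastolic
#' pressures are emitted as `SBP = MAP + 2/3 PP`, `DBP = MAP - PP/3`, so
#' the recorded MAP equals `DBP + (SBP - DBP)/3` exactly.
#'
#' @param duration_min Record duration in minutes (> 0).
#' @param monitoring `"invasive"` or `"non_invasive"`.
#' @param process A `map_process` list, see [sim_config].
#' @param seed Optional integer seed; `NULL` draws from the current RNG
#'   state (used when called inside [simulate_cohort]).
#' @param case_id Case identifier for the returned series.
#' @return An artifact-free [bp_series].
#' @export
simulate_map_trace <- function(duration_min,
                               monitoring = c("invasive", "non_invasive"),
                               process = sim_config()$map_process,
                               seed = NULL, case_id = "sim") {
  if (!is.numeric(duration_min) || duration_min <= 0)
    stop("'duration_min' must be positive", call. = FALSE)
  monitoring <- match.arg(monitoring)
  if (!is.null(seed)) set.seed(seed)
  end_s <- duration_min * 60
  if (monitoring == "invasive") {
    t <- seq(0, floor(end_s / 15) * 15, by = 15)
  } else {
    t <- 0
    while (t[length(t)] < end_s) t <- c(t, t[length(t)] + stats::runif(1, 180, 300))
    t <- t[t <= end_s]
  }
  n <- length(t)
  s <- process$noise_sd
  theta <- process$reversion_rate
  x <- numeric(n)
  if (s > 0) {
    x[1] <- stats::rnorm(1, 0, s)
    if (n > 1) {
      dt_min <- diff(t) / 60
      rho <- exp(-theta * dt_min)
      innov <- stats::rnorm(n - 1, 0, s * sqrt(1 - rho^2))
      if (length(unique(dt_min)) == 1L) {
        x[2:n] <- stats::filter(innov, rho[1], method = "recursive",
                                init = x[1])
      } else {
        for (i in 2:n) x[i] <- rho[i - 1] * x[i - 1] + innov[i - 1]
      }
    }
  }
  mean_t <- process$baseline -
    process$dip_depth * exp(-(t / 60) / process$dip_tau_min)
  map <- pmax(mean_t + x, 25)
  pp <- stats::rlnorm(n, log(45), 0.15)
  samples <- data.frame(t = t,
                        sbp = map + pp * 2 / 3,
                        dbp = map - pp / 3,
                        map = map,
                        source = monitoring,
                        stringsAsFactors = FALSE)
  bp_series(case_id, samples, anesthesia_end_s = end_s)
}

#' Stationary moments of the simulated MAP process
#'
#' Closed-form mean and SD of the fluctuation process at stationarity,
#' used as the independent oracle for trace-level tests.
#'
#' @param process A `map_process` list.
#' @return list(mean, sd): stationary mean (baseline; the dip is a
#'   transient) and SD.
#' @export
map_process_stationary <- function(process) {
  list(mean = process$baseline, sd = process$noise_sd)
}

artifact_templates <- function(baseline) {
  # each template violates exactly one of rules 1-5; rule 6 is an extreme
  # in-range deviation caught only by the 3-SD screen
  list(
    function() c(sbp = 310, dbp = 80),
    function() c(sbp = 15, dbp = 8),
    function() c(sbp = 120, dbp = 4),
    function() c(sbp = 250, dbp = 230),
    function() { d <- stats::runif(1, 60, 90); c(sbp = d + 2, dbp = d) },
    function() { m <- baseline + sample(c(-1, 1), 1) * stats::runif(1, 55, 70)
                 m <- max(m, 30); c(sbp = m + 30, dbp = m - 15) })
}

#' Inject labelled artifacts into a clean series
#'
#' Adds `Poisson(rate * hours)` extra samples at uniformly random times,
#' each built to violate exactly one of artifact rules 1-5 (e.g. SBP 310,
#' SBP 15, DBP 4, DBP 230, SBP = DBP + 2) or to be an extreme deviation
#' targeting the 3-SD rule 6.
#'
#' @param series An artifact-free [bp_series].
#' @param rate Artifacts per hour.
#' @param seed Optional integer seed (`NULL`: current RNG state).
#' @return list with `series` (the contaminated [bp_series]) and `truth`
#'   (data.frame `t`, `rule` of the injected samples; zero rows when
#'   `rate = 0`, in which case the series is returned unchanged).
#' @export
inject_artifacts <- function(series, rate, seed = NULL) {
  stopifnot(inherits(series, "bp_series"), rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0)
    return(list(series = series,
                truth = data.frame(t = numeric(), rule = integer())))
  hours <- series$anesthesia_end_s / 3600
  n_art <- stats::rpois(1, rate * hours)
  if (n_art == 0)
    return(list(series = series,
                truth = data.frame(t = numeric(), rule = integer())))
  existing <- series$samples$t
  tt <- numeric(0)
  while (length(tt) < n_art) {
    cand <- stats::runif(n_art - length(tt), 0, series$anesthesia_end_s)
    cand <- cand[!cand %in% c(existing, tt)]
    tt <- c(tt, cand)
  }
  rules <- sample.int(6, n_art, replace = TRUE)
  templates <- artifact_templates(mean(derive_map(series$samples$sbp,
                                                  series$samples$dbp,
                                                  series$samples$map)))
  press <- t(vapply(rules, function(r) templates[[r]](), numeric(2)))
  art <- data.frame(t = tt, sbp = press[, 1], dbp = press[, 2],
                    map = derive_map(press[, 1], press[, 2]),
                    source = series$samples$source[1],
                    stringsAsFactors = FALSE)
  all_s <- rbind(series$samples, art)
  ord <- order(all_s$t)
  contaminated <- bp_series(series$case_id, all_s[ord, , drop = FALSE],
                            series$anesthesia_end_s)
  list(series = contaminated,
       truth = data.frame(t = tt, rule = rules)[order(tt), ])
}

#' Simulate a synthetic perioperative cohort
#'
#' Draws patients, their surgeries, per-case covariates, MAP traces and a
#' binary PONV outcome. The outcome's log-odds are
#' `intercept + confounder terms + beta_nonzero * 1[exposure > 0] +
#' beta_per_unit * exposure + patient effect`, with the exposure computed
#' from the case's own artifact-free gridded trace via the
#' characterization in `config$true_effect$spec`. Artifacts (when
#' `artifact_rate > 0`) are injected only into the stored raw series;
#' the clean grids and the outcome truth are untouched.
#'
#' Covariate marginals approximate a general surgical population:
#' 54.5% female, age ~ N(53, 17) truncated at 18, 32.5% smokers, ASA
#' 1-4 at 48/26/24/2%, 64% volatile anesthesia, 17.7% high-PONV-risk
#' surgery, 15.3% PONV history, 56% postoperative opioids.
#'
#' @param config A [sim_config].
#' @return An object of class `synthetic_cohort`: list with `cases`
#'   (data.frame of covariates and outcome), `series` (named list of raw
#'   [bp_series], artifacts included), `clean_grids` (named list of
#'   artifact-free [map_grid]), `truth` (data.frame `case_id`,
#'   `true_exposure`, `true_prob`, `artifact_count`) and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  np <- config$n_patients
  n_surg <- 1L + stats::rpois(np, config$surgeries_per_patient_rate - 1)
  # patient-level covariates
  female <- stats::rbinom(np, 1, 0.545)
  age <- stats::rnorm(np, 53, 17)
  while (any(bad <- age < 18 | age > 95))
    age[bad] <- stats::rnorm(sum(bad), 53, 17)
  smoker <- stats::rbinom(np, 1, 0.325)
  history_ponv <- stats::rbinom(np, 1, 0.153)
  b_pat <- stats::rnorm(np, 0, config$patient_sd)

  pat <- rep(seq_len(np), n_surg)
  nc <- length(pat)
  cases <- data.frame(
    case_id = sprintf("c%05d", seq_len(nc)),
    patient_id = sprintf("p%05d", pat),
    female = female[pat],
    age = age[pat],
    smoker = smoker[pat],
    history_ponv = history_ponv[pat],
    asa = sample(1:4, nc, replace = TRUE,
                 prob = c(0.48, 0.26, 0.24, 0.02)),
    comorbidity_pos = stats::rbinom(nc, 1, 0.40),
    volatile = stats::rbinom(nc, 1, 0.64),
    ondansetron_ppx = stats::rbinom(nc, 1, 0.30),
    dexamethasone_ppx = stats::rbinom(nc, 1, 0.30),
    risk_surgery = stats::rbinom(nc, 1, 0.177),
    postop_opioids = stats::rbinom(nc, 1, 0.559),
    duration_h = stats::rlnorm(nc, config$duration_meanlog,
                               config$duration_sdlog),
    stringsAsFactors = FALSE)
  cases$monitoring <- ifelse(stats::runif(nc) < config$monitoring_mix,
                             "invasive", "non_invasive")

  series <- vector("list", nc); names(series) <- cases$case_id
  grids <- vector("list", nc); names(grids) <- cases$case_id
  expo <- numeric(nc); art_n <- integer(nc)
  for (i in seq_len(nc)) {
    tr <- simulate_map_trace(cases$duration_h[i] * 60, cases$monitoring[i],
                             config$map_process, seed = NULL,
                             case_id = cases$case_id[i])
    g <- interpolate_to_grid(tr)
    grids[[i]] <- g
    expo[i] <- compute_exposure(g, config$true_effect$spec)
    inj <- inject_artifacts(tr, config$artifact_rate, seed = NULL)
    series[[i]] <- inj$series
    art_n[i] <- nrow(inj$truth)
  }
  cb <- config$confounder_betas
  lp <- config$intercept +
    cb["female"] * cases$female +
    cb["age"] * (cases$age - 53) +
    cb["smoker"] * cases$smoker +
    cb["volatile"] * cases$volatile +
    cb["ondansetron_ppx"] * cases$ondansetron_ppx +
    cb["dexamethasone_ppx"] * cases$dexamethasone_ppx +
    cb["risk_surgery"] * cases$risk_surgery +
    cb["duration"] * (cases$duration_h - 1.7) +
    cb["comorbidity_pos"] * cases$comorbidity_pos +
    cb["asa2"] * (cases$asa == 2) +
    cb["asa3"] * (cases$asa == 3) +
    cb["asa4"] * (cases$asa == 4) +
    config$true_effect$beta_nonzero * (expo > 0) +
    config$true_effect$beta_per_unit * expo +
    b_pat[pat]
  lp <- as.numeric(lp)
  prob <- stats::plogis(lp)
  cases$ponv <- stats::rbinom(nc, 1, prob)
  truth <- data.frame(case_id = cases$case_id,
                      true_exposure = expo,
                      true_prob = prob,
                      artifact_count = art_n,
                      stringsAsFactors = FALSE)
  structure(list(cases = cases, series = series, clean_grids = grids,
                 truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d cases on %d patients; PONV rate %.3f\n",
              nrow(x$cases), length(unique(x$cases$patient_id)),
              mean(x$cases$ponv)))
  invisible(x)
}
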