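# Brute-force oracles, kept independent of the package implementations.

# min over every window start of the window max (O(n*m) scan)
oracle_sustained <- function(values, step_s, k) {
  m <- round(k * 60 / step_s) + 1
  n <- length(values)
  if (m > n) return(NA_real_)
  min(vapply(seq_len(n - m + 1),
             function(i) max(values[i:(i + m - 1)]), 0))
}

# smallest observed value v with time(MAP <= v) >= k minutes,
# by scanning every candidate threshold
oracle_cumulative <- function(values, step_s, k) {
  if (ceiling(k * 60 / step_s) > length(values)) return(NA_real_)
  cand <- sort(unique(values))
  for (v in cand) {
    if (sum(values <= v) * step_s >= k * 60) return(v)
  }
  NA_real_
}

# O(n^2) pair enumeration concordance, ties counted one half
oracle_cstat <- function(p, y) {
  ev <- p[y == 1]; ne <- p[y == 0]
  tot <- 0
  for (a in ev) for (b in ne)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ev) * length(ne))
}

random_grid <- function(n, lo = 40, hi = 110, id = "g") {
  map_grid(id, runif(n, lo, hi))
}

# covariate frame with a directly supplied exposure column, bypassing
# trace simulation; used for model-level tests
make_cases <- function(n_patients, cases_per_patient = 1,
                       exposure = NULL, beta_exposure = 0.3,
                       beta_nonzero = 0, intercept = -1.5,
                       patient_sd = 0) {
  pat <- rep(seq_len(n_patients), each = cases_per_patient)
  n <- length(pat)
  if (is.null(exposure)) exposure <- rexp(n, 0.5)
  b <- rnorm(n_patients, 0, patient_sd)
  d <- data.frame(
    case_id = sprintf("c%05d", seq_len(n)),
    patient_id = sprintf("p%05d", pat),
    female = rbinom(n_patients, 1, 0.5)[pat],
    age = pmax(18, rnorm(n_patients, 53, 15))[pat],
    smoker = rbinom(n, 1, 0.3),
    asa = sample(1:4, n, replace = TRUE, prob = c(.4, .3, .25, .05)),
    comorbidity_pos = rbinom(n, 1, 0.4),
    volatile = rbinom(n, 1, 0.6),
    ondansetron_ppx = rbinom(n, 1, 0.3),
    dexamethasone_ppx = rbinom(n, 1, 0.3),
    risk_surgery = rbinom(n, 1, 0.2),
    duration_h = rlnorm(n, log(1.7), 0.4),
    stringsAsFactors = FALSE)
  lp <- intercept + 0.6 * d$female - 0.01 * (d$age - 53) +
    beta_exposure * exposure + beta_nonzero * (exposure > 0) + b[pat]
  d$ponv <- rbinom(n, 1, plogis(lp))
  d$exposure <- exposure
  d
}

# feature table from an explicit exposure column under a given spec label
features_from <- function(cases, label) {
  out <- data.frame(case_id = cases$case_id, stringsAsFactors = FALSE)
  out[[label]] <- cases$exposure
  out
}
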