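test_that("winsorization caps only the extreme tail", {
  w <- winsorize_99(0:99)
  expect_equal(w$cap, quantile(0:99, 0.99, names = FALSE))
  expect_equal(sum(w$x != 0:99), 1L)           # only the top value capped
  expect_equal(max(w$x), w$cap)

  same <- winsorize_99(rep(7, 50))
  expect_equal(same$x, rep(7, 50))

  set.seed(2)
  x <- rlnorm(500)
  w2 <- winsorize_99(x)
  expect_equal(max(w2$x), quantile(x, 0.99, names = FALSE, type = 7))
  expect_true(all(w2$x[x <= w2$cap] == x[x <= w2$cap]))
  # stored cap reused on held-out data
  held <- winsorize_99(c(0.1, 50), cap = w2$cap)
  expect_equal(held$x, c(0.1, min(50, w2$cap)))
  expect_error(winsorize_99(c(NA, NA, 1)), "2 finite")
})

test_that("natural spline basis is linear beyond its boundary knots", {
  set.seed(3)
  x <- runif(200, 0, 10)
  b <- natural_spline_basis(x)
  far <- seq(11, 20, by = 0.5)                 # beyond the upper boundary
  co <- eval_spline_basis(b, far)
  for (j in 1:3) expect_equal(max(abs(diff(diff(co[, j])))), 0,
                              tolerance = 1e-10)
  # stored knots reproduce training coordinates on new evaluations
  tr <- eval_spline_basis(b, x[1:20])
  again <- eval_spline_basis(structure(list(knots = b$knots,
                                            boundary = b$boundary,
                                            degenerate = FALSE),
                                       class = "ns_basis"), x[1:20])
  expect_identical(tr, again)
})

test_that("the spline span reproduces functions built from it exactly", {
  set.seed(4)
  x <- seq(0, 10, length.out = 120)
  b <- natural_spline_basis(x)
  B <- eval_spline_basis(b, x)
  y <- 2 + B %*% c(1.5, -2, 0.7) + 0.3 * x     # in span + linear part
  fit <- lm(y ~ B + x)
  expect_lt(max(abs(resid(fit))), 1e-9)
})

test_that("degenerate inputs degrade the basis to a linear term", {
  expect_warning(b <- natural_spline_basis(rep(c(0, 1), 10)), "linear")
  expect_true(b$degenerate)
  expect_equal(ncol(eval_spline_basis(b, c(0, 1, 2))), 1L)
})

test_that("design matrix follows the documented column layout", {
  set.seed(5)
  d <- make_cases(120, exposure = ifelse(runif(120) < 0.5, 0,
                                         rexp(120, 0.3)))
  spec_tu <- ioh_spec("time_under", 50)
  spec_lo <- ioh_spec("sustained_lowest", 5)
  X_tu <- build_design(d, d$exposure, spec_tu)
  X_lo <- build_design(d, runif(120, 50, 80), spec_lo)
  expect_equal(ncol(X_tu), ncol(X_lo) + 1L)    # the zero indicator
  expect_true("exp_zero" %in% colnames(X_tu))
  expect_false("exp_zero" %in% colnames(X_lo))
  expect_equal(colnames(X_tu)[1], "(Intercept)")
  expect_equal(qr(X_tu)$rank, ncol(X_tu))

  # males carry no age-by-sex interaction
  agefem <- X_tu[, grep("^agefem", colnames(X_tu))]
  expect_true(all(agefem[d$female == 0, ] == 0))
  expect_equal(agefem[d$female == 1, ],
               X_tu[d$female == 1, grep("^age_ns", colnames(X_tu))],
               ignore_attr = TRUE)

  # a zero exposure sets the indicator and evaluates the spline at zero
  d0 <- d; d0$exposure[1] <- 0
  X0 <- build_design(d0, d0$exposure, spec_tu)
  expect_equal(unname(X0[1, "exp_zero"]), 1)
  expect_equal(unname(X0[1, grep("^exp_ns", colnames(X0))]),
               unname(drop(eval_spline_basis(attr(X0, "bases")$exposure, 0))))
})

test_that("GEE with singleton clusters equals ordinary logistic regression", {
  set.seed(6)
  d <- make_cases(400)
  X <- build_design(d, d$exposure, ioh_spec("time_under", 50))
  fit <- fit_gee_logistic(X, d$ponv, d$patient_id)
  ref <- glm.fit(X, d$ponv, family = binomial())
  expect_true(fit$converged)
  expect_equal(fit$alpha, 0)
  expect_equal(unname(fit$coefficients), unname(ref$coefficients),
               tolerance = 1e-6)
})

test_that("intercept-only GEE returns the logit of the event rate", {
  set.seed(7)
  y <- rbinom(300, 1, 0.3)
  X <- matrix(1, 300, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- fit_gee_logistic(X, y, rep(1:150, each = 2))
  expect_equal(unname(fit$coefficients), qlogis(mean(y)), tolerance = 1e-6)
})

test_that("predictions are the inverse-logit of the linear predictor", {
  set.seed(8)
  d <- make_cases(150)
  X <- build_design(d, d$exposure, ioh_spec("time_under", 50))
  fit <- fit_gee_logistic(X, d$ponv, d$patient_id)
  p <- predict_prob(fit, X)
  expect_equal(p, plogis(drop(X %*% fit$coefficients)))
  expect_true(all(p > 0 & p < 1))

  # zero coefficients: everything at one half
  fit0 <- fit
  fit0$coefficients[] <- 0
  expect_equal(unique(predict_prob(fit0, X)), 0.5)

  # huge linear predictor saturates without overflow
  fitL <- fit
  fitL$coefficients[] <- 0
  fitL$coefficients["(Intercept)"] <- 500
  expect_equal(unique(predict_prob(fitL, X)), 1)

  expect_error(predict_prob(fit, X[, -2]), "do not match")
})

test_that("predictions are invariant to affine covariate recoding", {
  set.seed(9)
  d <- make_cases(200)
  X <- build_design(d, d$exposure, ioh_spec("sustained_lowest", 5))
  Xr <- X
  Xr[, "age_ns1"] <- 10 + 2 * X[, "age_ns1"]   # affine recode one column
  f1 <- fit_gee_logistic(X, d$ponv, d$patient_id)
  f2 <- fit_gee_logistic(Xr, d$ponv, d$patient_id)
  expect_equal(predict_prob(f1, X), predict_prob(f2, Xr), tolerance = 1e-5)
})

test_that("robust SEs exceed naive independence SEs under positive
           clustering", {
  set.seed(10)
  d <- make_cases(250, cases_per_patient = 4, patient_sd = 1.2)
  X <- build_design(d, d$exposure, ioh_spec("time_under", 50))
  fit <- fit_gee_logistic(X, d$ponv, d$patient_id)
  expect_gt(fit$alpha, 0)
  # naive model-based covariance under a working-independence fit: the
  # classic quantity the sandwich corrects upward when clusters are
  # positively correlated (typical-case property)
  mu <- plogis(drop(X %*% fit$coefficients))
  w <- mu * (1 - mu)
  naive <- solve(crossprod(X, w * X))
  # the inflation concentrates in cluster-constant covariates (age is
  # drawn per patient); case-varying columns are not inflated
  j <- grep("^age_ns|^female$", colnames(X))
  expect_gt(mean(sqrt(diag(fit$vcov))[j] / sqrt(diag(naive))[j]), 1)
})

test_that("the GEE recovers a known clustered exposure effect", {
  reps <- vapply(1:5, function(s) {
    set.seed(s)
    d <- make_cases(800, cases_per_patient = 2, beta_exposure = 0.3,
                    patient_sd = 0.5)
    w <- winsorize_99(d$exposure)
    X <- build_design(d, w$x, ioh_spec("time_under", 50))
    fit <- fit_gee_logistic(X, d$ponv, d$patient_id)
    expect_true(fit$converged)
    m <- structure(list(fit = fit, spec = ioh_spec("time_under", 50),
                        cap = w$cap, bases = attr(X, "bases"),
                        omit = NULL, n_dropped = 0L),
                   class = "ioh_model")
    orc <- estimate_adjusted_or(m, 2)
    c(orc$log_or, orc$se)
  }, numeric(2))
  atten <- 1 / sqrt(1 + 0.346 * 0.5^2)         # logistic-normal attenuation
  truth <- atten * (0.3 * 2)
  # mean of 5 replicates within 3 SE of the replicate mean
  expect_lt(abs(mean(reps[1, ]) - truth), 3 * mean(reps[2, ]) / sqrt(5))
})

test_that("degenerate fitting inputs are rejected", {
  X <- matrix(1, 10, 1)
  expect_error(fit_gee_logistic(X, rep(1, 10), 1:10), "constant")
  expect_error(fit_gee_logistic(X, rbinom(10, 1, 0.5), rep(1, 10)),
               "2 clusters")
})
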