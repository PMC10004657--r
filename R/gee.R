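#' GEE logistic regression with exchangeable working correlation
#'
#' Fits the marginal logistic model by generalized estimating equations
#' with patient as the clustering variable and an exchangeable working
#' correlation, returning robust (sandwich) standard errors. The
#' exchangeable structure admits a closed-form cluster-inverse,
#' `R^{-1} = I/(1-a) - a J / ((1-a)(1+(n_i-1)a))`, so scoring and the
#' sandwich are computed by cluster sums without per-cluster matrix
#' inversion. The correlation parameter is updated each iteration by the
#' usual moment estimator on Pearson residuals. When every cluster has
#' size one the fit coincides with ordinary logistic regression.
#'
#' @param X Numeric design matrix (include the intercept column).
#' @param y Binary outcome vector (0/1).
#' @param id Cluster (patient) identifiers, one per row.
#' @param tol Convergence tolerance on the relative coefficient change.
#' @param maxit Maximum scoring iterations.
#' @return An object of class `gee_fit`: `coefficients`, `vcov` (robust),
#'   `vcov_model` (model-based), `alpha` (working correlation),
#'   `n_cases`, `n_clusters`, `converged`, `iterations`.
#' @export
fit_gee_logistic <- function(X, y, id, tol = 1e-6, maxit = 60L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, length(id) == n)
  if (length(unique(id)) < 2L)
    stop("need at least 2 clusters", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("outcome is constant", call. = FALSE)
  fid <- factor(id)
  ni <- as.numeric(table(fid))          # cluster sizes, factor-level order
  pairs <- sum(ni * (ni - 1))

  init <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial()))
  beta <- init$coefficients
  beta[!is.finite(beta)] <- 0
  alpha <- 0
  converged <- FALSE
  it <- 0L
  score_parts <- function(beta, alpha_fixed = NULL) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- (y - mu) / sqrt(w)             # Pearson residuals
    a <- alpha_fixed
    if (is.null(a)) {
      a <- 0
      if (pairs > 0) {
        phi <- sum(z^2) / max(n - p, 1)
        S1 <- drop(rowsum(z, fid))
        S2 <- drop(rowsum(z^2, fid))
        a <- sum(S1^2 - S2) / (phi * max(pairs - p, 1))
        amin <- -1 / max(max(ni) - 1, 1) + 1e-6
        a <- min(max(a, amin), 0.99)
      }
    }
    c1 <- 1 / (1 - a)
    c2 <- a / ((1 - a) * (1 + (ni - 1) * a))  # per cluster
    sw <- sqrt(w)
    U <- rowsum(sw * X, fid)            # n_clust x p
    B <- c1 * crossprod(X, w * X) - crossprod(U, c2 * U)
    S1 <- drop(rowsum(z, fid))
    g <- c1 * crossprod(X, y - mu) - crossprod(U, c2 * S1)
    list(B = B, g = g, alpha = a, gnorm = sqrt(sum(g^2)))
  }
  for (it in seq_len(maxit)) {
    sp <- score_parts(beta)
    alpha <- sp$alpha
    delta <- tryCatch(drop(solve(sp$B, sp$g)), error = function(e) NULL)
    if (is.null(delta)) break
    # step-halving on the estimating-equation norm guards against the
    # divergence Fisher scoring shows under (quasi-)separation
    step <- 1
    for (h in 1:12) {
      cand <- beta + step * delta
      gn <- score_parts(cand, alpha_fixed = alpha)$gnorm
      if (is.finite(gn) && gn <= sp$gnorm) break
      step <- step / 2
    }
    beta <- beta + step * delta
    if (max(abs(beta)) > 1e3) break      # diverged: flag, not report
    if (step * max(abs(delta)) / max(1, max(abs(beta))) < tol) {
      converged <- TRUE
      break
    }
  }
  # sandwich at the solution
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  z <- (y - mu) / sqrt(w)
  c1 <- 1 / (1 - alpha)
  c2 <- alpha / ((1 - alpha) * (1 + (ni - 1) * alpha))
  sw <- sqrt(w)
  U <- rowsum(sw * X, fid)
  S1 <- drop(rowsum(z, fid))
  B <- c1 * crossprod(X, w * X) - crossprod(U, c2 * U)
  G <- c1 * rowsum((y - mu) * X, fid) - (c2 * S1) * U   # per-cluster scores
  Binv <- tryCatch(solve(B), error = function(e) NULL)
  if (is.null(Binv)) {
    vc <- vcm <- matrix(NA_real_, p, p)
    converged <- FALSE
  } else {
    vc <- Binv %*% crossprod(G) %*% Binv
    vc <- (vc + t(vc)) / 2
    phi <- sum(z^2) / max(n - p, 1)
    vcm <- phi * Binv
  }
  dimnames(vc) <- dimnames(vcm) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  structure(list(coefficients = beta, vcov = vc, vcov_model = vcm,
                 alpha = alpha, n_cases = n,
                 n_clusters = nlevels(fid),
                 converged = converged, iterations = it,
                 column_names = colnames(X)),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf(
    "GEE logistic fit: %d cases in %d clusters; exchangeable alpha = %.4f%s\n",
    x$n_cases, x$n_clusters, x$alpha,
    if (x$converged) "" else " (NOT converged)"))
  se <- sqrt(diag(x$vcov))
  print(data.frame(estimate = x$coefficients, robust_se = se,
                   row.names = x$column_names))
  invisible(x)
}

#' @export
coef.gee_fit <- function(object, ...) object$coefficients

#' @export
vcov.gee_fit <- function(object, ...) object$vcov

#' Predicted event probabilities from a GEE fit
#'
#' Inverse-logit of the linear predictor; columns of `X` must match the
#' fit's design columns by name and order.
#'
#' @param fit A `gee_fit`.
#' @param X Design matrix built with the stored bases of the fit.
#' @return Vector of probabilities in (0, 1).
#' @export
predict_prob <- function(fit, X) {
  stopifnot(inherits(fit, "gee_fit"))
  X <- as.matrix(X)
  if (!identical(colnames(X), fit$column_names))
    stop("design columns do not match the fitted model", call. = FALSE)
  stats::plogis(drop(X %*% fit$coefficients))
}

#' Fit one characterization's multivariable model
#'
#' Higher-level wrapper holding the full modelling protocol for a single
#' characterization: winsorize the exposure at the 99th percentile, build
#' the spline design, fit the exchangeable GEE. The returned object
#' carries the winsorization cap and spline knots so the identical design
#' can be rebuilt on held-out data.
#'
#' @param cases Case data.frame (see [simulate_cohort]).
#' @param exposure Raw exposure column aligned to `cases` (`NA` rows are
#'   dropped with accounting).
#' @param spec The [ioh_spec].
#' @param omit Optional variable group to exclude (see [build_design]).
#' @return Object of class `ioh_model`: `fit` (`gee_fit`), `spec`, `cap`,
#'   `bases`, `n_dropped`.
#' @export
fit_characterization_model <- function(cases, exposure, spec, omit = NULL) {
  keep <- !is.na(exposure)
  cases <- cases[keep, , drop = FALSE]
  exposure <- exposure[keep]
  wz <- winsorize_99(exposure)
  X <- build_design(cases, wz$x, spec, omit = omit)
  fit <- fit_gee_logistic(X, cases$ponv, cases$patient_id)
  structure(list(fit = fit, spec = spec, cap = wz$cap,
                 bases = attr(X, "bases"), omit = omit,
                 n_dropped = sum(!keep)),
            class = "ioh_model")
}

#' @export
print.ioh_model <- function(x, ...) {
  cat("Multivariable PONV model, characterization:", x$spec$label, "\n")
  print(x$fit)
  invisible(x)
}
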