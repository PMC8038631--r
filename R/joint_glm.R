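# The alternating two-dimensional fitting algorithm: a Gaussian mean GLM and
# a gamma log-link dispersion GLM interlinked through the prior weights
# (mean model weighted by 1/phi) and the deviance components (response of
# the dispersion model).

#' Minus twice the Gaussian h-log-likelihood
#'
#' `sum((y - mu)^2 / phi + log(2 * pi * phi))`, i.e. -2 times the Gaussian
#' log-likelihood with observation-specific variances.
#'
#' @param y response vector.
#' @param mu fitted means.
#' @param phi strictly positive dispersions.
#' @return a scalar.
#' @export
minus2h <- function(y, mu, phi) {
  if (length(y) != length(mu) || length(y) != length(phi)) {
    stop("minus2h: y, mu and phi must have equal lengths", call. = FALSE)
  }
  if (any(!is.finite(phi)) || any(phi <= 0)) {
    stop("minus2h: phi must be strictly positive and finite", call. = FALSE)
  }
  sum((y - mu)^2 / phi + log(2 * pi * phi))
}

# log det(X' W X / (2 pi)) with W = diag(1/phi); errors if singular
adjustment_logdet <- function(X, phi) {
  X <- as.matrix(X)
  A <- crossprod(X / sqrt(phi)) / (2 * pi)
  dt <- determinant(A, logarithm = TRUE)
  if (dt$sign <= 0 || !is.finite(dt$modulus)) {
    stop("minus2pbeta: singular adjustment matrix X' W X", call. = FALSE)
  }
  as.numeric(dt$modulus)
}

#' Minus twice the adjusted profile likelihood
#'
#' The profile adjustment for the mean coefficients:
#' `minus2h + log det(X' W X / (2 pi))` with `W = diag(1 / phi)`. This is
#' the REML-type likelihood reported alongside -2h in the coefficient
#' tables.
#'
#' @param fit a [fit_joint()] result, or a list with elements `X` (mean
#'   design matrix), `phi` (dispersions) and `minus2h`.
#' @return a scalar.
#' @export
minus2pbeta <- function(fit) {
  if (inherits(fit, "joint_glm")) {
    X <- fit$mean_fit$X
    phi <- fit$disp_fit$phi
    m2h <- fit$criteria$minus2h
  } else {
    X <- fit$X; phi <- fit$phi; m2h <- fit$minus2h
  }
  m2h + adjustment_logdet(X, phi)
}

#' Likelihood-based model-selection criteria
#'
#' Packages the criteria used for comparing the constant-dispersion model
#' with the joint mean-dispersion model: `caic = minus2h + 2 * p_mean`
#' (only the mean-model coefficients are penalized),
#' `aic = minus2h + 2 * (p_mean + q_disp)` and
#' `bic = minus2h + (p_mean + q_disp) * log(n)`.
#'
#' @param minus2h -2 times the h-log-likelihood.
#' @param p_mean number of mean-model coefficients.
#' @param q_disp number of dispersion-model coefficients (`NA` to skip
#'   AIC/BIC).
#' @param n sample size (`NA` to skip BIC).
#' @param minus2pbeta -2 times the adjusted profile likelihood (optional).
#' @return an object of class `fit_criteria`.
#' @examples
#' fit_criteria(464.2776, p_mean = 10)$caic  # 484.2776
#' @export
fit_criteria <- function(minus2h, p_mean, q_disp = NA_integer_,
                         n = NA_integer_, minus2pbeta = NA_real_) {
  stopifnot(is.numeric(minus2h), length(minus2h) == 1,
            is.numeric(p_mean), length(p_mean) == 1, p_mean >= 0)
  k <- p_mean + q_disp
  structure(list(
    minus2h = minus2h,
    minus2pbeta = minus2pbeta,
    caic = minus2h + 2 * p_mean,
    aic = if (is.na(k)) NA_real_ else minus2h + 2 * k,
    bic = if (is.na(k) || is.na(n)) NA_real_ else minus2h + k * log(n),
    p_mean = p_mean, q_disp = q_disp, n = n),
    class = "fit_criteria")
}

#' @export
print.fit_criteria <- function(x, ...) {
  cat(sprintf("-2h          %.4f\n", x$minus2h))
  if (!is.na(x$minus2pbeta)) cat(sprintf("-2 p_beta(h) %.4f\n", x$minus2pbeta))
  cat(sprintf("cAIC         %.4f\n", x$caic))
  if (!is.na(x$aic)) cat(sprintf("AIC          %.4f\n", x$aic))
  if (!is.na(x$bic)) cat(sprintf("BIC          %.4f\n", x$bic))
  invisible(x)
}

#' Criteria of a fitted joint model
#'
#' Recomputes the [fit_criteria()] of a converged [fit_joint()] result.
#' With `caic_df = "leverage"` the cAIC penalty uses the summed mean-model
#' leverages instead of the coefficient count; for a fixed-effects weighted
#' least-squares mean model the leverages sum to the coefficient count, so
#' the two agree and the count is the default.
#'
#' @param fit a [fit_joint()] result.
#' @param caic_df `"count"` (default) or `"leverage"`.
#' @return a `fit_criteria` object.
#' @export
compute_criteria <- function(fit, caic_df = c("count", "leverage")) {
  caic_df <- match.arg(caic_df)
  stopifnot(inherits(fit, "joint_glm"))
  p <- length(fit$mean_fit$beta)
  q <- length(fit$disp_fit$gamma_coef)
  n <- length(fit$y)
  m2h <- minus2h(fit$y, fit$mean_fit$mu, fit$disp_fit$phi)
  out <- fit_criteria(m2h, p_mean = p, q_disp = q, n = n,
                      minus2pbeta = m2h + adjustment_logdet(fit$mean_fit$X,
                                                            fit$disp_fit$phi))
  if (caic_df == "leverage") {
    out$caic <- m2h + 2 * sum(fit$mean_fit$leverage)
  }
  out
}

#' Joint mean-dispersion fit on design matrices
#'
#' The alternating algorithm on explicit matrices (see [fit_joint()] for the
#' cohort-table interface):
#' \enumerate{
#'   \item initialize `phi` at the homoscedastic OLS residual variance
#'     `sum((y - yhat)^2) / (n - p)`;
#'   \item fit the Gaussian mean model with prior weights `1 / phi`;
#'   \item form deviance components `d = (y - mu)^2`; under REML use
#'     response `d / (1 - q)` with index weights `(1 - q) / 2` (q = mean
#'     model leverage), under ML use `d` with weights `1/2`;
#'   \item fit the gamma log-link dispersion model and set `phi` to its
#'     fitted values; repeat from 2 until both `|delta minus2h| < tol` and
#'     `max(abs(delta beta)) < tol`, cap `max_iter` iterations.
#' }
#' Non-convergence is reported with a warning (the partial result is
#' returned with `converged = FALSE`).
#'
#' @param y response vector.
#' @param X mean-model design matrix (n x p, full rank).
#' @param G dispersion-model design matrix (n x q, full rank).
#' @param method `"REML"` (default) or `"ML"` dispersion response weighting.
#' @param tol convergence tolerance (default 1e-8).
#' @param max_iter outer iteration cap (default 100).
#' @return an object of class `joint_glm`: list with `mean_fit`
#'   ([fit_gaussian()] result at the final weights), `disp_fit`
#'   ([fit_gamma_log()] result), `criteria` ([fit_criteria()]), `n_iter`,
#'   `converged`, `trace` (per-iteration minus2h), `method`, `y`.
#' @export
fit_joint_matrices <- function(y, X, G, method = c("REML", "ML"),
                               tol = 1e-8, max_iter = 100L) {
  method <- match.arg(method)
  X <- as.matrix(X); G <- as.matrix(G)
  n <- length(y)
  p <- ncol(X); q <- ncol(G)
  if (n <= p + q) {
    stop("fit_joint_matrices: need n > p_mean + q_disp", call. = FALSE)
  }
  ols <- fit_gaussian(X, y)
  phi <- rep(sum(ols$d) / (n - p), n)

  mfit <- NULL; dfit <- NULL
  trace <- numeric(0)
  last_m2h <- Inf
  last_beta <- NULL
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    mfit <- fit_gaussian(X, y, w = 1 / phi)
    lev <- mfit$leverage
    if (method == "REML") {
      dresp <- mfit$d / (1 - lev)
      wdisp <- (1 - lev) / 2
    } else {
      dresp <- mfit$d
      wdisp <- rep(0.5, n)
    }
    dfit <- fit_gamma_log(dresp, G, w = wdisp)
    phi <- dfit$phi
    m2h <- minus2h(y, mfit$mu, phi)
    trace <- c(trace, m2h)
    db <- if (is.null(last_beta)) Inf else max(abs(mfit$beta - last_beta))
    if (abs(m2h - last_m2h) < tol && db < tol) { converged <- TRUE; break }
    last_m2h <- m2h
    last_beta <- mfit$beta
  }
  # final mean refit so mean_fit$prior_weight == 1/phi at exit
  mfit <- fit_gaussian(X, y, w = 1 / phi)
  m2h <- minus2h(y, mfit$mu, phi)
  if (!converged) {
    warning(sprintf(
      "fit_joint_matrices: not converged after %d iterations (|delta -2h| = %.3e)",
      max_iter, abs(m2h - last_m2h)), call. = FALSE)
  }
  crit <- fit_criteria(m2h, p_mean = p, q_disp = q, n = n,
                       minus2pbeta = m2h + adjustment_logdet(X, phi))
  structure(list(mean_fit = mfit, disp_fit = dfit, criteria = crit,
                 n_iter = iter, converged = converged, trace = trace,
                 method = method, y = y),
            class = "joint_glm")
}

#' Fit the joint mean-dispersion model to a cohort
#'
#' Builds the mean and dispersion design matrices from term lists and runs
#' the alternating algorithm of [fit_joint_matrices()]. An intercept-only
#' dispersion term list (`character(0)`) reproduces the constant-dispersion
#' Gaussian GLM: the mean coefficients then equal ordinary least squares.
#'
#' @param table a [cohort_table()].
#' @param mean_terms term labels for the mean model (default
#'   [default_terms()]).
#' @param disp_terms term labels for the dispersion model; `character(0)`
#'   for a constant dispersion.
#' @param method `"REML"` (default) or `"ML"`.
#' @param tol,max_iter passed to [fit_joint_matrices()].
#' @return a `joint_glm` object (see [fit_joint_matrices()]).
#' @export
fit_joint <- function(table, mean_terms = default_terms(),
                      disp_terms = default_terms(),
                      method = c("REML", "ML"), tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(table, "cohort_table"))
  X <- build_design(table, mean_terms)
  G <- build_design(table, disp_terms)
  fit <- fit_joint_matrices(table$muac, X, G, method = method,
                            tol = tol, max_iter = max_iter)
  fit$mean_terms <- mean_terms
  fit$disp_terms <- disp_terms
  fit
}

#' @export
print.joint_glm <- function(x, ...) {
  cat(sprintf("Joint mean-dispersion GLM (%s), %s in %d iteration(s)\n",
              x$method, if (x$converged) "converged" else "NOT converged",
              x$n_iter))
  cat("\nMean model (Gaussian, identity link):\n")
  print(wald_table(x$mean_fit$beta, x$mean_fit$se))
  cat("\nDispersion model (gamma, log link):\n")
  print(wald_table(x$disp_fit$gamma_coef, x$disp_fit$se))
  cat("\n")
  print(x$criteria)
  invisible(x)
}

#' @export
summary.joint_glm <- function(object, ...) {
  list(mean = wald_table(object$mean_fit$beta, object$mean_fit$se),
       dispersion = wald_table(object$disp_fit$gamma_coef,
                               object$disp_fit$se),
       criteria = object$criteria,
       converged = object$converged, n_iter = object$n_iter,
       method = object$method)
}
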