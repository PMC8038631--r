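# Numeric data behind the model-checking plots: standardized residuals vs
# fitted with a running mean, absolute residuals, a normal QQ plot and a
# residual histogram. Plotting is a thin layer over the numeric bundle.

#' Standardized residuals
#'
#' `r_i = (y_i - mu_i) / sqrt(phi_i * (1 - q_i))`: raw residuals scaled by
#' the fitted dispersion and the mean-model leverage (the Gaussian
#' studentization). Under the true model these have approximately unit
#' variance.
#'
#' @param y response vector.
#' @param mu fitted means.
#' @param phi strictly positive dispersions.
#' @param leverage mean-model leverages in `[0, 1)`; default 0 (no leverage
#'   adjustment).
#' @return numeric vector of standardized residuals.
#' @export
standardized_residuals <- function(y, mu, phi, leverage = rep(0, length(y))) {
  nlen <- length(y)
  if (length(mu) != nlen || length(phi) != nlen || length(leverage) != nlen) {
    stop("standardized_residuals: inputs must have equal lengths",
         call. = FALSE)
  }
  if (any(!is.finite(phi)) || any(phi <= 0)) {
    stop("standardized_residuals: phi must be strictly positive",
         call. = FALSE)
  }
  if (any(leverage < 0) || any(leverage >= 1)) {
    stop("standardized_residuals: leverage must lie in [0, 1)",
         call. = FALSE)
  }
  (y - mu) / sqrt(phi * (1 - leverage))
}

#' Running mean of y ordered by x
#'
#' Sorts by `x` and returns the centered moving average with an odd window,
#' shrinking the window symmetrically-as-possible at the edges (indices are
#' truncated to the data range).
#'
#' @param x ordering values.
#' @param y values to average, same length.
#' @param window odd positive window width, at most `length(x)`.
#' @return data.frame with columns `center` (sorted x) and `mean`.
#' @export
running_mean <- function(x, y, window) {
  if (length(x) != length(y)) {
    stop("running_mean: x and y have different lengths", call. = FALSE)
  }
  if (window %% 2 == 0 || window < 1) {
    stop("running_mean: window must be an odd positive count", call. = FALSE)
  }
  n <- length(x)
  if (window > n) stop("running_mean: window larger than data", call. = FALSE)
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  h <- (window - 1) / 2
  m <- vapply(seq_len(n), function(i) {
    mean(ys[max(1, i - h):min(n, i + h)])
  }, numeric(1))
  data.frame(center = xs, mean = m)
}

#' Normal QQ points
#'
#' Sorted residuals against standard-normal quantiles at plotting positions
#' `(i - 0.5) / n`.
#'
#' @param r residual vector, length >= 2.
#' @return data.frame with columns `theoretical` and `sample` (both sorted
#'   nondecreasing).
#' @export
qq_points <- function(r) {
  n <- length(r)
  if (n < 2) stop("qq_points: need at least 2 residuals", call. = FALSE)
  data.frame(theoretical = stats::qnorm((seq_len(n) - 0.5) / n),
             sample = sort(r))
}

#' Histogram bin edges and counts
#'
#' Equal-width bins spanning `[min(r), max(r)]`, right-open except the last
#' (closed) bin, counts summing to `length(r)`. A zero-range input is
#' handled by a unit-width span centered on the common value, leaving a
#' single occupied bin.
#'
#' @param r residual vector.
#' @param bins number of bins (>= 1).
#' @return list with `edges` (length `bins + 1`) and `counts` (length
#'   `bins`).
#' @export
histogram_data <- function(r, bins) {
  if (!is.numeric(bins) || bins < 1 || bins != round(bins)) {
    stop("histogram_data: bins must be a positive integer", call. = FALSE)
  }
  rng <- range(r)
  if (diff(rng) == 0) {
    edges <- seq(rng[1] - 0.5, rng[1] + 0.5, length.out = bins + 1)
  } else {
    edges <- seq(rng[1], rng[2], length.out = bins + 1)
  }
  counts <- hist(r, breaks = edges, right = FALSE, include.lowest = TRUE,
                 plot = FALSE)$counts
  list(edges = edges, counts = counts)
}

#' Diagnostics bundle for a fitted joint model
#'
#' Collects the numeric data for the four model-checking panels:
#' standardized residuals against fitted values with a running mean,
#' absolute residuals, normal QQ points, and a residual histogram.
#'
#' @param fit a [fit_joint()] result.
#' @param window odd running-mean window; default the largest odd number
#'   `<= min(n, max(3, round(n / 8)))`.
#' @param bins histogram bin count (default 15).
#' @return an object of class `diagnostics_bundle` with fields `fitted`,
#'   `std_resid`, `abs_resid`, `running_mean`, `qq`, `hist`.
#' @export
diagnostics_bundle <- function(fit, window = NULL, bins = 15L) {
  stopifnot(inherits(fit, "joint_glm"))
  n <- length(fit$y)
  r <- standardized_residuals(fit$y, fit$mean_fit$mu, fit$disp_fit$phi,
                              fit$mean_fit$leverage)
  if (is.null(window)) {
    window <- min(n, max(3, round(n / 8)))
    if (window %% 2 == 0) window <- window - 1
  }
  structure(list(fitted = fit$mean_fit$mu,
                 std_resid = r,
                 abs_resid = abs(r),
                 running_mean = running_mean(fit$mean_fit$mu, r, window),
                 qq = qq_points(r),
                 hist = histogram_data(r, bins)),
            class = "diagnostics_bundle")
}

#' Four-panel diagnostics plot
#'
#' Residuals vs fitted with the running mean, absolute residuals vs fitted,
#' normal QQ plot, and residual histogram.
#'
#' @param x a [diagnostics_bundle()].
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.diagnostics_bundle <- function(x, ...) {
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  plot(x$fitted, x$std_resid, xlab = "Fitted MUAC (cm)",
       ylab = "Standardized residual", main = "Residuals vs fitted",
       pch = 20, col = "grey40")
  lines(x$running_mean$center, x$running_mean$mean, col = "red", lwd = 2)
  abline(h = 0, lty = 2)
  plot(x$fitted, x$abs_resid, xlab = "Fitted MUAC (cm)",
       ylab = "|Standardized residual|", main = "Absolute residuals",
       pch = 20, col = "grey40")
  plot(x$qq$theoretical, x$qq$sample, xlab = "Theoretical quantile",
       ylab = "Sample quantile", main = "Normal QQ", pch = 20,
       col = "grey40")
  abline(0, 1, lty = 2)
  edges <- x$hist$edges; counts <- x$hist$counts
  plot(range(edges), c(0, max(counts)), type = "n",
       xlab = "Standardized residual", ylab = "Count", main = "Histogram")
  rect(edges[-length(edges)], 0, edges[-1], counts, col = "grey80")
  invisible(x)
}
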