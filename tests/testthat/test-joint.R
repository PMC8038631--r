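test_that("minus2h matches the Gaussian density closed form", {
  expect_equal(minus2h(0, 0, 1), log(2 * pi))
  # terms cancel when phi = 1/(2*pi) and y = mu
  y <- rnorm(5)
  expect_equal(minus2h(y, y, rep(1 / (2 * pi), 5)), 0)
  # density oracle on a random vector
  set.seed(101)
  y <- rnorm(20); mu <- rnorm(20); phi <- exp(rnorm(20))
  expect_equal(minus2h(y, mu, phi),
               -2 * sum(dnorm(y, mu, sqrt(phi), log = TRUE)),
               tolerance = 1e-12)
  expect_error(minus2h(y, mu, c(phi[-1], -1)), "positive")
  expect_error(minus2h(y, mu[-1], phi[-1]), "length")
})

test_that("minus2pbeta adds the profile adjustment log-determinant", {
  # intercept-only, unit dispersion: adjustment is log(n / (2 pi))
  n <- 17
  y <- rnorm(n)
  fitlike <- list(X = matrix(1, n, 1), phi = rep(1, n),
                  minus2h = minus2h(y, rep(mean(y), n), rep(1, n)))
  expect_equal(minus2pbeta(fitlike),
               fitlike$minus2h + log(n / (2 * pi)), tolerance = 1e-12)

  # log-determinant agrees with an eigenvalue computation
  s <- random_system(30, 4, seed = 111)
  phi <- exp(rnorm(30))
  A <- crossprod(s$X / sqrt(phi)) / (2 * pi)
  expect_equal(minus2pbeta(list(X = s$X, phi = phi, minus2h = 0)),
               sum(log(eigen(A, symmetric = TRUE)$values)),
               tolerance = 1e-10)

  # duplicate column forces a labeled singularity error
  Xdup <- cbind(s$X, s$X[, 2])
  expect_error(minus2pbeta(list(X = Xdup, phi = phi, minus2h = 0)),
               "singular")
})

test_that("fit_criteria identities hold and cAIC penalizes mean terms only", {
  cr <- fit_criteria(464.2776, p_mean = 10, q_disp = 10, n = 163)
  expect_equal(cr$caic, 484.2776)
  expect_equal(cr$aic, 464.2776 + 2 * 20)
  expect_equal(cr$bic, 464.2776 + 20 * log(163))
  expect_equal(fit_criteria(438.4326, p_mean = 10)$caic, 458.4326)
  expect_equal(fit_criteria(100, p_mean = 0)$caic, 100)
})

test_that("intercept-only dispersion reduces to OLS with constant phi", {
  tab <- synth_cohort(120, seed = 7)
  for (method in c("REML", "ML")) {
    f <- fit_joint(tab, disp_terms = character(0), method = method)
    X <- build_design(tab)
    ols <- unname(drop(solve(crossprod(X), crossprod(X, tab$muac))))
    expect_equal(unname(f$mean_fit$beta), ols, tolerance = 1e-8)
    expect_lt(diff(range(f$disp_fit$phi)), 1e-12)
  }
  # under ML the constant dispersion is the mean deviance component
  fml <- fit_joint(tab, disp_terms = character(0), method = "ML")
  expect_equal(fml$disp_fit$phi[1], mean(fml$mean_fit$d), tolerance = 1e-8)
  # invariant: mean-model prior weights are 1/phi at exit
  expect_equal(fml$mean_fit$prior_weight, 1 / fml$disp_fit$phi,
               tolerance = 1e-12)
})

test_that("ML alternation fixed point maximizes the extended quasi-likelihood", {
  tab <- synth_cohort(50, seed = 13)
  X <- build_design(tab, c("weight"))
  G <- build_design(tab, c("hemoglobin"))
  y <- tab$muac
  fit <- fit_joint_matrices(y, X, G, method = "ML")
  expect_true(fit$converged)

  eql <- function(par) {
    mu <- drop(X %*% par[1:2])
    xi <- drop(G %*% par[3:4])
    sum((y - mu)^2 / exp(xi) + log(2 * pi) + xi)
  }
  grad <- function(par) {
    mu <- drop(X %*% par[1:2]); phi <- exp(drop(G %*% par[3:4]))
    c(-2 * crossprod(X, (y - mu) / phi),
      crossprod(G, 1 - (y - mu)^2 / phi))
  }
  start <- c(coef(lm.fit(X, y)), log(mean((y - drop(X %*% coef(lm.fit(X, y))))^2)), 0)
  opt <- optim(start, eql, grad, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 2000))
  expect_equal(unname(c(fit$mean_fit$beta, fit$disp_fit$gamma_coef)),
               unname(opt$par), tolerance = 1e-5)
  # and the criterion values agree
  expect_equal(fit$criteria$minus2h, opt$value, tolerance = 1e-8)
})

test_that("scaling the response acts predictably on all components", {
  tab <- synth_cohort(150, seed = 17)
  f1 <- fit_joint(tab, method = "ML")
  scaled <- as.data.frame(tab); cc <- 2.5
  scaled$muac <- scaled$muac * cc
  f2 <- fit_joint(cohort_table(scaled), method = "ML")
  n <- nrow(tab)
  expect_equal(f2$mean_fit$beta, cc * f1$mean_fit$beta, tolerance = 1e-5)
  dg <- f2$disp_fit$gamma_coef - f1$disp_fit$gamma_coef
  expect_equal(unname(dg["(Intercept)"]), 2 * log(cc), tolerance = 1e-5)
  expect_equal(unname(dg[-1]), rep(0, 9), tolerance = 1e-5)
  expect_equal(f2$criteria$minus2h, f1$criteria$minus2h + 2 * n * log(cc),
               tolerance = 1e-6)
})

test_that("the -2h trace settles into damped convergence", {
  ok <- 0; total <- 0
  for (seed in 201:210) {
    tab <- synth_cohort(300, seed = seed)
    f <- fit_joint(tab, method = "ML")
    tr <- f$trace
    steps <- abs(diff(tr))
    # only compare steps above numerical-noise level; near the fixed point
    # successive changes are dominated by roundoff
    big <- which(steps[-length(steps)] > 1e-6)
    if (length(big) > 1) {
      damped <- steps[big[-1] + 1] < steps[big[-1]]
      ok <- ok + sum(damped)
      total <- total + length(damped)
    }
    expect_true(f$converged)
  }
  expect_gte(ok / total, 0.95)
})

test_that("compute_criteria agrees with the stored criteria", {
  tab <- synth_cohort(163, seed = 19)
  f <- fit_joint(tab)
  cr <- compute_criteria(f)
  expect_equal(cr$minus2h, f$criteria$minus2h, tolerance = 1e-10)
  expect_equal(cr$caic, f$criteria$caic, tolerance = 1e-10)
  expect_equal(cr$minus2pbeta, f$criteria$minus2pbeta, tolerance = 1e-10)
  # leverage-based degrees of freedom coincide for a fixed-effects fit
  expect_equal(compute_criteria(f, caic_df = "leverage")$caic, cr$caic,
               tolerance = 1e-8)
  # the adjustment keeps -2 p_beta(h) above -2h here
  expect_gt(f$criteria$minus2pbeta, f$criteria$minus2h)
})
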