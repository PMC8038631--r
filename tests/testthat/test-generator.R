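test_that("default configuration carries the published calibration targets", {
  cfg <- default_generator_config(163, seed = 1)
  expect_equal(unname(cfg$covariate_means["age"]), 1.6334)
  expect_equal(unname(cfg$covariate_means["height"]), 78.5706)
  expect_equal(unname(cfg$covariate_sds["age"]), 1.18655)
  expect_equal(cfg$covariate_corr["age", "weight"], 0.799)
  expect_equal(unname(cfg$mean_beta["weight"]), 1.194023)
  expect_equal(unname(cfg$dispersion_gamma["hemoglobin"]), 0.2719)
  expect_equal(length(cfg$mean_beta), 10)
  expect_error(default_generator_config(-5), "non-negative")
})

test_that("invalid configurations are rejected with labeled errors", {
  cfg <- default_generator_config(10)
  bad_corr <- cfg$covariate_corr
  bad_corr[1, 2] <- bad_corr[2, 1] <- 1.5   # breaks positive definiteness
  expect_error(
    generator_config(10, 1, cfg$covariate_means, cfg$covariate_sds,
                     cfg$covariate_bounds, bad_corr, cfg$mean_beta,
                     cfg$dispersion_gamma),
    "positive definite")
  bad_bounds <- cfg$covariate_bounds
  bad_bounds$age <- c(5, 0.13)
  expect_error(
    generator_config(10, 1, cfg$covariate_means, cfg$covariate_sds,
                     bad_bounds, cfg$covariate_corr, cfg$mean_beta,
                     cfg$dispersion_gamma),
    "min < max")
  # bounds too tight for the requested sd: degenerate
  tight <- cfg$covariate_bounds
  tight$age <- c(1.6, 1.7)
  expect_error(
    generator_config(10, 1, cfg$covariate_means, cfg$covariate_sds,
                     tight, cfg$covariate_corr, cfg$mean_beta,
                     cfg$dispersion_gamma))
  expect_error(
    generator_config(10, 1, cfg$covariate_means, cfg$covariate_sds,
                     cfg$covariate_bounds, cfg$covariate_corr,
                     cfg$mean_beta[1:5], cfg$dispersion_gamma),
    "length")
})

test_that("generation is seed-deterministic, bounded, and leaves the caller RNG alone", {
  cfg <- default_generator_config(200, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(cfg, seed = 78)
  expect_false(identical(a, c2))

  for (cv in names(cfg$covariate_bounds)) {
    bnd <- cfg$covariate_bounds[[cv]]
    expect_true(all(a[[cv]] >= bnd[1] & a[[cv]] <= bnd[2]), label = cv)
  }
  expect_true(all(a$muac > 0))

  set.seed(123); before <- runif(1)
  set.seed(123); invisible(generate_cohort(cfg)); after <- runif(1)
  expect_identical(before, after)

  empty <- generate_cohort(cfg, n = 0)
  expect_s3_class(empty, "cohort_table")
  expect_equal(nrow(empty), 0)
})

test_that("generated moments and correlations match the configured targets", {
  cfg <- default_generator_config(40000, seed = 4)
  tab <- generate_cohort(cfg)
  d <- describe_cohort(tab)
  covs <- setdiff(d$variable, "muac")
  rel_err <- abs(d$mean[match(covs, d$variable)] -
                   cfg$covariate_means[covs]) / cfg$covariate_means[covs]
  expect_true(all(rel_err < 0.02))
  sd_err <- abs(d$sd[match(covs, d$variable)] -
                  cfg$covariate_sds[covs]) / cfg$covariate_sds[covs]
  expect_true(all(sd_err < 0.03))
  expect_lt(abs(cor(tab$age, tab$weight) - 0.799), 0.03)
  expect_lt(abs(cor(tab$protein, tab$albumen) - 0.658), 0.03)
})

test_that("response mechanism recovers mean coefficients by regression", {
  cfg <- default_generator_config(50000, seed = 10)
  tab <- generate_cohort(cfg)
  X <- build_design(tab)
  w <- 1 / exp(drop(X %*% cfg$dispersion_gamma))   # true precision weights
  f <- fit_gaussian(X, tab$muac, w)
  z <- (f$beta - cfg$mean_beta) / f$se
  expect_true(all(abs(z) < 3))
})

test_that("zero dispersion slopes give homoscedastic noise of the set variance", {
  cfg <- default_generator_config(50000, seed = 12)
  cval <- 0.8
  cfg2 <- generator_config(50000, 12, cfg$covariate_means, cfg$covariate_sds,
                           cfg$covariate_bounds, cfg$covariate_corr,
                           cfg$mean_beta,
                           c(log(cval), rep(0, 9)))
  tab <- generate_cohort(cfg2)
  mu <- drop(build_design(tab) %*% cfg2$mean_beta)
  v <- var(tab$muac - mu)
  expect_lt(abs(v - cval) / cval, 0.05)
})
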