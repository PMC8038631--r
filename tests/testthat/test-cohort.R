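test_that("cohort_table validates, reorders and drops incomplete rows", {
  tab <- tiny_cohort()
  expect_s3_class(tab, "cohort_table")
  expect_identical(names(tab),
                   c("age", "height", "weight", "hemoglobin", "protein",
                     "albumen", "muac"))

  df <- as.data.frame(tiny_cohort())
  df$muac[2] <- NA
  expect_message(dropped <- cohort_table(df), "dropped 1 row")
  expect_equal(nrow(dropped), 5)

  df2 <- as.data.frame(tiny_cohort()); df2$weight[1] <- -1
  expect_error(cohort_table(df2), "weight")
  df3 <- as.data.frame(tiny_cohort()); df3$age <- NULL
  expect_error(cohort_table(df3), "missing column")
})

test_that("build_design realizes intercept, main effects and products", {
  tab <- tiny_cohort()
  X <- build_design(tab, default_terms())
  expect_equal(dim(X), c(6, 10))
  expect_equal(colnames(X)[1], "(Intercept)")
  expect_true(all(X[, 1] == 1))
  expect_equal(colnames(X)[-1], default_terms())

  # interaction column is the elementwise product of its parents
  expect_equal(X[, "weight:height"], tab$weight * tab$height)
  expect_equal(X[, "age:height"], tab$age * tab$height)

  X0 <- build_design(tab, character(0))
  expect_equal(dim(X0), c(6, 1))
  expect_true(all(X0 == 1))

  df <- data.frame(age = c(1, 1, 1), height = c(10, 10, 20),
                   weight = c(1, 2, 3), hemoglobin = c(1, 1, 1),
                   protein = c(1, 1, 1), albumen = c(1, 1, 1),
                   muac = c(1, 1, 1))
  toy <- suppressMessages(cohort_table(df))
  expect_equal(unname(build_design(toy, "weight:height")[, 2]),
               c(10, 20, 60))

  expect_error(build_design(tab, "glucose"), "unknown covariate")
  expect_error(build_design(tab, c("age", "age")), "duplicate")
})

test_that("build_design is permutation-equivariant in the rows", {
  tab <- synth_cohort(40, seed = 3)
  X <- build_design(tab)
  perm <- sample(seq_len(40))
  Xp <- build_design(cohort_table(as.data.frame(tab)[perm, ]))
  expect_equal(Xp, X[perm, ], ignore_attr = TRUE)
})

test_that("describe_cohort reports min/max/mean/median/sd with n-1 sd", {
  df <- data.frame(age = c(1, 2, 6), height = c(5, 5, 5),
                   weight = c(1, 2, 3), hemoglobin = c(1, 2, 3),
                   protein = c(1, 2, 3), albumen = c(1, 2, 3),
                   muac = c(1, 2, 3))
  d <- describe_cohort(cohort_table(df))
  expect_equal(d$variable,
               c("age", "height", "weight", "hemoglobin", "protein",
                 "albumen", "muac"))
  age <- d[d$variable == "age", ]
  expect_equal(age$mean, 3)
  expect_equal(age$median, 2)
  expect_equal(age$sd, sqrt(7))          # 2.6458 at 4 dp
  expect_equal(round(age$sd, 4), 2.6458)
  # constant column: degenerate spread
  h <- d[d$variable == "height", ]
  expect_equal(c(h$minimum, h$maximum, h$mean, h$median), rep(5, 4))
  expect_equal(h$sd, 0)

  empty <- cohort_table(df[0, ])
  expect_error(describe_cohort(empty), "empty")
})

test_that("cohort_correlations computes Pearson r with t-transform p", {
  tab <- synth_cohort(50, seed = 5)
  cc <- cohort_correlations(tab)
  expect_equal(diag(cc$r), rep(1, 7), ignore_attr = TRUE)
  expect_equal(cc$r, t(cc$r))
  expect_true(all(abs(cc$r) <= 1))
  expect_true(all(is.na(diag(cc$p))))

  # hand-checked toy: x = (1,2,3,4), y = (2,1,4,3) -> r = 0.6
  r <- cor(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r, 0.6)
  # p from the t transform matches cor.test
  ct <- cor.test(tab$age, tab$weight)
  expect_equal(cc$p["age", "weight"], ct$p.value, tolerance = 1e-12)
  # perfect linearity in the underlying formula
  z <- tab$age
  expect_equal(cor(z, 2 * z + 1), 1)

  const <- as.data.frame(tab); const$protein <- 65
  expect_error(cohort_correlations(cohort_table(const)), "protein")
})

test_that("correlations are invariant to positive affine rescaling", {
  tab <- synth_cohort(60, seed = 6)
  cc1 <- cohort_correlations(tab)
  scaled <- as.data.frame(tab)
  scaled$weight <- scaled$weight * 2.2     # kg -> lb
  scaled$height <- scaled$height * 10 + 3
  cc2 <- cohort_correlations(cohort_table(scaled))
  expect_equal(cc2$r, cc1$r, tolerance = 1e-12)
  expect_identical(cc2$flags, cc1$flags)
})

test_that("CSV round trip reproduces all values exactly", {
  tab <- synth_cohort(30, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(tab, path)
  back <- read_cohort(path)
  expect_identical(as.data.frame(back), as.data.frame(tab))

  # duplicate headers rejected
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("age,age,height", "1,2,3"), bad)
  expect_error(read_cohort(bad), "duplicate")

  # mm -> cm conversion on ingest
  mm <- as.data.frame(tab); mm$muac <- mm$muac * 10
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort_table(mm), path2)
  back2 <- read_cohort(path2, muac_unit = "mm")
  expect_equal(back2$muac, tab$muac, tolerance = 1e-12)
})
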