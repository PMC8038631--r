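# Shared fixtures: a tiny hand-built cohort, a seeded synthetic cohort
# builder, and the published coefficient tables (estimate, se, printed
# Wald t, printed decimal places) used by the fixture tests.

tiny_cohort <- function() {
  cohort_table(data.frame(
    age        = c(0.5, 1.0, 1.5, 2.0, 3.0, 4.0),
    height     = c(60, 70, 75, 82, 95, 105),
    weight     = c(5.5, 7.8, 9.0, 10.5, 13.0, 15.5),
    hemoglobin = c(9.0, 10.5, 10.0, 11.2, 9.8, 10.9),
    protein    = c(60, 62, 66, 64, 70, 72),
    albumen    = c(30, 33, 35, 36, 40, 42),
    muac       = c(11.0, 12.1, 12.8, 13.3, 14.5, 15.2)))
}

synth_cohort <- function(n, seed, config = NULL) {
  if (is.null(config)) config <- default_generator_config(n, seed)
  generate_cohort(config, n = n, seed = seed)
}

# random full-rank regression system (not cohort-shaped)
random_system <- function(n, p, seed) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n))
  colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
  beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n)
  list(X = X, y = y, beta = beta)
}

# published coefficient tables: constant-dispersion mean model (glm),
# joint mean model (joint_mean), joint dispersion model (joint_disp);
# t_dp = decimal places of the printed Wald statistic
published_coef_tables <- function() {
  glm <- data.frame(
    term = c("(Intercept)", "age", "weight", "height", "hemoglobin",
             "protein", "albumen", "weight:height", "age:weight",
             "age:height"),
    estimate = c(3.297646, -2.44933, 1.214475, 0.046291, 0.061822,
                 0.010197, 0.024162, -0.007833, -0.024477, 0.022875),
    se = c(1.112371, 0.706229, 0.182097, 0.016303, 0.047596, 0.013159,
           0.017901, 0.002123, 0.028805, 0.008388),
    t_printed = c(2.9645, -3.4682, 6.6694, 2.8394, 1.2989, 0.7749,
                  1.3497, -3.6900, -0.8498, 2.7271),
    t_dp = 4)
  joint_mean <- data.frame(
    term = glm$term,
    estimate = c(3.514933, -2.161377, 1.194023, 0.028779, 0.033497,
                 0.016998, 0.032157, -0.006908, -0.051909, 0.024228),
    se = c(0.699909, 0.522314, 0.127182, 0.008209, 0.030733, 0.011937,
           0.015628, 0.001439, 0.021880, 0.006006),
    t_printed = c(5.022, -4.138, 9.388, 3.506, 1.090, 1.424, 2.058,
                  -4.800, -2.372, 4.034),
    t_dp = 3)
  joint_disp <- data.frame(
    term = glm$term,
    estimate = c(-3.686, -0.4625, 0.1549, 0.04431, 0.2719, -0.04087,
                 0.03496, -0.003353, 0.0382, 1.095e-05),
    se = c(1.721319, 0.986622, 0.256311, 0.027394, 0.065510, 0.017389,
           0.023711, 0.003065, 0.044118, 0.012225),
    t_printed = c(-2.1414, -0.4687, 0.6043, 1.6175, 4.1505, -2.3503,
                  1.4744, -1.0939, 0.8656, 0.0009),
    t_dp = 4)
  list(glm = glm, joint_mean = joint_mean, joint_disp = joint_disp)
}
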