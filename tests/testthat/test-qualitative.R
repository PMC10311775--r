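test_that("efficacy is near zero without drive and monotone in dose", {
  ## no drive: tiny learning rate with near-perfect retention, so the
  ## bracketing assessments differ only through beta * u
  traj0 <- generative_trajectory_draws(
    trial_design("dose"), hyperparameters(theta_alpha = 30,
                                          sigma_alpha = 1e-3,
                                          theta_beta = 0.001,
                                          sigma_beta = 1e-4,
                                          theta_gamma = 0.001,
                                          sigma_gamma = 1e-4),
    n_draws = 100, seed = 4)
  eff0 <- efficacy(traj0)
  cum0 <- subset(eff0$summary, bout == "cumulative")
  expect_lt(max(abs(cum0$median)), 0.05)
  ## shared parameter draws across arms: cumulative efficacy increases
  ## with dose, near-linearly over the positive doses
  traj <- generative_trajectory_draws(trial_design("dose"), n_draws = 300,
                                      seed = 5)
  eff <- efficacy(traj)
  cum <- subset(eff$summary, bout == "cumulative")
  cum <- cum[match(c("0h", "15h", "30h", "60h"), cum$arm), ]
  expect_true(all(diff(cum$median) > 0))
  expect_identical(cor(c(15, 30, 60), cum$median[2:4], method = "spearman"), 1)
})

test_that("efficiency decreases with dose and across bouts", {
  traj <- generative_trajectory_draws(trial_design("dose"), n_draws = 300,
                                      seed = 5)
  eff <- efficacy(traj)
  expect_message(efficiency(eff, traj), "zero-dose")
  ei <- suppressMessages(efficiency(eff, traj))$summary
  cum <- ei[ei$bout == "cumulative", ]
  cum <- cum[match(c("15h", "30h", "60h"), cum$arm), ]
  expect_true(all(diff(cum$median) < 0))
  for (a in c("15h", "30h", "60h")) {
    b1 <- ei$median[ei$arm == a & ei$bout == "bout1"]
    b3 <- ei$median[ei$arm == a & ei$bout == "bout3"]
    expect_gte(b1, b3)
  }
  ## hand arithmetic: 0.4 MAL over 20 h is 0.02 per hour
  expect_equal(0.4 / 20, 0.02)
})

test_that("decay profiles have the right signs and shrink over intervals", {
  ## pure decay (gamma = 0): all intervals negative, magnitude shrinking
  trajd <- generative_trajectory_draws(
    trial_design("dose"), hyperparameters(theta_gamma = 1e-6,
                                          sigma_gamma = 1e-7),
    n_draws = 150, seed = 6)
  dec <- decay_profile(trajd)
  expect_true(all(dec$median < 0))
  for (a in unique(dec$arm)) {
    m <- abs(dec$median[dec$arm == a])
    expect_true(all(diff(m) < 0))
  }
  ## strong self-training: the low-dose arm keeps improving post-training
  trajs <- generative_trajectory_draws(
    trial_design("dose"), hyperparameters(theta_gamma = 0.6,
                                          sigma_gamma = 0.05),
    n_draws = 150, seed = 6)
  decs <- decay_profile(trajs)
  expect_gt(decs$median[decs$arm == "0h" & decs$interval == 1], 0)
  ## flat trajectories change by zero in every interval
  trajf <- generative_trajectory_draws(
    trial_design("dose"), hyperparameters(theta_alpha = 30, sigma_alpha = 1e-3,
                                          theta_beta = 1e-9, sigma_beta = 1e-9,
                                          theta_gamma = 1e-9,
                                          sigma_gamma = 1e-9),
    n_draws = 20, seed = 7)
  decf <- decay_profile(trajf)
  expect_lt(max(abs(decf$median)), 1e-6)
})

test_that("threshold regression recovers constructed crossings", {
  ## exactly linear changes crossing zero at MAL 2.5
  mal <- seq(0.5, 4.5, length.out = 24)
  dose <- rep(c("a", "b"), 12)
  change <- 0.04 * (mal - 2.5)
  tf <- threshold_regression(change, mal, dose)
  expect_equal(tf$thresholds$threshold, c(2.5, 2.5), tolerance = 1e-6)
  expect_true(all(tf$thresholds$status == "ok"))
  ## all changes positive: crossing sits below the instrument range
  tf2 <- threshold_regression(0.05 + 0.04 * mal, mal, dose)
  expect_true(all(tf2$thresholds$status == "below_range"))
  ## lowering an arm's intercept raises its threshold
  shift <- ifelse(dose == "b", -0.08, 0)
  tf3 <- threshold_regression(change + shift, mal, dose)
  thr <- tf3$thresholds$threshold
  expect_gt(thr[2], thr[1])
  expect_equal(thr[2] - thr[1], 0.08 / tf3$slope, tolerance = 1e-8)
  expect_error(threshold_regression(1:3, 1:2, c("a", "b")), "equal length")
})

test_that("bootstrap correlation intervals behave correctly", {
  ## perfectly correlated pairs collapse to [1, 1]
  x <- runif(20)
  b <- bootstrap_correlations(data.frame(alpha = x, beta = 2 * x + 1),
                              n_boot = 200, seed = 1)
  expect_equal(b$r, 1)
  expect_equal(b$lo, 1)
  expect_equal(b$hi, 1)
  ## bootstrap mean tracks the sample correlation
  set.seed(11)
  df <- data.frame(alpha = rnorm(40), beta = rnorm(40), gamma = rnorm(40))
  bc <- bootstrap_correlations(df, n_boot = 2000, seed = 2)
  expect_identical(nrow(bc), 3L)
  expect_lt(max(abs(bc$boot_mean - bc$r)), 0.08)
  ## coverage: independent pairs include zero in ~95% of replicates
  set.seed(12)
  cover <- 0L
  for (r in 1:60) {
    d2 <- data.frame(alpha = rnorm(40), beta = rnorm(40))
    ci <- bootstrap_correlations(d2, n_boot = 300, seed = r)
    cover <- cover + (ci$lo <= 0 && ci$hi >= 0)
  }
  expect_gte(cover / 60, 0.85)
  ## constant column flagged
  expect_warning(bootstrap_correlations(
    data.frame(alpha = rep(1, 10), beta = rnorm(10)), n_boot = 50),
    "constant")
  expect_error(bootstrap_correlations(data.frame(alpha = 1:2, beta = 2:1)),
               "at least 3")
})
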