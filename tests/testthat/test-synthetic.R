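test_that("trial designs reproduce the assessment and dosing layouts", {
  d <- trial_design("dose")
  expect_identical(names(d$arms), c("0h", "15h", "30h", "60h"))
  for (a in 1:4) expect_length(make_assessment_weeks(d, a), 14L)
  ## weekly inputs are nominal/3 + 2 h of movement testing
  expect_equal(vapply(1:4, function(a)
    unique(make_dose_schedule(d, a)$hours[make_dose_schedule(d, a)$hours > 0]),
    numeric(1)), c(2, 7, 12, 22))
  sch60 <- make_dose_schedule(d, "60h")
  expect_identical(sch60$week[sch60$hours > 0], c(2L, 7L, 12L))
  ## final assessment 24 weeks (6 x 4-week months) after the last bout
  aw <- make_assessment_weeks(d, 1)
  post3 <- min(aw[aw > 12])
  expect_identical(max(aw) - post3, 24L)

  e <- trial_design("excite")
  for (a in 1:2) expect_length(make_assessment_weeks(e, a), 9L)
  schd <- make_dose_schedule(e, "delayed")
  expect_identical(schd$week[schd$hours > 0], 52L)
  expect_equal(schd$hours[schd$week == 52], 60)
  schi <- make_dose_schedule(e, "immediate")
  expect_identical(schi$week[schi$hours > 0], 0L)
  expect_error(make_dose_schedule(d, "90h"), "configuration error")
  expect_error(trial_design("dose", n_subjects = 10, n_per_arm = c(4, 4, 4, 4)),
               "partition")
})

test_that("cohort sizes partition arms with the default splits", {
  d <- trial_design("dose")
  expect_identical(d$n_per_arm, rep(10L, 4))
  e <- trial_design("excite")
  expect_identical(e$n_per_arm, c(50L, 45L))
  expect_identical(sum(trial_design("dose", n_subjects = 14)$n_per_arm), 14L)
})

test_that("subject-parameter draws respect supports and degenerate limits", {
  set.seed(1)
  h <- hyperparameters()
  p <- draw_subject_parameters(h, mal_ini = runif(5000, 0.5, 3.5))
  expect_true(all(p$alpha > 0 & p$alpha < 1))
  expect_true(all(p$beta >= 0) && all(p$gamma >= 0) && all(p$x0 >= 0))
  ## degenerate-prior limit: sigma_alpha -> 0 pins alpha at plogis(theta)
  pd <- draw_subject_parameters(hyperparameters(sigma_alpha = 1e-12), 2, n = 50)
  expect_equal(pd$alpha, rep(plogis(2), 50), tolerance = 1e-9)
  ## truncation floor: very negative location piles mass at zero
  pt <- draw_subject_parameters(hyperparameters(theta_beta = -10,
                                                sigma_beta = 0.1), 2, n = 200)
  expect_true(all(pt$beta >= 0) && median(pt$beta) < 0.01)
  ## mean of the logit-normal against an independent Monte-Carlo oracle
  set.seed(99)
  pa <- draw_subject_parameters(hyperparameters(theta_alpha = 2,
                                                sigma_alpha = 1), 2, n = 1e5)
  set.seed(1234)
  oracle <- plogis(rnorm(4e5, 2, 1))
  se <- sd(oracle) / sqrt(1e5) + sd(oracle) / sqrt(4e5)
  expect_lt(abs(mean(pa$alpha) - mean(oracle)), 3 * se)
})

test_that("simulated cohorts are deterministic, bounded and grid-complete", {
  d <- trial_design("dose", n_subjects = 8)
  c1 <- simulate_cohort(d, seed = 5)
  c2 <- simulate_cohort(d, seed = 5)
  expect_identical(c1, c2)
  obs <- c1$observations
  keep <- !is.na(obs$mal)
  expect_true(all(obs$mal[keep] >= 0 & obs$mal[keep] <= 5))
  ## every observed week exists in the schedule grid
  expect_true(all(obs$week %in% c1$schedule$week))
  ## each subject observed at exactly the 14 assessment weeks
  for (s in unique(obs$subject_id))
    expect_identical(sum(keep & obs$subject_id == s), 14L)
  ## noiseless limit: observations equal the model trajectory
  c0 <- simulate_cohort(d, hyperparameters(sigma_mal = 1e-9), seed = 5)
  traj <- cohort_trajectories(c0)
  for (s in unique(c0$observations$subject_id)) {
    o <- c0$observations[c0$observations$subject_id == s, ]
    w <- o$week[!is.na(o$mal)]
    expect_equal(o$mal[!is.na(o$mal)],
                 pmax(0, pmin(5, traj$draws[[s]][1, w + 1L])),
                 tolerance = 1e-6)
  }
})

test_that("measurement noise matches the Student-t scale", {
  ## residual spread over many draws against the generating t-distribution
  h <- hyperparameters(nu = 3, sigma_mal = 0.25)
  d <- trial_design("dose", n_subjects = 100)
  coh <- simulate_cohort(d, h, seed = 17)
  traj <- cohort_trajectories(coh)
  res <- NULL
  for (s in coh$truth$subject_id) {
    o <- coh$observations[coh$observations$subject_id == s, ]
    w <- o$week[!is.na(o$mal)]
    m <- traj$draws[[s]][1, w + 1L]
    keep <- m > 1 & m < 4             # avoid clipping distortion
    res <- c(res, (o$mal[!is.na(o$mal)] - m)[keep])
  }
  ## compare IQR (robust to the heavy nu = 3 tails) to its exact value
  expect_gt(length(res), 500)
  expect_equal(unname(diff(quantile(res, c(0.25, 0.75)))),
               0.25 * 2 * qt(0.75, 3), tolerance = 0.12)
})
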