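test_that("BF-RMSE matches hand arithmetic and the bias-variance identity", {
  expect_equal(bf_rmse(c(1, 3), 2), 1)
  expect_equal(bf_rmse(rep(2, 10), 2), 0)
  expect_equal(bf_rmse(rep(3.7, 10), 2), 1.7)     # |c - truth| for constants
  set.seed(9)
  for (r in 1:10) {
    d <- rnorm(200, runif(1, 0, 5), runif(1, 0.1, 1))
    t0 <- runif(1, 0, 5)
    lhs <- bf_rmse(d, t0)^2
    rhs <- (mean(d) - t0)^2 + mean((d - mean(d))^2)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
  expect_error(bf_rmse(numeric(0), 1), "draws")
})

test_that("point RMSE matches hand arithmetic and ignores order", {
  expect_equal(point_rmse(c(2, 2), c(1, 3)), 1)
  expect_equal(point_rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  x <- runif(6); y <- runif(6)
  o <- sample(6)
  expect_equal(point_rmse(x, y), point_rmse(x[o], y[o]))
  expect_error(point_rmse(NA, NA), "evaluation error")
})

test_that("sign-flip permutation test enumerates exactly", {
  expect_equal(permutation_compare(c(2, 2, 2), c(1, 1, 1)), 1 / 8)
  expect_equal(permutation_compare(c(0, 0, 0), c(1, 1, 1)), 1)
  expect_equal(permutation_compare(c(1, 1, 1), c(1, 1, 1)), 1)  # all ties
  ## exact and Monte-Carlo paths agree on an 8-subject toy
  set.seed(10)
  a <- runif(8, 0.5, 1.5); b <- runif(8, 0.4, 1.4)
  pe <- permutation_compare(a, b, method = "exact")
  pm <- permutation_compare(a, b, n_perm = 4000, seed = 2,
                            method = "montecarlo")
  se <- sqrt(pe * (1 - pe) / 4000)
  expect_lt(abs(pe - pm), 3 * se + 1 / 4000)
  expect_error(permutation_compare(1:3, 1:2), "data error")
})

test_that("scenario cutoffs are ordered suffix masks", {
  d <- trial_design("dose")
  scen <- forecast_scenarios(d)
  expect_identical(names(scen), c("baseline_only", "after_bout_1",
                                  "after_bout_2", "after_bout_3"))
  cuts <- vapply(scen, `[[`, integer(1), "cutoff")
  expect_identical(unname(cuts), c(0L, 3L, 8L, 13L))
  expect_true(all(diff(cuts) > 0))
  ## masked week sets shrink as the cutoff advances (suffix monotonicity)
  aw <- make_assessment_weeks(d, 1)
  masked <- lapply(cuts, function(cc) aw[aw > cc])
  for (k in 2:4) expect_true(all(masked[[k]] %in% masked[[k - 1]]))
})

test_that("LOSO forecasting masks, refits and recovers noiseless data", {
  coh <- simulate_cohort(trial_design("dose", n_subjects = 4),
                         hyperparameters(sigma_mal = 0.01), seed = 14)
  scen <- forecast_scenarios(coh$design)
  ## masking just the last assessment is one-step-ahead prediction
  fc1 <- suppressWarnings(suppressMessages(loso_forecast(
    coh, "S01", list(name = "last", cutoff = 36L),
    chains = 2, iter = 700, warmup = 400, seed = 1)))
  expect_identical(fc1$weeks, 37L)
  expect_identical(ncol(fc1$draws), 1L)
  ## empty mask errors
  expect_error(suppressWarnings(loso_forecast(
    coh, "S01", list(name = "none", cutoff = 37L),
    chains = 2, iter = 300, warmup = 200)), "scenario error")
  ## near-noiseless data: after bout 3 the forecast medians track the
  ## true trajectory closely
  fc <- suppressWarnings(suppressMessages(loso_forecast(
    coh, "S02", scen$after_bout_3,
    prior = hbdm_prior(sigma_mal = c(0.01, 0.005)),
    chains = 2, iter = 4000, warmup = 2000, seed = 2)))
  truth_traj <- cohort_trajectories(coh)$draws[["S02"]][1, fc$weeks + 1L]
  med <- apply(fc$draws, 2, median)
  expect_lt(max(abs(med - truth_traj)), 0.05)
  expect_true(all(fc$draws >= 0 & fc$draws < 5))
  expect_true(all(fc$bf_rmse >= 0))
})

test_that("scenario tables aggregate BF-RMSE and p-values", {
  coh <- simulate_cohort(trial_design("dose", n_subjects = 4), seed = 15)
  scen <- forecast_scenarios(coh$design)
  res <- suppressWarnings(suppressMessages(run_scenarios(
    coh, scenarios = scen["after_bout_3"], seed = 3,
    chains = 2, iter = 500, warmup = 300)))
  tab <- res$table
  expect_true(all(c("scenario", "model", "week", "mean_bf_rmse",
                    "n_subjects") %in% names(tab)))
  expect_true(all(tab$n_subjects == 4))
  expect_true(all(tab$mean_bf_rmse >= 0))
  expect_identical(sort(unique(tab$model)),
                   c("hierarchical", "non_hierarchical"))
  expect_true(!is.null(res$pvalues))
  expect_true(all(res$pvalues$p > 0 & res$pvalues$p <= 1))
})
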