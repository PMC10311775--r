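test_that("memory-to-MAL sigmoid matches its closed form and bounds", {
  expect_identical(mal_sigmoid(0), 0)
  ## high-precision reference value for x = 5
  expect_equal(mal_sigmoid(5), 2.310585786300049, tolerance = 1e-9)
  ## asymptote approached, never attained
  expect_lt(mal_sigmoid(100), 5)
  expect_gt(mal_sigmoid(100), 5 - 1e-6)
  x <- seq(-80, 80, length.out = 4001)
  m <- mal_sigmoid(x)
  expect_true(all(diff(m) > 0))              # strictly increasing
  expect_true(all(m > -5 & m < 5))
  expect_true(all(m[x >= 0] >= 0))
  expect_error(mal_sigmoid(Inf), "finite")
  expect_error(mal_sigmoid(NA_real_), "finite")
})

test_that("sigmoid round-trips with its inverse", {
  m <- seq(-4.99, 4.99, length.out = 997)
  expect_equal(mal_sigmoid(mal_sigmoid_inv(m)), m, tolerance = 1e-10)
  x <- seq(-40, 40, length.out = 501)
  expect_equal(mal_sigmoid_inv(mal_sigmoid(x)), x, tolerance = 1e-8)
  expect_error(mal_sigmoid_inv(5), "inside")
})

test_that("memory update follows the two-branch dynamics", {
  p_id <- subject_parameters(alpha = 1 - 1e-12, beta = 0, gamma = 0, x0 = 3)
  expect_equal(memory_update(3, p_id, mal_sigmoid(3), u = 0), 3,
               tolerance = 1e-9)
  ## zero is a fixed point of the no-training branch since m(0) = 0
  p <- subject_parameters(0.9, 0.1, 0.3, 0)
  expect_identical(memory_update(0, p, mal_sigmoid(0), u = 0), 0)
  ## training branch, retention anchored near the typical estimate 0.86
  p2 <- subject_parameters(0.86, 0.2, 0.3, 10)
  expect_equal(memory_update(10, p2, mal_sigmoid(10), u = 22), 13.0,
               tolerance = 1e-12)
  expect_error(memory_update(-1, p2, 0, 0), "nonnegative")
  expect_error(memory_update(1, p2, 0, -2), "nonnegative")
})

test_that("forward simulation reduces to geometric decay when beta = gamma = 0", {
  set.seed(42)
  for (rep in 1:20) {
    alpha <- runif(1, 0.01, 0.99)
    x0 <- runif(1, 0, 50)
    horizon <- sample(3:100, 1)
    tr <- forward_simulate(subject_parameters(alpha, 0, 0, x0),
                           rep(0, horizon), horizon)
    expect_equal(tr$x, x0 * alpha^(0:(horizon - 1)), tolerance = 1e-12)
  }
  ## the worked two-step example: training in week 0 only
  tr <- forward_simulate(subject_parameters(0.9, 0.1, 0, 0),
                         c(22, 0, 0), horizon = 3)
  expect_equal(tr$x[2], 2.2, tolerance = 1e-12)
  expect_equal(tr$x[3], 1.98, tolerance = 1e-12)
  ## explicit quarter-decay example
  tr2 <- forward_simulate(subject_parameters(0.5, 0, 0, 10), rep(0, 4), 4)
  expect_equal(tr2$x[4], 1.25, tolerance = 1e-12)
})

test_that("trajectories are bounded and monotone in the dose", {
  set.seed(7)
  for (rep in 1:25) {
    p <- subject_parameters(runif(1, 0.05, 0.95), runif(1, 0, 0.5),
                            runif(1, 0, 0.6), runif(1, 0, 30))
    u <- ifelse(runif(38) < 0.2, runif(38, 0, 25), 0)
    tr <- forward_simulate(p, u, 38)
    expect_true(all(tr$m >= 0 & tr$m < 5))
    expect_true(all(tr$x >= 0))
    ## pure decay when no input and no self-training
    p0 <- subject_parameters(p$alpha, p$beta, 0, p$x0)
    tr0 <- forward_simulate(p0, rep(0, 20), 20)
    expect_true(all(diff(tr0$x) <= 1e-12))
    ## raising the dose of a training week never decreases later memory
    ## (raising a rest week switches the update branch, so the guarantee
    ## applies within the training branch)
    dosed <- which(u[1:20] > 0)
    wk <- if (length(dosed)) dosed[1] else { u[3] <- 1e-9; 3 }
    tr <- forward_simulate(p, u, 38)
    u2 <- u; u2[wk] <- u[wk] + 5
    tr2 <- forward_simulate(p, u2, 38)
    expect_true(all(tr2$x - tr$x >= -1e-12))
  }
  expect_error(forward_simulate(subject_parameters(0.5, 0, 0, 1),
                                rep(0, 3), 5), "configuration error")
})

test_that("Student-t observation model is symmetric with known special cases", {
  ## symmetry about the predicted MAL
  d <- runif(10, 0, 2)
  expect_equal(observation_loglik(2 + d, 2, 0.3, 5),
               observation_loglik(2 - d, 2, 0.3, 5))
  ## Cauchy at its mode
  expect_equal(observation_loglik(0, 0, 1, 1), log(1 / pi), tolerance = 1e-12)
  ## maximal at y = m
  y <- seq(0, 5, by = 0.05)
  ll <- observation_loglik(y, 2.5, 0.25, 10)
  expect_equal(y[which.max(ll)], 2.5)
  ## Gaussian limit as nu grows (unit scale, so |z| <= 2.5 on the grid)
  expect_lt(max(abs(observation_loglik(y, 2.5, 1, 1e6) -
                    dnorm(y, 2.5, 1, log = TRUE))), 1e-4)
  expect_error(observation_loglik(1, 1, -0.2, 5), "sigma")
  expect_error(observation_loglik(1, 1, 0.2, 0), "nu")
})
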