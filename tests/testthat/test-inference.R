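test_that("sampling is deterministic given the seed", {
  coh <- small_cohort(n = 3, seed = 2)
  f1 <- suppressWarnings(suppressMessages(
    hbdm(coh, chains = 2, iter = 260, warmup = 160, seed = 4, quiet = TRUE)))
  f2 <- suppressWarnings(suppressMessages(
    hbdm(coh, chains = 2, iter = 260, warmup = 160, seed = 4, quiet = TRUE)))
  expect_identical(f1$draws, f2$draws)
  f3 <- suppressWarnings(suppressMessages(
    hbdm(coh, chains = 2, iter = 260, warmup = 160, seed = 5, quiet = TRUE)))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("a flat single-subject series is fitted at its level", {
  obs <- data.frame(subject_id = "S1", week = 0:13, mal = 2.5,
                    baseline_mal = 2.5)
  sch <- data.frame(subject_id = "S1", week = 0:13, hours = 0)
  fit <- suppressWarnings(suppressMessages(
    hbdm(obs, sch, prior = hbdm_prior(sigma_mal = c(0.05, 0.02)),
         chains = 2, iter = 2400, warmup = 1200, seed = 1, quiet = TRUE)))
  pr <- predict(fit, probs = 0.5)
  expect_true(all(abs(pr$q50 - 2.5) < 0.2))
})

test_that("near-noiseless data are interpolated by the posterior trajectories", {
  coh <- simulate_cohort(trial_design("dose", n_subjects = 4),
                         hyperparameters(sigma_mal = 0.01), seed = 8)
  fit <- suppressWarnings(suppressMessages(
    hbdm(coh, prior = hbdm_prior(sigma_mal = c(0.01, 0.005)),
         chains = 2, iter = 4000, warmup = 2000, seed = 2, quiet = TRUE)))
  f <- fitted(fit)
  expect_lt(max(abs(f$fitted - f$mal_obs)), 0.05)
})

test_that("non-convergence raises a structured warning", {
  coh <- small_cohort(n = 3, seed = 2)
  expect_warning(
    suppressMessages(hbdm(coh, chains = 2, iter = 16, warmup = 8, seed = 1,
                          quiet = TRUE)),
    "R-hat")
})

test_that("model variants drop the right terms and run end to end", {
  coh <- small_cohort(n = 4, seed = 12)
  for (form in c("no_learning", "no_self_training", "no_retention",
                 "fixed_effects")) {
    fit <- suppressWarnings(suppressMessages(
      hbdm(coh, model = hbdm_model(form), chains = 2, iter = 500,
           warmup = 300, seed = 1, quiet = TRUE)))
    co <- coef(fit)
    if (form == "no_learning") expect_true(all(co$beta == 0))
    if (form == "no_self_training") expect_true(all(co$gamma == 0))
    if (form == "no_retention") expect_true(all(co$alpha == 1))
    if (form == "fixed_effects") expect_identical(nrow(co), 1L)
    expect_true(all(is.finite(rehabdyn:::draw_matrix(fit))))
  }
  ## static forms: bounded logistic predictions, flat data give small slopes
  obs <- data.frame(subject_id = rep(c("A", "B"), each = 6),
                    week = rep(seq(0, 15, 3), 2),
                    mal = rep(c(2.2, 3.1), each = 6),
                    baseline_mal = rep(c(2.2, 3.1), each = 6))
  sch <- data.frame(subject_id = rep(c("A", "B"), each = 16),
                    week = rep(0:15, 2), hours = 0)
  for (form in c("linear", "logistic")) {
    sf <- suppressWarnings(suppressMessages(
      hbdm(obs, sch, model = hbdm_model(form), chains = 2, iter = 3000,
           warmup = 1500, seed = 3, quiet = TRUE)))
    co <- coef(sf)
    expect_lt(max(abs(co$d)), 0.05)
    pr <- predict(sf)
    if (form == "logistic") expect_true(all(pr$q97.5 < 5 & pr$q2.5 > -5))
  }
  ## the linear form is unbounded on extrapolation; the logistic is not
  expect_gt(3 + 0.2 * 38, 5)
})

test_that("the sampler agrees with an independent MCMC backend", {
  skip_if_not_installed("rjags")
  coh <- small_cohort(n = 6, seed = 21)
  fit <- suppressWarnings(suppressMessages(
    hbdm(coh, chains = 2, iter = 6000, warmup = 2000, thin = 2, seed = 1,
         quiet = TRUE)))
  g <- fit$grid
  mod <- "
  model {
    for (i in 1:S) {
      araw[i] ~ dnorm(theta_alpha, pow(sigma_alpha,-2))
      alpha[i] <- 1/(1+exp(-araw[i]))
      beta[i] ~ dnorm(theta_beta, pow(sigma_beta,-2)) T(0,)
      gam[i] ~ dnorm(theta_gamma, pow(sigma_gamma,-2)) T(0,)
      x0[i] ~ dnorm(k*mal_ini[i], pow(sigma_ini,-2)) T(0,)
      x[i,1] <- x0[i]
      for (t in 1:Tmax) { m[i,t] <- 10/(1+exp(-0.2*x[i,t])) - 5 }
      for (t in 1:(Tmax-1)) {
        x[i,t+1] <- alpha[i]*x[i,t] + tr[i,t]*beta[i]*u[i,t] +
                    (1-tr[i,t])*gam[i]*m[i,t]
      }
    }
    for (j in 1:N) { y[j] ~ dt(m[si[j], wi[j]], pow(sigma_mal,-2), nu) }
    theta_alpha ~ dnorm(2, 1)
    sigma_alpha <- 1/iga ; iga ~ dgamma(3, 2)
    theta_beta ~ dnorm(0, 1)
    sigma_beta <- 1/igb ; igb ~ dgamma(4, 2)
    theta_gamma ~ dnorm(0, 1)
    sigma_gamma <- 1/igg ; igg ~ dgamma(4, 2)
    k ~ dnorm(0, 0.25) T(0,)
    sigma_ini <- 1/igi ; igi ~ dgamma(3, 2)
    nu ~ dgamma(2, 0.1)
    sigma_mal ~ dnorm(0.25, 100) T(0,)
  }"
  idx <- which(g$has, arr.ind = TRUE)
  dat <- list(S = g$S, Tmax = g$Tmax, u = g$u, tr = (g$u > 0) * 1,
              mal_ini = g$mal_ini, N = nrow(idx),
              y = g$yobs[idx], si = idx[, 1], wi = idx[, 2])
  jm <- rjags::jags.model(textConnection(mod), data = dat, n.chains = 2,
                          n.adapt = 600, quiet = TRUE,
                          inits = lapply(1:2, function(c)
                            list(.RNG.name = "base::Mersenne-Twister",
                                 .RNG.seed = c)))
  update(jm, 1500, progress.bar = "none")
  sm <- rjags::coda.samples(jm, c("k", "sigma_mal", "sigma_ini", "alpha", "m"),
                            n.iter = 4000, thin = 2, progress.bar = "none")
  smm <- as.matrix(sm)
  dm <- rehabdyn:::draw_matrix(fit)
  ## well-identified hyper-parameters agree between backends
  expect_lt(abs(median(smm[, "k"]) - median(dm[, "k"])), 0.3)
  expect_lt(abs(median(smm[, "sigma_mal"]) - median(dm[, "sigma_mal"])), 0.04)
  expect_lt(abs(median(smm[, "sigma_ini"]) - median(dm[, "sigma_ini"])), 0.35)
  ## subject retention estimates track each other
  aJ <- vapply(seq_len(g$S), function(i)
    median(smm[, paste0("alpha[", i, "]")]), numeric(1))
  aM <- coef(fit)$alpha
  expect_lt(max(abs(aJ - aM)), 0.12)
  ## fitted trajectories agree pointwise
  fJ <- vapply(seq_len(g$S), function(i)
    median(smm[, paste0("m[", i, ",38]")]), numeric(1))
  prM <- predict(fit, probs = 0.5)
  fM <- prM$q50[prM$week == 37]
  expect_lt(max(abs(fJ - fM)), 0.25)
})
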