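## shared fixtures: tiny cohorts and a cached quick fit

small_cohort <- function(n = 8, seed = 3, hyper = hyperparameters()) {
  simulate_cohort(trial_design("dose", n_subjects = n), hyper, seed = seed)
}

.fit_cache <- new.env(parent = emptyenv())

## a modest 8-subject fit reused across test files
cached_small_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    coh <- small_cohort()
    .fit_cache$cohort <- coh
    .fit_cache$fit <- suppressWarnings(suppressMessages(
      hbdm(coh, chains = 2, iter = 3000, warmup = 1500, seed = 1,
           quiet = TRUE)))
  }
  list(cohort = .fit_cache$cohort, fit = .fit_cache$fit)
}

## independent brute-force WAIC from the defining sums (test oracle)
waic_brute <- function(ll) {
  S <- nrow(ll)
  lppd_i <- numeric(ncol(ll))
  p_i <- numeric(ncol(ll))
  for (j in seq_len(ncol(ll))) {
    lppd_i[j] <- log(mean(exp(ll[, j])))
    p_i[j] <- var(ll[, j])
  }
  -2 * sum(lppd_i - p_i)
}
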