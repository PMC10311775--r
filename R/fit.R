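#' Fit the hierarchical Bayesian dynamic model
#'
#' Fits the three-level model to all subjects simultaneously by Markov
#' chain Monte Carlo: level 1 is the deterministic weekly memory
#' dynamics with Student-t measurement noise, level 2 the subject
#' parameter priors \eqn{(\alpha_i, \beta_i, \gamma_i, x^0_i)}, level 3
#' the population hyper-priors of [hbdm_prior()].  Sampling uses the
#' package's adaptive Metropolis-within-Gibbs kernel (see the methods
#' vignette); proposal adaptation is confined to warmup.
#'
#' The sampler is deterministic given `seed`, the data and the
#' configuration.  After sampling, rank-normalised split R-hat is
#' computed for every parameter and a structured warning (not a silent
#' success) is emitted if any exceeds the 1.01 convergence threshold.
#'
#' @param observations Long data frame (`subject_id`, `week`, `mal`,
#'   `NA` = missing), or a `"mal_cohort"` from [simulate_cohort()] (in
#'   which case `schedule` is taken from the cohort).
#' @param schedule Long data frame (`subject_id`, `week`, `hours`).
#' @param model An [hbdm_model()] specification.
#' @param prior An [hbdm_prior()] specification.
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param iter Sweeps per chain, including warmup.
#' @param warmup Adaptation/burn-in sweeps per chain.
#' @param thin Keep every `thin`-th post-warmup sweep.
#' @param seed Integer seed governing all randomness.
#' @param mal_ini_from Baseline-MAL definition, see
#'   [build_weekly_grid()].
#' @param control List of sampler internals: `global_reps` (global
#'   hyper-move repetitions per sweep, default 6), `prior_reps`
#'   (prior-proposal repetitions per subject per sweep, default 3).
#' @param quiet Suppress the convergence warning check message.
#' @return An object of class `"hbdm"`; see [summary.hbdm()],
#'   [coef.hbdm()], [predict.hbdm()], [fitted.hbdm()],
#'   [residuals.hbdm()], [simulate.hbdm()] and [plot.hbdm()].
#' @examples
#' \donttest{
#' coh <- simulate_cohort(trial_design("dose", n_subjects = 8), seed = 1)
#' fit <- hbdm(coh, chains = 2, iter = 2000, warmup = 1000, seed = 1)
#' summary(fit)
#' }
#' @export
hbdm <- function(observations, schedule = NULL, model = hbdm_model("full"),
                 prior = hbdm_prior(), chains = 4, iter = 2000,
                 warmup = 1000, thin = 1, seed = 1,
                 mal_ini_from = c("column", "first", "pre_mean"),
                 control = list(), quiet = FALSE) {
  if (inherits(observations, "mal_cohort")) {
    if (is.null(schedule)) schedule <- observations$schedule
    observations <- observations$observations
  }
  if (is.null(schedule)) stop("`schedule` is required", call. = FALSE)
  stopifnot(inherits(model, "hbdm_model"), inherits(prior, "hbdm_prior"))
  chains <- as.integer(chains); iter <- as.integer(iter)
  warmup <- as.integer(warmup); thin <- as.integer(thin)
  if (chains < 1 || iter <= warmup || thin < 1)
    stop("need chains >= 1, iter > warmup, thin >= 1", call. = FALSE)
  keep <- (iter - warmup) %/% thin
  if (keep < 2) stop("fewer than 2 kept draws per chain", call. = FALSE)
  grid <- build_weekly_grid(observations, schedule, mal_ini_from)
  n_single <- sum(vapply(seq_len(grid$S), function(i) sum(grid$has[i, ]) == 1L,
                         logical(1)))
  if (n_single > 0 && !quiet)
    message(n_single, " subject(s) with a single observation; their ",
            "posteriors are prior-dominated")
  ctrl <- list(global_reps = 6L, prior_reps = 3L)
  ctrl[names(control)] <- control
  med <- hbdm_prior_medians(prior)
  t0 <- Sys.time()
  if (model$static) {
    res <- fit_static_backend(grid, model, prior, chains, warmup, keep, thin, seed)
  } else {
    res <- fit_dynamic_backend(grid, model, prior, med, chains, warmup, keep,
                               thin, seed, ctrl)
  }
  fit <- structure(list(draws = res$draws, par_names = colnames(res$draws[, 1, ]),
                        model = model, prior = prior, grid = grid,
                        chains = chains, iter = iter, warmup = warmup,
                        thin = thin, seed = as.integer(seed),
                        control = ctrl,
                        backend = paste0("rehabdyn adaptive MwG ",
                                         as.character(utils::packageVersion("rehabdyn"))),
                        time = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
                   class = "hbdm")
  fit$rhat <- rhat(fit)
  bad <- names(fit$rhat)[fit$rhat >= 1.01]
  if (length(bad))
    warning("convergence not reached (rank-normalised split R-hat >= 1.01) for: ",
            paste(utils::head(bad, 10L), collapse = ", "),
            if (length(bad) > 10L) sprintf(" ... (%d total)", length(bad)),
            call. = FALSE)
  fit
}

fit_dynamic_backend <- function(grid, model, prior, med, chains, warmup, keep,
                                thin, seed, ctrl) {
  dat <- list(S = grid$S, Tmax = grid$Tmax, u = grid$u, yobs = grid$yobs,
              has = grid$has, mal_ini = grid$mal_ini)
  pc <- prior_constants(prior)
  h_med <- as.numeric(unlist(med))
  G <- if (model$shared) 1L else grid$S
  draw_list <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed) + 1000L * (ch - 1L))
    if (model$hierarchical) {
      hj <- h_med * exp(stats::runif(10, -0.3, 0.3))
      hj[1] <- h_med[1] + stats::rnorm(1, 0, 0.5)
    } else {
      hj <- h_med  # fixed weakly-informative constants, no pooling
    }
    cfg <- list(use_a = model$use_a, use_b = model$use_b, use_g = model$use_g,
                shared = model$shared, hier = model$hierarchical,
                warmup = warmup, keep = keep, thin = thin,
                global_reps = ctrl$global_reps, prior_reps = ctrl$prior_reps,
                prior_const = pc, h_init = hj,
                s_init = c(hj[1], max(0.05, hj[3]), max(0.05, hj[5]), 1))
    draw_list[[ch]] <- run_hbdm_chain(dat, cfg)
  }
  ids <- if (model$shared) "pop" else grid$subjects
  pn <- as.vector(vapply(ids, function(id)
    paste0(c("logit_alpha", "beta", "gamma", "x0"), "[", id, "]"),
    character(4)))
  pn <- c(pn, c("theta_alpha", "sigma_alpha", "theta_beta", "sigma_beta",
                "theta_gamma", "sigma_gamma", "k", "sigma_ini",
                "sigma_mal", "nu"))
  arr <- array(NA_real_, dim = c(keep, chains, length(pn)),
               dimnames = list(NULL, paste0("chain", seq_len(chains)), pn))
  for (ch in seq_len(chains)) arr[, ch, ] <- draw_list[[ch]]$draws
  list(draws = arr)
}

fit_static_backend <- function(grid, model, prior, chains, warmup, keep,
                               thin, seed) {
  ## observations relative to each subject's first measurement
  obs_t <- list(); obs_y <- list(); c_init <- numeric(grid$S)
  for (i in seq_len(grid$S)) {
    w <- which(grid$has[i, ]) - 1L
    y <- grid$yobs[i, w + 1L]
    t0 <- min(w)
    obs_t[[i]] <- as.numeric(w - t0)
    obs_y[[i]] <- y
    c_init[i] <- if (model$form == "logistic")
      mal_sigmoid_inv(min(4.99, max(-4.99, y[1]))) else y[1]
  }
  len <- vapply(obs_t, length, integer(1))
  dat <- list(S = grid$S,
              obs_start = cumsum(c(0L, len[-grid$S])),
              obs_len = len,
              obs_t = unlist(obs_t), obs_y = unlist(obs_y),
              c_init = c_init)
  ## hierarchy on (c_i, d_i): weakly-informative defaults on the fitted
  ## scale; measurement priors shared with the dynamic model
  pc <- c(0, 5, 3, 2,          # theta_c N(0,5), sigma_c IG(3,2)
          0, 1, 4, 2,          # theta_d N(0,1), sigma_d IG(4,2)
          prior$sigma_mal, prior$nu)
  draw_list <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(as.integer(seed) + 1000L * (ch - 1L))
    hj <- c(stats::rnorm(1, mean(c_init), 0.5), exp(stats::runif(1, -0.5, 0.5)),
            stats::rnorm(1, 0, 0.05), 0.1 * exp(stats::runif(1, -0.5, 0.5)),
            0.25 * exp(stats::runif(1, -0.3, 0.3)),
            20 * exp(stats::runif(1, -0.3, 0.3)))
    cfg <- list(logistic = model$form == "logistic", warmup = warmup,
                keep = keep, thin = thin, prior_const = pc, h_init = hj)
    draw_list[[ch]] <- run_static_chain(dat, cfg)
  }
  pn <- as.vector(vapply(grid$subjects, function(id)
    paste0(c("c", "d"), "[", id, "]"), character(2)))
  pn <- c(pn, c("theta_c", "sigma_c", "theta_d", "sigma_d", "sigma_mal", "nu"))
  arr <- array(NA_real_, dim = c(keep, chains, length(pn)),
               dimnames = list(NULL, paste0("chain", seq_len(chains)), pn))
  for (ch in seq_len(chains)) arr[, ch, ] <- draw_list[[ch]]$draws
  list(draws = arr)
}

## flatten kept draws to (draws*chains) x npar
draw_matrix <- function(fit, pars = NULL) {
  d <- fit$draws
  m <- matrix(d, nrow = dim(d)[1] * dim(d)[2],
              dimnames = list(NULL, dimnames(d)[[3]]))
  if (!is.null(pars)) m[, pars, drop = FALSE] else m
}

hyper_par_names <- function(fit) {
  if (fit$model$static)
    c("theta_c", "sigma_c", "theta_d", "sigma_d", "sigma_mal", "nu")
  else {
    keep <- c("theta_alpha", "sigma_alpha")[rep(fit$model$use_a, 2)]
    keep <- c(keep, c("theta_beta", "sigma_beta")[rep(fit$model$use_b, 2)])
    keep <- c(keep, c("theta_gamma", "sigma_gamma")[rep(fit$model$use_g, 2)])
    keep <- c(keep, "k")
    if (!fit$model$shared) keep <- c(keep, "sigma_ini")
    if (!fit$model$hierarchical) keep <- character(0)
    c(keep, "sigma_mal", "nu")
  }
}

## names of parameters actually sampled (constant columns excluded)
sampled_par_names <- function(fit) {
  pn <- fit$par_names
  if (fit$model$static) return(pn)
  m <- fit$model
  drop <- character(0)
  if (!m$use_a) drop <- c(drop, grep("^logit_alpha\\[", pn, value = TRUE),
                          "theta_alpha", "sigma_alpha")
  if (!m$use_b) drop <- c(drop, grep("^beta\\[", pn, value = TRUE),
                          "theta_beta", "sigma_beta")
  if (!m$use_g) drop <- c(drop, grep("^gamma\\[", pn, value = TRUE),
                          "theta_gamma", "sigma_gamma")
  if (m$shared) drop <- c(drop, "sigma_ini", "x0[pop]")
  if (!m$hierarchical)
    drop <- c(drop, "theta_alpha", "sigma_alpha", "theta_beta", "sigma_beta",
              "theta_gamma", "sigma_gamma", "k", "sigma_ini")
  setdiff(pn, drop)
}
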