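#' Trajectory-draw containers for the qualitative analyses
#'
#' The dose-efficacy, efficiency, decay and threshold analyses operate
#' on sets of predicted-MAL trajectory draws.  `trajectory_draws()`
#' extracts them from a fitted model (posterior uncertainty);
#' `generative_trajectory_draws()` simulates them from the hierarchy at
#' given hyper-parameters (one unit per trial arm), which is how the
#' model's qualitative behaviour is probed without any fitting.
#'
#' @param fit An `"hbdm"` fit.
#' @param arms Optional arm label per subject (defaults to the truth
#'   labels when the fit was made from a [simulate_cohort()] cohort are
#'   not available, so `"all"`).
#' @return A list of class `"mal_trajectories"`: `draws` (per unit, a
#'   draws-by-weeks matrix of predicted MAL), `arm` (label per unit),
#'   `u` (weekly dose per unit), `dose_total` (nominal hours per unit)
#'   and `weeks`.
#' @export
trajectory_draws <- function(fit, arms = NULL) {
  stopifnot(inherits(fit, "hbdm"))
  S <- fit$grid$S
  dr <- lapply(seq_len(S), function(i) subject_m_draws(fit, i))
  names(dr) <- fit$grid$subjects
  arm <- arms %||% rep("all", S)
  dose <- vapply(seq_len(S), function(i) sum(fit$grid$u[i, ]), numeric(1))
  structure(list(draws = dr, arm = arm, u = fit$grid$u,
                 dose_total = dose, weeks = fit$grid$weeks),
            class = "mal_trajectories")
}

#' @rdname trajectory_draws
#' @param design A [trial_design()].
#' @param hyper [hyperparameters()] to draw subjects from.
#' @param n_draws Parameter draws per arm.
#' @param seed Seed.
#' @param mal_ini Baseline MAL used for every draw.
#' @export
generative_trajectory_draws <- function(design, hyper = hyperparameters(),
                                        n_draws = 500, seed = 1,
                                        mal_ini = 2) {
  stopifnot(inherits(design, "trial_design"))
  set.seed(as.integer(seed))
  n_arms <- length(design$arms)
  u <- matrix(0, n_arms, design$horizon)
  dr <- vector("list", n_arms)
  pars <- draw_subject_parameters(hyper, mal_ini, n_draws)
  for (a in seq_len(n_arms)) {
    sch <- make_dose_schedule(design, a)
    u[a, ] <- sch$hours
    m <- matrix(NA_real_, n_draws, design$horizon)
    for (r in seq_len(n_draws)) {
      m[r, ] <- forward_simulate(
        subject_parameters(pars$alpha[r], pars$beta[r], pars$gamma[r],
                           pars$x0[r]),
        sch, design$horizon)$m
    }
    dr[[a]] <- m
  }
  names(dr) <- names(design$arms)
  structure(list(draws = dr, arm = names(design$arms), u = u,
                 dose_total = vapply(design$arms, `[[`, numeric(1),
                                     "dose_total"),
                 weeks = seq_len(design$horizon) - 1L),
            class = "mal_trajectories")
}

#' @rdname trajectory_draws
#' @param cohort A `"mal_cohort"`; one unit per subject, a single
#'   deterministic trajectory computed from the ground-truth parameters.
#' @export
cohort_trajectories <- function(cohort) {
  stopifnot(inherits(cohort, "mal_cohort"))
  tr <- cohort$truth
  d <- cohort$design
  dr <- vector("list", nrow(tr))
  u <- matrix(0, nrow(tr), d$horizon)
  for (i in seq_len(nrow(tr))) {
    a <- match(tr$arm[i], names(d$arms))
    sch <- make_dose_schedule(d, a)
    u[i, ] <- sch$hours
    dr[[i]] <- matrix(forward_simulate(
      subject_parameters(tr$alpha[i], tr$beta[i], tr$gamma[i], tr$x0[i]),
      sch, d$horizon)$m, nrow = 1)
  }
  names(dr) <- tr$subject_id
  dose <- vapply(d$arms, `[[`, numeric(1), "dose_total")
  structure(list(draws = dr, arm = tr$arm, u = u,
                 dose_total = dose[match(tr$arm, names(d$arms))],
                 weeks = seq_len(d$horizon) - 1L),
            class = "mal_trajectories")
}

## mean across units of one draw-indexed column, robust to 1-draw units
pool_units <- function(lst) {
  m <- sapply(lst, identity)
  if (is.matrix(m)) rowMeans(m) else mean(m)
}

## bout bracketing weeks of unit i: pre = bout week, post = bout week + 1
unit_bouts <- function(traj, i) {
  b <- which(traj$u[i, ] > 0) - 1L
  if (!length(b))
    stop("unit has no training weeks (analysis error)", call. = FALSE)
  b
}

#' Short-term training efficacy
#'
#' Change in predicted MAL attributable to each training bout
#' (assessment immediately before the bout week vs immediately after),
#' and cumulatively from before the first bout to after the last, per
#' draw, summarised by arm.
#'
#' @param traj A `"mal_trajectories"` object.
#' @return List with `draws` (per unit: draws-by-(bouts + cumulative)
#'   matrix of MAL changes) and `summary` (arm, bout, median, q2.5,
#'   q97.5 of the within-arm mean change).
#' @export
efficacy <- function(traj) {
  stopifnot(inherits(traj, "mal_trajectories"))
  n <- length(traj$draws)
  Tmax <- length(traj$weeks)
  per <- vector("list", n)
  for (i in seq_len(n)) {
    b <- unit_bouts(traj, i)
    if (max(b) + 2L > Tmax)
      stop("trajectory too short to bracket the last bout (analysis error)",
           call. = FALSE)
    m <- traj$draws[[i]]
    ch <- sapply(b, function(w) m[, w + 2L] - m[, w + 1L])
    if (is.null(dim(ch))) ch <- matrix(ch, nrow = 1)
    cum <- m[, max(b) + 2L] - m[, min(b) + 1L]
    per[[i]] <- cbind(ch, cumulative = cum)
    colnames(per[[i]]) <- c(paste0("bout", seq_along(b)), "cumulative")
  }
  names(per) <- names(traj$draws)
  arms <- unique(traj$arm)
  rows <- NULL
  for (a in arms) {
    ii <- which(traj$arm == a)
    nb <- ncol(per[[ii[1]]])
    for (j in seq_len(nb)) {
      pool <- pool_units(lapply(ii, function(i) per[[i]][, j]))
      q <- stats::quantile(pool, c(0.025, 0.5, 0.975))
      rows <- rbind(rows, data.frame(arm = a,
                                     bout = colnames(per[[ii[1]]])[j],
                                     median = q[2], q2.5 = q[1], q97.5 = q[3]))
    }
  }
  rownames(rows) <- NULL
  list(draws = per, summary = rows)
}

#' Training efficiency (MAL change per hour)
#'
#' Divides the per-bout (and cumulative) efficacy draws by the nominal
#' training hours delivered; arms with zero nominal dose are excluded
#' with a notice.
#'
#' @param eff Result of [efficacy()].
#' @param traj The `"mal_trajectories"` the efficacy came from (carries
#'   the nominal doses).
#' @return Same shape as [efficacy()], in MAL change per hour.
#' @export
efficiency <- function(eff, traj) {
  stopifnot(inherits(traj, "mal_trajectories"))
  n <- length(eff$draws)
  per <- vector("list", n)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    total <- traj$dose_total[i]
    ## nominal dose excludes the 2 h/week of movement testing
    nb <- ncol(eff$draws[[i]]) - 1L
    nominal <- total
    if (nominal <= 0) {
      keep[i] <- FALSE
      next
    }
    div <- c(rep(nominal / nb, nb), nominal)
    per[[i]] <- sweep(eff$draws[[i]], 2, div, "/")
  }
  if (any(!keep))
    message("excluded zero-dose unit(s): ",
            paste(names(eff$draws)[!keep], collapse = ", "))
  per <- per[keep]
  names(per) <- names(eff$draws)[keep]
  arms <- unique(traj$arm[keep])
  rows <- NULL
  for (a in arms) {
    ii <- which(names(per) %in% names(eff$draws)[traj$arm == a])
    nbc <- ncol(per[[ii[1]]])
    for (j in seq_len(nbc)) {
      pool <- pool_units(lapply(ii, function(i) per[[i]][, j]))
      q <- stats::quantile(pool, c(0.025, 0.5, 0.975))
      rows <- rbind(rows, data.frame(arm = a, bout = colnames(per[[ii[1]]])[j],
                                     median = q[2], q2.5 = q[1], q97.5 = q[3]))
    }
  }
  rownames(rows) <- NULL
  list(draws = per, summary = rows)
}

#' Post-training decay profile
#'
#' Weekly MAL change over consecutive two-month (8-week) intervals
#' following the last training bout:
#' \eqn{(m_{end} - m_{start}) / 8} per interval and draw, summarised by
#' arm.  Negative values are decay; positive values indicate
#' self-training gains.
#'
#' @param traj A `"mal_trajectories"` object.
#' @param interval_weeks Interval length (default 8 = 2 months).
#' @param n_intervals Number of consecutive intervals (default 3 = 6
#'   months).
#' @return Data frame: arm, interval (1-based), start/end week, median
#'   and 95% CI of the weekly change.
#' @export
decay_profile <- function(traj, interval_weeks = 8L, n_intervals = 3L) {
  stopifnot(inherits(traj, "mal_trajectories"))
  Tmax <- length(traj$weeks)
  rows <- NULL
  for (a in unique(traj$arm)) {
    ii <- which(traj$arm == a)
    start0 <- max(unit_bouts(traj, ii[1])) + 1L
    if (start0 + n_intervals * interval_weeks > Tmax - 1L)
      stop("trajectory horizon shorter than ", n_intervals, " x ",
           interval_weeks, " weeks post-training (analysis error)",
           call. = FALSE)
    for (k in seq_len(n_intervals)) {
      w0 <- start0 + (k - 1L) * interval_weeks
      w1 <- w0 + interval_weeks
      pool <- pool_units(lapply(ii, function(i)
        (traj$draws[[i]][, w1 + 1L] - traj$draws[[i]][, w0 + 1L]) /
          interval_weeks))
      q <- stats::quantile(pool, c(0.025, 0.5, 0.975))
      rows <- rbind(rows, data.frame(arm = a, interval = k, start_week = w0,
                                     end_week = w1, median = q[2],
                                     q2.5 = q[1], q97.5 = q[3]))
    }
  }
  rownames(rows) <- NULL
  rows
}

#' Self-training threshold regression
#'
#' Linear regression of the weekly post-training MAL change on the mean
#' post-training MAL with dose as a factor (dose-specific intercepts,
#' common slope).  Where the slope is positive, the dose-specific
#' threshold is the MAL at which the predicted change crosses zero:
#' above it the MAL keeps improving without supervised training, below
#' it the MAL decays.
#'
#' @param weekly_change Weekly MAL change per unit (post-training to 6
#'   months post-training).
#' @param mal_post Mean post-training MAL per unit.
#' @param dose Dose label per unit (coerced to factor; needs >= 2
#'   levels unless a single level is supplied deliberately).
#' @return List of class `"threshold_fit"`: the `lm` fit,
#'   `coefficients`, `slope`, and `thresholds` (per dose, with status
#'   `"ok"`, `"below_range"` or `"above_range"` relative to the 0--5
#'   scale).
#' @export
threshold_regression <- function(weekly_change, mal_post, dose) {
  if (length(weekly_change) != length(mal_post) ||
      length(weekly_change) != length(dose))
    stop("inputs must have equal length", call. = FALSE)
  dose <- factor(dose)
  df <- data.frame(change = weekly_change, mal = mal_post, dose = dose)
  fit <- if (nlevels(dose) > 1L)
    stats::lm(change ~ mal + dose, data = df)
  else stats::lm(change ~ mal, data = df)
  if (any(!is.finite(stats::coef(fit))))
    stop("degenerate regression design (fit error)", call. = FALSE)
  cf <- stats::coef(fit)
  slope <- cf[["mal"]]
  lev <- levels(dose)
  ints <- cf[[1]] + c(0, if (nlevels(dose) > 1L)
    cf[paste0("dose", lev[-1])] else NULL)
  names(ints) <- lev
  thr <- -ints / slope
  status <- rep("ok", length(thr))
  status[slope <= 0] <- "no_positive_slope"
  status[slope > 0 & thr < 0] <- "below_range"
  status[slope > 0 & thr > 5] <- "above_range"
  structure(list(fit = fit, coefficients = cf, slope = slope,
                 thresholds = data.frame(dose = lev, threshold = unname(thr),
                                         status = status)),
            class = "threshold_fit")
}

#' Threshold analysis of trajectory draws
#'
#' Convenience wrapper computing, per unit, the posterior-median weekly
#' post-training change and mean post-training MAL, then calling
#' [threshold_regression()] with the arm as the dose factor.
#'
#' @param traj A `"mal_trajectories"` object.
#' @param horizon_weeks Post-training window (default 24 weeks = 6
#'   months).
#' @return A `"threshold_fit"`.
#' @export
threshold_analysis <- function(traj, horizon_weeks = 24L) {
  stopifnot(inherits(traj, "mal_trajectories"))
  n <- length(traj$draws)
  ch <- mal <- numeric(n)
  for (i in seq_len(n)) {
    start0 <- max(unit_bouts(traj, i)) + 1L
    end0 <- min(start0 + horizon_weeks, length(traj$weeks) - 1L)
    med <- apply(traj$draws[[i]], 2, stats::median)
    ch[i] <- (med[end0 + 1L] - med[start0 + 1L]) / (end0 - start0)
    mal[i] <- mean(med[(start0:end0) + 1L])
  }
  threshold_regression(ch, mal, traj$arm)
}

#' Bootstrap confidence intervals for parameter correlations
#'
#' Percentile-bootstrap 95% CIs (default 5000 resamples over subjects)
#' of the pairwise Pearson correlations between subject-level posterior
#' medians of the retention, learning and self-training rates.
#'
#' @param params Data frame with columns `alpha`, `beta`, `gamma`
#'   (e.g. from [coef.hbdm()]), or any numeric data frame whose
#'   pairwise correlations are wanted.
#' @param n_boot Bootstrap iterations.
#' @param seed Seed.
#' @return Data frame: `pair`, `r` (sample correlation), `lo`, `hi`
#'   (95% percentile CI), `boot_mean`.
#' @export
bootstrap_correlations <- function(params, n_boot = 5000, seed = 1) {
  cols <- intersect(c("alpha", "beta", "gamma"), names(params))
  if (length(cols) < 2L) cols <- names(params)[vapply(params, is.numeric,
                                                      logical(1))]
  x <- as.data.frame(params)[, cols, drop = FALSE]
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 subjects", call. = FALSE)
  if (any(vapply(x, function(v) stats::var(v) == 0, logical(1)))) {
    warning("constant parameter column: correlation undefined", call. = FALSE)
  }
  set.seed(as.integer(seed))
  pairs <- utils::combn(cols, 2)
  res <- NULL
  for (j in seq_len(ncol(pairs))) {
    a <- x[[pairs[1, j]]]; b <- x[[pairs[2, j]]]
    if (stats::var(a) == 0 || stats::var(b) == 0) {
      res <- rbind(res, data.frame(pair = paste(pairs[, j], collapse = "-"),
                                   r = NA, lo = NA, hi = NA, boot_mean = NA))
      next
    }
    r <- stats::cor(a, b)
    bs <- vapply(seq_len(n_boot), function(k) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::var(a[idx]) == 0 || stats::var(b[idx]) == 0) return(NA_real_)
      stats::cor(a[idx], b[idx])
    }, numeric(1))
    bs <- bs[is.finite(bs)]
    ci <- stats::quantile(bs, c(0.025, 0.975))
    res <- rbind(res, data.frame(pair = paste(pairs[, j], collapse = "-"),
                                 r = r, lo = unname(ci[1]), hi = unname(ci[2]),
                                 boot_mean = mean(bs)))
  }
  rownames(res) <- NULL
  res
}
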