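#' @export
print.hbdm <- function(x, ...) {
  m <- x$model
  form <- if (m$static) paste0("static ", m$form)
          else paste0("dynamic ", m$form,
                      if (!m$hierarchical) " (non-hierarchical)" else "")
  cat("Hierarchical Bayesian dynamic MAL model\n")
  cat("  structure: ", form, "\n", sep = "")
  cat("  subjects: ", x$grid$S, "   weekly grid: 0 .. ", x$grid$Tmax - 1L,
      "   observations: ", sum(x$grid$has), "\n", sep = "")
  cat("  chains: ", x$chains, "   kept draws/chain: ", dim(x$draws)[1],
      " (iter ", x$iter, ", warmup ", x$warmup, ", thin ", x$thin, ")\n",
      sep = "")
  cat("  sampler: ", x$backend, "   seed: ", x$seed,
      "   elapsed: ", sprintf("%.1fs", x$time), "\n", sep = "")
  cat("  max rank-normalised split R-hat: ",
      format(max(x$rhat), digits = 4), "\n", sep = "")
  hp <- hyper_par_names(x)
  if (length(hp)) {
    cat("\nPopulation-level posterior (median [95% CI]):\n")
    s <- summary(x, pars = hp, diagnostics = FALSE)
    for (i in seq_len(nrow(s)))
      cat(sprintf("  %-12s %8.3f [%8.3f, %8.3f]\n", s$parameter[i],
                  s$median[i], s$q2.5[i], s$q97.5[i]))
  }
  invisible(x)
}

#' Posterior summary of a fitted model
#'
#' @param object An `"hbdm"` fit.
#' @param pars Parameters to summarise (default: all sampled).
#' @param probs Quantiles to report in addition to the fixed 2.5/50/97.5
#'   and 0.5/99.5 percent levels.
#' @param diagnostics Include R-hat and ESS columns?
#' @param ... Unused.
#' @return Data frame with one row per parameter: posterior mean, sd,
#'   median, 95% and 99% credible limits, plus diagnostics.
#' @export
summary.hbdm <- function(object, pars = NULL, probs = NULL,
                         diagnostics = TRUE, ...) {
  pars <- pars %||% sampled_par_names(object)
  dm <- draw_matrix(object, pars)
  qs <- apply(dm, 2, stats::quantile,
              probs = c(0.005, 0.025, 0.5, 0.975, 0.995))
  res <- data.frame(parameter = pars,
                    mean = colMeans(dm),
                    sd = apply(dm, 2, stats::sd),
                    median = qs[3, ],
                    q0.5 = qs[1, ], q2.5 = qs[2, ],
                    q97.5 = qs[4, ], q99.5 = qs[5, ],
                    row.names = NULL)
  if (!is.null(probs)) {
    extra <- apply(dm, 2, stats::quantile, probs = probs)
    if (is.null(dim(extra))) extra <- matrix(extra, nrow = 1)
    for (i in seq_along(probs))
      res[[paste0("q", 100 * probs[i])]] <- extra[i, ]
  }
  if (diagnostics) {
    res$rhat <- unname(object$rhat[pars])
    res$ess_bulk <- unname(ess_bulk(object, pars))
    res$ess_tail <- unname(ess_tail(object, pars))
  }
  res
}

#' Subject-level posterior medians
#'
#' @param object An `"hbdm"` fit.
#' @param ... Unused.
#' @return For dynamic fits, a data frame with per-subject posterior
#'   medians of `alpha` (back-transformed from the logit scale),
#'   `beta`, `gamma` and `x0`; for static fits, medians of `c` and `d`.
#'   Population-level medians are attached as attribute `"population"`.
#' @export
coef.hbdm <- function(object, ...) {
  dm <- draw_matrix(object)
  med <- apply(dm, 2, stats::median)
  ids <- object$grid$subjects
  if (object$model$static) {
    res <- data.frame(subject_id = ids,
                      c = unname(med[paste0("c[", ids, "]")]),
                      d = unname(med[paste0("d[", ids, "]")]))
  } else if (object$model$shared) {
    res <- data.frame(subject_id = "pop",
                      alpha = stats::plogis(unname(med["logit_alpha[pop]"])),
                      beta = unname(med["beta[pop]"]),
                      gamma = unname(med["gamma[pop]"]))
  } else {
    res <- data.frame(
      subject_id = ids,
      alpha = stats::plogis(unname(med[paste0("logit_alpha[", ids, "]")])),
      beta = unname(med[paste0("beta[", ids, "]")]),
      gamma = unname(med[paste0("gamma[", ids, "]")]),
      x0 = unname(med[paste0("x0[", ids, "]")]))
    if (!object$model$use_a) res$alpha <- 1
    if (!object$model$use_b) res$beta <- 0
    if (!object$model$use_g) res$gamma <- 0
  }
  attr(res, "population") <- med[hyper_par_names(object)]
  res
}

## posterior draws of the predicted MAL for one subject (draws x weeks)
subject_m_draws <- function(fit, subject, schedule_hours = NULL) {
  idx <- if (is.character(subject)) match(subject, fit$grid$subjects)
         else as.integer(subject)
  if (is.na(idx) || idx < 1L || idx > fit$grid$S)
    stop("unknown subject", call. = FALSE)
  dm <- draw_matrix(fit)
  dat <- list(S = fit$grid$S, Tmax = fit$grid$Tmax, u = fit$grid$u,
              mal_ini = fit$grid$mal_ini)
  if (!is.null(schedule_hours)) {
    if (length(schedule_hours) != fit$grid$Tmax)
      stop("`schedule_hours` must cover the full weekly grid", call. = FALSE)
    u2 <- dat$u
    u2[idx, ] <- schedule_hours
    dat$u <- u2
  }
  if (fit$model$static) {
    w <- which(fit$grid$has[idx, ]) - 1L
    t0 <- min(w)
    tt <- fit$grid$weeks - t0
    id <- fit$grid$subjects[idx]
    eta <- outer(dm[, paste0("d[", id, "]")], tt) + dm[, paste0("c[", id, "]")]
    if (fit$model$form == "logistic") mal_sigmoid(eta) else eta
  } else {
    cfg <- list(use_a = fit$model$use_a, use_b = fit$model$use_b,
                use_g = fit$model$use_g, shared = fit$model$shared)
    m_draws_cpp(dm, dat, cfg, idx)
  }
}

#' Posterior predicted-MAL trajectories
#'
#' Posterior quantiles (and optionally raw draws) of the predicted MAL
#' \eqn{m} for selected subjects on the full weekly grid.  Supplying
#' `schedule_hours` replaces a subject's dose schedule, turning the
#' fitted model into a counterfactual simulator of alternative dosing.
#'
#' @param object An `"hbdm"` fit.
#' @param subjects Subject ids or indices (default: all).
#' @param probs Quantiles of the posterior trajectory to report.
#' @param schedule_hours Optional replacement weekly dose vector
#'   (length `Tmax`), applied to every requested subject.
#' @param draws Return the raw draws instead of quantiles?
#' @param ... Unused.
#' @return If `draws = FALSE` a long data frame (`subject_id`, `week`,
#'   one column per quantile); otherwise a named list of
#'   draws-by-weeks matrices.
#' @export
predict.hbdm <- function(object, subjects = NULL,
                         probs = c(0.025, 0.5, 0.975),
                         schedule_hours = NULL, draws = FALSE, ...) {
  subjects <- subjects %||% object$grid$subjects
  if (is.numeric(subjects)) subjects <- object$grid$subjects[subjects]
  if (draws) {
    out <- lapply(subjects, function(s)
      subject_m_draws(object, s, schedule_hours))
    names(out) <- subjects
    return(out)
  }
  res <- lapply(subjects, function(s) {
    md <- subject_m_draws(object, s, schedule_hours)
    q <- apply(md, 2, stats::quantile, probs = probs)
    if (is.null(dim(q))) q <- matrix(q, nrow = 1)
    df <- data.frame(subject_id = s, week = object$grid$weeks)
    for (i in seq_along(probs)) df[[paste0("q", 100 * probs[i])]] <- q[i, ]
    df
  })
  do.call(rbind, res)
}

#' Posterior-median fitted MAL values
#'
#' @param object An `"hbdm"` fit.
#' @param ... Unused.
#' @return Long data frame (`subject_id`, `week`, `mal_obs`, `fitted`)
#'   restricted to observed weeks.
#' @export
fitted.hbdm <- function(object, ...) {
  pr <- predict(object, probs = 0.5)
  res <- NULL
  for (i in seq_len(object$grid$S)) {
    w <- which(object$grid$has[i, ]) - 1L
    id <- object$grid$subjects[i]
    f <- pr$q50[pr$subject_id == id][w + 1L]
    res <- rbind(res, data.frame(subject_id = id, week = w,
                                 mal_obs = object$grid$yobs[i, w + 1L],
                                 fitted = f))
  }
  res
}

#' Residuals of the posterior-median fit
#'
#' @param object An `"hbdm"` fit.
#' @param ... Unused.
#' @return Long data frame with `residual = mal_obs - fitted`.
#' @export
residuals.hbdm <- function(object, ...) {
  f <- fitted(object)
  f$residual <- f$mal_obs - f$fitted
  f
}

#' Posterior-predictive MAL replicates
#'
#' Draws replicated MAL observations at the observed (subject, week)
#' cells: a random posterior draw's predicted MAL plus Student-t
#' measurement noise from the same draw, clipped to `[0, 5]`.
#'
#' @param object An `"hbdm"` fit.
#' @param nsim Number of replicate data sets.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `nsim` data frames shaped like
#'   `fitted(object)`.
#' @export
simulate.hbdm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  dm <- draw_matrix(object)
  n <- nrow(dm)
  out <- vector("list", nsim)
  obs <- fitted(object)[, c("subject_id", "week")]
  for (s in seq_len(nsim)) {
    r <- sample.int(n, 1)
    rows <- NULL
    for (i in seq_len(object$grid$S)) {
      id <- object$grid$subjects[i]
      md <- subject_m_draws(object, i)[r, ]
      w <- which(object$grid$has[i, ]) - 1L
      m <- md[w + 1L]
      y <- pmin(5, pmax(0, m + dm[r, "sigma_mal"] *
                          stats::rt(length(m), df = dm[r, "nu"])))
      rows <- rbind(rows, data.frame(subject_id = id, week = w, mal = y))
    }
    out[[s]] <- rows
  }
  out
}

#' Plot observed and fitted MAL trajectories
#'
#' Base-graphics panel per subject: observed MAL (points), posterior
#' median trajectory (line) and a 95% credible band (shading).
#'
#' @param x An `"hbdm"` fit.
#' @param subjects Subjects to show (default: first 4).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hbdm <- function(x, subjects = NULL, ...) {
  subjects <- subjects %||% utils::head(x$grid$subjects, 4L)
  if (is.numeric(subjects)) subjects <- x$grid$subjects[subjects]
  n <- length(subjects)
  nc <- ceiling(sqrt(n)); nr <- ceiling(n / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  pr <- predict(x, subjects = subjects)
  for (s in subjects) {
    i <- match(s, x$grid$subjects)
    ps <- pr[pr$subject_id == s, ]
    graphics::plot(ps$week, ps$q50, type = "n", ylim = c(0, 5),
                   xlab = "week", ylab = "MAL", main = s, ...)
    graphics::polygon(c(ps$week, rev(ps$week)), c(ps$q2.5, rev(ps$q97.5)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(ps$week, ps$q50, col = "steelblue4", lwd = 2)
    w <- which(x$grid$has[i, ]) - 1L
    graphics::points(w, x$grid$yobs[i, w + 1L], pch = 19, cex = 0.7)
  }
  invisible(x)
}
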