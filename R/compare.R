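#' Pointwise log-likelihood matrix
#'
#' Student-t log-density of every non-missing MAL observation under
#' every posterior draw's predicted trajectory; the draws-by-
#' observations matrix underlying WAIC and PSIS-LOO.  Observation
#' columns are ordered by subject (grid order) and week.
#'
#' @param fit An `"hbdm"` fit.
#' @return Matrix (total kept draws) x (observations), with attribute
#'   `"obs"` giving the (subject_id, week, mal) of each column.
#' @export
pointwise_loglik <- function(fit) {
  stopifnot(inherits(fit, "hbdm"))
  dm <- draw_matrix(fit)
  grid <- fit$grid
  obs_info <- NULL
  for (i in seq_len(grid$S)) {
    w <- which(grid$has[i, ]) - 1L
    obs_info <- rbind(obs_info,
                      data.frame(subject_id = grid$subjects[i], week = w,
                                 mal = grid$yobs[i, w + 1L]))
  }
  if (fit$model$static) {
    ll <- matrix(NA_real_, nrow(dm), nrow(obs_info))
    col <- 0L
    for (i in seq_len(grid$S)) {
      id <- grid$subjects[i]
      w <- which(grid$has[i, ]) - 1L
      t0 <- min(w)
      eta <- outer(dm[, paste0("d[", id, "]")], w - t0) + dm[, paste0("c[", id, "]")]
      m <- if (fit$model$form == "logistic") mal_sigmoid(eta) else eta
      y <- grid$yobs[i, w + 1L]
      for (j in seq_along(w)) {
        col <- col + 1L
        ll[, col] <- dstudent_t(y[j], m[, j], dm[, "sigma_mal"], dm[, "nu"],
                                log = TRUE)
      }
    }
  } else {
    dat <- list(S = grid$S, Tmax = grid$Tmax, u = grid$u, yobs = grid$yobs,
                has = grid$has, mal_ini = grid$mal_ini)
    cfg <- list(use_a = fit$model$use_a, use_b = fit$model$use_b,
                use_g = fit$model$use_g, shared = fit$model$shared)
    ll <- pointwise_ll_cpp(dm, dat, cfg)
  }
  attr(ll, "obs") <- obs_info
  ll
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Widely applicable information criterion
#'
#' WAIC estimates the expected log pointwise predictive density and
#' penalises it by the effective number of parameters
#' (`p_waic`, the posterior variance of the pointwise log-likelihood).
#' Reported on the deviance scale (`waic = -2 * elpd_waic`; lower is
#' better) alongside the log-scale quantities.
#'
#' @param x A draws-by-observations log-likelihood matrix (e.g. from
#'   [pointwise_loglik()]) or an `"hbdm"` fit.
#' @return A list of class `"hbdm_waic"`: `waic`, `elpd_waic`,
#'   `p_waic`, standard error `se_elpd_waic`, and the pointwise elpd
#'   contributions.
#' @export
waic <- function(x) {
  ll <- if (inherits(x, "hbdm")) pointwise_loglik(x) else x
  if (!is.matrix(ll)) stop("need a draws x observations matrix", call. = FALSE)
  if (nrow(ll) < 2L)
    stop("WAIC needs at least 2 posterior draws (diagnostic error)",
         call. = FALSE)
  S <- nrow(ll)
  lppd <- apply(ll, 2, log_sum_exp) - log(S)
  p_i <- apply(ll, 2, stats::var)
  elpd_i <- lppd - p_i
  structure(list(waic = -2 * sum(elpd_i),
                 elpd_waic = sum(elpd_i),
                 p_waic = sum(p_i),
                 se_elpd_waic = sqrt(ncol(ll) * stats::var(elpd_i)),
                 pointwise = data.frame(lppd = lppd, p_waic = p_i,
                                        elpd_waic = elpd_i)),
            class = "hbdm_waic")
}

#' @export
print.hbdm_waic <- function(x, ...) {
  cat(sprintf("WAIC %.1f (deviance scale)  elpd_waic %.1f  p_waic %.1f  se %.1f\n",
              x$waic, x$elpd_waic, x$p_waic, x$se_elpd_waic))
  invisible(x)
}

## Zhang-Stephens posterior-mean fit of the generalised Pareto shape and
## scale to sorted exceedances, with the small-sample shape regularisation
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5L || x[n] <= 0) return(list(k = NA_real_, sigma = NA_real_))
  prior_bs <- 3
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior_bs * xstar)
  theta <- theta[theta > 0 | theta < 1 / x[n]]   # keep valid support
  kfun <- vapply(theta, function(b) -mean(log1p(-b * x)), numeric(1))
  ok <- is.finite(kfun) & kfun > 0
  theta <- theta[ok]; kfun <- kfun[ok]
  if (!length(theta)) return(list(k = NA_real_, sigma = NA_real_))
  l_theta <- n * (log(theta / kfun) + kfun - 1)
  w <- exp(l_theta - log_sum_exp(l_theta))
  theta_hat <- sum(theta * w)
  k <- -mean(log1p(-theta_hat * x))
  sigma <- k / theta_hat
  ## weakly-informative shape regularisation towards 0.5
  k <- (n * k + 5) / (n + 10)
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) -sigma * log1p(-p)
  else sigma / k * ((1 - p)^(-k) - 1)
}

## Pareto-smooth one vector of log importance ratios; returns the
## smoothed log-weights (max-normalised, truncated at 0) and the shape k
psis_smooth <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (S < 16L || M < 5L) return(list(lw = lw, k = NA_real_))
  ord <- order(lw)
  cutoff <- lw[ord[S - M]]
  tail_ids <- ord[(S - M + 1L):S]
  exp_cut <- exp(cutoff)
  exceed <- exp(lw[tail_ids]) - exp_cut
  if (max(exceed) <= 0) return(list(lw = lw, k = 0))
  fit <- gpd_fit(exceed)
  if (is.finite(fit$k) && is.finite(fit$sigma) && fit$sigma > 0) {
    p <- (seq_len(M) - 0.5) / M
    smoothed <- log(qgpd(p, fit$k, fit$sigma) + exp_cut)
    lw[tail_ids[order(lw[tail_ids])]] <- smoothed
  }
  lw <- pmin(lw, 0)
  list(lw = lw, k = fit$k)
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Estimates the expected log pointwise predictive density under
#' leave-one-out cross-validation from a single posterior sample: the
#' importance ratios \eqn{1/p(y_i \mid \theta^{(s)})} are stabilised by
#' replacing their largest values with quantiles of a fitted
#' generalised Pareto distribution.  The per-observation Pareto shape
#' `k` diagnoses reliability; observations with `k > 0.7` are flagged.
#'
#' @param x A draws-by-observations log-likelihood matrix or an
#'   `"hbdm"` fit.
#' @return A list of class `"hbdm_loo"`: `elpd_loo`, `se_elpd_loo`,
#'   `p_loo`, `pointwise` elpd values, `pareto_k` per observation and
#'   `n_flagged` (k > 0.7).
#' @export
psis_loo <- function(x) {
  ll <- if (inherits(x, "hbdm")) pointwise_loglik(x) else x
  if (!is.matrix(ll)) stop("need a draws x observations matrix", call. = FALSE)
  S <- nrow(ll)
  if (S < 100L)
    warning("PSIS-LOO with fewer than 100 draws is unreliable", call. = FALSE)
  n <- ncol(ll)
  elpd_i <- numeric(n)
  k_i <- numeric(n)
  for (j in seq_len(n)) {
    sm <- psis_smooth(-ll[, j])
    elpd_i[j] <- log_sum_exp(sm$lw + ll[, j]) - log_sum_exp(sm$lw)
    k_i[j] <- sm$k
  }
  lppd <- apply(ll, 2, log_sum_exp) - log(S)
  structure(list(elpd_loo = sum(elpd_i),
                 se_elpd_loo = sqrt(n * stats::var(elpd_i)),
                 p_loo = sum(lppd - elpd_i),
                 pointwise = data.frame(elpd_loo = elpd_i, pareto_k = k_i),
                 pareto_k = k_i,
                 n_flagged = sum(is.finite(k_i) & k_i > 0.7)),
            class = "hbdm_loo")
}

#' @export
print.hbdm_loo <- function(x, ...) {
  cat(sprintf("elpd_loo %.1f  se %.1f  p_loo %.1f\n",
              x$elpd_loo, x$se_elpd_loo, x$p_loo))
  if (x$n_flagged)
    cat("  ", x$n_flagged, "observation(s) with Pareto k > 0.7\n")
  invisible(x)
}

#' Rank models by predictive accuracy
#'
#' Ranks fitted models by `elpd_loo`; for each non-best model reports
#' the difference to the best (`elpd_diff`, computed from the pointwise
#' elpd values of the shared observation set), its standard error and
#' 95% confidence interval under normality, and
#' `Pr(better) = Phi(elpd_diff / se_diff)` -- the probability that the
#' model beats the best one.  WAIC (deviance scale) is reported
#' alongside.
#'
#' @param ... Named `"hbdm"` fits, or a single named list of fits.
#'   All models must be fitted to the identical observation set.
#' @return A data frame of class `"hbdm_comparison"` ranked by
#'   `elpd_loo`: `model`, `waic`, `p_waic`, `elpd_loo`, `se_elpd_loo`,
#'   `elpd_diff`, `se_diff`, `ci_lower`, `ci_upper`, `pr_better`,
#'   `max_pareto_k`.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1]], "hbdm")) fits <- fits[[1]]
  if (length(fits) < 2L)
    stop("need at least 2 models to compare", call. = FALSE)
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- paste0("model", seq_along(fits))
  lls <- lapply(fits, function(f)
    if (inherits(f, "hbdm")) pointwise_loglik(f) else f)
  ncols <- vapply(lls, ncol, integer(1))
  if (length(unique(ncols)) != 1L)
    stop("models were fitted to different observation sets (comparison error)",
         call. = FALSE)
  obs_sets <- lapply(lls, function(l) attr(l, "obs"))
  if (!is.null(obs_sets[[1]])) {
    same <- vapply(obs_sets[-1], function(o)
      is.null(o) || isTRUE(all.equal(o, obs_sets[[1]])), logical(1))
    if (!all(same))
      stop("models were fitted to different observation sets (comparison error)",
           call. = FALSE)
  }
  loos <- lapply(lls, psis_loo)
  waics <- lapply(lls, waic)
  elpd <- vapply(loos, `[[`, numeric(1), "elpd_loo")
  best <- which.max(elpd)
  n <- ncols[1]
  res <- data.frame(
    model = names(fits),
    waic = vapply(waics, `[[`, numeric(1), "waic"),
    p_waic = vapply(waics, `[[`, numeric(1), "p_waic"),
    elpd_loo = elpd,
    se_elpd_loo = vapply(loos, `[[`, numeric(1), "se_elpd_loo"),
    max_pareto_k = vapply(loos, function(l)
      suppressWarnings(max(l$pareto_k, na.rm = TRUE)), numeric(1)),
    row.names = NULL)
  diff_stats <- t(vapply(seq_along(fits), function(i) {
    if (i == best) return(c(0, 0, 0, 0, 0.5))
    d_i <- loos[[i]]$pointwise$elpd_loo - loos[[best]]$pointwise$elpd_loo
    ed <- sum(d_i)
    se <- sqrt(n * stats::var(d_i))
    c(ed, se, ed - 1.96 * se, ed + 1.96 * se, pr_better(ed, se))
  }, numeric(5)))
  res$elpd_diff <- diff_stats[, 1]
  res$se_diff <- diff_stats[, 2]
  res$ci_lower <- diff_stats[, 3]
  res$ci_upper <- diff_stats[, 4]
  res$pr_better <- diff_stats[, 5]
  res <- res[order(-res$elpd_loo), ]
  rownames(res) <- NULL
  class(res) <- c("hbdm_comparison", "data.frame")
  res
}

#' Normal-approximation probability that a model beats the best
#'
#' @param elpd_diff Difference in `elpd_loo` to the best model
#'   (nonpositive by construction).
#' @param se_diff Standard error of the difference.
#' @return `Phi(elpd_diff / se_diff)`, or 0.5 when both are zero (a
#'   model compared with itself).
#' @export
pr_better <- function(elpd_diff, se_diff) {
  ifelse(se_diff > 0, stats::pnorm(elpd_diff / se_diff),
         ifelse(elpd_diff == 0, 0.5, as.numeric(elpd_diff > 0)))
}

#' @export
print.hbdm_comparison <- function(x, digits = 1, ...) {
  cat("Model comparison (ranked by elpd_loo; elpd_diff vs best)\n")
  print.data.frame(cbind(x["model"],
                         round(x[, c("waic", "elpd_loo", "elpd_diff",
                                     "se_diff")], digits),
                         pr_better = signif(x$pr_better, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
`[.hbdm_comparison` <- function(x, ...) {
  y <- NextMethod()
  if (is.data.frame(y)) class(y) <- "data.frame"
  y
}
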