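## -- rank-normalised split R-hat and effective sample size ------------------
## Implements the "improved" convergence diagnostics: draws are rank-
## normalised (with the usual Blom offset), chains are split in half, and
## the classic potential-scale-reduction / autocorrelation machinery is
## applied on the transformed scale.  The reported R-hat is the maximum of
## the bulk (rank-normalised) and folded (median-absolute-deviation)
## statistics.  Constant chains are reported as R-hat 1 by convention.

z_scale <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

split_chains <- function(mat) {
  n <- nrow(mat)
  half <- n %/% 2L
  cbind(mat[seq_len(half), , drop = FALSE],
        mat[(n - half + 1L):n, , drop = FALSE])
}

rhat_basic <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  if (n < 2L) return(NA_real_)
  mu <- colMeans(mat)
  v <- apply(mat, 2, stats::var)
  W <- mean(v)
  B <- n * stats::var(mu)
  if (!is.finite(W) || W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

rhat_matrix <- function(mat) {
  if (stats::var(as.numeric(mat)) == 0) return(1)      # degenerate: constant
  sp <- split_chains(mat)
  zb <- matrix(z_scale(as.numeric(sp)), nrow(sp), ncol(sp))
  folded <- abs(sp - stats::median(sp))
  zf <- matrix(z_scale(as.numeric(folded)), nrow(sp), ncol(sp))
  max(rhat_basic(zb), rhat_basic(zf))
}

ess_basic <- function(mat) {
  n <- nrow(mat); m <- ncol(mat)
  if (n < 4L) return(NA_real_)
  v <- apply(mat, 2, stats::var)
  W <- mean(v)
  if (!is.finite(W) || W == 0) return(m)               # constant chains
  mu <- colMeans(mat)
  varp <- (n - 1) / n * W + if (m > 1) n * stats::var(mu) / n else 0
  ## mean autocovariance across chains (FFT-free; n is modest)
  maxlag <- n - 2L
  acov <- matrix(0, maxlag + 1L, m)
  for (j in seq_len(m)) {
    xc <- mat[, j] - mu[j]
    a <- stats::acf(xc, lag.max = maxlag, type = "covariance",
                    plot = FALSE, demean = FALSE)$acf[, 1, 1]
    acov[, j] <- a
  }
  rho <- 1 - (W - rowMeans(acov)) / varp
  rho[1] <- 1
  ## Geyer initial monotone positive sequence over lag pairs
  tau <- 0
  prev <- Inf
  t <- 1L
  while (t + 1L <= length(rho)) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    pair <- min(pair, prev)
    prev <- pair
    tau <- tau + pair
    t <- t + 2L
  }
  tau <- 2 * tau - 1  # tau = -1 + 2 * sum of pair sums (rho_0 counted once)
  tau <- max(tau, 1 / log10(n))
  min(n * m / tau, n * m)
}

as_draw_array <- function(x, pars = NULL) {
  if (inherits(x, "hbdm")) {
    pars <- pars %||% sampled_par_names(x)
    x$draws[, , pars, drop = FALSE]
  } else if (is.array(x) && length(dim(x)) == 3L) {
    if (!is.null(pars)) x[, , pars, drop = FALSE] else x
  } else if (is.matrix(x)) {
    array(x, dim = c(nrow(x), ncol(x), 1L),
          dimnames = list(NULL, NULL, "par"))
  } else {
    stop("expected an `hbdm` fit, a draws array or an iterations x chains matrix",
         call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rank-normalised split R-hat
#'
#' The improved potential-scale-reduction diagnostic: chains are split
#' in half, draws are rank-normalised, and the larger of the bulk and
#' folded (tail-sensitive) statistics is reported.  Values below 1.01
#' indicate adequate mixing; identical constant chains report exactly 1.
#'
#' @param x An `"hbdm"` fit, a 3-d draws array (iterations, chains,
#'   parameters), or an iterations-by-chains matrix for one parameter.
#' @param pars Optional parameter subset.
#' @return Named numeric vector of R-hat values (a scalar for a matrix
#'   input).
#' @export
rhat <- function(x, pars = NULL) {
  a <- as_draw_array(x, pars)
  if (dim(a)[2] < 2L)
    stop("R-hat needs at least 2 chains (diagnostic error)", call. = FALSE)
  if (dim(a)[1] < 4L)
    stop("R-hat needs at least 4 draws per chain (diagnostic error)",
         call. = FALSE)
  out <- apply(a, 3, rhat_matrix)
  if (length(out) == 1L && is.matrix(x)) unname(out) else out
}

#' Bulk effective sample size
#'
#' Effective number of independent draws for location summaries,
#' computed on the rank-normalised split chains with Geyer's initial
#' monotone sequence estimator of the autocorrelation time.
#'
#' @inheritParams rhat
#' @return Named numeric vector of ESS values.
#' @export
ess_bulk <- function(x, pars = NULL) {
  a <- as_draw_array(x, pars)
  out <- apply(a, 3, function(mat) {
    if (stats::var(as.numeric(mat)) == 0) return(ncol(split_chains(mat)))
    sp <- split_chains(mat)
    zb <- matrix(z_scale(as.numeric(sp)), nrow(sp), ncol(sp))
    ess_basic(zb)
  })
  if (length(out) == 1L && is.matrix(x)) unname(out) else out
}

#' Tail effective sample size
#'
#' Minimum of the effective sample sizes of the 5% and 95% quantile
#' indicator functions; sensitive to poor mixing in the tails.
#'
#' @inheritParams rhat
#' @return Named numeric vector of ESS values.
#' @export
ess_tail <- function(x, pars = NULL) {
  a <- as_draw_array(x, pars)
  out <- apply(a, 3, function(mat) {
    if (stats::var(as.numeric(mat)) == 0) return(ncol(split_chains(mat)))
    sp <- split_chains(mat)
    q <- stats::quantile(sp, c(0.05, 0.95), names = FALSE)
    ess05 <- ess_basic(matrix(as.numeric(sp <= q[1]), nrow(sp), ncol(sp)))
    ess95 <- ess_basic(matrix(as.numeric(sp <= q[2]), nrow(sp), ncol(sp)))
    min(ess05, ess95)
  })
  if (length(out) == 1L && is.matrix(x)) unname(out) else out
}

#' Effective-sample-size check with warnings
#'
#' @param x An `"hbdm"` fit or draws array.
#' @param floor ESS floor below which a parameter is flagged.
#' @param pars Optional parameter subset.
#' @return Data frame with `parameter`, `ess_bulk`, `ess_tail` and
#'   `flagged`; flagged parameters are also reported via a warning.
#' @export
ess_check <- function(x, floor = 400, pars = NULL) {
  eb <- ess_bulk(x, pars)
  et <- ess_tail(x, pars)
  if (is.null(names(eb))) names(eb) <- paste0("par", seq_along(eb))
  res <- data.frame(parameter = names(eb), ess_bulk = unname(eb),
                    ess_tail = unname(et),
                    flagged = unname(pmin(eb, et) < floor))
  if (any(res$flagged))
    warning("low effective sample size (< ", floor, ") for: ",
            paste(utils::head(res$parameter[res$flagged], 10L), collapse = ", "),
            call. = FALSE)
  res
}

## -- prior-posterior overlap -------------------------------------------------

#' Prior-posterior overlap
#'
#' Overlap coefficient \eqn{\int \min(p_{prior}, p_{post})} between a
#' parameter's prior and posterior marginals.  High overlap means the
#' data barely updated the prior: values above 0.35 signal weak
#' identifiability (0.35--0.40 is treated as acceptable in the
#' diagnostics report).  Densities may be supplied analytically or
#' estimated from samples by kernel density on a common 512-point grid
#' spanning the union of supports.
#'
#' @param posterior Posterior samples (numeric vector) or a density
#'   function.
#' @param prior Prior samples (numeric vector) or a density function.
#' @param n_grid Number of grid points.
#' @param lower Optional hard lower support bound (e.g. 0 for scales);
#'   the grid is clipped there.
#' @return Overlap coefficient in `[0, 1]`.
#' @examples
#' prior_posterior_overlap(function(x) dnorm(x, 2, 1),
#'                         function(x) dnorm(x, 0, 1))  # 2*pnorm(-1)
#' @export
prior_posterior_overlap <- function(posterior, prior, n_grid = 512,
                                    lower = NULL) {
  is_fun_post <- is.function(posterior)
  is_fun_prior <- is.function(prior)
  if (!is_fun_post && (!is.numeric(posterior) || !length(posterior)))
    stop("empty posterior samples (diagnostic error)", call. = FALSE)
  if (!is_fun_prior && (!is.numeric(prior) || !length(prior)))
    stop("empty prior samples (diagnostic error)", call. = FALSE)
  rng <- range(c(if (!is_fun_post) stats::quantile(posterior, c(0.0005, 0.9995)),
                 if (!is_fun_prior) stats::quantile(prior, c(0.0005, 0.9995)),
                 if (is_fun_post && is_fun_prior) c(-20, 20)))
  if (!is.null(lower)) rng[1] <- max(rng[1], lower)
  pad <- 0.1 * diff(rng)
  lo <- if (!is.null(lower)) max(lower, rng[1] - pad) else rng[1] - pad
  hi <- rng[2] + pad
  grid <- seq(lo, hi, length.out = n_grid)
  dens_on <- function(obj) {
    if (is.function(obj)) obj(grid)
    else {
      d <- stats::density(obj, from = lo, to = hi, n = n_grid)
      d$y
    }
  }
  dp <- dens_on(posterior)
  dq <- dens_on(prior)
  ## densities are used as-is: the overlap integrand min(p, q) is
  ## negligible wherever either density has left the grid
  step <- diff(grid[1:2])
  min(1, sum(pmin(dp, dq)) * step)
}

## analytic prior marginal densities / samplers for the hyper-parameters
hyper_prior_density <- function(par, prior) {
  dig <- function(x, a, b) ifelse(x > 0, exp(a * log(b) - lgamma(a) -
                                               (a + 1) * log(x) - b / x), 0)
  dtn <- function(x, mu, sd) ifelse(x >= 0,
                                    stats::dnorm(x, mu, sd) / stats::pnorm(mu / sd), 0)
  switch(par,
    theta_alpha = function(x) stats::dnorm(x, prior$alpha_loc[1], prior$alpha_loc[2]),
    theta_beta  = function(x) stats::dnorm(x, prior$beta_loc[1], prior$beta_loc[2]),
    theta_gamma = function(x) stats::dnorm(x, prior$gamma_loc[1], prior$gamma_loc[2]),
    sigma_alpha = function(x) dig(x, prior$alpha_scale[1], prior$alpha_scale[2]),
    sigma_beta  = function(x) dig(x, prior$beta_scale[1], prior$beta_scale[2]),
    sigma_gamma = function(x) dig(x, prior$gamma_scale[1], prior$gamma_scale[2]),
    sigma_ini   = function(x) dig(x, prior$ini_scale[1], prior$ini_scale[2]),
    k           = function(x) dtn(x, prior$k[1], prior$k[2]),
    sigma_mal   = function(x) dtn(x, prior$sigma_mal[1], prior$sigma_mal[2]),
    nu          = function(x) stats::dgamma(x, prior$nu[1], rate = prior$nu[2]),
    theta_c     = function(x) stats::dnorm(x, 0, 5),
    sigma_c     = function(x) dig(x, 3, 2),
    theta_d     = function(x) stats::dnorm(x, 0, 1),
    sigma_d     = function(x) dig(x, 4, 2),
    NULL)
}

#' Per-parameter prior-posterior overlap of a fitted model
#'
#' For hyper-parameters the analytic hyper-prior density is used; for
#' subject-level parameters the prior marginal is approximated by
#' drawing, for each posterior draw of the hyper-parameters, one
#' subject-level value from the level-2 prior (for non-hierarchical
#' fits the fixed prior constants are used directly).
#'
#' @param fit An `"hbdm"` fit.
#' @param pars Parameters to evaluate (default: all sampled).
#' @param seed Seed for the subject-level prior draws.
#' @return Named numeric vector of overlap coefficients.
#' @export
ppo <- function(fit, pars = NULL, seed = 1) {
  stopifnot(inherits(fit, "hbdm"))
  pars <- pars %||% sampled_par_names(fit)
  dm <- draw_matrix(fit)
  set.seed(as.integer(seed))
  lower0 <- c("sigma_alpha", "sigma_beta", "sigma_gamma", "sigma_ini",
              "sigma_mal", "nu", "k", "sigma_c", "sigma_d")
  out <- vapply(pars, function(p) {
    post <- dm[, p]
    dfun <- hyper_prior_density(p, fit$prior)
    if (!is.null(dfun))
      return(prior_posterior_overlap(post, dfun,
                                     lower = if (p %in% lower0) 0 else NULL))
    ## subject-level parameter: prior mixture over posterior hyper draws
    n <- length(post)
    pri <- if (grepl("^logit_alpha\\[", p)) {
      stats::rnorm(n, dm[, "theta_alpha"], dm[, "sigma_alpha"])
    } else if (grepl("^beta\\[", p)) {
      rtruncnorm0(n, dm[, "theta_beta"], dm[, "sigma_beta"])
    } else if (grepl("^gamma\\[", p)) {
      rtruncnorm0(n, dm[, "theta_gamma"], dm[, "sigma_gamma"])
    } else if (grepl("^x0\\[", p)) {
      id <- sub("^x0\\[(.*)\\]$", "\\1", p)
      mi <- fit$grid$mal_ini[match(id, fit$grid$subjects)]
      rtruncnorm0(n, dm[, "k"] * mi, dm[, "sigma_ini"])
    } else if (grepl("^c\\[", p)) {
      stats::rnorm(n, dm[, "theta_c"], dm[, "sigma_c"])
    } else if (grepl("^d\\[", p)) {
      stats::rnorm(n, dm[, "theta_d"], dm[, "sigma_d"])
    } else {
      return(NA_real_)
    }
    lower <- if (grepl("^(beta|gamma|x0)\\[", p)) 0 else NULL
    prior_posterior_overlap(post, pri, lower = lower)
  }, numeric(1))
  out
}

#' Convergence and identifiability report
#'
#' Combines rank-normalised split R-hat, bulk/tail effective sample
#' size and prior-posterior overlap for every sampled parameter, with
#' pass/fail flags at the standard thresholds: R-hat < 1.01, ESS at or
#' above `ess_floor`, PPO at or below 0.35 ("acceptable" up to 0.40).
#'
#' @param fit An `"hbdm"` fit.
#' @param ess_floor ESS warning floor.
#' @param csv,jsonl Optional file paths; the report is written as CSV
#'   and/or JSON-lines.
#' @return A data frame of class `"hbdm_diagnostics"`.
#' @export
diagnostics_report <- function(fit, ess_floor = 400, csv = NULL, jsonl = NULL) {
  stopifnot(inherits(fit, "hbdm"))
  pars <- sampled_par_names(fit)
  rh <- rhat(fit, pars)
  eb <- ess_bulk(fit, pars)
  et <- ess_tail(fit, pars)
  ov <- ppo(fit, pars)
  ppo_status <- ifelse(ov <= 0.35, "pass",
                       ifelse(ov <= 0.40, "acceptable", "fail"))
  rep <- data.frame(parameter = pars,
                    rhat = unname(rh), rhat_pass = unname(rh < 1.01),
                    ess_bulk = unname(eb), ess_tail = unname(et),
                    ess_pass = unname(pmin(eb, et) >= ess_floor),
                    ppo = unname(ov), ppo_status = ppo_status,
                    row.names = NULL)
  if (!is.null(csv)) utils::write.csv(rep, csv, row.names = FALSE)
  if (!is.null(jsonl)) {
    con <- file(jsonl, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(rep))) {
      row <- rep[i, ]
      writeLines(sprintf(
        paste0('{"parameter":"%s","rhat":%.6g,"rhat_pass":%s,',
               '"ess_bulk":%.6g,"ess_tail":%.6g,"ess_pass":%s,',
               '"ppo":%.6g,"ppo_status":"%s"}'),
        row$parameter, row$rhat, tolower(row$rhat_pass),
        row$ess_bulk, row$ess_tail, tolower(row$ess_pass),
        row$ppo, row$ppo_status), con)
    }
  }
  class(rep) <- c("hbdm_diagnostics", "data.frame")
  rep
}

#' @export
print.hbdm_diagnostics <- function(x, ...) {
  cat("Convergence / identifiability report (", nrow(x), " parameters)\n",
      sep = "")
  cat("  max R-hat: ", format(max(x$rhat), digits = 4),
      "  (threshold 1.01: ", if (all(x$rhat_pass)) "all pass" else
        paste(sum(!x$rhat_pass), "fail"), ")\n", sep = "")
  cat("  min ESS (bulk/tail): ", round(min(x$ess_bulk)), "/",
      round(min(x$ess_tail)), "\n", sep = "")
  np <- sum(x$ppo_status == "fail")
  na_ <- sum(x$ppo_status == "acceptable")
  cat("  PPO: ", sum(x$ppo_status == "pass"), " pass, ", na_,
      " acceptable (0.35-0.40), ", np, " above 0.40\n", sep = "")
  invisible(x)
}
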