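#' Population-level hyper-parameters
#'
#' The ten quantities governing the three-level hierarchy: the location
#' and scale of the logit-normal retention-rate prior
#' (`theta_alpha`, `sigma_alpha`), of the truncated-normal learning-rate
#' prior (`theta_beta`, `sigma_beta`) and self-training-rate prior
#' (`theta_gamma`, `sigma_gamma`), the slope `k` of the baseline-MAL
#' covariate of the initial memory state with residual scale
#' `sigma_ini`, and the shared measurement-noise parameters `sigma_mal`
#' (Student-t scale) and `nu` (degrees of freedom).
#'
#' @param theta_alpha,sigma_alpha Location/scale of the normal on the
#'   logit of the retention rate.
#' @param theta_beta,sigma_beta Location/scale of the learning-rate
#'   prior, truncated to `[0, Inf)`.
#' @param theta_gamma,sigma_gamma Location/scale of the self-training
#'   prior, truncated to `[0, Inf)`.
#' @param k Slope of baseline MAL in the initial-memory regression
#'   (nonnegative).
#' @param sigma_ini Residual scale of the initial-memory prior.
#' @param sigma_mal Student-t measurement scale (subject-independent).
#' @param nu Student-t degrees of freedom.
#' @return A list of class `"hbdm_hyper"`.
#' @examples
#' hyperparameters()                       # defaults used by the cohort simulator
#' hyperparameters(theta_alpha = 2.5)      # higher typical retention
#' @export
hyperparameters <- function(theta_alpha = 2, sigma_alpha = 0.5,
                            theta_beta = 0.2, sigma_beta = 0.1,
                            theta_gamma = 0.3, sigma_gamma = 0.15,
                            k = 3, sigma_ini = 1,
                            sigma_mal = 0.25, nu = 20) {
  h <- list(theta_alpha = theta_alpha, sigma_alpha = sigma_alpha,
            theta_beta = theta_beta, sigma_beta = sigma_beta,
            theta_gamma = theta_gamma, sigma_gamma = sigma_gamma,
            k = k, sigma_ini = sigma_ini, sigma_mal = sigma_mal, nu = nu)
  num <- vapply(h, function(v) is.numeric(v) && length(v) == 1L && is.finite(v),
                logical(1))
  if (!all(num))
    stop("all hyper-parameters must be finite numeric scalars", call. = FALSE)
  scales <- c("sigma_alpha", "sigma_beta", "sigma_gamma", "sigma_ini",
              "sigma_mal", "nu")
  bad <- scales[vapply(scales, function(s) h[[s]] <= 0, logical(1))]
  if (length(bad))
    stop("hyper-parameter(s) ", paste(bad, collapse = ", "),
         " must be > 0", call. = FALSE)
  if (h$k < 0) stop("`k` must be >= 0", call. = FALSE)
  structure(h, class = "hbdm_hyper")
}

#' Weakly-informative hyper-prior specification
#'
#' The distributions placed on the hyper-parameters at the population
#' level.  Defaults: normal priors on the location parameters
#' (\eqn{\theta_\alpha \sim N(2, 1)} encodes a median retention rate of
#' about 0.86; \eqn{\theta_\beta, \theta_\gamma \sim N(0, 1)}),
#' inverse-gamma priors on the scales (\eqn{\sigma_\alpha, \sigma_{ini}
#' \sim} InvGamma(3, 2); \eqn{\sigma_\beta, \sigma_\gamma \sim}
#' InvGamma(4, 2)), a truncated normal on the baseline slope
#' (\eqn{k \sim N(0, 2)} on `[0, Inf)`), a Gamma(shape 2, rate 0.1)
#' prior on the degrees of freedom (mean 20), and a truncated
#' \eqn{N(0.25, 0.1)} on the measurement scale.
#'
#' Each element is a length-2 numeric: for `*_loc` entries the normal
#' mean/sd, for `*_scale` entries the inverse-gamma shape/scale, for `k`
#' the (pre-truncation) normal mean/sd, for `nu` the gamma shape/rate,
#' and for `sigma_mal` the (pre-truncation) normal mean/sd.
#'
#' @param alpha_loc,beta_loc,gamma_loc Normal mean/sd for the location
#'   hyper-parameters.
#' @param alpha_scale,beta_scale,gamma_scale,ini_scale Inverse-gamma
#'   shape/scale for the scale hyper-parameters.
#' @param k Mean/sd of the truncated-normal prior on `k`.
#' @param sigma_mal Mean/sd of the truncated-normal prior on the
#'   measurement scale.
#' @param nu Shape/rate of the gamma prior on the degrees of freedom.
#' @return A list of class `"hbdm_prior"`.
#' @export
hbdm_prior <- function(alpha_loc = c(2, 1), alpha_scale = c(3, 2),
                       beta_loc = c(0, 1), beta_scale = c(4, 2),
                       gamma_loc = c(0, 1), gamma_scale = c(4, 2),
                       k = c(0, 2), ini_scale = c(3, 2),
                       sigma_mal = c(0.25, 0.1), nu = c(2, 0.1)) {
  p <- list(alpha_loc = alpha_loc, alpha_scale = alpha_scale,
            beta_loc = beta_loc, beta_scale = beta_scale,
            gamma_loc = gamma_loc, gamma_scale = gamma_scale,
            k = k, ini_scale = ini_scale, sigma_mal = sigma_mal, nu = nu)
  ok <- vapply(p, function(v) is.numeric(v) && length(v) == 2L &&
                 all(is.finite(v)), logical(1))
  if (!all(ok))
    stop("each hyper-prior entry must be a length-2 finite numeric",
         call. = FALSE)
  pos2 <- c("alpha_scale", "beta_scale", "gamma_scale", "ini_scale", "nu")
  for (nm in pos2)
    if (any(p[[nm]] <= 0))
      stop("`", nm, "` parameters must be > 0", call. = FALSE)
  if (p$sigma_mal[2] <= 0 || p$alpha_loc[2] <= 0 || p$beta_loc[2] <= 0 ||
      p$gamma_loc[2] <= 0 || p$k[2] <= 0)
    stop("prior standard deviations must be > 0", call. = FALSE)
  structure(p, class = "hbdm_prior")
}

## flatten an hbdm_prior into the constant vector the C++ sampler expects
prior_constants <- function(prior) {
  stopifnot(inherits(prior, "hbdm_prior"))
  as.numeric(c(prior$alpha_loc, prior$alpha_scale,
               prior$beta_loc, prior$beta_scale,
               prior$gamma_loc, prior$gamma_scale,
               prior$k, prior$ini_scale,
               prior$sigma_mal, prior$nu))
}

#' Hyper-prior medians
#'
#' Medians of each hyper-prior marginal.  Used to fix the subject-level
#' prior constants of the non-hierarchical comparator model and to
#' initialise the sampler.
#'
#' @param prior An [hbdm_prior()] specification.
#' @return An [hyperparameters()] object holding the prior medians.
#' @export
hbdm_prior_medians <- function(prior = hbdm_prior()) {
  stopifnot(inherits(prior, "hbdm_prior"))
  ig_med <- function(sh, sc) sc / stats::qgamma(0.5, shape = sh)
  tn_med <- function(mu, sd) {
    ## median of N(mu, sd) truncated to [0, Inf)
    p0 <- stats::pnorm(0, mu, sd)
    stats::qnorm((1 + p0) / 2, mu, sd)
  }
  hyperparameters(
    theta_alpha = prior$alpha_loc[1],
    sigma_alpha = ig_med(prior$alpha_scale[1], prior$alpha_scale[2]),
    theta_beta  = prior$beta_loc[1],
    sigma_beta  = ig_med(prior$beta_scale[1], prior$beta_scale[2]),
    theta_gamma = prior$gamma_loc[1],
    sigma_gamma = ig_med(prior$gamma_scale[1], prior$gamma_scale[2]),
    k           = tn_med(prior$k[1], prior$k[2]),
    sigma_ini   = ig_med(prior$ini_scale[1], prior$ini_scale[2]),
    sigma_mal   = tn_med(prior$sigma_mal[1], prior$sigma_mal[2]),
    nu          = prior$nu[1] / prior$nu[2])
}

## truncated-normal sampler on [0, Inf): naive rejection in the bulk,
## Robert's exponential-rejection sampler when the truncation point sits
## far in the upper tail (z0 = -mean/sd large)
rtruncnorm0 <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- numeric(n)
  z0 <- -mean / sd
  tail <- z0 > 4
  if (any(!tail)) {
    idx <- which(!tail)
    draw <- stats::rnorm(length(idx), mean[idx], sd[idx])
    bad <- which(draw < 0)
    while (length(bad)) {
      draw[bad] <- stats::rnorm(length(bad), mean[idx][bad], sd[idx][bad])
      bad <- bad[draw[bad] < 0]
    }
    out[idx] <- draw
  }
  if (any(tail)) {
    for (i in which(tail)) {
      a <- z0[i]
      alpha <- (a + sqrt(a * a + 4)) / 2
      repeat {
        z <- a + stats::rexp(1, alpha)
        if (log(stats::runif(1)) <= -(z - alpha)^2 / 2) break
      }
      out[i] <- mean[i] + sd[i] * z
    }
  }
  out
}

#' Draw subject-level parameters from the hierarchy
#'
#' Samples `n` subjects' \eqn{(\alpha, \beta, \gamma, x^0)} from their
#' level-2 priors given population hyper-parameters: the retention rate
#' is the sigmoid of a \eqn{N(\theta_\alpha, \sigma_\alpha)} draw, the
#' learning and self-training rates are truncated-normal draws, and the
#' initial memory is a truncated-normal draw centred at
#' `k * mal_ini`.
#'
#' @param hyper An [hyperparameters()] object.
#' @param mal_ini Baseline MAL value(s), recycled to length `n`.
#' @param n Number of subjects to draw.
#' @return A data frame with columns `alpha`, `beta`, `gamma`, `x0`.
#' @export
draw_subject_parameters <- function(hyper, mal_ini, n = length(mal_ini)) {
  if (!inherits(hyper, "hbdm_hyper")) hyper <- do.call(hyperparameters, as.list(hyper))
  if (!is.numeric(mal_ini) || any(mal_ini < 0) || any(mal_ini > 5))
    stop("`mal_ini` must be baseline MAL values in [0, 5]", call. = FALSE)
  mal_ini <- rep_len(mal_ini, n)
  data.frame(
    alpha = stats::plogis(stats::rnorm(n, hyper$theta_alpha, hyper$sigma_alpha)),
    beta  = rtruncnorm0(n, hyper$theta_beta, hyper$sigma_beta),
    gamma = rtruncnorm0(n, hyper$theta_gamma, hyper$sigma_gamma),
    x0    = rtruncnorm0(n, hyper$k * mal_ini, hyper$sigma_ini))
}
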