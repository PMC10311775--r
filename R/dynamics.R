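#' Map motor memory to the predicted MAL scale
#'
#' The latent motor memory \eqn{x} is converted to a predicted Motor
#' Activity Log (MAL) score through a fixed-slope logistic map,
#' \deqn{m = 10 / (1 + e^{-0.2 x}) - 5,}
#' so that predictions always lie inside the instrument's 0--5 range for
#' nonnegative memory states (and inside (-5, 5) overall).  The slope
#' constant 0.2 is part of the model definition and is not estimated.
#'
#' @param x Numeric vector of memory states; must be finite.
#' @return Numeric vector of predicted MAL values, strictly increasing in
#'   `x`, bounded in (-5, 5), and in `[0, 5)` for `x >= 0`.
#' @seealso [mal_sigmoid_inv()] for the inverse map.
#' @examples
#' mal_sigmoid(0)            # 0
#' mal_sigmoid(c(5, 10, 50)) # approaches 5, never attains it
#' @export
mal_sigmoid <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x)))
    stop("`x` must be finite numeric (memory state)", call. = FALSE)
  10 / (1 + exp(-0.2 * x)) - 5
}

#' Inverse of the memory-to-MAL map
#'
#' @param m Numeric vector of predicted MAL values in (-5, 5).
#' @return Memory states `x` such that `mal_sigmoid(x) == m`.
#' @export
mal_sigmoid_inv <- function(m) {
  if (!is.numeric(m) || anyNA(m) || any(m <= -5) || any(m >= 5))
    stop("`m` must lie strictly inside (-5, 5)", call. = FALSE)
  -5 * log(10 / (m + 5) - 1)
}

#' Subject-level dynamic parameters
#'
#' Bundles the four subject-level quantities of the dynamic model: the
#' retention rate \eqn{\alpha \in (0, 1)} (weekly multiplicative memory
#' persistence; values near 1 mean little forgetting), the learning rate
#' \eqn{\beta \ge 0} (gain converting supervised training hours into
#' memory), the self-training rate \eqn{\gamma \ge 0} (gain feeding the
#' predicted MAL back into memory during non-training weeks), and the
#' initial memory state \eqn{x^0 \ge 0}.
#'
#' @param alpha Retention rate, strictly inside (0, 1).
#' @param beta Learning rate, nonnegative.
#' @param gamma Self-training rate, nonnegative.
#' @param x0 Initial memory state, nonnegative.
#' @return A list of class `"subject_parameters"`.
#' @export
subject_parameters <- function(alpha, beta, gamma, x0) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(gamma),
            is.numeric(x0), length(alpha) == 1L, length(beta) == 1L,
            length(gamma) == 1L, length(x0) == 1L)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("`alpha` (retention rate) must lie strictly in (0, 1)", call. = FALSE)
  if (!is.finite(beta) || beta < 0)
    stop("`beta` (learning rate) must be >= 0", call. = FALSE)
  if (!is.finite(gamma) || gamma < 0)
    stop("`gamma` (self-training rate) must be >= 0", call. = FALSE)
  if (!is.finite(x0) || x0 < 0)
    stop("`x0` (initial memory) must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, x0 = x0),
            class = "subject_parameters")
}

#' One-week update of the motor memory state
#'
#' Applies the first-order dynamics: during a training week
#' (\eqn{u > 0}) the memory retains a fraction \eqn{\alpha} of its value
#' and gains \eqn{\beta u} from the delivered dose; in all other weeks
#' the retained memory is topped up by self-training, \eqn{\gamma m},
#' driven by the current predicted MAL \eqn{m}.
#'
#' @param x Current memory state (nonnegative scalar).
#' @param params A [subject_parameters()] object.
#' @param m Predicted MAL at the current week, i.e. `mal_sigmoid(x)`.
#' @param u Training dose delivered this week, in hours (nonnegative).
#' @return The next week's memory state (nonnegative).
#' @examples
#' p <- subject_parameters(alpha = 0.86, beta = 0.2, gamma = 0.3, x0 = 10)
#' memory_update(10, p, mal_sigmoid(10), u = 22) # 0.86*10 + 0.2*22
#' @export
memory_update <- function(x, params, m, u) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    stop("memory state `x` must be a nonnegative finite scalar", call. = FALSE)
  if (!is.numeric(u) || length(u) != 1L || !is.finite(u) || u < 0)
    stop("dose `u` must be a nonnegative finite scalar", call. = FALSE)
  if (!inherits(params, "subject_parameters"))
    params <- do.call(subject_parameters, as.list(params)[c("alpha", "beta", "gamma", "x0")])
  if (u > 0) params$alpha * x + params$beta * u
  else       params$alpha * x + params$gamma * m
}

#' Deterministic forward simulation of a memory/MAL trajectory
#'
#' Iterates the weekly dynamics from `params$x0` over `horizon` weeks
#' driven by a dose schedule.  There is no process noise: given the
#' parameters and schedule the trajectory is fully determined.  The
#' predicted MAL `m` is recorded at every week, including weeks with no
#' assessment.
#'
#' @param params A [subject_parameters()] object.
#' @param schedule A data frame with columns `week` (0-based, unit-step)
#'   and `hours` (nonnegative weekly dose), or a plain numeric vector of
#'   weekly doses for weeks `0 .. horizon - 1`.
#' @param horizon Number of weeks to simulate (at least 1); the schedule
#'   must cover weeks `0 .. horizon - 1`.
#' @return A data frame of class `"memory_trajectory"` with columns
#'   `week`, `x` (memory state) and `m` (predicted MAL).
#' @examples
#' p <- subject_parameters(0.5, 0, 0, 10)
#' forward_simulate(p, rep(0, 4), horizon = 4)$x  # 10, 5, 2.5, 1.25
#' @export
forward_simulate <- function(params, schedule, horizon) {
  if (!inherits(params, "subject_parameters"))
    params <- do.call(subject_parameters, as.list(params)[c("alpha", "beta", "gamma", "x0")])
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < 1 ||
      horizon != round(horizon))
    stop("`horizon` must be a positive integer number of weeks", call. = FALSE)
  u <- schedule_hours(schedule, horizon)
  x <- numeric(horizon)
  m <- numeric(horizon)
  x[1] <- params$x0
  for (t in seq_len(horizon)) {
    m[t] <- mal_sigmoid(x[t])
    if (t < horizon)
      x[t + 1] <- memory_update(x[t], params, m[t], u[t])
  }
  structure(data.frame(week = seq_len(horizon) - 1L, x = x, m = m),
            class = c("memory_trajectory", "data.frame"))
}

## extract a length-`horizon` weekly dose vector from the accepted forms
schedule_hours <- function(schedule, horizon) {
  if (is.data.frame(schedule)) {
    if (!all(c("week", "hours") %in% names(schedule)))
      stop("schedule data frame needs columns `week` and `hours`", call. = FALSE)
    need <- seq_len(horizon) - 1L
    idx <- match(need, schedule$week)
    if (anyNA(idx))
      stop("schedule does not cover weeks 0 .. ", horizon - 1L,
           " (configuration error)", call. = FALSE)
    u <- schedule$hours[idx]
  } else if (is.numeric(schedule)) {
    if (length(schedule) < horizon)
      stop("dose vector shorter than `horizon` (configuration error)",
           call. = FALSE)
    u <- schedule[seq_len(horizon)]
  } else {
    stop("`schedule` must be a data frame or numeric vector", call. = FALSE)
  }
  if (anyNA(u) || any(u < 0))
    stop("weekly dose `hours` must be nonnegative and complete", call. = FALSE)
  u
}

#' Student-t density of the MAL measurement model
#'
#' Location-scale Student-t density used for the observed MAL: the
#' observation is centred on the predicted MAL \eqn{m} with scale
#' `sigma` and degrees of freedom `nu`; heavy tails absorb occasional
#' outlying self-reports.
#'
#' @param x Numeric vector of quantiles.
#' @param mu Location (predicted MAL).
#' @param sigma Scale, strictly positive.
#' @param nu Degrees of freedom, strictly positive.
#' @param log Return the log-density?
#' @return Density (or log-density) values.
#' @export
dstudent_t <- function(x, mu = 0, sigma = 1, nu = 1, log = FALSE) {
  if (!is.numeric(sigma) || any(sigma <= 0))
    stop("`sigma` must be > 0", call. = FALSE)
  if (!is.numeric(nu) || any(nu <= 0))
    stop("`nu` must be > 0", call. = FALSE)
  ld <- stats::dt((x - mu) / sigma, df = nu, log = TRUE) - log(sigma)
  if (log) ld else exp(ld)
}

#' Log-likelihood of one MAL observation
#'
#' @param y Observed MAL value(s).
#' @param m Predicted MAL (location of the measurement distribution).
#' @param sigma_mal Measurement scale, shared across subjects.
#' @param nu Student-t degrees of freedom.
#' @return Log-density of `y` under the measurement model.
#' @export
observation_loglik <- function(y, m, sigma_mal, nu) {
  dstudent_t(y, mu = m, sigma = sigma_mal, nu = nu, log = TRUE)
}
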