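#' Forecasting scenarios for a trial design
#'
#' The four data-availability scenarios used to evaluate forecasts for
#' a "new" subject: only the pre-training baseline assessments are
#' available (`baseline_only`), or additionally the assessments up to
#' and including the one immediately after training bout 1, 2 or 3.
#' Each scenario is a per-subject week cutoff: observations strictly
#' after the cutoff are masked.
#'
#' @param design A [trial_design()] (bout-based designs only).
#' @return Named list of scenarios, each with `name` and `cutoff`
#'   (week).
#' @export
forecast_scenarios <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  arm <- design$arms[[length(design$arms)]]
  aw <- arm$assessment_weeks
  bouts <- arm$bout_weeks
  ## baseline_only keeps the baseline MAL alone (the earliest assessment)
  cuts <- c(min(aw), vapply(bouts, function(b) min(aw[aw > b]), numeric(1)))
  names <- c("baseline_only", paste0("after_bout_", seq_along(bouts)))
  out <- lapply(seq_along(cuts), function(i)
    list(name = names[i], cutoff = as.integer(cuts[i])))
  names(out) <- names
  out
}

#' Leave-one-subject-out forecast
#'
#' Emulates forecasting a new patient: the left-out subject's
#' observations after the scenario cutoff are masked (treated as
#' missing), the model is refitted to the full cohort, and the
#' posterior draws of the predicted MAL at the masked assessment weeks
#' are the forecasts.  All other subjects contribute complete data.
#'
#' @param cohort A `"mal_cohort"` or a list with `observations` and
#'   `schedule` data frames.
#' @param left_out Subject id (or index) to forecast.
#' @param scenario A scenario from [forecast_scenarios()], or a week
#'   cutoff.
#' @param model An [hbdm_model()].  With `hierarchical = FALSE` the
#'   unpooled comparator is used: the left-out subject is fitted alone,
#'   so its parameter priors are the weakly-informative hyper-priors
#'   propagated through the hierarchy with no pooling from other
#'   participants (the other subjects' data cannot inform the fit).
#' @param prior,chains,iter,warmup,thin,seed Passed to [hbdm()].
#' @param predictive_noise Add Student-t measurement noise to the
#'   forecast draws (default `FALSE`: forecasts are draws of the
#'   noiseless predicted MAL).
#' @param ... Further arguments to [hbdm()].
#' @return A list of class `"loso_forecast"`: `subject_id`, `scenario`,
#'   `cutoff`, `weeks` (masked assessment weeks), `truth` (masked
#'   observed values), `draws` (posterior forecast draws, one column
#'   per masked week), `bf_rmse` (per masked week) and the refitted
#'   model's `fit`.
#' @export
loso_forecast <- function(cohort, left_out, scenario,
                          model = hbdm_model("full"), prior = hbdm_prior(),
                          chains = 2, iter = 3000, warmup = 1500, thin = 1,
                          seed = 1, predictive_noise = FALSE, ...) {
  obs <- cohort$observations
  sch <- cohort$schedule
  ids <- unique(as.character(obs$subject_id))
  if (is.numeric(left_out)) left_out <- ids[left_out]
  if (!left_out %in% ids) stop("unknown subject '", left_out, "'", call. = FALSE)
  cutoff <- if (is.list(scenario)) scenario$cutoff else as.integer(scenario)
  sname <- if (is.list(scenario)) scenario$name else paste0("cutoff_", cutoff)
  mask <- obs$subject_id == left_out & !is.na(obs$mal) & obs$week > cutoff
  if (!any(mask))
    stop("scenario masks nothing for subject ", left_out,
         " (scenario error)", call. = FALSE)
  if (!any(obs$subject_id == left_out & !is.na(obs$mal) & obs$week <= cutoff))
    stop("left-out subject has no unmasked observation", call. = FALSE)
  masked_weeks <- obs$week[mask]
  truth <- obs$mal[mask]
  obs2 <- obs
  obs2$mal[mask] <- NA_real_
  fit_model <- model
  if (!model$hierarchical) {
    ## no pooling: other participants cannot inform the left-out subject,
    ## so only that subject is fitted (marginal weakly-informative priors)
    obs2 <- obs2[obs2$subject_id == left_out, ]
    sch <- sch[sch$subject_id == left_out, ]
    fit_model <- hbdm_model(model$form, hierarchical = TRUE)
  }
  fit <- hbdm(obs2, sch, model = fit_model, prior = prior, chains = chains,
              iter = iter, warmup = warmup, thin = thin, seed = seed,
              quiet = TRUE, ...)
  md <- subject_m_draws(fit, left_out)[, masked_weeks + 1L, drop = FALSE]
  if (predictive_noise) {
    dm <- draw_matrix(fit)
    md <- md + dm[, "sigma_mal"] *
      matrix(stats::rt(length(md), df = rep(dm[, "nu"], ncol(md))),
             nrow(md), ncol(md))
    md <- pmin(5, pmax(0, md))
  }
  colnames(md) <- masked_weeks
  structure(list(subject_id = left_out, scenario = sname, cutoff = cutoff,
                 weeks = masked_weeks, truth = truth, draws = md,
                 bf_rmse = vapply(seq_along(masked_weeks), function(j)
                   bf_rmse(md[, j], truth[j]), numeric(1)),
                 fit = fit),
            class = "loso_forecast")
}

#' Bayesian forecasting RMSE
#'
#' Root mean squared deviation of the posterior forecast draws from the
#' masked true measurement: an interval estimate evaluated against a
#' point observation.  Satisfies the bias-variance identity
#' `bf_rmse^2 = (mean draw - truth)^2 + var(draws)` (population
#' variance).
#'
#' @param draws Numeric vector of forecast draws for one
#'   (subject, week).
#' @param truth The masked observed value.
#' @return Nonnegative scalar.
#' @export
bf_rmse <- function(draws, truth) {
  if (!length(draws)) stop("no forecast draws", call. = FALSE)
  if (is.na(truth)) stop("missing truth is excluded upstream", call. = FALSE)
  sqrt(mean((draws - truth)^2))
}

#' RMSE of posterior-median predictions
#'
#' @param predictions Posterior-median predicted MAL values.
#' @param observations Observed MAL values, aligned with
#'   `predictions`; `NA` pairs are dropped.
#' @return Root mean squared error.
#' @export
point_rmse <- function(predictions, observations) {
  keep <- !is.na(predictions) & !is.na(observations)
  if (!any(keep)) stop("no aligned non-missing pairs (evaluation error)",
                       call. = FALSE)
  sqrt(mean((predictions[keep] - observations[keep])^2))
}

#' Paired sign-flip permutation test
#'
#' One-sided test for paired per-subject error summaries: the
#' within-subject differences `a - b` have their signs flipped in all
#' (or `n_perm` random) combinations, and the p-value is the proportion
#' of permutations whose mean is at least the observed mean.  Exact
#' enumeration is used for up to 20 subjects; beyond that, Monte-Carlo
#' sampling with add-one smoothing.
#'
#' @param a,b Paired per-subject values (same subjects, same order).
#' @param n_perm Monte-Carlo permutations when enumeration is
#'   infeasible.
#' @param seed Seed for the Monte-Carlo path.
#' @param method `"auto"` (exact enumeration up to 20 subjects,
#'   Monte-Carlo beyond), or force `"exact"` / `"montecarlo"`.
#' @return One-sided p-value in `(0, 1]`.
#' @examples
#' permutation_compare(c(2, 2, 2), c(1, 1, 1))  # 1/8
#' @export
permutation_compare <- function(a, b, n_perm = 4000, seed = 1,
                                method = c("auto", "exact", "montecarlo")) {
  method <- match.arg(method)
  if (length(a) != length(b) || !length(a))
    stop("`a` and `b` must be paired values of equal length (data error)",
         call. = FALSE)
  if (anyNA(a) || anyNA(b))
    stop("paired values must be complete (data error)", call. = FALSE)
  d <- a - b
  n <- length(d)
  obs <- mean(d)
  use_exact <- method == "exact" || (method == "auto" && n <= 20L)
  if (method == "exact" && n > 24L)
    stop("exact enumeration limited to 24 subjects", call. = FALSE)
  if (use_exact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    perm_means <- as.numeric(signs %*% d) / n
    mean(perm_means >= obs - 1e-12)
  } else {
    set.seed(as.integer(seed))
    hits <- 0L
    for (r in seq_len(n_perm)) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      if (mean(s * d) >= obs - 1e-12) hits <- hits + 1L
    }
    (1 + hits) / (1 + n_perm)
  }
}

#' Scenario-by-scenario forecast evaluation
#'
#' Runs [loso_forecast()] for every subject under every scenario for
#' both the hierarchical model and the non-hierarchical (unpooled)
#' comparator, and aggregates the mean BF-RMSE per forecast week, with
#' per-week permutation p-values for the probability that the
#' non-hierarchical model forecasts better.
#'
#' @param cohort A `"mal_cohort"`.
#' @param scenarios Scenarios (default: [forecast_scenarios()] of the
#'   cohort's design).
#' @param subjects Subjects to leave out (default: all).
#' @param models Character subset of
#'   `c("hierarchical", "non_hierarchical")`.
#' @param seed Base seed; each refit gets a distinct derived seed.
#' @param ... Sampler settings passed to [loso_forecast()].
#' @return A list of class `"scenario_eval"`: `table` (scenario, model,
#'   week, mean_bf_rmse, n_subjects), `pvalues` (scenario, week, p),
#'   and `per_subject` (the underlying per-subject BF-RMSE values).
#' @export
run_scenarios <- function(cohort, scenarios = NULL, subjects = NULL,
                          models = c("hierarchical", "non_hierarchical"),
                          seed = 1, ...) {
  scenarios <- scenarios %||% forecast_scenarios(cohort$design)
  ids <- unique(as.character(cohort$observations$subject_id))
  subjects <- subjects %||% ids
  models <- match.arg(models, several.ok = TRUE)
  per <- NULL
  counter <- 0L
  for (sc in scenarios) {
    for (mod in models) {
      mspec <- hbdm_model("full", hierarchical = mod == "hierarchical")
      for (s in subjects) {
        counter <- counter + 1L
        fc <- loso_forecast(cohort, s, sc, model = mspec,
                            seed = as.integer(seed) + counter, ...)
        per <- rbind(per, data.frame(scenario = sc$name, model = mod,
                                     subject_id = s, week = fc$weeks,
                                     bf_rmse = fc$bf_rmse))
      }
    }
  }
  tab <- stats::aggregate(bf_rmse ~ scenario + model + week, data = per, mean)
  names(tab)[names(tab) == "bf_rmse"] <- "mean_bf_rmse"
  cnt <- stats::aggregate(subject_id ~ scenario + model + week, data = per,
                          function(x) length(unique(x)))
  tab$n_subjects <- cnt$subject_id[match(
    paste(tab$scenario, tab$model, tab$week),
    paste(cnt$scenario, cnt$model, cnt$week))]
  pv <- NULL
  if (all(c("hierarchical", "non_hierarchical") %in% models)) {
    for (scn in unique(per$scenario)) {
      wks <- sort(unique(per$week[per$scenario == scn]))
      for (w in wks) {
        h <- per[per$scenario == scn & per$model == "hierarchical" &
                   per$week == w, ]
        nh <- per[per$scenario == scn & per$model == "non_hierarchical" &
                    per$week == w, ]
        common <- intersect(h$subject_id, nh$subject_id)
        if (length(common) < 2L) next
        p <- permutation_compare(
          nh$bf_rmse[match(common, nh$subject_id)],
          h$bf_rmse[match(common, h$subject_id)],
          seed = seed)
        pv <- rbind(pv, data.frame(scenario = scn, week = w, p = p))
      }
    }
  }
  structure(list(table = tab, pvalues = pv, per_subject = per),
            class = "scenario_eval")
}

#' @export
print.scenario_eval <- function(x, ...) {
  cat("Leave-one-subject-out forecast evaluation\n")
  last <- max(x$table$week)
  at_last <- x$table[x$table$week == last, ]
  cat("mean BF-RMSE at the final forecast week (", last, "):\n", sep = "")
  print.data.frame(at_last[order(at_last$model, at_last$scenario),
                           c("scenario", "model", "mean_bf_rmse")],
                   row.names = FALSE, digits = 3)
  invisible(x)
}
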