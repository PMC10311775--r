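#' Align observations and dose schedules on a complete weekly grid
#'
#' Builds the rectangular weekly-grid representation the sampler
#' consumes: one row per subject, columns for weeks `0 .. Tmax - 1`,
#' with the observed-MAL matrix, an observed-indicator matrix, the
#' weekly dose matrix and the per-subject baseline MAL.  Weeks without a
#' measurement carry the missing marker and contribute nothing to the
#' likelihood.
#'
#' @param observations Long data frame with columns `subject_id`,
#'   `week` and `mal` (`NA` = missing).  Rows may cover only assessment
#'   weeks; gaps are filled with missing weeks.
#' @param schedule Long data frame with columns `subject_id`, `week`,
#'   `hours`.  Every observed week must be covered by the schedule.
#' @param mal_ini_from `"column"` (default): use the observations'
#'   `baseline_mal` column where present -- for synthetic cohorts this
#'   is the generative baseline covariate, keeping recovery studies
#'   self-consistent -- falling back to `"first"` otherwise.
#'   `"first"`: each subject's earliest non-missing observation.
#'   `"pre_mean"`: mean of all assessments strictly before the
#'   subject's first training week.
#' @return A list of class `"hbdm_grid"` with elements `S`, `Tmax`,
#'   `u`, `yobs`, `has`, `mal_ini`, `subjects` and `weeks`.
#' @export
build_weekly_grid <- function(observations, schedule,
                              mal_ini_from = c("column", "first", "pre_mean")) {
  mal_ini_from <- match.arg(mal_ini_from)
  if (mal_ini_from == "column" &&
      !("baseline_mal" %in% names(observations) &&
        any(is.finite(observations$baseline_mal))))
    mal_ini_from <- "first"
  req_o <- c("subject_id", "week", "mal")
  if (!all(req_o %in% names(observations)))
    stop("`observations` needs columns ", paste(req_o, collapse = ", "),
         call. = FALSE)
  if (!all(c("subject_id", "week", "hours") %in% names(schedule)))
    stop("`schedule` needs columns subject_id, week, hours", call. = FALSE)
  subjects <- unique(as.character(observations$subject_id))
  missing_sched <- setdiff(subjects, unique(as.character(schedule$subject_id)))
  if (length(missing_sched))
    stop("no dose schedule for subject(s): ",
         paste(missing_sched, collapse = ", "), call. = FALSE)
  S <- length(subjects)
  Tmax <- max(schedule$week, observations$week) + 1L
  u <- matrix(0, S, Tmax)
  yobs <- matrix(0, S, Tmax)
  has <- matrix(FALSE, S, Tmax)
  mal_ini <- numeric(S)
  for (i in seq_len(S)) {
    sid <- subjects[i]
    sch <- schedule[schedule$subject_id == sid, ]
    obs <- observations[observations$subject_id == sid & !is.na(observations$mal), ]
    if (nrow(obs) == 0L)
      stop("subject ", sid, " has no non-missing observation", call. = FALSE)
    if (any(obs$mal < 0 | obs$mal > 5))
      stop("subject ", sid, ": MAL outside [0, 5]", call. = FALSE)
    outside <- setdiff(obs$week, sch$week)
    if (length(outside))
      stop("subject ", sid, ": observation at week ",
           paste(outside, collapse = ", "),
           " outside schedule coverage (data error)", call. = FALSE)
    u[i, sch$week + 1L] <- sch$hours
    yobs[i, obs$week + 1L] <- obs$mal
    has[i, obs$week + 1L] <- TRUE
    if (mal_ini_from == "column") {
      bm <- observations$baseline_mal[observations$subject_id == sid]
      bm <- bm[is.finite(bm)]
      if (!length(bm))
        stop("subject ", sid, ": no baseline_mal value", call. = FALSE)
      mal_ini[i] <- bm[1]
    } else if (mal_ini_from == "first") {
      mal_ini[i] <- obs$mal[which.min(obs$week)]
    } else {
      first_train <- suppressWarnings(min(sch$week[sch$hours > 0]))
      pre <- obs$mal[obs$week < first_train]
      mal_ini[i] <- if (length(pre)) mean(pre) else obs$mal[which.min(obs$week)]
    }
  }
  structure(list(S = S, Tmax = as.integer(Tmax), u = u, yobs = yobs,
                 has = has, mal_ini = mal_ini, subjects = subjects,
                 weeks = seq_len(Tmax) - 1L),
            class = "hbdm_grid")
}

#' Model-structure specification
#'
#' Selects which structural terms of the dynamic model are active, or a
#' static comparator.  Dropping a term fixes its rate: `"no_learning"`
#' sets \eqn{\beta = 0}, `"no_self_training"` sets \eqn{\gamma = 0},
#' `"no_retention"` sets \eqn{\alpha = 1}.  `"fixed_effects"` replaces
#' subject-level parameters with one shared \eqn{(\alpha, \beta,
#' \gamma)} triple and the deterministic initial-memory regression
#' \eqn{x^0_i = k\,\mathrm{MAL}_{ini,i}}.  `"linear"` and `"logistic"`
#' are the static regressions in time \eqn{c_i + d_i t}, the latter
#' passed through the memory-to-MAL sigmoid.
#'
#' @param form Model structure (see Details).
#' @param hierarchical If `FALSE` (dynamic forms only), subject
#'   parameters get fixed weakly-informative priors -- the hyper-prior
#'   medians plugged in as constants -- with no pooling; used as the
#'   forecasting comparator.
#' @return A list of class `"hbdm_model"`.
#' @export
hbdm_model <- function(form = c("full", "no_learning", "no_self_training",
                                "no_retention", "fixed_effects",
                                "linear", "logistic"),
                       hierarchical = TRUE) {
  form <- match.arg(form)
  static <- form %in% c("linear", "logistic")
  if (!hierarchical && (static || form == "fixed_effects"))
    stop("`hierarchical = FALSE` applies to subject-level dynamic forms only",
         call. = FALSE)
  structure(list(form = form, static = static,
                 use_a = form != "no_retention",
                 use_b = form != "no_learning",
                 use_g = form != "no_self_training",
                 shared = form == "fixed_effects",
                 hierarchical = hierarchical),
            class = "hbdm_model")
}
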