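#' Synthetic clinical-trial designs
#'
#' Constructs the assessment and dosing layout of the two supported
#' upper-extremity rehabilitation trial designs on a uniform weekly grid
#' (calendar months are taken as 4 weeks throughout).
#'
#' `"dose"`: four arms with nominal total doses 0, 15, 30 and 60 h,
#' each split equally over three week-long training bouts separated by
#' one month; every bout week additionally carries 2 h of movement
#' testing, so weekly inputs are 2, 7, 12 or 22 h.  Each subject is
#' assessed 14 times: twice before training (weeks 0, 1), immediately
#' before and after each bout, and monthly for six months after the
#' last bout.  Bouts fall in weeks 2, 7 and 12; the final assessment is
#' 24 weeks after the last bout.
#'
#' `"excite"`: two arms receiving a single 60-h therapy week either
#' immediately (week 0) or after a one-year delay (week 52).  Both arms
#' are assessed 9 times: before and after each scheduled therapy window
#' (weeks 0, 2, 52, 54) and at months 4, 8, 16, 20 and 24
#' (weeks 16, 32, 64, 80, 96).
#'
#' @param name `"dose"` or `"excite"`.
#' @param n_subjects Total cohort size; defaults to 40 (dose, split
#'   10/10/10/10) or 95 (excite, split 50/45).
#' @param n_per_arm Optional explicit arm sizes (must sum to
#'   `n_subjects`).
#' @return A list of class `"trial_design"` with elements `name`,
#'   `arms` (per-arm dose totals, bout weeks, weekly bout input and
#'   assessment weeks), `horizon` (number of modelled weeks) and
#'   `n_per_arm`.
#' @examples
#' d <- trial_design("dose")
#' length(make_assessment_weeks(d, 1))  # 14
#' @export
trial_design <- function(name = c("dose", "excite"), n_subjects = NULL,
                         n_per_arm = NULL) {
  name <- match.arg(name)
  if (name == "dose") {
    bouts <- c(2L, 7L, 12L)
    assess <- c(0L, 1L,                     # two pre-training baselines
                2L, 3L, 7L, 8L, 12L, 13L,   # pre/post each bout
                13L + 4L * (1:6))           # monthly follow-ups
    assess <- sort(unique(assess))
    arms <- lapply(c(0, 15, 30, 60), function(total) {
      list(dose_total = total, bout_weeks = bouts,
           bout_hours = total / 3 + 2, assessment_weeks = assess)
    })
    names(arms) <- c("0h", "15h", "30h", "60h")
    horizon <- 38L
    if (is.null(n_subjects)) n_subjects <- 40L
    if (is.null(n_per_arm)) {
      base <- n_subjects %/% 4L
      n_per_arm <- rep(base, 4L)
      n_per_arm[seq_len(n_subjects %% 4L)] <- base + 1L
    }
  } else {
    assess <- c(0L, 2L, 16L, 32L, 52L, 54L, 64L, 80L, 96L)
    arms <- list(
      immediate = list(dose_total = 60, bout_weeks = 0L, bout_hours = 60,
                       assessment_weeks = assess),
      delayed   = list(dose_total = 60, bout_weeks = 52L, bout_hours = 60,
                       assessment_weeks = assess))
    horizon <- 97L
    if (is.null(n_subjects)) n_subjects <- 95L
    if (is.null(n_per_arm))
      n_per_arm <- c(ceiling(n_subjects * 50 / 95), 0L)
    if (length(n_per_arm) == 2L && n_per_arm[2] == 0L)
      n_per_arm[2] <- n_subjects - n_per_arm[1]
  }
  if (length(n_per_arm) != length(arms) || any(n_per_arm < 0) ||
      sum(n_per_arm) != n_subjects)
    stop("arm sizes must be nonnegative and partition `n_subjects`",
         call. = FALSE)
  structure(list(name = name, arms = arms, horizon = horizon,
                 n_subjects = as.integer(n_subjects),
                 n_per_arm = as.integer(n_per_arm)),
            class = "trial_design")
}

#' Weekly dose schedule of one trial arm
#'
#' @param design A [trial_design()].
#' @param arm Arm index (1-based) or arm name.
#' @return A data frame with columns `week` (`0 .. horizon - 1`) and
#'   `hours`: the weekly training input, positive only in bout weeks.
#' @export
make_dose_schedule <- function(design, arm) {
  a <- design_arm(design, arm)
  hours <- numeric(design$horizon)
  hours[a$bout_weeks + 1L] <- a$bout_hours
  data.frame(week = seq_len(design$horizon) - 1L, hours = hours)
}

#' Assessment weeks of one trial arm
#'
#' @inheritParams make_dose_schedule
#' @return Sorted integer vector of assessment weeks (14 for
#'   DOSE-like arms, 9 for EXCITE-like arms).
#' @export
make_assessment_weeks <- function(design, arm) {
  design_arm(design, arm)$assessment_weeks
}

design_arm <- function(design, arm) {
  if (!inherits(design, "trial_design"))
    stop("`design` must be a trial_design (configuration error)", call. = FALSE)
  if (is.character(arm)) {
    if (!arm %in% names(design$arms))
      stop("unknown arm '", arm, "' (configuration error)", call. = FALSE)
    design$arms[[arm]]
  } else {
    if (!is.numeric(arm) || length(arm) != 1L || arm < 1 ||
        arm > length(design$arms))
      stop("arm index out of range (configuration error)", call. = FALSE)
    design$arms[[as.integer(arm)]]
  }
}

#' Simulate a synthetic cohort from the generative model
#'
#' Draws each subject's baseline MAL (uniform on `mal_ini_range`),
#' subject parameters from the hierarchy via
#' [draw_subject_parameters()], simulates the noiseless trajectory with
#' [forward_simulate()], and samples observed MAL values at the design's
#' assessment weeks from the Student-t measurement model, clipped to the
#' instrument's `[0, 5]` range.  All other weeks are emitted with
#' missing MAL so downstream code sees the full weekly grid.
#'
#' @param design A [trial_design()].
#' @param hyper Population truth, an [hyperparameters()] object.
#' @param seed Integer seed; the cohort is reproducible given
#'   (`design`, `hyper`, `seed`).
#' @param mal_ini_range Range of the baseline MAL draw (default
#'   `c(0.5, 3.5)`, the mild-to-moderate impairment band the designs
#'   recruit from).
#' @return A list of class `"mal_cohort"`: `observations` (long data
#'   frame `subject_id`, `week`, `mal` with `NA` for unassessed weeks,
#'   `baseline_mal` = the subject's earliest observed MAL), `schedule`
#'   (`subject_id`, `week`, `hours`), `truth` (per-subject `arm`,
#'   drawn `mal_ini`, `alpha`, `beta`, `gamma`, `x0`), `design`,
#'   `hyper` and `seed`.
#' @export
simulate_cohort <- function(design, hyper = hyperparameters(), seed = 1,
                            mal_ini_range = c(0.5, 3.5)) {
  stopifnot(inherits(design, "trial_design"))
  if (!inherits(hyper, "hbdm_hyper")) hyper <- do.call(hyperparameters, as.list(hyper))
  set.seed(as.integer(seed))
  n_arm <- design$n_per_arm
  arm_of <- rep(seq_along(design$arms), n_arm)
  S <- design$n_subjects
  ids <- sprintf("S%02d", seq_len(S))
  mal_ini <- stats::runif(S, mal_ini_range[1], mal_ini_range[2])
  pars <- draw_subject_parameters(hyper, mal_ini)
  obs_list <- vector("list", S)
  sch_list <- vector("list", S)
  for (i in seq_len(S)) {
    arm <- arm_of[i]
    sch <- make_dose_schedule(design, arm)
    aw <- make_assessment_weeks(design, arm)
    traj <- forward_simulate(subject_parameters(pars$alpha[i], pars$beta[i],
                                                pars$gamma[i], pars$x0[i]),
                             sch, design$horizon)
    mal <- rep(NA_real_, design$horizon)
    noise <- hyper$sigma_mal * stats::rt(length(aw), df = hyper$nu)
    mal[aw + 1L] <- pmin(5, pmax(0, traj$m[aw + 1L] + noise))
    obs_list[[i]] <- data.frame(subject_id = ids[i], week = traj$week,
                                mal = mal,
                                baseline_mal = mal_ini[i])
    sch_list[[i]] <- data.frame(subject_id = ids[i], sch)
  }
  truth <- data.frame(subject_id = ids,
                      arm = names(design$arms)[arm_of],
                      mal_ini = mal_ini, pars)
  structure(list(observations = do.call(rbind, obs_list),
                 schedule = do.call(rbind, sch_list),
                 truth = truth, design = design, hyper = hyper,
                 seed = as.integer(seed)),
            class = "mal_cohort")
}

#' @export
print.mal_cohort <- function(x, ...) {
  n_obs <- sum(!is.na(x$observations$mal))
  cat("Synthetic MAL cohort (", x$design$name, "-like design)\n", sep = "")
  cat("  subjects:", x$design$n_subjects,
      " arms:", paste(names(x$design$arms), collapse = "/"),
      " (", paste(x$design$n_per_arm, collapse = "/"), ")\n", sep = " ")
  cat("  weekly grid: 0 ..", x$design$horizon - 1L,
      "  observed MAL values:", n_obs, "\n")
  invisible(x)
}
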