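#' Read MAL observations from CSV
#'
#' Expects header `subject_id, week, mal, baseline_mal`; an empty `mal`
#' cell is the missing marker.  Rows with MAL outside `[0, 5]` or
#' malformed numbers are rejected with their line numbers.
#'
#' @param path CSV file path.
#' @return Validated observations data frame.
#' @export
read_mal_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  need <- c("subject_id", "week", "mal")
  if (!all(need %in% names(df)))
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "),
         call. = FALSE)
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  if (!is.numeric(df$week) || anyNA(df$week))
    stop("malformed `week` at line(s) ",
         paste(utils::head(line[!is.finite(suppressWarnings(as.numeric(df$week)))], 5),
               collapse = ", "), call. = FALSE)
  df$mal <- suppressWarnings(as.numeric(df$mal))
  bad <- which(!is.na(df$mal) & (df$mal < 0 | df$mal > 5))
  if (length(bad))
    stop("MAL outside [0, 5] at line(s) ",
         paste(utils::head(line[bad], 5), collapse = ", "),
         " (validation error)", call. = FALSE)
  df
}

#' Write MAL observations to CSV
#'
#' @param observations Observations data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mal_observations <- function(observations, path) {
  utils::write.csv(observations, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a weekly dose schedule from CSV
#'
#' Expects header `subject_id, week, hours` with nonnegative hours.
#'
#' @param path CSV file path.
#' @return Validated schedule data frame.
#' @export
read_dose_schedule <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  if (!all(c("subject_id", "week", "hours") %in% names(df)))
    stop("schedule CSV needs columns subject_id, week, hours", call. = FALSE)
  if (anyNA(df$hours) || any(df$hours < 0))
    stop("schedule hours must be nonnegative and complete", call. = FALSE)
  df
}

#' @rdname read_dose_schedule
#' @param schedule Schedule data frame.
#' @param path Output path.
#' @export
write_dose_schedule <- function(schedule, path) {
  utils::write.csv(schedule, path, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic cohort's CSV files
#'
#' Writes `observations.csv`, `schedule.csv` and `truth.csv` (the
#' ground-truth subject parameters, for recovery studies) to a
#' directory.
#'
#' @param cohort A `"mal_cohort"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mal_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mal_observations(cohort$observations, file.path(dir, "observations.csv"))
  write_dose_schedule(cohort$schedule, file.path(dir, "schedule.csv"))
  utils::write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Save posterior draws and metadata of a fit
#'
#' The draws are written as a flat CSV with `chain` and `iter` index
#' columns (a named-dimension draws table) plus a YAML metadata file
#' recording the model structure, sampler settings, seed and backend
#' version, so archived runs are fully traceable.
#'
#' @param fit An `"hbdm"` fit.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
save_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "hbdm"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- fit$draws
  kc <- dim(d)[1] * dim(d)[2]
  flat <- data.frame(chain = rep(seq_len(dim(d)[2]), each = dim(d)[1]),
                     iter = rep(seq_len(dim(d)[1]), dim(d)[2]))
  m <- matrix(aperm(d, c(1, 2, 3)), nrow = kc)
  colnames(m) <- dimnames(d)[[3]]
  utils::write.csv(cbind(flat, m), file.path(dir, "draws.csv"),
                   row.names = FALSE)
  meta <- list(model = unclass(fit$model)[c("form", "hierarchical")],
               chains = fit$chains, iter = fit$iter, warmup = fit$warmup,
               thin = fit$thin, seed = fit$seed, backend = fit$backend,
               subjects = fit$grid$subjects,
               mal_ini = as.numeric(fit$grid$mal_ini),
               elapsed_sec = fit$time)
  yaml::write_yaml(meta, file.path(dir, "meta.yaml"))
  invisible(dir)
}

#' Read a posterior archive back into a draws array
#'
#' @param dir Directory written by [save_fit()].
#' @return A 3-d draws array (iterations, chains, parameters) with the
#'   archive metadata attached as attribute `"meta"`.
#' @export
read_fit_draws <- function(dir) {
  df <- utils::read.csv(file.path(dir, "draws.csv"), check.names = FALSE)
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  chains <- max(df$chain)
  iters <- max(df$iter)
  pars <- setdiff(names(df), c("chain", "iter"))
  arr <- array(NA_real_, c(iters, chains, length(pars)),
               dimnames = list(NULL, paste0("chain", seq_len(chains)), pars))
  for (ch in seq_len(chains))
    arr[, ch, ] <- as.matrix(df[df$chain == ch, pars])
  attr(arr, "meta") <- meta
  arr
}

#' Read a structured run configuration
#'
#' YAML with optional blocks `design` (`name`, `n_subjects`, `seed`,
#' `mal_ini_range`), `prior` (overrides of [hbdm_prior()] entries),
#' `sampler` (`chains`, `iter`, `warmup`, `thin`, `seed`), `scenarios`
#' (names to run) and `output` (`dir`).  Missing entries fall back to
#' package defaults; the returned object round-trips through
#' [yaml::write_yaml()] losslessly.
#'
#' @param path YAML file path.
#' @return A list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- list(
    design = utils::modifyList(list(name = "dose", seed = 1,
                                    mal_ini_range = c(0.5, 3.5)),
                               raw$design %||% list()),
    prior = raw$prior %||% list(),
    sampler = utils::modifyList(list(chains = 4, iter = 2000, warmup = 1000,
                                     thin = 1, seed = 1),
                                raw$sampler %||% list()),
    scenarios = raw$scenarios %||% NULL,
    output = utils::modifyList(list(dir = "."), raw$output %||% list()))
  if (!cfg$design$name %in% c("dose", "excite"))
    stop("config: design name must be 'dose' or 'excite'", call. = FALSE)
  structure(cfg, class = "run_config")
}

config_prior <- function(cfg) {
  do.call(hbdm_prior, cfg$prior)
}
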