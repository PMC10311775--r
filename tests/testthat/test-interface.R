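test_that("observation CSV reading validates rows", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("subject_id,week,mal,baseline_mal",
               "S1,0,2.5,2.5",
               "S1,4,,2.5"), f)
  obs <- read_mal_observations(f)
  expect_identical(nrow(obs), 2L)
  expect_equal(obs$mal[1], 2.5)
  expect_true(is.na(obs$mal[2]))          # empty cell = missing marker
  writeLines(c("subject_id,week,mal,baseline_mal",
               "S1,2,6.1,2.5"), f)
  expect_error(read_mal_observations(f), "\\[0, 5\\].*line")
  writeLines(c("subject_id,week", "S1,0"), f)
  expect_error(read_mal_observations(f), "missing column")
})

test_that("readers and writers round-trip", {
  coh <- small_cohort(n = 4, seed = 6)
  dir <- tempfile()
  write_cohort(coh, dir)
  obs <- read_mal_observations(file.path(dir, "observations.csv"))
  sch <- read_dose_schedule(file.path(dir, "schedule.csv"))
  expect_equal(obs$mal, coh$observations$mal)
  expect_equal(obs$week, coh$observations$week)
  expect_equal(sch$hours, coh$schedule$hours)
  ## write(read(x)) = x
  f2 <- file.path(dir, "obs2.csv")
  write_mal_observations(obs, f2)
  expect_identical(readLines(file.path(dir, "observations.csv")),
                   readLines(f2))
})

test_that("run configuration round-trips with defaults", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("design:", "  name: excite", "  seed: 9",
               "sampler:", "  chains: 2", "  iter: 500"), f)
  cfg <- read_run_config(f)
  expect_identical(cfg$design$name, "excite")
  expect_identical(cfg$sampler$chains, 2L)
  expect_identical(cfg$sampler$warmup, 1000)     # default preserved
  yaml::write_yaml(unclass(cfg), f)
  cfg2 <- read_run_config(f)
  expect_equal(unclass(cfg2)[c("design", "sampler", "output")],
               unclass(cfg)[c("design", "sampler", "output")])
  writeLines(c("design:", "  name: nope"), f)
  expect_error(read_run_config(f), "dose")
})

test_that("posterior archives round-trip draws and metadata", {
  sf <- cached_small_fit()
  dir <- tempfile()
  save_fit(sf$fit, dir)
  arr <- read_fit_draws(dir)
  expect_identical(dim(arr), dim(sf$fit$draws))
  expect_equal(max(abs(arr - sf$fit$draws)), 0, tolerance = 1e-6)
  meta <- attr(arr, "meta")
  expect_identical(meta$seed, sf$fit$seed)
  expect_match(meta$backend, "rehabdyn")
})

test_that("the command-line interface runs its subcommands", {
  out1 <- tempfile()
  ## unknown subcommand: usage error status 2
  expect_identical(suppressMessages(cli_main(c("frobnicate"))), 2L)
  expect_identical(suppressMessages(cli_main(character(0))), 2L)
  ## simulate is deterministic given the seed
  expect_identical(suppressMessages(
    cli_main(c("simulate", "--design", "dose", "--seed", "7", "--n", "4",
               "--out", out1))), 0L)
  expect_true(all(file.exists(file.path(out1, c("observations.csv",
                                                "schedule.csv",
                                                "truth.csv")))))
  out1b <- tempfile()
  suppressMessages(cli_main(c("simulate", "--design", "dose", "--seed", "7",
                              "--n", "4", "--out", out1b)))
  expect_identical(readLines(file.path(out1, "observations.csv")),
                   readLines(file.path(out1b, "observations.csv")))
  ## fit on the simulated files
  out2 <- tempfile()
  st <- suppressWarnings(suppressMessages(
    cli_main(c("fit", "--obs", file.path(out1, "observations.csv"),
               "--schedule", file.path(out1, "schedule.csv"),
               "--out", out2, "--chains", "2", "--iter", "400",
               "--warmup", "240", "--seed", "1"))))
  expect_identical(st, 0L)
  expect_true(all(file.exists(file.path(out2, c("draws.csv", "meta.yaml",
                                                "diagnostics.csv",
                                                "summary.csv")))))
  ## report on the archived fit
  out3 <- tempfile()
  expect_identical(suppressMessages(
    cli_main(c("report", "--fit", out2, "--out", out3))), 0L)
  rep <- read.csv(file.path(out3, "report.csv"))
  expect_true(all(c("parameter", "rhat", "ess_bulk") %in% names(rep)))
  ## qualitative evaluation writes its summary tables
  out4 <- tempfile()
  expect_identical(suppressMessages(
    cli_main(c("evaluate", "--design", "dose", "--seed", "2", "--draws", "60",
               "--out", out4))), 0L)
  expect_true(all(file.exists(file.path(out4, c("efficacy.csv",
                                                "efficiency.csv",
                                                "decay.csv",
                                                "thresholds.csv")))))
  ## runtime failure surfaces as status 1
  expect_identical(suppressMessages(
    cli_main(c("fit", "--obs", "no-such-file.csv", "--schedule", "x",
               "--out", out2))), 1L)
})
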