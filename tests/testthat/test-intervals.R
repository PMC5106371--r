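make_stream <- function(times, onset, offset, effector = "manual",
                        patient = "p1", block = "b1", step = NULL) {
  structure(list(event_times = times, stim_onset = onset,
                 stim_offset = offset, block = block, effector = effector,
                 patient = patient, quantization_step = step, config = NULL),
            class = "event_stream")
}

test_that("window labelling follows the half-open boundary convention", {
  s <- make_stream(c(0.0, 0.5, 1.0, 1.5, 2.0), onset = 1.0, offset = 2.0)
  d <- events_to_intervals(s, pre_window = 1.0)
  # event at exactly the onset belongs to the stim window
  expect_equal(d$interval_s[d$condition == "pre"], 0.5)
  expect_equal(d$interval_s[d$condition == "stim"], c(0.5, 0.5))
  log <- attr(d, "discard_log")
  expect_identical(log$n_pairs, 4L)
  expect_identical(log$n_pre, 1L)
  expect_identical(log$n_stim, 2L)
  expect_identical(log$n_discarded, 1L)
  expect_identical(log$n_straddle_onset, 1L)
})

test_that("events outside both windows are discarded and counted", {
  # pre window is [2, 4): the events at 0.5 and 1 fall outside it
  s <- make_stream(c(0.5, 1.0, 2.5, 3.0, 3.5, 4.0, 4.5, 5.5), onset = 4,
                   offset = 6)
  d <- events_to_intervals(s, pre_window = 2)
  log <- attr(d, "discard_log")
  expect_identical(log$n_pre, 2L)    # (2.5,3.0), (3.0,3.5)
  expect_identical(log$n_stim, 2L)   # (4.0,4.5), (4.5,5.5)
  expect_identical(log$n_pairs, 7L)
  expect_identical(log$n_discarded, 3L)
})

test_that("empty analysis windows raise errors naming the window", {
  s_all_pre <- make_stream(seq(0, 3, by = 0.5), onset = 4, offset = 6)
  expect_error(events_to_intervals(s_all_pre, pre_window = 4),
               regexp = "stim window", class = "laterace_insufficient_data")
  s_all_stim <- make_stream(seq(4, 6, by = 0.5), onset = 4, offset = 6)
  expect_error(events_to_intervals(s_all_stim, pre_window = 4),
               regexp = "pre window", class = "laterace_insufficient_data")
})

test_that("interval counts are conserved on simulated blocks", {
  for (seed in c(301, 302, 303)) {
    s <- simulate_experiment(experiment_config(seed = seed))
    d <- events_to_intervals(s)
    log <- attr(d, "discard_log")
    expect_identical(log$n_pre + log$n_stim + log$n_discarded, log$n_pairs)
    expect_identical(log$n_pairs, length(s$event_times) - 1L)
    expect_identical(nrow(d), log$n_pre + log$n_stim)
  }
})

test_that("labelling is invariant to a common time shift", {
  s <- simulate_experiment(experiment_config(seed = 311))
  d0 <- events_to_intervals(s, pre_window = 30)
  shift <- 17.3
  s2 <- s
  s2$event_times <- s$event_times + shift
  s2$stim_onset <- s$stim_onset + shift
  s2$stim_offset <- s$stim_offset + shift
  d1 <- events_to_intervals(s2, pre_window = 30)
  expect_equal(d1$interval_s, d0$interval_s)
  expect_identical(d1$condition, d0$condition)
})

test_that("interval datasets validate labels and quantization grids", {
  d <- interval_dataset(c(0.2, 0.4), c("pre", "stim"))
  expect_s3_class(d, "interval_dataset")
  expect_error(interval_dataset(c(0.2, -0.4), c("pre", "stim")),
               class = "laterace_domain")
  expect_error(interval_dataset(c(0.2, 0.4), c("pre", "during")),
               class = "laterace_domain")
  expect_error(interval_dataset(c(0.2, 0.41), c("pre", "stim"),
                                quantization_step = 0.04),
               class = "laterace_domain")
  ok <- interval_dataset(c(0.2, 0.4), c("pre", "stim"),
                         quantization_step = 0.04)
  expect_identical(attr(ok, "quantization_step"), 0.04)
})

test_that("interval tables round-trip through CSV", {
  s <- simulate_experiment(experiment_config(seed = 321))
  d <- events_to_intervals(s)
  path <- withr::local_tempfile(fileext = ".csv")
  write_intervals(d, path)
  back <- read_intervals(path)
  expect_equal(back$interval_s, d$interval_s)
  expect_identical(back$condition, d$condition)
  expect_identical(back$effector, d$effector)
  # a file without the required header is a parse error
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("0.5,pre,manual,p1", "0.4,stim,manual,p1"), bad)
  expect_error(read_intervals(bad), class = "laterace_parse")
})

test_that("cell means and SEMs match hand arithmetic", {
  d <- interval_dataset(1 / c(2, 3, 4), "pre")
  rep <- suppressWarnings(frequency_stats(d, min_n = 2))
  expect_equal(rep$cells$mean_hz, 3.0)
  expect_equal(rep$cells$sem_hz, 0.5774, tolerance = 1e-4)
  expect_identical(rep$cells$n, 3)
})

test_that("identical pre and stim samples give adjusted p of exactly 1", {
  x <- simulate_later(baseline_params(), 40, seed = 331)
  d <- bind_intervals(
    interval_dataset(x, "pre", effector = "manual", patient = "a"),
    interval_dataset(x, "stim", effector = "manual", patient = "a"),
    interval_dataset(x, "pre", effector = "vocal", patient = "a"),
    interval_dataset(x, "stim", effector = "vocal", patient = "a"))
  rep <- frequency_stats(d)
  expect_identical(nrow(rep$posthoc), 2L)
  expect_equal(rep$posthoc$p_adj, c(1, 1))
  expect_equal(rep$posthoc$t, c(0, 0))
})

test_that("Bonferroni adjustment never decreases p and caps at 1", {
  streams <- list(
    manual = simulate_experiment(experiment_config(
      effector = "manual", seed = 341)),
    vocal = simulate_experiment(experiment_config(
      effector = "vocal", stimulated_effector = "manual", seed = 342)))
  d <- bind_intervals(lapply(streams, events_to_intervals))
  rep <- frequency_stats(d)
  expect_true(all(rep$posthoc$p_adj >= rep$posthoc$p_raw))
  expect_true(all(rep$posthoc$p_adj <= 1))
  expect_equal(rep$posthoc$p_adj,
               pmin(1, rep$posthoc$p_raw * rep$m))
})

test_that("effector-specific stimulation is detected only where applied", {
  streams <- list(
    manual = simulate_experiment(experiment_config(
      effector = "manual", pre_duration = 120, stim_duration = 120,
      seed = 351)),
    vocal = simulate_experiment(experiment_config(
      effector = "vocal", stimulated_effector = "manual",
      pre_duration = 120, stim_duration = 120, seed = 352)))
  d <- bind_intervals(lapply(streams, events_to_intervals))
  rep <- frequency_stats(d)
  ph <- rep$posthoc
  expect_lt(ph$p_adj[ph$effector == "manual"], 0.05)
  expect_gt(ph$p_adj[ph$effector == "vocal"], 0.05)
  # omnibus stimulation main effect is present
  cond_row <- rep$omnibus[rep$omnibus$term == "condition", ]
  expect_lt(cond_row[["Pr(>F)"]], 0.001)
})

test_that("undersized cells are excluded with a warning, never silently", {
  d <- bind_intervals(
    interval_dataset(c(0.3, 0.35, 0.4), "pre", patient = "a"),
    interval_dataset(c(0.25, 0.3, 0.28), "stim", patient = "a"),
    interval_dataset(0.5, "pre", patient = "b"))
  expect_warning(rep <- frequency_stats(d, min_n = 2), regexp = "excluded")
  expect_identical(nrow(rep$cells), 2L)
  expect_false("b" %in% rep$cells$patient)
})

test_that("frequency report serialises to JSON", {
  s <- simulate_experiment(experiment_config(seed = 361))
  rep <- frequency_stats(events_to_intervals(s))
  path <- withr::local_tempfile(fileext = ".json")
  frequency_report_to_json(rep, path)
  back <- jsonlite::fromJSON(path)
  expect_true(grepl("fixed-effects", back$note))
  expect_equal(back$cells$mean_hz, rep$cells$mean_hz)
})
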