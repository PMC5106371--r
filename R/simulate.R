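#' Simulate LATER race trials
#'
#' Each trial draws a rate of rise from `N(mu_r, sigma_r^2)`, redrawing while
#' the rate is nonpositive (a nonpositive rate never reaches the threshold),
#' and returns the interval `theta / rate`. Equivalently, promptness is drawn
#' from the zero-truncated normal `N(mu_p, sigma_p^2)` and inverted.
#' Deterministic given `seed`.
#'
#' @param params A [race_params()] or [recinormal_params()] object.
#' @param n Number of trials (at least 1).
#' @param seed Optional integer seed; the caller's RNG stream is untouched.
#' @return Numeric vector of `n` intervals (s), with attribute `redraws`
#'   giving the number of rejected nonpositive-rate draws.
#' @examples
#' t <- simulate_later(recinormal_params(2.96, 0.44), 1000, seed = 1)
#' mean(1 / t)  # close to 2.96
#' @export
simulate_later <- function(params, n, seed = NULL) {
  params <- as_recinormal_params(params)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop_domain("n must be a positive count")
  }
  n <- as.integer(n)
  with_seed(seed, {
    p <- rnorm(n, params$mu_p, params$sigma_p)
    redraws <- 0L
    bad <- which(p <= 0)
    while (length(bad) > 0L) {
      redraws <- redraws + length(bad)
      p[bad] <- rnorm(length(bad), params$mu_p, params$sigma_p)
      bad <- bad[p[bad] <= 0]
    }
    structure(1 / p, redraws = redraws)
  })
}

#' Configuration of a simulated stimulation experiment
#'
#' Defines one block of self-paced alternating movements with an abrupt
#' condition switch at stimulation onset. The defaults reproduce the study
#' conditions: a baseline alternation frequency of 2.96 Hz and a decision
#' threshold reduced to 0.65 of its baseline value during stimulation of the
#' manual effector (0.56 is the corresponding vocal-condition value). The
#' promptness coefficient of variation (`promptness_cv`, default 0.15) sets
#' interval dispersion.
#'
#' Stimulation is implemented by default as a pure swivel -- both promptness
#' parameters divided by `threshold_factor`, preserving the infinite-time
#' intercept -- because a threshold change is the mechanism of interest;
#' `stim_mode = "shift"` instead rescales only `mu_p` (a rate-of-rise
#' change), for model-selection calibration. If `effector_specific` is set
#' and `effector != stimulated_effector`, stimulation has no effect.
#'
#' @param baseline_frequency Baseline alternation frequency (Hz), i.e. the
#'   mean promptness before stimulation.
#' @param promptness_cv Coefficient of variation of promptness
#'   (`sigma_p / mu_p`), dimensionless.
#' @param threshold_factor `theta_stim / theta_pre`, in (0, 1.5]; values
#'   below 1 shorten the race and accelerate behaviour.
#' @param pre_duration,stim_duration Durations (s) of the pre-stimulation
#'   and stimulation periods; stimulation onset is at `pre_duration`.
#' @param effector Effector label of this block (`"manual"` or `"vocal"`).
#' @param effector_specific Does stimulation affect only the stimulated
#'   effector?
#' @param stimulated_effector Which effector the stimulated site drives.
#' @param stim_mode `"swivel"` (threshold change) or `"shift"` (rate
#'   change).
#' @param early_weight Proportion of movements drawn from a minor early
#'   component, in `[0, 0.5)`.
#' @param early_params [recinormal_params()] of the early component
#'   (required when `early_weight > 0`).
#' @param quantization_step Optional video-frame step (s), e.g. 0.04 for a
#'   25 frame/s clinical recording; event times are rounded to this grid.
#' @param patient,block Identifiers carried into the event stream.
#' @param seed Integer seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(baseline_frequency = 2.96,
                              promptness_cv = 0.15,
                              threshold_factor = 0.65,
                              pre_duration = 60,
                              stim_duration = 60,
                              effector = "manual",
                              effector_specific = TRUE,
                              stimulated_effector = "manual",
                              stim_mode = c("swivel", "shift"),
                              early_weight = 0,
                              early_params = NULL,
                              quantization_step = NULL,
                              patient = "sim01",
                              block = "b1",
                              seed = 1L) {
  stim_mode <- match.arg(stim_mode)
  if (!is.numeric(baseline_frequency) || baseline_frequency <= 0) {
    stop_domain("baseline_frequency must be positive")
  }
  if (!is.numeric(promptness_cv) || promptness_cv <= 0) {
    stop_domain("promptness_cv must be positive")
  }
  if (!is.numeric(threshold_factor) || threshold_factor <= 0 ||
      threshold_factor > 1.5) {
    stop_domain("threshold_factor must lie in (0, 1.5]")
  }
  if (!is.numeric(pre_duration) || pre_duration <= 0 ||
      !is.numeric(stim_duration) || stim_duration <= 0) {
    stop_domain("durations must be positive")
  }
  if (!is.numeric(early_weight) || early_weight < 0 || early_weight >= 0.5) {
    stop_domain("early_weight must lie in [0, 0.5)")
  }
  if (early_weight > 0 && is.null(early_params)) {
    stop_domain("early_params required when early_weight > 0")
  }
  if (!is.null(early_params)) early_params <- as_recinormal_params(early_params)
  if (!is.null(quantization_step) &&
      (!is.numeric(quantization_step) || quantization_step <= 0)) {
    stop_domain("quantization_step must be positive or NULL")
  }
  structure(
    list(baseline_frequency = baseline_frequency,
         promptness_cv = promptness_cv,
         threshold_factor = threshold_factor,
         pre_duration = pre_duration, stim_duration = stim_duration,
         effector = effector, effector_specific = effector_specific,
         stimulated_effector = stimulated_effector,
         stim_mode = stim_mode,
         early_weight = early_weight, early_params = early_params,
         quantization_step = quantization_step,
         patient = patient, block = block, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

# draw one promptness value from the (truncated) normal, honouring the
# optional early-component mixture; single draws keep the event-by-event
# RNG stream simple and reproducible
.draw_promptness <- function(mu, sigma, early_weight, early_params) {
  if (early_weight > 0 && stats::runif(1) < early_weight) {
    mu <- early_params$mu_p
    sigma <- early_params$sigma_p
  }
  repeat {
    p <- rnorm(1, mu, sigma)
    if (p > 0) return(p)
  }
}

#' Simulate a stimulation-experiment event stream
#'
#' Generates movement events sequentially: `t_{k+1} = t_k + T_k`, with the
#' interval `T_k` drawn from the baseline promptness parameters while
#' `t_k < stim_onset` and from the stimulation parameters once
#' `t_k >= stim_onset` (so exactly one interval straddles the onset, drawn
#' under baseline parameters -- the analysis windowing discards it).
#' Generation stops at the first event that would fall beyond
#' `stim_offset`. Optionally mixes in a minor early component, and
#' optionally rounds event times to the nearest multiple of
#' `quantization_step` (rounding times, not intervals, so frame-quantization
#' error accumulates as it does in video annotation).
#'
#' @param config An [experiment_config()].
#' @return An object of class `event_stream`: `event_times` (strictly
#'   increasing, starting at 0), `stim_onset`, `stim_offset`, `block`,
#'   `effector`, `patient`, `quantization_step`, the generating `config`,
#'   and the generating promptness parameters `params_pre` / `params_stim`
#'   (under a swivel the two share `mu_p/sigma_p` exactly).
#' @export
simulate_experiment <- function(config) {
  if (!inherits(config, "experiment_config")) {
    stop_domain("config must be an experiment_config")
  }
  mu0 <- config$baseline_frequency
  sg0 <- config$promptness_cv * mu0
  stim_active <- !config$effector_specific ||
    identical(config$effector, config$stimulated_effector)
  if (stim_active) {
    if (config$stim_mode == "swivel") {
      mu1 <- mu0 / config$threshold_factor
      sg1 <- sg0 / config$threshold_factor
    } else {
      mu1 <- mu0 / config$threshold_factor
      sg1 <- sg0
    }
  } else {
    mu1 <- mu0
    sg1 <- sg0
  }
  onset <- config$pre_duration
  offset <- config$pre_duration + config$stim_duration

  times <- with_seed(config$seed, {
    buf <- numeric(ceiling(offset * mu1 * 2) + 16L)
    buf[1] <- 0
    m <- 1L
    t <- 0
    repeat {
      if (t < onset) {
        p <- .draw_promptness(mu0, sg0, config$early_weight, config$early_params)
      } else {
        p <- .draw_promptness(mu1, sg1, config$early_weight, config$early_params)
      }
      t2 <- t + 1 / p
      if (t2 > offset) break
      m <- m + 1L
      if (m > length(buf)) buf <- c(buf, numeric(length(buf)))
      buf[m] <- t2
      t <- t2
    }
    buf[seq_len(m)]
  })

  if (!is.null(config$quantization_step)) {
    step <- config$quantization_step
    times <- round(times / step) * step
    dup <- c(FALSE, diff(times) <= 0)
    if (any(dup)) {
      warning(sprintf("%d events collided on the %g s quantization grid and were dropped",
                      sum(dup), step))
      times <- times[!dup]
    }
  }

  structure(
    list(event_times = times, stim_onset = onset, stim_offset = offset,
         block = config$block, effector = config$effector,
         patient = config$patient,
         quantization_step = config$quantization_step,
         config = config,
         params_pre = recinormal_params(mu0, sg0),
         params_stim = recinormal_params(mu1, sg1)),
    class = "event_stream"
  )
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf("Event stream: %d events over %.1f s (patient %s, effector %s, block %s)\n",
              length(x$event_times), max(x$event_times), x$patient,
              x$effector, x$block))
  cat(sprintf("  stimulation window [%.2f, %.2f] s%s\n", x$stim_onset,
              x$stim_offset,
              if (is.null(x$quantization_step)) "" else
                sprintf("; times on a %g s grid", x$quantization_step)))
  invisible(x)
}

#' Quantize an event stream to a video-frame grid
#'
#' Rounds all event times to the nearest multiple of `step`, emulating the
#' temporal sampling of clinical video annotation (40 ms at 25 frames/s).
#' Events colliding on the grid are dropped with a warning.
#'
#' @param stream An `event_stream`.
#' @param step Grid step (s).
#' @return The quantized `event_stream`.
#' @export
quantize_events <- function(stream, step = 0.04) {
  stopifnot(inherits(stream, "event_stream"))
  if (!is.numeric(step) || step <= 0) stop_domain("step must be positive")
  times <- round(stream$event_times / step) * step
  dup <- c(FALSE, diff(times) <= 0)
  if (any(dup)) {
    warning(sprintf("%d events collided on the %g s quantization grid and were dropped",
                    sum(dup), step))
    times <- times[!dup]
  }
  stream$event_times <- times
  stream$quantization_step <- step
  stream
}

#' Write / read an event stream as CSV plus JSON sidecar
#'
#' The CSV holds one row per event (`time_s, block, effector, patient`); the
#' sidecar (same path with `.json` extension) records the stimulation window,
#' the generating parameters and the seed, so a stream round-trips
#' losslessly.
#'
#' @param stream An `event_stream`.
#' @param csv_path Output CSV path; the sidecar replaces the extension with
#'   `.json`.
#' @return `csv_path`, invisibly.
#' @export
write_event_stream <- function(stream, csv_path) {
  stopifnot(inherits(stream, "event_stream"))
  # full float precision so a stream round-trips bit-exactly
  df <- data.frame(time_s = sprintf("%.17g", stream$event_times),
                   block = stream$block,
                   effector = stream$effector, patient = stream$patient)
  write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  side <- list(stim_onset = stream$stim_onset,
               stim_offset = stream$stim_offset,
               quantization_step = stream$quantization_step,
               config = stream$config[setdiff(names(stream$config), "early_params")],
               early_params = if (is.null(stream$config$early_params)) NULL else
                 list(mu_p = stream$config$early_params$mu_p,
                      sigma_p = stream$config$early_params$sigma_p))
  json_path <- sub("\\.[^.]*$", ".json", csv_path)
  writeLines(jsonlite::toJSON(side, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE), json_path)
  invisible(csv_path)
}

#' @rdname write_event_stream
#' @param require_sidecar Error if the JSON sidecar is missing? When `FALSE`
#'   and no sidecar exists, the stimulation window must be supplied by the
#'   caller downstream.
#' @export
read_event_stream <- function(csv_path, require_sidecar = TRUE) {
  if (!file.exists(csv_path)) stop_laterace(sprintf("no such file: %s", csv_path),
                                            "laterace_io")
  df <- tryCatch(read.csv(csv_path, stringsAsFactors = FALSE),
                 error = function(e) stop_laterace(
                   sprintf("malformed CSV %s: %s", csv_path, conditionMessage(e)),
                   "laterace_parse"))
  needed <- c("time_s", "block", "effector", "patient")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop_laterace(sprintf("CSV %s lacks required column(s): %s (line 1)",
                          csv_path, paste(missing_cols, collapse = ", ")),
                  "laterace_parse")
  }
  json_path <- sub("\\.[^.]*$", ".json", csv_path)
  side <- NULL
  if (file.exists(json_path)) {
    side <- jsonlite::fromJSON(json_path)
  } else if (require_sidecar) {
    stop_laterace(sprintf("missing sidecar %s", json_path), "laterace_io")
  }
  ec <- side$config
  cfg <- NULL
  if (!is.null(ec)) {
    cfg <- experiment_config(
      baseline_frequency = ec$baseline_frequency,
      promptness_cv = ec$promptness_cv,
      threshold_factor = ec$threshold_factor,
      pre_duration = ec$pre_duration, stim_duration = ec$stim_duration,
      effector = ec$effector, effector_specific = ec$effector_specific,
      stimulated_effector = ec$stimulated_effector,
      stim_mode = ec$stim_mode,
      early_weight = ec$early_weight,
      early_params = if (is.null(side$early_params)) NULL else
        recinormal_params(side$early_params$mu_p, side$early_params$sigma_p),
      quantization_step = ec$quantization_step,
      patient = ec$patient, block = ec$block, seed = ec$seed)
  }
  structure(
    list(event_times = as.numeric(df$time_s),
         stim_onset = if (is.null(side$stim_onset)) NULL else
           as.numeric(side$stim_onset),
         stim_offset = if (is.null(side$stim_offset)) NULL else
           as.numeric(side$stim_offset),
         block = df$block[1], effector = df$effector[1],
         patient = df$patient[1],
         quantization_step = side$quantization_step,
         config = cfg),
    class = "event_stream"
  )
}

#' Canonical synthetic fixture suite
#'
#' Generates the standard set of test streams at the study conditions
#' (2.96 Hz baseline, threshold factor 0.65): a swivel-truth stream, a
#' shift-truth stream, a null stream (factor 1), a stream with a 15% early
#' component, and a 40 ms frame-quantized swivel stream. Per-stream seeds
#' are derived from `seed` so the suite is deterministic. When `dir` is
#' given, each stream is written as CSV + JSON sidecar and a
#' `manifest.json` listing every file and its generating parameters is
#' written alongside.
#'
#' @param seed Integer master seed.
#' @param dir Optional output directory (created if missing).
#' @param pre_duration,stim_duration Period durations (s) shared by all
#'   fixtures.
#' @return Named list of `event_stream` objects (`swivel`, `shift`, `null`,
#'   `early`, `quantized`) with a `manifest` attribute.
#' @export
make_fixture_suite <- function(seed = 1L, dir = NULL,
                               pre_duration = 60, stim_duration = 60) {
  seed <- as.integer(seed)
  sub <- function(k) (seed * 131L + k) %% 2147483647L
  cfgs <- list(
    swivel = experiment_config(threshold_factor = 0.65, stim_mode = "swivel",
                               pre_duration = pre_duration,
                               stim_duration = stim_duration,
                               block = "swivel", seed = sub(1L)),
    shift = experiment_config(threshold_factor = 0.65, stim_mode = "shift",
                              pre_duration = pre_duration,
                              stim_duration = stim_duration,
                              block = "shift", seed = sub(2L)),
    null = experiment_config(threshold_factor = 1, stim_mode = "swivel",
                             pre_duration = pre_duration,
                             stim_duration = stim_duration,
                             block = "null", seed = sub(3L)),
    early = experiment_config(threshold_factor = 0.65, stim_mode = "swivel",
                              early_weight = 0.15,
                              early_params = recinormal_params(5.9, 0.5),
                              pre_duration = pre_duration,
                              stim_duration = stim_duration,
                              block = "early", seed = sub(4L)),
    quantized = experiment_config(threshold_factor = 0.65,
                                  stim_mode = "swivel",
                                  quantization_step = 0.04,
                                  pre_duration = pre_duration,
                                  stim_duration = stim_duration,
                                  block = "quantized", seed = sub(5L))
  )
  streams <- lapply(cfgs, simulate_experiment)
  manifest <- list(master_seed = seed,
                   fixtures = lapply(cfgs, function(cc) {
                     cc2 <- unclass(cc)
                     if (!is.null(cc2$early_params)) {
                       cc2$early_params <- list(mu_p = cc2$early_params$mu_p,
                                                sigma_p = cc2$early_params$sigma_p)
                     }
                     cc2
                   }))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    files <- character(0)
    for (nm in names(streams)) {
      path <- file.path(dir, paste0(nm, ".csv"))
      write_event_stream(streams[[nm]], path)
      files <- c(files, basename(path), paste0(nm, ".json"))
    }
    manifest$files <- c(files, "manifest.json")
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE),
               file.path(dir, "manifest.json"))
  }
  attr(streams, "manifest") <- manifest
  streams
}
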