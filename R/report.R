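#' End-to-end analysis of one event stream
#'
#' Runs the full pipeline on a single block: event-to-interval conversion
#' with windowing, reciprobit transformation of each condition, recinormal
#' fits, four-model BIC comparison, threshold ratio with bootstrap CI, and
#' frequency statistics. When `out_dir` is given, writes the JSON report,
#' per-condition reciprobit CSVs, the interval table, and (optionally)
#' reciprobit and violin figures.
#'
#' Given the same stream, seed and settings the JSON report is byte
#' identical across runs.
#'
#' @param stream An `event_stream` (from [simulate_experiment()] or
#'   [read_event_stream()]).
#' @param n_boot Bootstrap resamples for the threshold-ratio CI.
#' @param seed Integer seed for the bootstrap.
#' @param pre_window Passed to [events_to_intervals()].
#' @param out_dir Optional output directory (created if missing).
#' @param plots Write PNG figures when `out_dir` is given?
#' @return A list of class `later_report`: `intervals`, `discard_log`,
#'   `fits` (per-condition [fit_recinormal()]), `reciprobit` (per-condition
#'   points), `comparison` ([compare_models()]), `ratio`
#'   ([bootstrap_ratio()]), `frequency` ([frequency_stats()]), and `seed`.
#' @export
analyze_stream <- function(stream, n_boot = 1000L, seed = 1L,
                           pre_window = NULL, out_dir = NULL, plots = TRUE) {
  intervals <- events_to_intervals(stream, pre_window = pre_window)
  pre <- intervals$interval_s[intervals$condition == "pre"]
  stim <- intervals$interval_s[intervals$condition == "stim"]
  fits <- list(pre = fit_recinormal(pre), stim = fit_recinormal(stim))
  pts <- list(pre = reciprobit_transform(pre),
              stim = reciprobit_transform(stim))
  comparison <- compare_models(pre, stim)
  ratio <- bootstrap_ratio(pre, stim, n_boot = n_boot, seed = seed)
  freq <- frequency_stats(intervals)

  report <- structure(
    list(intervals = intervals,
         discard_log = attr(intervals, "discard_log"),
         fits = fits, reciprobit = pts, comparison = comparison,
         ratio = ratio, frequency = freq, seed = as.integer(seed)),
    class = "later_report"
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_intervals(intervals, file.path(out_dir, "intervals.csv"))
    write_reciprobit(pts$pre, file.path(out_dir, "reciprobit_pre.csv"))
    write_reciprobit(pts$stim, file.path(out_dir, "reciprobit_stim.csv"))
    writeLines(report_to_json(report), file.path(out_dir, "report.json"))
    if (plots) {
      plot_reciprobit(pts, fits = list(pre = fits$pre$params,
                                       stim = fits$stim$params),
                      file = file.path(out_dir, "reciprobit.png"))
      plot_frequency_violins(intervals,
                             file = file.path(out_dir, "frequency_violins.png"))
    }
  }
  report
}

#' Serialise a pipeline report to JSON
#'
#' @param report A `later_report` from [analyze_stream()].
#' @return A JSON string.
#' @export
report_to_json <- function(report) {
  stopifnot(inherits(report, "later_report"))
  obj <- list(
    seed = report$seed,
    discard_log = report$discard_log,
    fits = lapply(report$fits, function(f) {
      list(mu_p = f$params$mu_p, sigma_p = f$params$sigma_p,
           loglik = f$loglik, n = f$n)
    }),
    comparison = list(
      winner = report$comparison$winner,
      ranking = report$comparison$ranking,
      delta_bic = report$comparison$delta_bic,
      models = lapply(report$comparison$fits, function(f) {
        list(loglik = f$loglik, n_params = f$n_params, n_obs = f$n_obs,
             bic = f$bic)
      })
    ),
    threshold_ratio = list(ratio = report$ratio$ratio,
                           ci_low = report$ratio$ci_low,
                           ci_high = report$ratio$ci_high,
                           n_boot = report$ratio$n_boot,
                           seed = report$ratio$seed),
    frequency = list(note = report$frequency$note,
                     cells = report$frequency$cells,
                     posthoc = report$frequency$posthoc)
  )
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                   dataframe = "rows", pretty = TRUE)
}

#' @export
print.later_report <- function(x, ...) {
  cat("LATER pipeline report\n")
  cat(sprintf("  intervals: %d pre, %d stim (%d discarded of %d pairs)\n",
              x$discard_log$n_pre, x$discard_log$n_stim,
              x$discard_log$n_discarded, x$discard_log$n_pairs))
  print(x$comparison)
  print(x$ratio)
  invisible(x)
}
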