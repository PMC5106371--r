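#' Labelled inter-movement interval dataset
#'
#' Constructor for the tabular container used throughout the analysis: one
#' row per interval with its condition (`"pre"` or `"stim"`), effector and
#' patient labels. If a `quantization_step` is recorded, every interval must
#' sit on that grid (within floating tolerance), since quantized event times
#' differ by grid multiples.
#'
#' @param interval_s Interval durations (s), strictly positive.
#' @param condition Condition label per interval (`"pre"` / `"stim"`).
#' @param effector,patient Labels (recycled if scalar).
#' @param quantization_step Optional grid step (s).
#' @return A data frame of class `interval_dataset` with columns
#'   `interval_s`, `condition`, `effector`, `patient`.
#' @export
interval_dataset <- function(interval_s, condition, effector = "manual",
                             patient = "p1", quantization_step = NULL) {
  check_intervals(interval_s, min_n = 1L, what = "interval_s")
  n <- length(interval_s)
  condition <- rep_len(as.character(condition), n)
  if (!all(condition %in% c("pre", "stim"))) {
    stop_domain("condition labels must be 'pre' or 'stim'")
  }
  if (!is.null(quantization_step)) {
    mult <- interval_s / quantization_step
    if (any(abs(mult - round(mult)) > 1e-6)) {
      stop_domain("intervals are not multiples of the stated quantization step")
    }
  }
  out <- data.frame(interval_s = interval_s, condition = condition,
                    effector = rep_len(as.character(effector), n),
                    patient = rep_len(as.character(patient), n))
  attr(out, "quantization_step") <- quantization_step
  class(out) <- c("interval_dataset", "data.frame")
  out
}

#' Read / write interval tables as CSV
#'
#' Columns `interval_s, condition, effector, patient`, header required,
#' UTF-8, '.' decimal.
#'
#' @param data An `interval_dataset` (or compatible data frame).
#' @param path File path.
#' @return `write_intervals`: `path` invisibly; `read_intervals`: an
#'   `interval_dataset`.
#' @export
write_intervals <- function(data, path) {
  cols <- c("interval_s", "condition", "effector", "patient")
  stopifnot(all(cols %in% names(data)))
  write.csv(as.data.frame(data)[, cols], path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop_laterace(sprintf("no such file: %s", path),
                                        "laterace_io")
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8"),
                 error = function(e) stop_laterace(
                   sprintf("malformed CSV %s: %s", path, conditionMessage(e)),
                   "laterace_parse"))
  cols <- c("interval_s", "condition", "effector", "patient")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    stop_laterace(sprintf("CSV %s lacks required column(s): %s (line 1)",
                          path, paste(missing_cols, collapse = ", ")),
                  "laterace_parse")
  }
  interval_dataset(df$interval_s, df$condition, df$effector, df$patient)
}

#' Convert an event stream to labelled intervals
#'
#' Intervals are successive differences between events of one block. Window
#' membership of an event follows a half-open convention: an event belongs
#' to the stimulation window when `stim_onset <= t <= stim_offset` (an event
#' at exactly the onset is "stim") and to the pre window when
#' `stim_onset - pre_window <= t < stim_onset`. An interval is labelled
#' `"stim"` iff both bounding events are in the stimulation window, `"pre"`
#' iff both are in the pre window; all other intervals -- straddling the
#' onset, or touching events outside both windows -- are discarded and
#' counted. The counts satisfy
#' `n_pre + n_stim + n_discarded = n_events - 1`.
#'
#' @param stream An `event_stream`.
#' @param pre_window Length (s) of the pre-stimulation analysis window,
#'   ending at onset. Defaults to the stimulation duration (capped at the
#'   available pre period), so the two conditions are comparable in
#'   exposure.
#' @return An [interval_dataset()] with attribute `discard_log`, a list with
#'   `n_pairs`, `n_pre`, `n_stim`, `n_discarded` and `n_straddle_onset`.
#' @examples
#' s <- simulate_experiment(experiment_config(seed = 7))
#' d <- events_to_intervals(s)
#' attr(d, "discard_log")
#' @export
events_to_intervals <- function(stream, pre_window = NULL) {
  stopifnot(inherits(stream, "event_stream"))
  times <- stream$event_times
  onset <- stream$stim_onset
  offset <- stream$stim_offset
  if (is.null(onset) || is.null(offset) || onset >= offset) {
    stop_domain("stream must carry a valid stimulation window (onset < offset)")
  }
  if (is.null(pre_window)) {
    pre_window <- min(offset - onset, onset - min(times))
  }
  if (pre_window <= 0) stop_domain("pre_window must be positive")
  if (any(diff(times) <= 0)) stop_domain("event times must be strictly increasing")

  in_pre <- times >= (onset - pre_window) & times < onset
  in_stim <- times >= onset & times <= offset
  if (sum(in_pre) < 2L) {
    stop_insufficient("fewer than 2 events in the pre window")
  }
  if (sum(in_stim) < 2L) {
    stop_insufficient("fewer than 2 events in the stim window")
  }
  n_ev <- length(times)
  a <- seq_len(n_ev - 1L)
  b <- a + 1L
  lab <- rep(NA_character_, n_ev - 1L)
  lab[in_pre[a] & in_pre[b]] <- "pre"
  lab[in_stim[a] & in_stim[b]] <- "stim"
  keep <- !is.na(lab)
  straddle <- times[a] < onset & times[b] >= onset &
    times[a] >= (onset - pre_window) & times[b] <= offset
  log <- list(n_pairs = n_ev - 1L,
              n_pre = sum(lab == "pre", na.rm = TRUE),
              n_stim = sum(lab == "stim", na.rm = TRUE),
              n_discarded = sum(!keep),
              n_straddle_onset = sum(straddle & !keep))
  out <- interval_dataset(diff(times)[keep], lab[keep],
                          effector = stream$effector,
                          patient = stream$patient,
                          quantization_step = stream$quantization_step)
  attr(out, "discard_log") <- log
  out
}

#' Combine interval datasets
#'
#' Row-binds datasets from several blocks/streams into one table for
#' [frequency_stats()].
#'
#' @param ... `interval_dataset` objects, or a single list of them.
#' @return An `interval_dataset`.
#' @export
bind_intervals <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "data.frame")) {
    parts <- parts[[1]]
  }
  df <- do.call(rbind, lapply(parts, as.data.frame))
  interval_dataset(df$interval_s, df$condition, df$effector, df$patient)
}

#' Frequency statistics across patients, effectors and conditions
#'
#' Computes, per patient x effector x condition cell, the mean and SEM of
#' instantaneous frequency (`1/interval`, Hz) with the cell size; an omnibus
#' ANOVA of frequency on stimulation condition, effector, patient and their
#' interactions; and post hoc pre-vs-stim pooled-variance t tests within
#' each patient x effector cell, Bonferroni-adjusted over the number of
#' cells tested.
#'
#' The omnibus model is an ordinary-least-squares fixed-effects
#' approximation: patient enters as a fixed categorical predictor, not as a
#' random effect -- with very few patients a random-effect variance is
#' ill-estimated. This is flagged in the report header. Factors with a
#' single observed level are dropped from the model formula.
#'
#' @param data An [interval_dataset()] (possibly combined with
#'   [bind_intervals()]).
#' @param min_n Minimum intervals per cell; smaller cells are excluded with
#'   a warning.
#' @return A list of class `frequency_report`: `note`, `cells` (data frame
#'   with `patient`, `effector`, `condition`, `mean_hz`, `sem_hz`, `n`),
#'   `omnibus` (ANOVA table as a data frame, or `NULL` when no factor
#'   varies), `posthoc` (data frame with raw and Bonferroni-adjusted p
#'   values), and `m` (number of post hoc comparisons).
#' @export
frequency_stats <- function(data, min_n = 2L) {
  stopifnot(inherits(data, "data.frame"))
  df <- as.data.frame(data)
  df$freq <- 1 / df$interval_s
  if (any(!is.finite(df$freq)) || any(df$freq <= 0)) {
    stop_domain("all instantaneous frequencies must be finite and positive")
  }

  cells <- aggregate(freq ~ patient + effector + condition, df,
                     function(v) c(mean = mean(v),
                                   sem = sd(v) / sqrt(length(v)),
                                   n = length(v)))
  cells <- cbind(cells[, c("patient", "effector", "condition")],
                 as.data.frame(cells$freq))
  names(cells) <- c("patient", "effector", "condition",
                    "mean_hz", "sem_hz", "n")
  small <- cells$n < min_n
  if (any(small)) {
    warning(sprintf("%d cell(s) below the minimum of %d intervals were excluded",
                    sum(small), min_n))
    drop_keys <- paste(cells$patient, cells$effector, cells$condition)[small]
    df <- df[!(paste(df$patient, df$effector, df$condition) %in% drop_keys), ]
    cells <- cells[!small, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop_insufficient("no cells meet the minimum size")

  # omnibus OLS with whatever factors actually vary
  preds <- c("condition", "effector", "patient")
  preds <- preds[vapply(preds, function(v) length(unique(df[[v]])) > 1, logical(1))]
  omnibus <- NULL
  if (length(preds) > 0) {
    for (v in preds) df[[v]] <- factor(df[[v]])
    fml <- stats::as.formula(paste("freq ~", paste(preds, collapse = " * ")))
    aovtab <- anova(lm(fml, data = df))
    omnibus <- data.frame(term = rownames(aovtab), as.data.frame(aovtab),
                          row.names = NULL, check.names = FALSE)
  }

  # post hoc pre-vs-stim per patient x effector cell
  combos <- unique(df[, c("patient", "effector")])
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sub <- df[df$patient == combos$patient[i] & df$effector == combos$effector[i], ]
    f_pre <- sub$freq[sub$condition == "pre"]
    f_stim <- sub$freq[sub$condition == "stim"]
    if (length(f_pre) >= min_n && length(f_stim) >= min_n) {
      tt <- t.test(f_stim, f_pre, var.equal = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        patient = combos$patient[i], effector = combos$effector[i],
        mean_pre_hz = mean(f_pre), mean_stim_hz = mean(f_stim),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p_raw = tt$p.value)
    }
  }
  posthoc <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  m <- if (is.null(posthoc)) 0L else nrow(posthoc)
  if (!is.null(posthoc)) posthoc$p_adj <- pmin(1, posthoc$p_raw * m)

  structure(
    list(note = paste("Omnibus test is an ordinary-least-squares fixed-effects",
                      "approximation: patient is a fixed factor, not a random",
                      "effect."),
         cells = cells, omnibus = omnibus, posthoc = posthoc, m = m),
    class = "frequency_report"
  )
}

#' @export
print.frequency_report <- function(x, ...) {
  cat("Frequency report\n")
  cat("  NOTE:", x$note, "\n\n")
  cat("Per-cell instantaneous frequency (Hz):\n")
  print(x$cells, row.names = FALSE, digits = 4)
  if (!is.null(x$omnibus)) {
    cat("\nOmnibus ANOVA (OLS):\n")
    print(x$omnibus, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$posthoc)) {
    cat(sprintf("\nPost hoc pre vs stim (pooled-variance t, Bonferroni m = %d):\n", x$m))
    print(x$posthoc, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Frequency report as JSON
#'
#' @param report A `frequency_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written).
#' @export
frequency_report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "frequency_report"))
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           null = "null", dataframe = "rows", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Violin plot of instantaneous frequency per cell
#'
#' Shows the distribution of `1/interval` (Hz) per condition, faceted by
#' patient and effector, pre vs stim side by side.
#'
#' @param data An [interval_dataset()].
#' @param file Optional path (`.png`/`.svg`) to save to.
#' @param width,height Device size in inches when saving.
#' @return The ggplot object, invisibly.
#' @export
plot_frequency_violins <- function(data, file = NULL, width = 6, height = 4.5) {
  df <- as.data.frame(data)
  df$freq <- 1 / df$interval_s
  df$condition <- factor(df$condition, levels = c("pre", "stim"))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = condition, y = freq,
                                         fill = condition)) +
    ggplot2::geom_violin(trim = TRUE, alpha = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.4,
                          colour = "red", linewidth = 0.3) +
    ggplot2::facet_grid(patient ~ effector) +
    ggplot2::labs(x = NULL, y = "instantaneous frequency (Hz)") +
    ggplot2::theme_classic() +
    ggplot2::theme(legend.position = "none")
  if (!is.null(file)) ggplot2::ggsave(file, gg, width = width, height = height)
  invisible(gg)
}
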