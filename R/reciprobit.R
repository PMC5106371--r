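#' Reciprobit transformation of an interval sample
#'
#' Maps intervals to the coordinates in which a recinormal sample is linear:
#' abscissa `-1/t` (negated promptness, so that time still increases to the
#' right, reaching 0 at infinite time) and ordinate the probit (standard
#' normal quantile) of the empirical cumulative position. Plotting positions
#' follow the Hazen convention `(i - 0.5)/n`, which keeps the extreme probits
#' finite. Tied interval values are collapsed to a single point whose
#' position is the mean of the tied plotting positions (probit applied after
#' averaging).
#'
#' Under a true recinormal the points fall on the line
#' `ordinate = abscissa / sigma_p + mu_p / sigma_p`: slope `1/sigma_p` and
#' intercept `mu_p/sigma_p` at abscissa 0 (infinite time).
#'
#' @param intervals Interval durations (s); at least 3.
#' @return A data frame of class `reciprobit_points` with columns `abscissa`
#'   (strictly increasing) and `ordinate` (strictly increasing), and
#'   attribute `n` (the sample size before tie collapsing).
#' @examples
#' pts <- reciprobit_transform(c(1, 1/2, 1/3))
#' pts$abscissa  # -3 -2 -1
#' @export
reciprobit_transform <- function(intervals) {
  check_intervals(intervals, min_n = 3L)
  n <- length(intervals)
  x <- sort(-1 / intervals)           # ascending: fastest first
  pos <- (seq_len(n) - 0.5) / n       # Hazen plotting positions
  # collapse exact ties to the mean of their plotting positions
  grp <- match(x, unique(x))
  ux <- unique(x)
  upos <- vapply(split(pos, grp), mean, numeric(1))
  out <- data.frame(abscissa = ux, ordinate = qnorm(upos))
  attr(out, "n") <- n
  class(out) <- c("reciprobit_points", "data.frame")
  out
}

#' Theoretical reciprobit line of a recinormal distribution
#'
#' @param params A [recinormal_params()] object.
#' @return A list with `slope` (`1/sigma_p`), `intercept` (`mu_p/sigma_p`,
#'   the ordinate at abscissa 0, i.e. infinite time).
#' @export
reciprobit_line <- function(params) {
  params <- as_recinormal_params(params)
  list(slope = 1 / params$sigma_p, intercept = params$mu_p / params$sigma_p)
}

#' Write reciprobit points to CSV
#'
#' Two columns, `abscissa` and `ordinate`, for external plotting.
#'
#' @param points A `reciprobit_points` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reciprobit <- function(points, path) {
  stopifnot(inherits(points, "reciprobit_points"))
  write.csv(as.data.frame(points)[, c("abscissa", "ordinate")],
            path, row.names = FALSE)
  invisible(path)
}

#' Reciprobit chart
#'
#' Plots interval samples in reciprobit coordinates, optionally overlaying
#' fitted recinormal lines, in the style standard for LATER analyses: the
#' abscissa is reciprocal time (labelled in seconds), the ordinate the
#' z-score of cumulative position.
#'
#' @param points A `reciprobit_points` object, or a named list of them (one
#'   per condition).
#' @param fits Optional [recinormal_params()] object or named list matching
#'   `points`, drawn as dashed lines.
#' @param file Optional path (`.png` or `.svg`) to save to.
#' @param width,height Device size in inches when saving.
#' @return The ggplot object, invisibly.
#' @export
plot_reciprobit <- function(points, fits = NULL, file = NULL,
                            width = 6, height = 4.5) {
  if (inherits(points, "reciprobit_points")) points <- list(sample = points)
  df <- do.call(rbind, lapply(names(points), function(nm) {
    cbind(as.data.frame(points[[nm]]), condition = nm)
  }))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = abscissa, y = ordinate,
                                         colour = condition)) +
    ggplot2::geom_point(size = 1, alpha = 0.7)
  if (!is.null(fits)) {
    if (inherits(fits, "recinormal_params")) fits <- list(sample = fits)
    for (nm in names(fits)) {
      ln <- reciprobit_line(fits[[nm]])
      gg <- gg + ggplot2::geom_abline(slope = ln$slope,
                                      intercept = ln$intercept,
                                      linetype = "dashed")
    }
  }
  brk_t <- c(0.2, 0.3, 0.5, 1, Inf)   # seconds marked on the reciprocal axis
  gg <- gg +
    ggplot2::scale_x_continuous(breaks = -1 / brk_t,
                                labels = c("0.2", "0.3", "0.5", "1", "Inf")) +
    ggplot2::labs(x = "interval (s, reciprocal scale)",
                  y = "z score of cumulative position",
                  colour = NULL) +
    ggplot2::theme_classic()
  if (!is.null(file)) {
    ggplot2::ggsave(file, gg, width = width, height = height)
  }
  invisible(gg)
}
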