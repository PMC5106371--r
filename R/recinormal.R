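#' Recinormal (reciprocal-normal) parameter set
#'
#' Parameters of an interval distribution on the promptness scale: if `T` is
#' an inter-movement interval, the promptness `1/T` is modelled as
#' `N(mu_p, sigma_p^2)`. In LATER terms `mu_p = mu_r / theta` and
#' `sigma_p = sigma_r / theta`, where `theta` is the baseline-to-threshold
#' distance and `mu_r`, `sigma_r` the mean and SD of the rate of rise.
#'
#' The promptness normal is left untruncated: mass at or below zero promptness
#' corresponds to "no response" trials and is ignored by the likelihood. When
#' `mu_p / sigma_p < 2` (more than about 2.3% of promptness mass at or below
#' zero) the object carries `near_boundary = TRUE` as a validity flag; this is
#' a warning sign, not an error.
#'
#' @param mu_p Mean promptness (1/s); must be positive.
#' @param sigma_p SD of promptness (1/s); must be positive.
#' @return An object of class `recinormal_params` with fields `mu_p`,
#'   `sigma_p`, `k` (the infinite-time reciprobit intercept `mu_p / sigma_p`)
#'   and `near_boundary`.
#' @examples
#' p <- recinormal_params(2.96, 0.44)
#' p$k  # reciprobit intercept at infinite time
#' @export
recinormal_params <- function(mu_p, sigma_p) {
  if (!is.numeric(mu_p) || length(mu_p) != 1L || !is.finite(mu_p) || mu_p <= 0) {
    stop_domain("mu_p must be a single finite positive number")
  }
  if (!is.numeric(sigma_p) || length(sigma_p) != 1L || !is.finite(sigma_p) ||
      sigma_p <= 0) {
    stop_domain("sigma_p must be a single finite positive number")
  }
  structure(
    list(mu_p = mu_p, sigma_p = sigma_p, k = mu_p / sigma_p,
         near_boundary = (mu_p / sigma_p) < 2),
    class = "recinormal_params"
  )
}

#' @export
print.recinormal_params <- function(x, ...) {
  cat(sprintf("Recinormal parameters: mu_p = %.4g /s, sigma_p = %.4g /s (intercept k = %.4g)\n",
              x$mu_p, x$sigma_p, x$k))
  if (x$near_boundary) {
    cat("  note: mu_p/sigma_p < 2; appreciable promptness mass at or below zero\n")
  }
  invisible(x)
}

as_recinormal_params <- function(params) {
  if (inherits(params, "recinormal_params")) return(params)
  if (inherits(params, "race_params")) {
    return(recinormal_params(params$mu_r / params$theta,
                             params$sigma_r / params$theta))
  }
  stop_domain("params must be recinormal_params or race_params")
}

#' Recinormal density
#'
#' Density of an interval `T` whose reciprocal (promptness) is
#' `N(mu_p, sigma_p^2)`. By change of variables,
#' `f(t) = t^-2 * sigma_p^-1 * phi((1/t - mu_p)/sigma_p)`. The density
#' integrates over `(0, Inf)` to `pnorm(mu_p/sigma_p)`: the untruncated
#' promptness normal assigns its remaining mass to non-responses.
#'
#' @param t Interval durations (s); strictly positive.
#' @param params A [recinormal_params()] object (or `race_params`).
#' @param log Return log-density?
#' @return Density values (1/s), vectorised over `t`.
#' @seealso [precinorm()], [fit_recinormal()]
#' @export
drecinorm <- function(t, params, log = FALSE) {
  params <- as_recinormal_params(params)
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t)) || any(t <= 0)) {
    stop_domain("t must be finite and strictly positive")
  }
  ld <- dnorm(1 / t, mean = params$mu_p, sd = params$sigma_p, log = TRUE) -
    2 * base::log(t)
  if (log) ld else exp(ld)
}

#' Recinormal cumulative distribution function
#'
#' `P(T <= t) = P(promptness >= 1/t) = pnorm((mu_p - 1/t) / sigma_p)`.
#' Monotone nondecreasing in `t`, with limit `pnorm(mu_p / sigma_p)` as
#' `t -> Inf` (the non-response mass is never reached).
#'
#' @inheritParams drecinorm
#' @return Probabilities, vectorised over `t`.
#' @export
precinorm <- function(t, params) {
  params <- as_recinormal_params(params)
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t)) || any(t <= 0)) {
    stop_domain("t must be finite and strictly positive")
  }
  pnorm((params$mu_p - 1 / t) / params$sigma_p)
}

#' Recinormal quantile function
#'
#' Inverse of [precinorm()]. Defined for `p < pnorm(mu_p/sigma_p)`; above that
#' limit the interval is infinite (no response) and `Inf` is returned.
#'
#' @param p Probabilities.
#' @inheritParams drecinorm
#' @return Interval durations (s).
#' @export
qrecinorm <- function(p, params) {
  params <- as_recinormal_params(params)
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop_domain("p must lie in [0, 1]")
  }
  inv <- params$mu_p - params$sigma_p * qnorm(p)
  ifelse(inv > 0, 1 / inv, Inf)
}

#' Recinormal log-likelihood of a set of intervals
#'
#' Sum of log recinormal densities, i.e. the promptness-scale normal
#' log-likelihood plus the Jacobian term `-2 * sum(log(t))`.
#'
#' @param intervals Interval durations (s).
#' @inheritParams drecinorm
#' @return A single number.
#' @export
recinormal_loglik <- function(intervals, params) {
  params <- as_recinormal_params(params)
  check_intervals(intervals, min_n = 1L)
  sum(drecinorm(intervals, params, log = TRUE))
}

#' Maximum-likelihood recinormal fit
#'
#' The MLE is closed-form on the promptness scale: with `p_i = 1/t_i`,
#' `mu_p = mean(p_i)` and `sigma_p = sqrt(mean((p_i - mu_p)^2))` (divisor `n`,
#' the ML variance estimator). The reported log-likelihood is on the interval
#' scale (it includes the reciprocal-transform Jacobian), so it is comparable
#' across models fitted to the same intervals.
#'
#' @param intervals Interval durations (s); at least 3, strictly positive,
#'   not all identical.
#' @return A list of class `recinormal_fit` with elements `params`
#'   ([recinormal_params()]), `loglik`, and `n`.
#' @examples
#' fit <- fit_recinormal(c(0.5, 0.5, 0.25, 0.25))
#' fit$params$mu_p   # 3
#' fit$params$sigma_p  # 1
#' @export
fit_recinormal <- function(intervals) {
  check_intervals(intervals, min_n = 3L)
  p <- 1 / intervals
  mu <- mean(p)
  s2 <- mean((p - mu)^2)
  if (s2 <= 0) {
    stop_degenerate("all intervals identical: promptness variance is zero")
  }
  params <- recinormal_params(mu, sqrt(s2))
  structure(
    list(params = params,
         loglik = recinormal_loglik(intervals, params),
         n = length(intervals)),
    class = "recinormal_fit"
  )
}

#' @export
print.recinormal_fit <- function(x, ...) {
  cat(sprintf("Recinormal ML fit (n = %d): mu_p = %.4g, sigma_p = %.4g, loglik = %.4f\n",
              x$n, x$params$mu_p, x$params$sigma_p, x$loglik))
  invisible(x)
}

#' Mechanistic race parameters
#'
#' LATER parameterisation: a decision signal rises linearly from baseline at a
#' rate drawn per trial from `N(mu_r, sigma_r^2)` and triggers a movement on
#' reaching a threshold at distance `theta`. The interval is `theta / rate`,
#' so on the promptness scale `mu_p = mu_r/theta`, `sigma_p = sigma_r/theta`.
#' Only two of the three parameters are identifiable from interval data; the
#' package convention fixes `theta = 1` in the baseline condition, so only
#' ratios of `theta` across conditions are meaningful.
#'
#' @param theta Baseline-to-threshold distance (arbitrary units), positive.
#' @param mu_r Mean rate of rise (units/s), positive.
#' @param sigma_r SD of the rate of rise (units/s), positive.
#' @return An object of class `race_params`.
#' @seealso [as_race_params()] for the reverse mapping.
#' @export
race_params <- function(theta, mu_r, sigma_r) {
  vals <- c(theta = theta, mu_r = mu_r, sigma_r = sigma_r)
  if (!is.numeric(vals) || any(!is.finite(vals)) || any(vals <= 0)) {
    stop_domain("theta, mu_r and sigma_r must all be finite and positive")
  }
  structure(list(theta = theta, mu_r = mu_r, sigma_r = sigma_r),
            class = "race_params")
}

#' @export
print.race_params <- function(x, ...) {
  cat(sprintf("Race parameters: theta = %.4g, mu_r = %.4g /s, sigma_r = %.4g /s\n",
              x$theta, x$mu_r, x$sigma_r))
  invisible(x)
}

#' Convert promptness parameters to race parameters
#'
#' Applies the identifiability convention `theta = 1` (so `mu_r = mu_p` and
#' `sigma_r = sigma_p`) unless another `theta` is supplied.
#'
#' @param params A [recinormal_params()] object.
#' @param theta Threshold distance to assume; default 1.
#' @return A [race_params()] object.
#' @export
as_race_params <- function(params, theta = 1) {
  params <- as_recinormal_params(params)
  race_params(theta, params$mu_p * theta, params$sigma_p * theta)
}
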