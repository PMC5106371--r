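# Two-condition constrained LATER fits and BIC model comparison.
#
# All four models are normal models on the promptness scale p = 1/t:
#   null          one (mu_p, sigma_p) shared by both conditions    (2 params)
#   shift         per-condition mu_p, shared sigma_p               (3 params)
#                   -> reciprobit lines translate along the time axis at
#                      constant slope (changed rate of rise)
#   swivel        shared intercept k0 = mu_p/sigma_p, per-condition
#                   sigma_p                                        (3 params)
#                   -> reciprobit lines pivot about the infinite-time
#                      intercept (changed baseline-to-threshold distance)
#   unconstrained per-condition (mu_p, sigma_p)                    (4 params)
#
# Sufficient statistics (n, sum p, sum p^2) make every likelihood evaluation
# O(1); null/shift/unconstrained have closed-form MLEs, and swivel reduces to
# a 1-D profile likelihood in k0 whose inner per-condition sigma maximiser is
# the positive root of a quadratic.

.suffstats <- function(p) {
  list(n = length(p), s1 = sum(p), s2 = sum(p * p))
}

# normal loglik (promptness scale, no Jacobian) from sufficient statistics
.norm_ll <- function(ss, mu, sigma) {
  -ss$n / 2 * log(2 * pi) - ss$n * log(sigma) -
    (ss$s2 - 2 * mu * ss$s1 + ss$n * mu * mu) / (2 * sigma * sigma)
}

# profile over sigma for fixed intercept k0 (mu = k0 * sigma): the stationary
# condition n*sigma^2 + k0*s1*sigma - s2 = 0 has a unique positive root.
.swivel_sigma <- function(ss, k0) {
  (-k0 * ss$s1 + sqrt(k0 * k0 * ss$s1 * ss$s1 + 4 * ss$n * ss$s2)) / (2 * ss$n)
}

.swivel_profile_ll <- function(k0, ss_pre, ss_stim) {
  s_pre <- .swivel_sigma(ss_pre, k0)
  s_stim <- .swivel_sigma(ss_stim, k0)
  .norm_ll(ss_pre, k0 * s_pre, s_pre) + .norm_ll(ss_stim, k0 * s_stim, s_stim)
}

# swivel ML from sufficient statistics; coarse profile grid over k0_range
# then Brent refinement on the bracketing subinterval
.fit_swivel_suff <- function(ss_pre, ss_stim, k0_range = c(0.5, 50),
                             n_grid = 40L) {
  grid <- exp(seq(log(k0_range[1]), log(k0_range[2]), length.out = n_grid))
  ll_grid <- vapply(grid, .swivel_profile_ll, numeric(1), ss_pre, ss_stim)
  i <- which.max(ll_grid)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(n_grid, i + 1L)]
  opt <- optimize(.swivel_profile_ll, c(lo, hi), ss_pre = ss_pre,
                  ss_stim = ss_stim, maximum = TRUE, tol = 1e-10)
  k0 <- opt$maximum
  ll <- opt$objective
  if (i == 1L || i == n_grid) {
    # best coarse value at the edge of the search interval: report the best
    # iterate but flag non-convergence
    at_edge <- (i == 1L && ll_grid[1] > ll) || (i == n_grid && ll_grid[n_grid] > ll)
    if (at_edge) {
      k0 <- grid[i]
      ll <- ll_grid[i]
    }
    warning(sprintf("swivel intercept optimum at the boundary of [%g, %g]; best iterate k0 = %.4g returned",
                    k0_range[1], k0_range[2], k0))
  }
  s_pre <- .swivel_sigma(ss_pre, k0)
  s_stim <- .swivel_sigma(ss_stim, k0)
  list(k0 = k0, loglik = ll,
       pre = c(mu = k0 * s_pre, sigma = s_pre),
       stim = c(mu = k0 * s_stim, sigma = s_stim))
}

.check_condition <- function(x, what) {
  check_intervals(x, min_n = 3L, what = sprintf("%s intervals", what))
  if (var(1 / x) <= 0) {
    stop_degenerate(sprintf("%s intervals are all identical: zero promptness variance", what))
  }
  invisible(x)
}

#' Joint two-condition constrained maximum-likelihood fit
#'
#' Fits one of four nested LATER models to a pre-stimulation and a
#' stimulation interval sample. On the promptness scale the models are
#' Gaussian: `"null"` shares both parameters across conditions; `"shift"`
#' shares `sigma_p` (common reciprobit slope: a change of rate of rise);
#' `"swivel"` shares the infinite-time intercept `mu_p/sigma_p` (a change of
#' baseline-to-threshold distance); `"unconstrained"` frees all four
#' parameters. Null, shift and unconstrained have closed-form MLEs; swivel is
#' maximised along its one-dimensional profile in the shared intercept, with
#' the per-condition `sigma_p` maximiser in closed form.
#'
#' Reported log-likelihoods are on the interval scale (the reciprocal
#' Jacobian is included), and `bic = -2 * loglik + n_params * log(n_obs)`
#' with `n_obs` the total number of intervals across both conditions.
#'
#' @param pre Pre-stimulation intervals (s); at least 3, positive, with
#'   nonzero promptness variance.
#' @param stim Stimulation-window intervals (s); same requirements.
#' @param model_kind One of `"null"`, `"shift"`, `"swivel"`,
#'   `"unconstrained"`.
#' @param k0_range Search interval for the shared swivel intercept
#'   `mu_p/sigma_p`.
#' @return An object of class `joint_fit`: `model_kind`, `params_pre`,
#'   `params_stim` ([recinormal_params()]), `loglik`, `n_params`, `n_obs`,
#'   `bic`.
#' @examples
#' pre <- simulate_later(recinormal_params(3, 0.4), 500, seed = 1)
#' stim <- simulate_later(recinormal_params(4.5, 0.6), 500, seed = 2)
#' fit_joint(pre, stim, "swivel")
#' @export
fit_joint <- function(pre, stim,
                      model_kind = c("null", "shift", "swivel", "unconstrained"),
                      k0_range = c(0.5, 50)) {
  model_kind <- match.arg(model_kind)
  .check_condition(pre, "pre")
  .check_condition(stim, "stim")
  p1 <- 1 / pre
  p2 <- 1 / stim
  ss1 <- .suffstats(p1)
  ss2 <- .suffstats(p2)
  n <- ss1$n + ss2$n
  jac <- -2 * (sum(log(pre)) + sum(log(stim)))

  if (model_kind == "null") {
    mu <- (ss1$s1 + ss2$s1) / n
    s2 <- (ss1$s2 + ss2$s2) / n - mu * mu
    if (s2 <= 0) stop_degenerate("pooled promptness variance is zero")
    sg <- sqrt(s2)
    ll <- .norm_ll(ss1, mu, sg) + .norm_ll(ss2, mu, sg)
    pp <- recinormal_params(mu, sg)
    ps <- pp
    k <- 2L
  } else if (model_kind == "unconstrained") {
    mu1 <- ss1$s1 / ss1$n; sg1 <- sqrt(ss1$s2 / ss1$n - mu1 * mu1)
    mu2 <- ss2$s1 / ss2$n; sg2 <- sqrt(ss2$s2 / ss2$n - mu2 * mu2)
    ll <- .norm_ll(ss1, mu1, sg1) + .norm_ll(ss2, mu2, sg2)
    pp <- recinormal_params(mu1, sg1)
    ps <- recinormal_params(mu2, sg2)
    k <- 4L
  } else if (model_kind == "shift") {
    mu1 <- ss1$s1 / ss1$n
    mu2 <- ss2$s1 / ss2$n
    s2 <- ((ss1$s2 - ss1$n * mu1 * mu1) + (ss2$s2 - ss2$n * mu2 * mu2)) / n
    if (s2 <= 0) stop_degenerate("pooled within-condition promptness variance is zero")
    sg <- sqrt(s2)
    ll <- .norm_ll(ss1, mu1, sg) + .norm_ll(ss2, mu2, sg)
    pp <- recinormal_params(mu1, sg)
    ps <- recinormal_params(mu2, sg)
    k <- 3L
  } else {  # swivel
    sw <- .fit_swivel_suff(ss1, ss2, k0_range = k0_range)
    ll <- sw$loglik
    pp <- recinormal_params(unname(sw$pre["mu"]), unname(sw$pre["sigma"]))
    ps <- recinormal_params(unname(sw$stim["mu"]), unname(sw$stim["sigma"]))
    k <- 3L
  }

  ll <- ll + jac
  structure(
    list(model_kind = model_kind, params_pre = pp, params_stim = ps,
         loglik = ll, n_params = k, n_obs = n,
         bic = -2 * ll + k * log(n)),
    class = "joint_fit"
  )
}

#' @export
print.joint_fit <- function(x, ...) {
  cat(sprintf("Joint %s fit (n_obs = %d, %d params): loglik = %.4f, BIC = %.4f\n",
              x$model_kind, x$n_obs, x$n_params, x$loglik, x$bic))
  cat(sprintf("  pre:  mu_p = %.4g, sigma_p = %.4g\n",
              x$params_pre$mu_p, x$params_pre$sigma_p))
  cat(sprintf("  stim: mu_p = %.4g, sigma_p = %.4g\n",
              x$params_stim$mu_p, x$params_stim$sigma_p))
  invisible(x)
}

#' Evidence labels for BIC differences
#'
#' Kass--Raftery bands on `delta = BIC(rival) - BIC(winner)`:
#' `(0, 2]` "weak", `(2, 6]` "substantial", `(6, 10]` "strong", `> 10`
#' "very strong"; nonpositive differences are labelled "none".
#'
#' @param delta Numeric vector of BIC differences.
#' @return Character vector of labels.
#' @examples
#' bic_evidence_label(c(4.82, 13.45, 32.38))
#' @export
bic_evidence_label <- function(delta) {
  if (!is.numeric(delta)) stop_domain("delta must be numeric")
  out <- character(length(delta))
  out[delta <= 0] <- "none"
  out[delta > 0 & delta <= 2] <- "weak"
  out[delta > 2 & delta <= 6] <- "substantial"
  out[delta > 6 & delta <= 10] <- "strong"
  out[delta > 10] <- "very strong"
  out
}

#' Compare the four two-condition LATER models by BIC
#'
#' Fits null, shift, swivel and unconstrained models to the same data, ranks
#' them by BIC (ascending: lower is better) and labels the winner's BIC
#' advantage over each rival with Kass--Raftery evidence bands.
#'
#' @inheritParams fit_joint
#' @return An object of class `model_comparison`: `fits` (named list of
#'   [fit_joint()] results), `ranking` (model names, best first), `winner`,
#'   and `delta_bic` (data frame of rival, BIC difference to the winner, and
#'   evidence label).
#' @export
compare_models <- function(pre, stim, k0_range = c(0.5, 50)) {
  kinds <- c("null", "shift", "swivel", "unconstrained")
  fits <- lapply(kinds, function(k) fit_joint(pre, stim, k, k0_range = k0_range))
  names(fits) <- kinds
  bics <- vapply(fits, function(f) f$bic, numeric(1))
  ranking <- names(sort(bics))
  winner <- ranking[1]
  rivals <- ranking[-1]
  delta <- bics[rivals] - bics[winner]
  structure(
    list(fits = fits, ranking = ranking, winner = winner,
         delta_bic = data.frame(rival = rivals, delta_bic = unname(delta),
                                evidence = bic_evidence_label(unname(delta)),
                                row.names = NULL)),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf("Model comparison (BIC): winner = %s\n", x$winner))
  tab <- data.frame(
    model = names(x$fits),
    loglik = vapply(x$fits, function(f) f$loglik, numeric(1)),
    n_params = vapply(x$fits, function(f) f$n_params, integer(1)),
    bic = vapply(x$fits, function(f) f$bic, numeric(1)),
    row.names = NULL
  )
  print(tab[order(tab$bic), ], row.names = FALSE)
  cat("Winner's advantage:\n")
  print(x$delta_bic, row.names = FALSE)
  invisible(x)
}

#' Model-comparison report as JSON
#'
#' Serialises a [compare_models()] result (optionally with a
#' [bootstrap_ratio()] estimate) to JSON: per-model loglik, parameter count,
#' n, BIC; the ranking; the winner's BIC margins with evidence labels; and
#' the threshold ratio with its CI, seed and resample count when supplied.
#'
#' @param comparison A `model_comparison` object.
#' @param ratio Optional `threshold_ratio_estimate` from [bootstrap_ratio()].
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
comparison_to_json <- function(comparison, ratio = NULL, path = NULL) {
  stopifnot(inherits(comparison, "model_comparison"))
  obj <- list(
    models = lapply(comparison$fits, function(f) {
      list(loglik = f$loglik, n_params = f$n_params, n_obs = f$n_obs,
           bic = f$bic,
           params_pre = list(mu_p = f$params_pre$mu_p,
                             sigma_p = f$params_pre$sigma_p),
           params_stim = list(mu_p = f$params_stim$mu_p,
                              sigma_p = f$params_stim$sigma_p))
    }),
    ranking = comparison$ranking,
    winner = comparison$winner,
    delta_bic = comparison$delta_bic
  )
  if (!is.null(ratio)) {
    obj$threshold_ratio <- list(ratio = ratio$ratio, ci_low = ratio$ci_low,
                                ci_high = ratio$ci_high,
                                n_boot = ratio$n_boot, seed = ratio$seed)
  }
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Decision-threshold ratio from a swivel fit
#'
#' Under the swivel constraint the two conditions share the infinite-time
#' intercept `mu_p/sigma_p`, so the change is a pure rescaling of the
#' baseline-to-threshold distance: `theta_stim / theta_pre =
#' mu_p_pre / mu_p_stim = sigma_p_pre / sigma_p_stim`. A ratio below 1 means
#' the race was shortened (reversed procrastination). The two parameter
#' ratios are asserted equal within optimizer tolerance.
#'
#' @param fit A [fit_joint()] result with `model_kind == "swivel"`.
#' @param tol Relative tolerance for the mu/sigma ratio agreement check.
#' @return The ratio `theta_stim / theta_pre` (dimensionless).
#' @export
threshold_ratio <- function(fit, tol = 1e-6) {
  if (!inherits(fit, "joint_fit") || fit$model_kind != "swivel") {
    stop_domain("threshold_ratio requires a joint_fit of kind 'swivel'")
  }
  r_mu <- fit$params_pre$mu_p / fit$params_stim$mu_p
  r_sg <- fit$params_pre$sigma_p / fit$params_stim$sigma_p
  if (abs(r_mu - r_sg) > tol * max(r_mu, r_sg)) {
    stop_laterace(sprintf("swivel ratios disagree beyond tolerance: mu ratio %.8g vs sigma ratio %.8g",
                          r_mu, r_sg), "laterace_internal")
  }
  r_mu
}

#' Bootstrap confidence interval for the threshold ratio
#'
#' Resamples intervals with replacement within each condition (condition
#' membership is fixed by the stimulation protocol, so sizes are preserved),
#' refits the swivel model to each resample and collects the threshold
#' ratio. The interval is the percentile CI at level `conf`. Deterministic
#' given `seed`. A resample on which the swivel fit fails (e.g. a degenerate
#' resample) is redrawn, up to `10 * n_boot` total draws.
#'
#' @inheritParams fit_joint
#' @param n_boot Number of bootstrap resamples (at least 200).
#' @param seed Integer seed controlling the resampling.
#' @param conf Confidence level (default 0.95 for a 2.5/97.5 percentile CI).
#' @return An object of class `threshold_ratio_estimate`: `ratio` (the
#'   point estimate from the full data), `ci_low`, `ci_high`, `n_boot`,
#'   `seed`, `conf` and the vector of bootstrap `ratios`.
#' @export
bootstrap_ratio <- function(pre, stim, n_boot = 1000L, seed = NULL,
                            conf = 0.95, k0_range = c(0.5, 50)) {
  if (!is.numeric(n_boot) || n_boot < 200) {
    stop_domain("n_boot must be at least 200")
  }
  n_boot <- as.integer(n_boot)
  fit <- fit_joint(pre, stim, "swivel", k0_range = k0_range)
  point <- threshold_ratio(fit)
  p1 <- 1 / pre
  p2 <- 1 / stim
  n1 <- length(p1)
  n2 <- length(p2)
  ratios <- with_seed(seed, {
    out <- numeric(n_boot)
    got <- 0L
    attempts <- 0L
    max_attempts <- 10L * n_boot
    while (got < n_boot) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop_laterace(sprintf("bootstrap exhausted %d resample attempts", max_attempts),
                      "laterace_bootstrap_failure")
      }
      b1 <- p1[sample.int(n1, n1, replace = TRUE)]
      b2 <- p2[sample.int(n2, n2, replace = TRUE)]
      if (var(b1) <= 0 || var(b2) <= 0) next
      sw <- tryCatch(
        suppressWarnings(.fit_swivel_suff(.suffstats(b1), .suffstats(b2),
                                          k0_range = k0_range)),
        error = function(e) NULL
      )
      if (is.null(sw)) next
      got <- got + 1L
      out[got] <- sw$pre["mu"] / sw$stim["mu"]
    }
    out
  })
  alpha <- (1 - conf) / 2
  ci <- quantile(ratios, c(alpha, 1 - alpha), names = FALSE, type = 7)
  structure(
    list(ratio = point, ci_low = ci[1], ci_high = ci[2],
         n_boot = n_boot, seed = seed, conf = conf, ratios = ratios),
    class = "threshold_ratio_estimate"
  )
}

#' @export
print.threshold_ratio_estimate <- function(x, ...) {
  cat(sprintf("Threshold ratio theta_stim/theta_pre = %.3f (%.0f%% percentile bootstrap CI %.3f to %.3f, %d resamples)\n",
              x$ratio, 100 * x$conf, x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}
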