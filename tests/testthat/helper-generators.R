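# Shared generators for the test suite. All stochastic helpers take an
# explicit seed so every test is reproducible.

# study-condition baseline promptness parameters (2.96 Hz, CV 0.15)
baseline_params <- function() recinormal_params(2.96, 0.15 * 2.96)

# scale both promptness parameters by 1/factor: a pure swivel
swivel_params <- function(params, factor) {
  recinormal_params(params$mu_p / factor, params$sigma_p / factor)
}

# pre/stim interval pair under a chosen generating truth
make_condition_pair <- function(truth = c("swivel", "shift", "null"),
                                factor = 0.65, n = 2000, seed = 1) {
  truth <- match.arg(truth)
  base <- baseline_params()
  stim_par <- switch(truth,
    swivel = swivel_params(base, factor),
    shift = recinormal_params(base$mu_p / factor, base$sigma_p),
    null = base
  )
  list(pre = simulate_later(base, n, seed = seed),
       stim = simulate_later(stim_par, n, seed = seed + 500000L),
       params_pre = base, params_stim = stim_par)
}

# deterministic threshold factor in (0.5, 1.2) for property tests
runif_seeded <- function(seed) withr::with_seed(seed, runif(1, 0.5, 1.2))

# independent dense-grid maximiser of the single-condition recinormal
# likelihood around a centre (used as the MLE oracle)
grid_loglik_max <- function(intervals, mu_centre, sigma_centre,
                            half_width = 0.05, step = 1e-3) {
  mus <- seq(mu_centre - half_width, mu_centre + half_width, by = step)
  sgs <- seq(max(step, sigma_centre - half_width),
             sigma_centre + half_width, by = step)
  p <- 1 / intervals
  n <- length(p)
  s1 <- sum(p)
  s2 <- sum(p * p)
  jac <- -2 * sum(log(intervals))
  best <- -Inf
  for (sg in sgs) {
    ll <- -n / 2 * log(2 * pi) - n * log(sg) -
      (s2 - 2 * mus * s1 + n * mus^2) / (2 * sg^2)
    m <- max(ll)
    if (m > best) best <- m
  }
  best + jac
}

# independent dense 3-D grid maximiser of the swivel likelihood, exploiting
# the separability of the joint likelihood over conditions at fixed shared
# intercept k0 (for each k0, the per-condition sigma grids are searched
# exhaustively and independently)
swivel_grid_oracle <- function(pre, stim, n_k0 = 400, n_sigma = 400) {
  ll_cond <- function(x, k0, sgs) {
    p <- 1 / x
    n <- length(p)
    s1 <- sum(p)
    s2 <- sum(p * p)
    # matrix over (k0 x sigma): loglik of N(k0*sigma, sigma)
    out <- matrix(NA_real_, length(k0), length(sgs))
    for (j in seq_along(sgs)) {
      sg <- sgs[j]
      mu <- k0 * sg
      out[, j] <- -n / 2 * log(2 * pi) - n * log(sg) -
        (s2 - 2 * mu * s1 + n * mu^2) / (2 * sg^2)
    }
    apply(out, 1, max)
  }
  f1 <- fit_recinormal(pre)$params
  f2 <- fit_recinormal(stim)$params
  k_lo <- 0.6 * min(f1$k, f2$k)
  k_hi <- 1.4 * max(f1$k, f2$k)
  k0 <- seq(k_lo, k_hi, length.out = n_k0)
  sg1 <- seq(0.6 * f1$sigma_p, 1.6 * f1$sigma_p, length.out = n_sigma)
  sg2 <- seq(0.6 * f2$sigma_p, 1.6 * f2$sigma_p, length.out = n_sigma)
  jac <- -2 * (sum(log(pre)) + sum(log(stim)))
  max(ll_cond(pre, k0, sg1) + ll_cond(stim, k0, sg2)) + jac
}
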