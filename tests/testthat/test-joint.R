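test_that("identical samples make the null model the clear BIC winner", {
  x <- simulate_later(baseline_params(), 300, seed = 91)
  cm <- compare_models(x, x)
  expect_identical(cm$winner, "null")
  expect_equal(cm$fits$null$loglik, cm$fits$unconstrained$loglik,
               tolerance = 1e-9)
  expect_true(all(cm$fits$null$bic < vapply(
    cm$fits[c("shift", "swivel", "unconstrained")],
    function(f) f$bic, numeric(1))))
})

test_that("nesting inequalities and the BIC identity hold on random data", {
  for (seed in c(101, 102, 103, 104, 105)) {
    pair <- make_condition_pair("swivel", factor = runif_seeded(seed),
                                n = 120, seed = seed)
    fits <- lapply(c("null", "shift", "swivel", "unconstrained"),
                   function(k) fit_joint(pair$pre, pair$stim, k))
    names(fits) <- c("null", "shift", "swivel", "unconstrained")
    lls <- vapply(fits, function(f) f$loglik, numeric(1))
    expect_gte(lls["unconstrained"], lls["shift"] - 1e-9)
    expect_gte(lls["unconstrained"], lls["swivel"] - 1e-9)
    expect_gte(lls["shift"], lls["null"] - 1e-9)
    expect_gte(lls["swivel"], lls["null"] - 1e-9)
    for (f in fits) {
      expect_equal(f$bic, -2 * f$loglik + f$n_params * log(f$n_obs))
      expect_identical(f$n_obs, length(pair$pre) + length(pair$stim))
    }
    expect_identical(vapply(fits, function(f) f$n_params, integer(1)),
                     c(null = 2L, shift = 3L, swivel = 3L, unconstrained = 4L))
  }
})

test_that("constraints are satisfied by the fitted parameters", {
  pair <- make_condition_pair("swivel", n = 400, seed = 111)
  f_null <- fit_joint(pair$pre, pair$stim, "null")
  expect_equal(f_null$params_pre$mu_p, f_null$params_stim$mu_p)
  expect_equal(f_null$params_pre$sigma_p, f_null$params_stim$sigma_p)
  f_shift <- fit_joint(pair$pre, pair$stim, "shift")
  expect_equal(f_shift$params_pre$sigma_p, f_shift$params_stim$sigma_p)
  f_swivel <- fit_joint(pair$pre, pair$stim, "swivel")
  expect_equal(f_swivel$params_pre$k, f_swivel$params_stim$k,
               tolerance = 1e-8)
})

test_that("swivel fit recovers an exact-swivel truth", {
  pre <- simulate_later(recinormal_params(3.0, 0.4), 2000, seed = 121)
  stim <- simulate_later(recinormal_params(4.5, 0.6), 2000, seed = 122)
  fit <- fit_joint(pre, stim, "swivel")
  expect_lt(abs(fit$params_pre$mu_p - 3.0) / 3.0, 0.03)
  expect_lt(abs(fit$params_pre$sigma_p - 0.4) / 0.4, 0.03)
  expect_lt(abs(fit$params_stim$mu_p - 4.5) / 4.5, 0.03)
  expect_lt(abs(fit$params_stim$sigma_p - 0.6) / 0.6, 0.03)
  expect_lt(abs(threshold_ratio(fit) - 2/3), 0.02)
})

test_that("swivel ML matches an independent dense grid search", {
  for (seed in c(131, 132, 133)) {
    pair <- make_condition_pair("swivel", n = 50, seed = seed)
    fit <- fit_joint(pair$pre, pair$stim, "swivel")
    oracle <- swivel_grid_oracle(pair$pre, pair$stim)
    # the optimizer must reach at least the grid's best likelihood
    expect_lt((oracle - fit$loglik) / abs(fit$loglik), 1e-6)
  }
})

test_that("degenerate inputs are rejected with classed errors", {
  x <- simulate_later(baseline_params(), 50, seed = 141)
  expect_error(fit_joint(rep(0.3, 10), x, "swivel"),
               class = "laterace_degenerate")
  expect_error(fit_joint(x[1:2], x, "null"),
               class = "laterace_insufficient_data")
})

test_that("threshold ratio requires a swivel fit and is 1 under no change", {
  pair <- make_condition_pair("null", n = 2000, seed = 151)
  f_unc <- fit_joint(pair$pre, pair$stim, "unconstrained")
  expect_error(threshold_ratio(f_unc), class = "laterace_domain")
  f_sw <- fit_joint(pair$pre, pair$stim, "swivel")
  expect_lt(abs(threshold_ratio(f_sw) - 1), 0.03)
  # exactly equal conditions give exactly ratio 1
  f_same <- fit_joint(pair$pre, pair$pre, "swivel")
  expect_equal(threshold_ratio(f_same), 1, tolerance = 1e-9)
})

test_that("BIC selection of the generating model sharpens with sample size", {
  win_rate <- function(truth, n) {
    wins <- 0L
    for (s in 1:20) {
      pair <- make_condition_pair(truth, factor = 0.65, n = n,
                                  seed = 1000L * n + s)
      cm <- compare_models(pair$pre, pair$stim)
      wins <- wins + (cm$winner == truth)
    }
    wins
  }
  for (truth in c("swivel", "shift")) {
    rates <- vapply(c(50, 200, 2000), function(n) win_rate(truth, n),
                    integer(1))
    # counts at 20 replicates carry binomial noise; allow one win of slack
    # around the expected nondecreasing trend
    expect_true(all(diff(rates) >= -1L))
    expect_gte(rates[3], 18L)
  }
})

test_that("evidence labels follow the Kass-Raftery bands", {
  expect_identical(bic_evidence_label(c(-1, 0)), c("none", "none"))
  expect_identical(bic_evidence_label(c(0.5, 2)), c("weak", "weak"))
  expect_identical(bic_evidence_label(c(2.1, 6)),
                   c("substantial", "substantial"))
  expect_identical(bic_evidence_label(c(6.01, 10)), c("strong", "strong"))
  expect_identical(bic_evidence_label(10.0001), "very strong")
})

test_that("bootstrap CI is deterministic, ordered, and honest under null", {
  pair <- make_condition_pair("null", n = 200, seed = 161)
  b1 <- bootstrap_ratio(pair$pre, pair$stim, n_boot = 300, seed = 7)
  b2 <- bootstrap_ratio(pair$pre, pair$stim, n_boot = 300, seed = 7)
  expect_identical(b1$ratios, b2$ratios)
  expect_identical(c(b1$ci_low, b1$ci_high), c(b2$ci_low, b2$ci_high))
  expect_lte(b1$ci_low, b1$ratio)
  expect_gte(b1$ci_high, b1$ratio)
  expect_true(b1$ci_low <= 1 && b1$ci_high >= 1)
  # identical pre/stim samples: CI must straddle 1
  x <- simulate_later(baseline_params(), 150, seed = 162)
  b3 <- bootstrap_ratio(x, x, n_boot = 300, seed = 8)
  expect_true(b3$ci_low <= 1 && b3$ci_high >= 1)
  expect_error(bootstrap_ratio(pair$pre, pair$stim, n_boot = 100),
               class = "laterace_domain")
})

test_that("model comparison report serialises to JSON with all fields", {
  pair <- make_condition_pair("swivel", n = 300, seed = 171)
  cm <- compare_models(pair$pre, pair$stim)
  br <- bootstrap_ratio(pair$pre, pair$stim, n_boot = 200, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  comparison_to_json(cm, ratio = br, path = path)
  back <- jsonlite::fromJSON(path)
  expect_setequal(names(back$models),
                  c("null", "shift", "swivel", "unconstrained"))
  expect_identical(back$winner, cm$winner)
  expect_equal(back$models$swivel$bic, cm$fits$swivel$bic)
  expect_equal(back$threshold_ratio$ratio, br$ratio)
  expect_equal(back$threshold_ratio$n_boot, br$n_boot)
})
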