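test_that("zero drift from a centered start gives symmetric boundary densities", {
  p <- ddm_params(a = 1.2, z_rel = 0.5, t0 = 0)
  t <- c(0.05, 0.2, 0.5, 1, 2, 4)
  up <- wiener_fpt_density(t, p, drift = 0, boundary = "upper")
  lo <- wiener_fpt_density(t, p, drift = 0, boundary = "lower")
  expect_equal(up, lo, tolerance = 1e-10)
  expect_true(all(up >= 0))
  expect_error(wiener_fpt_density(0, p, 0), "> 0")
})

test_that("boundary densities integrate to unit total absorption mass", {
  for (prm in list(c(1.5, 1 / 3, 0.8), c(1.0, 0.5, 0), c(2.2, 0.7, -1.2))) {
    p <- ddm_params(a = prm[1], z_rel = prm[2], t0 = 0)
    v <- prm[3]
    iu <- integrate(function(t) wiener_fpt_density(t, p, v, "upper"),
                    0, Inf, rel.tol = 1e-8)$value
    il <- integrate(function(t) wiener_fpt_density(t, p, v, "lower"),
                    0, Inf, rel.tol = 1e-8)$value
    expect_equal(iu + il, 1, tolerance = 1e-5)
    # the closed-form absorption probability matches the quadrature
    expect_equal(iu, upper_choice_probability(p, v), tolerance = 1e-5)
  }
})

test_that("absorption probability has the zero-drift limit and is continuous", {
  p <- ddm_params(z_rel = 1 / 3)
  expect_equal(upper_choice_probability(p, 0), 1 / 3)
  expect_equal(upper_choice_probability(p, 1e-12), 1 / 3, tolerance = 1e-6)
  expect_equal(upper_choice_probability(p, -1e-12), 1 / 3, tolerance = 1e-6)
  # extremes saturate without overflow
  expect_equal(upper_choice_probability(p, 50), 1)
  expect_equal(upper_choice_probability(p, -50), 0)
  expect_true(all(diff(upper_choice_probability(p, seq(-3, 3, 0.1))) > 0))
})

test_that("the series density matches an Euler-Maruyama path histogram", {
  p <- ddm_params(a = 1.5, z_rel = 1 / 3, t0 = 0)
  v <- 0.6
  n <- 1e5
  sim <- simulate_ddm_trials(p, drifts = rep(v, n), max_rt = 6, dt = 1e-4,
                             seed = 99)
  # compare bin masses of upper-boundary passages against quadrature of the
  # analytic density, at binomial-error tolerance
  breaks <- c(0.1, 0.25, 0.4, 0.6, 0.9, 1.4, 2.2)
  rt_yes <- sim$rt_s[sim$choice == "yes"]
  for (i in seq_len(length(breaks) - 1)) {
    p_bin <- integrate(function(t) wiener_fpt_density(t, p, v, "upper"),
                       breaks[i], breaks[i + 1], rel.tol = 1e-8)$value
    obs <- mean(rt_yes >= breaks[i] & rt_yes < breaks[i + 1]) *
      length(rt_yes) / n
    se <- sqrt(p_bin * (1 - p_bin) / n)
    expect_lt(abs(obs - p_bin), 4 * se + 0.002)
  }
  # choice fractions also match the analytic absorption probability
  expect_lt(abs(mean(sim$choice == "yes") - upper_choice_probability(p, v)),
            4 * sqrt(0.25 / n) + 0.002)
})

test_that("survival mass complements the first-passage CDF", {
  p <- ddm_params(a = 1.5, z_rel = 1 / 3, t0 = 0)
  v <- 0.4
  s <- wiener_survival(1.2, p, v)
  cdf <- integrate(function(t) {
    wiener_fpt_density(t, p, v, "upper") + wiener_fpt_density(t, p, v, "lower")
  }, 0, 1.2, rel.tol = 1e-9)$value
  expect_equal(s, 1 - cdf, tolerance = 1e-5)
  expect_true(wiener_survival(8, p, v) < 1e-3)
})

test_that("non-decision time floors all reaction times", {
  s <- simulate_ddm_trials(ddm_params(t0 = 0.3), drifts = rep(0.5, 2000),
                           seed = 2)
  expect_true(all(s$rt_s[s$choice != "missed"] > 0.3))
})

test_that("strong positive drift makes yes responses faster than no", {
  s <- simulate_ddm_trials(ddm_params(z_rel = 0.5), drifts = rep(2, 20000),
                           seed = 3)
  r <- s[s$choice != "missed", ]
  expect_lt(median(r$rt_s[r$choice == "yes"]),
            median(r$rt_s[r$choice == "no"]))
})

test_that("the censored MLE recovers generating parameters", {
  gen <- ddm_params(a = 1.5, z_rel = 1 / 3, t0 = 0.3, drift_scale = 0.8)
  set.seed(5)
  sv <- rnorm(1000, 0, 2)
  sim <- simulate_ddm_trials(gen, drifts = gen$drift_scale * sv, seed = 6)
  fit <- fit_ddm_mle(tibble::tibble(choice = sim$choice, rt_s = sim$rt_s,
                                    sv = sv))
  expect_true(abs(fit$params$z_rel - 1 / 3) < 0.05)
  expect_true(abs(fit$params$a - 1.5) < 0.2)
  expect_true(abs(fit$params$t0 - 0.3) < 0.05)
  expect_true(abs(fit$params$drift_scale - 0.8) < 0.2)
  # likelihood consistency: the optimum beats perturbed parameters
  nll_hat <- fit$neg_loglik
  for (shift in list(c(0.3, 0, 0, 0), c(0, 0.15, 0, 0), c(0, 0, 0, 0.5))) {
    par_pert <- c(fit$params$a, fit$params$z_rel, fit$params$t0,
                  fit$params$drift_scale) + shift
    expect_gt(
      selfreg:::ddm_neg_loglik(par_pert, sim$choice, sim$rt_s, sv),
      nll_hat
    )
  }
})

test_that("a symmetric zero-drift generator is fitted as unbiased", {
  gen <- ddm_params(a = 1.5, z_rel = 0.5, t0 = 0.3, drift_scale = 0.8)
  sv <- rep(0, 1500)
  sim <- simulate_ddm_trials(gen, drifts = sv, seed = 7)
  fit <- fit_ddm_mle(tibble::tibble(choice = sim$choice, rt_s = sim$rt_s,
                                    sv = rnorm(1500)))
  expect_lt(abs(fit$params$z_rel - 0.5), 0.05)
  expect_lt(abs(fit$params$drift_scale), 0.15)
})

test_that("underdetermined and one-sided inputs are flagged", {
  gen <- ddm_params()
  sim <- simulate_ddm_trials(gen, drifts = rep(0, 5), seed = 8)
  tiny <- tibble::tibble(choice = sim$choice, rt_s = sim$rt_s, sv = rnorm(5))
  if (all(tiny$choice == "missed")) skip("degenerate draw")
  fit <- if (length(unique(tiny$choice[tiny$choice != "missed"])) < 2) {
    suppressWarnings(fit_ddm_mle(tiny))
  } else {
    fit_ddm_mle(tiny)
  }
  expect_false(fit$converged)

  one_sided <- tibble::tibble(
    choice = rep("no", 60), rt_s = runif(60, 0.4, 1.5), sv = rnorm(60)
  )
  expect_warning(f2 <- fit_ddm_mle(one_sided), "one boundary")
  expect_false(f2$converged)
})

test_that("starting-point recovery bias shrinks with trials per participant", {
  gen <- ddm_params(a = 1.5, z_rel = 1 / 3, t0 = 0.3, drift_scale = 0.8)
  bias_at <- function(n, seed) {
    set.seed(seed)
    sv <- rnorm(n, 0, 2)
    sim <- simulate_ddm_trials(gen, drifts = gen$drift_scale * sv,
                               seed = seed + 1)
    fit <- suppressWarnings(
      fit_ddm_mle(tibble::tibble(choice = sim$choice, rt_s = sim$rt_s,
                                 sv = sv), min_responded = 20)
    )
    abs(fit$params$z_rel - 1 / 3)
  }
  errs <- c(
    mean(vapply(1:4, function(i) bias_at(100, 100 + i), 0)),
    mean(vapply(1:4, function(i) bias_at(2000, 200 + i), 0))
  )
  expect_lt(errs[2], errs[1] + 0.01)
  expect_lt(errs[2], 0.03)
})
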