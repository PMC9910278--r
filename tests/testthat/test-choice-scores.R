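test_that("taste/health weights are recovered from logistic-generated choices", {
  d <- logistic_choices(5000, w_taste = 1.5, w_health = 1.5, seed = 42)
  fit <- fit_taste_health_weights(d)
  expect_false(fit$separation_flag)
  expect_true(abs(fit$w_taste - 1.5) < 0.1)
  expect_true(abs(fit$w_health - 1.5) < 0.1)
})

test_that("IRLS solution attains the grid-search likelihood optimum", {
  d <- logistic_choices(50, w_taste = 1.0, w_health = 0.8, seed = 7)
  fit <- fit_taste_health_weights(d)
  y <- as.integer(d$choice == "yes")
  x1 <- d$tr - mean(d$tr)
  x2 <- d$hr - mean(d$hr)
  # coarse independent grid over the three coefficients
  grid <- expand.grid(
    b0 = seq(-2, 2, by = 0.1),
    b1 = seq(-0.5, 3, by = 0.1),
    b2 = seq(-0.5, 3, by = 0.1)
  )
  ll <- mapply(logistic_loglik, grid$b0, grid$b1, grid$b2,
               MoreArgs = list(y = y, x1 = x1, x2 = x2))
  best <- grid[which.max(ll), ]
  ll_fit <- logistic_loglik(fit$beta0, fit$w_taste, fit$w_health, y, x1, x2)
  expect_gte(ll_fit, max(ll))
  expect_lt(abs(fit$beta0 - best$b0), 0.11)
  expect_lt(abs(fit$w_taste - best$b1), 0.11)
  expect_lt(abs(fit$w_health - best$b2), 0.11)
})

test_that("one-sided choosers are flagged for separation, degenerate inputs error", {
  never <- tibble::tibble(tr = runif(60, -5, 5), hr = runif(60, -5, 5),
                          choice = "no")
  fit <- fit_taste_health_weights(never)
  expect_true(fit$separation_flag)
  expect_true(all(is.finite(c(fit$beta0, fit$w_taste, fit$w_health))))

  const_taste <- tibble::tibble(tr = 2, hr = runif(30, -5, 5),
                                choice = rep(c("yes", "no"), 15))
  expect_error(fit_taste_health_weights(const_taste), "zero variance")
  all_missed <- tibble::tibble(tr = 1:5, hr = 1:5, choice = "missed")
  expect_error(fit_taste_health_weights(all_missed), "missed")
})

test_that("subjective value is the weighted rating sum, linear and intercept-free", {
  f <- structure(list(w_taste = 1.47, w_health = 1.46, converged = TRUE),
                 class = "weight_fit")
  expect_equal(subjective_value(1, -1, f), 0.01)
  expect_equal(subjective_value(0, 0, f), 0)
  f2 <- structure(list(w_taste = 2 * 1.47, w_health = 2 * 1.46,
                       converged = TRUE), class = "weight_fit")
  expect_equal(subjective_value(1.3, -0.4, f2),
               2 * subjective_value(1.3, -0.4, f))
  f_bad <- structure(list(w_taste = 1, w_health = 1, converged = FALSE),
                     class = "weight_fit")
  expect_error(subjective_value(1, 1, f_bad), "converge")
})

test_that("decision conflict is negative absolute value, maximal at sv = 0", {
  f <- structure(list(w_taste = 1, w_health = 1, converged = TRUE),
                 class = "weight_fit")
  expect_equal(decision_conflict(0, 0, f), 0)
  expect_equal(decision_conflict(1.5, -3.8, f), -abs(1.5 - 3.8))
  # symmetry: mirrored trial has identical conflict
  expect_equal(decision_conflict(2, -1, f), decision_conflict(-2, 1, f))
  expect_true(all(decision_conflict(runif(50, -5, 5), runif(50, -5, 5), f) <= 0))
})

test_that("stakes are |tr|+|hr| on challenges and exactly zero on aligned trials", {
  expect_equal(stakes(4, -3), 7)
  expect_equal(stakes(-2, 3), 5)
  expect_equal(stakes(2, 3), 0)
  expect_equal(stakes(-2, -3), 0)
  expect_error(stakes(-0.2, 3), "neutral")
  # property over a grid: nonnegative, positive iff challenge
  g <- expand.grid(tr = seq(-5, 5, 0.7), hr = seq(-5, 5, 0.7))
  g <- g[classify_trial_type(g$tr, g$hr) != "excluded", ]
  s <- stakes(g$tr, g$hr)
  expect_true(all(s >= 0))
  expect_identical(s > 0, is_challenge(classify_trial_type(g$tr, g$hr)))
})

test_that("orthogonalization matches the normal-equations solution", {
  set.seed(9)
  target <- rnorm(20)
  reference <- rnorm(20)
  res <- orthogonalize_modulator(target, reference)
  # independent oracle: solve X'X b = X'y directly and take residuals
  X <- cbind(1, reference - mean(reference))
  y <- target - mean(target)
  b <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(res, as.numeric(y - X %*% b), tolerance = 1e-12)
  expect_lt(abs(mean(res)), 1e-12)
  expect_lt(abs(sum(res * (reference - mean(reference)))), 1e-9)
})

test_that("orthogonalized stakes ignore affine functions of the reference", {
  set.seed(10)
  conflict <- -abs(rnorm(40))
  st <- abs(rnorm(40)) + 2
  base <- orthogonalize_modulator(st, conflict)
  shifted <- orthogonalize_modulator(st + 3 - 1.7 * conflict, conflict)
  expect_equal(base, shifted, tolerance = 1e-10)
  # full collinearity collapses to zero; orthogonal input passes through
  expect_equal(orthogonalize_modulator(conflict, conflict), rep(0, 40),
               tolerance = 1e-10)
  expect_warning(orthogonalize_modulator(st, rep(1, 40)), "constant")
})

test_that("self-control success counts responded challenge trials only", {
  trials <- tibble::tibble(
    trial_type = c("HTLH", "HTLH", "LTHH", "LTHH", "HTHH", "HTLH"),
    choice = c("no", "no", "yes", "no", "yes", "missed")
  )
  s <- score_self_control(trials)
  expect_equal(s$success_overall, 0.75)   # 3 of 4 responded challenges
  expect_equal(s$success_htlh, 1.0)
  expect_equal(s$success_lthh, 0.5)
  expect_equal(s$n_challenge, 5)
  expect_equal(s$n_missed_challenge, 1)
  expect_true(is.na(s$scs[5]))            # aligned trial never scored
  # success + failure partition the responded challenges
  scs <- s$scs[!is.na(s$scs)]
  expect_equal(mean(scs == "success") + mean(scs == "failure"), 1)

  none <- score_self_control(tibble::tibble(
    trial_type = c("HTHH", "HTLH"), choice = c("yes", "missed")
  ))
  expect_true(none$undefined)
  expect_true(is.na(none$success_overall))
})

test_that("refusal-biased cohorts succeed more on HTLH than LTHH challenges", {
  cfg <- small_config(n = 8, seed = 33)
  cohort <- generate_cohort(cfg)
  sc <- score_cohort(cohort)
  ps <- sc$participant_scores[!sc$participant_scores$excluded_flag, ]
  expect_gt(mean(ps$success_htlh, na.rm = TRUE),
            mean(ps$success_lthh, na.rm = TRUE))
})

test_that("score_trials assembles all trial-wise scores coherently", {
  cfg <- small_config(n = 1, seed = 12)
  cohort <- generate_cohort(cfg)
  d <- cohort$choices
  fit <- fit_taste_health_weights(d)
  sc <- score_trials(d, fit)
  expect_true(all(c("sv", "conflict", "stakes", "stakes_orth") %in% names(sc)))
  expect_equal(sc$conflict, -abs(sc$sv))
  ch <- is_challenge(sc$trial_type)
  expect_true(all(sc$stakes[!ch] == 0))
  expect_true(all(sc$stakes[ch] > 0))
  expect_true(all(is.na(sc$stakes_orth[!ch])))
  expect_lt(abs(mean(sc$stakes_orth[ch])), 1e-9)
})
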