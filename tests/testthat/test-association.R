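test_that("perfectly monotone data give rho 1 with a degenerate upper bound", {
  x <- 1:12
  y <- exp(x / 3)
  r <- correlate(x, y, method = "rank", n_resamples = 500, seed = 1)
  expect_equal(r$rho, 1)
  expect_equal(r$interval_high, 1)
  expect_equal(r$pp_positive, 1)
})

test_that("Spearman on bivariate normals matches the closed-form attenuation", {
  # independent oracle: population Spearman = (6/pi) asin(rho/2)
  set.seed(11)
  n <- 10000
  x <- rnorm(n)
  y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  r <- correlate(x, y, method = "rank", n_resamples = 200, seed = 2)
  expect_lt(abs(r$rho - (6 / pi) * asin(0.25)), 0.02)
})

test_that("correlate is symmetric and rank-invariant to monotone transforms", {
  set.seed(12)
  x <- rnorm(38)
  y <- rnorm(38)
  a <- correlate(x, y, n_resamples = 300, seed = 3)
  b <- correlate(y, x, n_resamples = 300, seed = 3)
  expect_equal(a$rho, b$rho)
  mono <- correlate(exp(x), rank(y)^3, n_resamples = 300, seed = 3)
  expect_equal(mono$rho, a$rho)
  # linear method differs under non-linear transforms
  lin <- correlate(x, y, method = "linear", n_resamples = 300, seed = 3)
  expect_equal(lin$rho, cor(x, y))
})

test_that("degenerate and undersized inputs error cleanly", {
  expect_error(correlate(rep(1, 10), rnorm(10)), "constant")
  expect_error(correlate(1:3, 3:1), "4 complete pairs")
  # pairwise-complete handling drops NA pairs
  x <- c(1:9, NA)
  y <- c(NA, 2:10)
  r <- correlate(x, y, n_resamples = 200, seed = 4)
  expect_equal(r$n, 8)
})

test_that("two-stage summaries average stage-1 coefficients with t intervals", {
  fits <- tibble::tibble(
    participant_id = sprintf("P%d", 1:6),
    taste = c(1.2, 1.5, 1.4, 1.6, 1.3, 1.5),
    health = c(1.1, 1.4, 1.5, 1.7, 1.2, 1.6),
    converged = TRUE
  )
  g <- two_stage_group_model(fits)
  expect_equal(g$estimate[g$term == "taste"], mean(fits$taste))
  tt <- t.test(fits$taste)
  expect_equal(g$interval_low[g$term == "taste"], unname(tt$conf.int[1]))
  expect_true(all(g$interval_low <= g$estimate & g$estimate <= g$interval_high))
  # degenerate: identical participants flagged
  same <- tibble::tibble(participant_id = sprintf("P%d", 1:4), b = rep(2, 4))
  expect_true(two_stage_group_model(same)$degenerate)
  expect_error(two_stage_group_model(fits[1:2, ]), "fewer than 3")
})

test_that("group estimates agree for equal generating taste and health weights", {
  cfg <- small_config(
    n = 12, seed = 41,
    weight_means = c(taste = 1.5, health = 1.5),
    weight_sds = c(taste = 0.15, health = 0.15)
  )
  cohort <- generate_cohort(cfg)
  s1 <- fit_stage1_models(cohort, model = "choice")
  g <- two_stage_group_model(s1)
  est <- setNames(g$estimate, g$term)
  half <- setNames((g$interval_high - g$interval_low) / 2, g$term)
  expect_lt(abs(est[["taste"]] - est[["health"]]),
            half[["taste"]] + half[["health"]])
})

test_that("stage-1 models run for all four trial-level regressions", {
  cfg <- small_config(n = 5, seed = 42)
  cohort <- generate_cohort(cfg)
  scores <- score_cohort(cohort)
  # rt model needs trial scores merged in
  cohort_scored <- cohort
  cohort_scored$choices <- scores$trial_scores

  rating <- fit_stage1_models(cohort, "rating")
  expect_true(all(c("negative_view", "positive_view") %in% names(rating)))
  expect_equal(nrow(rating), 5)
  # negative view sits far below the neutral-view intercept
  expect_lt(mean(rating$negative_view), -1)

  choice <- fit_stage1_models(cohort, "choice")
  expect_true(all(choice$taste > 0))

  success <- fit_stage1_models(cohort, "success")
  expect_true(nrow(success) >= 3)

  rt <- fit_stage1_models(cohort_scored, "rt")
  expect_true(all(c("yes", "stakes", "difficulty") %in% names(rt)))
  g <- two_stage_group_model(rt)
  # refusal bias: accepting is slower on HTLH challenges
  expect_gt(g$estimate[g$term == "yes_x_htlh"], 0)
})

test_that("cross-task association joins on participants and reports three rhos", {
  set.seed(43)
  ps <- tibble::tibble(
    participant_id = sprintf("P%02d", 1:20),
    success_overall = runif(20),
    excluded_flag = c(rep(FALSE, 4), TRUE, rep(FALSE, 15))
  )
  rs <- tibble::tibble(
    participant_id = sprintf("P%02d", 3:22),
    success_neg = rnorm(20, 1.5), success_pos = rnorm(20, 1.9),
    success_overall = rnorm(20, 1.7)
  )
  out <- cross_task_association(ps, rs, n_resamples = 300, seed = 5)
  expect_named(out, c("overall", "negative", "positive"))
  expect_equal(out$overall$n, 17) # 18 overlap minus 1 excluded
  expect_error(
    cross_task_association(ps[1:4, ], rs[15:20, ], n_resamples = 100),
    "overlapping"
  )
})

test_that("a coupled cohort shows the induced cross-task correlation", {
  cfg <- cohort_config(n_participants = 60, coupling_rho = 0.8, seed = 44,
                       n_trials = 60, n_challenge_target = 45,
                       min_challenge = 25)
  cohort <- generate_cohort(cfg)
  sc <- score_cohort(cohort)
  out <- cross_task_association(sc$participant_scores, sc$reappraisal_scores,
                                n_resamples = 500, seed = 6)
  # behavioral correlation should echo the ground-truth coupling direction
  gt <- cohort$ground_truth
  rho_gt <- cor((gt$delta_neg + gt$delta_pos) / 2, gt$w_health,
                method = "spearman")
  expect_gt(rho_gt, 0.5)
  expect_gt(out$overall$rho, 0)
})

test_that("recovery reports carry the declared fields", {
  cfg <- small_config(n = 4, seed = 45)
  rep <- parameter_recovery_experiment(cfg, fit_ddm = FALSE)
  expect_true(all(c("w_ratio", "success_neg", "success_pos", "coupling") %in%
                    names(rep)))
  expect_true(is.numeric(rep$w_ratio$bias) && is.numeric(rep$w_ratio$rmse))
  js <- jsonlite::toJSON(unclass(rep), auto_unbox = TRUE)
  expect_true(jsonlite::validate(js))
})
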