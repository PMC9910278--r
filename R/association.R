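#' Correlation with bootstrap uncertainty
#'
#' Spearman rank or Pearson linear correlation between two per-participant
#' score vectors, with a bias-corrected accelerated (BCa) bootstrap 95%
#' interval and the bootstrap fraction of positive correlations
#' (`pp_positive`, an analogue of a posterior probability that the
#' correlation is positive). Incomplete pairs are dropped pairwise.
#'
#' @param x,y numeric vectors of equal length.
#' @param method `"rank"` (Spearman) or `"linear"` (Pearson).
#' @param n_resamples bootstrap replicates (default 10000).
#' @param seed integer seed for the bootstrap.
#' @param conf interval level.
#' @return an object of class `correlation_result`: list with `rho`,
#'   `interval_low`, `interval_high`, `pp_positive`, `method`, `n`.
#' @examples
#' set.seed(1)
#' x <- rnorm(30); y <- x + rnorm(30)
#' correlate(x, y, method = "rank", n_resamples = 500, seed = 1)
#' @export
correlate <- function(x, y, method = c("rank", "linear"),
                      n_resamples = 10000, seed = 1L, conf = 0.95) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("constant input vector: correlation undefined", call. = FALSE)
  }
  cor_method <- if (method == "rank") "spearman" else "pearson"
  rho <- cor(x, y, method = cor_method)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  dat <- cbind(x, y)
  stat <- function(d, idx) {
    xs <- d[idx, 1]
    ys <- d[idx, 2]
    if (sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
    cor(xs, ys, method = cor_method)
  }
  bt <- boot::boot(dat, stat, R = n_resamples)
  reps <- bt$t[is.finite(bt$t)]
  ci <- tryCatch(
    boot::boot.ci(bt, conf = conf, type = "bca")$bca[4:5],
    error = function(e) quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                                 names = FALSE)
  )
  # degenerate bootstrap (e.g. perfectly monotone data): the interval
  # collapses onto the point estimate side
  if (is.null(ci) || any(!is.finite(ci))) ci <- range(reps)
  structure(
    list(
      rho = rho,
      interval_low = min(ci[1], rho),
      interval_high = max(ci[2], rho),
      pp_positive = mean(reps > 0),
      method = method,
      n = length(x)
    ),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf(
    "<correlation_result> %s rho = %.3f, 95%% CI [%.3f; %.3f], P(rho > 0) = %.3f, n = %d\n",
    x$method, x$rho, x$interval_low, x$interval_high, x$pp_positive, x$n
  ))
  invisible(x)
}

#' Two-stage group summary of per-participant fits
#'
#' Stage 2 of the summary-statistics approximation to hierarchical
#' regression: given a table of per-participant stage-1 coefficients (one
#' row per participant, one column per term), returns the across-
#' participant mean of each coefficient with a t-based 95% interval. A
#' degenerate stage-2 SD of zero is flagged.
#'
#' @param per_participant_fits data frame of stage-1 coefficients; columns
#'   other than `participant_id` and `converged` are treated as terms. Rows
#'   with `converged == FALSE` are dropped when the column is present.
#' @param conf interval level.
#' @return tibble with columns `term`, `estimate`, `se`, `interval_low`,
#'   `interval_high`, `n`, `degenerate`.
#' @export
two_stage_group_model <- function(per_participant_fits, conf = 0.95) {
  df <- tibble::as_tibble(per_participant_fits)
  if ("converged" %in% names(df)) {
    df <- df[is.na(df$converged) | df$converged != FALSE, , drop = FALSE]
  }
  terms <- setdiff(names(df), c("participant_id", "converged"))
  terms <- terms[vapply(df[terms], is.numeric, logical(1))]
  if (length(terms) == 0) stop("no numeric coefficient columns", call. = FALSE)
  n_ok <- sum(stats::complete.cases(df[terms]))
  if (n_ok < 3) {
    stop("fewer than 3 participants with converged stage-1 fits", call. = FALSE)
  }
  rows <- lapply(terms, function(tm) {
    v <- df[[tm]]
    v <- v[is.finite(v)]
    n <- length(v)
    m <- mean(v)
    s <- sd(v) / sqrt(n)
    half <- qt(1 - (1 - conf) / 2, df = n - 1) * s
    tibble::tibble(
      term = tm, estimate = m, se = s,
      interval_low = m - half, interval_high = m + half,
      n = n, degenerate = sd(v) < 1e-12
    )
  })
  dplyr::bind_rows(rows)
}

#' Stage-1 per-participant regressions
#'
#' Fits, for every participant, one of the study's trial-level models and
#' returns the coefficient table that [two_stage_group_model()] summarizes:
#'
#' * `"rating"` — linear regression of the SAM rating on the five emotion
#'   block types (neutral view as reference).
#' * `"choice"` — logistic regression of the yes/eat indicator on
#'   mean-centered taste and health ratings.
#' * `"success"` — logistic regression of challenge-trial success on
#'   within-participant z-scored taste and health, the LTHH indicator, and
#'   their interactions.
#' * `"rt"` — linear regression of log RT (responded trials) on the yes
#'   indicator, trial type, stakes, decision conflict (difficulty), and the
#'   yes x type interaction.
#'
#' @param cohort a [generate_cohort()] result, or a list with the needed
#'   tables (`choices` with scores for `"rt"`, `emotion` for `"rating"`).
#' @param model which model to fit.
#' @return tibble of per-participant coefficients with a `converged` flag.
#' @export
fit_stage1_models <- function(cohort,
                              model = c("rating", "choice", "success", "rt")) {
  model <- match.arg(model)
  safely_coef <- function(expr) {
    tryCatch(expr, error = function(e) NULL, warning = function(w) {
      tryCatch(suppressWarnings(expr), error = function(e) NULL)
    })
  }
  if (model == "rating") {
    dat <- cohort$emotion
    split_l <- split(dat, dat$participant_id)
    rows <- lapply(names(split_l), function(pid) {
      d <- split_l[[pid]]
      d$block_type <- stats::relevel(factor(d$block_type), ref = "neutral_view")
      f <- safely_coef(lm(rating_inscan ~ block_type, data = d))
      if (is.null(f)) return(NULL)
      cf <- coef(f)
      names(cf) <- sub("^block_type", "", names(cf))
      names(cf)[1] <- "intercept"
      tibble::tibble(participant_id = pid, !!!as.list(cf), converged = TRUE)
    })
    return(dplyr::bind_rows(rows))
  }

  dat <- cohort$choices
  split_l <- split(dat, dat$participant_id)
  rows <- lapply(names(split_l), function(pid) {
    d <- split_l[[pid]]
    d <- d[d$choice != "missed", , drop = FALSE]
    if (nrow(d) < 10) return(NULL)
    if (model == "choice") {
      fit <- fit_taste_health_weights(d)
      return(tibble::tibble(
        participant_id = pid, intercept = fit$beta0,
        taste = fit$w_taste, health = fit$w_health,
        converged = !fit$separation_flag
      ))
    }
    if (model == "success") {
      d <- d[is_challenge(d$trial_type), , drop = FALSE]
      if (nrow(d) < 10 || length(unique(d$trial_type)) < 2) return(NULL)
      scs <- score_self_control(d)$scs
      y <- as.integer(scs == "success")
      taste_z <- as.numeric(scale(d$tr))
      health_z <- as.numeric(scale(d$hr))
      lthh <- as.integer(d$trial_type == "LTHH")
      if (length(unique(y)) < 2) return(NULL)
      f <- safely_coef(suppressWarnings(
        glm(y ~ taste_z + health_z + lthh + taste_z:lthh + health_z:lthh,
            family = binomial())
      ))
      if (is.null(f) || !f$converged) return(NULL)
      cf <- coef(f)
      return(tibble::tibble(
        participant_id = pid,
        intercept = cf[["(Intercept)"]],
        taste = cf[["taste_z"]], health = cf[["health_z"]],
        lthh = cf[["lthh"]],
        taste_x_lthh = cf[["taste_z:lthh"]],
        health_x_lthh = cf[["health_z:lthh"]],
        converged = TRUE
      ))
    }
    # RT model: requires score columns (stakes, conflict)
    if (!all(c("stakes", "conflict") %in% names(d))) {
      stop("rt model needs scored choices (run score_cohort first)",
           call. = FALSE)
    }
    yes <- as.integer(d$choice == "yes")
    type_htlh <- as.integer(d$trial_type == "HTLH")
    type_lthh <- as.integer(d$trial_type == "LTHH")
    f <- safely_coef(lm(
      log(d$rt_s) ~ yes + type_htlh + type_lthh + d$stakes + d$conflict +
        yes:type_htlh + yes:type_lthh
    ))
    if (is.null(f) || anyNA(coef(f))) return(NULL)
    cf <- coef(f)
    tibble::tibble(
      participant_id = pid,
      intercept = cf[[1]], yes = cf[["yes"]],
      htlh = cf[["type_htlh"]], lthh = cf[["type_lthh"]],
      stakes = cf[["d$stakes"]], difficulty = -cf[["d$conflict"]],
      yes_x_htlh = cf[["yes:type_htlh"]], yes_x_lthh = cf[["yes:type_lthh"]],
      converged = TRUE
    )
  })
  dplyr::bind_rows(rows)
}

#' Cross-task association between self-control and reappraisal success
#'
#' Joins the per-participant dietary and reappraisal score tables on
#' participant id (task-specific exclusions applied per task, so a
#' participant may contribute to one task only) and reports rank
#' correlations of the overall dietary self-control success level against
#' the overall, negative-only and positive-only reappraisal success
#' scores.
#'
#' @param participant_scores tibble with `participant_id`,
#'   `success_overall`, and optionally `excluded_flag`.
#' @param reappraisal_scores tibble with `participant_id`, `success_neg`,
#'   `success_pos`, `success_overall`.
#' @param n_resamples,seed bootstrap settings passed to [correlate()].
#' @return named list of [correlate()] results: `overall`, `negative`,
#'   `positive`.
#' @export
cross_task_association <- function(participant_scores, reappraisal_scores,
                                   n_resamples = 10000, seed = 1L) {
  ps <- tibble::as_tibble(participant_scores)
  if ("excluded_flag" %in% names(ps)) {
    ps <- ps[!ps$excluded_flag, , drop = FALSE]
  }
  rs <- tibble::as_tibble(reappraisal_scores)
  joined <- dplyr::inner_join(
    ps[, c("participant_id", "success_overall")],
    rs[, c("participant_id", "success_neg", "success_pos", "success_overall")],
    by = "participant_id", suffix = c("_diet", "_reap")
  )
  if (nrow(joined) < 4) {
    stop("fewer than 4 overlapping participants across tasks", call. = FALSE)
  }
  list(
    overall = correlate(joined$success_overall_diet,
                        joined$success_overall_reap,
                        method = "rank", n_resamples = n_resamples, seed = seed),
    negative = correlate(joined$success_overall_diet, joined$success_neg,
                         method = "rank", n_resamples = n_resamples,
                         seed = seed + 1L),
    positive = correlate(joined$success_overall_diet, joined$success_pos,
                         method = "rank", n_resamples = n_resamples,
                         seed = seed + 2L)
  )
}

#' End-to-end parameter-recovery experiment
#'
#' Simulates a cohort, runs the full scoring and fitting pipeline, and
#' compares recovered quantities against the generative ground truth:
#' the relative starting point `z_rel`, the taste/health weight ratio
#' (scale-free, so the logistic refit is comparable to the diffusion-scale
#' generating weights), the valence-wise reappraisal success scores
#' against their generating efficacies, and the cross-task coupling
#' against the correlation measured directly on the ground-truth
#' parameters.
#'
#' @param config a [cohort_config()] object.
#' @param fit_ddm whether to refit the diffusion model per participant
#'   (the slow step).
#' @param ddm_trials when refitting, number of diffusion trials to
#'   simulate per participant for the recovery (defaults to the
#'   choice-set size if `NULL`).
#' @return an object of class `recovery_report` (a list, JSON-ready) with
#'   per-quantity `bias`, `rmse`, and where available `coverage`.
#' @export
parameter_recovery_experiment <- function(config, fit_ddm = TRUE,
                                          ddm_trials = NULL) {
  cohort <- generate_cohort(config)
  scored <- score_cohort(cohort)
  gt <- cohort$ground_truth

  ps <- scored$participant_scores
  m <- dplyr::inner_join(ps, gt, by = "participant_id",
                         suffix = c("_hat", "_true"))

  # weight-ratio recovery (scale-free across logit vs drift parameterization)
  ok <- !m$excluded_flag & is.finite(m$w_taste_hat) & is.finite(m$w_health_hat)
  ratio_hat <- m$w_taste_hat[ok] / m$w_health_hat[ok]
  ratio_true <- m$w_taste_true[ok] / m$w_health_true[ok]

  # reappraisal success vs generating efficacy
  rs <- dplyr::inner_join(scored$reappraisal_scores, gt, by = "participant_id")

  report <- list(
    n_participants = nrow(gt),
    w_ratio = list(
      bias = mean(ratio_hat - ratio_true),
      rmse = sqrt(mean((ratio_hat - ratio_true)^2)),
      n = sum(ok)
    ),
    success_neg = list(
      bias = mean(rs$success_neg - rs$delta_neg),
      rmse = sqrt(mean((rs$success_neg - rs$delta_neg)^2)),
      n = nrow(rs)
    ),
    success_pos = list(
      bias = mean(rs$success_pos - rs$delta_pos),
      rmse = sqrt(mean((rs$success_pos - rs$delta_pos)^2)),
      n = nrow(rs)
    )
  )

  # coupling: behavioral correlation vs ground-truth correlation
  gt_eff <- (gt$delta_neg + gt$delta_pos) / 2
  rho_gt <- cor(gt_eff, gt$w_health, method = "spearman")
  keep <- !m$excluded_flag
  rho_beh <- cor(
    m$success_overall[keep],
    dplyr::inner_join(scored$reappraisal_scores, m[keep, "participant_id"],
                      by = "participant_id")$success_overall,
    method = "spearman", use = "complete.obs"
  )
  report$coupling <- list(
    configured = config$coupling_rho,
    ground_truth_rho = rho_gt,
    behavioral_rho = rho_beh
  )

  if (fit_ddm) {
    z_hat <- rep(NA_real_, nrow(gt))
    for (i in seq_len(nrow(gt))) {
      p <- gt[i, ]
      trials <- if (is.null(ddm_trials)) {
        sc <- scored$trial_scores[
          scored$trial_scores$participant_id == p$participant_id, ,
          drop = FALSE
        ]
        if (nrow(sc) == 0) next
        sc
      } else {
        # fresh simulation at the requested trial count, resampling the
        # participant's own task subjective values where available
        sc <- scored$trial_scores[
          scored$trial_scores$participant_id == p$participant_id, ,
          drop = FALSE
        ]
        old <- .Random.seed_save()
        set.seed(participant_seed(config$seed, 10000 + i))
        sv <- if (nrow(sc) > 0) {
          sample(sc$sv, ddm_trials, replace = TRUE)
        } else {
          rnorm(ddm_trials, 0, 4)
        }
        .Random.seed_restore(old)
        sim <- simulate_ddm_trials(
          ddm_params(p$a, p$z_rel, p$t0, p$drift_scale),
          drifts = p$drift_scale * sv,
          seed = participant_seed(config$seed, 20000 + i)
        )
        tibble::tibble(choice = sim$choice, rt_s = sim$rt_s, sv = sv)
      }
      fit <- tryCatch(suppressWarnings(fit_ddm_mle(trials)),
                      error = function(e) NULL)
      if (!is.null(fit)) z_hat[i] <- fit$params$z_rel
    }
    okz <- is.finite(z_hat)
    report$z_rel <- list(
      bias = mean(z_hat[okz] - gt$z_rel[okz]),
      rmse = sqrt(mean((z_hat[okz] - gt$z_rel[okz])^2)),
      mean_recovered = mean(z_hat[okz]),
      mean_true = mean(gt$z_rel[okz]),
      n = sum(okz)
    )
  }
  structure(report, class = c("recovery_report", "list"))
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>\n")
  for (nm in setdiff(names(x), "n_participants")) {
    it <- x[[nm]]
    if (is.list(it) && !is.null(it$bias)) {
      cat(sprintf("  %-12s bias % .4f  rmse %.4f  (n = %d)\n",
                  nm, it$bias, it$rmse, it$n %||% NA_integer_))
    }
  }
  invisible(x)
}
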