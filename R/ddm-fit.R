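#' Simulate diffusion trials
#'
#' Draws choices and reaction times from the Wiener diffusion by fine-step
#' Euler-Maruyama simulation. Trials whose first passage would occur after
#' `max_rt` are censored: `choice = "missed"` with no RT, matching a task
#' deadline within which a response must be registered.
#'
#' @param params a [ddm_params()] object.
#' @param drifts per-trial drift rates.
#' @param max_rt response deadline in seconds (default 3).
#' @param dt Euler step in seconds (default 1e-3).
#' @param seed optional integer seed.
#' @return tibble with columns `choice` (`"yes"`, `"no"`, `"missed"`) and
#'   `rt_s` (`t0` + decision time; `NA` when missed).
#' @examples
#' simulate_ddm_trials(ddm_params(), drifts = rep(0, 5), seed = 1)
#' @export
simulate_ddm_trials <- function(params, drifts, max_rt = CHOICE_DEADLINE_S,
                                dt = 1e-3, seed = NULL) {
  stopifnot(inherits(params, "ddm_params"), is.numeric(drifts))
  if (length(drifts) == 0) stop("no trials to simulate", call. = FALSE)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  max_dec <- max_rt - params$t0
  if (max_dec <= 0) stop("t0 exceeds the response deadline", call. = FALSE)
  m <- .ddm_simulate_cpp(as.numeric(drifts), params$a, params$z_rel, dt, max_dec)
  choice <- c("no", "missed", "yes")[m[, 1] + 2]
  tibble::tibble(
    choice = choice,
    rt_s = ifelse(choice == "missed", NA_real_, params$t0 + m[, 2])
  )
}

#' Censored negative log-likelihood of diffusion trials
#'
#' Responded trials contribute the first-passage density at the chosen
#' boundary; missed trials contribute the survival mass beyond the
#' deadline. Drift on each trial is `drift_scale * sv`.
#'
#' @param par numeric `(a, z_rel, t0, drift_scale)`.
#' @param choice character vector (`"yes"`, `"no"`, `"missed"`).
#' @param rt_s reaction times (`NA` for missed).
#' @param sv per-trial subjective values.
#' @param max_rt censoring deadline, seconds.
#' @return scalar negative log-likelihood (large when `par` is infeasible).
#' @keywords internal
ddm_neg_loglik <- function(par, choice, rt_s, sv, max_rt = CHOICE_DEADLINE_S) {
  a <- par[1]; z <- par[2]; t0 <- par[3]; ds <- par[4]
  if (a <= 0 || z <= 0 || z >= 1 || t0 < 0) return(1e10)
  responded <- choice != "missed"
  td <- rt_s[responded] - t0
  if (any(td <= 1e-6)) return(1e10)
  p <- ddm_params(a = a, z_rel = z, t0 = t0, drift_scale = ds)
  v <- ds * sv
  dens <- numeric(sum(responded))
  up <- choice[responded] == "yes"
  if (any(up)) dens[up] <- wiener_fpt_density(td[up], p, v[responded][up], "upper")
  if (any(!up)) dens[!up] <- wiener_fpt_density(td[!up], p, v[responded][!up], "lower")
  ll <- sum(log(pmax(dens, 1e-300)))
  if (any(!responded)) {
    surv <- wiener_survival(max_rt - t0, p, v[!responded])
    ll <- ll + sum(log(pmax(surv, 1e-300)))
  }
  if (!is.finite(ll)) return(1e10)
  -ll
}

#' Fit the diffusion model by censored maximum likelihood
#'
#' Estimates boundary separation, relative starting point, non-decision
#' time and drift scaling from one participant's choices, reaction times
#' and per-trial subjective food values. Missed trials enter as censored
#' mass beyond the deadline rather than being dropped. Optimization is
#' bounded (L-BFGS-B) from several deterministic starting points.
#'
#' @param trials data frame with columns `choice`, `rt_s`, `sv`.
#' @param max_rt censoring deadline, seconds.
#' @param n_starts number of starting points.
#' @param min_responded below this many responded trials the fit is flagged
#'   unconverged (underdetermined).
#' @return an object of class `ddm_fit`: list with `params`
#'   ([ddm_params()]), `neg_loglik`, `converged`, `n_used`, `boundary_warn`
#'   (TRUE when all responses hit one boundary and the starting point is
#'   pinned near its bound).
#' @export
fit_ddm_mle <- function(trials, max_rt = CHOICE_DEADLINE_S, n_starts = 3,
                        min_responded = 40) {
  stopifnot(all(c("choice", "rt_s", "sv") %in% names(trials)))
  choice <- trials$choice
  rt_s <- trials$rt_s
  sv <- trials$sv
  responded <- choice != "missed"
  n_resp <- sum(responded)
  if (n_resp == 0) stop("no responded trials to fit", call. = FALSE)
  one_sided <- length(unique(choice[responded])) < 2
  if (one_sided) {
    warning("all responses at one boundary; starting point poorly identified",
            call. = FALSE)
  }
  min_rt <- min(rt_s[responded])
  lower <- c(a = 0.3, z_rel = 0.03, t0 = 0, drift_scale = -6)
  upper <- c(a = 5, z_rel = 0.97, t0 = max(min_rt - 1e-3, 1e-3), drift_scale = 6)

  p_yes <- mean(choice[responded] == "yes")
  starts <- list(
    c(1.5, min(max(p_yes, 0.1), 0.9), 0.8 * min_rt, 0.5),
    c(1.0, 1 / 3, 0.5 * min_rt, 1.0),
    c(2.0, 0.5, 0.6 * min_rt, 0.2)
  )[seq_len(n_starts)]

  best <- NULL
  for (s in starts) {
    s <- pmin(pmax(s, lower + 1e-4), upper - 1e-4)
    fit <- tryCatch(
      optim(s, ddm_neg_loglik,
        choice = choice, rt_s = rt_s, sv = sv, max_rt = max_rt,
        method = "L-BFGS-B", lower = lower, upper = upper,
        control = list(maxit = 500)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("diffusion-model optimization failed", call. = FALSE)
  est <- best$par
  converged <- best$convergence == 0 && n_resp >= min_responded && !one_sided
  structure(
    list(
      params = ddm_params(a = est[1], z_rel = est[2], t0 = est[3],
                          drift_scale = est[4]),
      neg_loglik = best$value,
      converged = converged,
      n_used = n_resp,
      boundary_warn = one_sided
    ),
    class = "ddm_fit"
  )
}

#' @export
print.ddm_fit <- function(x, ...) {
  cat(sprintf(
    "<ddm_fit> a = %.3f, z_rel = %.3f, t0 = %.3f, drift_scale = %.3f\n  -logLik = %.2f over %d responded trials (converged: %s)\n",
    x$params$a, x$params$z_rel, x$params$t0, x$params$drift_scale,
    x$neg_loglik, x$n_used, x$converged
  ))
  invisible(x)
}
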