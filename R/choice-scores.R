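#' Fit per-participant taste and health weights
#'
#' Maximum-likelihood logistic regression of the yes/eat indicator on the
#' participant's own taste and health ratings,
#' `yes ~ 1 + tr_c + hr_c`, fitted by iteratively reweighted least squares
#' (IRLS). Ratings are mean-centered within participant over the presented
#' foods before entering the fit. When complete or quasi-complete
#' separation is detected (a participant who, e.g., never chose to eat),
#' the fit is redone with a small quadratic (ridge) penalty on the
#' coefficients and flagged, so downstream stages can exclude the
#' participant as the experimental pipeline would.
#'
#' @param trials data frame with columns `tr`, `hr` and `choice`
#'   (`"yes"`, `"no"`, `"missed"`); missed trials are dropped.
#' @param ridge penalty used on detected separation.
#' @return an object of class `weight_fit`: list with `beta0`, `w_taste`,
#'   `w_health`, `converged`, `separation_flag`, `n_used`, and `vcov`
#'   (coefficient covariance, unpenalized fits only).
#' @examples
#' set.seed(1)
#' tr <- runif(200, -5, 5); hr <- runif(200, -5, 5)
#' p <- plogis(1.5 * scale(tr, scale = FALSE) + 1.5 * scale(hr, scale = FALSE))
#' fit <- fit_taste_health_weights(
#'   data.frame(tr = tr, hr = hr,
#'              choice = ifelse(rbinom(200, 1, p) == 1, "yes", "no"))
#' )
#' c(fit$w_taste, fit$w_health)
#' @export
fit_taste_health_weights <- function(trials, ridge = 0.05) {
  stopifnot(all(c("tr", "hr", "choice") %in% names(trials)))
  resp <- trials[trials$choice != "missed", , drop = FALSE]
  if (nrow(resp) == 0) stop("all choices missed; nothing to fit", call. = FALSE)
  y <- as.integer(resp$choice == "yes")
  tr_c <- resp$tr - mean(resp$tr)
  hr_c <- resp$hr - mean(resp$hr)
  if (var(tr_c) < 1e-12 || var(hr_c) < 1e-12) {
    stop("taste or health ratings have zero variance; weights undefined",
         call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    # one-sided choices: certain separation, go straight to the ridge path
    return(.ridge_logistic(y, tr_c, hr_c, ridge, n_used = length(y)))
  }
  fit <- suppressWarnings(glm(y ~ tr_c + hr_c, family = binomial()))
  # (quasi-)separation shows up as runaway coefficients or exploded
  # standard errors, not merely saturated fitted values on extreme trials
  ses <- sqrt(diag(summary(fit)$cov.unscaled))
  separated <- !fit$converged ||
    any(abs(coef(fit)) > 12) || any(ses > 25)
  if (separated) {
    return(.ridge_logistic(y, tr_c, hr_c, ridge, n_used = length(y)))
  }
  cf <- coef(fit)
  structure(
    list(
      beta0 = unname(cf[1]), w_taste = unname(cf[2]), w_health = unname(cf[3]),
      converged = TRUE, separation_flag = FALSE, n_used = length(y),
      vcov = summary(fit)$cov.unscaled
    ),
    class = "weight_fit"
  )
}

# Quadratically penalized logistic fit used on separation: minimizes
# -loglik + ridge/2 * (b0^2 + b1^2 + b2^2) by Newton iterations.
.ridge_logistic <- function(y, tr_c, hr_c, ridge, n_used) {
  X <- cbind(1, tr_c, hr_c)
  b <- c(qlogis(max(min(mean(y), 0.99), 0.01)), 0, 0)
  for (it in 1:100) {
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    g <- drop(crossprod(X, y - mu)) - ridge * b
    W <- mu * (1 - mu)
    H <- crossprod(X * W, X) + diag(ridge, 3)
    step <- solve(H, g)
    b <- b + step
    if (max(abs(step)) < 1e-9) break
  }
  structure(
    list(
      beta0 = b[1], w_taste = b[2], w_health = b[3],
      converged = TRUE, separation_flag = TRUE, n_used = n_used,
      vcov = NULL
    ),
    class = "weight_fit"
  )
}

#' @export
print.weight_fit <- function(x, ...) {
  cat(sprintf(
    "<weight_fit> beta0 = %.3f, w_taste = %.3f, w_health = %.3f (n = %d%s)\n",
    x$beta0, x$w_taste, x$w_health, x$n_used,
    if (x$separation_flag) ", separation flagged" else ""
  ))
  invisible(x)
}

#' Subjective food value
#'
#' The per-trial sum of the taste and health ratings, each weighted by the
#' participant's fitted logistic coefficient:
#' `sv = w_taste * tr_c + w_health * hr_c`. The intercept is excluded; the
#' value is the weighted evidence for eating, in log-odds units. Ratings
#' must be centered the same way as in the fit.
#'
#' @param tr_c,hr_c mean-centered taste and health ratings.
#' @param fit a [fit_taste_health_weights()] result.
#' @return numeric vector of subjective values.
#' @examples
#' f <- structure(list(w_taste = 1.47, w_health = 1.46, converged = TRUE),
#'                class = "weight_fit")
#' subjective_value(1, -1, f)
#' @export
subjective_value <- function(tr_c, hr_c, fit) {
  stopifnot(inherits(fit, "weight_fit"))
  if (!isTRUE(fit$converged)) {
    stop("weight fit did not converge; subjective value undefined", call. = FALSE)
  }
  fit$w_taste * tr_c + fit$w_health * hr_c
}

#' Decision conflict
#'
#' Negative absolute subjective value, `-(|sv|)`: conflict is maximal (zero)
#' when the weighted taste and health evidence exactly balances and grows
#' more negative the more one-sided the trial is.
#'
#' @inheritParams subjective_value
#' @return numeric vector, always `<= 0`.
#' @export
decision_conflict <- function(tr_c, hr_c, fit) {
  -abs(subjective_value(tr_c, hr_c, fit))
}

#' Self-control stakes
#'
#' What is to be gained or lost by exerting self-control on a trial: the
#' sum of the absolute taste and health ratings, `|tr| + |hr|`, on
#' challenge trials (taste and health in opposition), and zero by
#' definition on aligned (non-challenge) trials, where no self-control is
#' required. Raw, uncentered ratings are used — the stakes measure distance
#' from the rating scale's neutral point.
#'
#' @param tr,hr raw taste and health ratings in `[-5, 5]`.
#' @param trial_type trial types from [classify_trial_type()]; recomputed
#'   from the ratings when omitted.
#' @return numeric vector of stakes, `>= 0`.
#' @examples
#' stakes(tr = c(4, 2), hr = c(-3, 3))  # 7 on the challenge, 0 on aligned
#' @export
stakes <- function(tr, hr, trial_type = NULL) {
  if (is.null(trial_type)) trial_type <- classify_trial_type(tr, hr)
  if (any(trial_type == "excluded")) {
    stop("neutral-zone items cannot appear in a choice set; stakes undefined",
         call. = FALSE)
  }
  ifelse(is_challenge(trial_type), abs(tr) + abs(hr), 0)
}

#' Orthogonalize one trial-wise modulator against another
#'
#' Residualizes `target` on `[intercept, reference]` by least squares after
#' mean-centering both, the standard treatment of serially orthogonalized
#' parametric modulators: the result carries only the variance in `target`
#' not explained by `reference`, has exactly zero mean and zero inner
#' product with the centered reference.
#'
#' @param target numeric vector (e.g. trial-wise stakes).
#' @param reference numeric vector of equal length (e.g. decision conflict).
#' @return numeric residual vector.
#' @export
orthogonalize_modulator <- function(target, reference) {
  stopifnot(length(target) == length(reference), length(target) >= 2)
  tc <- target - mean(target)
  rc <- reference - mean(reference)
  if (var(rc) < 1e-12) {
    warning("constant reference; returning the mean-centered target",
            call. = FALSE)
    return(tc)
  }
  tc - rc * (sum(tc * rc) / sum(rc * rc))
}

#' Score all trials of one participant
#'
#' Computes the trial-wise scores in one pass: mean-centered ratings,
#' subjective value, decision conflict, stakes and, over the responded
#' challenge trials, stakes orthogonalized against conflict.
#'
#' @param trials data frame with columns `tr`, `hr`, `trial_type`, `choice`.
#' @param fit a [fit_taste_health_weights()] result for this participant.
#' @return the input with added columns `tr_c`, `hr_c`, `sv`, `conflict`,
#'   `stakes`, `stakes_orth` (`NA` off the challenge trials).
#' @export
score_trials <- function(trials, fit) {
  stopifnot(all(c("tr", "hr", "trial_type", "choice") %in% names(trials)))
  out <- tibble::as_tibble(trials)
  out$tr_c <- out$tr - mean(out$tr)
  out$hr_c <- out$hr - mean(out$hr)
  out$sv <- subjective_value(out$tr_c, out$hr_c, fit)
  out$conflict <- decision_conflict(out$tr_c, out$hr_c, fit)
  out$stakes <- stakes(out$tr, out$hr, out$trial_type)
  out$stakes_orth <- NA_real_
  ch <- is_challenge(out$trial_type)
  if (sum(ch) >= 2) {
    out$stakes_orth[ch] <- orthogonalize_modulator(out$stakes[ch],
                                                   out$conflict[ch])
  }
  out
}

#' Self-control success scoring
#'
#' A responded challenge trial counts as a success when the healthier
#' option was taken: refusing a tasty-unhealthy (HTLH) food or accepting a
#' healthy-unpalatable (LTHH) one. Missed challenge trials enter neither
#' numerator nor denominator. Returns the overall success level (the
#' proportion of responded challenge trials resolved for health) together
#' with per-type levels and counts.
#'
#' @param trials data frame with columns `trial_type` and `choice`.
#' @return an object of class `self_control_summary`: list with
#'   `success_overall`, `success_htlh`, `success_lthh`, counts
#'   `n_challenge`, `n_responded`, `n_missed_challenge`, per-trial vector
#'   `scs` (`"success"`/`"failure"`/`NA`), and `undefined` flag (no
#'   responded challenge trials).
#' @examples
#' score_self_control(data.frame(
#'   trial_type = c("HTLH", "HTLH", "LTHH", "HTHH"),
#'   choice = c("no", "yes", "yes", "yes")
#' ))
#' @export
score_self_control <- function(trials) {
  stopifnot(all(c("trial_type", "choice") %in% names(trials)))
  ch <- is_challenge(trials$trial_type)
  responded <- trials$choice != "missed"
  scs <- rep(NA_character_, nrow(trials))
  use <- ch & responded
  scs[use] <- ifelse(
    (trials$trial_type[use] == "HTLH" & trials$choice[use] == "no") |
      (trials$trial_type[use] == "LTHH" & trials$choice[use] == "yes"),
    "success", "failure"
  )
  lev <- function(mask) {
    m <- mask & use
    if (!any(m)) return(NA_real_)
    mean(scs[m] == "success")
  }
  n_resp <- sum(use)
  structure(
    list(
      success_overall = lev(rep(TRUE, nrow(trials))),
      success_htlh = lev(trials$trial_type == "HTLH"),
      success_lthh = lev(trials$trial_type == "LTHH"),
      n_challenge = sum(ch),
      n_responded = n_resp,
      n_missed_challenge = sum(ch & !responded),
      scs = scs,
      undefined = n_resp == 0
    ),
    class = "self_control_summary"
  )
}

#' @export
print.self_control_summary <- function(x, ...) {
  cat(sprintf(
    "<self_control_summary> overall %.3f (HTLH %.3f, LTHH %.3f) over %d responded of %d challenge trials\n",
    x$success_overall, x$success_htlh, x$success_lthh,
    x$n_responded, x$n_challenge
  ))
  invisible(x)
}
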