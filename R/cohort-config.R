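#' Drift-diffusion parameter set
#'
#' Parameters of the Wiener diffusion used to generate and fit food choices.
#' Evidence accumulates between a lower ("no / refuse") and an upper
#' ("yes / eat") boundary; the process starts at `z_rel * a` above the lower
#' boundary, so `z_rel < 1/2` expresses a starting-point bias toward
#' refusing. The diffusion coefficient is fixed at 1 for identifiability.
#'
#' @param a boundary separation, evidence units (> 0).
#' @param z_rel relative starting point in (0, 1), measured from the lower
#'   (refuse) boundary. Default 1/3: the refusal bias reported for this task.
#' @param t0 non-decision time in seconds (>= 0).
#' @param drift_scale drift per unit subjective food value.
#' @return an object of class `ddm_params`.
#' @examples
#' ddm_params(a = 1.5, z_rel = 1 / 3, t0 = 0.3, drift_scale = 0.8)
#' @export
ddm_params <- function(a = 1.5, z_rel = 1 / 3, t0 = 0.3, drift_scale = 0.8) {
  stopifnot(is.numeric(a), length(a) == 1, is.finite(a))
  if (a <= 0) stop("boundary separation `a` must be > 0", call. = FALSE)
  if (!is.finite(z_rel) || z_rel <= 0 || z_rel >= 1) {
    stop("`z_rel` must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.finite(t0) || t0 < 0) stop("`t0` must be >= 0", call. = FALSE)
  if (!is.finite(drift_scale)) stop("`drift_scale` must be finite", call. = FALSE)
  structure(
    list(a = a, z_rel = z_rel, t0 = t0, drift_scale = drift_scale, sigma = 1),
    class = "ddm_params"
  )
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf(
    "<ddm_params> a = %.3f, z_rel = %.3f, t0 = %.3f s, drift_scale = %.3f\n",
    x$a, x$z_rel, x$t0, x$drift_scale
  ))
  invisible(x)
}

#' Cohort configuration
#'
#' Describes the synthetic cohort: its size, the food-rating profile
#' generator, the emotion-task condition means, default diffusion
#' parameters, and the latent coupling between emotion-regulation efficacy
#' and the health weight in food choice.
#'
#' @details
#' `rating_model` is a list with elements
#' `quadrant_mass` (named probabilities for the four taste/health quadrants
#' `htlh`, `lthh`, `hthh`, `ltlh`; the default favours tasty-unhealthy items,
#' which is the composition that yields challenge-heavy choice sets) and
#' `neutral_frac` (probability that an item falls in the neutral band on at
#' least one attribute and is therefore excluded from choice sets).
#'
#' `condition_means` holds the SAM means of the unregulated "view" blocks
#' (negative, neutral, positive); regulated ("reappraise") means are derived
#' per participant by shifting the view mean toward the scale midpoint 5 by
#' that participant's regulation efficacy (`delta_neg`, `delta_pos`).
#'
#' @param n_participants number of participants.
#' @param n_items number of foods rated per participant (default 180).
#' @param rating_model list, see Details.
#' @param coupling_rho latent correlation in `[-1, 1]` between mean
#'   regulation efficacy `(delta_neg + delta_pos)/2` and `w_health`.
#' @param seed integer cohort seed.
#' @param condition_means named numeric vector with entries `negative_view`,
#'   `neutral_view`, `positive_view` on the 1-9 SAM scale.
#' @param sam_sd trial-level SD of the latent Gaussian behind SAM ratings.
#' @param ddm_defaults a [ddm_params()] object: population means of the
#'   diffusion parameters.
#' @param weight_means,weight_sds length-2 numeric (taste, health):
#'   population mean and SD of the logistic-scale attribute weights.
#' @param delta_means,delta_sds length-2 numeric (negative, positive):
#'   population mean and SD of the regulation efficacies, SAM units.
#' @param n_trials,n_challenge_target,min_challenge choice-set geometry, see
#'   [build_choice_set()].
#' @return an object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(n_participants = 38, seed = 1)
#' cfg$n_items
#' @export
cohort_config <- function(n_participants = 38,
                          n_items = 180,
                          rating_model = list(
                            quadrant_mass = c(
                              htlh = 0.42, lthh = 0.13,
                              hthh = 0.30, ltlh = 0.15
                            ),
                            neutral_frac = 0.05
                          ),
                          coupling_rho = 0,
                          seed = 1L,
                          condition_means = c(
                            negative_view = 2.69,
                            neutral_view = 5.26,
                            positive_view = 7.09
                          ),
                          sam_sd = 1.2,
                          ddm_defaults = ddm_params(),
                          weight_means = c(taste = 1.47, health = 1.46),
                          weight_sds = c(taste = 0.45, health = 0.45),
                          delta_means = c(negative = 1.56, positive = 1.88),
                          delta_sds = c(negative = 0.6, positive = 0.6),
                          n_trials = 100,
                          n_challenge_target = 75,
                          min_challenge = 50) {
  if (!is.numeric(coupling_rho) || length(coupling_rho) != 1 ||
      !is.finite(coupling_rho) || abs(coupling_rho) > 1) {
    stop("`coupling_rho` must be a number in [-1, 1]", call. = FALSE)
  }
  stopifnot(
    n_participants >= 1, n_items >= 1,
    is.list(rating_model),
    all(c("negative_view", "neutral_view", "positive_view") %in%
          names(condition_means)),
    inherits(ddm_defaults, "ddm_params"),
    n_trials >= 1, n_challenge_target <= n_trials
  )
  qm <- rating_model$quadrant_mass
  if (is.null(qm) || !all(c("htlh", "lthh", "hthh", "ltlh") %in% names(qm)) ||
      any(qm < 0) || sum(qm) <= 0) {
    stop("rating_model$quadrant_mass must be nonnegative masses for htlh/lthh/hthh/ltlh",
         call. = FALSE)
  }
  rating_model$quadrant_mass <- qm / sum(qm)
  rating_model$neutral_frac <- rating_model$neutral_frac %||% 0.05
  structure(
    list(
      n_participants = as.integer(n_participants),
      n_items = as.integer(n_items),
      rating_model = rating_model,
      coupling_rho = coupling_rho,
      seed = as.integer(seed),
      condition_means = condition_means,
      sam_sd = sam_sd,
      ddm_defaults = ddm_defaults,
      weight_means = weight_means,
      weight_sds = weight_sds,
      delta_means = delta_means,
      delta_sds = delta_sds,
      n_trials = as.integer(n_trials),
      n_challenge_target = as.integer(n_challenge_target),
      min_challenge = as.integer(min_challenge)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<cohort_config> %d participants, %d foods each\n",
      "  choice set: %d trials, %d challenge target (min %d)\n",
      "  coupling_rho = %.2f, seed = %d\n"
    ),
    x$n_participants, x$n_items, x$n_trials, x$n_challenge_target,
    x$min_challenge, x$coupling_rho, x$seed
  ))
  invisible(x)
}

#' Read a cohort configuration from YAML or JSON
#'
#' The file mirrors the arguments of [cohort_config()]; absent fields keep
#' their defaults. `ddm_defaults` may be given as a named list.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a `cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$ddm_defaults)) {
    raw$ddm_defaults <- do.call(ddm_params, raw$ddm_defaults)
  }
  for (nm in c("condition_means", "weight_means", "weight_sds",
               "delta_means", "delta_sds")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  if (!is.null(raw$rating_model) && !is.null(raw$rating_model$quadrant_mass)) {
    raw$rating_model$quadrant_mass <- unlist(raw$rating_model$quadrant_mass)
  }
  do.call(cohort_config, raw)
}
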