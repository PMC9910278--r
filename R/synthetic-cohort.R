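#' Generate ground-truth participant profiles
#'
#' Draws each participant's generative parameters: logistic-scale taste and
#' health weights, diffusion parameters, regulation efficacies for negative
#' and positive stimuli (`delta_neg`, `delta_pos`, in SAM units, truncated
#' at zero), and inert person-level covariates (hunger, BMI, restraint,
#' gender) that exist so covariate-style group models are exercisable but
#' carry no effect in the default generative model.
#'
#' The configured `coupling_rho` is induced between the mean regulation
#' efficacy `(delta_neg + delta_pos)/2` and `w_health` through a shared
#' latent Gaussian: the standardized efficacy latent `M` and the `w_health`
#' innovation satisfy `cor = coupling_rho` exactly before the (rare)
#' truncation of the deltas at zero.
#'
#' @param config a [cohort_config()] object.
#' @return tibble with one row per participant and columns
#'   `participant_id`, `beta0`, `w_taste`, `w_health`, `a`, `z_rel`, `t0`,
#'   `drift_scale`, `delta_neg`, `delta_pos`, `hunger_pct`, `bmi`,
#'   `restraint`, `gender`.
#' @examples
#' profiles <- generate_participant_profiles(cohort_config(n_participants = 4))
#' profiles$participant_id
#' @export
generate_participant_profiles <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_participants
  rho <- config$coupling_rho

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(participant_seed(config$seed, 0))

  # shared efficacy latents
  a_neg <- rnorm(n)
  a_pos <- rnorm(n)
  sd_n <- config$delta_sds[["negative"]]
  sd_p <- config$delta_sds[["positive"]]
  delta_neg <- pmax(0, config$delta_means[["negative"]] + sd_n * a_neg)
  delta_pos <- pmax(0, config$delta_means[["positive"]] + sd_p * a_pos)
  # standardized latent behind (delta_neg + delta_pos)/2
  m <- (sd_n * a_neg + sd_p * a_pos) / sqrt(sd_n^2 + sd_p^2)
  z_h <- rho * m + sqrt(1 - rho^2) * rnorm(n)
  w_health <- config$weight_means[["health"]] + config$weight_sds[["health"]] * z_h
  w_taste <- config$weight_means[["taste"]] +
    config$weight_sds[["taste"]] * rnorm(n)

  dd <- config$ddm_defaults
  tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    beta0 = rnorm(n, -1.0, 0.4),
    w_taste = w_taste,
    w_health = w_health,
    a = pmax(0.6, rnorm(n, dd$a, 0.15)),
    z_rel = pmin(pmax(rnorm(n, dd$z_rel, 0.04), 0.05), 0.95),
    t0 = pmax(0.1, rnorm(n, dd$t0, 0.03)),
    drift_scale = pmax(0.1, rnorm(n, dd$drift_scale, 0.1)),
    delta_neg = delta_neg,
    delta_pos = delta_pos,
    hunger_pct = pmin(pmax(rnorm(n, 67, 18), 0), 100),
    bmi = rnorm(n, 22, 2.3),
    restraint = rnorm(n),
    gender = sample(c("female", "male"), n, replace = TRUE,
                    prob = c(21, 17) / 38)
  )
}

#' Generate one participant's food-rating profile
#'
#' Draws `n_items` (taste, health) rating pairs from a mixture over the
#' four taste/health quadrants with configurable masses; the default
#' favours tasty-unhealthy items, the composition that makes challenge-
#' heavy choice sets constructible. Values are uniform within the
#' non-neutral part of each quadrant; a small fraction of items
#' (`neutral_frac`) instead lands in the neutral band on one attribute and
#' is therefore unusable for choice sets.
#'
#' @param profile one row of [generate_participant_profiles()] (used for
#'   its `participant_id`), or any list with a `participant_id`.
#' @param config a [cohort_config()] object.
#' @param seed integer seed.
#' @return tibble with columns `participant_id`, `food_id`, `tr`, `hr`.
#' @export
generate_food_ratings <- function(profile, config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"), config$n_items >= 1)
  n <- config$n_items
  qm <- config$rating_model$quadrant_mass
  nf <- config$rating_model$neutral_frac

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  quadrant <- sample(names(qm), n, replace = TRUE, prob = qm)
  runif_side <- function(n, positive) {
    if (positive) {
      runif(n, NEUTRAL_HALF_WIDTH, RATING_MAX)
    } else {
      runif(n, RATING_MIN, -NEUTRAL_HALF_WIDTH)
    }
  }
  taste_pos <- quadrant %in% c("htlh", "hthh")
  health_pos <- quadrant %in% c("lthh", "hthh")
  tr <- ifelse(taste_pos, runif_side(n, TRUE), runif_side(n, FALSE))
  hr <- ifelse(health_pos, runif_side(n, TRUE), runif_side(n, FALSE))
  # a small share of items sits in the neutral band on one attribute
  neutral <- runif(n) < nf
  which_attr <- runif(n) < 0.5
  nn <- sum(neutral)
  if (nn > 0) {
    neutral_vals <- runif(nn, -NEUTRAL_HALF_WIDTH, NEUTRAL_HALF_WIDTH)
    tr[neutral & which_attr] <- neutral_vals[which_attr[neutral]]
    hr[neutral & !which_attr] <- neutral_vals[!which_attr[neutral]]
  }
  tr <- pmin(pmax(tr, RATING_MIN), RATING_MAX)
  hr <- pmin(pmax(hr, RATING_MIN), RATING_MAX)
  tibble::tibble(
    participant_id = profile$participant_id,
    food_id = sprintf("food_%03d", seq_len(n)),
    tr = tr, hr = hr
  )
}

#' Simulate one participant's food choices
#'
#' Runs the diffusion simulator over a built choice set. The drift on each
#' trial is `drift_scale * (w_taste * tr_c + w_health * hr_c)` with ratings
#' mean-centered over the presented foods (the same centering the scoring
#' stage applies). Trials whose first passage falls outside the 3-s
#' response window are missed.
#'
#' @param profile one row of [generate_participant_profiles()].
#' @param choice_set a [build_choice_set()] result.
#' @param seed integer seed.
#' @param dt Euler step for the simulator.
#' @return the choice set with added columns `choice`, `rt_s`, `missed`.
#' @export
simulate_food_choices <- function(profile, choice_set, seed = 1L, dt = 1e-3) {
  if (is.null(choice_set) || nrow(choice_set) == 0) {
    stop("empty choice set", call. = FALSE)
  }
  stopifnot(all(c("tr", "hr") %in% names(choice_set)))
  params <- ddm_params(
    a = profile$a, z_rel = profile$z_rel, t0 = profile$t0,
    drift_scale = profile$drift_scale
  )
  tr_c <- choice_set$tr - mean(choice_set$tr)
  hr_c <- choice_set$hr - mean(choice_set$hr)
  sv <- profile$w_taste * tr_c + profile$w_health * hr_c
  sim <- simulate_ddm_trials(params, drifts = params$drift_scale * sv,
                             max_rt = CHOICE_DEADLINE_S, dt = dt, seed = seed)
  out <- tibble::as_tibble(choice_set)
  out$choice <- sim$choice
  out$rt_s <- sim$rt_s
  out$missed <- sim$choice == "missed"
  out
}

#' Simulate one participant's emotion-task session
#'
#' Generates the 100-trial session: 5 block types (negative/positive view,
#' negative/positive reappraise, neutral view) of 20 trials each. In-scan
#' ratings are discretized truncated Gaussians around the block-type mean;
#' reappraise blocks shift the view mean toward the scale midpoint 5 by the
#' participant's regulation efficacy (`delta_neg` upward for negative,
#' `delta_pos` downward for positive). Every reappraised stimulus also
#' receives a post-scan re-rating drawn from the unregulated view
#' distribution, emulating the post-scan viewing of the same pictures.
#'
#' @param profile one row of [generate_participant_profiles()].
#' @param config a [cohort_config()] object.
#' @param seed integer seed.
#' @return tibble with columns `participant_id`, `block_type`, `stim_id`,
#'   `condition`, `valence_class`, `rating_inscan`, `rating_postscan`.
#' @export
simulate_emotion_session <- function(profile, config, seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  cm <- config$condition_means
  blocks <- tibble::tibble(
    valence_class = c("negative", "negative", "neutral", "positive", "positive"),
    condition = c("view", "reappraise", "view", "reappraise", "view")
  )
  # regulated means move toward the midpoint of the SAM scale
  block_mean <- function(vc, cond) {
    base <- switch(vc,
      negative = cm[["negative_view"]],
      neutral = cm[["neutral_view"]],
      positive = cm[["positive_view"]]
    )
    if (cond == "view") return(base)
    if (vc == "negative") base + profile$delta_neg else base - profile$delta_pos
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  sam_draw <- function(n, mu) {
    pmin(pmax(round(rnorm(n, mu, config$sam_sd)), 1), 9)
  }
  res <- lapply(seq_len(nrow(blocks)), function(i) {
    vc <- blocks$valence_class[i]
    cond <- blocks$condition[i]
    bt <- paste(vc, cond, sep = "_")
    inscan <- sam_draw(20, block_mean(vc, cond))
    post <- if (cond == "reappraise") {
      # post-scan re-rating is unregulated viewing of the same picture
      sam_draw(20, block_mean(vc, "view"))
    } else {
      rep(NA_integer_, 20)
    }
    tibble::tibble(
      participant_id = profile$participant_id,
      block_type = bt,
      stim_id = sprintf("%s_%02d", bt, seq_len(20)),
      condition = cond,
      valence_class = vc,
      rating_inscan = as.integer(inscan),
      rating_postscan = as.integer(post)
    )
  })
  dplyr::bind_rows(res)
}

#' Generate a full synthetic cohort
#'
#' For every participant: a ground-truth profile, a 180-item rating
#' profile, a tailored choice set, simulated diffusion choices within the
#' 3-s window, and a simulated emotion session. Participants whose rating
#' profile cannot supply enough challenge items are retained with an
#' exclusion flag and reason rather than dropped, mirroring how exclusions
#' are reported in practice; their choice and emotion data are still
#' generated where possible.
#'
#' @param config a [cohort_config()] object.
#' @return an object of class `cohort_dataset`: list of tibbles `ratings`,
#'   `choice_sets`, `choices`, `emotion`, `ground_truth`, `participants`
#'   (with `excluded_choice`, `exclusion_reason`), plus the `config`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_config(n_participants = 3, seed = 7))
#' names(cohort)
#' }
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  profiles <- generate_participant_profiles(config)
  n <- nrow(profiles)

  ratings_l <- vector("list", n)
  sets_l <- vector("list", n)
  choices_l <- vector("list", n)
  emotion_l <- vector("list", n)
  excluded <- logical(n)
  reason <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    p <- profiles[i, ]
    s <- participant_seed(config$seed, i)
    ratings_l[[i]] <- generate_food_ratings(p, config, seed = s)
    cs <- tryCatch(
      build_choice_set(
        ratings_l[[i]],
        n_trials = config$n_trials,
        n_challenge_target = config$n_challenge_target,
        min_challenge = config$min_challenge,
        seed = s + 1L
      ),
      error = function(e) e
    )
    if (inherits(cs, "error")) {
      excluded[i] <- TRUE
      reason[i] <- conditionMessage(cs)
    } else {
      sets_l[[i]] <- tibble::tibble(participant_id = p$participant_id,
                                    tibble::as_tibble(cs))
      choices_l[[i]] <- simulate_food_choices(p, cs, seed = s + 2L)
      choices_l[[i]]$participant_id <- p$participant_id
    }
    emotion_l[[i]] <- simulate_emotion_session(p, config, seed = s + 3L)
  }

  participants <- tibble::tibble(
    participant_id = profiles$participant_id,
    excluded_choice = excluded,
    exclusion_reason = reason
  )
  structure(
    list(
      config = config,
      participants = participants,
      ground_truth = profiles,
      ratings = dplyr::bind_rows(ratings_l),
      choice_sets = dplyr::bind_rows(sets_l),
      choices = dplyr::bind_rows(choices_l),
      emotion = dplyr::bind_rows(emotion_l)
    ),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat(sprintf(
    "<cohort_dataset> %d participants (%d excluded from choice task), %d ratings, %d choice trials, %d emotion trials\n",
    nrow(x$participants), sum(x$participants$excluded_choice),
    nrow(x$ratings), nrow(x$choices), nrow(x$emotion)
  ))
  invisible(x)
}

#' Write the cohort tables to TSV
#'
#' Writes `ratings.tsv`, `choiceset.tsv`, `choices.tsv`, `emotion.tsv` and
#' `ground_truth.tsv` (tab-separated, header row, UTF-8, "." decimal) into
#' `dir`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    ratings = file.path(dir, "ratings.tsv"),
    choiceset = file.path(dir, "choiceset.tsv"),
    choices = file.path(dir, "choices.tsv"),
    emotion = file.path(dir, "emotion.tsv"),
    ground_truth = file.path(dir, "ground_truth.tsv")
  )
  readr::write_tsv(
    cohort$ratings[, c("participant_id", "food_id", "tr", "hr")],
    paths["ratings"]
  )
  readr::write_tsv(
    cohort$choice_sets[, c("participant_id", "trial_idx", "food_id", "trial_type")],
    paths["choiceset"]
  )
  ch <- cohort$choices
  readr::write_tsv(
    ch[, c("participant_id", "trial_idx", "food_id", "trial_type",
           "choice", "rt_s", "missed")],
    paths["choices"]
  )
  readr::write_tsv(
    cohort$emotion[, c("participant_id", "block_type", "stim_id", "condition",
                       "valence_class", "rating_inscan", "rating_postscan")],
    paths["emotion"]
  )
  gt <- dplyr::left_join(cohort$ground_truth, cohort$participants,
                         by = "participant_id")
  readr::write_tsv(gt, paths["ground_truth"])
  invisible(paths)
}
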