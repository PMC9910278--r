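#' Classify a rating against the neutral zone
#'
#' Foods are rated from -5 to +5 on a scale whose middle carries a 'neutral'
#' band spanning 5% of the total 10-unit length on each side of zero, i.e.
#' `|r| <= 0.5`. Ratings in the band are `neutral`; below it `negative`;
#' above it `positive`. The band is closed: boundary ratings count as
#' neutral, the conservative choice for exclusion.
#'
#' @param r numeric vector of ratings in `[-5, 5]`.
#' @return character vector in `{"negative", "neutral", "positive"}`.
#' @examples
#' classify_rating(c(0.4, 0.6, -5))
#' @export
classify_rating <- function(r) {
  if (!is.numeric(r) || any(!is.finite(r))) {
    stop("ratings must be finite numbers", call. = FALSE)
  }
  if (any(r < RATING_MIN | r > RATING_MAX)) {
    stop("ratings must lie in [-5, +5]", call. = FALSE)
  }
  out <- rep("neutral", length(r))
  out[r < -NEUTRAL_HALF_WIDTH] <- "negative"
  out[r > NEUTRAL_HALF_WIDTH] <- "positive"
  out
}

#' Classify foods into trial types
#'
#' A food whose taste and health ratings both escape the neutral zone maps
#' to one of four types: `HTLH` (tasty but unhealthy) and `LTHH` (healthy
#' but unpalatable) are the two self-control challenge types, where the
#' attributes conflict; `HTHH` and `LTLH` are aligned, non-challenge types.
#' Foods neutral on either attribute are `excluded` and never enter a
#' choice set.
#'
#' @param tr,hr numeric vectors of taste and health ratings in `[-5, 5]`.
#' @return character vector in `{"HTLH","LTHH","HTHH","LTLH","excluded"}`.
#' @examples
#' classify_trial_type(tr = c(4, -2, 0.2), hr = c(-3, 3, 3))
#' @export
classify_trial_type <- function(tr, hr) {
  stopifnot(length(tr) == length(hr))
  t_cls <- classify_rating(tr)
  h_cls <- classify_rating(hr)
  out <- rep("excluded", length(tr))
  out[t_cls == "positive" & h_cls == "negative"] <- "HTLH"
  out[t_cls == "negative" & h_cls == "positive"] <- "LTHH"
  out[t_cls == "positive" & h_cls == "positive"] <- "HTHH"
  out[t_cls == "negative" & h_cls == "negative"] <- "LTLH"
  out
}

#' Is a trial type a self-control challenge?
#' @param trial_type character vector of trial types.
#' @return logical vector.
#' @export
is_challenge <- function(trial_type) trial_type %in% c("HTLH", "LTHH")

#' Build a participant's tailored choice set
#'
#' Constructs the food-choice trial list from a participant's own ratings:
#' exactly `n_trials` distinct non-neutral foods in randomized order, with
#' as close to `n_challenge_target` self-control challenges as the rating
#' profile allows. The mix of the two challenge types is proportional to
#' their availability in the profile (participants typically contribute far
#' more tasty-unhealthy than unpalatable-healthy items). Participants whose
#' profiles cannot supply at least `min_challenge` challenge items cannot be
#' run on the paradigm and raise an error, mirroring the exclusion applied
#' in practice.
#'
#' @param ratings data frame with columns `food_id`, `tr`, `hr`.
#' @param n_trials number of trials (default 100).
#' @param n_challenge_target challenge trials aimed for (default 75).
#' @param min_challenge minimum acceptable challenge availability
#'   (default 50).
#' @param seed integer seed controlling sampling and trial order.
#' @return an object of class `choice_set`: a tibble with columns
#'   `trial_idx`, `food_id`, `trial_type`, `tr`, `hr`, plus attributes
#'   `n_challenge` and `n_nonchallenge`.
#' @export
build_choice_set <- function(ratings, n_trials = 100, n_challenge_target = 75,
                             min_challenge = 50, seed = 1L) {
  stopifnot(all(c("food_id", "tr", "hr") %in% names(ratings)))
  ratings <- tibble::as_tibble(ratings)
  ratings$trial_type <- classify_trial_type(ratings$tr, ratings$hr)
  usable <- ratings[ratings$trial_type != "excluded", , drop = FALSE]
  if (nrow(usable) < n_trials) {
    stop(sprintf(
      "only %d non-neutral foods available; %d trials requested",
      nrow(usable), n_trials
    ), call. = FALSE)
  }
  chall <- usable[is_challenge(usable$trial_type), , drop = FALSE]
  nonch <- usable[!is_challenge(usable$trial_type), , drop = FALSE]
  if (nrow(chall) < min_challenge) {
    stop(sprintf(
      "insufficient challenge trials: %d available, %d required",
      nrow(chall), min_challenge
    ), call. = FALSE)
  }
  n_ch <- min(n_challenge_target, nrow(chall))
  n_non <- n_trials - n_ch
  if (nrow(nonch) < n_non) {
    # fall back on extra challenge items when aligned items are scarce
    n_non <- nrow(nonch)
    n_ch <- n_trials - n_non
    if (n_ch > nrow(chall)) {
      stop("cannot assemble the requested number of trials", call. = FALSE)
    }
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # challenge-type mix proportional to availability, without replacement
  n_htlh_avail <- sum(chall$trial_type == "HTLH")
  n_lthh_avail <- sum(chall$trial_type == "LTHH")
  n_htlh <- round(n_ch * n_htlh_avail / (n_htlh_avail + n_lthh_avail))
  n_htlh <- min(max(n_htlh, n_ch - n_lthh_avail), n_htlh_avail)
  n_lthh <- n_ch - n_htlh
  pick <- function(df, n) df[sample.int(nrow(df), n), , drop = FALSE]
  sel <- rbind(
    pick(chall[chall$trial_type == "HTLH", , drop = FALSE], n_htlh),
    pick(chall[chall$trial_type == "LTHH", , drop = FALSE], n_lthh),
    pick(nonch, n_non)
  )
  sel <- sel[sample.int(nrow(sel)), , drop = FALSE]
  sel$trial_idx <- seq_len(nrow(sel))
  out <- tibble::as_tibble(sel[, c("trial_idx", "food_id", "trial_type", "tr", "hr")])
  structure(out,
    class = c("choice_set", class(out)),
    n_challenge = n_ch, n_nonchallenge = n_non
  )
}

#' @export
print.choice_set <- function(x, ...) {
  cat(sprintf(
    "<choice_set> %d trials: %d challenge (%d HTLH, %d LTHH), %d aligned\n",
    nrow(x), attr(x, "n_challenge"),
    sum(x$trial_type == "HTLH"), sum(x$trial_type == "LTHH"),
    attr(x, "n_nonchallenge")
  ))
  NextMethod()
}

# Save/restore the global RNG state so seeded helpers do not disturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
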