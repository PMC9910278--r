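#' Per-condition SAM rating means
#'
#' Mean and SD of the in-scan SAM valence ratings for each of the five
#' block types of the emotion task (negative/positive view, negative/
#' positive reappraise, neutral view). Conditions absent from the data are
#' reported with `NA` and flagged.
#'
#' @param trials data frame with columns `valence_class`
#'   (`"negative"`, `"neutral"`, `"positive"`), `condition`
#'   (`"view"`, `"reappraise"`), `rating_inscan`.
#' @return tibble with columns `block_type`, `n`, `mean`, `sd`, `absent`.
#' @export
condition_means <- function(trials) {
  stopifnot(all(c("valence_class", "condition", "rating_inscan") %in%
                  names(trials)))
  blocks <- tibble::tibble(
    valence_class = c("negative", "negative", "neutral", "positive", "positive"),
    condition = c("view", "reappraise", "view", "reappraise", "view")
  )
  blocks$block_type <- paste(blocks$valence_class, blocks$condition, sep = "_")
  res <- lapply(seq_len(nrow(blocks)), function(i) {
    r <- trials$rating_inscan[
      trials$valence_class == blocks$valence_class[i] &
        trials$condition == blocks$condition[i]
    ]
    tibble::tibble(
      block_type = blocks$block_type[i],
      n = length(r),
      mean = if (length(r)) mean(r) else NA_real_,
      sd = if (length(r)) sd(r) else NA_real_,
      absent = length(r) == 0
    )
  })
  dplyr::bind_rows(res)
}

#' Classify one reappraisal trial as success or failure
#'
#' A reappraised stimulus counts as a success when the regulated in-scan
#' rating moved strictly toward neutral relative to the unregulated
#' post-scan view rating of the same picture: higher for negative stimuli,
#' lower for positive ones. Ties count as failures — success requires an
#' actual rating change.
#'
#' @param valence_class `"negative"` or `"positive"`.
#' @param rating_inscan,rating_postscan SAM ratings, 1-9.
#' @return character vector, `"success"` or `"failure"`.
#' @examples
#' classify_reappraisal_trial("negative", 5, 3)
#' @export
classify_reappraisal_trial <- function(valence_class, rating_inscan,
                                       rating_postscan) {
  n <- max(length(valence_class), length(rating_inscan), length(rating_postscan))
  valence_class <- rep_len(valence_class, n)
  rating_inscan <- rep_len(rating_inscan, n)
  rating_postscan <- rep_len(rating_postscan, n)
  if (any(!valence_class %in% c("negative", "positive"))) {
    stop("only reappraised negative/positive stimuli can be classified",
         call. = FALSE)
  }
  if (any(is.na(rating_postscan))) {
    stop("post-scan rating required to classify a reappraisal trial",
         call. = FALSE)
  }
  ifelse(
    (valence_class == "negative" & rating_inscan > rating_postscan) |
      (valence_class == "positive" & rating_inscan < rating_postscan),
    "success", "failure"
  )
}

#' Reappraisal success scores
#'
#' Per-stimulus rating differences between the regulated in-scan rating and
#' the unregulated post-scan view rating of the same picture, signed so
#' that larger means more successful regulation: `reappraise - view` for
#' negative stimuli, `view - reappraise` for positive ones. Differences are
#' averaged within valence, and the overall score is the mean of the two
#' valence scores. Stimuli missing a post-scan rating are skipped with a
#' warning; a valence with no usable stimuli leaves that score (and the
#' overall score) undefined.
#'
#' @param trials data frame with columns `valence_class`, `condition`,
#'   `rating_inscan`, `rating_postscan` (NA allowed for view trials).
#' @return an object of class `reappraisal_scores`: list with
#'   `success_neg`, `success_pos`, `success_overall`, `n_neg`, `n_pos`.
#' @examples
#' reappraisal_success_scores(data.frame(
#'   valence_class = c("negative", "positive"),
#'   condition = "reappraise",
#'   rating_inscan = c(4, 5), rating_postscan = c(3, 7)
#' ))
#' @export
reappraisal_success_scores <- function(trials) {
  stopifnot(all(c("valence_class", "condition", "rating_inscan",
                  "rating_postscan") %in% names(trials)))
  re <- trials[trials$condition == "reappraise", , drop = FALSE]
  if (nrow(re) == 0) stop("no reappraise trials present", call. = FALSE)
  miss <- is.na(re$rating_postscan)
  if (any(miss)) {
    warning(sprintf("%d reappraised stimuli lack a post-scan rating; skipped",
                    sum(miss)), call. = FALSE)
    re <- re[!miss, , drop = FALSE]
  }
  valence_score <- function(vc) {
    r <- re[re$valence_class == vc, , drop = FALSE]
    if (nrow(r) == 0) return(list(score = NA_real_, n = 0L))
    d <- if (vc == "negative") {
      r$rating_inscan - r$rating_postscan
    } else {
      r$rating_postscan - r$rating_inscan
    }
    list(score = mean(d), n = nrow(r))
  }
  neg <- valence_score("negative")
  pos <- valence_score("positive")
  overall <- if (is.na(neg$score) || is.na(pos$score)) {
    NA_real_
  } else {
    (neg$score + pos$score) / 2
  }
  structure(
    list(
      success_neg = neg$score, success_pos = pos$score,
      success_overall = overall, n_neg = neg$n, n_pos = pos$n
    ),
    class = "reappraisal_scores"
  )
}

#' @export
print.reappraisal_scores <- function(x, ...) {
  cat(sprintf(
    "<reappraisal_scores> negative %.3f (n=%d), positive %.3f (n=%d), overall %.3f\n",
    x$success_neg, x$n_neg, x$success_pos, x$n_pos, x$success_overall
  ))
  invisible(x)
}
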