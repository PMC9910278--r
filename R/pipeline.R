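#' Score a whole cohort
#'
#' Runs the participant-level scoring over every participant of a cohort:
#' taste/health weight fits, trial-wise subjective value, conflict, stakes
#' and orthogonalized stakes, self-control success levels, and reappraisal
#' success scores. Participants excluded at the design stage, or flagged
#' for separation in the weight fit, are carried through with
#' `excluded_flag` set and a reason, never silently dropped.
#'
#' @param cohort a [generate_cohort()] result, or a list with tibbles
#'   `choices` (columns `participant_id`, `trial_type`, `tr`, `hr`,
#'   `choice`, `rt_s`), `emotion`, and `participants` (optional).
#' @return list of tibbles: `trial_scores`, `participant_scores`,
#'   `reappraisal_scores`, `condition_means`.
#' @export
score_cohort <- function(cohort) {
  choices <- tibble::as_tibble(cohort$choices)
  if (!"participant_id" %in% names(choices)) {
    # no participant produced choice data (e.g. all excluded at design)
    choices <- tibble::tibble(participant_id = character())
  }
  emotion <- tibble::as_tibble(cohort$emotion)
  participants <- cohort$participants %||% tibble::tibble(
    participant_id = unique(c(choices$participant_id, emotion$participant_id)),
    excluded_choice = FALSE, exclusion_reason = NA_character_
  )

  trial_rows <- list()
  part_rows <- list()
  for (pid in participants$participant_id) {
    pinfo <- participants[participants$participant_id == pid, ]
    d <- choices[choices$participant_id == pid, , drop = FALSE]
    if (isTRUE(pinfo$excluded_choice) || nrow(d) == 0) {
      part_rows[[pid]] <- tibble::tibble(
        participant_id = pid, w_taste = NA_real_, w_health = NA_real_,
        success_overall = NA_real_, success_htlh = NA_real_,
        success_lthh = NA_real_, n_challenge = 0L,
        excluded_flag = TRUE,
        exclusion_reason = pinfo$exclusion_reason %||% "no choice data"
      )
      next
    }
    fit <- fit_taste_health_weights(d)
    sc <- score_trials(d, fit)
    summ <- score_self_control(sc)
    sc$scs <- summ$scs
    trial_rows[[pid]] <- sc
    excluded <- fit$separation_flag || summ$undefined
    part_rows[[pid]] <- tibble::tibble(
      participant_id = pid,
      w_taste = fit$w_taste, w_health = fit$w_health,
      success_overall = summ$success_overall,
      success_htlh = summ$success_htlh,
      success_lthh = summ$success_lthh,
      n_challenge = summ$n_challenge,
      excluded_flag = excluded,
      exclusion_reason = if (fit$separation_flag) {
        "separation in taste/health weight fit"
      } else if (summ$undefined) {
        "no responded challenge trials"
      } else {
        NA_character_
      }
    )
  }

  reap_rows <- list()
  cm_rows <- list()
  for (pid in unique(emotion$participant_id)) {
    e <- emotion[emotion$participant_id == pid, , drop = FALSE]
    rs <- reappraisal_success_scores(e)
    reap_rows[[pid]] <- tibble::tibble(
      participant_id = pid,
      success_neg = rs$success_neg, success_pos = rs$success_pos,
      success_overall = rs$success_overall,
      n_neg = rs$n_neg, n_pos = rs$n_pos
    )
    cm <- condition_means(e)
    cm$participant_id <- pid
    cm_rows[[pid]] <- cm
  }

  list(
    trial_scores = dplyr::bind_rows(trial_rows),
    participant_scores = dplyr::bind_rows(part_rows),
    reappraisal_scores = dplyr::bind_rows(reap_rows),
    condition_means = dplyr::bind_rows(cm_rows)
  )
}

#' Fit the diffusion model for every participant
#'
#' @param trial_scores scored trials ([score_cohort()]'s `trial_scores`)
#'   with columns `participant_id`, `choice`, `rt_s`, `sv`.
#' @return tibble `participant_id`, `a`, `z_rel`, `t0`, `drift_scale`,
#'   `neg_loglik`, `converged`.
#' @export
fit_cohort_ddm <- function(trial_scores) {
  rows <- lapply(unique(trial_scores$participant_id), function(pid) {
    d <- trial_scores[trial_scores$participant_id == pid, , drop = FALSE]
    fit <- tryCatch(suppressWarnings(fit_ddm_mle(d)),
                    error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble::tibble(
        participant_id = pid, a = NA_real_, z_rel = NA_real_, t0 = NA_real_,
        drift_scale = NA_real_, neg_loglik = NA_real_, converged = FALSE
      ))
    }
    tibble::tibble(
      participant_id = pid,
      a = fit$params$a, z_rel = fit$params$z_rel, t0 = fit$params$t0,
      drift_scale = fit$params$drift_scale,
      neg_loglik = fit$neg_loglik, converged = fit$converged
    )
  })
  dplyr::bind_rows(rows)
}

#' Pipeline configuration
#'
#' @param cohort a [cohort_config()] object.
#' @param out_dir output directory.
#' @param steps ordered subset of
#'   `c("simulate", "score", "fit_ddm", "associate", "recover", "report")`.
#' @param seed integer seed (overrides the cohort config seed).
#' @param n_resamples bootstrap replicates for association stages.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(cohort = cohort_config(), out_dir = "selfreg-out",
                            steps = c("simulate", "score", "fit_ddm",
                                      "associate", "report"),
                            seed = NULL, n_resamples = 2000) {
  all_steps <- c("simulate", "score", "fit_ddm", "associate", "recover",
                 "report")
  if (length(steps) == 0 || !all(steps %in% all_steps)) {
    stop("steps must be a nonempty subset of: ",
         paste(all_steps, collapse = ", "), call. = FALSE)
  }
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  structure(
    list(cohort = cohort, out_dir = out_dir, steps = steps,
         seed = cohort$seed, n_resamples = n_resamples),
    class = "pipeline_config"
  )
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order: simulate a cohort
#' (or read externally supplied `ratings.tsv`/`choices.tsv`/`emotion.tsv`
#' from `out_dir`), score trials and participants, fit the diffusion model,
#' compute cross-task associations, optionally run a parameter-recovery
#' experiment, and render a text report. Every file written is listed in a
#' manifest with its MD5 hash; the manifest also records the seed and the
#' exclusion decisions.
#'
#' @param config a [pipeline_config()] object.
#' @param verbose print progress.
#' @return invisibly, a list with the stage outputs and the `manifest`
#'   tibble.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  written <- character()
  add_written <- function(paths) written <<- c(written, unname(paths))
  state <- list()

  need <- function(stage, what) {
    if (is.null(state[[what]])) {
      stop(sprintf("stage '%s' needs '%s'; run that stage first", stage, what),
           call. = FALSE)
    }
  }

  for (step in config$steps) {
    if (step == "simulate") {
      say("simulating cohort (n = %d, seed = %d)",
          config$cohort$n_participants, config$seed)
      state$cohort <- generate_cohort(config$cohort)
      add_written(write_cohort(state$cohort, config$out_dir))
    } else if (step == "score") {
      if (is.null(state$cohort)) {
        state$cohort <- read_cohort_tables(config$out_dir)
      }
      need("score", "cohort")
      say("scoring trials and participants")
      state$scores <- score_cohort(state$cohort)
      p <- file.path(config$out_dir, c(
        "trial_scores.tsv", "participant_scores.tsv",
        "reappraisal_scores.tsv", "condition_means.tsv"
      ))
      readr::write_tsv(
        state$scores$trial_scores[, c("participant_id", "trial_idx", "sv",
                                      "conflict", "stakes", "stakes_orth",
                                      "scs")],
        p[1]
      )
      readr::write_tsv(state$scores$participant_scores, p[2])
      readr::write_tsv(state$scores$reappraisal_scores, p[3])
      readr::write_tsv(state$scores$condition_means, p[4])
      add_written(p)
    } else if (step == "fit_ddm") {
      need("fit_ddm", "scores")
      say("fitting the diffusion model per participant")
      state$ddm_fits <- fit_cohort_ddm(state$scores$trial_scores)
      p <- file.path(config$out_dir, "ddm_fits.tsv")
      readr::write_tsv(state$ddm_fits, p)
      add_written(p)
    } else if (step == "associate") {
      need("associate", "scores")
      say("cross-task association inference")
      assoc <- cross_task_association(
        state$scores$participant_scores, state$scores$reappraisal_scores,
        n_resamples = config$n_resamples, seed = config$seed
      )
      state$associations <- assoc
      p <- file.path(config$out_dir, "associations.json")
      jsonlite::write_json(
        lapply(assoc, function(a) a[c("rho", "interval_low", "interval_high",
                                      "pp_positive", "method", "n")]),
        p, auto_unbox = TRUE, digits = NA
      )
      add_written(p)
    } else if (step == "recover") {
      say("parameter-recovery experiment")
      state$recovery <- parameter_recovery_experiment(config$cohort)
      p <- file.path(config$out_dir, "recovery_report.json")
      jsonlite::write_json(unclass(state$recovery), p, auto_unbox = TRUE,
                           digits = NA)
      add_written(p)
    } else if (step == "report") {
      p <- file.path(config$out_dir, "report.txt")
      writeLines(write_report(state), p)
      add_written(p)
    }
  }

  manifest <- tibble::tibble(
    file = basename(written),
    md5 = unname(tools::md5sum(written))
  )
  manifest_path <- file.path(config$out_dir, "manifest.tsv")
  readr::write_tsv(manifest, manifest_path)
  log_lines <- c(
    sprintf("seed: %d", config$seed),
    sprintf("R: %s", as.character(getRversion())),
    sprintf("steps: %s", paste(config$steps, collapse = ", "))
  )
  if (!is.null(state$scores)) {
    ex <- state$scores$participant_scores
    ex <- ex[ex$excluded_flag, , drop = FALSE]
    log_lines <- c(log_lines, sprintf("excluded participants: %d", nrow(ex)),
                   sprintf("  %s: %s", ex$participant_id, ex$exclusion_reason))
  }
  writeLines(log_lines, file.path(config$out_dir, "pipeline_log.txt"))
  state$manifest <- manifest
  invisible(state)
}

#' Read externally supplied cohort tables
#'
#' Reads `ratings.tsv`, `choices.tsv` and `emotion.tsv` (the schemas
#' written by [write_cohort()]) from a directory, so deposited behavioral
#' data can be dropped into the pipeline in place of simulation. Ratings
#' are joined onto choices when the choices table lacks `tr`/`hr`.
#'
#' @param dir directory holding the TSV files.
#' @return a list shaped like a [generate_cohort()] result (without ground
#'   truth).
#' @export
read_cohort_tables <- function(dir) {
  pth <- function(f) file.path(dir, f)
  if (!file.exists(pth("choices.tsv")) || !file.exists(pth("emotion.tsv"))) {
    stop("missing choices.tsv / emotion.tsv in ", dir, call. = FALSE)
  }
  choices <- readr::read_tsv(pth("choices.tsv"), show_col_types = FALSE)
  emotion <- readr::read_tsv(pth("emotion.tsv"), show_col_types = FALSE)
  if (!all(c("tr", "hr") %in% names(choices))) {
    ratings <- readr::read_tsv(pth("ratings.tsv"), show_col_types = FALSE)
    choices <- dplyr::left_join(choices, ratings,
                                by = c("participant_id", "food_id"))
  }
  if (!"trial_type" %in% names(choices)) {
    choices$trial_type <- classify_trial_type(choices$tr, choices$hr)
  }
  list(
    choices = tibble::as_tibble(choices),
    emotion = tibble::as_tibble(emotion),
    participants = tibble::tibble(
      participant_id = unique(choices$participant_id),
      excluded_choice = FALSE, exclusion_reason = NA_character_
    )
  )
}

#' Render a human-readable pipeline report
#'
#' Pure function of the collected stage outputs: the per-condition SAM
#' rating table, success levels by challenge type, diffusion fits, and
#' association estimates. Stages that did not run are marked "not run".
#'
#' @param state the list returned by [run_pipeline()] (or assembled by
#'   hand).
#' @return character vector of report lines.
#' @export
write_report <- function(state) {
  lines <- c("selfreg pipeline report", "=======================", "")
  if (!is.null(state$scores)) {
    cm <- state$scores$condition_means
    agg <- dplyr::summarise(
      dplyr::group_by(cm, .data$block_type),
      sd = sd(.data$mean, na.rm = TRUE),
      mean = mean(.data$mean, na.rm = TRUE),
      .groups = "drop"
    )
    lines <- c(lines, "Emotion ratings by condition (participant means):",
               sprintf("  %-20s %6.2f +/- %.2f", agg$block_type, agg$mean,
                       agg$sd), "")
    ps <- state$scores$participant_scores
    ok <- !ps$excluded_flag
    lines <- c(
      lines, "Dietary self-control success levels:",
      sprintf("  overall %5.1f%%   HTLH %5.1f%%   LTHH %5.1f%%   (n = %d)",
              100 * mean(ps$success_overall[ok], na.rm = TRUE),
              100 * mean(ps$success_htlh[ok], na.rm = TRUE),
              100 * mean(ps$success_lthh[ok], na.rm = TRUE), sum(ok)), ""
    )
    ex <- ps[ps$excluded_flag, , drop = FALSE]
    lines <- c(lines, sprintf("Exclusions: %d", nrow(ex)))
    if (nrow(ex) > 0) {
      lines <- c(lines, sprintf("  %s: %s", ex$participant_id,
                                ex$exclusion_reason))
    }
    lines <- c(lines, "")
  } else {
    lines <- c(lines, "Scoring: not run", "")
  }
  if (!is.null(state$ddm_fits)) {
    f <- state$ddm_fits[state$ddm_fits$converged, , drop = FALSE]
    lines <- c(
      lines, "Diffusion-model fits (converged participants):",
      sprintf("  a %.2f   z_rel %.3f   t0 %.3f   drift_scale %.2f   (n = %d)",
              mean(f$a), mean(f$z_rel), mean(f$t0), mean(f$drift_scale),
              nrow(f)), ""
    )
  } else {
    lines <- c(lines, "Diffusion fits: not run", "")
  }
  if (!is.null(state$associations)) {
    lines <- c(lines, "Cross-task rank correlations (dietary success vs):")
    for (nm in names(state$associations)) {
      a <- state$associations[[nm]]
      lines <- c(lines, sprintf(
        "  %-9s rho = %6.3f  [%6.3f; %6.3f]  P(rho>0) = %.3f  n = %d",
        nm, a$rho, a$interval_low, a$interval_high, a$pp_positive, a$n
      ))
    }
    lines <- c(lines, "")
  } else {
    lines <- c(lines, "Associations: not run", "")
  }
  lines
}
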