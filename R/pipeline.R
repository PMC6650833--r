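# End-to-end glue: per-window feature extraction for a session, labeled
# calibration datasets, per-subject testing datasets, and cohort-level
# evaluation drivers.

#' Pipeline configuration
#'
#' Aggregates the pipeline's tunable constants with their standard
#' defaults: 15 s analysis windows moved in 1 s steps, 45 s warm-up
#' discarded from calibration recordings, a 45-240 bpm rPPG band with a
#' 12 bpm history constraint, 5 s test-sample spacing, and alpha = 0.05
#' for the chance-level calibration. All values are overridable and
#' round-trip through YAML/JSON config files.
#'
#' @param window_s Analysis-window length in seconds.
#' @param step_s Analysis-window step in seconds.
#' @param warmup_s Calibration warm-up to discard, seconds.
#' @param sampling_s Test-set sampling interval, seconds.
#' @param alpha Significance level for chance-level calibration.
#' @param rppg An [rppg_config()].
#' @param model A [model_config()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(window_s = 15, step_s = 1, warmup_s = 45,
                            sampling_s = 5, alpha = 0.05,
                            rppg = rppg_config(), model = model_config()) {
  structure(list(window_s = window_s, step_s = step_s, warmup_s = warmup_s,
                 sampling_s = sampling_s, alpha = alpha,
                 rppg = rppg, model = model),
            class = "pipeline_config")
}

#' Per-window feature vectors for a session over given windows
#'
#' Computes the facial features F1-F7 (per-frame, then aggregated with
#' the mean/standard-deviation rules of [aggregate_features()]), the
#' rPPG heart-rate feature F8, and - when a sensor stream is present -
#' the sensor heart-rate feature F9, for each supplied window.
#'
#' @param session A [simulate_session()] result, or any list with
#'   elements `track` ([landmark_track()]), `trace` ([rgb_trace()]) and
#'   optionally `sensor` (tibble `t`, `bpm`).
#' @param windows Window tibble (columns `window_start_s`,
#'   `window_end_s`).
#' @param features_used Which features to compute (default F1-F8, plus
#'   F9 if a sensor stream exists).
#' @param cfg A [pipeline_config()].
#' @return A tibble with `window_start_s` and the requested feature
#'   columns; F8 is `NA` for leading windows with no heart-rate estimate.
#' @export
session_features <- function(session, windows, features_used = NULL,
                             cfg = pipeline_config()) {
  if (is.null(features_used)) {
    features_used <- c(paste0("F", 1:8), if (!is.null(session$sensor)) "F9")
  }
  out <- tibble(window_start_s = windows$window_start_s)
  facial <- intersect(paste0("F", 1:7), features_used)
  if (length(facial)) {
    ff <- facial_features(session$track)
    agg <- aggregate_features(ff[c("t", facial)], windows)
    out <- left_join(out, agg, by = "window_start_s")
  }
  if ("F8" %in% features_used) {
    hr <- estimate_hr(session$trace, windows, cfg$rppg)
    out <- left_join(out, dplyr::select(hr, "window_start_s", F8 = "bpm"),
                     by = "window_start_s")
  }
  if ("F9" %in% features_used) {
    if (is.null(session$sensor)) stop_invalid("F9 requested but session has no sensor stream")
    out <- left_join(out, sensor_hr_feature(session$sensor, windows),
                     by = "window_start_s")
  }
  out
}

#' Labeled calibration windows for one subject
#'
#' For each calibration game: discards the warm-up, takes the equal-length
#' boring (H0) and stressful (H1) thirds ([segment_calibration()]),
#' enumerates moving windows anchored at each segment's start, extracts
#' the per-window features and labels them (H0 -> boredom, H1 -> stress).
#'
#' @param calibration List of calibration sessions (one per game).
#' @param features_used Feature columns to compute (see
#'   [session_features()]).
#' @param cfg A [pipeline_config()].
#' @param subject Optional subject id attached as provenance.
#' @return A labeled tibble: `subject`, `game`, `role`, `window_start_s`,
#'   features, `label` (see [build_training_set()]).
#' @export
calibration_samples <- function(calibration, features_used = NULL,
                                cfg = pipeline_config(), subject = NA) {
  purrr::imap_dfr(calibration, function(session, g) {
    dur <- max(session$track$t) + 1 / session$fps
    segs <- dplyr::filter(segment_calibration(dur, cfg$warmup_s),
                          .data$role != "discarded")
    feats <- purrr::pmap_dfr(segs, function(role, start_s, end_s) {
      w <- analysis_windows(start_s, end_s, cfg$window_s, cfg$step_s)
      if (!nrow(w)) return(NULL)
      dplyr::mutate(session_features(session, w, features_used, cfg),
                    role = role, .before = 1)
    })
    dplyr::mutate(feats, subject = subject, game = g, .before = 1)
  }) |>
    build_training_set(features_used = features_used)
}

#' Independent testing dataset for one subject
#'
#' Scores the subject's self-reports, selects up to two stressful and two
#' boring evaluation levels ([select_eval_levels()]), lays test windows
#' on the 5-second grid of each selected level ([sample_test_set()]) and
#' extracts their feature vectors. Windows with missing features are
#' dropped.
#'
#' @param evaluation List of evaluation-level sessions, indexed by level.
#' @param reports Self-report tibble for the subject (columns `level`,
#'   `rstress`, `rboredom`).
#' @param features_used Feature columns.
#' @param cfg A [pipeline_config()].
#' @param subject Optional subject id.
#' @return A labeled tibble of test samples (possibly zero rows for an
#'   unevaluable subject), with a `selected_levels` attribute.
#' @export
testing_samples <- function(evaluation, reports, features_used = NULL,
                            cfg = pipeline_config(), subject = NA) {
  selected <- select_eval_levels(reports)
  empty <- tibble(subject = subject, level = integer(0),
                  label = factor(character(0), levels = c("boredom", "stress")),
                  window_start_s = numeric(0))
  if (!length(unique(selected$class)) || !all(c("stress", "boredom") %in% selected$class)) {
    # zero surviving levels in one class: subject unevaluable
    attr(empty, "selected_levels") <- selected
    return(empty)
  }
  out <- purrr::pmap_dfr(selected, function(level, class, score) {
    session <- evaluation[[level]]
    dur <- max(session$track$t) + 1 / session$fps
    w <- test_windows(0, dur, cfg$window_s, cfg$sampling_s)
    if (!nrow(w)) return(NULL)
    feats <- session_features(session, w, features_used, cfg)
    dplyr::mutate(feats, subject = subject, level = level,
                  label = factor(class, levels = c("boredom", "stress")),
                  .before = 1)
  })
  if (is.null(out) || !nrow(out)) {
    attr(empty, "selected_levels") <- selected
    return(empty)
  }
  fu <- intersect(c(paste0("F", 1:9)), names(out))
  out <- out[stats::complete.cases(out[fu]), ]
  attr(out, "selected_levels") <- selected
  out
}

#' Cohort-level cross-game evaluation
#'
#' For every subject of a simulated (or assembled) study-2 cohort: build
#' the labeled calibration training set, train the user-tailored model,
#' sample the independent testing dataset from the self-report-selected
#' evaluation levels, and measure accuracy. The cohort aggregate is the
#' mean per-subject accuracy over evaluable subjects.
#'
#' @param cohort A [simulate_cohort()] result (study 2).
#' @param features_used Feature columns (default the remote set F1-F8).
#' @param cfg A [pipeline_config()].
#' @return A list of class `cohort_result`: `per_subject` tibble
#'   (`subject`, `accuracy`, `n_train`, `n_test`, `n_stress`,
#'   `n_boredom`, `cv_auc`), `mean_accuracy`, `n_evaluable`.
#' @export
evaluate_cohort <- function(cohort, features_used = feature_set("STUDY2"),
                            cfg = pipeline_config()) {
  rows <- purrr::map_dfr(cohort$subjects, function(su) {
    train <- calibration_samples(su$calibration, features_used, cfg,
                                 subject = su$subject)
    test <- testing_samples(su$evaluation, su$reports, features_used, cfg,
                            subject = su$subject)
    cfg_i <- cfg$model
    cfg_i$seed <- cfg$model$seed + su$subject
    res <- cross_game_evaluate(train, test, cfg = cfg_i,
                               features_used = features_used,
                               subject = su$subject)
    if (is.null(res)) {
      return(tibble(subject = su$subject, accuracy = NA_real_,
                    n_train = nrow(train), n_test = 0L,
                    n_stress = 0L, n_boredom = 0L, cv_auc = NA_real_))
    }
    tibble(subject = su$subject, accuracy = res$accuracy,
           n_train = nrow(train), n_test = nrow(test),
           n_stress = as.integer(sum(test$label == "stress")),
           n_boredom = as.integer(sum(test$label == "boredom")),
           cv_auc = res$model$cv_auc)
  })
  structure(list(
    per_subject = rows,
    mean_accuracy = mean(rows$accuracy, na.rm = TRUE),
    n_evaluable = sum(!is.na(rows$accuracy))
  ), class = "cohort_result")
}

#' Cohort-level leave-one-session-out evaluation
#'
#' Runs [losocv_evaluate()] for every subject of a study-1 style cohort
#' with the requested feature set and pools the per-fold accuracies
#' (the `J` sample used for paired test comparisons).
#'
#' @param cohort A [simulate_cohort()] result.
#' @param test_id A [feature_set()] preset id (default `"MULTI_R"`).
#' @param cfg A [pipeline_config()].
#' @return A list of class `cohort_result` with `per_subject`
#'   (`subject`, `accuracy` = `A_i`), `fold_accuracies` (pooled `J`
#'   values), and `mean_accuracy`.
#' @export
losocv_cohort <- function(cohort, test_id = "MULTI_R", cfg = pipeline_config()) {
  features_used <- feature_set(test_id)
  res <- lapply(cohort$subjects, function(su) {
    train <- calibration_samples(su$calibration, features_used, cfg,
                                 subject = su$subject)
    cfg_i <- cfg$model
    cfg_i$seed <- cfg$model$seed + su$subject
    losocv_evaluate(train, cfg = cfg_i, features_used = features_used,
                    subject = su$subject)
  })
  per_subject <- purrr::map_dfr(res, glance)
  structure(list(
    test_id = test_id,
    per_subject = per_subject,
    fold_accuracies = unlist(lapply(res, function(r) r$folds$accuracy)),
    results = res,
    mean_accuracy = mean(per_subject$accuracy)
  ), class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result: mean accuracy %.3f over %d subject(s)>\n",
              x$mean_accuracy, nrow(x$per_subject)))
  invisible(x)
}
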