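# Assembly of labeled training samples from calibration segments and of
# the independent testing dataset from evaluation-game self-reports.

#' Feature-set presets
#'
#' Named feature subsets used by the evaluation protocols: `MULTI_R`
#' (facial + rPPG heart rate, F1-F6 + F8), `MULTI_G` (facial + sensor
#' heart rate, F1-F6 + F9), `FACE` (facial only, F1-F6), `HR_R` (F8
#' only), `HR_G` (F9 only), and `STUDY2` (F1-F8, the full remote set used
#' for cross-game evaluation).
#'
#' @param test_id One of `"MULTI_R"`, `"MULTI_G"`, `"FACE"`, `"HR_R"`,
#'   `"HR_G"`, `"STUDY2"`.
#' @return A character vector of feature column names.
#' @export
#' @examples
#' feature_set("MULTI_R")
feature_set <- function(test_id) {
  presets <- list(
    MULTI_R = c(paste0("F", 1:6), "F8"),
    MULTI_G = c(paste0("F", 1:6), "F9"),
    FACE = paste0("F", 1:6),
    HR_R = "F8",
    HR_G = "F9",
    STUDY2 = paste0("F", 1:8)
  )
  if (!test_id %in% names(presets)) {
    stop_invalid(sprintf("unknown feature-set id '%s'", test_id))
  }
  presets[[test_id]]
}

#' Label per-window feature vectors from calibration segments
#'
#' Windows carrying a `role` of `"H0"` are labeled `boredom` and `"H1"`
#' windows `stress` (the design of the calibration games guarantees those
#' parts elicit those states). Windows with any missing configured
#' feature are dropped, with the count recorded in the `n_dropped`
#' attribute. Because H0 and H1 are equal length, the result is
#' class-balanced per game by construction (up to dropped windows).
#'
#' @param features A tibble of per-window features with columns
#'   `window_start_s`, `role` (`"H0"`/`"H1"`), the configured feature
#'   columns, and any provenance columns (e.g. `subject`, `game`).
#' @param features_used Character vector of feature columns to keep (see
#'   [feature_set()]); defaults to every `F1`..`F9` column present.
#' @return The input rows restricted to H0/H1, with a `label` factor
#'   (`boredom`, `stress`) and only the configured feature columns.
#' @export
build_training_set <- function(features, features_used = NULL) {
  if (!nrow(features)) {
    out <- dplyr::mutate(features, label = factor(character(0),
                                                  levels = c("boredom", "stress")))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  if (is.null(features_used)) {
    features_used <- intersect(paste0("F", 1:9), names(features))
  }
  missing_cols <- setdiff(features_used, names(features))
  if (length(missing_cols)) {
    stop_invalid(paste("missing feature columns:", paste(missing_cols, collapse = ", ")))
  }
  keep <- dplyr::filter(features, .data$role %in% c("H0", "H1"))
  complete <- stats::complete.cases(keep[features_used])
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(sprintf("build_training_set: dropped %d window(s) with missing features",
                    n_dropped))
  }
  out <- keep[complete, ]
  out$label <- factor(ifelse(out$role == "H0", "boredom", "stress"),
                      levels = c("boredom", "stress"))
  prov <- intersect(c("subject", "game", "role", "window_start_s"), names(out))
  out <- out[c(prov, features_used, "label")]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Stress and boredom scores from Likert self-reports
#'
#' After each evaluation-game level, subjects rate experienced stress and
#' boredom on 5-point Likert scales. The level's stress score is
#' `rstress - rboredom` and its boredom score the negation, so the two
#' scores always sum to zero and a level cannot be simultaneously
#' stressful and boring.
#'
#' @param reports A tibble with columns `subject`, `level`, `rstress`,
#'   `rboredom` (integers in 1..5).
#' @return The input with `stress_score` and `boredom_score` columns.
#' @export
level_scores <- function(reports) {
  ok <- function(v) all(v %in% 1:5)
  if (!ok(reports$rstress) || !ok(reports$rboredom)) {
    stop_invalid("Likert ratings must be integers in 1..5")
  }
  dplyr::mutate(reports,
                stress_score = .data$rstress - .data$rboredom,
                boredom_score = .data$rboredom - .data$rstress)
}

#' Select evaluation-game levels for testing
#'
#' For one subject, the two levels with the highest stress score are
#' selected to sample stress entries, and the two with the highest
#' boredom score to sample boredom entries (ties broken by
#' earliest-played level). Any selected level whose relevant score is not
#' at least 1 is then excluded, which removes inconclusive reports; a
#' level can therefore appear in at most one class. A subject with no
#' surviving level in either class is unevaluable (zero rows for that
#' class; callers exclude such subjects from cohort aggregates).
#'
#' @param reports Self-report tibble for a single subject (columns
#'   `level`, `rstress`, `rboredom`; see [level_scores()]).
#' @return A tibble with columns `level`, `class` (`"stress"` or
#'   `"boredom"`) and `score`.
#' @export
select_eval_levels <- function(reports) {
  scored <- level_scores(reports)
  pick <- function(score_col, cls) {
    s <- scored[order(-scored[[score_col]], seq_len(nrow(scored))), ]
    s <- head(s, 2)
    s <- s[s[[score_col]] >= 1, ]
    if (!nrow(s)) {
      return(tibble(level = integer(0), class = character(0), score = integer(0)))
    }
    tibble(level = s$level, class = cls, score = s[[score_col]])
  }
  out <- bind_rows(pick("stress_score", "stress"), pick("boredom_score", "boredom"))
  dup <- out$level[duplicated(out$level)]
  out[!(out$level %in% dup), ]
}

#' Test-sample windows on the 5-second grid of a level
#'
#' Test samples are taken every `interval_s` seconds: windows
#' `[t - length_s, t)` ending at `t = length_s, length_s + interval_s,
#' ...` within the level. A level shorter than one window contributes no
#' samples.
#'
#' @param start_s,end_s Level interval bounds in seconds.
#' @param length_s Window length (default 15 s).
#' @param interval_s Sampling interval (default 5 s).
#' @return A tibble with columns `window_start_s`, `window_end_s`.
#' @export
#' @examples
#' nrow(test_windows(0, 60))  # 10 samples
test_windows <- function(start_s, end_s, length_s = 15, interval_s = 5) {
  span <- end_s - start_s
  if (span < length_s - 1e-9) {
    return(tibble(window_start_s = numeric(0), window_end_s = numeric(0)))
  }
  ends <- seq(length_s, span + 1e-9, by = interval_s)
  tibble(window_start_s = start_s + ends - length_s,
         window_end_s = start_s + ends)
}

#' Lay out the labeled testing dataset for one subject
#'
#' Combines [select_eval_levels()] with the 5-second sampling rule: every
#' selected level contributes one labeled sample specification per grid
#' window, labeled with the level's class. Feature values are attached by
#' the caller (the windows here say *where* to sample).
#'
#' @param selected Output of [select_eval_levels()].
#' @param level_intervals A tibble with columns `level`, `start_s`,
#'   `end_s` giving each level's recording interval.
#' @param length_s,interval_s Window geometry (defaults 15 s / 5 s).
#' @return A tibble with columns `level`, `label`, `window_start_s`,
#'   `window_end_s`.
#' @export
sample_test_set <- function(selected, level_intervals, length_s = 15,
                            interval_s = 5) {
  rows <- purrr::pmap_dfr(selected, function(level, class, score) {
    iv <- level_intervals[level_intervals$level == level, ]
    if (!nrow(iv)) stop_invalid(sprintf("no interval for level %s", level))
    w <- test_windows(iv$start_s[1], iv$end_s[1], length_s, interval_s)
    if (!nrow(w)) return(NULL)
    dplyr::mutate(w, level = level, label = class, .before = 1)
  })
  if (is.null(rows) || !nrow(rows)) {
    return(tibble(level = integer(0),
                  label = factor(character(0), levels = c("boredom", "stress")),
                  window_start_s = numeric(0), window_end_s = numeric(0)))
  }
  rows$label <- factor(rows$label, levels = c("boredom", "stress"))
  rows
}
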