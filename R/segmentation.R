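# Session segmentation: warm-up removal, H0/H1 thirds, moving analysis
# windows, and design bookkeeping over session manifests.

#' Enumerate moving analysis windows over an interval
#'
#' Windows are half-open intervals `[a + k*step, a + k*step + length)` laid
#' on a grid anchored at the interval start. An interval shorter than one
#' window yields an empty tibble (not an error).
#'
#' @param start_s,end_s Interval bounds in seconds, half-open `[start, end)`.
#' @param length_s Window length in seconds (default 15).
#' @param step_s Window step in seconds (default 1; i.e. 93.33% overlap of
#'   consecutive windows at the default length).
#' @return A tibble with columns `window_start_s`, `window_end_s`.
#' @export
#' @examples
#' nrow(analysis_windows(0, 20))  # 6 windows
analysis_windows <- function(start_s, end_s, length_s = 15, step_s = 1) {
  stopifnot(length_s > 0, step_s > 0, start_s >= 0, end_s > start_s)
  span <- end_s - start_s
  if (span < length_s - 1e-9) {
    return(tibble(window_start_s = numeric(0), window_end_s = numeric(0)))
  }
  k <- 0:floor((span - length_s) / step_s + 1e-9)
  tibble(window_start_s = start_s + k * step_s,
         window_end_s = start_s + k * step_s + length_s)
}

#' Split a calibration-game recording into labeled thirds
#'
#' The initial `warmup_s` seconds are discarded (players are still settling
#' in and learning the game). The remainder `R = T - warmup_s` is divided
#' into three equal parts of `L = floor(R / 3)` whole seconds: the first,
#' `H0 = [warmup_s, warmup_s + L)`, is the boring part (low difficulty);
#' the last, `H1 = [T - L, T)`, is the stressful part (overwhelming
#' difficulty); the middle (plus any flooring slack) has unknown emotional
#' state and is discarded.
#'
#' @param duration_s Total recording duration `T` in seconds.
#' @param warmup_s Warm-up duration to discard (default 45 s).
#' @return A tibble with columns `role` (`"H0"`, `"H1"`, `"discarded"`),
#'   `start_s`, `end_s`.
#' @export
#' @examples
#' segment_calibration(345)  # H0 = [45, 145), H1 = [245, 345)
segment_calibration <- function(duration_s, warmup_s = 45) {
  if (duration_s <= warmup_s + 3) {
    stop_invalid(sprintf(
      "session too short: duration %g s leaves no room for thirds after %g s warm-up",
      duration_s, warmup_s))
  }
  L <- floor((duration_s - warmup_s) / 3)
  tibble(
    role = c("discarded", "H0", "discarded", "H1"),
    start_s = c(0, warmup_s, warmup_s + L, duration_s - L),
    end_s = c(warmup_s, warmup_s + L, duration_s - L, duration_s)
  )
}

#' Session manifest constructor
#'
#' A manifest is the tabular bookkeeping of a study: one row per recorded
#' game or evaluation level, with half-open time intervals and exclusion
#' flags. Excluding any calibration game of a subject excludes the whole
#' subject from calibration bookkeeping (calibration problems contaminate
#' all of that subject's H0/H1 pairs).
#'
#' @param subject Subject identifier vector.
#' @param kind `"calibration"` or `"evaluation"` per row.
#' @param id Game id (1-3) for calibration rows, level id (1-7) for
#'   evaluation rows.
#' @param start_s,end_s Interval bounds in seconds.
#' @param excluded Logical exclusion flag (default `FALSE`).
#' @param reason Optional exclusion reason.
#' @return A tibble of class `session_manifest`.
#' @export
session_manifest <- function(subject, kind, id, start_s, end_s,
                             excluded = FALSE, reason = NA_character_) {
  m <- tibble(subject = subject, kind = kind, id = as.integer(id),
              start_s = start_s, end_s = end_s,
              excluded = excluded, reason = reason)
  if (!all(m$kind %in% c("calibration", "evaluation"))) {
    stop_invalid("manifest `kind` must be 'calibration' or 'evaluation'")
  }
  if (any(m$end_s <= m$start_s)) stop_invalid("manifest intervals must have end > start")
  class(m) <- c("session_manifest", class(m))
  m
}

#' Count usable segments in session manifests
#'
#' Reports the number of (H0, H1) calibration pairs and evaluation
#' segments after exclusions. Exclusion is whole-subject for calibration:
#' if any calibration row of a subject is flagged, all of that subject's
#' pairs are dropped.
#'
#' @param manifest A manifest tibble (see [session_manifest()]), possibly
#'   covering many subjects.
#' @return A one-row tibble: `n_subjects`, `n_excluded_subjects`,
#'   `h0_h1_pairs`, `eval_segments`.
#' @export
count_segments <- function(manifest) {
  cal <- dplyr::filter(manifest, .data$kind == "calibration")
  ev <- dplyr::filter(manifest, .data$kind == "evaluation")
  excluded_subjects <- unique(cal$subject[cal$excluded])
  kept <- dplyr::filter(cal, !(.data$subject %in% excluded_subjects))
  tibble(
    n_subjects = length(unique(manifest$subject)),
    n_excluded_subjects = length(excluded_subjects),
    h0_h1_pairs = nrow(kept),
    eval_segments = sum(!ev$excluded)
  )
}
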