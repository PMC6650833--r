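# Plain-text readers and writers for the pipeline's file formats:
# landmark CSVs, RGB-trace CSVs, 1 Hz sensor CSVs, self-report CSVs,
# YAML/JSON session manifests, and session directories emitted by the
# simulator.

#' Read / write a landmark track CSV
#'
#' Format: a header row, then one row per frame:
#' `t, x0, y0, x1, y1, ..., x67, y67[, confidence]`. Input files indexed
#' from 1 (`x1..x68`) are remapped with `one_based = TRUE`.
#'
#' @param path CSV file path.
#' @param fps Frames per second; inferred from the time column when `NULL`.
#' @param one_based Set `TRUE` if the file's point columns are numbered
#'   1..68 instead of 0..67.
#' @return A landmark track tibble (see [landmark_track()]).
#' @export
read_landmarks <- function(path, fps = NULL, one_based = FALSE) {
  d <- as_tibble(read.csv(path, check.names = TRUE))
  if (one_based) {
    idx <- 1:68
    names(d)[match(paste0("x", idx), names(d))] <- paste0("x", idx - 1)
    names(d)[match(paste0("y", idx), names(d))] <- paste0("y", idx - 1)
  }
  need <- c("t", landmark_cols())
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop_invalid(paste("landmark file lacks column(s):",
                       paste(head(miss, 4), collapse = ", ")))
  }
  if (is.null(fps)) fps <- 1 / stats::median(diff(d$t))
  n <- nrow(d)
  pts <- array(c(as.matrix(d[paste0("x", 0:67)]),
                 as.matrix(d[paste0("y", 0:67)])), dim = c(n, 68, 2))
  landmark_track(d$t, pts, fps = fps,
                 confidence = if ("confidence" %in% names(d)) d$confidence)
}

#' @rdname read_landmarks
#' @param track A landmark track tibble.
#' @export
write_landmarks <- function(track, path) {
  ord <- c("t", as.vector(rbind(paste0("x", 0:67), paste0("y", 0:67))))
  if ("confidence" %in% names(track)) ord <- c(ord, "confidence")
  write.csv(as.data.frame(track)[ord], path, row.names = FALSE)
  invisible(path)
}

#' Read / write an RGB-trace CSV (`t, mean_r, mean_g, mean_b`)
#'
#' @param path CSV file path.
#' @param fps Frames per second; inferred from the time column when `NULL`.
#' @return An [rgb_trace()] tibble.
#' @export
read_rgb_trace <- function(path, fps = NULL) {
  d <- read.csv(path)
  need <- c("t", "mean_r", "mean_g", "mean_b")
  if (!all(need %in% names(d))) {
    stop_invalid("RGB trace file needs columns t, mean_r, mean_g, mean_b")
  }
  if (is.null(fps)) fps <- 1 / stats::median(diff(d$t))
  rgb_trace(d$t, d$mean_r, d$mean_g, d$mean_b, fps = fps)
}

#' @rdname read_rgb_trace
#' @param trace An [rgb_trace()] tibble.
#' @export
write_rgb_trace <- function(trace, path) {
  write.csv(data.frame(t = trace$t, mean_r = trace$r, mean_g = trace$g,
                       mean_b = trace$b), path, row.names = FALSE)
  invisible(path)
}

#' Read a 1 Hz sensor heart-rate CSV (`t, bpm`)
#'
#' @param path CSV file path.
#' @return A tibble with columns `t`, `bpm`.
#' @export
read_sensor_hr <- function(path) {
  d <- as_tibble(read.csv(path))
  if (!all(c("t", "bpm") %in% names(d))) {
    stop_invalid("sensor HR file needs columns t, bpm")
  }
  d[c("t", "bpm")]
}

#' Read a self-report CSV (`subject, level, rstress, rboredom`)
#'
#' @param path CSV file path.
#' @return A validated tibble (see [level_scores()]).
#' @export
read_self_reports <- function(path) {
  d <- as_tibble(read.csv(path))
  need <- c("subject", "level", "rstress", "rboredom")
  if (!all(need %in% names(d))) {
    stop_invalid("self-report file needs columns subject, level, rstress, rboredom")
  }
  level_scores(d[need])[need] # validates ranges
}

#' Read / write a session manifest (YAML or JSON)
#'
#' The manifest lists per-subject recording intervals:
#' `{subject, kind: calibration|evaluation, id, start_s, end_s,
#' excluded?, reason?}`.
#'
#' @param path File path; `.json` is parsed as JSON, anything else as
#'   YAML.
#' @return A [session_manifest()] tibble.
#' @export
read_manifest <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  rows <- if (is.data.frame(raw)) raw else bind_rows(lapply(raw, as_tibble))
  session_manifest(
    subject = rows$subject, kind = rows$kind, id = rows$id,
    start_s = rows$start_s, end_s = rows$end_s,
    excluded = if ("excluded" %in% names(rows)) {
      !is.na(rows$excluded) & rows$excluded
    } else FALSE,
    reason = if ("reason" %in% names(rows)) rows$reason else NA_character_)
}

#' @rdname read_manifest
#' @param manifest A [session_manifest()] tibble.
#' @export
write_manifest <- function(manifest, path) {
  recs <- purrr::pmap(as.data.frame(manifest), function(...) {
    r <- list(...)
    r$reason <- if (is.na(r$reason)) NULL else r$reason
    r
  })
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(recs, path)
  }
  invisible(path)
}

#' Write a simulated session to a ready-to-run directory
#'
#' Emits exactly the CSV formats the readers consume: `landmarks.csv`,
#' `rgb_trace.csv`, `sensor_hr.csv`, plus `truth.csv` (ground-truth heart
#' rate and state) and `schedule.csv`.
#'
#' @param session A [simulate_session()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_landmarks(session$track, file.path(dir, "landmarks.csv"))
  write_rgb_trace(session$trace, file.path(dir, "rgb_trace.csv"))
  write.csv(as.data.frame(session$sensor), file.path(dir, "sensor_hr.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(session$truth), file.path(dir, "truth.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(session$schedule), file.path(dir, "schedule.csv"),
            row.names = FALSE)
  invisible(dir)
}
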