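# Remote photoplethysmography: per-window heart-rate estimation from
# mean-RGB pixel traces via blind source separation (seeded FastICA) and
# spectral peak selection in the physiological band.

#' rPPG configuration
#'
#' @param band_bpm Physiological search band in beats per minute
#'   (default 45-240, i.e. 0.75-4 Hz).
#' @param history_bpm Maximum allowed jump between consecutive accepted
#'   estimates (default 12 bpm); larger jumps fall back to the
#'   next-highest in-band spectral peak, or carry the previous value.
#' @param min_peak_ratio Minimum in-band peak-to-total power ratio for an
#'   estimate to count at all; below it the window yields no estimate.
#'   Peak power is the power within +/- 2 bpm of the spectral peak.
#' @param max_bin_bpm Maximum spectral bin spacing in bpm; the FFT is
#'   zero-padded until the spacing is at or below this (default 1 bpm).
#' @param seed RNG seed for the FastICA initialisation.
#' @return A list of class `rppg_config`.
#' @export
rppg_config <- function(band_bpm = c(45, 240), history_bpm = 12,
                        min_peak_ratio = 0.2, max_bin_bpm = 1, seed = 1L) {
  stopifnot(length(band_bpm) == 2, band_bpm[1] > 0, band_bpm[2] > band_bpm[1],
            history_bpm > 0, min_peak_ratio >= 0, max_bin_bpm > 0)
  structure(list(band_bpm = band_bpm, history_bpm = history_bpm,
                 min_peak_ratio = min_peak_ratio, max_bin_bpm = max_bin_bpm,
                 seed = as.integer(seed)),
            class = "rppg_config")
}

#' Build an RGB trace tibble
#'
#' @param t Sample times in seconds (uniform spacing).
#' @param r,g,b Per-frame spatial means of the red, green and blue
#'   channels over the facial region, each in \[0, 255\].
#' @param fps Frames per second.
#' @return A tibble with columns `t`, `r`, `g`, `b` and an `fps` attribute.
#' @export
rgb_trace <- function(t, r, g, b, fps) {
  stopifnot(length(t) >= 1, length(r) == length(t), length(g) == length(t),
            length(b) == length(t))
  if (any(!is.finite(c(r, g, b)))) stop_invalid("RGB channels must be finite")
  out <- tibble(t = t, r = r, g = g, b = b)
  attr(out, "fps") <- fps
  class(out) <- c("rgb_trace", class(out))
  out
}

trace_fps <- function(trace) {
  fps <- attr(trace, "fps")
  if (is.null(fps)) fps <- 1 / stats::median(diff(trace$t))
  fps
}

#' Spatially average video frames over a region of interest
#'
#' Convenience plumbing for callers who hold decoded video frames in
#' memory; the synthetic generator emits RGB traces directly and bypasses
#' this.
#'
#' @param frames List of numeric `H x W x 3` arrays (one per frame).
#' @param roi Integer vector `c(row0, row1, col0, col1)` (inclusive), or a
#'   list of one such vector per frame.
#' @param fps Frames per second.
#' @param t Optional frame times; defaults to `(seq_along(frames) - 1) / fps`.
#' @return An [rgb_trace()] tibble.
#' @export
extract_rgb_trace <- function(frames, roi, fps, t = NULL) {
  if (is.null(t)) t <- (seq_along(frames) - 1) / fps
  rois <- if (is.list(roi)) roi else rep(list(roi), length(frames))
  means <- purrr::map2(frames, rois, function(fr, rc) {
    if (rc[1] > rc[2] || rc[3] > rc[4]) stop_invalid("empty ROI")
    sub <- fr[rc[1]:rc[2], rc[3]:rc[4], , drop = FALSE]
    apply(sub, 3, mean)
  })
  m <- do.call(rbind, means)
  rgb_trace(t, m[, 1], m[, 2], m[, 3], fps = fps)
}

#' Condition RGB channels over a window
#'
#' Each channel is linearly detrended (least-squares line removed) and
#' z-normalised (zero mean, unit variance) over the window, the standard
#' preparation before blind source separation.
#'
#' @param trace An [rgb_trace()] tibble.
#' @param window_start_s,window_end_s Half-open window bounds in seconds.
#' @return A tibble with columns `t`, `r`, `g`, `b` of conditioned values.
#' @export
condition_channels <- function(trace, window_start_s, window_end_s) {
  inside <- trace$t >= window_start_s - 1e-9 & trace$t < window_end_s - 1e-9
  if (!any(inside)) stop_invalid("window not covered by trace")
  tt <- trace$t[inside]
  cond <- lapply(c("r", "g", "b"), function(ch) {
    y <- trace[[ch]][inside]
    d <- residuals(lm(y ~ tt))
    s <- sd(d)
    if (!is.finite(s) || s < 1e-10) {
      rlang::abort(sprintf("channel '%s' is degenerate (zero variance after detrend)", ch),
                   class = "remoteaffect_degenerate_signal")
    }
    as.numeric((d - mean(d)) / s)
  })
  tibble(t = tt, r = cond[[1]], g = cond[[2]], b = cond[[3]])
}

# Symmetric FastICA with logcosh (tanh) nonlinearity on an n x p matrix of
# observations; returns sources as an n x n_comp matrix. Deterministic for
# a given seed.
fast_ica <- function(X, n_comp = 3, seed = 1L, max_iter = 200, tol = 1e-7) {
  X <- as.matrix(X)
  n <- nrow(X)
  Xc <- scale(X, scale = FALSE)
  e <- eigen(crossprod(Xc) / n, symmetric = TRUE)
  keep <- e$values > 1e-12 * max(e$values)
  K <- e$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(e$values[keep]), sum(keep))
  Z <- Xc %*% K
  k <- ncol(Z)
  n_comp <- min(n_comp, k)
  decorrelate <- function(W) {
    s <- eigen(W %*% t(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(s$values), length(s$values)) %*%
      t(s$vectors) %*% W
  }
  W <- with_seed(seed, matrix(rnorm(n_comp * k), n_comp, k))
  W <- decorrelate(W)
  for (it in seq_len(max_iter)) {
    G <- tanh(Z %*% t(W))
    W1 <- crossprod(G, Z) / n - diag(colMeans(1 - G^2), n_comp) %*% W
    W1 <- decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  Z %*% t(W)
}

# run code under a temporary RNG state so package internals never disturb
# the caller's random stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Hamming-windowed, zero-padded power spectrum. Returns tibble(freq_hz, power).
power_spectrum <- function(x, fs, max_bin_hz) {
  n <- length(x)
  w <- signal::hamming(n)
  xw <- (x - mean(x)) * w
  nfft <- 2^ceiling(log2(max(n, fs / max_bin_hz)))
  p <- Mod(fft(c(xw, rep(0, nfft - n))))^2
  half <- seq_len(floor(nfft / 2) + 1)
  tibble(freq_hz = (half - 1) * fs / nfft, power = p[half])
}

# in-band peak candidates (local maxima) sorted by power, plus the
# peak-to-total ratio of the global in-band peak (power within +/-2 bpm of
# the peak over total in-band power)
spectral_peaks <- function(spec, band_hz) {
  inb <- spec$freq_hz >= band_hz[1] & spec$freq_hz <= band_hz[2]
  s <- spec[inb, ]
  if (nrow(s) < 3 || sum(s$power) <= 0) {
    return(list(peaks = tibble(freq_hz = numeric(0), power = numeric(0)), ratio = 0))
  }
  p <- s$power
  loc <- which(p > c(-Inf, head(p, -1)) & p >= c(tail(p, -1), Inf))
  peaks <- s[loc, ]
  peaks <- peaks[order(-peaks$power), ]
  top <- peaks$freq_hz[1]
  near <- abs(s$freq_hz - top) <= 2 / 60
  list(peaks = peaks, ratio = sum(s$power[near]) / sum(s$power))
}

# estimate for one window; prev_bpm is the last *accepted* estimate or NA
hr_one_window <- function(trace, window_start_s, window_end_s, cfg, prev_bpm) {
  fs <- trace_fps(trace)
  band_hz <- cfg$band_bpm / 60
  no_est <- tibble(window_start_s = window_start_s,
                   bpm = if (is.na(prev_bpm)) NA_real_ else prev_bpm,
                   peak_power_ratio = 0, accepted = FALSE)
  cond <- tryCatch(
    condition_channels(trace, window_start_s, window_end_s),
    remoteaffect_degenerate_signal = function(e) NULL)
  if (is.null(cond)) return(no_est)
  S <- fast_ica(as.matrix(cond[c("r", "g", "b")]), n_comp = 3, seed = cfg$seed)
  cand <- lapply(seq_len(ncol(S)), function(j) {
    sp <- power_spectrum(S[, j], fs, cfg$max_bin_bpm / 60)
    spectral_peaks(sp, band_hz)
  })
  ratios <- vapply(cand, function(cc) cc$ratio, numeric(1))
  best <- which.max(ratios)
  if (ratios[best] < cfg$min_peak_ratio) return(no_est)
  peaks <- cand[[best]]$peaks
  bpm <- 60 * peaks$freq_hz[1]
  accepted <- TRUE
  if (!is.na(prev_bpm) && abs(bpm - prev_bpm) > cfg$history_bpm) {
    ok <- which(abs(60 * peaks$freq_hz - prev_bpm) <= cfg$history_bpm)
    if (length(ok)) {
      bpm <- 60 * peaks$freq_hz[ok[1]]
    } else {
      bpm <- prev_bpm
      accepted <- FALSE
    }
  }
  tibble(window_start_s = window_start_s, bpm = bpm,
         peak_power_ratio = ratios[best], accepted = accepted)
}

#' Per-window heart-rate estimates from an RGB trace (feature F8)
#'
#' For each analysis window the three channels are detrended and
#' z-normalised, separated into three independent components with seeded
#' FastICA, and each component's Hamming-windowed, zero-padded power
#' spectrum (bin spacing at most 1 bpm) is searched in the physiological
#' band (default 45-240 bpm). The component with the largest in-band
#' peak-to-total power ratio wins and its peak frequency times 60 is the
#' bpm estimate. A history constraint suppresses physiologically
#' implausible jumps: if an estimate differs from the previous accepted
#' one by more than `history_bpm`, the next-highest in-band peak within
#' range is used instead, or the previous value is carried forward with
#' `accepted = FALSE`. Windows with no usable estimate and no history
#' yield `NA` (callers drop such leading windows).
#'
#' @param trace An [rgb_trace()] tibble.
#' @param windows Window tibble from [analysis_windows()].
#' @param cfg An [rppg_config()].
#' @return A tibble with one row per window: `window_start_s`, `bpm`,
#'   `peak_power_ratio`, `accepted`.
#' @export
estimate_hr <- function(trace, windows, cfg = rppg_config()) {
  prev <- NA_real_
  out <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    est <- hr_one_window(trace, windows$window_start_s[i],
                         windows$window_end_s[i], cfg, prev)
    if (est$accepted) prev <- est$bpm
    out[[i]] <- est
  }
  bind_rows(out)
}

#' Per-window mean of 1 Hz sensor heart rate (feature F9)
#'
#' The sensor-based counterpart of the rPPG estimate: the mean of all
#' sensor samples whose timestamps fall inside each window. No rPPG
#' machinery is involved.
#'
#' @param sensor A tibble with columns `t` (seconds) and `bpm`.
#' @param windows Window tibble from [analysis_windows()].
#' @return A tibble with columns `window_start_s`, `F9`.
#' @export
sensor_hr_feature <- function(sensor, windows) {
  purrr::pmap_dfr(
    windows[c("window_start_s", "window_end_s")],
    function(window_start_s, window_end_s) {
      inside <- sensor$t >= window_start_s - 1e-9 & sensor$t < window_end_s - 1e-9
      tibble(window_start_s = window_start_s,
             F9 = if (any(inside)) mean(sensor$bpm[inside]) else NA_real_)
    })
}
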