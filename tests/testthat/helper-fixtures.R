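# Shared fixtures built in code.

# a frame with every point at `at`
coincident_frame <- function(at = c(0, 0)) {
  matrix(rep(at, each = 68), 68, 2)
}

# template frame with selected 0-based points replaced
frame_with <- function(points0, coords, base = face_template()) {
  base[points0 + 1, ] <- coords
  base
}

# landmark track from a function i -> 68x2 matrix
track_from <- function(n, fps, frame_fun) {
  pts <- array(0, dim = c(n, 68, 2))
  for (i in seq_len(n)) pts[i, , ] <- frame_fun(i)
  landmark_track((seq_len(n) - 1) / fps, pts, fps = fps)
}

# trace with identical pulse on all channels plus optional noise
pulse_trace <- function(freq_hz, dur_s = 60, fps = 50, noise = 0.05,
                        amp = c(0.3, 1, 0.6), seed = 1) {
  t <- seq(0, dur_s - 1 / fps, by = 1 / fps)
  s <- sin(2 * pi * freq_hz * t)
  set.seed(seed)
  rgb_trace(t,
            120 + amp[1] * s + rnorm(length(t), 0, noise),
            100 + amp[2] * s + rnorm(length(t), 0, noise),
            80 + amp[3] * s + rnorm(length(t), 0, noise), fps = fps)
}

# reduced-scale model search used by pipeline-level tests; the method
# (3x10-fold stratified CV on AUC, random search) is unchanged
desk_model_config <- function(seed = 1L) {
  model_config(iterations = 4, hidden_sizes = c(2, 4, 8), maxit = 150,
               seed = seed)
}

desk_pipeline_config <- function(seed = 1L) {
  pipeline_config(model = desk_model_config(seed))
}

# well-separated two-cluster training set
separable_samples <- function(n_per_class = 40, sep = 10, seed = 1,
                              features = c("F1", "F2")) {
  set.seed(seed)
  n <- 2 * n_per_class
  lab <- factor(rep(c("boredom", "stress"), each = n_per_class),
                levels = c("boredom", "stress"))
  d <- tibble::as_tibble(setNames(
    lapply(seq_along(features), function(j) {
      rnorm(n) + ifelse(lab == "stress", sep, 0)
    }), features))
  d$label <- lab
  d
}
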