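# Programmatic fixtures: hand-built layouts, trial specs, policies and gaze
# streams used across the test files.

# A layout with fully controlled geometry (bypasses the random generator).
fixture_layout <- function(length_px = 9000L, obstacles = NULL,
                           drift = NULL, difficulty = "easy",
                           id = "fixture") {
  if (is.null(obstacles)) obstacles <- data.frame(x = integer(0), y = integer(0))
  if (is.null(drift)) {
    drift <- data.frame(y_start = integer(0), span_px = integer(0),
                        direction = character(0), bar_offset_px = integer(0),
                        bar_width_px = integer(0))
  } else {
    drift$span_px <- 270L; drift$bar_offset_px <- 45L; drift$bar_width_px <- 18L
  }
  structure(list(id = id, length_px = as.integer(length_px), width_px = 720L,
                 difficulty = difficulty, obstacles = obstacles,
                 drift_sections = drift, training = FALSE, seed = 0L),
            class = "dodge_layout")
}

fixture_spec <- function(layout, noise_sd = 0, drift_enabled = FALSE,
                         block = "none", types = NULL) {
  n_sec <- nrow(layout$drift_sections)
  if (is.null(types)) types <- rep(if (drift_enabled) "normal" else "off", n_sec)
  sp <- dodgegaze:::new_trialspec(layout$id, 1L, noise_sd, drift_enabled,
                                  block, types)
  sp$spec_id <- "fx01"
  sp
}

# Policy that always presses one key (drives the ship into a wall).
constant_policy <- function(key) {
  structure(list(name = paste0("always_", key), params = list(),
                 fn = function(state, layout, params) key),
            class = "dodge_policy")
}

# Binocular stream from a shared (cyclopean) path: both eyes follow the
# path with a fixed vergence offset; validity flags default to all valid.
fixture_stream <- function(xs, ys, vergence = 6, vl = TRUE, vr = TRUE) {
  n <- length(xs)
  data.frame(t = (seq_len(n) - 1) / 2000,
             lx = xs - vergence / 2, ly = ys,
             rx = xs + vergence / 2, ry = ys,
             vl = rep_len(vl, n), vr = rep_len(vr, n))
}

# Stream with one stable run of `run_len` samples (0.3-px steps) flanked by
# `flank` large jumps (8 px per sample) on each side.
fixture_run_stream <- function(run_len, flank = 10L) {
  steps <- c(rep(8, flank), rep(0.3, run_len - 1L), rep(8, flank))
  xs <- 500 + cumsum(c(0, steps))
  fixture_stream(xs, rep(400, length(xs)))
}

# Random-walk stream with mixed step sizes (exercises arbitrary run
# structure); occasionally drops one eye's validity.
fixture_random_stream <- function(n, seed) {
  set.seed(seed)
  mags <- sample(c(0.2, 0.6, 1.0, 1.2, 1.3, 2.5, 8), n - 1, replace = TRUE,
                 prob = c(.35, .2, .15, .1, .05, .05, .1))
  ang <- runif(n - 1, 0, 2 * pi)
  xs <- 500 + cumsum(c(0, mags * cos(ang)))
  ys <- 400 + cumsum(c(0, mags * sin(ang)))
  st <- fixture_stream(xs, ys)
  if (runif(1) < 0.5) {
    drop <- sample(n, max(1, n %/% 10))
    if (runif(1) < 0.5) st$vl[drop] <- FALSE else st$vr[drop] <- FALSE
  }
  st
}
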