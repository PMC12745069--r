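lay_g <- generate_layout(9000, "medium", seed = 20)
spec_g <- fixture_spec(lay_g, noise_sd = 3)
log_g <- run_trial(spec_g, lay_g, greedy_gap_policy(), seed = 20)

test_that("noiseless synthesis round-trips through the detector exactly", {
  gp <- gaze_params(1, intra_fixation_jitter_px = 0, dropout_rate = 0)
  g <- synth_trial_gaze(log_g, gp, 0, seed = 21)
  ev <- attr(g, "events")
  fx <- detect_fixations(g)
  expect_equal(nrow(fx), nrow(ev))
  expect_equal(fx$onset_t, ev$onset_t)
  expect_equal(fx$onset_x, ev$onset_x)
  expect_equal(fx$onset_y, ev$onset_y)
})

test_that("gaze streams sit on a strict 0.5-ms grid and are seed-reproducible", {
  g1 <- synth_trial_gaze(log_g, gaze_params(1), 0.1, seed = 22)
  g2 <- synth_trial_gaze(log_g, gaze_params(1), 0.1, seed = 22)
  expect_identical(g1, g2)
  expect_equal(g1$t, (seq_len(nrow(g1)) - 1) * 5e-4)
  g3 <- synth_trial_gaze(log_g, gaze_params(1), 0.1, seed = 23)
  expect_false(identical(g1$lx, g3$lx))
})

test_that("a degenerate mixture weight keeps all fixations in one class", {
  gp <- gaze_params(1, p_distant = 0, close_sd = 0.4,
                    intra_fixation_jitter_px = 0, dropout_rate = 0)
  g <- synth_trial_gaze(log_g, gp, 0, seed = 24)
  fx <- detect_fixations(g)
  rows <- dodgegaze:::trial_fixation_rows(fx, log_g, lay_g)
  # all distances stay below the Close/Distant boundary region
  expect_true(all(rows$dist_to_ship_deg < 5.5))
})

test_that("single-eye dropout leaves every fixation recoverable", {
  gp <- gaze_params(1, dropout_rate = 1, intra_fixation_jitter_px = 0)
  g <- synth_trial_gaze(log_g, gp, 0, seed = 25)
  ev <- attr(g, "events")
  expect_true(all(ev$dropout_eye %in% 1:2))       # one eye lost per fixation
  expect_false(any(!g$vl & !g$vr))                # never both
  fx <- detect_fixations(g)
  expect_equal(nrow(fx), nrow(ev))
  expect_equal(fx$onset_t, ev$onset_t)
})

test_that("trials shorter than one minimal fixation yield an empty stream", {
  short <- log_g
  short$n_frames <- 0L
  expect_warning(g <- synth_trial_gaze(short, gaze_params(1), 0, seed = 1),
                 "shorter")
  expect_equal(nrow(g), 0L)
})

test_that("planned saccades exceed the minimum amplitude", {
  gp <- gaze_params(1, intra_fixation_jitter_px = 0, dropout_rate = 0)
  g <- synth_trial_gaze(log_g, gp, 0, seed = 26)
  ev <- attr(g, "events")
  # each saccade runs from the previous fixation's (pursuit-drifted) end
  # point to the next onset
  scroll <- -360  # px/s on screen
  end_x <- ev$onset_x
  end_y <- ev$onset_y + scroll * (ev$n_samples - 1) / 2000
  n <- nrow(ev)
  amp <- sqrt((ev$onset_x[-1] - end_x[-n])^2 + (ev$onset_y[-1] - end_y[-n])^2)
  expect_true(all(px_to_deg(amp) >= 0.5))
})

test_that("judgments follow the latent model, clipped to the 1-7 scale", {
  trials <- data.frame(
    completed = c(TRUE, FALSE), difficulty = c("easy", "hard"),
    noise_sd = c(0, 6), drift_enabled = c(FALSE, TRUE),
    block = c("none", "none"), n_fixations = c(50L, 50L),
    consecutive_crash_completions = c(0L, 2L)
  )
  jp <- joc_params(1, residual_sd = 0)
  j <- synth_joc(trials, jp, 0, seed = 1)
  expect_true(all(j >= 1 & j <= 7))
  expect_gt(j[1], j[2])   # completion and easy difficulty raise the rating
  # zero effects: mean equals the intercept
  jp0 <- joc_params(1, completion = 0, difficulty = c(easy = 0, medium = 0, hard = 0),
                    noise = c("0" = 0, "3" = 0, "6" = 0), n_fixations = 0,
                    crash_completion = 0, residual_sd = 0.01)
  many <- trials[rep(1, 200), ]
  expect_equal(mean(synth_joc(many, jp0, 0, seed = 2)), jp0$intercept,
               tolerance = 0.2)
  # extreme negative latent clips to 1
  jneg <- synth_joc(trials, joc_params(1, intercept = -50), 0, seed = 3)
  expect_true(all(jneg == 1))
  jpos <- synth_joc(trials, joc_params(1, intercept = 50), 0, seed = 4)
  expect_true(all(jpos == 7))
})

test_that("cohort bundles are reproducible and carry matching manifests", {
  spec <- cohort_spec(2, 2, seed = 31, max_trials_per_session = 6)
  a <- make_cohort(spec)
  b <- make_cohort(spec)
  expect_identical(a$manifest$fixation_hash, b$manifest$fixation_hash)
  expect_identical(a$manifest$trial_hash, b$manifest$trial_hash)
  expect_equal(a$fixations, b$fixations)
  # a different seed changes the data
  c <- make_cohort(cohort_spec(2, 2, seed = 32, max_trials_per_session = 6))
  expect_false(identical(a$manifest$fixation_hash, c$manifest$fixation_hash))
})

test_that("cohort bundles write layouts, tables and manifest to disk", {
  dir <- tempfile("cohort")
  spec <- cohort_spec(2, 2, seed = 33, max_trials_per_session = 4)
  out <- make_cohort(spec, dir = dir, write_gaze = TRUE)
  expect_true(file.exists(file.path(dir, "fixations.csv")))
  expect_true(file.exists(file.path(dir, "trials.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  expect_length(list.files(dir, pattern = "^layout_.*json$"), 6L)
  gz <- list.files(file.path(dir, "gaze"), pattern = "csv$", full.names = TRUE)
  expect_gt(length(gz), 0L)
  g <- utils::read.csv(gz[1])
  expect_identical(names(g), c("t", "lx", "ly", "rx", "ry", "vl", "vr"))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$n_fixations, nrow(out$fixations))
  unlink(dir, recursive = TRUE)
})
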