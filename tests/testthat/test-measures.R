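test_that("distance to the ship is measured from the sprite center", {
  smap <- screen_map()
  expect_equal(distance_to_ship(smap$ship_center_x, smap$ship_center_y), 0)
  expect_equal(distance_to_ship(smap$ship_center_x + 125, smap$ship_center_y),
               125 * 0.026 / 1.25)   # 2.6 degrees
})

test_that("closest-obstacle distance is the argmin over on-screen centers", {
  vis <- data.frame(screen_x = c(1072 - 18, 1272 - 18),
                    screen_y = c(288 - 18, 288 - 18))
  d <- distance_to_closest_obstacle(972, 288, vis)
  expect_equal(d, px_to_deg(100))
  expect_true(is.na(distance_to_closest_obstacle(972, 288, vis[0, ])))
  # obstacle centered exactly at the onset point
  at <- data.frame(screen_x = 972 - 18, screen_y = 288 - 18)
  expect_equal(distance_to_closest_obstacle(972, 288, at), 0)
  # randomized scenes: equality with brute-force min over all pairs
  set.seed(12)
  for (k in 1:20) {
    vis <- data.frame(screen_x = runif(15, 0, 1800), screen_y = runif(15, 0, 900))
    p <- c(runif(1, 0, 1900), runif(1, 0, 800))
    want <- px_to_deg(sqrt(min((p[1] - vis$screen_x - 18)^2 +
                               (p[2] - vis$screen_y - 18)^2)))
    expect_equal(distance_to_closest_obstacle(p[1], p[2], vis), want)
  }
})

test_that("consecutive crash-completions count crash-then-complete pairs", {
  expect_equal(consecutive_crash_completions(character(0)), 0L)
  expect_equal(consecutive_crash_completions(c("completed", "completed")), 0L)
  expect_equal(consecutive_crash_completions(
    c("crashed", "completed", "crashed", "completed")), 2L)
  expect_equal(consecutive_crash_completions(
    c("crashed", "crashed", "completed")), 1L)
  expect_equal(consecutive_crash_completions(c("completed", "crashed")), 0L)
})

test_that("fixation rows carry the onset frame's logged covariates", {
  lay <- generate_layout(9000, "medium", seed = 14)
  spec <- fixture_spec(lay)
  tl <- run_trial(spec, lay, greedy_gap_policy(), seed = 14)
  g <- synth_trial_gaze(tl, gaze_params(1, intra_fixation_jitter_px = 0,
                                        dropout_rate = 0), 0, seed = 14)
  fx <- detect_fixations(g)
  rows <- dodgegaze:::trial_fixation_rows(fx, tl, lay)
  expect_equal(rows$n_obstacles_on_screen,
               tl$frames$n_obstacles_on_screen[rows$onset_frame + 1])
  # measured distance equals the generated distance (noiseless round trip)
  ev <- attr(g, "events")
  gen <- ev[ev$onset_frame %in% rows$onset_frame &
              tl$frames$phase[ev$onset_frame + 1] == "control", ]
  expect_equal(rows$dist_to_ship_deg,
               gen$dist_deg[match(rows$onset_frame, gen$onset_frame)],
               tolerance = 1e-8)
})

test_that("entry-phase fixations are excluded from the tables", {
  lay <- fixture_layout()
  spec <- fixture_spec(lay)
  tl <- run_trial(spec, lay, null_policy(), seed = 2)
  g <- synth_trial_gaze(tl, gaze_params(1, intra_fixation_jitter_px = 0,
                                        dropout_rate = 0), 0, seed = 2)
  fx <- detect_fixations(g)
  rows <- dodgegaze:::trial_fixation_rows(fx, tl, lay)
  expect_true(all(tl$frames$phase[rows$onset_frame + 1] == "control"))
  expect_lt(nrow(rows), nrow(fx))   # the entry-phase fixation(s) dropped
})

test_that("an able player's Experiment-2 session yields 30 trial rows", {
  lays <- make_experiment_layouts(2, 15)
  for (nm in names(lays)) lays[[nm]]$obstacles <- data.frame(x = integer(0),
                                                             y = integer(0))
  session <- run_session(2, null_policy(), seed = 15, layouts = lays,
                         include_training = FALSE)
  events <- list()
  gp <- gaze_params(2, intra_fixation_jitter_px = 0, dropout_rate = 0)
  for (i in seq_along(session$logs)) {
    g <- synth_trial_gaze(session$logs[[i]], gp, 0, seed = 100 + i)
    events[[as.character(i)]] <- detect_fixations(g)
  }
  tabs <- build_tables(events, session, participant = "p01")
  expect_equal(nrow(tabs$trials), 30L)
  expect_true(all(tabs$trials$completed))
  # every fixation row's trial exists in the trial table
  expect_true(all(tabs$fixations$trial %in% tabs$trials$trial))
  # trial fixation counts add up
  cnt <- table(tabs$fixations$trial)
  expect_equal(unname(tabs$trials$n_fixations[match(names(cnt), tabs$trials$trial)]),
               as.integer(cnt))
})
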