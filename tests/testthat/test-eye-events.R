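test_that("pixel/degree conversion uses the printed equivalence", {
  expect_equal(px_to_deg(1.25), 0.026)
  expect_equal(px_to_deg(0), 0)
  expect_equal(deg_to_px(px_to_deg(7.3)), 7.3, tolerance = 1e-12)
  expect_error(px_to_deg(-1), "nonnegative")
  expect_error(deg_to_px(-0.1), "nonnegative")
})

test_that("cyclopean combination averages, falls back, and drops samples", {
  g <- data.frame(t = c(0, 0.0005, 0.001),
                  lx = c(0, 0, 1), ly = c(0, 0, 1),
                  rx = c(10, 10, 2), ry = c(0, 0, 2),
                  vl = c(TRUE, FALSE, FALSE), vr = c(TRUE, TRUE, FALSE))
  out <- combine_eyes(g)
  expect_equal(nrow(out), 2L)                       # both-invalid dropped
  expect_equal(out$x, c(5, 10))
  expect_identical(out$source, c("both", "right_only"))
  expect_equal(nrow(combine_eyes(g[0, ])), 0L)
})

test_that("fixation annotation requires 25 consecutive sub-threshold samples", {
  expect_equal(nrow(detect_fixations(fixture_run_stream(30))), 1L)
  expect_equal(nrow(detect_fixations(fixture_run_stream(24))), 0L)
  expect_equal(nrow(detect_fixations(fixture_run_stream(25))), 1L)
  fx <- detect_fixations(fixture_run_stream(40))
  expect_equal(fx$n_samples, 40L)
  expect_equal(fx$duration, 40 / 2000)
})

test_that("single-eye stretches are annotated from the surviving eye", {
  st <- fixture_run_stream(30)
  st$vl <- FALSE                                   # left eye lost throughout
  fx <- detect_fixations(st)
  expect_equal(nrow(fx), 1L)
  # onset position equals the right eye's position (fallback rule)
  expect_equal(fx$onset_x, st$rx[11])
})

test_that("detector output is invariant to uniform translation", {
  st <- fixture_random_stream(200, seed = 8)
  shifted <- st
  shifted[c("lx", "rx")] <- shifted[c("lx", "rx")] + 123
  shifted[c("ly", "ry")] <- shifted[c("ly", "ry")] - 57
  a <- detect_fixations(st); b <- detect_fixations(shifted)
  expect_equal(a$onset_t, b$onset_t)
  expect_equal(a$n_samples, b$n_samples)
  expect_equal(b$onset_x, a$onset_x + 123)
})

test_that("fixation detection equals the brute-force maximal-run scan", {
  for (seed in 1:300) {
    st <- fixture_random_stream(sample(60:140, 1), seed = seed)
    got <- detect_fixations(st)
    want <- oracle_fixation_scan(st)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$onset_t, st$t[want$onset])
      expect_equal(got$offset_t, st$t[want$offset])
    }
  }
})

test_that("saccade verification needs both eyes fast, 4 samples and 0.5 deg", {
  # stationary stream with one 1-degree (48-px) jump spread over 6 samples
  jump <- function(amp_px, n_jump = 6L) {
    xs <- c(rep(500, 200), 500 + amp_px * seq_len(n_jump) / n_jump,
            rep(500 + amp_px, 200))
    st <- fixture_stream(xs, rep(400, length(xs)))
    st$lx <- st$lx + rnorm(length(xs), 0, 0.05)   # tiny tremor for a finite
    st$rx <- st$rx + rnorm(length(xs), 0, 0.05)   # velocity spread estimate
    st$ly <- st$ly + rnorm(length(xs), 0, 0.05)
    st$ry <- st$ry + rnorm(length(xs), 0, 0.05)
    st
  }
  set.seed(21)
  expect_equal(nrow(detect_saccades(jump(deg_to_px(1)))), 1L)
  expect_equal(nrow(detect_saccades(jump(deg_to_px(0.4)))), 0L)
  expect_equal(nrow(detect_saccades(jump(deg_to_px(1)),
                                    saccade_params(lambda = 1e9))), 0L)
  expect_warning(detect_saccades(jump(deg_to_px(1))[1:3, ]), "shorter")
})

test_that("saccade samples are excluded from fixation runs", {
  set.seed(22)
  xs <- c(rep(500, 100), 500 + deg_to_px(1) * seq_len(6) / 6,
          rep(500 + deg_to_px(1), 100))
  st <- fixture_stream(xs, rep(400, length(xs)))
  for (cc in c("lx", "ly", "rx", "ry")) st[[cc]] <- st[[cc]] + rnorm(nrow(st), 0, 0.05)
  ev <- annotate_events(st)
  expect_equal(nrow(ev$saccades), 1L)
  expect_equal(nrow(ev$fixations), 2L)
  # no overlap between any fixation and the saccade interval
  for (i in seq_len(nrow(ev$fixations))) {
    expect_true(ev$fixations$offset_t[i] < ev$saccades$onset_t[1] ||
                ev$fixations$onset_t[i] > ev$saccades$offset_t[1])
  }
})

test_that("onset frames floor onset time against the 60-FPS clock", {
  expect_equal(assign_onset_frame(0.5, 60), 30L)
  expect_equal(assign_onset_frame(1 / 60 - 1e-9, 60), 0L)
  expect_error(assign_onset_frame(2.0, 60), "outside")
  expect_error(assign_onset_frame(-0.1, 60), "outside")
  # brute-force nearest-preceding-frame search
  set.seed(30)
  ts <- runif(200, 0, 0.99)
  frames <- assign_onset_frame(ts, 60)
  want <- vapply(ts, function(t) max(which(seq(0, 59) / 60 <= t)) - 1L, 0L)
  expect_equal(frames, want)
})
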