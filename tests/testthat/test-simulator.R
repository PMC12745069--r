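lay0 <- fixture_layout()                       # empty 9000-px corridor
spec0 <- fixture_spec(lay0)

test_that("free fall advances 6 px per frame with no horizontal motion", {
  st <- step_ship(ship_state(y = 100), "none", spec0, lay0)
  expect_equal(st$y - 100, 6)
  expect_equal(attr(st, "dx"), 0)
})

test_that("keyed steps are exact at zero noise and signed by direction", {
  st <- ship_state(y = 100)
  expect_equal(attr(step_ship(st, "right", spec0, lay0), "dx"), 6)
  expect_equal(attr(step_ship(st, "left", spec0, lay0), "dx"), -6)
})

test_that("stepping a dead ship errors", {
  dead <- ship_state(alive = FALSE)
  expect_error(step_ship(dead, "none", spec0, lay0), "dead")
})

test_that("noisy steps follow Normal(6, sd) (Monte-Carlo)", {
  layn <- fixture_layout()
  specn <- fixture_spec(layn, noise_sd = 6)
  st <- ship_state(y = 100)
  dx <- with_seed(99, vapply(seq_len(1e5), function(i) {
    attr(step_ship(st, "right", specn, layn), "dx")
  }, 0))
  expect_equal(mean(dx), 6, tolerance = 0.02)
  expect_equal(sd(dx), 6, tolerance = 0.02)
})

test_that("drift pushes 3 px in the section direction while inside it", {
  layd <- fixture_layout(drift = data.frame(y_start = 600L, direction = "right"))
  specd <- fixture_spec(layd, drift_enabled = TRUE)
  inside <- step_ship(ship_state(y = 600), "none", specd, layd)
  expect_equal(attr(inside, "dx"), 3)
  expect_true(attr(inside, "drift_active"))
  outside <- step_ship(ship_state(y = 300), "none", specd, layd)
  expect_equal(attr(outside, "dx"), 0)
  # left-pushing section, and disabled drift
  layl <- fixture_layout(drift = data.frame(y_start = 600L, direction = "left"))
  specl <- fixture_spec(layl, drift_enabled = TRUE)
  expect_equal(attr(step_ship(ship_state(y = 600), "none", specl, layl), "dx"), -3)
  spec_off <- fixture_spec(layd, drift_enabled = FALSE)
  expect_equal(attr(step_ship(ship_state(y = 600), "none", spec_off, layd), "dx"), 0)
  # fake sections show a bar but exert no force
  spec_fake <- fixture_spec(layd, drift_enabled = TRUE, types = "fake")
  expect_equal(attr(step_ship(ship_state(y = 600), "none", spec_fake, layd), "dx"), 0)
  # invisible sections exert force without a bar
  spec_inv <- fixture_spec(layd, drift_enabled = TRUE, types = "invisible")
  expect_equal(attr(step_ship(ship_state(y = 600), "none", spec_inv, layd), "dx"), 3)
})

test_that("a full uncontrolled drift-section traversal displaces exactly 135 px", {
  # closed form: 270-px span / 6 px per frame = 45 frames x 3 px
  layd <- fixture_layout(drift = data.frame(y_start = 1203L, direction = "right"))
  specd <- fixture_spec(layd, drift_enabled = TRUE)
  tl <- run_trial(specd, layd, null_policy(), seed = 1)
  expect_equal(sum(tl$frames$dx), 270 / 6 * 3)
  expect_equal(sum(tl$frames$drift_active), 45)
})

test_that("collision uses half-open 36-px boxes and walls", {
  lay <- fixture_layout(obstacles = data.frame(x = 200L, y = 200L))
  expect_false(check_collision(ship_state(x = 100, y = 100), lay))
  lay2 <- fixture_layout(obstacles = data.frame(x = 135L, y = 135L))
  expect_true(check_collision(ship_state(x = 100, y = 100), lay2))
  expect_true(check_collision(ship_state(x = -1, y = 100), lay0))
  expect_true(check_collision(ship_state(x = 720 - 36 + 1, y = 100), lay0))
  # abutting sprites do not collide
  lay3 <- fixture_layout(obstacles = data.frame(x = 136L, y = 100L))
  expect_false(check_collision(ship_state(x = 100, y = 100), lay3))
})

test_that("collision agrees with a rasterized overlap oracle", {
  set.seed(5)
  for (k in 1:40) {
    sx <- runif(1, 80, 200); sy <- runif(1, 80, 200)
    ox <- floor(runif(1, 50, 250)); oy <- floor(runif(1, 50, 250))
    lay <- fixture_layout(obstacles = data.frame(x = ox, y = oy))
    got <- check_collision(ship_state(x = floor(sx), y = floor(sy)), lay)
    want <- oracle_boxes_overlap(floor(sx), floor(sy), ox, oy)
    expect_identical(got, want)
  }
})

test_that("visibility window is the top 810 px of the screen", {
  lay <- fixture_layout(obstacles = data.frame(x = c(342L, 342L), y = c(1400L, 1900L)))
  st <- ship_state(x = 342, y = 1000)
  vis <- visible_objects(st, lay)
  # +400 px ahead: screen y 270+400 = 670 < 810 -> visible;
  # +900 px ahead: screen y 1170 -> hidden
  expect_equal(vis$n_obstacles, 1L)
  expect_equal(vis$obstacles$screen_y, 670)
  expect_equal(visible_objects(st, lay0)$n_obstacles, 0L)
  expect_equal(visible_objects(st, lay0)$n_drift_sections, 0L)
})

test_that("object on-screen dwell matches the geometry's closed form", {
  # box [sy, sy+36) intersects [0, 810) while oy - y is in (-306, 540): an
  # 846-px relative span = 141 frames at 6 px/frame (y chosen off the 6-px
  # grid so neither open endpoint lands on a frame)
  lay <- fixture_layout(obstacles = data.frame(x = 100L, y = 3001L))
  spec <- fixture_spec(lay)
  tl <- run_trial(spec, lay, null_policy(), seed = 1)
  expect_equal(sum(tl$frames$n_obstacles_on_screen), (810 + 36) / 6)
})

test_that("null-policy trials complete in length/6 control frames", {
  tl <- run_trial(spec0, lay0, null_policy(), seed = 1)
  expect_equal(tl$outcome, "completed")
  expect_equal(sum(tl$frames$phase == "control"), 9000 / 6)
  expect_equal(sum(tl$frames$phase == "entry"), 45)
})

test_that("trials are deterministic given the seed", {
  lays <- make_experiment_layouts(1, 3)
  specs <- enumerate_configurations(1, lays)
  sp <- Filter(function(s) s$input_noise_sd == 6, specs)[[1]]
  a <- run_trial(sp, lays[[sp$layout_id]], greedy_gap_policy(), seed = 17)
  b <- run_trial(sp, lays[[sp$layout_id]], greedy_gap_policy(), seed = 17)
  expect_identical(a$frames, b$frames)
  expect_identical(a$outcome, b$outcome)
})

test_that("compiled and R reference loops produce identical trials", {
  lays <- make_experiment_layouts(1, 3)
  specs <- enumerate_configurations(1, lays)
  picks <- Filter(function(s) s$input_noise_sd %in% c(0, 6), specs)[c(1, 5, 9)]
  for (sp in picks) {
    f <- run_trial(sp, lays[[sp$layout_id]], greedy_gap_policy(), seed = 31)
    r <- run_trial(sp, lays[[sp$layout_id]], greedy_gap_policy(), seed = 31,
                   use_r = TRUE)
    expect_equal(f$frames, r$frames)
    expect_identical(f$outcome, r$outcome)
  }
})

test_that("with zero noise and no drift, x is the integral of keyed steps", {
  lay <- fixture_layout()
  spec <- fixture_spec(lay)
  tl <- run_trial(spec, lay, constant_policy("right"), seed = 1)
  ctrl <- tl$frames[tl$frames$phase == "control", ]
  expect_true(all(ctrl$dx == 6))
  expect_equal(diff(ctrl$x), rep(6, nrow(ctrl) - 1))
  expect_equal(tl$outcome, "crashed")   # runs into the right wall
})
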