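test_that("the three experiments enumerate 36/30/36 pairwise-distinct configurations", {
  for (exp in 1:3) {
    specs <- enumerate_configurations(exp, seed = 2)
    expect_length(specs, c(36L, 30L, 36L)[exp])
    keys <- vapply(specs, function(s) {
      paste(s$layout_id, s$input_noise_sd, s$drift_enabled, s$block,
            paste(s$section_types, collapse = ""), sep = "|")
    }, "")
    expect_identical(anyDuplicated(keys), 0L)
  }
})

test_that("experiment designs respect their manipulation sets", {
  s1 <- enumerate_configurations(1, seed = 1)
  expect_setequal(unique(vapply(s1, `[[`, 0, "input_noise_sd")), c(0, 3, 6))
  s2 <- enumerate_configurations(2, seed = 1)
  expect_setequal(unique(vapply(s2, `[[`, 0, "input_noise_sd")), c(0, 3, 6, 9, 12))
  expect_false(any(vapply(s2, `[[`, NA, "drift_enabled")))
  s3 <- enumerate_configurations(3, seed = 1)
  expect_true(all(vapply(s3, `[[`, 0, "input_noise_sd") == 0))
  expect_setequal(unique(vapply(s3, `[[`, "", "block")),
                  c("normal", "invisible", "fake"))
})

test_that("Experiment-3 assignments are complementary halves of the sections", {
  lays <- make_experiment_layouts(3, 4)
  specs <- enumerate_configurations(3, lays, 4)
  for (lid in names(lays)) for (blk in c("normal", "invisible", "fake")) {
    pair <- Filter(function(s) s$layout_id == lid && s$block == blk, specs)
    expect_length(pair, 2)
    special <- switch(blk, normal = "off", invisible = "invisible", fake = "fake")
    a <- which(pair[[1]]$section_types == special)
    b <- which(pair[[2]]$section_types == special)
    expect_length(a, 4); expect_length(b, 4)
    expect_length(intersect(a, b), 0)
    expect_setequal(c(a, b), 1:8)
  }
})

test_that("a session completes every configuration exactly once with an able player", {
  # obstacle-free layouts: the null player completes all 30 Exp-2 configs
  lays <- make_experiment_layouts(2, 5)
  for (nm in names(lays)) lays[[nm]]$obstacles <- data.frame(x = integer(0),
                                                             y = integer(0))
  s <- run_session(2, null_policy(), seed = 5, layouts = lays,
                   include_training = FALSE)
  st <- session_table(s)
  expect_equal(nrow(st), 30L)
  expect_true(all(st$completed))
  expect_setequal(st$spec_id, sprintf("cfg%02d", 1:30))
})

test_that("an always-crashing player exhausts three attempts per configuration", {
  s <- run_session(1, constant_policy("left"), seed = 6,
                   include_training = FALSE)
  st <- session_table(s)
  expect_equal(nrow(st), 36L * 3L)
  expect_true(all(!st$completed))
  expect_true(all(st$attempt <= 3))
  expect_true(all(table(st$spec_id) == 3L))
})

test_that("Experiment-3 sessions run normal first, then counterbalanced blocks", {
  s <- run_session(3, greedy_gap_policy(), seed = 7, counterbalance = FALSE)
  st <- session_table(s)
  main <- st[!st$training, ]
  expect_identical(rle(main$block)$values, c("normal", "invisible", "fake"))
  s2 <- run_session(3, greedy_gap_policy(), seed = 7, counterbalance = TRUE)
  st2 <- session_table(s2)
  expect_identical(rle(st2$block[!st2$training])$values,
                   c("normal", "fake", "invisible"))
  # training: once before the session and once between each pair of blocks
  expect_equal(sum(rle(st$training)$values), 3L)
})

test_that("sessions are reproducible from the seed", {
  a <- session_table(run_session(1, greedy_gap_policy(), seed = 11))
  b <- session_table(run_session(1, greedy_gap_policy(), seed = 11))
  expect_identical(a, b)
})
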