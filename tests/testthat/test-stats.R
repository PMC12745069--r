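test_that("Box-Cox selection maps the profile maximum to named transforms", {
  set.seed(40)
  expect_equal(boxcox_select(exp(rnorm(400)))$transform, "log")
  expect_equal(boxcox_select(rnorm(400, 10, 1))$transform, "identity")
  expect_equal(boxcox_select(rnorm(400, 5, 0.7)^2)$transform, "sqrt")
  expect_equal(boxcox_select(1 / abs(rnorm(400, 4, 0.6)))$transform, "reciprocal")
  expect_error(boxcox_select(c(1, -2, 3)), "positive")
})

test_that("transform selection is idempotent", {
  set.seed(41)
  y <- rnorm(400, 5, 0.7)^2
  sel <- boxcox_select(y)
  y2 <- apply_response_transform(y, sel$transform)
  expect_equal(boxcox_select(as.numeric(y2))$transform, "identity")
})

test_that("the shift rule moves nonpositive values into the transform domain", {
  y <- c(0, 0.5, 2, 4)
  out <- apply_response_transform(y, "log")
  expect_true(all(is.finite(out)))
  expect_equal(attr(out, "shift"), 0.25)   # half the smallest positive value
  rl <- apply_response_transform(c(0.8, 2, 5), "reciprocal_of_log")
  expect_true(all(is.finite(rl)))
  plain <- apply_response_transform(c(1, 2, 3), "sqrt")
  expect_null(attr(plain, "shift"))
  expect_error(apply_response_transform(1:3, "cube"), "unknown")
})

test_that("successive-difference contrasts compare each level to the previous", {
  m <- successive_difference_contrasts(c("0", "3", "6", "9", "12"))
  expect_equal(dim(m), c(5L, 4L))
  expect_equal(colSums(m), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(successive_difference_contrasts("a"), "two levels")
  # coefficients recover the successive mean differences exactly
  mu <- c(2, 5, 4)
  g <- factor(rep(c("a", "b", "c"), each = 40), levels = c("a", "b", "c"))
  y <- mu[as.integer(g)]
  contrasts(g) <- successive_difference_contrasts(levels(g))
  beta <- coef(lm(y ~ g))
  expect_equal(unname(beta[2]), 3)    # b - a
  expect_equal(unname(beta[3]), -1)   # c - b
  # with two levels the coefficient equals the treatment-coded one
  g2 <- factor(rep(c("a", "b"), each = 30))
  y2 <- c(rep(1, 30), rep(4, 30)) + rnorm(60, 0, 0.1)
  contrasts(g2) <- successive_difference_contrasts(levels(g2))
  b_sdif <- coef(lm(y2 ~ g2))[2]
  b_treat <- coef(lm(y2 ~ factor(rep(c("a", "b"), each = 30))))[2]
  expect_equal(unname(b_sdif), unname(b_treat))
})

test_that("fit_mixed reports ML fits with z-scores and |z| >= 2 flags", {
  tab <- simulate_lmm_table(10, 25, betas = list(intercept = 2, x1 = 0.6,
                                                 x2 = 0, g2 = 0, g3 = 0),
                            seed = 42)
  fit <- fit_mixed(tab, model_spec("y", "x1 + x2"))
  co <- fit$coefficients
  expect_equal(co$z, co$beta / co$se)
  expect_true(co$significant[co$term == "x1"])
  expect_false(co$significant[co$term == "x2"])
  expect_equal(fit$n_obs, 250L)
  expect_s4_class(fit$model, "merMod")
})

test_that("BIC selection prefers the simpler random structure without planted variance", {
  tab <- simulate_lmm_table(10, 30, participant_sd = 0, seed = 43)
  fit <- fit_mixed(tab, model_spec("y", "x1",
    random_candidates = c("(1 | participant)", "(1 + x1 | participant)")))
  expect_identical(fit$random_structure, "(1 | participant)")
  # the intercept variance estimate collapses toward zero
  vc <- as.data.frame(lme4::VarCorr(fit$model))
  expect_lt(vc$sdcor[vc$grp == "participant"], 0.15)
  # with real slope variance the richer structure wins
  tab2 <- simulate_lmm_table(12, 40, seed = 44)
  slope <- rep(rnorm(12, 0, 0.8), each = 40)
  tab2$y <- tab2$y + slope * tab2$x1
  fit2 <- fit_mixed(tab2, model_spec("y", "x1",
    random_candidates = c("(1 | participant)", "(1 + x1 | participant)")))
  expect_identical(fit2$random_structure, "(1 + x1 | participant)")
})

test_that("the parametric bootstrap brackets the estimate and reproduces by seed", {
  tab <- simulate_lmm_table(8, 15, betas = list(intercept = 1, x1 = 0.8,
                                                x2 = 0, g2 = 0, g3 = 0),
                            seed = 45)
  fit <- fit_mixed(tab, model_spec("y", "x1"))
  b1 <- parametric_bootstrap(fit, n_reps = 200, seed = 9)
  co <- b1$coefficients
  expect_true(all(co$ci_low <= co$beta & co$beta <= co$ci_high))
  b2 <- parametric_bootstrap(fit, n_reps = 200, seed = 9)
  expect_identical(b1$coefficients, b2$coefficients)
  expect_equal(b1$boot_failures, 0L)
  # two independent half-size runs agree within Monte-Carlo error
  h1 <- parametric_bootstrap(fit, n_reps = 300, seed = 10)$coefficients
  h2 <- parametric_bootstrap(fit, n_reps = 300, seed = 11)$coefficients
  expect_equal(h1$ci_low, h2$ci_low, tolerance = 0.12)
  expect_equal(h1$ci_high, h2$ci_high, tolerance = 0.12)
})

test_that("highest-density intervals are the shortest covering intervals", {
  set.seed(46)
  x <- c(rnorm(2000), rnorm(50, 8))   # contaminated: HDI hugs the main mass
  ci <- dodgegaze:::hdi_interval(x, 0.95)
  expect_lt(ci[2], 6)
  expect_gt(ci[1], -4)
  q <- quantile(x, c(0.025, 0.975))
  expect_lt(diff(ci), diff(q) + 1e-9)   # never wider than the quantile CI
})

test_that("the proportion-of-Distant model handles degenerate inputs", {
  trials <- data.frame(
    participant = rep(c("p1", "p2", "p3", "p4"), each = 12),
    difficulty = rep(c("medium", "medium", "hard", "hard"), 12),
    drift_enabled = rep(c(TRUE, FALSE), each = 24),
    n_fixations = rep(c(0L, 10L), 24),
    n_distant = rep(c(0L, 10L), 24)
  )
  expect_message(
    expect_warning(fit <- proportion_distant_model(trials), "zero variance"),
    "excluded")
  expect_equal(fit$n_obs, 24L)   # zero-fixation trials dropped
  # proportions lie in [0, 1] by construction
  kept <- trials[trials$n_fixations > 0, ]
  expect_true(all(kept$n_distant / kept$n_fixations >= 0 &
                  kept$n_distant / kept$n_fixations <= 1))
})
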