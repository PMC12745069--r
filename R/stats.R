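# Inference stage: transform selection, mixed models with BIC-selected
# random structures, successive-difference contrasts, the |z| >= 2
# criterion, and parametric-bootstrap highest-density intervals.
#
# Model fitting is delegated to lme4 (maximum likelihood); everything
# around it -- the transform ladder, contrast handling, random-structure
# competition, bootstrap and reporting -- lives here.

#' Select a response transform by Box-Cox profile likelihood
#'
#' Profiles the Box-Cox likelihood of an intercept-only model over a lambda
#' grid and maps the maximizing lambda to the nearest named transform:
#' about -1 to `reciprocal`, about 0 to `log`, about 0.5 to `sqrt`, about 1
#' to `identity`. The `reciprocal_of_log` transform is never selected
#' automatically; it is available as an explicit override in
#' [apply_response_transform()].
#'
#' @param y Positive response values.
#' @param lambda_grid Grid for the profile.
#' @return A list with `transform` (name) and `lambda` (profile maximum).
#' @export
#' @examples
#' boxcox_select(exp(rnorm(200)))$transform  # "log"
boxcox_select <- function(y, lambda_grid = seq(-2, 2, by = 0.05)) {
  if (any(!is.finite(y))) stop("response contains non-finite values")
  if (any(y <= 0)) stop("Box-Cox requires positive responses; shift first")
  df <- data.frame(y = y)
  fit <- stats::lm(y ~ 1, data = df, y = TRUE, qr = TRUE)
  prof <- MASS::boxcox(fit, lambda = lambda_grid, plotit = FALSE)
  lam <- prof$x[which.max(prof$y)]
  transform <-
    if (lam < -0.5) "reciprocal"
    else if (lam < 0.25) "log"
    else if (lam < 0.75) "sqrt"
    else "identity"
  list(transform = transform, lambda = lam)
}

#' Apply a named response transform
#'
#' Nonpositive values (or values <= 1 for `reciprocal_of_log`) are handled
#' by the half-step shift rule: the response is shifted by half the
#' smallest observation above the transform's domain boundary, and the
#' shift is recorded in the `"shift"` attribute.
#'
#' @param y Numeric response.
#' @param transform One of `identity`, `log`, `sqrt`, `reciprocal`,
#'   `reciprocal_of_log`.
#' @return Transformed vector (attribute `"shift"` when a shift was used).
#' @export
apply_response_transform <- function(y, transform) {
  boundary <- switch(transform, identity = -Inf, sqrt = 0, log = 0,
                     reciprocal = 0, reciprocal_of_log = 1,
                     stop("unknown transform ", transform))
  shift <- 0
  if (is.finite(boundary) && any(y <= boundary)) {
    above <- y[y > boundary]
    if (length(above) == 0L) stop("no values inside the transform domain")
    shift <- (min(above) - boundary) / 2 + (boundary - min(y))
    y <- y + shift
  }
  out <- switch(transform,
    identity = y, log = log(y), sqrt = sqrt(y), reciprocal = 1 / y,
    reciprocal_of_log = 1 / log(y))
  if (shift != 0) attr(out, "shift") <- shift
  out
}

#' Successive-difference contrast matrix
#'
#' Factor coding in which coefficient i estimates `level[i+1] - level[i]`
#' (each level compared with the previous one); columns sum to zero.
#'
#' @param levels Character vector of ordered levels (>= 2).
#' @return A contrast matrix with `length(levels) - 1` columns.
#' @export
#' @examples
#' successive_difference_contrasts(c("0", "3", "6", "9", "12"))  # 4 columns
successive_difference_contrasts <- function(levels) {
  n <- length(levels)
  if (n < 2L) stop("need at least two levels")
  m <- MASS::contr.sdif(n)
  dimnames(m) <- list(levels, paste0(levels[-1], "-", levels[-n]))
  m
}

#' Mixed-model specification
#'
#' @param response Response column name.
#' @param fixed Right-hand-side string of fixed terms (never pruned).
#' @param random_candidates Character vector of candidate random-effects
#'   structures compared by BIC (the default ladder starts at a
#'   per-participant random intercept).
#' @param family `"gaussian"` or `"bernoulli"` (`bernoulli` only for
#'   completion).
#' @param transform Response transform name, or `"auto"` for Box-Cox
#'   selection (Gaussian family only).
#' @param contrasts Named list mapping factor columns to
#'   `"treatment"` or `"successive_difference"`.
#' @return A `dodge_modelspec` list.
#' @export
model_spec <- function(response, fixed, random_candidates = "(1 | participant)",
                       family = c("gaussian", "bernoulli"),
                       transform = "identity", contrasts = list()) {
  family <- match.arg(family)
  if (family == "bernoulli" && !identical(transform, "identity")) {
    stop("transforms apply to Gaussian responses only")
  }
  structure(list(response = response, fixed = fixed,
                 random_candidates = random_candidates, family = family,
                 transform = transform, contrasts = contrasts),
            class = "dodge_modelspec")
}

#' Fit a (generalized) linear mixed model
#'
#' Applies the spec's response transform (or selects one by Box-Cox when
#' `transform = "auto"`), sets the requested factor contrasts, fits every
#' candidate random-effects structure by maximum likelihood, keeps the one
#' with the lowest BIC, and reports per-coefficient estimates, standard
#' errors, z-scores and the |z| >= 2 significance flag. Confidence bounds
#' are filled in by [parametric_bootstrap()].
#'
#' @param data Data.frame with the response, fixed covariates and
#'   `participant`.
#' @param spec A `dodge_modelspec`.
#' @return A `dodge_modelresult`: list with `coefficients` (data.frame),
#'   `random_structure`, `bic`, `n_obs`, `family`, `transform`, `model`
#'   (the fitted merMod), `converged`, `messages`.
#' @export
fit_mixed <- function(data, spec) {
  stopifnot(inherits(spec, "dodge_modelspec"))
  data <- as.data.frame(data)
  transform <- spec$transform
  if (spec$family == "gaussian") {
    y <- data[[spec$response]]
    if (identical(transform, "auto")) {
      ypos <- if (any(y <= 0)) y + (min(y[y > 0], Inf) / 2 - min(y, 0)) else y
      transform <- boxcox_select(ypos)$transform
    }
    data$.resp <- as.numeric(apply_response_transform(y, transform))
  } else {
    data$.resp <- as.numeric(data[[spec$response]])
    transform <- "identity"
  }
  for (nm in names(spec$contrasts)) {
    data[[nm]] <- as.factor(data[[nm]])
    stats::contrasts(data[[nm]]) <-
      if (spec$contrasts[[nm]] == "successive_difference") {
        successive_difference_contrasts(levels(data[[nm]]))
      } else {
        stats::contr.treatment(levels(data[[nm]]))
      }
  }
  fits <- list(); msgs <- character(0)
  for (rc in spec$random_candidates) {
    fml <- stats::as.formula(paste(".resp ~", spec$fixed, "+", rc))
    fit <- tryCatch(
      withCallingHandlers(suppressMessages({
        if (spec$family == "gaussian") {
          lme4::lmer(fml, data = data, REML = FALSE)
        } else {
          lme4::glmer(fml, data = data, family = stats::binomial())
        }
      }), warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w)); invokeRestart("muffleWarning")
      }),
      error = function(e) { msgs <<- c(msgs, conditionMessage(e)); NULL }
    )
    if (!is.null(fit)) fits[[rc]] <- fit
  }
  if (length(fits) == 0L) {
    stop("no random-effects candidate converged: ",
         paste(unique(msgs), collapse = "; "))
  }
  bics <- vapply(fits, stats::BIC, 0)
  best <- names(which.min(bics))
  model <- fits[[best]]
  beta <- lme4::fixef(model)
  # a degenerate fit (e.g. zero-variance response, quasi-separation) can
  # make the vcov fall back or fail entirely; report NA rather than error
  V <- tryCatch(
    withCallingHandlers(as.matrix(stats::vcov(model)),
                        warning = function(w) {
                          msgs <<- c(msgs, conditionMessage(w))
                          invokeRestart("muffleWarning")
                        }),
    error = function(e) { msgs <<- c(msgs, conditionMessage(e)); NULL })
  se <- if (is.null(V)) rep(NA_real_, length(beta)) else {
    d <- diag(V)
    ifelse(is.finite(d) & d >= 0, sqrt(d), NA_real_)
  }
  z <- beta / se
  coefs <- data.frame(
    term = names(beta), beta = unname(beta), se = unname(se), z = unname(z),
    significant = !is.na(z) & abs(unname(z)) >= 2,
    ci_low = NA_real_, ci_high = NA_real_
  )
  degenerate <- is.null(V) || anyNA(se)
  structure(list(
    coefficients = coefs, random_structure = best,
    bic = unname(bics[best]), all_bic = bics, n_obs = nrow(data),
    family = spec$family, transform = transform, response = spec$response,
    model = model, vcov = V,
    converged = !degenerate &&
      length(model@optinfo$conv$lme4$messages %||% character(0)) == 0L,
    messages = unique(msgs)
  ), class = "dodge_modelresult")
}

#' @export
print.dodge_modelresult <- function(x, ...) {
  cat(sprintf("<dodge_modelresult> %s (%s), transform=%s, random=%s, BIC=%.1f, n=%d\n",
              x$response, x$family, x$transform, x$random_structure, x$bic, x$n_obs))
  co <- x$coefficients
  co$sig <- ifelse(co$significant, "*", "")
  print(format(co, digits = 3), row.names = FALSE)
  invisible(x)
}

# Shortest interval containing `level` of the draws (highest-density
# interval for a unimodal bootstrap distribution).
hdi_interval <- function(x, level = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  k <- ceiling(level * n)
  if (k >= n) return(c(x[1], x[n]))
  w <- x[k:n] - x[1:(n - k + 1)]
  i <- which.min(w)
  c(x[i], x[i + k - 1])
}

#' Parametric bootstrap confidence intervals
#'
#' Simulates responses from the fitted model, refits, collects the fixed
#' effects, and reports 95% highest-density intervals per coefficient.
#' Replications are split into seeded chunks so results are reproducible
#' regardless of how the chunks are scheduled.
#'
#' @param result A `dodge_modelresult`.
#' @param n_reps Number of replications (10,000 for final inference; tests
#'   and examples use fewer).
#' @param seed Master seed.
#' @param level Interval mass.
#' @param n_chunks Number of independently seeded chunks.
#' @return The `dodge_modelresult` with `ci_low`/`ci_high` filled in,
#'   plus `boot_draws` (matrix) and `boot_failures`.
#' @export
parametric_bootstrap <- function(result, n_reps = 10000L, seed = 1L,
                                 level = 0.95, n_chunks = 10L) {
  stopifnot(inherits(result, "dodge_modelresult"))
  model <- result$model
  beta <- lme4::fixef(model)
  per <- diff(round(seq(0, n_reps, length.out = n_chunks + 1L)))
  draws <- vector("list", n_chunks)
  failures <- 0L
  for (ch in seq_len(n_chunks)) {
    if (per[ch] == 0L) next
    sims <- with_seed(derive_seed(seed, "boot", ch),
                      stats::simulate(model, nsim = per[ch]))
    mat <- matrix(NA_real_, nrow = per[ch], ncol = length(beta))
    for (i in seq_len(per[ch])) {
      ref <- tryCatch(
        suppressWarnings(suppressMessages(lme4::refit(model, sims[[i]]))),
        error = function(e) NULL)
      if (is.null(ref)) { failures <- failures + 1L; next }
      mat[i, ] <- lme4::fixef(ref)
    }
    draws[[ch]] <- mat
  }
  draws <- do.call(rbind, draws)
  colnames(draws) <- names(beta)
  if (failures > 0.01 * n_reps) {
    warning(sprintf("%d of %d bootstrap refits failed", failures, n_reps))
  }
  cis <- t(apply(draws, 2L, hdi_interval, level = level))
  result$coefficients$ci_low <- cis[, 1]
  result$coefficients$ci_high <- cis[, 2]
  result$boot_draws <- draws
  result$boot_failures <- failures
  result
}

#' Model the per-trial proportion of Distant fixations
#'
#' Computes each trial's proportion of Distant fixations and models it with
#' the same mixed-model machinery (Gaussian, identity), by default with the
#' difficulty-by-drift interaction among the fixed effects. Trials without
#' fixations are excluded with a message.
#'
#' @param trials Trial table with `n_fixations` and `n_distant` columns.
#' @param fixed Fixed-effects string.
#' @param random_candidates Random-structure candidates.
#' @return A `dodge_modelresult`.
#' @export
proportion_distant_model <- function(trials,
                                     fixed = "difficulty * drift_enabled",
                                     random_candidates = "(1 | participant)") {
  drop <- trials$n_fixations == 0L
  if (any(drop)) {
    message(sum(drop), " trial(s) without fixations excluded")
    trials <- trials[!drop, , drop = FALSE]
  }
  trials$prop_distant <- trials$n_distant / trials$n_fixations
  if (stats::var(trials$prop_distant) == 0) {
    warning("proportion of Distant fixations has zero variance")
  }
  fit_mixed(trials, model_spec("prop_distant", fixed,
                               random_candidates = random_candidates))
}

#' Simulate a mixed-model table
#'
#' Draws a balanced dataset from a Gaussian random-intercept model:
#' continuous covariates `x1`, `x2` (standard normal), a three-level factor
#' `g`, per-participant intercepts, and i.i.d. residual noise. Used for
#' calibration studies of the inference machinery (type-I error of the
#' |z| >= 2 rule, bootstrap coverage).
#'
#' @param n_participants,n_per_participant Design size.
#' @param betas Named list: `intercept`, `x1`, `x2`, `g2`, `g3`.
#' @param participant_sd,residual_sd Variance components.
#' @param seed Integer seed.
#' @return A data.frame with `participant`, `x1`, `x2`, `g`, `y`.
#' @export
simulate_lmm_table <- function(n_participants = 12L, n_per_participant = 20L,
                               betas = list(intercept = 1, x1 = 0, x2 = 0,
                                            g2 = 0, g3 = 0),
                               participant_sd = 0.5, residual_sd = 1,
                               seed = 1L) {
  n <- n_participants * n_per_participant
  with_seed(seed, {
    pid <- rep(sprintf("p%02d", seq_len(n_participants)), each = n_per_participant)
    b <- rep(stats::rnorm(n_participants, 0, participant_sd),
             each = n_per_participant)
    x1 <- stats::rnorm(n); x2 <- stats::rnorm(n)
    g <- factor(sample(c("g1", "g2", "g3"), n, replace = TRUE),
                levels = c("g1", "g2", "g3"))
    y <- betas$intercept + betas$x1 * x1 + betas$x2 * x2 +
      betas$g2 * (g == "g2") + betas$g3 * (g == "g3") +
      b + stats::rnorm(n, 0, residual_sd)
    data.frame(participant = pid, x1 = x1, x2 = x2, g = g, y = y)
  })
}
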