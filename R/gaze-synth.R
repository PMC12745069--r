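# Synthetic binocular 2000-Hz gaze aligned to a trial log.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: alternating fixations and saccades; fixation onset distances to
# the ship drawn from a two-component (Close/Distant) mixture whose
# component means shift linearly -- on the component's generation scale --
# with the on-screen covariates of the onset frame, the trial's
# manipulation levels, and a per-participant random intercept; smooth
# pursuit of the fixated scene point as the world scrolls (6 px/frame
# upward on screen, 0.18 px/sample, well under the 1.25-px annotation
# threshold); saccades of at least 0.5 deg taking >= 4 samples with
# per-sample steps large enough to break fixation runs; and occasional
# single-eye signal loss.

#' Gaze generation parameters
#'
#' Defaults encode the synthetic study conditions. Close fixations center
#' around 3 deg from the ship, Distant fixations around 8 deg, with the
#' class boundary falling in between (the empirical splits land near
#' 5-5.7 deg). Experiment 2 generates Close distances on the square-root
#' scale (right-skewed distances), exercising the Box-Cox selection stage;
#' the other experiments generate on the identity scale. Effect
#' coefficients are per-unit shifts of the component means on the
#' generation scale: per on-screen obstacle, per on-screen drift section,
#' per input-noise level (named by SD), and per Experiment-3 block.
#'
#' @param experiment 1, 2 or 3 (selects the per-experiment effect defaults).
#' @param ... Named overrides of any default.
#' @return A `dodge_gazeparams` list.
#' @export
gaze_params <- function(experiment = 1, ...) {
  experiment <- as.integer(experiment)
  # level shifts are cumulative successive differences, so e.g. Experiment
  # 1's strong-vs-weak contrast is -0.09
  noise_close <- switch(experiment,
    c("0" = 0, "3" = -0.02, "6" = -0.11),
    # cumulative successive differences on the sqrt scale
    c("0" = 0, "3" = 0.04, "6" = -0.04, "9" = 0.06, "12" = -0.04),
    c("0" = 0))
  p <- list(
    rate_hz = .dodge$rate_hz,
    close_mean = if (experiment == 2L) 1.8 else 3.0,
    close_sd = if (experiment == 2L) 0.30 else 1.0,
    close_transform = if (experiment == 2L) "sqrt" else "identity",
    distant_mean = 8.0, distant_sd = 1.5, distant_transform = "identity",
    p_distant = 0.40,
    fixation_duration = list(mean = 0.45, sd = 0.15, min = 0.10),
    # positional sd per axis and sample; small enough that the chance of a
    # jitter step exceeding the 1.25-px annotation threshold (which would
    # split a fixation run) is negligible over a whole cohort
    intra_fixation_jitter_px = 0.15,
    saccade_min_amp_deg = 0.5,
    vergence_offset_px = 6,
    dropout_rate = 0.02,
    participant_sd = 0.3,
    effects = list(
      close = list(
        obstacles = 0.07, noise = noise_close, drift_sections = 0,
        block = c(normal = 0, invisible = -0.03, fake = -0.02, none = 0)
      ),
      distant = list(
        obstacles = 0.10, noise = noise_close * 0, drift_sections =
          if (experiment == 3L) 0.25 else 0,
        block = c(normal = 0, invisible = 0, fake = 0, none = 0)
      )
    )
  )
  over <- list(...)
  p[names(over)] <- over
  structure(p, class = "dodge_gazeparams")
}

apply_transform <- function(x, transform) {
  switch(transform, identity = x, sqrt = x^2,
         stop("unknown generation transform ", transform))
}

# Linear predictor of a component mean on its generation scale.
component_mean <- function(base, eff, n_obst, n_drift, noise_key, block,
                           participant_intercept) {
  noise_shift <- if (noise_key %in% names(eff$noise)) eff$noise[[noise_key]] else 0
  block_shift <- if (block %in% names(eff$block)) eff$block[[block]] else 0
  base + participant_intercept + eff$obstacles * n_obst +
    eff$drift_sections * n_drift + noise_shift + block_shift
}

#' Synthesize a binocular gaze stream for one trial
#'
#' Plans a sequence of fixations and connecting saccades covering the trial
#' duration, then assembles the 2000-Hz sample stream: each eye follows the
#' fixated point (offset by half the vergence) with smooth pursuit as the
#' world scrolls, plus independent per-sample jitter; saccades are linear
#' interpolations whose per-sample steps exceed the annotation threshold.
#' With zero jitter and zero dropout, the displacement-based detector
#' recovers the generated fixation onsets exactly.
#'
#' @param log A `dodge_triallog`.
#' @param params A `dodge_gazeparams`.
#' @param participant_intercept Per-participant shift of both component
#'   means (generation scale).
#' @param seed Integer seed.
#' @return A gaze stream data.frame (`t, lx, ly, rx, ry, vl, vr`) with the
#'   generated event plan in attribute `"events"`.
#' @export
synth_trial_gaze <- function(log, params = gaze_params(), participant_intercept = 0,
                             seed = 1L) {
  n_total <- floor(log$n_frames * .dodge$rate_hz / .dodge$fps)
  dt <- 1 / .dodge$rate_hz
  if (n_total < 25L) {
    warning("trial shorter than one minimal fixation; empty gaze stream")
    out <- data.frame(t = numeric(0), lx = numeric(0), ly = numeric(0),
                      rx = numeric(0), ry = numeric(0),
                      vl = logical(0), vr = logical(0))
    attr(out, "events") <- data.frame()
    return(out)
  }
  smap <- screen_map()
  noise_key <- as.character(log$spec$input_noise_sd)
  block <- log$spec$block
  scroll <- -(.dodge$fall_px * .dodge$fps)   # screen px/s, upward
  min_gap_px <- deg_to_px(params$saccade_min_amp_deg) * 1.1

  with_seed(seed, {
    # --- event plan ---------------------------------------------------
    ev_start <- integer(0); ev_len <- integer(0); ev_fix <- logical(0)
    ev_ax <- numeric(0); ev_bx <- numeric(0)
    ev_ay <- numeric(0); ev_by <- numeric(0)
    ev_class <- character(0); ev_dist <- numeric(0); ev_drop <- integer(0)
    cursor <- 1L
    prev_end <- c(smap$ship_center_x, smap$ship_center_y)
    while (cursor <= n_total) {
      remaining <- n_total - cursor + 1L
      dur <- max(params$fixation_duration$min,
                 stats::rnorm(1L, params$fixation_duration$mean,
                              params$fixation_duration$sd))
      n_fix <- min(round(dur * params$rate_hz), remaining)
      onset_t <- (cursor - 1L) * dt
      fr0 <- min(floor(onset_t * .dodge$fps), log$n_frames - 1L)
      row <- fr0 + 1L
      n_obst <- log$frames$n_obstacles_on_screen[row]
      n_drift <- log$frames$n_drift_sections_on_screen[row]
      distant <- stats::runif(1L) < params$p_distant
      if (distant) {
        m <- component_mean(params$distant_mean, params$effects$distant,
                            n_obst, n_drift, noise_key, block,
                            participant_intercept)
        val <- stats::rnorm(1L, m, params$distant_sd)
        for (k in 1:20) {
          if (val > 0.3) break
          val <- stats::rnorm(1L, m, params$distant_sd)
        }
        d_deg <- apply_transform(max(val, 0.3), params$distant_transform)
      } else {
        m <- component_mean(params$close_mean, params$effects$close,
                            n_obst, n_drift, noise_key, block,
                            participant_intercept)
        val <- stats::rnorm(1L, m, params$close_sd)
        for (k in 1:20) {
          if (val > 0.2) break
          val <- stats::rnorm(1L, m, params$close_sd)
        }
        d_deg <- apply_transform(max(val, 0.2), params$close_transform)
      }
      r_px <- deg_to_px(d_deg)
      # gaze direction biased toward where the action comes from (below)
      point <- NULL
      for (k in 1:30) {
        phi <- stats::rnorm(1L, 0, 0.9)
        cand <- c(smap$ship_center_x + r_px * sin(phi),
                  smap$ship_center_y + r_px * cos(phi))
        ok <- cand[1] > 5 && cand[1] < smap$screen_w - 5 &&
              cand[2] > 5 && cand[2] < smap$visible_h - 5 &&
              sqrt(sum((cand - prev_end)^2)) >= min_gap_px
        if (ok) { point <- cand; break }
      }
      if (is.null(point)) {
        point <- c(smap$ship_center_x,
                   min(smap$ship_center_y + r_px, smap$visible_h - 5))
        if (sqrt(sum((point - prev_end)^2)) < min_gap_px) {
          point[1] <- point[1] + min_gap_px
        }
      }
      # connecting saccade (not before the first event)
      if (length(ev_start) > 0L) {
        gap <- sqrt(sum((point - prev_end)^2))
        n_sac <- max(4L, ceiling(gap / 4))
        if (n_sac <= n_total - cursor + 1L - 25L) {
          frac <- 1 / (n_sac + 1L)
          ev_start <- c(ev_start, cursor); ev_len <- c(ev_len, n_sac)
          ev_fix <- c(ev_fix, FALSE)
          ev_ax <- c(ev_ax, prev_end[1] + (point[1] - prev_end[1]) * frac)
          ev_bx <- c(ev_bx, (point[1] - prev_end[1]) * params$rate_hz * frac)
          ev_ay <- c(ev_ay, prev_end[2] + (point[2] - prev_end[2]) * frac)
          ev_by <- c(ev_by, (point[2] - prev_end[2]) * params$rate_hz * frac)
          ev_class <- c(ev_class, NA); ev_dist <- c(ev_dist, NA)
          ev_drop <- c(ev_drop, 0L)
          cursor <- cursor + n_sac
        }
      }
      n_fix <- min(n_fix, n_total - cursor + 1L)
      if (n_fix < 25L) {
        # too short to register; extend the previous fixation's span instead
        if (length(ev_start) > 0L && ev_fix[length(ev_fix)]) {
          ev_len[length(ev_len)] <- ev_len[length(ev_len)] + n_fix
        }
        break
      }
      drop <- if (stats::runif(1L) < params$dropout_rate) sample(1:2, 1L) else 0L
      ev_start <- c(ev_start, cursor); ev_len <- c(ev_len, n_fix)
      ev_fix <- c(ev_fix, TRUE)
      ev_ax <- c(ev_ax, point[1]); ev_bx <- c(ev_bx, 0)
      ev_ay <- c(ev_ay, point[2]); ev_by <- c(ev_by, scroll)
      ev_class <- c(ev_class, if (distant) "distant" else "close")
      ev_dist <- c(ev_dist, d_deg); ev_drop <- c(ev_drop, drop)
      prev_end <- c(point[1], point[2] + scroll * (n_fix - 1L) * dt)
      cursor <- cursor + n_fix
    }

    # --- sample assembly (compiled per-sample kernel) ------------------
    out <- fast_df(cpp_assemble_gaze(
      as.integer(ev_len), ev_ax, ev_bx, ev_ay, ev_by, as.integer(ev_drop),
      dt, params$vergence_offset_px / 2, params$intra_fixation_jitter_px))
    t0 <- (ev_start - 1L) * dt
    fix_idx <- which(ev_fix)
    events <- data.frame(
      onset_sample = ev_start[fix_idx],
      onset_t = t0[fix_idx],
      onset_frame = pmin(floor(t0[fix_idx] * .dodge$fps), log$n_frames - 1L),
      onset_x = ev_ax[fix_idx], onset_y = ev_ay[fix_idx],
      n_samples = ev_len[fix_idx],
      class = ev_class[fix_idx],
      dist_deg = ev_dist[fix_idx],
      dropout_eye = ev_drop[fix_idx]
    )
    attr(out, "events") <- events
    out
  })
}

#' Judgment-of-control generation parameters
#'
#' Coefficients of the latent-Gaussian judgment model: the post-trial
#' control rating is a linear function of trial outcome and design
#' covariates plus participant intercept and residual noise, rounded and
#' clipped to the 1-7 response scale.
#'
#' @param experiment 1, 2 or 3.
#' @param ... Named overrides.
#' @return A `dodge_jocparams` list.
#' @export
joc_params <- function(experiment = 1, ...) {
  experiment <- as.integer(experiment)
  noise <- switch(experiment,
    c("0" = 0, "3" = -0.10, "6" = -0.34),
    c("0" = 0, "3" = -0.10, "6" = -0.20, "9" = -1.09, "12" = -1.20),
    c("0" = 0))
  p <- list(
    intercept = 3.4,
    completion = 1.5,
    difficulty = c(easy = 0, medium = -0.20, hard = if (experiment == 1L) -0.44 else -0.19),
    noise = noise,
    drift = 0,
    block = c(none = 0, normal = 0, invisible = -0.69, fake = -0.03),
    n_fixations = 0.0116,
    crash_completion = 0.03,
    residual_sd = 1.0
  )
  if (experiment != 1L) p$difficulty <- c(easy = 0, medium = 0,
                                          hard = unname(p$difficulty["hard"]))
  over <- list(...)
  p[names(over)] <- over
  structure(p, class = "dodge_jocparams")
}

#' Generate judgments of control for a trial table
#'
#' @param trials Trial table (from [build_tables()]) with `completed`,
#'   `difficulty`, `noise_sd`, `drift_enabled`, `block`, `n_fixations`,
#'   `consecutive_crash_completions`.
#' @param params A `dodge_jocparams`.
#' @param participant_intercept Participant shift of the latent mean.
#' @param seed Integer seed.
#' @return Integer vector of ratings in 1..7.
#' @export
synth_joc <- function(trials, params = joc_params(), participant_intercept = 0,
                      seed = 1L) {
  if (nrow(trials) == 0L) return(integer(0))
  latent <- params$intercept + participant_intercept +
    params$completion * trials$completed +
    params$difficulty[trials$difficulty] +
    vapply(as.character(trials$noise_sd),
           function(k) if (k %in% names(params$noise)) params$noise[[k]] else 0, 0) +
    params$drift * trials$drift_enabled +
    params$block[trials$block] +
    params$n_fixations * trials$n_fixations +
    params$crash_completion * trials$consecutive_crash_completions
  latent <- latent + with_seed(seed, stats::rnorm(nrow(trials), 0, params$residual_sd))
  pmin(pmax(round(unname(latent)), 1L), 7L)
}
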