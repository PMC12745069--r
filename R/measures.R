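# Per-fixation distance measures and per-trial covariates.

#' Distance from a fixation onset to the ship center
#'
#' Euclidean distance in screen px from the onset location to the center of
#' the ship sprite (fixed on screen at 954 + 18, 270 + 18), converted to
#' degrees of visual angle.
#'
#' @param onset_x,onset_y Screen coordinates of fixation onset(s).
#' @param smap Screen map.
#' @return Distance(s) in degrees.
#' @export
#' @examples
#' distance_to_ship(972 + 125, 288)  # 125 px right of center = 2.6 deg
distance_to_ship <- function(onset_x, onset_y, smap = screen_map()) {
  px_to_deg(sqrt((onset_x - smap$ship_center_x)^2 +
                 (onset_y - smap$ship_center_y)^2))
}

#' Distance from a fixation onset to the closest on-screen obstacle
#'
#' Minimum Euclidean distance from the onset location to the centers of the
#' obstacles visible at the onset frame, in degrees; `NA` when no obstacle
#' is on screen (such rows are excluded from the obstacle-distance model).
#'
#' @param onset_x,onset_y Screen coordinates of one fixation onset.
#' @param visible_obstacles Data.frame with `screen_x`, `screen_y` (top-left
#'   corners) of on-screen obstacles, as from [visible_objects()].
#' @return Distance in degrees, or `NA_real_`.
#' @export
distance_to_closest_obstacle <- function(onset_x, onset_y, visible_obstacles) {
  if (is.null(visible_obstacles) || nrow(visible_obstacles) == 0L) return(NA_real_)
  h <- .dodge$ship_px / 2
  d2 <- (onset_x - (visible_obstacles$screen_x + h))^2 +
        (onset_y - (visible_obstacles$screen_y + h))^2
  px_to_deg(sqrt(min(d2)))
}

#' Consecutive crash-completions in a session history
#'
#' Counts, over the strictly prior attempts of a session (in chronological
#' order), how often a crash was immediately followed by a completion of
#' the very next trial.
#'
#' @param outcomes Character vector of prior outcomes
#'   (`"crashed"`/`"completed"`), chronological.
#' @return Integer count.
#' @export
#' @examples
#' consecutive_crash_completions(c("crashed", "completed", "crashed", "completed"))  # 2
consecutive_crash_completions <- function(outcomes) {
  n <- length(outcomes)
  if (n < 2L) return(0L)
  sum(outcomes[-n] == "crashed" & outcomes[-1L] == "completed")
}

# Fixation rows for one trial: onset frames, covariates from the trial log,
# and the two distance measures. Entry-phase fixations are excluded (the
# ship is not yet controllable); the log ends at the crash frame, so no
# post-crash fixations exist. Obstacle distances use a per-layout index of
# obstacles sorted by y so each fixation only touches its visible window.
trial_fixation_rows <- function(fixations, log, layout, smap = screen_map()) {
  if (nrow(fixations) == 0L) return(NULL)
  fr0 <- assign_onset_frame(fixations$onset_t, log$n_frames)
  row <- fr0 + 1L
  keep <- log$frames$phase[row] == "control"
  if (!any(keep)) return(NULL)
  fixations <- fixations[keep, , drop = FALSE]
  row <- row[keep]; fr0 <- fr0[keep]
  fx <- fixations$onset_x; fy <- fixations$onset_y
  d_ship <- distance_to_ship(fx, fy, smap)

  idx <- layout_obstacle_index(layout)
  ship_x <- log$frames$x[row]; ship_y <- log$frames$y[row]
  half <- .dodge$ship_px / 2
  n <- length(row)
  d_obs <- rep(NA_real_, n)
  if (length(idx$oy) > 0L) {
    lo <- findInterval(ship_y - 306, idx$oy) + 1L   # first oy > y - 306
    hi <- findInterval(ship_y + 540 - 1e-9, idx$oy) # last oy < y + 540
    for (i in seq_len(n)) {
      if (lo[i] > hi[i]) next
      w <- lo[i]:hi[i]
      sx <- smap$ship_screen_x + idx$ox[w] - ship_x[i] + half
      sy <- smap$ship_screen_y + idx$oy[w] - ship_y[i] + half
      d_obs[i] <- sqrt(min((fx[i] - sx)^2 + (fy[i] - sy)^2))
    }
    d_obs <- px_to_deg(d_obs)
  }
  fast_df(list(
    onset_t = fixations$onset_t, onset_frame = fr0,
    onset_x = fx, onset_y = fy,
    duration = fixations$duration,
    dist_to_ship_deg = d_ship,
    dist_to_obstacle_deg = d_obs,
    n_obstacles_on_screen = log$frames$n_obstacles_on_screen[row],
    n_drift_sections_on_screen = log$frames$n_drift_sections_on_screen[row]
  ))
}

# Obstacles sorted by y, cached on the layout object's environment-free
# list (recomputed cheaply when absent).
layout_obstacle_index <- function(layout) {
  cached <- attr(layout, "obstacle_index")
  if (!is.null(cached)) return(cached)
  o <- order(layout$obstacles$y)
  list(ox = layout$obstacles$x[o], oy = layout$obstacles$y[o])
}

#' Build fixation and trial tables from detected events and session logs
#'
#' Joins per-trial fixation events with their trial logs and specs into the
#' two analysis tables: one row per gameplay fixation (onset covariates and
#' distance measures) and one row per attempt (outcome, design covariates,
#' fixation count, consecutive crash-completions). Training trials are
#' excluded from both.
#'
#' @param events Named list: for each trial index (as character), a
#'   data.frame of fixation events from [detect_fixations()].
#' @param session A `dodge_session`.
#' @param participant Participant id stamped into both tables.
#' @return A list with `fixations` and `trials` data.frames.
#' @export
build_tables <- function(events, session, participant = "p01") {
  smap <- screen_map()
  fix_rows <- list(); trial_rows <- list()
  outcomes_so_far <- character(0)
  for (i in seq_along(session$logs)) {
    log <- session$logs[[i]]
    if (isTRUE(log$training)) next
    spec <- log$spec
    layout <- session$layouts[[log$layout_id]]
    ev <- events[[as.character(i)]]
    fr <- if (!is.null(ev)) trial_fixation_rows(ev, log, layout, smap) else NULL
    n_fix <- if (is.null(fr)) 0L else nrow(fr)
    if (!is.null(fr)) {
      fr$participant <- participant; fr$trial <- i
      fr$spec_id <- spec$spec_id; fr$layout_id <- log$layout_id
      fr$difficulty <- layout$difficulty
      fr$noise_sd <- spec$input_noise_sd
      fr$drift_enabled <- isTRUE(spec$drift_enabled)
      fr$block <- spec$block
      fix_rows[[length(fix_rows) + 1L]] <- fr
    }
    trial_rows[[length(trial_rows) + 1L]] <- data.frame(
      participant = participant, trial = i, spec_id = spec$spec_id,
      layout_id = log$layout_id, difficulty = layout$difficulty,
      noise_sd = spec$input_noise_sd,
      drift_enabled = isTRUE(spec$drift_enabled), block = spec$block,
      attempt = log$attempt_index,
      completed = log$outcome == "completed",
      n_frames = log$n_frames, n_fixations = n_fix,
      consecutive_crash_completions = consecutive_crash_completions(outcomes_so_far)
    )
    outcomes_so_far <- c(outcomes_so_far, log$outcome)
  }
  list(
    fixations = if (length(fix_rows)) do.call(rbind, fix_rows) else NULL,
    trials = if (length(trial_rows)) do.call(rbind, trial_rows) else NULL
  )
}
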