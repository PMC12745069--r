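# Frame-stepped ship simulator. The R functions here are the reference
# semantics; `run_trial()` dispatches to a compiled loop for the built-in
# policies (identical RNG draw order, tested for equivalence) and falls back
# to this R path for arbitrary policy closures.

#' Create a ship state
#'
#' @param x,y Environment coordinates of the sprite's top-left corner
#'   (px; `y` grows downwards along the corridor).
#' @param frame Frame index.
#' @param alive Logical.
#' @return A `dodge_shipstate` list.
#' @export
ship_state <- function(x = (720 - 36) / 2, y = 0, frame = 0L, alive = TRUE) {
  structure(list(x = x, y = y, frame = as.integer(frame), alive = alive),
            class = "dodge_shipstate")
}

# Drift membership: the ship is inside a section while its top edge y lies
# in [y_start, y_start + 270). With a 6-px fall this makes a full traversal
# last exactly 270/6 = 45 frames (135 px of lateral push), independent of
# alignment.
drift_push <- function(y, spec, layout) {
  dr <- layout$drift_sections
  if (!isTRUE(spec$drift_enabled) || nrow(dr) == 0L) return(0)
  if (y < spec$manipulation_from_y) return(0)
  inside <- which(y >= dr$y_start & y < dr$y_start + dr$span_px)
  if (length(inside) == 0L) return(0)
  i <- inside[1L]
  type <- if (length(spec$section_types) >= i) spec$section_types[i] else "normal"
  if (!type %in% c("normal", "invisible")) return(0)
  if (dr$direction[i] == "right") .dodge$drift_px else -.dodge$drift_px
}

#' Advance the ship by one frame
#'
#' The ship falls 6 px. If a key is held, the horizontal step is drawn from
#' `Normal(6, input_noise_sd)` in the keyed direction (exactly 6 px at SD 0;
#' the signed draw is applied as-is, so extreme draws can momentarily move
#' against the key). If the ship is inside a drift section whose type exerts
#' force (`normal` or `invisible`), an additional 3 px is applied in the
#' section's push direction. Drift membership is evaluated at the post-fall
#' vertical position.
#'
#' @param state A `dodge_shipstate` with `alive = TRUE`.
#' @param key `"left"`, `"right"` or `"none"`.
#' @param spec A `dodge_trialspec`.
#' @param layout The `dodge_layout` the spec refers to.
#' @return The new `dodge_shipstate`; attribute `"dx"` carries the applied
#'   horizontal displacement and `"drift_active"` whether drift acted.
#' @export
#' @examples
#' s <- ship_state(y = 100)
#' lay <- generate_layout(9000, "easy", n_drift_sections = 0, seed = 1)
#' spec <- enumerate_configurations(1, make_experiment_layouts(1, 1))[[2]]
#' step_ship(s, "none", spec, lay)$y - s$y  # 6
step_ship <- function(state, key, spec, layout) {
  if (!isTRUE(state$alive)) stop("cannot step a dead ship")
  y2 <- state$y + .dodge$fall_px
  dx <- 0
  if (key %in% c("left", "right")) {
    sd <- spec$input_noise_sd
    if (y2 < spec$manipulation_from_y) sd <- 0
    delta <- if (sd > 0) stats::rnorm(1L, .dodge$key_step_px, sd) else .dodge$key_step_px
    dx <- dx + if (key == "right") delta else -delta
  }
  push <- drift_push(y2, spec, layout)
  dx <- dx + push
  out <- ship_state(state$x + dx, y2, state$frame + 1L, TRUE)
  attr(out, "dx") <- dx
  attr(out, "drift_active") <- push != 0
  out
}

#' Collision test
#'
#' TRUE when the 36x36 ship box (half-open pixel boxes, so abutting sprites
#' do not collide) overlaps any obstacle box, or the ship touches a wall
#' (`x < 0` or `x + 36 > 720`).
#'
#' @param state A `dodge_shipstate`.
#' @param layout A `dodge_layout`.
#' @return Logical.
#' @export
check_collision <- function(state, layout) {
  s <- .dodge$ship_px
  if (state$x < 0 || state$x + s > layout$width_px) return(TRUE)
  ob <- layout$obstacles
  if (nrow(ob) == 0L) return(FALSE)
  any(abs(state$x - ob$x) < s & abs(state$y - ob$y) < s)
}

#' Objects inside the observation window
#'
#' Maps environment objects to screen coordinates
#' (`screen = ship_screen + (object_env - ship_env)`) and counts those whose
#' box intersects the visible region: the full screen width by the top
#' 810 px (the bottom 270 px are occluded). Drift sections are counted via
#' their bar rectangle's vertical span whether or not the bar is drawn for
#' the trial's section type.
#'
#' @param state A `dodge_shipstate`.
#' @param layout A `dodge_layout`.
#' @param smap Screen map from [screen_map()].
#' @return A list with `n_obstacles`, `n_drift_sections`, and `obstacles`
#'   (data.frame of on-screen obstacles with env and screen coordinates).
#' @export
visible_objects <- function(state, layout, smap = screen_map()) {
  s <- .dodge$ship_px
  ob <- layout$obstacles
  sy <- smap$ship_screen_y + (ob$y - state$y)
  sx <- smap$ship_screen_x + (ob$x - state$x)
  on <- (sy + s > 0) & (sy < smap$visible_h) & (sx + s > 0) & (sx < smap$screen_w)
  dr <- layout$drift_sections
  if (nrow(dr) > 0L) {
    by <- smap$ship_screen_y + (dr$y_start - state$y)
    dron <- (by + dr$span_px > 0) & (by < smap$visible_h)
  } else dron <- logical(0)
  list(
    n_obstacles = sum(on),
    n_drift_sections = sum(dron),
    obstacles = data.frame(x = ob$x[on], y = ob$y[on],
                           screen_x = sx[on], screen_y = sy[on])
  )
}

# Number of frames in the automatic entry phase: the ship flies in from the
# top of the screen (270 px above the control point) at 6 px per frame.
entry_frames <- function() .dodge$ship_screen_y %/% .dodge$fall_px  # 45

#' Run one trial
#'
#' The ship spawns 270 px above the corridor entry and falls automatically
#' for 45 frames (the entry phase); from corridor entry on, the policy is
#' consulted every frame. The trial ends when the ship's y crosses the
#' layout length (completed) or a collision occurs (crashed). The log holds
#' one row per frame.
#'
#' @param spec A `dodge_trialspec`.
#' @param layout The matching `dodge_layout`.
#' @param policy A `dodge_policy` (see [greedy_gap_policy()], [null_policy()]).
#' @param seed Integer seed; identical seeds give identical logs.
#' @param use_r Force the R reference loop even for built-in policies.
#' @return A `dodge_triallog`: list with `spec`, `frames` (data.frame
#'   `frame`, `x`, `y`, `key`, `dx`, `drift_active`, `n_obstacles_on_screen`,
#'   `n_drift_sections_on_screen`, `phase`), `outcome`
#'   (`"completed"`/`"crashed"`), `crash_frame`, `n_frames`, `attempt_index`.
#' @export
run_trial <- function(spec, layout, policy = null_policy(), seed = 1L,
                      use_r = FALSE) {
  stopifnot(inherits(spec, "dodge_trialspec"), inherits(layout, "dodge_layout"))
  if (!use_r && policy$name %in% c("null", "greedy_gap")) {
    return(run_trial_fast(spec, layout, policy, seed))
  }
  with_seed(seed, run_trial_r(spec, layout, policy))
}

run_trial_r <- function(spec, layout, policy) {
  n_entry <- entry_frames()
  max_frames <- n_entry + layout$length_px %/% .dodge$fall_px + 10L
  frame <- integer(max_frames); xs <- numeric(max_frames); ys <- numeric(max_frames)
  keys <- character(max_frames); dxs <- numeric(max_frames)
  drifts <- logical(max_frames); nobs <- integer(max_frames); ndr <- integer(max_frames)
  phase <- character(max_frames)

  st <- ship_state(x = (layout$width_px - .dodge$ship_px) / 2, y = -n_entry * .dodge$fall_px)
  lag <- policy$params$reaction_lag_frames %||% 0L
  key_queue <- rep("none", lag)
  outcome <- "completed"; crash_frame <- NA_integer_; i <- 0L
  while (st$y < layout$length_px) {
    i <- i + 1L
    # frames landing at y <= 0 are the automatic entry; control starts with
    # the first step past the corridor entry (entry collisions are ignored:
    # the ship is flying in and not yet steerable)
    if (st$y + .dodge$fall_px <= 0) {
      key <- "none"; ph <- "entry"
    } else {
      ph <- "control"
      # plan from the state predicted once the already-queued keys land
      # (6 px per keyed frame), so the reaction lag does not cause
      # systematic overshoot; expose the drift push the ship will feel
      # there so policies can counteract it
      st_pred <- st
      if (lag > 0L) {
        queued_drift <- sum(vapply(seq_len(lag), function(q) {
          drift_push(st$y + .dodge$fall_px * q, spec, layout)
        }, 0))
        st_pred$x <- st$x + .dodge$key_step_px *
          (sum(key_queue == "right") - sum(key_queue == "left")) + queued_drift
        st_pred$y <- st$y + .dodge$fall_px * lag
        st_pred$frame <- st$frame + lag
      }
      st_pred$drift_push <- drift_push(st_pred$y + .dodge$fall_px, spec, layout)
      planned <- policy$fn(st_pred, layout, policy$params)
      if (lag > 0L) {
        key_queue <- c(key_queue, planned)
        key <- key_queue[1L]; key_queue <- key_queue[-1L]
      } else key <- planned
    }
    st <- step_ship(st, key, spec, layout)
    vis <- visible_objects(st, layout)
    frame[i] <- st$frame; xs[i] <- st$x; ys[i] <- st$y; keys[i] <- key
    dxs[i] <- attr(st, "dx"); drifts[i] <- attr(st, "drift_active")
    nobs[i] <- vis$n_obstacles; ndr[i] <- vis$n_drift_sections; phase[i] <- ph
    if (ph == "control" && check_collision(st, layout)) {
      outcome <- "crashed"; crash_frame <- st$frame; break
    }
    if (i >= max_frames) break
  }
  idx <- seq_len(i)
  new_triallog(spec, layout,
               data.frame(frame = frame[idx], x = xs[idx], y = ys[idx],
                          key = keys[idx], dx = dxs[idx],
                          drift_active = drifts[idx],
                          n_obstacles_on_screen = nobs[idx],
                          n_drift_sections_on_screen = ndr[idx],
                          phase = phase[idx], stringsAsFactors = FALSE),
               outcome, crash_frame)
}

new_triallog <- function(spec, layout, frames, outcome, crash_frame,
                         attempt_index = 1L) {
  structure(list(
    spec = spec, layout_id = layout$id, frames = frames,
    outcome = outcome, crash_frame = crash_frame,
    n_frames = nrow(frames), attempt_index = attempt_index,
    training = isTRUE(spec$training)
  ), class = "dodge_triallog")
}

#' @export
print.dodge_triallog <- function(x, ...) {
  cat(sprintf("<dodge_triallog> spec=%s layout=%s %s after %d frames (attempt %d)\n",
              x$spec$spec_id, x$layout_id, x$outcome, x$n_frames, x$attempt_index))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Compiled fast path: marshals layout/spec into plain vectors and calls the
# C++ loop, which draws from R's RNG in the same order as run_trial_r.
run_trial_fast <- function(spec, layout, policy, seed) {
  dr <- layout$drift_sections
  n_sec <- nrow(dr)
  types <- if (n_sec > 0) {
    tt <- spec$section_types
    if (length(tt) < n_sec) tt <- rep("normal", n_sec)
    match(tt, c("off", "normal", "invisible", "fake")) - 1L
  } else integer(0)
  p <- policy$params
  res <- with_seed(seed, cpp_run_trial(
    as.numeric(layout$obstacles$x), as.numeric(layout$obstacles$y),
    as.numeric(dr$y_start), as.integer(types),
    as.integer(dr$direction == "right"),
    layout$length_px, layout$width_px,
    as.numeric(spec$input_noise_sd), isTRUE(spec$drift_enabled),
    as.numeric(spec$manipulation_from_y),
    policy$name == "greedy_gap",
    as.numeric(p$lookahead_px %||% 540), as.numeric(p$skill %||% 1),
    as.integer(p$reaction_lag_frames %||% 0L)
  ))
  frames <- data.frame(
    frame = res$frame, x = res$x, y = res$y,
    key = c("none", "left", "right")[res$key + 1L],
    dx = res$dx, drift_active = res$drift_active,
    n_obstacles_on_screen = res$n_obstacles_on_screen,
    n_drift_sections_on_screen = res$n_drift_sections_on_screen,
    phase = c("entry", "control")[res$control + 1L],
    stringsAsFactors = FALSE
  )
  new_triallog(spec, layout, frames,
               if (res$completed) "completed" else "crashed",
               if (res$completed) NA_integer_ else res$crash_frame)
}
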