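# Scripted controllers. These exist so that every downstream stage has
# inputs without human data: they are deliberately simple, deterministic
# given the seed, and tuned only so that completion probability is sensitive
# to the noise/drift manipulations.

#' Null policy
#'
#' Never presses a key; the ship falls straight down.
#' @return A `dodge_policy`.
#' @export
null_policy <- function() {
  structure(list(name = "null", params = list(),
                 fn = function(state, layout, params) "none"),
            class = "dodge_policy")
}

#' Greedy gap-seeking policy
#'
#' Looks `lookahead_px` ahead of the ship, collects the horizontal intervals
#' blocked by obstacles that could still collide, and steers toward the
#' center of the widest collision-free gap. Emits `"none"` when the current
#' column is already clear. With probability `1 - skill` per control frame
#' the planned key is dropped (an attention lapse), and the emitted key is
#' the decision computed `reaction_lag_frames` frames earlier.
#'
#' @param lookahead_px Planning horizon ahead of the ship in px (<= 810).
#' @param skill Probability of acting on the planned key each frame.
#' @param reaction_lag_frames Delay between decision and key press, frames.
#' @return A `dodge_policy`.
#' @export
#' @examples
#' p <- greedy_gap_policy(skill = 1)
#' p$name
greedy_gap_policy <- function(lookahead_px = 540, skill = 0.92,
                              reaction_lag_frames = 6L) {
  stopifnot(skill >= 0, skill <= 1, lookahead_px <= 810)
  params <- list(lookahead_px = lookahead_px, skill = skill,
                 reaction_lag_frames = as.integer(reaction_lag_frames))
  structure(list(name = "greedy_gap", params = params, fn = greedy_gap_decide),
            class = "dodge_policy")
}

# One runif draw per control frame (lapse gate) before any step noise is
# drawn -- the compiled loop reproduces this order exactly. When the plan
# is to hold and the ship is being pushed by drift (state$drift_push, set
# by the run loop), the player counter-taps on alternate frames: one
# 6-px key every second frame cancels the 3-px-per-frame push on average,
# which is how a player station-holds against a visible, predictable
# force.
greedy_gap_decide <- function(state, layout, params) {
  lapse <- stats::runif(1L) > params$skill
  push <- state$drift_push %||% 0
  key <- greedy_gap_plan(state$x, state$y, layout$obstacles,
                         layout$width_px, params$lookahead_px, push = push)
  if (key == "none" && push != 0 && state$frame %% 2L == 0L) {
    key <- if (push > 0) "left" else "right"
  }
  if (lapse) "none" else key
}

# Deterministic core, exposed for tests. When the current column is blocked
# within the lookahead, the planner evaluates each free gap by simulating a
# straight transit at 6 px/frame toward the gap's nearest point and checks
# every obstacle column crossed on the way against its time of arrival
# (with a clearance margin of `margin_frames`); it steers toward the
# nearest transit-safe gap, falling back to the widest gap when none is
# safe. When the column is clear it holds, easing off the walls so drift
# cannot pin the ship against them.
greedy_gap_plan <- function(x, y, obstacles, width, lookahead,
                            wall_margin = 45, margin_frames = 3, push = 0) {
  s <- .dodge$ship_px
  fall <- .dodge$fall_px
  ahead <- obstacles[obstacles$y + s > y & obstacles$y <= y + lookahead, , drop = FALSE]
  gaps_lo <- 0; gaps_hi <- width - s
  if (nrow(ahead) > 0L) {
    lo <- pmax(0, ahead$x - (s - 1)); hi <- pmin(width - s, ahead$x + (s - 1))
    o <- order(lo); lo <- lo[o]; hi <- hi[o]
    gaps_lo <- numeric(0); gaps_hi <- numeric(0)
    cursor <- 0
    for (i in seq_along(lo)) {
      if (lo[i] > cursor) { gaps_lo <- c(gaps_lo, cursor); gaps_hi <- c(gaps_hi, lo[i] - 1) }
      cursor <- max(cursor, hi[i] + 1)
    }
    if (cursor <= width - s) { gaps_lo <- c(gaps_lo, cursor); gaps_hi <- c(gaps_hi, width - s) }
  }
  if (length(gaps_lo) == 0L) return("none")  # fully walled: nowhere to go
  # gaps narrower than min_gap cannot be held reliably with 6-px quantized
  # steps: never target them, and vacate one if currently inside
  min_gap <- 18
  wide <- gaps_hi - gaps_lo >= min_gap
  inside <- x >= gaps_lo & x <= gaps_hi & wide
  if (any(inside)) {
    g <- which(inside)[1L]
    if (x < wall_margin && gaps_hi[g] > x) return("right")
    if (x > width - s - wall_margin && gaps_lo[g] < x) return("left")
    # active steering: keep working toward the gap center rather than
    # coasting, as a player continuously micro-adjusts; this is also what
    # exposes the trajectory to input noise on most frames
    center <- (gaps_lo[g] + gaps_hi[g]) / 2
    if (x < center - 12) return("right")
    if (x > center + 12) return("left")
    return("none")
  }
  # transit safety: crossing obstacle column ox during frames
  # [(|ox-x|-36)/6, (|ox-x|+36)/6] must not overlap its arrival window
  # [(oy-36-y)/6, (oy+36-y)/6], with margin_frames of clearance
  transit_safe <- function(target) {
    span_lo <- min(x, target) - (s - 1); span_hi <- max(x, target) + (s - 1)
    on_path <- ahead$x >= span_lo & ahead$x <= span_hi
    if (!any(on_path)) return(TRUE)
    # effective lateral speed accounts for the currently felt drift push
    dir <- if (target >= x) 1 else -1
    speed <- .dodge$key_step_px + push * dir
    dx <- abs(ahead$x[on_path] - x)
    t1 <- (dx - s) / speed
    t2 <- (dx + s) / speed
    a1 <- (ahead$y[on_path] - s - y) / fall
    a2 <- (ahead$y[on_path] + s - y) / fall
    !any(t1 < a2 + margin_frames & t2 > a1 - margin_frames)
  }
  # aim at least 6 px inside the gap edges so a quantized step cannot land
  # in the adjacent blocked column
  targets <- pmin(pmax(x, gaps_lo + 6), gaps_hi - 6)
  dist <- abs(targets - x)
  safe <- wide & vapply(targets, transit_safe, NA)
  g <- if (any(safe)) {
    # nearest safe gap; distance ties go to the wider gap
    cand <- which(safe)
    cand[order(dist[cand], -(gaps_hi - gaps_lo)[cand])][1L]
  } else which.max(gaps_hi - gaps_lo)
  # aim past the gap edge toward its center for clearance
  target <- (targets[g] + (gaps_lo[g] + gaps_hi[g]) / 2) / 2
  if (abs(target - x) < 1e-9) "none" else if (target > x) "right" else "left"
}

#' @export
print.dodge_policy <- function(x, ...) {
  cat(sprintf("<dodge_policy %s>%s\n", x$name,
              if (length(x$params)) paste0(" ", paste(names(x$params),
                unlist(x$params), sep = "=", collapse = " ")) else ""))
  invisible(x)
}
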