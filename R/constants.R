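#' @useDynLib dodgegaze, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Fixed task geometry. The game world is a 720-px-wide corridor of up to
# 18,000 px length; the 36-px ship falls 6 px per logical frame at 60 FPS and
# is drawn at a fixed screen position while the world scrolls around it.
.dodge <- list(
  ship_px          = 36L,
  env_width        = 720L,
  fall_px          = 6L,
  key_step_px      = 6,
  drift_px         = 3,
  drift_span_px    = 270L,
  drift_bar_offset = 45L,
  drift_bar_width  = 18L,
  screen_w         = 1920L,
  screen_h         = 1080L,
  ship_screen_x    = 954L,
  ship_screen_y    = 270L,
  occluder_h       = 270L,
  visible_h        = 810L,   # screen_h - occluder_h
  fps              = 60L,
  rate_hz          = 2000L,
  deg_per_px       = 0.026 / 1.25
)

#' Screen geometry of the task display
#'
#' Returns the fixed display mapping: a 1920x1080 screen, the ship sprite
#' anchored at screen top-left (954, 270), a 270-px gray occluder bar at the
#' bottom (so the visible play area is the top 810 px), and the 60-FPS logical
#' clock. Environment objects are mapped to the screen by
#' `screen = ship_screen + (object_env - ship_env)`.
#'
#' @return A list with elements `screen_w`, `screen_h`, `ship_screen_x`,
#'   `ship_screen_y`, `ship_center_x`, `ship_center_y`, `occluder_h`,
#'   `visible_h`, `fps`.
#' @export
#' @examples
#' screen_map()$visible_h  # 810
screen_map <- function() {
  list(
    screen_w = .dodge$screen_w, screen_h = .dodge$screen_h,
    ship_screen_x = .dodge$ship_screen_x, ship_screen_y = .dodge$ship_screen_y,
    ship_center_x = .dodge$ship_screen_x + .dodge$ship_px / 2,
    ship_center_y = .dodge$ship_screen_y + .dodge$ship_px / 2,
    occluder_h = .dodge$occluder_h, visible_h = .dodge$visible_h,
    fps = .dodge$fps
  )
}

# Evaluate `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards. All user-facing stochastic entry points go through
# this so results are reproducible and side-effect free.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  expr
}

# Deterministically derive a child seed from a master seed and a stream label,
# kept below 2^31. Used to give each participant / trial / bootstrap chunk an
# independent reproducible stream.
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- 17
  for (b in utf8ToInt(parts)) {
    h <- (h * 31 + b) %% 2147483647   # stays exact in double arithmetic
  }
  as.integer(h %% 2147483629 + 1)
}

# Minimal data.frame constructor for hot paths (no name mangling, no
# coercion checks); all columns must already have equal length.
fast_df <- function(cols) {
  structure(cols, class = "data.frame",
            row.names = .set_row_names(length(cols[[1L]])))
}

# Tiny polynomial content hash for artifact provenance stamps (hex string).
content_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 17
  for (b in utf8ToInt(s)) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}
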