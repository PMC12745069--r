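# Layout generation: obstacle fields and drift sections for one level.

# Obstacle counts by (length, difficulty). Short (9000) and long (18000)
# layouts have fixed counts; 13,500-px layouts are defined by count ranges
# and only exist at medium/hard difficulty.
.obstacle_table <- list(
  `9000`  = c(easy = 12L, medium = 34L, hard = 68L),
  `18000` = c(easy = 32L, medium = 84L, hard = 168L)
)
.obstacle_range_13500 <- list(medium = c(58L, 62L), hard = c(116L, 124L))

# Default drift-section counts by (length, difficulty).
.drift_table <- list(
  `9000`  = c(easy = 4L, medium = 4L, hard = 8L),
  `13500` = c(easy = 8L, medium = 8L, hard = 8L),
  `18000` = c(easy = 9L, medium = 9L, hard = 18L)
)

#' Number of obstacles for a layout length and difficulty
#'
#' For 9000- and 18,000-px layouts this is the fixed design value; for
#' 13,500-px layouts the design specifies a range and the count is drawn
#' uniformly from it (hence the `seed` argument).
#'
#' @param length_px Layout length: 9000, 13500 or 18000.
#' @param difficulty `"easy"`, `"medium"` or `"hard"`.
#' @param seed Integer seed (only consulted for 13,500-px layouts).
#' @return Integer obstacle count.
#' @export
obstacle_count <- function(length_px, difficulty, seed = 1L) {
  difficulty <- match.arg(difficulty, c("easy", "medium", "hard"))
  if (length_px %in% c(9000, 18000)) {
    return(unname(.obstacle_table[[as.character(length_px)]][difficulty]))
  }
  if (length_px == 13500) {
    rng <- .obstacle_range_13500[[difficulty]]
    if (is.null(rng)) {
      stop("invalid-spec: 13,500-px layouts are only defined at medium/hard difficulty")
    }
    return(with_seed(derive_seed(seed, "nobs"),
                     sample(seq(rng[1], rng[2]), 1L)))
  }
  stop("invalid-spec: unknown layout length ", length_px)
}

#' Generate a random layout
#'
#' Scatters `n` 36x36 obstacles uniformly over the corridor (coordinates are
#' integer top-left corners in `[0, width-36] x [0, length-36]`) and places
#' `n_drift_sections` non-overlapping 270-px drift sections at uniform random
#' vertical positions, each with a random push direction. Layouts in which
#' some vertical position has no collision-free horizontal column are
#' rejected and resampled with an incremented seed, so every layout is
#' completable by a sufficiently good player.
#'
#' @param length_px Layout length in px: 9000, 13500 or 18000.
#' @param difficulty `"easy"`, `"medium"` or `"hard"`.
#' @param n_drift_sections Number of drift sections; `NULL` uses the design
#'   default for the length/difficulty, 0 gives a drift-free layout.
#' @param seed Integer seed; identical seeds give identical layouts.
#' @param id Layout identifier (defaults to a descriptive label).
#' @param training Flag marking a training layout (excluded from analysis
#'   tables downstream).
#' @return An object of class `dodge_layout`: a list with `id`, `length_px`,
#'   `width_px`, `difficulty`, `obstacles` (data.frame `x`, `y`),
#'   `drift_sections` (data.frame `y_start`, `span_px`, `direction`,
#'   `bar_offset_px`, `bar_width_px`), `training`, `seed`.
#' @export
#' @examples
#' lay <- generate_layout(9000, "easy", seed = 1)
#' nrow(lay$obstacles)  # 12
generate_layout <- function(length_px, difficulty,
                            n_drift_sections = NULL, seed = 1L,
                            id = NULL, training = FALSE) {
  difficulty <- match.arg(difficulty, c("easy", "medium", "hard"))
  if (!length_px %in% c(9000, 13500, 18000)) {
    stop("invalid-spec: layout length must be 9000, 13500 or 18000 px")
  }
  n_obs <- obstacle_count(length_px, difficulty, seed)
  if (is.null(n_drift_sections)) {
    n_drift_sections <- unname(.drift_table[[as.character(length_px)]][difficulty])
  }
  n_drift_sections <- as.integer(n_drift_sections)

  w <- .dodge$env_width; s <- .dodge$ship_px
  for (attempt in 0:99) {
    lay_seed <- as.integer(seed) + attempt
    layout <- with_seed(derive_seed(lay_seed, "layout"), {
      obstacles <- data.frame(
        x = floor(stats::runif(n_obs, 0, w - s + 1)),
        y = floor(stats::runif(n_obs, 0, length_px - s + 1))
      )
      drift <- place_drift_sections(n_drift_sections, length_px)
      list(obstacles = obstacles, drift_sections = drift)
    })
    if (spawn_corridor_clear(layout$obstacles) &&
        has_free_column(layout$obstacles, length_px)) {
      out <- structure(list(
        id = if (is.null(id)) sprintf("L%d_%s_s%d", length_px, difficulty, lay_seed) else id,
        length_px = as.integer(length_px), width_px = w,
        difficulty = difficulty,
        obstacles = layout$obstacles,
        drift_sections = layout$drift_sections,
        training = isTRUE(training), seed = lay_seed
      ), class = "dodge_layout")
      return(out)
    }
  }
  stop("could not generate a completable layout in 100 attempts")
}

# Non-overlapping drift-section vertical placement by rejection sampling.
place_drift_sections <- function(n, length_px) {
  span <- .dodge$drift_span_px
  if (n == 0L) {
    return(data.frame(y_start = integer(0), span_px = integer(0),
                      direction = character(0), bar_offset_px = integer(0),
                      bar_width_px = integer(0)))
  }
  if (n * span > length_px) stop("too many drift sections for layout length")
  repeat {
    ys <- sort(floor(stats::runif(n, 0, length_px - span + 1)))
    if (n == 1L || all(diff(ys) >= span)) break
  }
  data.frame(
    y_start = as.integer(ys), span_px = span,
    direction = sample(c("left", "right"), n, replace = TRUE),
    bar_offset_px = .dodge$drift_bar_offset,
    bar_width_px = .dodge$drift_bar_width
  )
}

# The ship enters at the corridor center and cannot steer until it passes
# the control point; obstacles over the spawn column in the first 360 px
# would crash it before it can react, so such layouts are resampled.
spawn_corridor_clear <- function(obstacles) {
  spawn_x <- (.dodge$env_width - .dodge$ship_px) / 2
  !any(abs(obstacles$x - spawn_x) < .dodge$ship_px + 18 & obstacles$y < 360)
}

# TRUE if at every vertical position there is at least one ship x-column
# free of obstacle overlap (so the layout is completable in principle).
# The set of obstacles whose y-span can touch the ship changes only at
# y = oy - 35 and y = oy + 36; checking just after each entry event suffices.
has_free_column <- function(obstacles, length_px) {
  s <- .dodge$ship_px; w <- .dodge$env_width
  if (nrow(obstacles) == 0L) return(TRUE)
  ys <- sort(unique(pmax(0, obstacles$y - (s - 1))))
  for (y in ys) {
    active <- obstacles$x[abs(obstacles$y - y) < s]
    if (length(active) == 0L) next
    # blocked ship-x intervals: |x - ox| < 36  ->  [ox - 35, ox + 35]
    o <- order(active)
    lo <- pmax(0L, active[o] - (s - 1)); hi <- pmin(w - s, active[o] + (s - 1))
    # merge and look for a gap in [0, w - s]
    cursor <- 0L; found <- FALSE
    for (i in seq_along(lo)) {
      if (lo[i] > cursor) { found <- TRUE; break }
      cursor <- max(cursor, hi[i] + 1L)
    }
    if (!found && cursor <= w - s) found <- TRUE
    if (!found) return(FALSE)
  }
  TRUE
}

#' Validate layout invariants
#'
#' Checks that obstacle coordinates lie inside the corridor, drift spans are
#' 270 px and non-overlapping, and the obstacle count matches the design
#' table for the layout's length and difficulty.
#'
#' @param layout A `dodge_layout`.
#' @return Invisibly `TRUE`; errors describe the first violated invariant.
#' @export
validate_layout <- function(layout) {
  stopifnot(inherits(layout, "dodge_layout"))
  s <- .dodge$ship_px
  ob <- layout$obstacles
  if (nrow(ob) > 0 &&
      (any(ob$x < 0) || any(ob$x > layout$width_px - s) ||
       any(ob$y < 0) || any(ob$y > layout$length_px - s))) {
    stop("obstacle coordinates outside corridor")
  }
  dr <- layout$drift_sections
  if (nrow(dr) > 0) {
    if (any(dr$span_px != .dodge$drift_span_px)) stop("drift span must be 270 px")
    ys <- sort(dr$y_start)
    if (length(ys) > 1 && any(diff(ys) < .dodge$drift_span_px)) {
      stop("drift sections overlap in y")
    }
  }
  if (layout$length_px %in% c(9000, 18000)) {
    want <- obstacle_count(layout$length_px, layout$difficulty)
    if (nrow(ob) != want) stop("obstacle count does not match difficulty table")
  } else {
    rng <- .obstacle_range_13500[[layout$difficulty]]
    if (nrow(ob) < rng[1] || nrow(ob) > rng[2]) {
      stop("obstacle count outside 13,500-px design range")
    }
  }
  invisible(TRUE)
}

#' @export
print.dodge_layout <- function(x, ...) {
  cat(sprintf("<dodge_layout %s>  %d x %d px, %s, %d obstacles, %d drift sections%s\n",
              x$id, x$width_px, x$length_px, x$difficulty,
              nrow(x$obstacles), nrow(x$drift_sections),
              if (isTRUE(x$training)) " [training]" else ""))
  invisible(x)
}

#' Write / read a layout as JSON
#'
#' @param layout A `dodge_layout`.
#' @param path File path.
#' @return `write_layout_json` returns `path` invisibly; `read_layout_json`
#'   returns the reconstructed `dodge_layout`.
#' @export
write_layout_json <- function(layout, path) {
  obj <- unclass(layout)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$obstacles <- as.data.frame(obj$obstacles)
  obj$drift_sections <- as.data.frame(obj$drift_sections)
  if (nrow(obj$drift_sections) == 0) {
    obj$drift_sections <- place_drift_sections(0L, obj$length_px)
  }
  structure(obj, class = "dodge_layout")
}
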