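# Binocular preprocessing, displacement-based fixation annotation, and
# velocity-based saccade verification on 2000-Hz gaze streams.
#
# Conventions: a gaze stream is a data.frame with columns
#   t (s), lx, ly, rx, ry (screen px), vl, vr (validity flags),
# sampled on a strict 0.5-ms grid. All detection operates in screen px;
# conversion to visual degrees happens only in the measures stage, via the
# fixed constant 0.026 deg = 1.25 px.

#' Pixel / degree conversion
#'
#' Uses the display's fixed equivalence 1.25 px = 0.026 degrees of visual
#' angle (0.0208 deg/px).
#'
#' @param d_px,d_deg Nonnegative distances.
#' @return Converted distances.
#' @export
#' @examples
#' px_to_deg(1.25)  # 0.026
px_to_deg <- function(d_px) {
  if (any(d_px < 0, na.rm = TRUE)) stop("distance must be nonnegative")
  d_px * .dodge$deg_per_px
}

#' @rdname px_to_deg
#' @export
deg_to_px <- function(d_deg) {
  if (any(d_deg < 0, na.rm = TRUE)) stop("distance must be nonnegative")
  d_deg / .dodge$deg_per_px
}

#' Combine the two eyes into a cyclopean stream
#'
#' The analyzed gaze position is the Euclidean center point of both eyes;
#' when one eye's signal is lost the other eye's position is used, and
#' samples with both eyes invalid are dropped.
#'
#' @param gaze A gaze stream data.frame (`t, lx, ly, rx, ry, vl, vr`).
#' @return A data.frame `t, x, y, source` with
#'   `source` in `both`, `left_only`, `right_only`.
#' @export
combine_eyes <- function(gaze) {
  if (nrow(gaze) == 0L) {
    return(data.frame(t = numeric(0), x = numeric(0), y = numeric(0),
                      source = character(0), stringsAsFactors = FALSE))
  }
  vl <- as.logical(gaze$vl); vr <- as.logical(gaze$vr)
  keep <- vl | vr
  x <- ifelse(vl & vr, (gaze$lx + gaze$rx) / 2, ifelse(vl, gaze$lx, gaze$rx))
  y <- ifelse(vl & vr, (gaze$ly + gaze$ry) / 2, ifelse(vl, gaze$ly, gaze$ry))
  src <- ifelse(vl & vr, "both", ifelse(vl, "left_only", "right_only"))
  data.frame(t = gaze$t[keep], x = x[keep], y = y[keep], source = src[keep],
             stringsAsFactors = FALSE)
}

# Per-gap stability: for each consecutive sample pair, TRUE when every eye
# valid at both endpoints moved <= 1.25 px (single-eye stretches use that
# eye alone; pairs with no eye valid at both endpoints are unstable).
gap_stability <- function(gaze, threshold_px = 1.25) {
  if (nrow(gaze) < 2L) return(logical(0))
  cpp_gap_stability(as.numeric(gaze$lx), as.numeric(gaze$ly),
                    as.numeric(gaze$rx), as.numeric(gaze$ry),
                    as.logical(gaze$vl), as.logical(gaze$vr), threshold_px)
}

#' Detect fixations
#'
#' Annotates as fixations the maximal runs in which both eyes travel no
#' more than 1.25 px (0.026 deg) between consecutive samples, for at least
#' `min_samples` consecutive samples. The onset location is the cyclopean
#' position at the first sample of the run. Optionally, sample gaps falling
#' inside verified saccade intervals are broken before the run rule is
#' applied.
#'
#' @param gaze A gaze stream data.frame.
#' @param min_samples Minimum run length in samples (25).
#' @param threshold_px Per-sample displacement threshold (1.25 px).
#' @param exclude Optional data.frame of intervals (`onset_t`, `offset_t`),
#'   e.g. verified saccades, whose samples may not belong to fixation runs.
#' @return A data.frame of fixation events: `onset_t`, `offset_t`,
#'   `onset_x`, `onset_y`, `n_samples`, `duration`.
#' @export
detect_fixations <- function(gaze, min_samples = 25L, threshold_px = 1.25,
                             exclude = NULL) {
  n <- nrow(gaze)
  empty <- data.frame(onset_t = numeric(0), offset_t = numeric(0),
                      onset_x = numeric(0), onset_y = numeric(0),
                      n_samples = integer(0), duration = numeric(0))
  if (n < min_samples) return(empty)
  stable <- gap_stability(gaze, threshold_px)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    # a gap whose either endpoint lies inside a saccade interval is broken
    bad <- rep(FALSE, n)
    for (k in seq_len(nrow(exclude))) {
      bad <- bad | (gaze$t >= exclude$onset_t[k] & gaze$t <= exclude$offset_t[k])
    }
    stable <- stable & !(bad[-n] | bad[-1L])
  }
  r <- rle(stable)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= (min_samples - 1L))
  if (length(runs) == 0L) return(empty)
  i0 <- starts[runs]            # first sample index of the run
  i1 <- ends[runs] + 1L         # last sample index
  pos <- cyclopean_at(gaze, i0)
  fast_df(list(
    onset_t = gaze$t[i0], offset_t = gaze$t[i1],
    onset_x = pos$x, onset_y = pos$y,
    n_samples = i1 - i0 + 1L,
    duration = (i1 - i0 + 1L) / .dodge$rate_hz
  ))
}

# Cyclopean coordinates at selected sample indices (NA when both invalid).
cyclopean_at <- function(gaze, idx) {
  vl <- as.logical(gaze$vl[idx]); vr <- as.logical(gaze$vr[idx])
  lx <- gaze$lx[idx]; ly <- gaze$ly[idx]
  rx <- gaze$rx[idx]; ry <- gaze$ry[idx]
  x <- rep(NA_real_, length(idx)); y <- x
  both <- vl & vr
  x[both] <- (lx[both] + rx[both]) / 2; y[both] <- (ly[both] + ry[both]) / 2
  lo <- vl & !vr; x[lo] <- lx[lo]; y[lo] <- ly[lo]
  ro <- vr & !vl; x[ro] <- rx[ro]; y[ro] <- ry[ro]
  list(x = x, y = y)
}

#' Saccade detection parameters
#'
#' @param lambda Velocity-threshold multiplier (6): the per-trial, per-eye
#'   threshold is `lambda` times a median-based estimate of the velocity
#'   spread.
#' @param min_samples Minimum saccade duration in samples (4, i.e. 2 ms).
#' @param min_amp_deg Minimum amplitude in degrees (0.5).
#' @param velocity_window Samples in the centered velocity window (5).
#' @return A list of parameters.
#' @export
saccade_params <- function(lambda = 6, min_samples = 4L, min_amp_deg = 0.5,
                           velocity_window = 5L) {
  stopifnot(lambda > 0, min_samples >= 1)
  list(lambda = lambda, min_samples = as.integer(min_samples),
       min_amp_deg = min_amp_deg, velocity_window = as.integer(velocity_window))
}

# 5-sample centered-difference velocity (px/s) of one coordinate series.
centered_velocity <- function(v, dt) {
  n <- length(v)
  out <- rep(NA_real_, n)
  if (n >= 5L) {
    idx <- 3:(n - 2L)
    out[idx] <- (v[idx + 2L] + v[idx + 1L] - v[idx - 1L] - v[idx - 2L]) / (6 * dt)
  }
  out
}

# Median-based velocity spread (Engbert-Kliegl estimator).
median_sd <- function(v) {
  v <- v[is.finite(v)]
  sqrt(pmax(stats::median(v^2) - stats::median(v)^2, 1e-12))
}

#' Detect saccades
#'
#' Velocity-based verification: per eye, horizontal and vertical velocities
#' come from a centered moving window; a per-trial, per-eye elliptic
#' threshold is set at `lambda` times a median-based velocity spread.
#' Intervals in which both eyes exceed their thresholds for at least
#' `min_samples` consecutive samples and whose total cyclopean displacement
#' is at least `min_amp_deg` are saccades (the amplitude gate is applied
#' after the threshold crossing).
#'
#' @param gaze A gaze stream data.frame.
#' @param params From [saccade_params()].
#' @return A data.frame `onset_t, offset_t, n_samples, amplitude_deg`.
#' @export
detect_saccades <- function(gaze, params = saccade_params()) {
  n <- nrow(gaze)
  empty <- data.frame(onset_t = numeric(0), offset_t = numeric(0),
                      n_samples = integer(0), amplitude_deg = numeric(0))
  if (n < params$velocity_window) {
    warning("stream shorter than the velocity window; no saccades detected")
    return(empty)
  }
  dt <- 1 / .dodge$rate_hz
  over <- rep(TRUE, n)
  for (eye in c("l", "r")) {
    vx <- centered_velocity(gaze[[paste0(eye, "x")]], dt)
    vy <- centered_velocity(gaze[[paste0(eye, "y")]], dt)
    ex <- params$lambda * median_sd(vx)
    ey <- params$lambda * median_sd(vy)
    crit <- (vx / ex)^2 + (vy / ey)^2 > 1
    crit[!is.finite(crit)] <- FALSE
    valid <- as.logical(gaze[[paste0("v", eye)]])
    over <- over & crit & valid
  }
  r <- rle(over)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values & r$lengths >= params$min_samples)
  if (length(runs) == 0L) return(empty)
  i0 <- starts[runs]; i1 <- ends[runs]
  p0 <- cyclopean_at(gaze, i0); p1 <- cyclopean_at(gaze, i1)
  amp_px <- sqrt((p1$x - p0$x)^2 + (p1$y - p0$y)^2)
  amp <- px_to_deg(amp_px)
  keep <- !is.na(amp) & amp >= params$min_amp_deg
  data.frame(onset_t = gaze$t[i0[keep]], offset_t = gaze$t[i1[keep]],
             n_samples = (i1 - i0 + 1L)[keep], amplitude_deg = amp[keep])
}

#' Annotate a gaze stream with fixation and saccade events
#'
#' Runs saccade verification first, removes verified saccade samples from
#' candidate fixation runs, then applies the 25-sample fixation rule, so
#' fixation and saccade intervals never overlap.
#'
#' @param gaze A gaze stream data.frame.
#' @param sacc_params From [saccade_params()].
#' @return A list with `fixations` and `saccades` data.frames.
#' @export
annotate_events <- function(gaze, sacc_params = saccade_params()) {
  sac <- suppressWarnings(detect_saccades(gaze, sacc_params))
  fix <- detect_fixations(gaze, exclude = sac)
  list(fixations = fix, saccades = sac)
}

#' Map a fixation onset time to a game frame
#'
#' Frames last 1/60 s; the onset frame is the frame in progress at the
#' onset time, `floor(onset_t * 60)`, relative to trial start (frame 0 is
#' the first frame).
#'
#' @param onset_t Onset time(s) in seconds from trial start.
#' @param n_frames Number of frames in the trial log.
#' @return Integer frame indices in `[0, n_frames - 1]`.
#' @export
assign_onset_frame <- function(onset_t, n_frames) {
  fr <- floor(onset_t * .dodge$fps)
  if (any(onset_t < 0) || any(fr >= n_frames)) {
    stop("fixation onset outside the trial span")
  }
  as.integer(fr)
}
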