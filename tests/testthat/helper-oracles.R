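# Independent brute-force oracles, re-implemented directly from the
# definitions (no code shared with the package's optimized paths).

# Maximal-run fixation scan: walks the stream sample by sample, tracking
# per-gap stability exactly as defined (each eye valid at both endpoints
# must move <= thr px; pairs with no eye valid at both endpoints break the
# run), and emits every maximal run of >= min_samples samples.
oracle_fixation_scan <- function(gaze, min_samples = 25L, thr = 1.25) {
  n <- nrow(gaze)
  onsets <- integer(0); offsets <- integer(0)
  run_start <- 1L
  gap_ok <- function(i) {
    lv <- gaze$vl[i - 1] && gaze$vl[i]
    rv <- gaze$vr[i - 1] && gaze$vr[i]
    if (!lv && !rv) return(FALSE)
    if (lv) {
      if ((gaze$lx[i] - gaze$lx[i - 1])^2 +
          (gaze$ly[i] - gaze$ly[i - 1])^2 > thr^2) return(FALSE)
    }
    if (rv) {
      if ((gaze$rx[i] - gaze$rx[i - 1])^2 +
          (gaze$ry[i] - gaze$ry[i - 1])^2 > thr^2) return(FALSE)
    }
    TRUE
  }
  if (n >= 2) {
    for (i in 2:n) {
      if (!gap_ok(i)) {
        if (i - run_start >= min_samples) {
          onsets <- c(onsets, run_start); offsets <- c(offsets, i - 1L)
        }
        run_start <- i
      }
    }
    if (n - run_start + 1L >= min_samples) {
      onsets <- c(onsets, run_start); offsets <- c(offsets, n)
    }
  }
  data.frame(onset = onsets, offset = offsets)
}

# Exhaustive k-quantiles split: standardize, then evaluate every contiguous
# split of the sorted data with a naive O(n) profile over the same fixed
# theta grid the method defines.
oracle_kq_side <- function(v) {
  m <- length(v); vs <- sort(v); best <- Inf
  for (theta in seq(0.01, 0.99, by = 0.01)) {
    c0 <- vs[min(max(ceiling(theta * m), 1), m)]
    u <- v - c0
    sig <- max(sum(u * (theta - (u < 0))) / m, 1e-9)
    nll <- m * (log(sig) - log(theta * (1 - theta)) + 1)
    if (nll < best) best <- nll
  }
  best
}

oracle_kq_split <- function(x) {
  z <- (x - mean(x)) / sd(x)
  xs <- sort(z); n <- length(xs)
  best <- Inf; bi <- NA_integer_
  for (i in 2:(n - 2)) {
    nll <- oracle_kq_side(xs[1:i]) + oracle_kq_side(xs[(i + 1):n])
    if (nll < best) { best <- nll; bi <- i }
  }
  list(n_close = bi, nll = best)
}

# Rasterized sprite-overlap check: paints both 36x36 boxes on a pixel grid.
oracle_boxes_overlap <- function(x1, y1, x2, y2, s = 36L) {
  px1 <- outer(seq(floor(x1), floor(x1) + s - 1), seq(floor(y1), floor(y1) + s - 1),
               function(a, b) paste(a, b))
  px2 <- outer(seq(floor(x2), floor(x2) + s - 1), seq(floor(y2), floor(y2) + s - 1),
               function(a, b) paste(a, b))
  any(px1 %in% px2)
}
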