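#' Jerk magnitude from triaxial acceleration
#'
#' The jerk is the norm of the forward-differenced triaxial acceleration
#' scaled by the sampling rate: `j[k] = fs * ||a[k+1] - a[k]||`, in m/s^3.
#'
#' @param accel numeric matrix (n x 3) of acceleration in m/s^2.
#' @param fs sampling rate in Hz.
#' @return Numeric vector of length `n - 1`.
#' @export
compute_jerk <- function(accel, fs) {
  accel <- as.matrix(accel)
  if (fs <= 0) stop("fs must be positive")
  if (nrow(accel) < 2L) stop("need at least two acceleration samples")
  d <- diff(accel)
  fs * sqrt(rowSums(d^2))
}

#' Sliding root-mean-square of the jerk
#'
#' Centred sliding RMS with a hop of one sample; windows shrink at the
#' record edges so the output has the same length as the input.
#'
#' @param jerk numeric jerk magnitude series (m/s^3).
#' @param fs sampling rate in Hz.
#' @param window window length in seconds (default 0.2); must cover at
#'   least 2 samples and not exceed the record.
#' @return Numeric vector of RMS-jerk, same length as `jerk`.
#' @export
rms_jerk <- function(jerk, fs, window = 0.2) {
  n <- length(jerk)
  w <- round(window * fs)
  if (w < 2L) stop("window must span at least 2 samples")
  if (w > n) stop("window longer than the record")
  h <- w %/% 2L
  sqrt(moving_mean(jerk^2, h))
}

#' Detect prey capture attempts in an RMS-jerk series
#'
#' Raw events are maximal runs above `threshold`; runs separated by gaps
#' shorter than `merge_gap` are consolidated into one event (a long capture
#' attempt made of several jerk peaks), and only then are events shorter
#' than `min_duration` discarded.
#'
#' @param rms numeric RMS-jerk series (m/s^3).
#' @param fs sampling rate of `rms`, Hz.
#' @param threshold detection threshold, m/s^3 (default 150).
#' @param min_duration minimum event duration in seconds (default 5).
#' @param merge_gap gaps strictly shorter than this (s) are merged
#'   (default 5).
#' @param t0 time of the first sample, seconds (default 0).
#' @return data.frame with columns `id`, `start`, `end` (sample indices),
#'   `t_start`, `t_end`, `duration_s`, `peak_rms`; events are sorted and
#'   disjoint.
#' @export
detect_events <- function(rms, fs, threshold = 150, min_duration = 5,
                          merge_gap = 5, t0 = 0) {
  if (threshold <= 0 || min_duration <= 0 || merge_gap <= 0)
    stop("threshold, min_duration and merge_gap must be positive")
  above <- rms > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  s <- starts[r$values]
  e <- ends[r$values]
  empty <- data.frame(id = integer(), start = integer(), end = integer(),
                      t_start = numeric(), t_end = numeric(),
                      duration_s = numeric(), peak_rms = numeric())
  if (length(s) == 0L) return(empty)
  # merge runs separated by gaps < merge_gap
  ms <- s[1]; me <- e[1]
  out_s <- integer(); out_e <- integer()
  if (length(s) > 1L) {
    for (i in 2L:length(s)) {
      gap <- (s[i] - me - 1L) / fs
      if (gap < merge_gap) {
        me <- e[i]
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- s[i]; me <- e[i]
      }
    }
  }
  out_s <- c(out_s, ms); out_e <- c(out_e, me)
  dur <- (out_e - out_s + 1L) / fs
  keep <- dur >= min_duration
  out_s <- out_s[keep]; out_e <- out_e[keep]
  if (length(out_s) == 0L) return(empty)
  data.frame(
    id = seq_along(out_s),
    start = out_s, end = out_e,
    t_start = t0 + (out_s - 1L) / fs,
    t_end = t0 + (out_e - 1L) / fs,
    duration_s = (out_e - out_s + 1L) / fs,
    peak_rms = vapply(seq_along(out_s),
                      function(i) max(rms[out_s[i]:out_e[i]]), numeric(1))
  )
}

#' Prey capture attempt detection from raw acceleration
#'
#' Convenience wrapper chaining [compute_jerk()], [rms_jerk()] and
#' [detect_events()].
#'
#' @inheritParams compute_jerk
#' @inheritParams detect_events
#' @param rms_window RMS window in seconds (default 0.2).
#' @return See [detect_events()].
#' @export
detect_prca <- function(accel, fs, threshold = 150, min_duration = 5,
                        merge_gap = 5, rms_window = 0.2, t0 = 0) {
  j <- compute_jerk(accel, fs)
  r <- rms_jerk(j, fs, rms_window)
  detect_events(r, fs, threshold, min_duration, merge_gap, t0 = t0)
}

#' Survival curve of inter-event gaps
#'
#' `S(delta)` is the fraction of gaps strictly greater than `delta`. The
#' suggested merge threshold is the elbow of S -- the grid point of maximum
#' distance below the chord joining the curve's endpoints, which marks the
#' sharpest bend between short within-burst gaps and long between-event
#' gaps (a chord-based knee is used because a raw second difference is
#' noisy on an empirical step curve). It is reported for inspection only;
#' the default merge gap is not changed automatically.
#'
#' @param gaps non-negative inter-event gaps in seconds.
#' @param grid evaluation grid in seconds; defaults to 201 points spanning
#'   the gap range.
#' @return list with `delta`, `S`, and `suggested_threshold` (NA when fewer
#'   than 3 grid points carry information), or an empty curve for no gaps.
#' @export
survival_curve <- function(gaps, grid = NULL) {
  if (any(gaps < 0)) stop("gaps must be non-negative")
  if (length(gaps) == 0L)
    return(list(delta = numeric(), S = numeric(), suggested_threshold = NA_real_))
  if (is.null(grid)) grid <- seq(0, max(gaps), length.out = 201L)
  S <- vapply(grid, function(d) mean(gaps > d), numeric(1))
  suggested <- NA_real_
  if (length(grid) >= 3L && grid[length(grid)] > grid[1L]) {
    u <- (grid - grid[1L]) / (grid[length(grid)] - grid[1L])
    chord <- S[1L] + (S[length(S)] - S[1L]) * u
    suggested <- grid[which.max(chord - S)]
  }
  list(delta = grid, S = S, suggested_threshold = suggested)
}

#' Attach depth and dive context to detected events
#'
#' Each event is given the depth at its start sample and the id of the dive
#' containing it. Events that do not fall inside a dive (i.e. shallower than
#' the dive threshold) are flagged `excluded` and should be omitted from
#' downstream counts.
#'
#' @param events event data.frame from [detect_events()] (times in seconds
#'   on the same clock as the depth record).
#' @param seg a `dive_segmentation` from [segment_dives()].
#' @param depth depth series used for the segmentation (m).
#' @param fs sampling rate of `depth`, Hz (default 5).
#' @param t0 time of the first depth sample (default 0).
#' @return `events` with added columns `depth_m`, `dive_id`, `excluded`.
#' @export
contextualize_events <- function(events, seg, depth, fs = 5, t0 = 0) {
  if (nrow(events) == 0L) {
    events$depth_m <- numeric(); events$dive_id <- integer()
    events$excluded <- logical()
    return(events)
  }
  idx <- round((events$t_start - t0) * fs) + 1L
  if (any(idx < 1L | idx > length(depth)))
    stop("event outside the depth record")
  events$depth_m <- pmax(depth[idx], 0)
  d <- seg$dives
  events$dive_id <- vapply(events$t_start, function(tt) {
    k <- which(tt >= d$t_start & tt <= d$t_end)
    if (length(k) == 1L) d$id[k] else NA_integer_
  }, integer(1))
  events$excluded <- is.na(events$dive_id)
  events
}

#' Estimate a jerk detection threshold from a bimodal RMS distribution
#'
#' Fits a kernel density to `log(rms)` and returns the antilog of the
#' deepest valley between the two largest modes. Intended for exploring new
#' datasets; the default detector threshold stays at 150 m/s^3.
#'
#' @param rms positive RMS-jerk values.
#' @return Threshold in m/s^3, or NA when no interior valley exists.
#' @export
estimate_jerk_threshold <- function(rms) {
  rms <- rms[rms > 0]
  if (length(rms) < 10L) return(NA_real_)
  d <- stats::density(log(rms), n = 512L)
  y <- d$y
  is_min <- which(diff(sign(diff(y))) == 2) + 1L
  if (length(is_min) == 0L) return(NA_real_)
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_max) < 2L) return(NA_real_)
  m <- sort(is_max[order(y[is_max], decreasing = TRUE)][1:2])
  valley <- is_min[is_min > m[1] & is_min < m[2]]
  if (length(valley) == 0L) return(NA_real_)
  exp(d$x[valley[which.min(y[valley])]])
}
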