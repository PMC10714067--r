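# Conventions used throughout the orientation code:
# body axes x forward, y left, z dorsal (up); world frame (east, north, up).
# pitch = rotation about the lateral axis, positive nose-up;
# roll  = rotation about the antero-posterior axis;
# heading = compass angle of the body x axis, 0 = magnetic north,
# negative = leftward (counter-clockwise seen from above), in (-180, 180].

#' Body-to-world rotation matrix from pitch, roll, heading
#'
#' @param pitch,roll,heading angles in degrees (see conventions above).
#' @return 3 x 3 rotation matrix mapping body coordinates to (east, north,
#'   up) world coordinates.
#' @export
orientation_matrix <- function(pitch, roll, heading) {
  th <- deg2rad(pitch); ph <- deg2rad(roll); al <- deg2rad(90 - heading)
  Rz <- matrix(c(cos(al), sin(al), 0, -sin(al), cos(al), 0, 0, 0, 1), 3L)
  Ry <- matrix(c(cos(-th), 0, -sin(-th), 0, 1, 0, sin(-th), 0, cos(-th)), 3L)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3L)
  Rz %*% Ry %*% Rx
}

#' Pitch, roll and heading from accelerometer and magnetometer
#'
#' The static (gravitational) component of the acceleration is isolated by
#' a zero-phase low-pass filter; pitch and roll follow from the gravity
#' direction, and heading from the tilt-compensated magnetic field,
#' optionally corrected for declination. Samples whose static acceleration
#' magnitude deviates from g by more than 30% are flagged unreliable.
#'
#' @param accel n x 3 calibrated acceleration (m/s^2), body axes as above;
#'   a device at rest and level reads (0, 0, g).
#' @param mag n x 3 calibrated magnetic field on the same time base.
#' @param fs sampling rate, Hz.
#' @param lp_cutoff low-pass cutoff for the static component, Hz
#'   (default 0.5); use NA to skip filtering.
#' @param declination magnetic declination added to the heading, degrees
#'   (default 0).
#' @param g gravitational acceleration (default 9.81 m/s^2).
#' @return data.frame with `pitch`, `roll`, `heading` (degrees, heading
#'   wrapped to (-180, 180]) and `reliable`.
#' @export
compute_orientation <- function(accel, mag, fs, lp_cutoff = 0.5,
                                declination = 0, g = 9.81) {
  accel <- as.matrix(accel); mag <- as.matrix(mag)
  stopifnot(ncol(accel) == 3L, ncol(mag) == 3L, nrow(accel) == nrow(mag))
  stat <- accel
  if (!is.na(lp_cutoff) && lp_cutoff < fs / 2 && nrow(accel) > 12L) {
    bf <- signal::butter(2, lp_cutoff / (fs / 2), type = "low")
    stat <- apply(accel, 2L, function(col) signal::filtfilt(bf, col))
  }
  amag <- sqrt(rowSums(stat^2))
  reliable <- abs(amag - g) <= 0.3 * g
  pitch <- asin(clamp(stat[, 1L] / g, -1, 1))
  roll <- atan2(stat[, 2L], stat[, 3L])
  cth <- cos(pitch); sth <- sin(pitch)
  cph <- cos(roll); sph <- sin(roll)
  m1y <- cph * mag[, 2L] - sph * mag[, 3L]
  m1z <- sph * mag[, 2L] + cph * mag[, 3L]
  m2x <- cth * mag[, 1L] - sth * m1z
  heading <- rad2deg(atan2(m1y, m2x))
  data.frame(pitch = rad2deg(pitch), roll = rad2deg(roll),
             heading = wrap_angle(heading + declination),
             reliable = reliable)
}

#' Dead-reckoned local 3D track
#'
#' Integrates heading and pitch with a depth-rate speed model: where the
#' body is steep enough (|pitch| > `pitch_min`) the speed along the body
#' axis is |depth rate| / |sin(pitch)| clamped to `speed_clamp`; elsewhere a
#' fallback constant speed drives the horizontal step and the vertical step
#' follows the measured depth, so the track stays depth-consistent.
#'
#' @param orientation data.frame from [compute_orientation()] sampled at
#'   `fs`.
#' @param depth depth series (m, positive down) on the same base.
#' @param fs sampling rate, Hz (default 5).
#' @param pitch_min pitch (deg) above which the depth-rate speed model is
#'   trusted (default 20).
#' @param speed_clamp speed bounds, m/s (default c(0.2, 3)).
#' @param fallback_speed speed used in flat swimming, m/s (default 1).
#' @return data.frame: `t` (s), `x` east, `y` north (m from start),
#'   `z` (m, down), `speed` and `model` ("depth_rate" or "fallback").
#' @export
dead_reckon <- function(orientation, depth, fs = 5, pitch_min = 20,
                        speed_clamp = c(0.2, 3), fallback_speed = 1) {
  n <- nrow(orientation)
  stopifnot(length(depth) == n)
  dt <- 1 / fs
  th <- deg2rad(orientation$pitch)
  ps <- deg2rad(orientation$heading)
  drate <- c(diff(depth), 0) * fs          # m/s, positive descending
  steep <- abs(orientation$pitch) > pitch_min
  s <- ifelse(steep,
              clamp(abs(drate) / pmax(abs(sin(th)), 1e-6),
                    speed_clamp[1L], speed_clamp[2L]),
              fallback_speed)
  dx <- s * dt * cos(th) * sin(ps)
  dy <- s * dt * cos(th) * cos(ps)
  dz <- ifelse(steep, -s * dt * sin(th), c(diff(depth), 0))
  data.frame(t = (seq_len(n) - 1L) * dt,
             x = cumsum(c(0, dx[-n])),
             y = cumsum(c(0, dy[-n])),
             z = depth[1L] + cumsum(c(0, dz[-n])),
             speed = s,
             model = ifelse(steep, "depth_rate", "fallback"))
}

#' Separate swimming strokes from other lateral movements
#'
#' Zero-phase band-pass filtering of the lateral acceleration isolates the
#' periodic flipper-stroke component; a low-pass below the band captures
#' the slow gravity/posture trend, and what remains (head turns and other
#' transients) goes to the residual channel.
#'
#' @param x lateral acceleration series (m/s^2).
#' @param fs sampling rate, Hz.
#' @param band stroke band in Hz (default c(0.4, 2.5)); must lie inside
#'   (0, fs/2).
#' @return List with `stroke`, `trend` and `residual`
#'   (`x = stroke + trend + residual`).
#' @export
filter_strokes <- function(x, fs, band = c(0.4, 2.5)) {
  if (length(band) != 2L || band[1L] <= 0 || band[2L] >= fs / 2 ||
      band[1L] >= band[2L]) stop("invalid stroke band")
  bp <- signal::butter(2, band * 2 / fs, type = "pass")
  stroke <- signal::filtfilt(bp, x)
  lp <- signal::butter(2, band[1L] / fs, type = "low")   # cutoff band[1]/2
  trend <- signal::filtfilt(lp, x)
  list(stroke = stroke, trend = trend, residual = x - stroke - trend)
}

#' Count flipper strokes as prominent peaks
#'
#' Counts local maxima of the filtered lateral acceleration whose
#' prominence (height above the higher of the bounding valleys up to the
#' nearest taller sample, or the record edge) reaches `amp_min`, enforcing
#' a minimum peak spacing (taller peaks win).
#'
#' @param x filtered stroke series (m/s^2).
#' @param fs sampling rate, Hz.
#' @param amp_min minimum prominence, m/s^2 (default 0.3).
#' @param min_spacing minimum peak separation, s (default 0.3).
#' @return Integer stroke count.
#' @export
count_strokes <- function(x, fs, amp_min = 0.3, min_spacing = 0.3) {
  n <- length(x)
  if (n < 3L) return(0L)
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (length(cand) == 0L) return(0L)
  prom <- vapply(cand, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1L)]
    higher <- which(left > h)
    lmin <- min(left[seq.int(if (length(higher)) max(higher) else 1L, i - 1L)])
    right <- x[seq.int(i + 1L, n)]
    higher <- which(right > h)
    rmin <- min(right[seq_len(if (length(higher)) min(higher) else length(right))])
    h - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= amp_min]
  if (length(keep) <= 1L) return(length(keep))
  ord <- keep[order(x[keep], decreasing = TRUE)]
  min_gap <- round(min_spacing * fs)
  taken <- integer(0)
  for (i in ord) {
    if (all(abs(taken - i) >= min_gap)) taken <- c(taken, i)
  }
  length(taken)
}

#' Detect a head turn around a prey reaction
#'
#' The net wrapped heading change over +-`half_window` seconds around the
#' reaction time (accumulated sample-to-sample so the +-180 wrap causes no
#' spurious turns) is compared with `angle_min`: clearly negative = left
#' turn, clearly positive = right turn, otherwise none.
#'
#' @param heading heading series in degrees, sampled at `fs` from time
#'   `t0`.
#' @param fs sampling rate, Hz.
#' @param t_reaction reaction time on the same clock, s.
#' @param half_window window half width, s (default 1).
#' @param angle_min minimum net change to call a turn, degrees (default 10).
#' @param t0 time of the first heading sample (default 0).
#' @return "left", "right" or "none".
#' @export
detect_head_turn <- function(heading, fs, t_reaction, half_window = 1,
                             angle_min = 10, t0 = 0) {
  i1 <- round((t_reaction - half_window - t0) * fs) + 1L
  i2 <- round((t_reaction + half_window - t0) * fs) + 1L
  if (i1 < 1L || i2 > length(heading)) stop("window outside the heading record")
  net <- sum(wrap_angle(diff(heading[i1:i2])))
  if (net <= -angle_min) "left" else if (net >= angle_min) "right" else "none"
}

#' Characterize approach windows around capture attempts
#'
#' For every capture attempt with a reactive prey trace, examines the
#' window from 10 s before the event start to 5 s after its end: when the
#' prey reacted relative to the event (before / during / after), whether
#' the seal was stroking in the 5 s before the reaction and kept stroking
#' during the event, and the head-turn direction within +-1 s of the
#' reaction.
#'
#' @param events contextualized event data.frame (needs `id`, `t_start`,
#'   `t_end`, `duration_s`).
#' @param prey per-echogram analysis rows (needs `prca_id`, `reaction`,
#'   `onset_time_s`); only reactive rows are used.
#' @param heading heading series (deg) at `fs_or` from time `t0`.
#' @param stroke filtered stroke series at `fs_acc` from time `t0`.
#' @param fs_or,fs_acc sampling rates of the two series, Hz.
#' @param t0 series start time, s (default 0).
#' @param amp_min,min_spacing stroke-counting parameters
#'   (see [count_strokes()]).
#' @param angle_min head-turn threshold, degrees (default 10).
#' @return data.frame with one row per reactive capture attempt:
#'   `prca_id`, `reaction`, `timing` (before/during/after),
#'   `strokes_before`, `strokes_during` (logical), `turn`.
#' @export
build_approach_windows <- function(events, prey, heading, stroke,
                                   fs_or, fs_acc, t0 = 0,
                                   amp_min = 0.3, min_spacing = 0.3,
                                   angle_min = 10) {
  re <- prey[!is.na(prey$reaction) &
               prey$reaction %in% c("escape", "leave_seafloor"), , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(re))) {
    ev <- events[events$id == re$prca_id[i], , drop = FALSE]
    if (nrow(ev) != 1L || is.na(re$onset_time_s[i])) next
    t_re <- ev$t_start + re$onset_time_s[i]
    timing <- if (re$onset_time_s[i] < 0) "before"
              else if (re$onset_time_s[i] <= ev$duration_s) "during"
              else "after"
    seg <- function(x, fs, ta, tb) {
      a <- max(1L, round((ta - t0) * fs) + 1L)
      b <- min(length(x), round((tb - t0) * fs) + 1L)
      if (b <= a) numeric(0) else x[a:b]
    }
    sb <- count_strokes(seg(stroke, fs_acc, t_re - 5, t_re), fs_acc,
                        amp_min, min_spacing) > 0L
    sd_ <- count_strokes(seg(stroke, fs_acc, ev$t_start, ev$t_end), fs_acc,
                         amp_min, min_spacing) > 0L
    turn <- tryCatch(
      detect_head_turn(heading, fs_or, t_re, angle_min = angle_min, t0 = t0),
      error = function(e) NA_character_)
    out[[length(out) + 1L]] <- data.frame(
      prca_id = re$prca_id[i], reaction = re$reaction[i], timing = timing,
      strokes_before = sb, strokes_during = sd_, turn = turn,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(prca_id = integer(), reaction = character(),
                      timing = character(), strokes_before = logical(),
                      strokes_during = logical(), turn = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Summarize approach behavior by reaction type
#'
#' Tabulates, per reaction type and pooled: the number of capture attempts,
#' the percentage of reactions before / during / after the event, the
#' percentage with strokes in the 5 s before the reaction, with strokes
#' continuing during the event, and with left / right head turns.
#'
#' @param windows data.frame from [build_approach_windows()].
#' @param digits rounding for percentages (default 0).
#' @return data.frame with one row per reaction type plus a `total` row.
#' @export
summarize_approach <- function(windows, digits = 0) {
  if (nrow(windows) == 0L) {
    return(data.frame(reaction = character(), n = integer()))
  }
  one <- function(df, label) {
    p <- function(x) round(100 * mean(x), digits)
    data.frame(reaction = label, n = nrow(df),
               pct_before = p(df$timing == "before"),
               pct_during = p(df$timing == "during"),
               pct_after = p(df$timing == "after"),
               pct_strokes_before = p(df$strokes_before),
               pct_strokes_during = p(df$strokes_during),
               pct_left = p(!is.na(df$turn) & df$turn == "left"),
               pct_right = p(!is.na(df$turn) & df$turn == "right"),
               stringsAsFactors = FALSE)
  }
  types <- intersect(c("escape", "leave_seafloor"), unique(windows$reaction))
  parts <- lapply(types, function(ty)
    one(windows[windows$reaction == ty, , drop = FALSE], ty))
  out <- do.call(rbind, c(parts, list(one(windows, "total"))))
  rownames(out) <- NULL
  out
}
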