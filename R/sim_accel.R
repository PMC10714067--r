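#' Simulate triaxial acceleration with stroke and capture-attempt structure
#'
#' The baseline is the gravity projection for the supplied pitch schedule
#' (level posture when omitted) plus sinusoidal lateral flipper strokes
#' during dives and a sub-threshold broadband noise floor whose slowly
#' varying amplitude follows a log-normal regime. During each scheduled
#' capture attempt, broadband bursts on all three axes push the RMS-jerk
#' above the detection threshold for the scheduled duration; elsewhere the
#' RMS-jerk stays well below it.
#'
#' The white-noise amplitude `sigma` that yields a target RMS-jerk `J` at
#' sampling rate `fs` is `J / (fs * sqrt(6))` (forward difference of
#' independent noise on three axes).
#'
#' @param duration_s record length, s.
#' @param fs sampling rate, Hz (must be 200 or 250).
#' @param dives data.frame with `t_start`, `t_end` of dives (strokes occur
#'   inside them); may be empty.
#' @param prcas data.frame with `t_start`, `t_end` of capture attempts (may
#'   be empty); an optional `amp` column overrides the event RMS-jerk.
#' @param config a [sim_config()].
#' @param pitch optional pitch schedule in degrees at `fs` (recycled or
#'   interpolated to length); tilts the gravity baseline.
#' @param stroke_gate optional logical vector at `fs`: FALSE suppresses
#'   strokes at that sample (used to realise scheduled stroke pauses).
#' @return Matrix n x 3 of acceleration in m/s^2.
#' @export
simulate_acceleration <- function(duration_s, fs, dives = NULL, prcas = NULL,
                                  config = sim_config(), pitch = NULL,
                                  stroke_gate = NULL) {
  if (!fs %in% c(200, 250)) stop("fs must be 200 or 250 Hz")
  n <- round(duration_s * fs)
  if (n == 0L) return(matrix(numeric(0), 0L, 3L,
                             dimnames = list(NULL, c("ax", "ay", "az"))))
  g <- 9.81
  t <- (seq_len(n) - 1L) / fs
  if (is.null(pitch)) pitch <- rep(0, n)
  if (length(pitch) != n)
    pitch <- stats::approx(seq(0, 1, length.out = length(pitch)),
                           pitch, xout = seq(0, 1, length.out = n))$y
  th <- deg2rad(pitch)
  acc <- cbind(ax = g * sin(th), ay = rep(0, n), az = g * cos(th))

  # flipper strokes: lateral sinusoid inside dives
  if (!is.null(dives) && nrow(dives) > 0L) {
    gate <- rep(FALSE, n)
    for (i in seq_len(nrow(dives))) {
      a <- max(1L, floor(dives$t_start[i] * fs) + 1L)
      b <- min(n, ceiling(dives$t_end[i] * fs))
      if (b >= a) gate[a:b] <- TRUE
    }
    if (!is.null(stroke_gate)) gate <- gate & stroke_gate
    acc[gate, "ay"] <- acc[gate, "ay"] +
      config$stroke_amp * sin(2 * pi * config$stroke_freq * t[gate])
  }

  # sub-threshold noise floor with a slow log-normal amplitude regime
  sigma_for <- function(rms_jerk) rms_jerk / (fs * sqrt(6))
  block <- 30 * fs
  n_blocks <- ceiling(n / block)
  amp <- rep(stats::rlnorm(n_blocks, log(config$jerk_noise_amp), 0.1),
             each = block)[seq_len(n)]
  noise <- matrix(stats::rnorm(3L * n), n, 3L) * sigma_for(amp)
  acc <- acc + noise

  # capture-attempt bursts: log-normal supra-threshold amplitude regime
  if (!is.null(prcas) && nrow(prcas) > 0L) {
    for (i in seq_len(nrow(prcas))) {
      a <- max(1L, floor(prcas$t_start[i] * fs) + 1L)
      b <- min(n, ceiling(prcas$t_end[i] * fs))
      if (b < a) next
      amp_i <- if (!is.null(prcas$amp)) prcas$amp[i] else
        stats::rlnorm(1, log(config$jerk_event_amp), 0.15)
      m <- b - a + 1L
      acc[a:b, ] <- acc[a:b, ] +
        matrix(stats::rnorm(3L * m), m, 3L) * sigma_for(amp_i)
    }
  }
  acc
}
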