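#' Simulate the echogram of one capture-attempt window
#'
#' Builds an ENR image spanning 5 s before the capture-attempt start to 5 s
#' after its end at the sonar ping rate: a noise floor, a seafloor ridge
#' when the attempt is benthic, and -- when a prey trace is scheduled -- an
#' echo with the scheduled geometry:
#' \itemize{
#'   \item `leave_seafloor`: a straight trace of negative slope departing
#'     from the seafloor ridge at the scheduled onset time and range;
#'   \item `escape`: a stationary echo clear of the seafloor that follows a
#'     curved (range decreasing then increasing) path from the onset;
#'   \item `none`: a range-stationary blob;
#' }
#' schooling prey add a second disjoint echo sharing ping columns. The
#' supra-threshold pixel extent of the trace in each ping column matches the
#' scheduled acoustic size.
#'
#' @param prey list/row describing the scheduled interaction: `duration_s`
#'   (capture-attempt duration), `benthic`, `visible`, `reaction` (one of
#'   "none", "escape", "leave_seafloor"), `onset_time_s` (relative to the
#'   attempt start, may be negative), `onset_range_cm`, `size_cm`, `school`.
#' @param config a [sim_config()].
#' @param prca_id id stored on the echogram (default NA).
#' @return List: `echogram` (an [compute_enr()] object, window clock with 0
#'   at the attempt start) and `truth` (the scheduled values actually
#'   realised, with onset time clamped into the window).
#' @export
simulate_echogram <- function(prey, config = sim_config(), prca_id = NA) {
  if (config$range_resolution <= 0) stop("range_resolution must be positive")
  res <- config$range_resolution
  nb <- round(config$range_max / res)
  dur <- prey$duration_s
  ping_t <- seq(-5, dur + 5, by = 1 / config$ping_rate)
  np <- length(ping_t)

  noise_ref <- matrix(20, np, nb)          # flat background noise estimate
  echo <- noise_ref + matrix(stats::rnorm(np * nb, 0, config$noise_floor_db),
                             np, nb)
  add_band <- function(p, lo_bin, hi_bin, level) {
    lo_bin <- max(1L, lo_bin); hi_bin <- min(nb, hi_bin)
    if (hi_bin >= lo_bin)
      echo[p, lo_bin:hi_bin] <<- noise_ref[p, lo_bin:hi_bin] + level +
        stats::rnorm(hi_bin - lo_bin + 1L, 0, 1)
  }

  truth <- list(benthic = isTRUE(prey$benthic),
                visible = isTRUE(prey$visible),
                reaction = if (isTRUE(prey$visible)) prey$reaction else NA_character_,
                school = isTRUE(prey$school),
                onset_time_s = NA_real_, onset_range_cm = NA_real_,
                size_cm = NA_real_, seafloor_range_m = NA_real_)

  size_m <- if (isTRUE(prey$visible)) prey$size_cm / 100 else NA_real_
  onset_r <- if (isTRUE(prey$visible)) prey$onset_range_cm / 100 else NA_real_
  # reactive onsets are kept early enough that the reaction geometry fits
  # inside the +-5 s analysis window
  onset_t <- if (isTRUE(prey$visible) && !is.na(prey$onset_time_s))
    clamp(prey$onset_time_s, -4.5, dur + 2) else NA_real_

  # trace geometry first (the escape floor is placed just below the path)
  trace_t <- numeric(0); trace_r <- numeric(0)
  reaction <- truth$reaction
  if (isTRUE(prey$visible)) {
    if (is.na(reaction) || reaction == "none") {
      r0 <- if (!is.na(onset_r)) onset_r else stats::runif(1, 0.3, 1.2)
      span <- stats::runif(1, 1.2, 3)
      tc <- stats::runif(1, -2, dur + 2)
      trace_t <- ping_t[ping_t >= tc - span / 2 & ping_t <= tc + span / 2]
      trace_r <- rep(r0, length(trace_t))
      truth$onset_range_cm <- 100 * r0
    } else if (reaction == "leave_seafloor") {
      v <- stats::runif(1, 0.12, 0.3)
      tend <- min(onset_t + stats::runif(1, 1.5, 3), dur + 4.8)
      trace_t <- ping_t[ping_t >= onset_t & ping_t <= tend]
      trace_r <- pmax(onset_r - v * (trace_t - onset_t), 0.05)
      truth$onset_time_s <- onset_t
      truth$onset_range_cm <- 100 * onset_r
    } else { # escape
      tau <- stats::runif(1, 0.7, 1.2)
      v0 <- min(stats::runif(1, 0.15, 0.3), 0.6 * onset_r / tau)
      pre <- stats::runif(1, 0.6, 1.5)
      t_lo <- max(onset_t - pre, -5)
      t_hi <- min(onset_t + 2.4 * tau, dur + 4.8)
      trace_t <- ping_t[ping_t >= t_lo & ping_t <= t_hi]
      u <- pmax(trace_t - onset_t, 0)
      trace_r <- pmax(onset_r - v0 * u + (v0 / (2 * tau)) * u^2, 0.05)
      truth$onset_time_s <- onset_t
      truth$onset_range_cm <- 100 * onset_r
    }
    truth$size_cm <- prey$size_cm
  }

  # seafloor ridge
  floor_r <- NULL
  if (isTRUE(prey$benthic)) {
    base <- if (isTRUE(prey$visible) && !is.na(reaction) &&
                reaction == "leave_seafloor") {
      onset_r
    } else if (isTRUE(prey$visible) && !is.na(reaction) && reaction == "escape") {
      max(trace_r) + stats::runif(1, 0.13, 0.3)
    } else if (isTRUE(prey$visible)) {
      max(trace_r) + stats::runif(1, 0.2, 0.5)
    } else {
      stats::runif(1, 0.5, 1.5)
    }
    base <- min(base, config$range_max - 0.5)
    wig <- stats::filter(stats::rnorm(np, 0, 0.002), rep(1, 5), sides = 2)
    wig[is.na(wig)] <- 0
    floor_r <- base + cumsum(as.numeric(wig))
    floor_r <- clamp(floor_r, base - 0.02, base + 0.02)
    truth$seafloor_range_m <- base
    fb <- round(floor_r / res)
    for (p in seq_len(np))
      add_band(p, fb[p], fb[p] + round(0.35 / res),
               config$seafloor_enr_db + stats::rnorm(1, 0, 1))
  }

  put_trace <- function(tt, rr, sz) {
    for (k in seq_along(tt)) {
      p <- which.min(abs(ping_t - tt[k]))
      lo <- round(rr[k] / res)
      add_band(p, lo, lo + round(sz / res) - 1L, config$prey_enr_db)
    }
  }
  if (length(trace_t) > 0L) {
    put_trace(trace_t, trace_r, size_m)
    if (isTRUE(prey$school)) {
      # second echo shallower than the first, clear of it and of the floor
      off <- size_m + stats::runif(1, 0.08, 0.2)
      put_trace(trace_t, pmax(trace_r - off, 0.03), size_m)
    }
  }

  eg <- compute_enr(echo, noise_ref[1L, ], ping_t = ping_t, range_res = res,
                    prca_id = prca_id, t_prca_start = 0)
  list(echogram = eg, truth = truth)
}
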