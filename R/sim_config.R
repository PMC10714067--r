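#' Simulation configuration for synthetic deployments
#'
#' Builds and validates the parameter set driving the synthetic-deployment
#' generator. Defaults emulate the statistical structure of a lactating
#' Weddell seal sonar-tag deployment: dive depth/duration statistics and
#' foraging rates, capture-attempt depths of 88 +- 30 m, a bimodal RMS-jerk
#' regime around the 150 m/s^3 detection threshold, 25 Hz pings over a 7 m
#' sonar range at 1 cm/bin, prey reaction distances of 51 +- 18 cm within
#' [16, 121] cm, reaction onset times of 9 +- 7 s (negative = before the
#' capture attempt), acoustic sizes of 5 +- 1 cm within [3, 13] cm, and
#' approach-behaviour rates (strokes before/during, left/right head turns).
#'
#' @param ... named overrides of any default listed below.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_individuals = 3L,
    duration_hours = 2,
    accel_fs = 200,
    mag_depth_fs = 50,
    analysis_fs = 5,
    dive_rate = 7,                       # dives per in-water hour
    archetype_weights = c(0.10, 0.26, 0.11, 0.25, 0.28),
    depth_mean_sd = rbind(c(60, 30), c(90, 35), c(50, 25), c(90, 35), c(20, 8)),
    duration_mean_sd = c(7, 8),          # minutes
    duration_range = c(0.3, 55),         # minutes
    frac_foraging = 0.0913,
    prca_per_foraging_dive = 4,
    prca_depth_mean_sd = c(88, 30),      # m
    prca_duration_range = c(5.5, 12),    # s
    jerk_event_amp = 400,                # supra-threshold RMS-jerk, m/s^3
    jerk_noise_amp = 30,                 # sub-threshold RMS-jerk, m/s^3
    stroke_freq = 1,                     # Hz
    stroke_amp = 1.5,                    # m/s^2
    ping_rate = 25,                      # Hz
    range_max = 7,                       # m
    range_resolution = 0.01,             # m per bin
    noise_floor_db = 2.5,                # SD of ENR noise, dB
    seafloor_enr_db = 25,
    prey_enr_db = 18,
    enr_threshold = 9,
    p_benthic = 0.98,
    p_trace_visible = 0.38,
    p_reactive = 0.56,
    p_leave_seafloor = 0.70,
    p_school = 2 / 125,
    reaction_distance_mean_sd = c(51, 18),   # cm
    reaction_distance_range = c(16, 121),    # cm
    reaction_time_mean_sd = c(9, 7),         # s, relative to event start
    acoustic_size_mean_sd = c(5, 1),         # cm
    acoustic_size_range = c(3, 13),          # cm
    p_strokes_before = 0.74,
    p_strokes_during = 0.79,
    p_turn_left = 0.43,
    p_turn_right = 0.27,
    gps_per_day = 30,
    gps_step_km = 0.2,
    max_radius_km = 3,
    colony = c(lat = -66.665, lon = 140.01),
    mag_field = c(h = 18, u = 55),       # uT, horizontal / upward components
    echograms = TRUE,
    # optional exact totals (per individual or scalar totals); NULL = random
    n_dives = NULL,
    n_foraging_dives = NULL,
    n_prca_total = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown sim_config fields: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (!cfg$accel_fs %in% c(200, 250)) stop("accel_fs must be 200 or 250")
  probs <- c(cfg$p_benthic, cfg$p_trace_visible, cfg$p_reactive,
             cfg$p_leave_seafloor, cfg$p_school, cfg$p_strokes_before,
             cfg$p_strokes_during, cfg$p_turn_left, cfg$p_turn_right,
             cfg$frac_foraging)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (cfg$p_turn_left + cfg$p_turn_right > 1)
    stop("turn probabilities must sum to at most 1")
  if (any(cfg$archetype_weights < 0) || length(cfg$archetype_weights) != 5L)
    stop("archetype_weights must be 5 non-negative values")
  cfg$archetype_weights <- cfg$archetype_weights / sum(cfg$archetype_weights)
  sds <- c(cfg$depth_mean_sd[, 2L], cfg$duration_mean_sd[2L],
           cfg$prca_depth_mean_sd[2L], cfg$reaction_distance_mean_sd[2L],
           cfg$reaction_time_mean_sd[2L], cfg$acoustic_size_mean_sd[2L])
  if (any(sds < 0)) stop("standard deviations must be non-negative")
  if (cfg$range_resolution <= 0) stop("range_resolution must be positive")
  if (cfg$duration_hours < 0) stop("duration_hours must be non-negative")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: %d individuals x %g h, accel %g Hz, ",
                     "%g dives/h, foraging fraction %.3f\n"),
              x$n_individuals, x$duration_hours, x$accel_fs, x$dive_rate,
              x$frac_foraging))
  invisible(x)
}
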