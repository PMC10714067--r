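# shared fixtures, all generated in code

# small acceleration record with known injected events
make_accel_fixture <- function(events, duration_s = 60, fs = 200,
                               cfg = sim_config()) {
  dives <- data.frame(t_start = 0, t_end = duration_s)
  simulate_acceleration(duration_s, fs, dives = dives, prcas = events,
                        config = cfg)
}

# archetype population of dive profiles with Table-1-style depth statistics
make_archetype_profiles <- function(n, weights = rep(0.2, 5)) {
  arch <- sample.int(5L, n, replace = TRUE, prob = weights)
  depth_ms <- rbind(c(60, 30), c(90, 35), c(50, 25), c(90, 35), c(20, 8))
  profs <- lapply(arch, function(a) {
    md <- sealforage:::rtruncnorm(1, depth_ms[a, 1], depth_ms[a, 2], 6, 330)
    simulate_dive_profile(a, md, stats::runif(1, 120, 600), fs = 5)
  })
  list(archetype = arch, profiles = profs)
}

# one scheduled prey interaction for the echogram simulator
make_prey_spec <- function(reaction = "leave_seafloor", duration_s = 8,
                           onset_time_s = 2, onset_range_cm = 51,
                           size_cm = 5, benthic = TRUE, visible = TRUE,
                           school = FALSE) {
  list(duration_s = duration_s, benthic = benthic, visible = visible,
       reaction = reaction, onset_time_s = onset_time_s,
       onset_range_cm = onset_range_cm, size_cm = size_cm, school = school)
}
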