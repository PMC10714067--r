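test_that("config validation enforces ranges and normalizes weights", {
  cfg <- sim_config(archetype_weights = c(2, 2, 2, 2, 2))
  expect_equal(cfg$archetype_weights, rep(0.2, 5))
  expect_error(sim_config(accel_fs = 100), "200 or 250")
  expect_error(sim_config(p_reactive = 1.2), "probabilities")
  expect_error(sim_config(range_resolution = 0), "positive")
  expect_error(sim_config(not_a_field = 1), "unknown")
})

test_that("simulated acceleration honours the jerk regimes", {
  set.seed(60)
  cfg <- sim_config()
  # no events: whole record stays below the detection threshold
  acc <- simulate_acceleration(40, 200, dives = data.frame(t_start = 0, t_end = 40),
                               config = cfg)
  r <- rms_jerk(compute_jerk(acc, 200), 200)
  expect_lt(max(r), 150)

  # no strokes, no events, constant posture: jerk is essentially zero
  cfg0 <- sim_config(stroke_amp = 0, jerk_noise_amp = 0.1)
  acc0 <- simulate_acceleration(10, 200, config = cfg0)
  expect_lt(max(rms_jerk(compute_jerk(acc0, 200), 200)), 1)

  # a single injected 6 s event is found by the detector, once
  set.seed(61)
  for (rep in 1:20) {
    acc1 <- simulate_acceleration(
      60, 200, dives = data.frame(t_start = 0, t_end = 60),
      prcas = data.frame(t_start = 25, t_end = 31), config = cfg)
    det <- detect_prca(acc1, 200)
    ov <- pmin(det$t_end, 31) - pmax(det$t_start, 25)
    expect_equal(sum(ov > 0), 1L)
  }
  expect_error(simulate_acceleration(10, 123, config = cfg), "200 or 250")
})

test_that("scheduled prey distributions are recovered within 2 SE at n = 500", {
  set.seed(62)
  cfg <- sim_config()
  n <- 500
  dist <- sealforage:::rtruncnorm(n, 51, 18, 16, 121)
  tim <- rnorm(n, 9, 7)
  sz <- sealforage:::rtruncnorm(n, 5, 1, 3, 13)
  # the truncated draws should sit near the configured centres
  expect_lt(abs(mean(dist) - 51), 2 * 18 / sqrt(n) + 2)  # truncation shift allowance
  expect_lt(abs(mean(tim) - 9), 2 * 7 / sqrt(n))
  expect_lt(abs(mean(sz) - 5), 2 * 1 / sqrt(n) + 0.1)
  expect_true(all(dist >= 16 & dist <= 121))
  expect_true(all(sz >= 3 & sz <= 13))
})

test_that("leave-seafloor traces depart the ridge at the scheduled bin", {
  set.seed(63)
  cfg <- sim_config()
  sim <- simulate_echogram(make_prey_spec("leave_seafloor",
                                          onset_range_cm = 51), cfg)
  sf <- detect_seafloor(sim$echogram)
  expect_lt(abs(stats::median(sf$range, na.rm = TRUE) - 0.51), 0.03)
  row <- analyze_echogram(sim$echogram)
  expect_equal(row$reaction, "leave_seafloor")
  expect_lt(abs(row$onset_range_cm - 51), 5)
  expect_error(
    simulate_echogram(make_prey_spec(), sim_config(range_resolution = 0)),
    "positive")
})

test_that("acoustic size maps to contiguous pixels per trace column", {
  set.seed(64)
  cfg <- sim_config()   # 1 cm per bin
  sim <- simulate_echogram(make_prey_spec("escape", onset_range_cm = 80,
                                          size_cm = 5), cfg)
  sf <- detect_seafloor(sim$echogram)
  tr <- extract_prey_traces(sim$echogram, sf)
  main <- tr$traces[[which.max(vapply(tr$traces, function(x)
    length(x$pings), integer(1)))]]
  E <- sim$echogram$enr
  ext <- vapply(sort(unique(main$pings)), function(p) {
    above <- E[p, ] >= 9
    r <- rle(above); ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    tb <- main$bins[main$pings == p][1]
    k <- which(r$values & starts <= tb & ends >= tb)
    r$lengths[k[1]]
  }, numeric(1))
  expect_equal(stats::median(ext), 5)
})

test_that("deployments are deterministic under seed and consistent with truth", {
  cfg <- sim_config(duration_hours = 0.3, n_individuals = 2)
  d1 <- simulate_deployment(cfg, seed = 5)
  d2 <- simulate_deployment(cfg, seed = 5)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$individuals[[1]]$sensors$accel,
                   d2$individuals[[1]]$sensors$accel)
  d3 <- simulate_deployment(cfg, seed = 6)
  expect_false(identical(d1$truth$dives, d3$truth$dives))

  # every labelled capture attempt lies inside a labelled dive
  cfg2 <- sim_config(duration_hours = 0.5, n_individuals = 1,
                     n_dives = 4, n_foraging_dives = 2, n_prca_total = 5)
  dep <- simulate_deployment(cfg2, seed = 7)
  tp <- dep$truth$prca; td <- dep$truth$dives
  expect_equal(nrow(tp), 5L)
  expect_equal(nrow(td), 4L)
  expect_equal(sum(td$foraging), 2L)
  for (i in seq_len(nrow(tp))) {
    d <- td[td$individual == tp$individual[i] & td$id == tp$dive_id[i], ]
    expect_gte(tp$t_start[i], d$t_start)
    expect_lte(tp$t_end[i], d$t_end)
  }
  expect_true(all(is.na(tp$onset_range_cm) |
                    (tp$onset_range_cm >= 0 & tp$onset_range_cm <= 700)))
  expect_true(all(is.na(tp$reaction) |
                    tp$reaction %in% c("none", "escape", "leave_seafloor")))

  # zero-duration deployment: empty streams, empty truth
  dep0 <- simulate_deployment(sim_config(duration_hours = 0,
                                         n_individuals = 1), seed = 1)
  expect_equal(nrow(dep0$individuals[[1]]$sensors$accel), 0L)
  expect_equal(nrow(dep0$truth$dives), 0L)
})

test_that("requested dive/foraging/event totals are honoured exactly", {
  cfg <- sim_config(n_individuals = 3, n_dives = c(10, 6, 8),
                    n_foraging_dives = c(3, 1, 2),
                    n_prca_total = c(9, 2, 5),
                    duration_hours = 1, echograms = FALSE)
  dep <- simulate_deployment(cfg, seed = 8)
  td <- dep$truth$dives; tp <- dep$truth$prca
  expect_equal(as.integer(table(td$individual)), c(10L, 6L, 8L))
  expect_equal(as.integer(table(factor(tp$individual, 1:3))), c(9L, 2L, 5L))
  expect_equal(sum(td$foraging), 6L)
})

test_that("the movement chain reproduces ground-truth dive metrics", {
  cfg <- sim_config(duration_hours = 0.4, n_individuals = 1,
                    n_dives = 5, n_foraging_dives = 2, n_prca_total = 6,
                    echograms = FALSE)
  dep <- simulate_deployment(cfg, seed = 9)
  proc <- process_deployment(dep)
  td <- dep$truth$dives
  expect_equal(nrow(proc$dives), nrow(td))
  # max depths agree within a sample; each scheduled dive contains exactly
  # one detected dive (detection starts at the 5 m crossing, after the
  # scheduled surfacing moment)
  expect_lt(max(abs(sort(proc$dives$max_depth) - sort(td$max_depth))), 1)
  for (i in seq_len(nrow(td))) {
    inside <- proc$dives$t_start >= td$t_start[i] - 0.2 &
      proc$dives$t_end <= td$t_end[i] + 0.2
    expect_equal(sum(inside), 1L)
  }

  # per-dive detected event counts match the schedule
  ev <- proc$events[!proc$events$excluded, ]
  tp <- dep$truth$prca
  expect_equal(nrow(ev), nrow(tp))
  expect_equal(sum(!is.na(ev$matched_prca)), nrow(tp))
  # segmentation idempotence: re-segmenting the profiles returns them unchanged
  seg <- proc$segs[[1]]
  for (k in seq_along(seg$profiles)) {
    p <- seg$profiles[[k]]
    seg2 <- segment_dives(c(0, p, 0), fs = 5)
    expect_equal(nrow(seg2$dives), 1L)
    expect_equal(seg2$dives$max_depth, max(p))
  }
})

test_that("deployment files round-trip through the directory layout", {
  cfg <- sim_config(duration_hours = 0.2, n_individuals = 1,
                    n_dives = 2, n_foraging_dives = 1, n_prca_total = 1)
  dep <- simulate_deployment(cfg, seed = 10)
  dir <- file.path(tempdir(), "dep_io_test")
  write_deployment(dep, dir)
  expect_true(file.exists(file.path(dir, "individual_1", "accel.csv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  sb <- read_sensor_bundle(file.path(dir, "individual_1"),
                           accel_fs = cfg$accel_fs)
  expect_equal(dim(sb$accel), dim(dep$individuals[[1]]$sensors$accel))
  expect_equal(sb$magdepth$depth, dep$individuals[[1]]$sensors$magdepth$depth,
               tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
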