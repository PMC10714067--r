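test_that("orientation round-trips a synthetic rotation", {
  g <- 9.81; B <- c(0, 18, 55)   # world (E, N, U) magnetic field
  cases <- expand.grid(pitch = c(-60, -30, 0, 30, 60),
                       roll = c(-40, 0, 40),
                       heading = c(-150, -90, 0, 45, 170))
  for (i in seq_len(nrow(cases))) {
    R <- orientation_matrix(cases$pitch[i], cases$roll[i], cases$heading[i])
    a <- matrix(rep(t(R) %*% c(0, 0, g), each = 10), ncol = 3)
    m <- matrix(rep(t(R) %*% B, each = 10), ncol = 3)
    o <- compute_orientation(a, m, fs = 5, lp_cutoff = NA)
    expect_lt(abs(o$pitch[1] - cases$pitch[i]), 0.5)
    expect_lt(abs(o$roll[1] - cases$roll[i]), 0.5)
    expect_lt(abs(wrap_angle(o$heading[1] - cases$heading[i])), 1)
  }
  # level pose pointing at magnetic north
  R0 <- orientation_matrix(0, 0, 0)
  o <- compute_orientation(matrix(t(R0) %*% c(0, 0, g), 1),
                           matrix(t(R0) %*% B, 1), fs = 5, lp_cutoff = NA)
  expect_equal(unlist(o[1, 1:3]), c(pitch = 0, roll = 0, heading = 0),
               tolerance = 1e-9)
  # far-from-g samples are flagged unreliable
  o2 <- compute_orientation(matrix(c(0, 0, 2 * g), 1), matrix(B, 1),
                            fs = 5, lp_cutoff = NA)
  expect_false(o2$reliable[1])
})

test_that("a full heading sweep is recovered without unwrap artefacts", {
  g <- 9.81; B <- c(0, 18, 55)
  hs <- seq(-179, 180, by = 1)
  am <- t(vapply(hs, function(h) {
    R <- orientation_matrix(5, 0, h)
    c(t(R) %*% c(0, 0, g), t(R) %*% B)
  }, numeric(6)))
  o <- compute_orientation(am[, 1:3], am[, 4:6], fs = 5, lp_cutoff = NA)
  expect_lt(max(abs(wrap_angle(o$heading - hs))), 1)
})

test_that("dead reckoning integrates the kinematic model consistently", {
  # level northward swim at fallback speed: 10 m north in 10 s
  n <- 51
  orient <- data.frame(pitch = rep(0, n), roll = 0, heading = 0)
  tr <- dead_reckon(orient, rep(10, n), fs = 5, fallback_speed = 1)
  expect_equal(tr$y[n], 10, tolerance = 1e-6)
  expect_equal(tr$x[n], 0, tolerance = 1e-6)
  expect_equal(tr$z[n], 10)

  # steep descent with matching depth rate: z tracks depth within 5%
  depth <- 10 + (0:(n - 1)) * 0.2          # 1 m/s descent at 5 Hz
  orient <- data.frame(pitch = rep(-45, n), roll = 0, heading = 90)
  tr <- dead_reckon(orient, depth, fs = 5)
  expect_lt(max(abs(tr$z - depth)) / max(depth), 0.05)
  expect_equal(tr$model[1], "depth_rate")

  # out and back with reversed heading: no net horizontal displacement
  orient <- data.frame(pitch = 0, roll = 0,
                       heading = rep(c(45, -135), each = 25))
  tr <- dead_reckon(orient, rep(20, 50), fs = 5)
  expect_lt(abs(tr$x[50]), 0.3)
  expect_lt(abs(tr$y[50]), 0.3)
})

test_that("track depth consistency holds on a simulated dive", {
  set.seed(50)
  prof <- simulate_dive_profile(2, 60, 240, fs = 5)
  n <- length(prof)
  drate <- c(diff(prof), 0) * 5
  pitch <- -asin(pmax(pmin(drate / 1.3, 0.98), -0.98)) * 180 / pi
  orient <- data.frame(pitch = pitch, roll = 0, heading = 0)
  tr <- dead_reckon(orient, prof, fs = 5, fallback_speed = 1.3)
  expect_true(all(abs(tr$z - prof) <= pmax(1, 0.1 * prof)))
})

test_that("stroke filtering isolates the band and routes steps to residual", {
  fs <- 50
  t <- seq(0, 20, by = 1 / fs)
  s1 <- sin(2 * pi * 1 * t)
  out <- filter_strokes(s1, fs)
  expect_gt(max(out$stroke[200:800]) / 1, 0.95)   # in-band passes

  drift <- sin(2 * pi * 0.05 * t)
  out <- filter_strokes(drift, fs)
  expect_lt(max(abs(out$stroke[200:800])), 0.1)    # out-of-band attenuated >= 90%

  step <- ifelse(t > 10, 2, 0)
  out <- filter_strokes(s1 + step, fs)
  expect_gt(cor(out$stroke[100:900], s1[100:900]), 0.95)
  late <- t > 12 & t < 19; early <- t > 1 & t < 8
  expect_gt(mean((out$trend + out$residual)[late]) -
              mean((out$trend + out$residual)[early]), 1.5)
  expect_error(filter_strokes(s1, fs, band = c(0, 30)), "invalid")
})

test_that("stroke counting matches an exhaustive peak-scan oracle", {
  fs <- 50
  t <- seq(0, 10 - 1 / fs, by = 1 / fs)
  expect_equal(count_strokes(sin(2 * pi * t), fs), 10L)
  expect_equal(count_strokes(rep(0, 500), fs), 0L)

  peak_oracle <- function(x, fs, amp_min = 0.3, min_spacing = 0.3) {
    n <- length(x)
    cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
    prom <- sapply(cand, function(i) {
      h <- x[i]
      lm <- i - 1L
      while (lm > 1L && x[lm] <= h) lm <- lm - 1L
      lmin <- min(x[if (x[lm] > h) (lm + 1L):(i - 1L) else lm:(i - 1L)])
      rm <- i + 1L
      while (rm < n && x[rm] <= h) rm <- rm + 1L
      rmin <- min(x[(i + 1L):(if (x[rm] > h) rm - 1L else rm)])
      h - max(lmin, rmin)
    })
    keep <- cand[prom >= amp_min]
    if (length(keep) <= 1L) return(length(keep))
    ord <- keep[order(x[keep], decreasing = TRUE)]
    taken <- integer(0)
    for (i in ord) if (all(abs(taken - i) >= round(min_spacing * fs)))
      taken <- c(taken, i)
    length(taken)
  }
  set.seed(51)
  for (rep in 1:20) {
    x <- filter_strokes(rnorm(600, 0, 0.5) +
                          sin(2 * pi * runif(1, 0.6, 2) *
                                seq(0, 11.98, by = 1 / fs)), fs)$stroke
    expect_equal(count_strokes(x, fs), peak_oracle(x, fs))
  }
})

test_that("head-turn detection uses net wrapped change and a dead band", {
  fs <- 5
  t <- seq(0, 10, by = 1 / fs)
  mk <- function(delta) 10 + delta * plogis((t - 5) / 0.1)
  expect_equal(detect_head_turn(mk(-20), fs, 5), "left")
  expect_equal(detect_head_turn(mk(20), fs, 5), "right")
  expect_equal(detect_head_turn(mk(3), fs, 5), "none")
  # a +-180 wrap crossing is not a spurious turn
  steady <- wrap_angle(179 + 0.5 * (t - 5))
  expect_equal(detect_head_turn(steady, fs, 5), "none")
  # constant offsets do not matter
  expect_equal(detect_head_turn(mk(-20) + 77, fs, 5), "left")
  expect_error(detect_head_turn(mk(20), fs, 0.5), "outside")
})

test_that("approach summaries recover the scheduled behaviour rates", {
  set.seed(52)
  cfg <- sim_config()
  n <- 70
  fs_or <- 50; fs_acc <- 200
  # schedule: timing mix 34/59/7, strokes 74/79, turns 43/27
  timing <- sample(c("before", "during", "after"), n, TRUE, c(0.34, 0.59, 0.07))
  reaction <- sample(c("leave_seafloor", "escape"), n, TRUE, c(0.7, 0.3))
  str_b <- runif(n) < 0.74
  str_d <- runif(n) < 0.79
  turn <- sample(c("left", "right", "none"), n, TRUE, c(0.43, 0.27, 0.30))

  dur <- runif(n, 5.5, 9)
  onset <- ifelse(timing == "before", runif(n, -4, -0.5),
           ifelse(timing == "during", runif(n, 0.3, dur - 0.3),
                  dur + runif(n, 0.5, 2)))
  rows <- list(); evs <- list()
  t_cursor <- 20
  total_s <- 20 + n * 40
  t_or <- seq(0, total_s, by = 1 / fs_or)
  heading <- cumsum(rnorm(length(t_or), 0, 2 / sqrt(fs_or)))
  stroke_env <- rep(0, round(total_s * fs_acc))
  for (i in seq_len(n)) {
    t_start <- t_cursor; t_end <- t_start + dur[i]
    t_re <- t_start + onset[i]
    if (turn[i] != "none") {
      delta <- runif(1, 15, 30) * if (turn[i] == "left") -1 else 1
      heading <- heading + delta * plogis((t_or - t_re) / 0.1)
    }
    if (str_b[i]) {
      idx <- round((t_re - 5) * fs_acc):round(t_re * fs_acc)
      stroke_env[idx[idx > 0]] <- 1
    }
    if (str_d[i]) {
      idx <- round(t_start * fs_acc):round(t_end * fs_acc)
      stroke_env[idx[idx > 0]] <- 1
    }
    evs[[i]] <- data.frame(id = i, t_start = t_start, t_end = t_end,
                           duration_s = dur[i])
    rows[[i]] <- data.frame(prca_id = i, reaction = reaction[i],
                            onset_time_s = onset[i])
    t_cursor <- t_cursor + 40
  }
  t_acc <- (seq_along(stroke_env) - 1) / fs_acc
  stroke <- filter_strokes(stroke_env * sin(2 * pi * 1 * t_acc) * 1.5,
                           fs_acc)$stroke
  win <- build_approach_windows(do.call(rbind, evs), do.call(rbind, rows),
                                wrap_angle(heading), stroke,
                                fs_or, fs_acc)
  s <- summarize_approach(win)
  tot <- s[s$reaction == "total", ]
  expect_equal(tot$n, n)
  expect_lt(abs(tot$pct_before - 100 * mean(timing == "before")), 5)
  expect_lt(abs(tot$pct_during - 100 * mean(timing == "during")), 5)
  expect_lt(abs(tot$pct_after - 100 * mean(timing == "after")), 5)
  # when the reaction falls inside the event, strokes scheduled "during"
  # also occupy part of the 5 s pre-reaction window
  eff_b <- str_b | (str_d & onset > 0.5)
  expect_lt(abs(tot$pct_strokes_before - 100 * mean(eff_b)), 10)
  expect_lt(abs(tot$pct_strokes_during - 100 * mean(str_d)), 10)
  expect_lt(abs(tot$pct_left - 100 * mean(turn == "left")), 10)
  expect_lt(abs(tot$pct_right - 100 * mean(turn == "right")), 10)
  expect_equal(tot$pct_before + tot$pct_during + tot$pct_after, 100,
               tolerance = 1.5)
  expect_equal(nrow(summarize_approach(win[0, ])), 0L)
})
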