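# Full synthetic-deployment generator: multi-rate sensor streams plus a
# complete ground truth, per individual, reproducible under a fixed seed.

split_total <- function(x, n) {
  # spread a scalar total over n individuals (or pass a per-individual vector)
  if (is.null(x)) return(rep(list(NULL), n))
  if (length(x) == n) return(as.list(as.integer(x)))
  tot <- as.integer(x)
  base <- tot %/% n
  out <- rep(base, n)
  extra <- tot - base * n
  if (extra > 0L) out[seq_len(extra)] <- out[seq_len(extra)] + 1L
  as.list(out)
}

# place events inside one dive so the depth at each event start matches its
# scheduled depth; events keep >= 6 s clearance (so the 5 s merge gap never
# joins distinct events)
place_events <- function(profile, fs, depths, durations) {
  n <- length(profile)
  Ts <- n / fs
  lo <- ceiling(0.10 * n); hi <- floor(0.90 * n)
  taken <- matrix(numeric(0), 0L, 2L)
  starts <- numeric(length(depths)); actual <- numeric(length(depths))
  for (i in order(depths, decreasing = TRUE)) {
    dmax <- hi - ceiling(durations[i] * fs)
    if (dmax <= lo) dmax <- lo + 1L
    cand <- lo:dmax
    cand <- cand[order(abs(profile[cand] - depths[i]))]
    placed <- FALSE
    for (k in cand) {
      t1 <- (k - 1L) / fs; t2 <- t1 + durations[i]
      if (nrow(taken) == 0L ||
          all(t2 + 6 < taken[, 1L] | t1 - 6 > taken[, 2L])) {
        taken <- rbind(taken, c(t1, t2))
        starts[i] <- t1; actual[i] <- profile[k]
        placed <- TRUE
        break
      }
    }
    if (!placed) {  # crowded dive: take the least-bad free slot
      k <- cand[1L]
      starts[i] <- (k - 1L) / fs; actual[i] <- profile[k]
    }
  }
  list(t_start = starts, depth = actual)
}

simulate_individual <- function(cfg, ind, n_dive_i, n_forage_i, n_prca_i) {
  empty <- list(
    sensors = list(accel = matrix(numeric(0), 0, 3), accel_fs = cfg$accel_fs,
                   magdepth = data.frame(t = numeric(), mx = numeric(),
                                         my = numeric(), mz = numeric(),
                                         depth = numeric()),
                   gps = data.frame(t = numeric(), lat = numeric(),
                                    lon = numeric()), t0 = 0),
    echograms = list(),
    dives = data.frame(), prca = data.frame())
  n_dives <- if (!is.null(n_dive_i)) n_dive_i
             else stats::rpois(1, cfg$duration_hours * cfg$dive_rate)
  if (!is.null(n_forage_i) && n_forage_i > n_dives) n_dives <- n_forage_i
  if (cfg$duration_hours == 0 && is.null(n_dive_i)) n_dives <- 0L
  if (n_dives == 0L) return(empty)

  arch <- sample.int(5L, n_dives, replace = TRUE, prob = cfg$archetype_weights)
  dur_min <- rtruncnorm(n_dives, cfg$duration_mean_sd[1L], cfg$duration_mean_sd[2L],
                        cfg$duration_range[1L], cfg$duration_range[2L])
  dur_s <- dur_min * 60

  n_forage <- if (!is.null(n_forage_i)) n_forage_i
              else stats::rbinom(1, n_dives, cfg$frac_foraging)
  w <- ifelse(arch %in% c(2L, 4L, 5L), 1, 0.05)
  foraging <- rep(FALSE, n_dives)
  if (n_forage > 0L)
    foraging[sample.int(n_dives, min(n_forage, n_dives), prob = w)] <- TRUE
  nf <- sum(foraging)

  # capture-attempt counts per foraging dive
  counts <- integer(n_dives)
  if (nf > 0L) {
    if (!is.null(n_prca_i)) {
      cc <- rep(1L, nf)
      rem <- n_prca_i - nf
      if (rem < 0L) { cc <- c(rep(1L, n_prca_i), rep(0L, nf - n_prca_i)) ; rem <- 0L }
      while (rem > 0L) {
        room <- which(cc < 6L)   # keep dives uncrowded so depths place cleanly
        add <- stats::rmultinom(1L, rem, rep(1, length(room)))[, 1L]
        cc[room] <- pmin(cc[room] + add, 6L)
        rem <- n_prca_i - sum(cc)
        if (length(room) == nf && all(cc >= 6L)) { cc[seq_len(rem)] <- cc[seq_len(rem)] + 1L; rem <- 0L }
      }
      counts[foraging] <- cc
    } else {
      counts[foraging] <- 1L + stats::rpois(nf, max(cfg$prca_per_foraging_dive - 1, 0))
    }
  }

  # depths: scheduled capture depths drive foraging-dive maxima
  max_depth <- numeric(n_dives)
  prca_depths <- vector("list", n_dives)
  for (i in seq_len(n_dives)) {
    if (counts[i] > 0L) {
      d <- rtruncnorm(counts[i], cfg$prca_depth_mean_sd[1L],
                      cfg$prca_depth_mean_sd[2L], lower = 6)
      prca_depths[[i]] <- d
      max_depth[i] <- max(d) * 1.03
      dur_s[i] <- max(dur_s[i], counts[i] * 55 + 80)
    } else {
      m <- cfg$depth_mean_sd[arch[i], ]
      max_depth[i] <- rtruncnorm(1, m[1L], m[2L], lower = 6, upper = 330)
    }
  }

  fs50 <- cfg$mag_depth_fs
  # lay out dives with surface gaps; optional shallow bouts in the gaps
  gaps <- 30 + stats::rexp(n_dives, 1 / 60)
  dive_t0 <- cumsum(gaps + c(0, head(dur_s, -1L)))
  total_s <- dive_t0[n_dives] + dur_s[n_dives] + 60
  n50 <- round(total_s * fs50)
  depth <- numeric(n50)
  shallow_sched <- list()
  for (i in seq_len(n_dives)) {
    prof <- simulate_dive_profile(arch[i], max_depth[i], dur_s[i], fs = fs50)
    a <- round(dive_t0[i] * fs50) + 1L
    b <- a + length(prof) - 1L
    depth[a:b] <- prof
    if (gaps[i] > 80 && stats::runif(1) < 0.35) {
      sd_ <- stats::runif(1, 20, min(gaps[i] - 40, 120))
      st <- dive_t0[i] - gaps[i] + stats::runif(1, 10, gaps[i] - sd_ - 20)
      sa <- round(st * fs50) + 1L
      sb <- sa + round(sd_ * fs50)
      bump <- stats::runif(1, 1, 4)
      u <- seq(0, 1, length.out = sb - sa + 1L)
      depth[sa:sb] <- pmax(depth[sa:sb], bump * sin(pi * u)^0.5)
      shallow_sched[[length(shallow_sched) + 1L]] <- c(st, st + sd_)
    }
  }

  # schedule capture attempts on the realized profiles
  prca <- list()
  for (i in which(counts > 0L)) {
    a <- round(dive_t0[i] * fs50) + 1L
    prof <- depth[a:(a + round(dur_s[i] * fs50) - 1L)]
    durs <- stats::runif(counts[i], cfg$prca_duration_range[1L],
                         cfg$prca_duration_range[2L])
    pl <- place_events(prof, fs50, prca_depths[[i]], durs)
    prca[[length(prca) + 1L]] <- data.frame(
      dive_id = i, t_start = dive_t0[i] + pl$t_start,
      t_end = dive_t0[i] + pl$t_start + durs,
      duration_s = durs, depth = pl$depth)
  }
  prca <- if (length(prca)) do.call(rbind, prca) else
    data.frame(dive_id = integer(), t_start = numeric(), t_end = numeric(),
               duration_s = numeric(), depth = numeric())
  if (nrow(prca) > 0L) {
    prca <- prca[order(prca$t_start), , drop = FALSE]
    prca$id <- seq_len(nrow(prca))
  } else prca$id <- integer(0)

  # prey interaction schedule per capture attempt
  np <- nrow(prca)
  prey <- data.frame(
    benthic = stats::runif(np) < cfg$p_benthic,
    visible = stats::runif(np) < cfg$p_trace_visible,
    reaction = rep(NA_character_, np), onset_time_s = rep(NA_real_, np),
    onset_range_cm = rep(NA_real_, np), size_cm = rep(NA_real_, np),
    school = rep(FALSE, np), stringsAsFactors = FALSE)
  if (np > 0L) {
    reactive <- prey$visible & stats::runif(np) < cfg$p_reactive
    prey$reaction[prey$visible] <- "none"
    prey$reaction[reactive] <- ifelse(
      stats::runif(sum(reactive)) < cfg$p_leave_seafloor,
      "leave_seafloor", "escape")
    prey$school <- prey$visible & stats::runif(np) < cfg$p_school
    nv <- sum(prey$visible)
    prey$onset_range_cm[prey$visible] <- rtruncnorm(
      nv, cfg$reaction_distance_mean_sd[1L], cfg$reaction_distance_mean_sd[2L],
      cfg$reaction_distance_range[1L], cfg$reaction_distance_range[2L])
    prey$size_cm[prey$visible] <- rtruncnorm(
      nv, cfg$acoustic_size_mean_sd[1L], cfg$acoustic_size_mean_sd[2L],
      cfg$acoustic_size_range[1L], cfg$acoustic_size_range[2L])
    is_re <- !is.na(prey$reaction) & prey$reaction != "none"
    prey$onset_time_s[is_re] <- clamp(
      stats::rnorm(sum(is_re), cfg$reaction_time_mean_sd[1L],
                   cfg$reaction_time_mean_sd[2L]),
      -4.5, prca$duration_s[is_re] + 2)
    # leave-seafloor reactions are benthic by definition
    prey$benthic[!is.na(prey$reaction) & prey$reaction == "leave_seafloor"] <- TRUE
  }

  # approach-behaviour schedule for reactive prey
  is_re <- !is.na(prey$reaction) & prey$reaction != "none"
  appr <- data.frame(strokes_before = rep(NA, np), strokes_during = rep(NA, np),
                     turn = rep(NA_character_, np), stringsAsFactors = FALSE)
  if (any(is_re)) {
    k <- sum(is_re)
    appr$strokes_before[is_re] <- stats::runif(k) < cfg$p_strokes_before
    appr$strokes_during[is_re] <- stats::runif(k) < cfg$p_strokes_during
    u <- stats::runif(k)
    appr$turn[is_re] <- ifelse(u < cfg$p_turn_left, "left",
                        ifelse(u < cfg$p_turn_left + cfg$p_turn_right,
                               "right", "none"))
  }

  # orientation schedule at 50 Hz: pitch from the depth rate, heading as a
  # slow walk + visual scanning + injected head turns at reaction times
  t50 <- (seq_len(n50) - 1L) / fs50
  drate <- moving_mean(c(diff(depth), 0) * fs50, 25L)
  pitch50 <- -rad2deg(asin(clamp(drate / 1.3, -0.98, 0.98)))
  heading50 <- cumsum(stats::rnorm(n50, 0, 2 / sqrt(fs50))) +
    3 * sin(2 * pi * 0.3 * t50 + stats::runif(1, 0, 2 * pi))
  if (any(is_re)) {
    for (j in which(is_re)) {
      if (is.na(appr$turn[j]) || appr$turn[j] == "none") next
      t_re <- prca$t_start[j] + prey$onset_time_s[j]
      delta <- stats::runif(1, 15, 30) * if (appr$turn[j] == "left") -1 else 1
      heading50 <- heading50 + delta * stats::plogis((t50 - t_re) / 0.15)
    }
  }
  thr <- deg2rad(pitch50); psr <- deg2rad(wrap_angle(heading50))
  Bh <- cfg$mag_field[["h"]]; Bu <- cfg$mag_field[["u"]]
  mdx <- Bh * cos(psr); mdy <- Bh * sin(psr)
  mag <- cbind(mx = cos(thr) * mdx + sin(thr) * Bu,
               my = mdy,
               mz = -sin(thr) * mdx + cos(thr) * Bu)

  # acceleration at accel_fs with stroke gating from the approach schedule
  fsa <- cfg$accel_fs
  na <- round(total_s * fsa)
  gate <- rep(TRUE, na)
  if (any(is_re)) {
    for (j in which(is_re)) {
      t_re <- prca$t_start[j] + prey$onset_time_s[j]
      if (isFALSE(appr$strokes_before[j])) {
        a <- max(1L, round((t_re - 5) * fsa)); b <- min(na, round(t_re * fsa))
        if (b > a) gate[a:b] <- FALSE
      }
      if (isFALSE(appr$strokes_during[j])) {
        a <- max(1L, round(prca$t_start[j] * fsa))
        b <- min(na, round(prca$t_end[j] * fsa))
        if (b > a) gate[a:b] <- FALSE
      }
    }
  }
  dives_df <- data.frame(t_start = dive_t0, t_end = dive_t0 + dur_s)
  accel <- simulate_acceleration(total_s, fsa, dives = dives_df, prcas = prca,
                                 config = cfg, pitch = pitch50,
                                 stroke_gate = gate)

  # GPS fixes: random walk around the colony, reflected at the radius cap
  n_fix <- max(2L, stats::rpois(1, cfg$gps_per_day * total_s / 86400) + 1L)
  gps_t <- sort(stats::runif(n_fix, 0, total_s))
  pos <- matrix(0, n_fix, 2L)
  pos[1L, ] <- c(cfg$colony[["lon"]], cfg$colony[["lat"]])
  for (i in seq_len(n_fix - 1L)) {
    step <- stats::rexp(1, 1 / (cfg$gps_step_km * 1000))
    brg <- stats::runif(1, 0, 360)
    cand <- geosphere::destPoint(pos[i, ], brg, step)
    home <- c(cfg$colony[["lon"]], cfg$colony[["lat"]])
    if (geosphere::distHaversine(cand, home) > cfg$max_radius_km * 1000)
      cand <- geosphere::destPoint(pos[i, ], geosphere::bearing(pos[i, ], home), step)
    pos[i + 1L, ] <- cand
  }
  gps <- data.frame(t = gps_t, lat = pos[, 2L], lon = pos[, 1L])

  # echograms for every capture attempt
  egs <- list()
  if (isTRUE(cfg$echograms) && np > 0L) {
    for (j in seq_len(np)) {
      spec <- c(as.list(prey[j, ]), list(duration_s = prca$duration_s[j]))
      egs[[j]] <- simulate_echogram(spec, cfg, prca_id = prca$id[j])
    }
  }

  truth_dives <- data.frame(
    individual = ind, id = seq_len(n_dives), t_start = dive_t0,
    t_end = dive_t0 + dur_s, archetype = arch, max_depth = max_depth,
    duration_s = dur_s, foraging = counts > 0L)
  truth_prca <- cbind(data.frame(individual = rep(ind, np)), prca, prey, appr)

  list(sensors = list(accel = accel, accel_fs = fsa,
                      magdepth = data.frame(t = t50, mx = mag[, 1L],
                                            my = mag[, 2L], mz = mag[, 3L],
                                            depth = depth),
                      gps = gps, t0 = 0),
       echograms = egs, dives = truth_dives, prca = truth_prca,
       heading_true = wrap_angle(heading50), pitch_true = pitch50)
}

#' Simulate a full multi-individual tag deployment
#'
#' Generates, per individual: triaxial acceleration at `accel_fs`,
#' magnetometry and depth at 50 Hz, GPS surface fixes near the colony, an
#' echogram for every scheduled capture attempt, and the complete ground
#' truth (dives with archetype labels, capture attempts with depths, prey
#' descriptors and the approach-behaviour schedule). Reproducible under a
#' fixed seed; individuals are generated from independent sub-seeds.
#'
#' @param config a [sim_config()]. Set `config$echograms <- FALSE` to skip
#'   echogram synthesis (large deployments where only the motion channels
#'   are needed).
#' @param seed integer seed (default 1).
#' @return Object of class `sim_deployment`: `individuals` (list of
#'   per-individual lists with `sensors`, `echograms`, `heading_true`,
#'   `pitch_true`), `truth` (`dives`, `prca` data.frames pooled across
#'   individuals), `config`, `seed`.
#' @export
simulate_deployment <- function(config = sim_config(), seed = 1) {
  if (is.null(config$echograms)) config$echograms <- TRUE
  set.seed(seed)
  n <- config$n_individuals
  sub_seeds <- sample.int(.Machine$integer.max, n)
  nd <- split_total(config$n_dives, n)
  nf <- split_total(config$n_foraging_dives, n)
  npr <- split_total(config$n_prca_total, n)
  indivs <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(sub_seeds[i])
    indivs[[i]] <- simulate_individual(config, i, nd[[i]], nf[[i]], npr[[i]])
  }
  dives <- do.call(rbind, lapply(indivs, `[[`, "dives"))
  prca <- do.call(rbind, lapply(indivs, `[[`, "prca"))
  structure(list(
    individuals = lapply(indivs, function(x)
      x[c("sensors", "echograms", "heading_true", "pitch_true")]),
    truth = list(dives = dives, prca = prca),
    config = config, seed = seed), class = "sim_deployment")
}

#' @export
print.sim_deployment <- function(x, ...) {
  cat(sprintf("sim_deployment: %d individuals, %d dives, %d capture attempts (seed %d)\n",
              length(x$individuals),
              if (is.null(x$truth$dives)) 0L else nrow(x$truth$dives),
              if (is.null(x$truth$prca)) 0L else nrow(x$truth$prca),
              x$seed))
  invisible(x)
}
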