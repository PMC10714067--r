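#' Construct an echogram from echo levels and a noise estimate
#'
#' The echo-to-noise ratio (ENR) is the per-bin echo level minus the
#' background noise estimate, floored at 0 dB, so that only signal above the
#' noise remains.
#'
#' @param echo matrix of echo levels in dB, pings in rows, range bins in
#'   columns.
#' @param noise background noise: either a per-bin vector (length = number
#'   of range bins) or a matrix of the same shape as `echo`.
#' @param ping_t ping times in seconds (defaults to 25 Hz from 0).
#' @param range_res range bin width in metres (default 0.01).
#' @param prca_id optional id of the linked capture attempt.
#' @param t_prca_start time of the capture-attempt start on the `ping_t`
#'   clock (default 0); reaction onset times are reported relative to it.
#' @return Object of class `echogram`: list with `enr` (pings x bins),
#'   `ping_t`, `range` (bin centre ranges, m), `range_res`, `prca_id`,
#'   `t_prca_start`.
#' @export
compute_enr <- function(echo, noise, ping_t = NULL, range_res = 0.01,
                        prca_id = NA, t_prca_start = 0) {
  echo <- as.matrix(echo)
  if (is.matrix(noise)) {
    if (!all(dim(noise) == dim(echo))) stop("echo/noise shape mismatch")
    enr <- echo - noise
  } else {
    if (length(noise) != ncol(echo)) stop("echo/noise shape mismatch")
    enr <- sweep(echo, 2L, noise, "-")
  }
  enr[enr < 0] <- 0
  if (is.null(ping_t)) ping_t <- (seq_len(nrow(echo)) - 1L) / 25
  structure(list(
    enr = enr, ping_t = ping_t,
    range = (seq_len(ncol(echo)) - 0.5) * range_res,
    range_res = range_res, prca_id = prca_id, t_prca_start = t_prca_start
  ), class = "echogram")
}

#' @export
print.echogram <- function(x, ...) {
  cat(sprintf("echogram: %d pings x %d bins (%.0f cm/bin, %.1f m range)\n",
              nrow(x$enr), ncol(x$enr), 100 * x$range_res,
              ncol(x$enr) * x$range_res))
  invisible(x)
}

#' Detect the seafloor line on an echogram
#'
#' Per ping, the seafloor candidate is the near edge (minimum range) of the
#' deepest contiguous supra-threshold run. Candidates are kept only where
#' they are range-continuous with the ridge consensus (within
#' `max_jump_bins` of a running median); the line is reported present when
#' the kept fraction of pings reaches `min_coverage`. A present seafloor
#' marks the capture attempt -- and its dive -- as benthic.
#'
#' @param eg an `echogram`.
#' @param enr_min ENR threshold in dB for ridge pixels (default 9).
#' @param min_coverage minimum fraction of pings carrying the ridge
#'   (default 0.3).
#' @param max_jump_bins allowed per-ping range jump of the ridge, in bins
#'   (default 3).
#' @return List of class `seafloor_line`: `range` (per-ping seafloor range
#'   in m, NA where absent), `coverage`, `present`.
#' @export
detect_seafloor <- function(eg, enr_min = 9, min_coverage = 0.3,
                            max_jump_bins = 3) {
  E <- eg$enr
  np <- nrow(E)
  cand <- rep(NA_real_, np)   # bin index of ridge top per ping
  for (p in seq_len(np)) {
    above <- E[p, ] >= enr_min
    if (!any(above)) next
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    cand[p] <- starts[runs[length(runs)]]   # deepest run, near edge
  }
  ok <- !is.na(cand)
  if (mean(ok) >= min_coverage && sum(ok) >= 3L) {
    med <- stats::median(cand[ok])
    # consensus pass: running median over neighbours, then continuity gate
    sm <- cand
    sm[!ok] <- med
    k <- 9L
    run_med <- stats::runmed(sm, k = min(k, 2L * (length(sm) %/% 2L) - 1L))
    keep <- ok & abs(cand - run_med) <= max_jump_bins
    cand[!keep] <- NA_real_
  } else {
    cand[] <- NA_real_
  }
  coverage <- mean(!is.na(cand))
  present <- coverage >= min_coverage
  if (!present) cand[] <- NA_real_
  structure(list(range = (cand - 0.5) * eg$range_res,
                 coverage = coverage, present = present),
            class = "seafloor_line")
}

# label 8-connected components among supra-threshold pixels.
# Returns an integer label matrix (0 = background).
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  nr <- nrow(mask)
  nxt <- 0L
  # union-find
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  # predecessors in column-major order: (r-1, c), (r-1, c-1), (r, c-1), (r+1, c-1)
  for (i in idx) {
    r <- ((i - 1L) %% nr) + 1L
    nb <- integer(0)
    if (r > 1L && lab[i - 1L] > 0L) nb <- c(nb, lab[i - 1L])
    if (i > nr) {
      j <- i - nr
      if (lab[j] > 0L) nb <- c(nb, lab[j])
      if (r > 1L && lab[j - 1L] > 0L) nb <- c(nb, lab[j - 1L])
      if (r < nr && lab[j + 1L] > 0L) nb <- c(nb, lab[j + 1L])
    }
    if (length(nb) == 0L) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[i] <- nxt
    } else {
      roots <- vapply(unique(nb), find, integer(1))
      root <- min(roots)
      lab[i] <- root
      for (rt in roots) parent[rt] <- root
    }
  }
  # second pass: path-compress labels and renumber densely
  if (nxt > 0L) {
    final <- vapply(seq_len(nxt), find, integer(1))
    dense <- match(final, sort(unique(final)))
    pos <- which(lab > 0L)
    lab[pos] <- dense[lab[pos]]
  }
  lab
}

#' Extract prey traces from an echogram
#'
#' After masking the seafloor ridge (plus a guard band above it), prey
#' candidates are 8-connected components of supra-threshold pixels covering
#' at least `min_pixels` pixels and `min_pings` ping columns. Components
#' that co-occur in three or more ping columns indicate more than one prey
#' echo within the same ping, so `n_targets` is "several"; otherwise "one".
#'
#' @param eg an `echogram`.
#' @param seafloor a `seafloor_line` from [detect_seafloor()] (may be
#'   absent).
#' @param enr_min pixel inclusion threshold, dB (default 9).
#' @param min_pixels minimum component size in pixels (default 6).
#' @param min_pings minimum distinct ping columns per component (default 3).
#' @param guard_bins bins above the ridge excluded together with it
#'   (default 2).
#' @return List of class `prey_traces`: `traces` (list; each has `pings`,
#'   `bins`, `polyline` data.frame of per-ping minimum range, `isolated`),
#'   and `n_targets` ("one", "several" or NA when empty).
#' @export
extract_prey_traces <- function(eg, seafloor = NULL, enr_min = 9,
                                min_pixels = 6, min_pings = 3,
                                guard_bins = 2) {
  E <- eg$enr
  mask <- E >= enr_min
  if (!is.null(seafloor) && seafloor$present) {
    fb <- round(seafloor$range / eg$range_res + 0.5)   # ridge top bin per ping
    fb[is.na(fb)] <- stats::median(fb, na.rm = TRUE)   # bridge dropped pings
    for (p in seq_along(fb)) {
      lo <- max(1L, fb[p] - guard_bins)
      mask[p, lo:ncol(E)] <- FALSE
    }
  }
  lab <- label_components(mask)
  ids <- setdiff(unique(as.integer(lab)), 0L)
  traces <- list()
  for (id in ids) {
    w <- which(lab == id, arr.ind = TRUE)
    if (nrow(w) < min_pixels) next
    pings <- w[, 1L]; bins <- w[, 2L]
    if (length(unique(pings)) < min_pings) next
    up <- sort(unique(pings))
    min_bin <- vapply(up, function(p) min(bins[pings == p]), numeric(1))
    traces[[length(traces) + 1L]] <- list(
      pings = pings, bins = bins,
      polyline = data.frame(ping = up, t = eg$ping_t[up],
                            range = (min_bin - 0.5) * eg$range_res),
      isolated = TRUE
    )
  }
  n_targets <- NA_character_
  if (length(traces) >= 1L) n_targets <- "one"
  if (length(traces) >= 2L) {
    cols <- lapply(traces, function(tr) unique(tr$pings))
    for (i in seq_along(traces)) {
      shared <- 0L
      for (j in seq_along(traces)) {
        if (i == j) next
        shared <- max(shared, length(intersect(cols[[i]], cols[[j]])))
      }
      if (shared >= 3L) {
        traces[[i]]$isolated <- FALSE
        n_targets <- "several"
      }
    }
  }
  structure(list(traces = traces, n_targets = n_targets),
            class = "prey_traces")
}

#' Classify a prey reaction from its trace geometry
#'
#' The per-ping minimum-range polyline is fitted by linear and quadratic
#' least squares. A trace whose first point sits within `eps_floor` of the
#' seafloor and whose linear slope is clearly negative is "leave_seafloor"
#' (prey hidden in the bottom departing as the seal approaches); a trace
#' clear of the floor whose quadratic opens upward with an interior slope
#' sign change (range decreasing then increasing) is "escape"; anything
#' else -- including range-stationary blobs -- is "none". When both
#' patterns fire, the departure origin on the floor dominates and
#' "leave_seafloor" wins.
#'
#' The onset is the first ping where the absolute range rate over a 3-ping
#' span exceeds `v_min`. For leave-seafloor reactions the onset range is
#' the seafloor range at that ping (the departure origin); otherwise it is
#' the polyline range.
#'
#' @param trace one element of `extract_prey_traces()$traces`.
#' @param eg the source `echogram` (for the capture-attempt clock).
#' @param seafloor a `seafloor_line` (may be absent).
#' @param eps_floor floor-proximity tolerance in metres (default 0.10).
#' @param slope_min minimum departure slope magnitude, m/s (default 0.02).
#' @param v_min onset range-rate threshold, m/s (default 0.05).
#' @return List: `reaction` ("none"/"escape"/"leave_seafloor"),
#'   `onset_time` (s relative to the capture-attempt start, negative =
#'   before it), `onset_range_cm`.
#' @export
classify_reaction <- function(trace, eg, seafloor = NULL, eps_floor = 0.10,
                              slope_min = 0.02, v_min = 0.05) {
  pl <- trace$polyline
  none <- list(reaction = "none", onset_time = NA_real_, onset_range_cm = NA_real_)
  if (nrow(pl) < 4L) return(none)
  tt <- pl$t; rr <- pl$range
  floor_at <- function(p) {
    if (is.null(seafloor) || !seafloor$present) return(NA_real_)
    f <- seafloor$range[p]
    if (is.na(f)) f <- stats::median(seafloor$range, na.rm = TRUE)
    f
  }
  # range rate over 3-ping centred spans
  nr <- length(rr)
  rate <- rep(NA_real_, nr)
  if (nr >= 3L)
    rate[2:(nr - 1)] <- (rr[3:nr] - rr[1:(nr - 2)]) / (tt[3:nr] - tt[1:(nr - 2)])
  moving <- which(abs(rate) > v_min)
  onset_i <- if (length(moving) > 0L) moving[1L] else NA_integer_

  lin <- stats::lm(rr ~ tt)
  slope <- stats::coef(lin)[2L]
  quad <- stats::lm(rr ~ tt + I(tt^2))
  a2 <- stats::coef(quad)[3L]

  f0 <- floor_at(pl$ping[1L])
  near_floor_start <- !is.na(f0) && abs(rr[1L] - f0) <= eps_floor

  fl <- vapply(pl$ping, floor_at, numeric(1))
  clearance <- fl - rr
  min_clear <- if (all(is.na(clearance))) Inf else min(clearance, na.rm = TRUE)

  # interior minimum of the quadratic with a - to + slope change, and a
  # real range excursion (so jittering stationary blobs do not qualify)
  has_interior_min <- FALSE
  if (is.finite(a2) && a2 > 0) {
    b1 <- stats::coef(quad)[2L]
    tmin <- -b1 / (2 * a2)
    if (tmin > tt[1L] && tmin < tt[nr]) {
      qv <- function(t) stats::coef(quad)[1L] + b1 * t + a2 * t^2
      has_interior_min <- (qv(tt[1L]) - qv(tmin)) >= 0.03 &&
                          (qv(tt[nr]) - qv(tmin)) >= 0.02
    }
  }

  reaction <- "none"
  if (near_floor_start && slope < -slope_min) {
    reaction <- "leave_seafloor"
  } else if (min_clear > eps_floor && has_interior_min &&
             length(moving) > 0L) {
    reaction <- "escape"
  }
  if (reaction == "none" || is.na(onset_i)) {
    if (reaction == "none") return(none)
    onset_i <- 1L
  }
  onset_range <- if (reaction == "leave_seafloor") {
    f <- floor_at(pl$ping[onset_i])
    if (is.na(f)) rr[onset_i] else f
  } else rr[onset_i]
  list(reaction = reaction,
       onset_time = tt[onset_i] - eg$t_prca_start,
       onset_range_cm = 100 * onset_range)
}

#' Acoustic size of a prey trace
#'
#' The acoustic size is the median, over the trace's ping columns, of the
#' contiguous supra-threshold pixel extent containing the trace, times the
#' range-bin width -- a relative size of the echo along the range axis, not
#' an anatomical length. It is only defined for traces clearly separated
#' from other echoes (`isolated`).
#'
#' @param trace one element of `extract_prey_traces()$traces`.
#' @param eg the source `echogram`.
#' @param enr_min pixel threshold, dB (default 9).
#' @return Size in cm, or NA (with a warning) for non-isolated traces.
#' @export
measure_acoustic_size <- function(trace, eg, enr_min = 9) {
  if (!isTRUE(trace$isolated)) {
    warning("acoustic size undefined for a trace not clearly separated")
    return(NA_real_)
  }
  E <- eg$enr
  up <- sort(unique(trace$pings))
  ext <- vapply(up, function(p) {
    above <- E[p, ] >= enr_min
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    tb <- trace$bins[trace$pings == p][1L]
    k <- which(r$values & starts <= tb & ends >= tb)
    if (length(k) == 0L) return(NA_real_)
    r$lengths[k[1L]]
  }, numeric(1))
  stats::median(ext, na.rm = TRUE) * eg$range_res * 100
}

#' Analyze one capture-attempt echogram end to end
#'
#' Runs seafloor detection, prey-trace extraction, reaction classification
#' of the dominant (largest) trace and acoustic sizing, and returns one
#' summary row.
#'
#' @param eg an `echogram`.
#' @param enr_min pixel threshold, dB (default 9).
#' @param ... passed to [classify_reaction()].
#' @return One-row data.frame: `prca_id`, `benthic`, `trace_present`,
#'   `n_targets`, `reaction`, `onset_time_s`, `onset_range_cm`, `size_cm`.
#' @export
analyze_echogram <- function(eg, enr_min = 9, ...) {
  sf <- detect_seafloor(eg, enr_min = enr_min)
  tr <- extract_prey_traces(eg, sf, enr_min = enr_min)
  row <- data.frame(prca_id = eg$prca_id, benthic = sf$present,
                    trace_present = length(tr$traces) > 0L,
                    n_targets = tr$n_targets, reaction = NA_character_,
                    onset_time_s = NA_real_, onset_range_cm = NA_real_,
                    size_cm = NA_real_, stringsAsFactors = FALSE)
  if (length(tr$traces) == 0L) return(row)
  sizes <- vapply(tr$traces, function(x) length(x$pings), integer(1))
  main <- tr$traces[[which.max(sizes)]]
  cls <- classify_reaction(main, eg, sf, ...)
  row$reaction <- cls$reaction
  row$onset_time_s <- cls$onset_time
  row$onset_range_cm <- cls$onset_range_cm
  if (cls$reaction != "none" && isTRUE(main$isolated))
    row$size_cm <- measure_acoustic_size(main, eg, enr_min = enr_min)
  row
}

#' Summarize prey characteristics over all capture attempts
#'
#' Aggregates per-echogram analysis rows into the prey summary: counts of
#' capture attempts with traces, single vs schooling echoes, reaction types,
#' and min/max/mean +- SD of reaction distance, reaction onset time and
#' acoustic size, per individual and pooled.
#'
#' @param prey data.frame of [analyze_echogram()] rows, optionally with an
#'   `individual` column.
#' @return data.frame with one row per individual plus a pooled `total` row.
#' @export
summarize_prey <- function(prey) {
  if (nrow(prey) == 0L) {
    return(data.frame(individual = character(), n_prca = integer(),
                      n_traces = integer()))
  }
  if (is.null(prey$individual)) prey$individual <- "all"
  one <- function(df, label) {
    re <- df$reaction[!is.na(df$reaction)]
    stat <- function(x) {
      x <- x[!is.na(x)]
      if (length(x) == 0L) return(c(NA, NA, NA, NA))
      c(min(x), max(x), mean(x), stats::sd(x))
    }
    dist <- stat(df$onset_range_cm[df$reaction %in% c("escape", "leave_seafloor")])
    tim <- stat(df$onset_time_s[df$reaction %in% c("escape", "leave_seafloor")])
    siz <- stat(df$size_cm)
    data.frame(
      individual = label,
      n_prca = nrow(df),
      n_traces = sum(df$trace_present, na.rm = TRUE),
      n_school = sum(df$n_targets == "several", na.rm = TRUE),
      n_single = sum(df$n_targets == "one", na.rm = TRUE),
      n_reactive = sum(re %in% c("escape", "leave_seafloor")),
      n_leave = sum(re == "leave_seafloor"),
      n_escape = sum(re == "escape"),
      n_benthic = sum(df$benthic, na.rm = TRUE),
      dist_min = dist[1], dist_max = dist[2], dist_mean = dist[3], dist_sd = dist[4],
      time_min = tim[1], time_max = tim[2], time_mean = tim[3], time_sd = tim[4],
      size_min = siz[1], size_max = siz[2], size_mean = siz[3], size_sd = siz[4],
      stringsAsFactors = FALSE
    )
  }
  parts <- lapply(split(prey, prey$individual), function(df)
    one(df, df$individual[1L]))
  out <- do.call(rbind, c(parts, list(one(prey, "total"))))
  rownames(out) <- NULL
  out
}
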