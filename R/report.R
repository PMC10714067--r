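#' Percentage of a count over a denominator
#'
#' `pct(78, 854)` is 9.13 with `digits = 2` -- the convention used in the
#' deployment summary tables (2 decimals where ratios are printed with
#' them, whole percentages otherwise).
#'
#' @param n numerator.
#' @param d denominator.
#' @param digits rounding digits (default 0).
#' @return `round(100 * n / d, digits)`.
#' @export
pct <- function(n, d, digits = 0) round(100 * n / d, digits)

#' Daily maximum track radius from GPS fixes
#'
#' Per calendar day, the maximum great-circle distance of any fix from the
#' day's first fix; summarised as mean +- SD across days.
#'
#' @param gps data.frame with `t` (seconds from deployment start or
#'   POSIXct), `lat`, `lon` in decimal degrees.
#' @return List: `per_day` (data.frame day, radius_km) and `mean_km`,
#'   `sd_km`.
#' @export
daily_radius <- function(gps) {
  if (nrow(gps) == 0L)
    return(list(per_day = data.frame(day = integer(), radius_km = numeric()),
                mean_km = NA_real_, sd_km = NA_real_))
  tsec <- if (inherits(gps$t, "POSIXct")) as.numeric(gps$t) else gps$t
  day <- floor(tsec / 86400)
  per_day <- lapply(split(seq_len(nrow(gps)), day), function(idx) {
    idx <- idx[order(tsec[idx])]
    p0 <- c(gps$lon[idx[1L]], gps$lat[idx[1L]])
    dmax <- max(geosphere::distHaversine(
      cbind(gps$lon[idx], gps$lat[idx]), p0)) / 1000
    data.frame(day = day[idx[1L]], radius_km = dmax)
  })
  per_day <- do.call(rbind, per_day)
  rownames(per_day) <- NULL
  list(per_day = per_day, mean_km = mean(per_day$radius_km),
       sd_km = stats::sd(per_day$radius_km))
}

#' Deployment summary report
#'
#' Aggregates the processed stages into the deployment summary: per
#' individual and pooled dive counts, time budgets above/below the 5 m
#' threshold, depth and duration statistics, capture-attempt counts, dives
#' with capture attempts (count and percentage), attempts per dive, mean
#' attempt depth, benthic echogram and prey-trace tallies, and GPS
#' statistics when fixes are supplied.
#'
#' @param proc result of [process_deployment()] (or a compatible list with
#'   `dives`, `shallow`, `events`, `prey`).
#' @param gps optional pooled GPS data.frame with `individual`, `t`, `lat`,
#'   `lon`.
#' @return data.frame with one row per individual plus a pooled `total`
#'   row.
#' @export
build_reports <- function(proc, gps = NULL) {
  if (is.null(proc$dives)) stop("missing upstream stage: dive segmentation")
  if (is.null(proc$events)) stop("missing upstream stage: event detection")
  inds <- sort(unique(proc$dives$individual))
  one <- function(sel_d, sel_s, sel_e, sel_p, sel_g, label) {
    nd <- nrow(sel_d)
    ev <- sel_e[!sel_e$excluded, , drop = FALSE]
    n_ev <- nrow(ev)
    dives_with <- length(unique(paste(ev$individual, ev$dive_id)))
    per_dive <- if (dives_with > 0L)
      as.integer(table(paste(ev$individual, ev$dive_id))) else integer(0)
    out <- data.frame(
      individual = label,
      n_dives = nd,
      time_shallow_h = sum(sel_s$duration_min) / 60,
      time_deep_h = sum(sel_d$duration_min) / 60,
      depth_max = if (nd) max(sel_d$max_depth) else NA_real_,
      depth_min = if (nd) min(sel_d$max_depth) else NA_real_,
      depth_mean = if (nd) mean(sel_d$max_depth) else NA_real_,
      depth_sd = if (nd) stats::sd(sel_d$max_depth) else NA_real_,
      dur_max = if (nd) max(sel_d$duration_min) else NA_real_,
      dur_min = if (nd) min(sel_d$duration_min) else NA_real_,
      dur_mean = if (nd) mean(sel_d$duration_min) else NA_real_,
      dur_sd = if (nd) stats::sd(sel_d$duration_min) else NA_real_,
      n_prca = n_ev,
      n_dives_with_prca = dives_with,
      pct_dives_with_prca = pct(dives_with, nd, 2),
      prca_per_dive_mean = if (length(per_dive)) mean(per_dive) else NA_real_,
      prca_per_dive_sd = if (length(per_dive)) stats::sd(per_dive) else NA_real_,
      prca_depth_mean = if (n_ev) mean(ev$depth_m) else NA_real_,
      prca_depth_sd = if (n_ev) stats::sd(ev$depth_m) else NA_real_,
      stringsAsFactors = FALSE)
    if (!is.null(sel_p)) {
      out$n_benthic <- sum(sel_p$benthic, na.rm = TRUE)
      out$pct_benthic <- pct(out$n_benthic, nrow(sel_p))
      out$n_traces <- sum(sel_p$trace_present, na.rm = TRUE)
      out$pct_traces <- pct(out$n_traces, nrow(sel_p))
    }
    if (!is.null(sel_g) && nrow(sel_g) > 0L) {
      dr <- daily_radius(sel_g)
      out$gps_fixes_per_day <- nrow(sel_g) /
        max(diff(range(sel_g$t)) / 86400, 1e-9)
      steps <- geosphere::distHaversine(
        cbind(sel_g$lon[-nrow(sel_g)], sel_g$lat[-nrow(sel_g)]),
        cbind(sel_g$lon[-1L], sel_g$lat[-1L])) / 1000
      out$gps_step_mean_km <- mean(steps)
      out$gps_daily_radius_km <- dr$mean_km
    }
    out
  }
  rows <- lapply(inds, function(i) one(
    proc$dives[proc$dives$individual == i, , drop = FALSE],
    proc$shallow[proc$shallow$individual == i, , drop = FALSE],
    proc$events[proc$events$individual == i, , drop = FALSE],
    if (!is.null(proc$prey)) proc$prey[proc$prey$individual == i, , drop = FALSE],
    if (!is.null(gps)) gps[gps$individual == i, , drop = FALSE],
    as.character(i)))
  total <- one(proc$dives, proc$shallow, proc$events, proc$prey, gps, "total")
  out <- do.call(rbind, c(rows, list(total)))
  rownames(out) <- NULL
  out
}
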