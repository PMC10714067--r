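#' Run the motion/sonar analysis chain on a simulated deployment
#'
#' For every individual: downsamples depth to the analysis rate, segments
#' dives at the 5 m threshold, detects capture attempts from the jerk
#' signal, attaches depth and dive context, and (when echograms are
#' present) analyses the window around every capture attempt. Detected
#' events are matched to scheduled echogram windows by temporal overlap.
#'
#' @param dep a [simulate_deployment()] result.
#' @param threshold,min_duration,merge_gap,rms_window detector settings
#'   (see [detect_events()]).
#' @param enr_min echogram pixel threshold, dB (default 9).
#' @param analysis_fs dive-analysis depth rate, Hz (default 5).
#' @return List: `dives` (pooled, with `individual`), `shallow`, `events`
#'   (contextualized, with `individual` and `matched_prca` = scheduled
#'   capture-attempt id overlapping the detection, NA if none), `prey`
#'   (per-echogram analysis rows with `individual`), `segs` (per-individual
#'   `dive_segmentation` objects).
#' @export
process_deployment <- function(dep, threshold = 150, min_duration = 5,
                               merge_gap = 5, rms_window = 0.2,
                               enr_min = 9, analysis_fs = 5) {
  cfg <- dep$config
  dives <- list(); shallow <- list(); events <- list(); prey <- list()
  segs <- list()
  for (i in seq_along(dep$individuals)) {
    ind <- dep$individuals[[i]]
    depth50 <- ind$sensors$magdepth$depth
    if (length(depth50) == 0L) next
    depth5 <- downsample(depth50, cfg$mag_depth_fs, analysis_fs)
    seg <- segment_dives(depth5, fs = analysis_fs)
    segs[[i]] <- seg
    d <- seg$dives; d$individual <- i
    s <- seg$shallow; s$individual <- i
    ev <- detect_prca(ind$sensors$accel, cfg$accel_fs, threshold,
                      min_duration, merge_gap, rms_window)
    ev <- contextualize_events(ev, seg, depth5, fs = analysis_fs)
    ev$individual <- rep(i, nrow(ev))
    # match detections to scheduled attempts by overlap
    tp <- dep$truth$prca
    tp <- tp[tp$individual == i, , drop = FALSE]
    ev$matched_prca <- rep(NA_integer_, nrow(ev))
    if (nrow(ev) > 0L && nrow(tp) > 0L) {
      for (k in seq_len(nrow(ev))) {
        ov <- pmin(ev$t_end[k], tp$t_end) - pmax(ev$t_start[k], tp$t_start)
        j <- which.max(ov)
        if (length(j) == 1L && ov[j] > 0) ev$matched_prca[k] <- tp$id[j]
      }
    }
    dives[[length(dives) + 1L]] <- d
    shallow[[length(shallow) + 1L]] <- s
    events[[length(events) + 1L]] <- ev
    if (length(ind$echograms) > 0L) {
      rows <- lapply(ind$echograms, function(e)
        analyze_echogram(e$echogram, enr_min = enr_min))
      pr <- do.call(rbind, rows)
      pr$individual <- i
      prey[[length(prey) + 1L]] <- pr
    }
  }
  list(dives = do.call(rbind, dives), shallow = do.call(rbind, shallow),
       events = do.call(rbind, events),
       prey = if (length(prey)) do.call(rbind, prey) else NULL,
       segs = segs)
}

#' Cluster dive shapes of a processed deployment
#'
#' Normalizes all dive profiles, fits the functional PCA, and clusters the
#' leading scores with the Gaussian-mixture model.
#'
#' @param segs list of `dive_segmentation` objects (one per individual).
#' @param n_points,n_basis,n_components see [normalize_dive()] and
#'   [fit_fpca()].
#' @param ... passed to [fit_cluster_model()].
#' @return List: `curves`, `fpca`, `model`, `assignment`, and `keep` (row
#'   index of usable dives per input order).
#' @export
cluster_dive_shapes <- function(segs, n_points = 101, n_basis = 15,
                                n_components = 3, ...) {
  profiles <- list(); keep <- list()
  for (i in seq_along(segs)) {
    seg <- segs[[i]]
    if (is.null(seg)) next
    for (k in seq_along(seg$profiles)) {
      p <- seg$profiles[[k]]
      if (length(p) >= 4L && stats::sd(p) > 0) {
        profiles[[length(profiles) + 1L]] <- p
        keep[[length(keep) + 1L]] <- c(individual = i, dive = k)
      }
    }
  }
  curves <- normalize_dives(profiles, n_points = n_points)
  fp <- fit_fpca(curves, n_basis = n_basis, n_components = n_components)
  model <- fit_cluster_model(fp$scores, ...)
  list(curves = curves, fpca = fp, model = model,
       assignment = model$assignment,
       keep = do.call(rbind, keep))
}
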