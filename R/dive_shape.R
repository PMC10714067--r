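#' Summarize dive-shape clusters
#'
#' Per-cluster dive counts (per individual and total), capture-attempt
#' tallies, the cluster mean curve and pointwise quantile envelopes at
#' 2.5, 25, 75 and 97.5%.
#'
#' @param assignment integer cluster ids per dive (NA = unclassified), as
#'   returned by [assign_with_threshold()].
#' @param curves matrix of normalized dive curves (dives x points).
#' @param dives data.frame with one row per dive; must contain `id`, and
#'   optionally `individual`.
#' @param events optional contextualized event data.frame (see
#'   [contextualize_events()]); rows with `excluded = TRUE` are ignored.
#'   When `dives$individual` exists, events are matched on
#'   (`individual`, `dive_id`), otherwise on `dive_id` alone.
#' @return List: `table` (one row per cluster: n dives per individual,
#'   total, n capture attempts), `envelopes` (per cluster: `mean` curve and
#'   `quantiles` matrix 4 x points), `n_assigned`, `n_unclassified`.
#' @export
summarize_clusters <- function(assignment, curves, dives, events = NULL) {
  stopifnot(length(assignment) == nrow(dives), nrow(curves) == nrow(dives))
  ind <- dives$individual %||% rep("all", nrow(dives))
  clusters <- sort(unique(assignment[!is.na(assignment)]))
  qs <- c(0.025, 0.25, 0.75, 0.975)
  rows <- list(); envelopes <- list()
  for (cl in clusters) {
    sel <- which(!is.na(assignment) & assignment == cl)
    n_by_ind <- table(factor(ind[sel], levels = sort(unique(ind))))
    n_prca <- 0L
    if (!is.null(events) && nrow(events) > 0L) {
      excl <- if (is.null(events$excluded)) rep(FALSE, nrow(events)) else events$excluded
      ev <- events[!excl & !is.na(events$dive_id), , drop = FALSE]
      if (!is.null(dives$individual) && !is.null(ev$individual)) {
        key_d <- paste(ind[sel], dives$id[sel])
        key_e <- paste(ev$individual, ev$dive_id)
        n_prca <- sum(key_e %in% key_d)
      } else {
        n_prca <- sum(ev$dive_id %in% dives$id[sel])
      }
    }
    sub <- curves[sel, , drop = FALSE]
    envelopes[[as.character(cl)]] <- list(
      mean = colMeans(sub),
      quantiles = apply(sub, 2L, stats::quantile, probs = qs)
    )
    rows[[length(rows) + 1L]] <- data.frame(
      cluster = cl, t(as.matrix(n_by_ind)), total = length(sel),
      n_prca = n_prca, check.names = FALSE
    )
  }
  list(table = if (length(rows)) do.call(rbind, rows) else data.frame(),
       envelopes = envelopes,
       n_assigned = sum(!is.na(assignment)),
       n_unclassified = sum(is.na(assignment)))
}

#' Pairwise agreement between two partitions
#'
#' Fraction of dive pairs on which two clusterings agree (both place the
#' pair together, or both apart) -- a simple co-assignment agreement for
#' comparing clustering methods. Pairs involving an unclassified dive (NA)
#' are ignored.
#'
#' @param a,b cluster-label vectors of equal length (NA = unclassified).
#' @return Agreement fraction in [0, 1] (NA when fewer than 2 labelled
#'   dives are shared).
#' @export
cluster_agreement <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 2L) return(NA_real_)
  sa <- outer(a, a, "==")[upper.tri(diag(n))]
  sb <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(sa == sb)
}
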