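#' Calibrate a triaxial sensor stream
#'
#' Applies a per-axis affine correction (`gain * (raw - offset)`) followed by
#' an optional fixed mounting rotation, the usual first step for tag
#' accelerometer and magnetometer channels.
#'
#' @param x numeric matrix (n x 3) or data.frame of raw axis values.
#' @param spec calibration list with elements `offset` (length 3),
#'   `gain` (length 3, non-zero) and optionally `rotation` (3 x 3 matrix).
#' @return Matrix of calibrated values, same dimensions as `x`.
#' @export
calibrate <- function(x, spec = list(offset = c(0, 0, 0), gain = c(1, 1, 1))) {
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("`x` must have 3 axis columns")
  offset <- spec$offset %||% c(0, 0, 0)
  gain <- spec$gain %||% c(1, 1, 1)
  if (length(offset) != 3L || length(gain) != 3L) stop("axis mismatch in calibration spec")
  if (any(gain == 0)) stop("calibration gains must be non-zero")
  out <- sweep(sweep(x, 2L, offset, "-"), 2L, gain, "*")
  if (!is.null(spec$rotation)) {
    R <- spec$rotation
    if (!is.matrix(R) || any(dim(R) != 3L)) stop("rotation must be a 3x3 matrix")
    out <- out %*% t(R)
  }
  dimnames(out) <- dimnames(x)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Anti-aliased downsampling by an integer factor
#'
#' Averages each block of `native_fs / target_fs` consecutive samples
#' (a moving-average anti-alias filter aligned with the decimation grid)
#' and returns one value per block. A trailing partial block is averaged
#' over the samples available, so the output length is
#' `ceiling(n * target_fs / native_fs)`.
#'
#' @param x numeric vector or matrix (columns are channels).
#' @param native_fs original sampling rate, Hz.
#' @param target_fs desired rate, Hz; must divide `native_fs`.
#' @return Downsampled vector/matrix.
#' @export
downsample <- function(x, native_fs, target_fs) {
  if (native_fs %% target_fs != 0) stop("target_fs must divide native_fs")
  q <- native_fs %/% target_fs
  if (q == 1L) return(x)
  block_mean <- function(v) {
    n <- length(v)
    grp <- rep(seq_len(ceiling(n / q)), each = q, length.out = n)
    as.numeric(tapply(v, grp, mean))
  }
  if (is.matrix(x)) apply(x, 2L, block_mean) else block_mean(x)
}

#' Segment a depth record into dives and shallow bouts
#'
#' Splits a cleaned depth series (positive down, surface at 0) into maximal
#' runs deeper than `threshold` (dives) and runs in `(0, threshold]`
#' (shallow under-ice activity). Raw negative depths are clamped to 0 before
#' segmentation. Boundaries are the first and last samples of each
#' supra-threshold run; samples exactly at the threshold count as shallow.
#'
#' @param depth numeric depth series in metres, positive down.
#' @param fs sampling rate of the series, Hz (default 5).
#' @param threshold dive depth threshold in metres (default 5, strict `>`).
#' @param t0 time of the first sample in seconds (default 0).
#' @return An object of class `dive_segmentation`: a list with `dives`
#'   (data.frame: id, start, end sample indices, t_start, t_end,
#'   duration_min, max_depth), `shallow` (same layout, max depth of each
#'   bout), `profiles` (list of per-dive depth vectors), and `fs`.
#' @export
segment_dives <- function(depth, fs = 5, threshold = 5, t0 = 0) {
  if (length(depth) == 0L) stop("empty depth series")
  depth <- pmax(depth, 0)
  state <- ifelse(depth > threshold, 2L, ifelse(depth > 0, 1L, 0L))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mk <- function(keep) {
    s <- starts[keep]; e <- ends[keep]
    data.frame(
      id = seq_along(s),
      start = s, end = e,
      t_start = t0 + (s - 1L) / fs,
      t_end = t0 + (e - 1L) / fs,
      duration_min = (e - s + 1L) / fs / 60,
      max_depth = vapply(seq_along(s), function(i) max(depth[s[i]:e[i]]), numeric(1))
    )
  }
  dives <- mk(r$values == 2L)
  shallow <- mk(r$values == 1L)
  profiles <- lapply(seq_len(nrow(dives)),
                     function(i) depth[dives$start[i]:dives$end[i]])
  structure(list(dives = dives, shallow = shallow, profiles = profiles,
                 fs = fs, threshold = threshold),
            class = "dive_segmentation")
}

#' @export
print.dive_segmentation <- function(x, ...) {
  cat(sprintf("dive segmentation: %d dives, %d shallow bouts (threshold %g m, %g Hz)\n",
              nrow(x$dives), nrow(x$shallow), x$threshold, x$fs))
  invisible(x)
}

#' Count dives per maximum-depth bin
#'
#' Bin k covers maximum depths in `[k * width, (k + 1) * width)`.
#'
#' @param max_depths numeric vector of per-dive maximum depths (m), or a
#'   `dive_segmentation` object.
#' @param bin_width bin width in metres (default 40).
#' @return data.frame with `bin` (0-based index), `lower`, `upper` (m) and
#'   `n`; counts sum to the number of dives.
#' @export
bin_dives_by_depth <- function(max_depths, bin_width = 40) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (inherits(max_depths, "dive_segmentation")) max_depths <- max_depths$dives$max_depth
  if (length(max_depths) == 0L) {
    return(data.frame(bin = integer(), lower = numeric(), upper = numeric(), n = integer()))
  }
  bin <- floor(max_depths / bin_width)
  tab <- table(bin)
  b <- as.integer(names(tab))
  data.frame(bin = b, lower = b * bin_width, upper = (b + 1) * bin_width,
             n = as.integer(tab))
}
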