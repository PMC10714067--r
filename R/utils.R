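#' @keywords internal
"_PACKAGE"

# radians/degrees helpers used throughout
deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Wrap angles to (-180, 180]
#'
#' @param x angles in degrees.
#' @return Wrapped angles in degrees, in the half-open interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  w <- (x + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

# truncated normal draws by rejection; bounds may be +-Inf
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

# moving average with shrunken edge windows (centered, half-width h)
moving_mean <- function(x, h) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  k <- seq_len(n)
  lo <- pmax(1L, k - h)
  hi <- pmin(n, k + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
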