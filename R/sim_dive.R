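# Dive-shape archetypes:
#   1 square  : direct descent/ascent, flat bottom covering >= 30% of the dive
#   2 V       : symmetric V, vertical sinuosity throughout
#   3 left-V  : sinuous descent, straight ascent (apex late)
#   4 right-V : straight descent, sinuous ascent (apex early)
#   5 W       : two bottom excursions, typically shallow

#' Simulate one dive depth profile
#'
#' Generates a depth time series (positive down) for one of five dive-shape
#' archetypes. The profile starts and ends at the surface, reaches exactly
#' `max_depth`, and honours the archetype geometry; sinuosity is a small
#' random oscillation superimposed where the archetype calls for it, tapered
#' so that limb trends stay monotone and the apex structure is preserved.
#'
#' @param archetype integer 1..5 (see above).
#' @param max_depth maximum dive depth, m (> 5).
#' @param duration dive duration, s (> 0).
#' @param fs sampling rate of the returned profile, Hz (default 5).
#' @param sinuosity oscillation amplitude as a fraction of depth
#'   (default 0.03).
#' @param deformation amplitude of the smooth random multi-harmonic
#'   deformation, as a fraction of depth (default 0.5); masked near the
#'   surface and near the archetype's apex structure so the diagnostic
#'   geometry survives. Models the broad dive-to-dive variability of real
#'   profiles.
#' @return Numeric depth vector of length `round(duration * fs)`.
#' @export
simulate_dive_profile <- function(archetype, max_depth, duration, fs = 5,
                                  sinuosity = 0.03, deformation = 0.5) {
  if (!archetype %in% 1:5) stop("unknown archetype id")
  if (duration <= 0) stop("duration must be positive")
  if (max_depth <= 5) stop("max_depth must exceed the 5 m dive threshold")
  n <- max(5L, round(duration * fs))
  s <- seq(0, 1, length.out = n)
  osc <- function(u, cycles) {
    # tapered oscillation: zero at both ends of its segment
    phase <- stats::runif(1, 0, 2 * pi)
    sin(2 * pi * cycles * u + phase) * sin(pi * u)^2
  }
  # geometry parameters vary dive to dive within each archetype
  shape <- switch(archetype,
    { # 1: trapezoid, direct limbs, flat bottom covering >= 30% of duration
      b1 <- stats::runif(1, 0.18, 0.30)
      b2 <- stats::runif(1, 0.70, 0.82)
      d <- pmin(s / b1, 1, (1 - s) / (1 - b2))
      bottom <- s > b1 & s < b2
      d[bottom] <- 1 - 0.015 * (1 + osc((s[bottom] - b1) / (b2 - b1), 2))
      d
    },
    { # 2: symmetric V, sinuosity over the whole dive but tapered at the apex
      ex <- stats::runif(1, 1.1, 1.5)
      base <- 1 - abs(2 * s - 1)^ex
      base + sinuosity * stats::runif(1, 0.7, 1.3) *
        osc(s, sample(3:5, 1)) * abs(2 * s - 1)
    },
    { # 3: apex late, oscillation on the (long, sinuous) descent limb
      p <- stats::runif(1, 0.56, 0.68)
      ex <- stats::runif(1, 1.0, 1.3)
      base <- ifelse(s <= p, (s / p)^ex, (1 - s) / (1 - p))
      add <- ifelse(s <= p, sinuosity * osc(pmin(s / p, 1), 3), 0)
      base + add
    },
    { # 4: apex early, oscillation on the (long, sinuous) ascent limb
      p <- stats::runif(1, 0.32, 0.44)
      ex <- stats::runif(1, 1.0, 1.3)
      base <- ifelse(s <= p, s / p, ((1 - s) / (1 - p))^ex)
      add <- ifelse(s > p, sinuosity * osc(pmin((s - p) / (1 - p), 1), 3), 0)
      base + add
    },
    { # 5: smooth W, two Gaussian bottom excursions with a mid-dive recovery
      s1 <- stats::runif(1, 0.25, 0.31)
      s2 <- stats::runif(1, 0.69, 0.75)
      w1 <- stats::runif(1, 0.14, 0.17)
      w2 <- stats::runif(1, 0.14, 0.17)
      h2 <- stats::runif(1, 0.88, 0.98)
      bumps <- exp(-((s - s1) / w1)^2) + h2 * exp(-((s - s2) / w2)^2)
      bumps * pmin(s / 0.08, 1, (1 - s) / 0.08)
    })
  # smooth random deformation; masks keep the diagnostic geometry intact
  # (the V family carries the full amplitude, the square bottom and the W
  # excursions are protected)
  if (deformation > 0) {
    z <- stats::rnorm(3L)
    def <- (z[1L] * sin(2 * pi * s) + z[2L] * sin(4 * pi * s) +
              z[3L] * sin(6 * pi * s)) / sqrt(3)
    # squared ramps keep the mask flat (zero slope) at the protected points
    mask <- switch(archetype,
      0.25 * sin(pi * s)^2 *
        pmin((pmax(0.18 - s, s - 0.82, 0) / 0.1)^2, 1),   # limbs only
      sin(pi * s)^2 * abs(2 * s - 1),
      sin(pi * s)^2 * pmin((pmax(p - 0.15 - s, 0) / 0.1)^2, 1),  # descent limb
      sin(pi * s)^2 * pmin((pmax(s - p - 0.15, 0) / 0.1)^2, 1),  # ascent limb
      0.05 * sin(pi * s)^2 * pmin((pmin(abs(s - s1), abs(s - (s1 + s2) / 2),
                                        abs(s - s2)) / 0.11)^2, 1))
    shape <- shape + deformation * def * mask
  }
  shape <- pmax(shape, 0)
  shape[c(1L, n)] <- 0
  prof <- shape / max(shape) * max_depth
  # one dive = one contiguous supra-threshold excursion: lift any interior
  # deformation dip back above the 5 m dive threshold
  above <- which(prof > 5.2)
  if (length(above) > 1L) {
    span <- above[1L]:above[length(above)]
    prof[span] <- pmax(prof[span], min(5.45, max_depth))
  }
  prof
}
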