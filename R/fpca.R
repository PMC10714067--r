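#' Normalize a dive profile to a comparable shape curve
#'
#' Rescales time to [0, 1], interpolates linearly onto `n_points` uniform
#' points, and z-scores depth within the dive (centred, unit SD). The
#' normalisation removes depth magnitude and duration so that clustering
#' compares shapes only; the record needed to undo it is kept.
#'
#' @param profile numeric depth samples of one dive (m, positive down).
#' @param fs sampling rate of the profile, Hz (default 5).
#' @param n_points number of resample points (default 101).
#' @return Object of class `dive_curve`: list with `curve` (length
#'   `n_points`, mean 0, SD 1), `duration_s`, `depth_mean`, `depth_sd`.
#' @export
normalize_dive <- function(profile, fs = 5, n_points = 101) {
  if (length(profile) < 4L) stop("profile needs at least 4 samples")
  if (stats::sd(profile) == 0) stop("constant-depth profile cannot be normalized")
  u <- seq(0, 1, length.out = length(profile))
  g <- seq(0, 1, length.out = n_points)
  res <- stats::approx(u, profile, xout = g)$y
  m <- mean(res); s <- stats::sd(res)   # z-score after resampling: the
  curve <- (res - m) / s                # curve has exactly mean 0, SD 1
  structure(list(curve = curve, duration_s = length(profile) / fs,
                 depth_mean = m, depth_sd = s),
            class = "dive_curve")
}

#' Undo dive-curve normalisation
#'
#' @param dc a `dive_curve`.
#' @param fs target sampling rate, Hz (default 5).
#' @return Depth samples at the original duration and scale (up to
#'   interpolation error).
#' @export
denormalize_dive <- function(dc, fs = 5) {
  n <- max(4L, round(dc$duration_s * fs))
  g <- seq(0, 1, length.out = length(dc$curve))
  u <- seq(0, 1, length.out = n)
  stats::approx(g, dc$curve, xout = u)$y * dc$depth_sd + dc$depth_mean
}

#' Stack normalized dive curves into a matrix
#'
#' @param profiles list of depth profiles (or of `dive_curve` objects).
#' @param fs,n_points passed to [normalize_dive()].
#' @return Matrix, one row per dive, `n_points` columns.
#' @export
normalize_dives <- function(profiles, fs = 5, n_points = 101) {
  rows <- lapply(profiles, function(p) {
    if (inherits(p, "dive_curve")) p$curve else normalize_dive(p, fs, n_points)$curve
  })
  do.call(rbind, rows)
}

# cubic B-spline basis with n_basis functions on [0, 1], evaluated at x
bspline_basis <- function(x, n_basis) {
  if (n_basis < 4L) stop("need at least 4 cubic B-spline basis functions")
  interior <- seq(0, 1, length.out = n_basis - 2L)[-c(1L, n_basis - 2L)]
  knots <- c(rep(0, 4L), interior, rep(1, 4L))
  splines::splineDesign(knots, x, ord = 4L, outer.ok = FALSE)
}

#' Functional principal component analysis of dive curves
#'
#' Curves are smoothed on a cubic B-spline basis by least squares; the
#' eigenproblem of the covariance operator is solved in coefficient space
#' under the basis inner product (Gram matrix via its Cholesky factor), so
#' the eigenfunctions are orthonormal in L2[0, 1]. Components are ordered
#' by explained variance and scores are the projections of the centred
#' curves on the eigenfunctions.
#'
#' @param curves matrix of normalized curves (dives x points), e.g. from
#'   [normalize_dives()].
#' @param n_basis number of B-spline basis functions (default 15).
#' @param n_components number of leading components kept (default 3).
#' @return Object of class `fpca`: `grid`, `meanfun`, `efuns` (points x
#'   components, orthonormal), `scores` (dives x components), `varprop`
#'   (fractions of total variance for every eigenvalue, non-increasing),
#'   `values`, `n_basis`, `n_components`, plus the basis internals needed
#'   for reconstruction.
#' @export
fit_fpca <- function(curves, n_basis = 15, n_components = 3) {
  curves <- as.matrix(curves)
  n <- nrow(curves)
  if (n < n_components + 1L) stop("need more curves than components")
  Fp <- ncol(curves)
  grid <- seq(0, 1, length.out = Fp)
  B <- bspline_basis(grid, n_basis)

  # Gram matrix of the basis by trapezoidal quadrature on a fine grid
  fine <- seq(0, 1, length.out = 2001L)
  Bf <- bspline_basis(fine, n_basis)
  wq <- rep(fine[2L] - fine[1L], length(fine))
  wq[c(1L, length(fine))] <- wq[1L] / 2
  W <- crossprod(Bf * sqrt(wq))

  C <- t(solve(crossprod(B), crossprod(B, t(curves))))   # n x p coefficients
  cbar <- colMeans(C)
  Cc <- sweep(C, 2L, cbar)

  U <- chol(W)
  Y <- Cc %*% t(U)
  ev <- eigen(crossprod(Y) / (n - 1L), symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  varprop <- vals / sum(vals)
  k <- n_components
  uvec <- ev$vectors[, seq_len(k), drop = FALSE]
  harm <- backsolve(U, uvec)                      # basis coefficients of eigenfunctions
  efuns <- B %*% harm
  scores <- Y %*% uvec

  structure(list(grid = grid, meanfun = as.numeric(B %*% cbar),
                 mean_coef = cbar, efuns = efuns, harmonics = harm,
                 scores = scores, values = vals, varprop = varprop,
                 n_basis = n_basis, n_components = k, basis = B, gram = W),
            class = "fpca")
}

#' @export
print.fpca <- function(x, ...) {
  cat(sprintf("fPCA: %d components of %d basis functions; variance fractions %s\n",
              x$n_components, x$n_basis,
              paste(sprintf("%.1f%%", 100 * x$varprop[seq_len(x$n_components)]),
                    collapse = ", ")))
  invisible(x)
}

#' Rebuild curves from fPCA scores
#'
#' @param model an `fpca` object.
#' @param scores score matrix (default: the model's own scores).
#' @return Matrix of reconstructed curves on the model grid.
#' @export
reconstruct_curves <- function(model, scores = model$scores) {
  sweep(scores %*% t(model$efuns), 2L, model$meanfun, "+")
}
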