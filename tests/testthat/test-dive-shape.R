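test_that("dive normalization is scale invariant and invertible", {
  set.seed(40)
  v <- function(depth, n) depth * (1 - abs(2 * seq(0, 1, length.out = n) - 1))
  # same shape at different depth/duration: identical curve up to regridding
  c1 <- normalize_dive(v(50, 120) + 6)$curve
  c2 <- normalize_dive(v(300, 600) + 6)$curve
  expect_equal(c1, c2, tolerance = 0.02)
  # exactly identical when the grids coincide
  expect_equal(normalize_dive(v(50, 101) + 6)$curve,
               normalize_dive(v(300, 101) + 6)$curve, tolerance = 1e-12)
  expect_equal(mean(c1), 0, tolerance = 1e-9)
  expect_equal(sd(c1), 1, tolerance = 1e-9)

  # already-uniform 101-point profile: interpolation is the identity
  p <- v(80, 101) + 10
  dc <- normalize_dive(p)
  expect_equal(dc$curve, (p - mean(p)) / sd(p))

  # round trip back to original units
  prof <- simulate_dive_profile(2, 90, 200, fs = 5)
  dc <- normalize_dive(prof)
  back <- denormalize_dive(dc)
  expect_equal(length(back), length(prof))
  expect_lt(max(abs(back - prof)), 2)

  expect_error(normalize_dive(rep(10, 50)), "constant")
  expect_error(normalize_dive(c(1, 2, 3)), "4 samples")
})

test_that("archetype geometries are honoured", {
  set.seed(41)
  nmax <- function(x) {
    d <- diff(x); d <- d[d != 0]
    sum(diff(sign(d)) < 0)
  }
  for (rep in 1:20) {
    # 1: flat bottom at least 30% of duration
    p1 <- simulate_dive_profile(1, 100, 300)
    expect_gte(mean(p1 > 0.85 * 100), 0.30)
    # 2: single apex near mid-dive
    p2 <- simulate_dive_profile(2, 100, 300)
    apex <- which.max(p2) / length(p2)
    expect_gt(apex, 0.35); expect_lt(apex, 0.65)
    # 5: exactly two bottom excursions after light smoothing
    p5 <- simulate_dive_profile(5, 30, 300)
    sm <- stats::filter(p5, rep(1 / 5, 5))
    expect_equal(nmax(sm[!is.na(sm)]), 2L)
  }
  # 3 vs 4: the sinuous limb is rougher and the apex sits on its side
  # in the clear majority of draws
  roughness <- function(p, from, to) {
    seg <- p[seq(round(from * length(p)) + 1, round(to * length(p)))]
    sd(diff(seg, differences = 2))
  }
  a3 <- a4 <- r3 <- r4 <- logical(30)
  for (k in 1:30) {
    p3 <- simulate_dive_profile(3, 100, 300)
    p4 <- simulate_dive_profile(4, 100, 300)
    a3[k] <- which.max(p3) / length(p3) > 0.5
    a4[k] <- which.max(p4) / length(p4) < 0.5
    r3[k] <- roughness(p3, 0.08, 0.42) > roughness(p3, 0.72, 0.92)
    r4[k] <- roughness(p4, 0.55, 0.92) > roughness(p4, 0.08, 0.28)
  }
  expect_gte(mean(a3), 0.7); expect_gte(mean(a4), 0.7)
  expect_gte(mean(r3), 0.9); expect_gte(mean(r4), 0.9)

  # all profiles surface at both ends and reach the requested depth
  for (a in 1:5) {
    p <- simulate_dive_profile(a, 50, 120)
    expect_lt(p[1], 5); expect_lt(p[length(p)], 5)
    expect_equal(max(p), 50, tolerance = 1e-9)
  }
  # boundary case barely over the dive threshold
  pb <- simulate_dive_profile(1, 5.01, 10)
  expect_equal(max(pb), 5.01)
  expect_error(simulate_dive_profile(6, 50, 100), "archetype")
  expect_error(simulate_dive_profile(1, 50, -1), "duration")
})

test_that("fPCA recovers a rank-1 structure and stays orthonormal", {
  set.seed(42)
  g <- seq(0, 1, length.out = 101)
  phi <- sqrt(2) * sin(2 * pi * g)
  X <- outer(rnorm(80, 0, 2), phi)
  fp <- fit_fpca(X)
  expect_gt(fp$varprop[1], 0.999)

  # eigenfunctions are exactly orthonormal under the basis Gram inner
  # product, and nearly so under a trapezoid quadrature on the grid
  Gexact <- t(fp$harmonics) %*% fp$gram %*% fp$harmonics
  expect_equal(Gexact, diag(3), tolerance = 1e-6, ignore_attr = TRUE)
  w <- rep(g[2] - g[1], 101); w[c(1, 101)] <- w[1] / 2
  G <- t(fp$efuns * w) %*% fp$efuns
  expect_equal(G, diag(3), tolerance = 0.05, ignore_attr = TRUE)
  expect_true(all(diff(fp$varprop) <= 1e-12))
  expect_error(fit_fpca(X[1:3, ]), "more curves")
})

test_that("fPCA recovers a 6:4:3 variance split from 3 eigenfunctions", {
  set.seed(43)
  g <- seq(0, 1, length.out = 101)
  phi <- cbind(sqrt(2) * sin(2 * pi * g), sqrt(2) * cos(2 * pi * g),
               sqrt(2) * sin(4 * pi * g))
  n <- 500
  sc <- cbind(rnorm(n), rnorm(n), rnorm(n))
  # variance-exact draw isolates estimator error from Monte-Carlo error
  sc <- sweep(sc, 2, apply(sc, 2, sd), "/")
  sc <- sweep(sc, 2, sqrt(c(6, 4, 3)), "*")
  X <- sc %*% t(phi)
  fp <- fit_fpca(X)
  expect_equal(100 * fp$varprop[1:3], c(46.2, 30.8, 23.1), tolerance = 3,
               ignore_attr = TRUE)
  # reconstruction from the kept components explains the kept variance
  R <- reconstruct_curves(fp)
  resid_frac <- var(as.numeric(X - R)) / var(as.numeric(sweep(X, 2, colMeans(X))))
  expect_lt(abs(resid_frac - (1 - sum(fp$varprop[1:3]))), 0.02)
})

test_that("mixture posteriors match the closed-form Bayes responsibilities", {
  set.seed(44)
  X <- matrix(c(rnorm(60, 0, 1), rnorm(60, 4, 1.5)), ncol = 1)
  w <- c(0.4, 0.6); mu <- matrix(c(0, 4), 2, 1)
  covs <- list(matrix(1), matrix(2.25))
  post <- gmm_posteriors(X, w, mu, covs)$posterior
  p1 <- w[1] * dnorm(X[, 1], 0, 1)
  p2 <- w[2] * dnorm(X[, 1], 4, 1.5)
  expect_equal(post[, 1], p1 / (p1 + p2), tolerance = 1e-6)
  expect_equal(rowSums(post), rep(1, nrow(X)))
})

test_that("well-separated blobs select K = 2 with confident posteriors", {
  set.seed(45)
  X <- rbind(matrix(rnorm(200, 0, 0.5), ncol = 2),
             matrix(rnorm(200, 6, 0.5), ncol = 2))
  m <- fit_cluster_model(X, K_range = 1:4, n_restarts = 5)
  expect_equal(m$K, 2L)
  expect_true(all(apply(m$posterior, 1, max) > 0.99))
})

test_that("threshold assignment is gated and monotone in the threshold", {
  fake <- list(posterior = rbind(c(0.85, 0.15), c(0.79, 0.21), c(0.5, 0.5)))
  expect_equal(assign_with_threshold(fake, 0.8), c(1L, NA, NA))
  expect_equal(assign_with_threshold(fake, 0), c(1L, 1L, 1L))
  set.seed(46)
  P <- t(apply(matrix(rexp(300), ncol = 3), 1, function(x) x / sum(x)))
  fake <- list(posterior = P)
  counts <- sapply(seq(0, 1, 0.1), function(th)
    sum(!is.na(assign_with_threshold(fake, th))))
  expect_true(all(diff(counts) <= 0))
})

test_that("cluster summaries conserve totals and bound envelopes", {
  set.seed(47)
  pop <- make_archetype_profiles(120)
  curves <- normalize_dives(pop$profiles)
  fp <- fit_fpca(curves)
  m <- fit_cluster_model(fp$scores, K_range = 2:6, n_restarts = 3)
  dives <- data.frame(id = seq_len(120),
                      individual = rep(1:2, each = 60))
  events <- data.frame(individual = c(1, 1, 2), dive_id = c(1, 1, 61),
                       excluded = c(FALSE, FALSE, FALSE))
  s <- summarize_clusters(m$assignment, curves, dives, events)
  expect_equal(s$n_assigned + s$n_unclassified, 120L)
  expect_equal(sum(s$table$total), s$n_assigned)
  expect_lte(sum(s$table$n_prca), nrow(events))
  for (env in s$envelopes) {
    expect_true(all(env$mean >= env$quantiles[1, ] - 1e-9))
    expect_true(all(env$mean <= env$quantiles[4, ] + 1e-9))
  }
  # label permutation leaves the dive-count table contents invariant
  perm <- m$assignment
  perm[!is.na(perm)] <- (perm[!is.na(perm)] %% m$K) + 1L
  s2 <- summarize_clusters(perm, curves, dives, events)
  expect_equal(sort(s2$table$total), sort(s$table$total))
})

test_that("the EM fit agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))  # Mclust needs attachment
  set.seed(48)
  X <- rbind(matrix(rnorm(300, 0, 1), ncol = 3),
             matrix(rnorm(300, 3, 1), ncol = 3))
  ours <- sealforage:::fit_gmm_restarts(X, K = 2, family = "VVV",
                                        n_restarts = 5, tol = 1e-8,
                                        max_iter = 1000)
  ref <- mclust::Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  expect_lt(abs(ours$loglik - ref$loglik) / abs(ref$loglik), 1e-3)
  agree <- mean(abs(ours$posterior[, 1] - ref$z[, 1]) < 0.02)
  agree <- max(agree, mean(abs(ours$posterior[, 1] - ref$z[, 2]) < 0.02))
  expect_gt(agree, 0.98)
})

test_that("partition agreement is label-invariant and handles NA", {
  a <- c(1, 1, 2, 2, 3, NA)
  expect_equal(cluster_agreement(a, a), 1)
  relab <- c(7, 7, 1, 1, 9, NA)          # same partition, different labels
  expect_equal(cluster_agreement(a, relab), 1)
  b <- c(1, 2, 1, 2, 1, 1)
  # brute-force oracle over labelled pairs
  ok <- !is.na(a)
  pairs <- combn(which(ok), 2)
  oracle <- mean(apply(pairs, 2, function(p)
    (a[p[1]] == a[p[2]]) == (b[p[1]] == b[p[2]])))
  expect_equal(cluster_agreement(a, b), oracle)
  expect_true(is.na(cluster_agreement(c(1, NA), c(1, NA))))
})
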