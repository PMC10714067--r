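# Gaussian-mixture model-based clustering with covariance-family selection.
#
# Families (mclust-style naming): EII spherical-equal, VII spherical-varying,
# EEI diagonal-equal, VVI diagonal-varying, EEE full-equal, VVV full-varying.

gmm_families <- c("EII", "VII", "EEI", "VVI", "EEE", "VVV")

# log N(x; mu, Sigma) for all rows of X, Sigma given by its Cholesky factor
log_dmvnorm <- function(X, mu, chol_sigma) {
  n <- nrow(X); d <- ncol(X)
  Xc <- X - matrix(mu, n, d, byrow = TRUE)
  z <- Xc %*% backsolve(chol_sigma, diag(d))
  -0.5 * rowSums(z * z) - sum(log(diag(chol_sigma))) - 0.5 * d * log(2 * pi)
}

cov_df <- function(family, K, d) {
  switch(family,
    EII = 1, VII = K, EEI = d, VVI = K * d,
    EEE = d * (d + 1) / 2, VVV = K * d * (d + 1) / 2,
    stop("unknown covariance family"))
}

# list of K covariance matrices from responsibilities, per family
mstep_cov <- function(X, R, mu, family) {
  n <- nrow(X); d <- ncol(X); K <- ncol(R)
  Nk <- colSums(R)
  Sk <- lapply(seq_len(K), function(k) {
    Xc <- X - matrix(mu[k, ], n, d, byrow = TRUE)
    crossprod(Xc * R[, k], Xc)
  })
  ridge <- diag(1e-8, d)
  switch(family,
    VVV = lapply(seq_len(K), function(k) Sk[[k]] / Nk[k] + ridge),
    EEE = { S <- Reduce(`+`, Sk) / n + ridge; rep(list(S), K) },
    VVI = lapply(seq_len(K), function(k) diag(diag(Sk[[k]]) / Nk[k], d) + ridge),
    EEI = { S <- diag(diag(Reduce(`+`, Sk)) / n, d) + ridge; rep(list(S), K) },
    VII = lapply(seq_len(K), function(k)
      diag(sum(diag(Sk[[k]])) / (Nk[k] * d), d) + ridge),
    EII = { s2 <- sum(vapply(Sk, function(S) sum(diag(S)), numeric(1))) / (n * d)
            rep(list(diag(s2, d)), K) })
}

#' Posterior component probabilities of a Gaussian mixture
#'
#' Bayes responsibilities `p(k | x)` for given mixture weights, means and
#' covariance matrices.
#'
#' @param X data matrix (n x d).
#' @param weights mixture weights (length K, summing to 1).
#' @param means matrix of component means (K x d).
#' @param covs list of K covariance matrices (d x d).
#' @return List: `posterior` (n x K, rows sum to 1) and `loglik` (total
#'   observed-data log-likelihood).
#' @export
gmm_posteriors <- function(X, weights, means, covs) {
  X <- as.matrix(X)
  n <- nrow(X)
  K <- length(weights)
  L <- matrix(0, n, K)
  for (k in seq_len(K))
    L[, k] <- log(weights[k]) + log_dmvnorm(X, means[k, ], chol(covs[[k]]))
  m <- L[, 1L]
  if (K > 1L) for (k in 2:K) m <- pmax(m, L[, k])
  lse <- m + log(rowSums(exp(L - m)))
  list(posterior = exp(L - lse), loglik = sum(lse))
}

# one EM fit from given initial means
em_gmm <- function(X, K, family, mu0, tol = 1e-6, max_iter = 500) {
  n <- nrow(X); d <- ncol(X)
  mu <- mu0
  # initial hard assignment to nearest mean
  dists <- vapply(seq_len(K), function(k)
    rowSums((X - matrix(mu[k, ], n, d, byrow = TRUE))^2), numeric(n))
  z <- max.col(-matrix(dists, nrow = n))
  R <- matrix(0, n, K); R[cbind(seq_len(n), z)] <- 1
  R <- R + 1e-6; R <- R / rowSums(R)
  w <- colSums(R) / n
  covs <- mstep_cov(X, R, mu, family)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    ep <- gmm_posteriors(X, w, mu, covs)
    R <- ep$posterior
    ll <- ep$loglik
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (1 + abs(ll))) break
    ll_old <- ll
    Nk <- colSums(R)
    if (any(Nk < d + 1e-3)) stop("degenerate component")
    w <- Nk / n
    mu <- t(R) %*% X / Nk
    covs <- mstep_cov(X, R, mu, family)
  }
  df <- (K - 1) + K * d + cov_df(family, K, d)
  list(loglik = ll, weights = w, means = mu, covs = covs, posterior = R,
       K = K, family = family, df = df, bic = -2 * ll + df * log(n))
}

fit_gmm_restarts <- function(X, K, family, n_restarts, tol, max_iter) {
  n <- nrow(X)
  best <- NULL
  reproduced <- 0L
  for (r in seq_len(n_restarts)) {
    mu0 <- if (r == 1L && K > 1L && n > K) {
      km <- tryCatch(stats::kmeans(X, K, nstart = 3L), error = function(e) NULL)
      if (is.null(km)) X[sample.int(n, K), , drop = FALSE] else km$centers
    } else {
      X[sample.int(n, K), , drop = FALSE]
    }
    fit <- tryCatch(em_gmm(X, K, family, mu0, tol, max_iter),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (!is.null(best) && abs(fit$loglik - best$loglik) < 1e-4 * (1 + abs(best$loglik)))
      reproduced <- reproduced + 1L
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
    # the dominant optimum has been reproduced: further restarts are redundant
    if (r >= 3L && reproduced >= 2L) break
  }
  best
}

#' Model-based clustering of fPCA scores
#'
#' Fits Gaussian mixtures by expectation-maximisation for every number of
#' components in `K_range` and every covariance family (spherical, diagonal
#' and full, each with equal or varying volume/shape across components), and
#' selects the model minimising the Bayesian information criterion.
#' Each fit uses multiple restarts (one k-means seeding plus random means);
#' restarts stop early once the best log-likelihood has been reproduced
#' twice, since further restarts cannot improve a reproduced optimum in
#' practice.
#'
#' @param scores numeric score matrix (dives x dimensions).
#' @param K_range candidate component counts (default 1:9).
#' @param families covariance families to try (default all six).
#' @param n_restarts EM restarts per model (default 10).
#' @param threshold posterior threshold for assignment (default 0.8).
#' @param tol EM convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_iter maximum EM iterations (default 500).
#' @return Object of class `cluster_model`: selected `K`, `family`,
#'   `weights`, `means`, `covs`, `posterior`, `assignment` (NA =
#'   unclassified below the threshold), `threshold`, `bic`, and a `trace`
#'   data.frame of all (K, family, BIC) fits.
#' @export
fit_cluster_model <- function(scores, K_range = 1:9, families = gmm_families,
                              n_restarts = 10, threshold = 0.8,
                              tol = 1e-6, max_iter = 500) {
  X <- as.matrix(scores)
  if (nrow(X) < 2L * max(K_range)) stop("too few score vectors for K_range")
  trace <- list(); best <- NULL
  for (K in K_range) {
    for (fam in families) {
      fit <- fit_gmm_restarts(X, K, fam, n_restarts, tol, max_iter)
      if (is.null(fit)) {
        warning(sprintf("family %s with K = %d skipped (degenerate covariance)",
                        fam, K))
        next
      }
      trace[[length(trace) + 1L]] <-
        data.frame(K = K, family = fam, loglik = fit$loglik,
                   df = fit$df, bic = fit$bic)
      if (is.null(best) || fit$bic < best$bic) best <- fit
    }
  }
  if (is.null(best)) stop("no mixture model could be fitted")
  out <- best
  out$trace <- do.call(rbind, trace)
  out$threshold <- threshold
  class(out) <- "cluster_model"
  out$assignment <- assign_with_threshold(out, threshold)
  out
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("Gaussian mixture: K = %d (%s), BIC = %.1f; %d/%d assigned at %.0f%%\n",
              x$K, x$family, x$bic, sum(!is.na(x$assignment)),
              nrow(x$posterior), 100 * x$threshold))
  invisible(x)
}

#' Posterior probabilities for new data
#'
#' @param object a `cluster_model`.
#' @param newdata score matrix; defaults to the training scores' posteriors.
#' @param ... unused.
#' @return Posterior matrix (rows sum to 1).
#' @export
predict.cluster_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$posterior)
  gmm_posteriors(as.matrix(newdata), object$weights, object$means,
                 object$covs)$posterior
}

#' Threshold-gated cluster assignment
#'
#' A dive is assigned to its maximum-posterior cluster only when that
#' posterior reaches the threshold; otherwise it stays unclassified (NA).
#' Raising the threshold can only shrink the assigned set.
#'
#' @param model a `cluster_model` (or any object with a `posterior` matrix).
#' @param threshold posterior certainty required (default 0.8).
#' @return Integer vector of cluster ids with NA for unclassified dives.
#' @export
assign_with_threshold <- function(model, threshold = 0.8) {
  P <- model$posterior
  amax <- max.col(P, ties.method = "first")
  pmaxv <- P[cbind(seq_len(nrow(P)), amax)]
  ifelse(pmaxv >= threshold, amax, NA_integer_)
}
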