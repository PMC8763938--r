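# Full-covariance Gaussian mixture fitting by EM with k-means++ restarts.
# This is the clustering engine behind radial-layer identification; BIC
# over a candidate range of component counts selects the layer number.

# log N(x | mu, Sigma) for all rows of X; closed form for d = 2 (the
# common case here), Cholesky otherwise
log_dmvnorm <- function(X, mu, sigma) {
  d <- ncol(X)
  if (d == 2L) {
    det_s <- sigma[1, 1] * sigma[2, 2] - sigma[1, 2]^2
    if (!is.finite(det_s) || det_s <= 0) return(rep(-Inf, nrow(X)))
    x1 <- X[, 1] - mu[1]; x2 <- X[, 2] - mu[2]
    quad <- (sigma[2, 2] * x1 * x1 - 2 * sigma[1, 2] * x1 * x2 +
               sigma[1, 1] * x2 * x2) / det_s
    return(-0.5 * (2 * log(2 * pi) + log(det_s) + quad))
  }
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) return(rep(-Inf, nrow(X)))
  xc <- sweep(X, 2, mu)
  z <- xc %*% chol2inv(ch)
  quad <- rowSums(z * xc)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + quad)
}

rowmax_mat <- function(m) {
  out <- m[, 1]
  if (ncol(m) > 1) for (j in 2:ncol(m)) out <- pmax(out, m[, j])
  out
}

# k-means++ seeding of component means
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  idx <- sample.int(n, 1)
  centers <- X[idx, , drop = FALSE]
  mind2 <- rowSums(sweep(X, 2, X[idx, ])^2)
  while (nrow(centers) < k) {
    cum <- cumsum(mind2)
    idx <- findInterval(stats::runif(1) * cum[n], cum) + 1L
    centers <- rbind(centers, X[idx, , drop = FALSE])
    mind2 <- pmin(mind2, rowSums(sweep(X, 2, X[idx, ])^2))
  }
  centers
}

gmm_em_once <- function(X, k, max_iter, tol, reg) {
  n <- nrow(X); d <- ncol(X)
  if (d == 2L) return(gmm_em_once_2d(X, k, max_iter, tol, reg))
  mu <- kmeanspp_init(X, k)
  w <- rep(1 / k, k)
  s0 <- stats::cov(X) + diag(reg, d)
  sigma <- replicate(k, s0, simplify = FALSE)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    logd <- vapply(seq_len(k),
                   function(j) log(w[j]) + log_dmvnorm(X, mu[j, ], sigma[[j]]),
                   numeric(n))
    m <- rowmax_mat(logd)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    resp <- exp(logd - lse)
    nk <- colSums(resp)
    if (any(nk < 1e-10)) return(list(converged = FALSE, loglik = -Inf))
    w <- nk / n
    mu <- t(vapply(seq_len(k),
                   function(j) colSums(resp[, j] * X) / nk[j], numeric(d)))
    sigma <- lapply(seq_len(k), function(j) {
      xc <- sweep(X, 2, mu[j, ])
      s <- crossprod(xc * resp[, j], xc) / nk[j]
      s + diag(reg, d)
    })
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      return(list(weights = w, means = mu, covs = sigma, loglik = ll,
                  converged = TRUE, n_iter = iter))
    }
    ll_old <- ll
  }
  list(weights = w, means = mu, covs = sigma, loglik = ll_old,
       converged = FALSE, n_iter = max_iter)
}

# hand-vectorised bivariate EM (the layer-clustering workhorse)
gmm_em_once_2d <- function(X, k, max_iter, tol, reg) {
  n <- nrow(X)
  x1 <- X[, 1]; x2 <- X[, 2]
  mu <- kmeanspp_init(X, k)
  w <- rep(1 / k, k)
  s0 <- stats::cov(X)
  s11 <- rep(s0[1, 1] + reg, k); s22 <- rep(s0[2, 2] + reg, k)
  s12 <- rep(s0[1, 2], k)
  logd <- matrix(0, n, k)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      det_s <- s11[j] * s22[j] - s12[j]^2
      if (!is.finite(det_s) || det_s <= 0) {
        return(list(converged = FALSE, loglik = -Inf))
      }
      c1 <- x1 - mu[j, 1]; c2 <- x2 - mu[j, 2]
      quad <- (s22[j] * c1 * c1 - 2 * s12[j] * c1 * c2 + s11[j] * c2 * c2) /
        det_s
      logd[, j] <- log(w[j]) - 0.5 * (2 * log(2 * pi) + log(det_s) + quad)
    }
    m <- rowmax_mat(logd)
    lse <- m + log(rowSums(exp(logd - m)))
    ll <- sum(lse)
    resp <- exp(logd - lse)
    nk <- colSums(resp)
    if (any(nk < 1e-10)) return(list(converged = FALSE, loglik = -Inf))
    w <- nk / n
    for (j in seq_len(k)) {
      r <- resp[, j]
      m1 <- sum(r * x1) / nk[j]; m2 <- sum(r * x2) / nk[j]
      c1 <- x1 - m1; c2 <- x2 - m2
      mu[j, 1] <- m1; mu[j, 2] <- m2
      s11[j] <- sum(r * c1 * c1) / nk[j] + reg
      s22[j] <- sum(r * c2 * c2) / nk[j] + reg
      s12[j] <- sum(r * c1 * c2) / nk[j]
    }
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      covs <- lapply(seq_len(k), function(j) {
        matrix(c(s11[j], s12[j], s12[j], s22[j]), 2, 2)
      })
      return(list(weights = w, means = mu, covs = covs, loglik = ll,
                  converged = TRUE, n_iter = iter))
    }
    ll_old <- ll
  }
  covs <- lapply(seq_len(k), function(j) {
    matrix(c(s11[j], s12[j], s12[j], s22[j]), 2, 2)
  })
  list(weights = w, means = mu, covs = covs, loglik = ll_old,
       converged = FALSE, n_iter = max_iter)
}

#' Fit a full-covariance Gaussian mixture by EM
#'
#' Expectation-maximisation with `n_init` k-means++ restarts; the restart
#' with the highest log-likelihood wins. Covariances are regularised by
#' adding `reg` to the diagonal at every M-step.
#'
#' @param X Numeric matrix (observations x dimensions).
#' @param k Number of mixture components.
#' @param n_init Number of random restarts (default 10).
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Relative log-likelihood convergence tolerance (default 1e-4).
#' @param reg Diagonal covariance regulariser.
#' @param seed Optional RNG seed for reproducible restarts.
#' @return List with `weights`, `means` (k x d), `covs` (list of d x d),
#'   `loglik`, `bic`, `converged`, `k`, `n_params`.
#' @export
gmm_fit <- function(X, k, n_init = 10, max_iter = 100, tol = 1e-4,
                    reg = 1e-6, seed = NULL) {
  X <- as.matrix(X)
  stopifnot(k >= 1, nrow(X) >= 2 * k, all(is.finite(X)))
  if (!is.null(seed)) set.seed(seed)
  best <- list(loglik = -Inf, converged = FALSE)
  if (k == 1L) {
    # single Gaussian has a closed-form MLE; restarts are pointless
    mu <- matrix(colMeans(X), nrow = 1)
    s <- stats::cov(X) * (nrow(X) - 1) / nrow(X) + diag(reg, ncol(X))
    ll <- sum(log_dmvnorm(X, mu[1, ], s))
    best <- list(weights = 1, means = mu, covs = list(s), loglik = ll,
                 converged = TRUE, n_iter = 0L)
    n_init <- 0L
  }
  for (i in seq_len(n_init)) {
    fit <- gmm_em_once(X, k, max_iter, tol, reg)
    if (isTRUE(fit$converged) && fit$loglik > best$loglik) best <- fit
  }
  if (!isTRUE(best$converged)) {
    return(list(k = k, converged = FALSE, loglik = NA_real_, bic = NA_real_))
  }
  n <- nrow(X); d <- ncol(X)
  n_params <- (k - 1) + k * d + k * d * (d + 1) / 2
  best$k <- k
  best$n_params <- n_params
  best$bic <- -2 * best$loglik + n_params * log(n)
  best
}

#' Posterior component responsibilities under a fitted mixture
#'
#' @param fit A converged [gmm_fit()] result.
#' @param X Numeric matrix of observations.
#' @return Matrix (n x k) of posterior probabilities; rows sum to 1.
#' @export
gmm_posterior <- function(fit, X) {
  X <- as.matrix(X)
  k <- fit$k
  logd <- vapply(seq_len(k),
                 function(j) log(fit$weights[j]) +
                   log_dmvnorm(X, fit$means[j, ], fit$covs[[j]]),
                 numeric(nrow(X)))
  if (!is.matrix(logd)) logd <- matrix(logd, nrow = 1)
  m <- rowmax_mat(logd)
  p <- exp(logd - m)
  p / rowSums(p)
}
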