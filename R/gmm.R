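# Diagonal-covariance Gaussian mixture codebooks and Fisher-vector encoding.

#' Fit a diagonal-covariance Gaussian mixture codebook
#'
#' EM with k-means++ initialization; variances are floored at a small
#' fraction of the global per-dimension variance for numerical stability.
#'
#' @param features Numeric matrix, one local feature per row.
#' @param G Number of mixture components.
#' @param seed RNG seed.
#' @param max_iter EM iteration cap.
#' @param tol Relative log-likelihood convergence tolerance.
#' @return Object of class `srp_gmm`: list with `weights` (length G,
#'   positive, summing to 1), `means` (G x D), `variances` (G x D,
#'   positive), `seed`, `loglik`.
#' @export
fit_gmm <- function(features, G, seed = 42L, max_iter = 100L, tol = 1e-6) {
  x <- as.matrix(features)
  n <- nrow(x)
  d <- ncol(x)
  if (n < G) stop_srp("need at least G features to fit the mixture")
  km <- kmeans_pp(x, G, seed, nstart = 3L)
  gvar <- apply(x, 2L, stats::var)
  gvar[!is.finite(gvar) | gvar <= 0] <- 1
  floorv <- gvar * 1e-4 + 1e-12
  mu <- unname(km$centers)
  w <- as.vector(table(factor(km$cluster, levels = seq_len(G)))) / n
  w <- pmax(w, 1e-6); w <- w / sum(w)
  sig2 <- matrix(rep(gvar, each = G), G, d)
  prev <- -Inf
  loglik <- -Inf
  for (it in seq_len(max_iter)) {
    lp <- gmm_log_posteriors(x, w, mu, sig2)
    loglik <- sum(lp$norm)
    gamma <- exp(lp$logpost)
    ng <- colSums(gamma)
    ng <- pmax(ng, 1e-10)
    w <- ng / n
    mu <- sweep(t(gamma) %*% x, 1L, ng, `/`)
    ex2 <- sweep(t(gamma) %*% (x^2), 1L, ng, `/`)
    sig2 <- pmax(ex2 - mu^2, rep(floorv, each = G))
    if (is.finite(prev) && abs(loglik - prev) <= tol * (abs(prev) + 1)) break
    prev <- loglik
  }
  structure(list(weights = w, means = mu, variances = sig2, seed = seed,
                 loglik = loglik, G = G, D = d),
            class = "srp_gmm")
}

# Log posteriors (n x G) and per-row log normalizer under a diagonal GMM.
gmm_log_posteriors <- function(x, w, mu, sig2) {
  n <- nrow(x)
  G <- length(w)
  lg <- matrix(0, n, G)
  for (g in seq_len(G)) {
    z <- sweep(x, 2L, mu[g, ])^2
    z <- sweep(z, 2L, sig2[g, ], `/`)
    lg[, g] <- log(w[g]) - 0.5 * (sum(log(2 * pi * sig2[g, ])) + rowSums(z))
  }
  m <- apply(lg, 1L, max)
  norm <- m + log(rowSums(exp(lg - m)))
  list(logpost = lg - norm, norm = norm)
}

#' Fisher-vector encoding of local features
#'
#' Encodes a set of local features as the gradient of the GMM
#' log-likelihood with respect to the component means and standard
#' deviations (the improved Fisher vector: the weight-gradient block is
#' omitted, giving dimension 2GD). Power (signed square root) and L2
#' post-normalization are applied by default.
#'
#' @param features Numeric matrix, one local feature per row (dimension D).
#' @param gmm An `srp_gmm` with matching dimension.
#' @param normalize Apply power + L2 normalization (default TRUE).
#' @return Object of class `srp_encoded` with `vector` of length 2 * G * D
#'   and `kind = "fv"`.
#' @export
encode_fv <- function(features, gmm, normalize = TRUE) {
  x <- as.matrix(features)
  if (!inherits(gmm, "srp_gmm")) stop_srp("`gmm` must be an srp_gmm")
  if (ncol(x) != ncol(gmm$means)) {
    stop_srp(sprintf("feature dimension %d does not match GMM dimension %d",
                     ncol(x), ncol(gmm$means)))
  }
  n <- nrow(x)
  G <- length(gmm$weights)
  d <- ncol(x)
  gamma <- exp(gmm_log_posteriors(x, gmm$weights, gmm$means, gmm$variances)$logpost)
  sig <- sqrt(gmm$variances)
  u <- matrix(0, G, d)
  v <- matrix(0, G, d)
  for (g in seq_len(G)) {
    z <- sweep(sweep(x, 2L, gmm$means[g, ]), 2L, sig[g, ], `/`)
    gz <- gamma[, g]
    u[g, ] <- colSums(z * gz) / (n * sqrt(gmm$weights[g]))
    v[g, ] <- colSums((z^2 - 1) * gz) / (n * sqrt(2 * gmm$weights[g]))
  }
  fv <- c(as.vector(t(u)), as.vector(t(v)))
  if (normalize) {
    fv <- sign(fv) * sqrt(abs(fv))
    nrm <- sqrt(sum(fv^2))
    if (nrm > 0) fv <- fv / nrm
  }
  structure(list(vector = fv, kind = "fv", G = G, D = d),
            class = "srp_encoded")
}
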