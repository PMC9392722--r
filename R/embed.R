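#' Neighbor-graph manifold embedding of waveforms
#'
#' Nonlinear dimensionality reduction of a set of waveforms (rows) by the
#' fuzzy k-nearest-neighbor graph construction: per-point bandwidths are
#' calibrated so each point's effective neighborhood has size `log2(k)`,
#' edge memberships are symmetrized by fuzzy union, the layout is initialized
#' from the spectral embedding of the graph Laplacian, and then optimized by
#' stochastic gradient descent on the graph cross-entropy with an attraction
#' curve `1 / (1 + a d^(2b))` fitted from `min_dist`. This is the standard
#' UMAP construction; deterministic under a fixed seed.
#'
#' @param x numeric matrix, rows = items (e.g. one evoked potential per row,
#'   time points as columns).
#' @param d embedding dimension (2 to 100).
#' @param n_neighbors neighborhood size (default 15).
#' @param min_dist minimum separation of embedded neighbors (default 0.1).
#' @param n_epochs optimization epochs.
#' @param seed integer seed (recorded in the result).
#' @param learning_rate initial SGD step size.
#' @param negative_samples repulsive samples per attractive update.
#' @return An `esconn_embedding`: list with `coordinates` (rows x d),
#'   `n_neighbors`, `min_dist`, `seed`, `ab` (fitted curve parameters).
#' @export
embed_waveforms <- function(x, d = 2, n_neighbors = 15, min_dist = 0.1,
                            n_epochs = 200, seed = 1234, learning_rate = 1,
                            negative_samples = 5) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n <= n_neighbors) stop("need more rows (", n, ") than n_neighbors (",
                             n_neighbors, ")")
  if (d < 2 || d > 100) stop("embedding dimension must be in [2, 100]")
  set.seed(seed)
  D <- as.matrix(stats::dist(x))
  ## k nearest neighbors (excluding self)
  knn_idx <- t(apply(D, 1, function(r) order(r)[2:(n_neighbors + 1)]))
  knn_dist <- t(vapply(seq_len(n), function(i) D[i, knn_idx[i, ]],
                       numeric(n_neighbors)))
  ## smooth-kNN bandwidth calibration: rho = nearest distance, sigma solved
  ## so that sum exp(-(d - rho)+ / sigma) = log2(k)
  rho <- knn_dist[, 1]
  target <- log2(n_neighbors)
  sigma <- vapply(seq_len(n), function(i) {
    dd <- pmax(knn_dist[i, ] - rho[i], 0)
    if (all(dd == 0)) return(1)
    lo <- 1e-6; hi <- max(dd) * 10
    for (it in 1:64) {
      mid <- (lo + hi) / 2
      s <- sum(exp(-dd / mid))
      if (s > target) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  ## directed memberships, then fuzzy union symmetrization
  W <- matrix(0, n, n)
  for (i in seq_len(n))
    W[i, knn_idx[i, ]] <- exp(-pmax(knn_dist[i, ] - rho[i], 0) / sigma[i])
  W <- W + t(W) - W * t(W)

  ## attraction curve parameters from min_dist
  ab <- fit_ab(min_dist)
  a <- ab[1]; b <- ab[2]

  ## spectral initialization from the symmetric normalized Laplacian
  deg <- pmax(rowSums(W), 1e-12)
  Lsym <- diag(n) - diag(1 / sqrt(deg)) %*% W %*% diag(1 / sqrt(deg))
  ev <- eigen(symmetrize(Lsym), symmetric = TRUE)
  emb <- ev$vectors[, (n - 1):(n - d), drop = FALSE]
  emb <- emb / max(abs(emb)) * 10
  emb <- emb + matrix(stats::rnorm(n * d, 0, 1e-4), n, d)

  ## SGD on the cross-entropy, vectorized per epoch
  eidx <- which(W > 0 & upper.tri(W), arr.ind = TRUE)
  ei <- eidx[, 1]; ej <- eidx[, 2]; ew <- W[eidx]
  clip4 <- function(v) pmax(pmin(v, 4), -4)
  for (epoch in seq_len(n_epochs)) {
    alpha <- learning_rate * (1 - (epoch - 1) / n_epochs)
    sel <- stats::runif(length(ew)) < ew
    if (!any(sel)) next
    ii <- ei[sel]; jj <- ej[sel]
    diff <- emb[ii, , drop = FALSE] - emb[jj, , drop = FALSE]
    d2 <- rowSums(diff^2)
    coef <- -2 * a * b * d2^(b - 1) / (1 + a * d2^b)
    coef[!is.finite(coef)] <- 0
    grad <- clip4(coef * diff)
    upd <- rowsum(rbind(grad, -grad), c(ii, jj))
    ridx <- as.integer(rownames(upd))
    emb[ridx, ] <- emb[ridx, ] + alpha * upd
    ## negative sampling: repulsion from random points
    for (s in seq_len(negative_samples)) {
      kk <- sample.int(n, length(ii), replace = TRUE)
      diff <- emb[ii, , drop = FALSE] - emb[kk, , drop = FALSE]
      d2 <- rowSums(diff^2)
      coef <- 2 * b / ((0.001 + d2) * (1 + a * d2^b))
      coef[kk == ii] <- 0
      grad <- clip4(coef * diff)
      upd <- rowsum(grad, ii)
      ridx <- as.integer(rownames(upd))
      emb[ridx, ] <- emb[ridx, ] + alpha * upd
    }
  }
  structure(list(coordinates = emb, n_neighbors = n_neighbors,
                 min_dist = min_dist, seed = seed, ab = c(a = a, b = b)),
            class = "esconn_embedding")
}

## Least-squares fit of 1/(1 + a d^(2b)) to the target membership curve
## exp(-(d - min_dist)) for d > min_dist (1 below), on a grid.
fit_ab <- function(min_dist, spread = 1) {
  dgrid <- seq(0, 3 * spread, length.out = 300)
  target <- ifelse(dgrid <= min_dist, 1, exp(-(dgrid - min_dist) / spread))
  obj <- function(p) {
    a <- exp(p[1]); b <- exp(p[2])
    sum((1 / (1 + a * dgrid^(2 * b)) - target)^2)
  }
  o <- stats::optim(c(log(1.5), log(1)), obj)
  exp(o$par)
}
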