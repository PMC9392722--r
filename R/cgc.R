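## Nonparametric spectral conditional Granger causality.
##
## The estimator is model-free: a multitaper cross-spectral matrix is
## factorized with Wilson's algorithm into a minimum-phase transfer function
## and an innovation covariance, from which Geweke-style directed measures
## are formed. Conditional causality uses the two-factorization (reduced
## model) construction, avoiding multivariate autoregressive model
## misspecification.

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the standard symmetric tridiagonal eigenproblem whose
#' eigenvectors are the DPSS sequences. Tapers are normalized to unit energy.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product.
#' @param k number of tapers (k <= 2*nw - 1 is well-concentrated).
#' @return Matrix `n x k`; columns are tapers ordered by concentration.
#' @export
dpss_tapers <- function(n, nw = 2, k = 3) {
  stopifnot(n >= 2, k >= 1, k <= n)
  W <- nw / n
  t <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  diag_off <- t[-1] * (n - t[-1]) / 2
  M <- diag(diag_main)
  M[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- diag_off
  M[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- diag_off
  e <- eigen(M, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  ## sign convention: symmetric tapers positive mean, antisymmetric positive
  ## initial slope
  for (j in seq_len(k)) {
    s <- sum(v[, j])
    if (abs(s) > 1e-8) { if (s < 0) v[, j] <- -v[, j] }
    else if (v[2, j] - v[1, j] < 0) v[, j] <- -v[, j]
  }
  sweep(v, 2, sqrt(colSums(v^2)), "/")
}

#' Multitaper cross-spectral density from trials
#'
#' Extracts an analysis window from each trial, demeans each trial-channel
#' segment, applies Slepian tapers, and averages the tapered FFT
#' cross-products over trials and tapers. The frequency grid comes from a
#' zero-padded FFT, making specific evaluation frequencies (such as 8 Hz)
#' addressable despite the short epoch.
#'
#' @param trials an `esconn_trialset`.
#' @param window_ms analysis window in ms relative to onset (default the
#'   late-response epoch \[70, 200) ms); `NULL` uses the whole record.
#' @param nw time-bandwidth product of the tapers.
#' @param n_tapers number of tapers.
#' @param nfft FFT length (>= window length; default the next power of two
#'   of at least twice the window length and at least 512, so the spectral
#'   factor is representable on the grid).
#' @param channels optional channel subset (indices or names).
#' @return An `esconn_csd`: list with `S` (ch x ch x n_freqs, complex,
#'   Hermitian at each frequency), `freqs` (Hz, 0..Nyquist), `fs`, `nfft`,
#'   `n_trials`, `n_tapers`, `window_ms`, `channel_names`.
#' @export
estimate_csd <- function(trials, window_ms = c(70, 200), nw = 2, n_tapers = 3,
                         nfft = NULL, channels = NULL) {
  stopifnot(inherits(trials, "esconn_trialset"))
  d <- dim(trials$data)
  if (d[2] < 2) stop("at least 2 trials required")
  idx <- if (is.null(window_ms)) seq_len(d[3])
         else window_indices(window_ms, trials$fs, trials$t0_index, d[3])
  ch <- seq_len(d[1])
  if (!is.null(channels)) {
    ch <- if (is.character(channels)) match(channels, trials$channels$name)
          else channels
  }
  nseg <- length(idx)
  if (nseg < 8) stop("analysis window shorter than taper support")
  ## nfft >= 2*nseg: the exact spectral factor of a lag-limited spectrum is
  ## then representable on the grid, so Wilson factorization can converge to
  ## machine precision rather than a wrap-around floor
  if (is.null(nfft)) nfft <- max(512, 2^ceiling(log2(2 * nseg)))
  if (nfft < nseg) stop("nfft must be >= window length")
  tapers <- dpss_tapers(nseg, nw, n_tapers)
  m <- length(ch)
  nf <- nfft %/% 2 + 1
  ## tapered FFTs: channels x (trials*tapers) per frequency
  X <- array(complex(real = 0), dim = c(m, d[2] * n_tapers, nf))
  for (ci in seq_along(ch)) {
    col <- 0
    for (tr in seq_len(d[2])) {
      seg <- trials$data[ch[ci], tr, idx]
      seg <- seg - mean(seg)
      for (k in seq_len(n_tapers)) {
        col <- col + 1
        xt <- c(seg * tapers[, k], numeric(nfft - nseg))
        X[ci, col, ] <- stats::fft(xt)[seq_len(nf)]
      }
    }
  }
  S <- array(complex(real = 0), dim = c(m, m, nf))
  for (f in seq_len(nf)) {
    Xf <- X[, , f, drop = FALSE]; dim(Xf) <- c(m, d[2] * n_tapers)
    S[, , f] <- (Xf %*% Conj(t(Xf))) / (d[2] * n_tapers)
  }
  structure(list(S = S, freqs = (seq_len(nf) - 1) * trials$fs / nfft,
                 fs = trials$fs, nfft = nfft, n_trials = d[2],
                 n_tapers = n_tapers, window_ms = window_ms,
                 channel_names = trials$channels$name[ch]),
            class = "esconn_csd")
}

## Extract a channel-subset CSD.
csd_subset <- function(csd, idx) {
  out <- csd
  out$S <- csd$S[idx, idx, , drop = FALSE]
  out$channel_names <- csd$channel_names[idx]
  out
}

#' Wilson spectral matrix factorization
#'
#' Iterative factorization `S(f) = H(f) Sigma H(f)^*` of a cross-spectral
#' matrix into a minimum-phase transfer function `H` and a real innovation
#' covariance `Sigma` (Wilson's algorithm). Rank-deficient spectra receive
#' diagonal loading `eps = 1e-8 * trace(S)/ch` before factorization.
#'
#' @param csd an `esconn_csd` (one-sided spectrum; the full circle is
#'   reconstructed internally by Hermitian extension).
#' @param tol relative convergence tolerance on the factor update.
#' @param max_iter maximum iterations; non-convergence is an error carrying
#'   the residual.
#' @param recon_tol acceptable relative reconstruction error when the update
#'   stalls above `tol` (the iteration has a small discretization floor when the
#'   true factor is not lag-limited on the FFT grid).
#' @return An `esconn_sf`: list with `H` (ch x ch x n_freqs, complex, on the
#'   one-sided grid), `Sigma`, `freqs`, `iterations`, `rel_error`
#'   (reconstruction error), `loaded` (whether diagonal loading engaged).
#' @export
wilson_factorize <- function(csd, tol = 1e-9, max_iter = 500,
                             recon_tol = 1e-6) {
  stopifnot(inherits(csd, "esconn_csd"))
  m <- dim(csd$S)[1]; nf <- dim(csd$S)[3]
  nfft <- csd$nfft
  ## full-circle Hermitian extension: S(-f) = Conj(S(f))
  Sfull <- array(complex(real = 0), dim = c(m, m, nfft))
  Sfull[, , seq_len(nf)] <- csd$S
  if (nfft > nf)
    for (f in 2:(nfft - nf + 1)) Sfull[, , nfft - f + 2] <- Conj(csd$S[, , f])

  ## diagonal loading when any S(f) is numerically rank-deficient
  loaded <- FALSE
  min_eig <- min(vapply(seq_len(nf), function(f)
    min(eigen(symmetrize_h(matrix(csd$S[, , f], m, m)),
              symmetric = TRUE, only.values = TRUE)$values), numeric(1)))
  tr_mean <- mean(vapply(seq_len(nf), function(f) {
    Sf <- matrix(csd$S[, , f], m, m)
    sum(Re(Sf[cbind(seq_len(m), seq_len(m))]))
  }, numeric(1)))
  if (min_eig < 1e-12 * tr_mean) {
    eps <- 1e-8 * tr_mean / m
    for (f in seq_len(nfft)) Sfull[, , f] <- Sfull[, , f] + diag(eps, m)
    loaded <- TRUE
  }

  ## initialization: Cholesky factor of the zero-lag autocovariance
  gam0 <- matrix(0, m, m)
  for (f in seq_len(nfft)) gam0 <- gam0 + Re(Sfull[, , f])
  gam0 <- symmetrize(gam0 / nfft)
  h0 <- tryCatch(chol(gam0), error = function(e)
    chol(gam0 + diag(1e-10 * sum(diag(gam0)) / m, m)))
  psi <- array(complex(real = 0), dim = c(m, m, nfft))
  for (f in seq_len(nfft)) psi[, , f] <- h0

  I_m <- diag(m)
  g <- array(complex(real = 0), dim = c(m, m, nfft))
  converged <- FALSE; it <- 0; delta <- Inf
  best_delta <- Inf; stall <- 0; damp <- 1
  for (it in seq_len(max_iter)) {
    for (f in seq_len(nfft)) {
      pf <- psi[, , f]
      ## g = psi^{-1} S psi^{-*} + I
      gi <- solve(pf, Sfull[, , f])
      g[, , f] <- t(solve(Conj(pf), t(gi))) + I_m
    }
    gp <- plus_operator(g)
    psi_new <- array(complex(real = 0), dim = c(m, m, nfft))
    for (f in seq_len(nfft))
      psi_new[, , f] <- psi[, , f] %*%
        (damp * gp[, , f] + (1 - damp) * I_m)
    delta <- max(Mod(psi_new - psi)) / max(max(Mod(psi)), 1e-300)
    psi <- psi_new
    if (delta < tol) { converged <- TRUE; break }
    ## the undamped (Newton-speed) update can fall into a small 2-cycle on
    ## rough spectra; damping breaks the cycle at a linear rate
    if (delta < best_delta * 0.999) { best_delta <- delta; stall <- 0 }
    else {
      stall <- stall + 1
      if (stall >= 5) {
        if (damp > 0.5) { damp <- 0.5; stall <- 0; best_delta <- Inf }
        else break
      }
    }
  }
  ## reconstruction error over the one-sided grid
  rel_err <- 0
  for (f in seq_len(nf)) {
    R <- psi[, , f] %*% Conj(t(psi[, , f]))
    rel_err <- max(rel_err,
                   sqrt(sum(Mod(R - Sfull[, , f])^2)) /
                     max(sqrt(sum(Mod(Sfull[, , f])^2)), 1e-300))
  }
  if (!converged && rel_err >= recon_tol)
    stop("Wilson factorization did not converge in ", it,
         " iterations (update ", signif(delta, 3),
         ", reconstruction error ", signif(rel_err, 3), ")")
  ## A0 = zero-lag coefficient of psi; Sigma = A0 A0'; H = psi A0^{-1}
  A0 <- matrix(0, m, m)
  for (f in seq_len(nfft)) A0 <- A0 + Re(psi[, , f])
  A0 <- A0 / nfft
  Sigma <- symmetrize(A0 %*% t(A0))
  H <- array(complex(real = 0), dim = c(m, m, nf))
  A0inv <- solve(A0)
  for (f in seq_len(nf)) H[, , f] <- psi[, , f] %*% A0inv
  structure(list(H = H, Sigma = Sigma, freqs = csd$freqs,
                 iterations = it, rel_error = rel_err, loaded = loaded,
                 channel_names = csd$channel_names),
            class = "esconn_sf")
}

## Hermitian symmetrization of a single matrix.
symmetrize_h <- function(m) (m + Conj(t(m))) / 2

## Causal projection used by the Wilson iteration: transform to the lag
## domain, keep non-negative lags (half weight at lag zero, upper-triangular
## part only, which fixes the normalization), zero the rest.
plus_operator <- function(g) {
  m <- dim(g)[1]; nfft <- dim(g)[3]
  gam <- array(0, dim = c(m, m, nfft))
  for (i in seq_len(m)) for (j in seq_len(m))
    gam[i, j, ] <- Re(stats::fft(g[i, j, ], inverse = TRUE)) / nfft
  beta0 <- matrix(gam[, , 1], m, m) / 2
  beta0[lower.tri(beta0)] <- 0
  gam[, , 1] <- beta0
  half <- nfft %/% 2
  if (half + 2 <= nfft) gam[, , (half + 2):nfft] <- 0
  gp <- array(complex(real = 0), dim = c(m, m, nfft))
  for (i in seq_len(m)) for (j in seq_len(m))
    gp[i, j, ] <- stats::fft(gam[i, j, ])
  gp
}

#' Conditional (or pairwise) spectral Granger causality for one pair
#'
#' Geweke-style conditional spectral causality from source to target given a
#' conditioning set, via two Wilson factorizations: the full system
#' (target, conditioning, source) and the reduced system with the source
#' removed. The reduced-model innovation process of the target is expressed
#' through the full model; the causality spectrum is the log ratio of the
#' reduced innovation variance to its component intrinsic to the target.
#' With an empty conditioning set this reduces to the pairwise Geweke
#' measure.
#'
#' @param csd an `esconn_csd` over at least the involved channels.
#' @param source,target channel indices (into the CSD) or names.
#' @param cond conditioning channel indices/names; default all remaining
#'   channels; `character(0)`/`integer(0)` gives the pairwise measure.
#' @param tol,max_iter passed to [wilson_factorize()].
#' @return List with `f` (causality spectrum, >= 0), `freqs`, `source`,
#'   `target`, `cond`.
#' @export
conditional_gc <- function(csd, source, target, cond = NULL,
                           tol = 1e-9, max_iter = 500) {
  stopifnot(inherits(csd, "esconn_csd"))
  nm <- csd$channel_names
  as_idx <- function(x) if (is.character(x)) match(x, nm) else x
  source <- as_idx(source); target <- as_idx(target)
  if (is.null(cond)) cond <- setdiff(seq_along(nm), c(source, target))
  else cond <- as_idx(cond)
  if (source == target) stop("source and target must differ")
  full_idx <- c(target, cond, source)    # target first, source last
  red_idx <- c(target, cond)
  sf_full <- wilson_factorize(csd_subset(csd, full_idx), tol, max_iter)
  sf_red <- wilson_factorize(csd_subset(csd, red_idx), tol, max_iter)
  nf <- length(csd$freqs)
  k_full <- length(full_idx)
  k_red <- length(red_idx)

  ## decorrelate the target innovation from the rest (full model):
  ## P = [[1, 0], [-Sigma_rx / Sigma_xx, I]], x = target (index 1)
  Sig <- sf_full$Sigma
  P <- diag(k_full)
  if (k_full > 1) P[2:k_full, 1] <- -Sig[2:k_full, 1] / Sig[1, 1]
  Pinv <- solve(P)
  sig_xx <- Sig[1, 1]
  sig_red_xx <- sf_red$Sigma[1, 1]

  f_spec <- numeric(nf)
  for (f in seq_len(nf)) {
    ## embed the inverse reduced transfer: bigG = I with G on (target, cond)
    bigG <- diag(k_full) + 0i
    bigG[seq_len(k_red), seq_len(k_red)] <- sf_red$H[, , f]
    Q <- solve(bigG, sf_full$H[, , f] %*% Pinv)
    intrinsic <- Mod(Q[1, 1])^2 * sig_xx
    f_spec[f] <- log(sig_red_xx / intrinsic)
  }
  f_spec[f_spec < 0 & f_spec > -1e-8] <- 0   # clamp numerical noise
  list(f = f_spec, freqs = csd$freqs,
       source = nm[source], target = nm[target], cond = nm[cond])
}

#' All-pairs conditional Granger causality
#'
#' Computes the conditional causality spectrum for every ordered channel
#' pair, conditioning each on all remaining channels. One full-system
#' factorization is shared; one reduced factorization per source channel
#' serves all of its targets.
#'
#' @param csd an `esconn_csd`.
#' @param tol,max_iter passed to [wilson_factorize()].
#' @return An `esconn_cgc`: list with `cgc` (source x target x n_freqs,
#'   `NA` on the diagonal), `freqs`, `channel_names`.
#' @export
cgc_all_pairs <- function(csd, tol = 1e-9, max_iter = 500) {
  stopifnot(inherits(csd, "esconn_csd"))
  m <- dim(csd$S)[1]
  nm <- csd$channel_names
  nf <- length(csd$freqs)
  cgc <- array(NA_real_, dim = c(m, m, nf),
               dimnames = list(nm, nm, NULL))
  ## The Wilson factor with H(0) = I is unique, so it transforms covariantly
  ## under channel permutation: one full-system factorization serves every
  ## (source, target) ordering, and one reduced factorization per source
  ## serves all of its targets.
  sf_full <- wilson_factorize(csd, tol, max_iter)
  for (src in seq_len(m)) {
    red_idx <- setdiff(seq_len(m), src)
    sf_red <- wilson_factorize(csd_subset(csd, red_idx), tol, max_iter)
    for (tgt in red_idx) {
      ## order the full system as (target, other conditioning, source)
      cond <- setdiff(red_idx, tgt)
      perm <- c(tgt, cond, src)
      k_full <- m; k_red <- m - 1
      Sig <- sf_full$Sigma[perm, perm]
      P <- diag(k_full)
      P[2:k_full, 1] <- -Sig[2:k_full, 1] / Sig[1, 1]
      Pinv <- solve(P)
      sig_xx <- Sig[1, 1]
      tpos <- match(tgt, red_idx)
      rperm <- c(tpos, setdiff(seq_len(k_red), tpos))
      sig_red_xx <- sf_red$Sigma[tpos, tpos]
      for (f in seq_len(nf)) {
        bigG <- diag(k_full) + 0i
        bigG[seq_len(k_red), seq_len(k_red)] <- sf_red$H[rperm, rperm, f]
        Q <- solve(bigG, sf_full$H[perm, perm, f] %*% Pinv)
        v <- log(sig_red_xx / (Mod(Q[1, 1])^2 * sig_xx))
        cgc[src, tgt, f] <- max(v, 0)
      }
    }
  }
  structure(list(cgc = cgc, freqs = csd$freqs, channel_names = nm),
            class = "esconn_cgc")
}

## Phase-randomize one trial set: FFT each (channel, trial) record,
## randomize phases independently per channel and trial with conjugate
## symmetry (output real, amplitude spectrum preserved), inverse FFT.
phase_randomize_trials <- function(trials) {
  d <- dim(trials$data)
  n <- d[3]
  half <- (n - 1) %/% 2
  out <- trials
  for (c in seq_len(d[1])) for (tr in seq_len(d[2])) {
    X <- stats::fft(trials$data[c, tr, ])
    ph <- stats::runif(half, 0, 2 * pi)
    rot <- rep(1 + 0i, n)
    rot[2:(half + 1)] <- exp(1i * ph)
    rot[n:(n - half + 1)] <- Conj(rot[2:(half + 1)])
    out$data[c, tr, ] <- Re(stats::fft(X * rot, inverse = TRUE)) / n
  }
  out
}

#' Surrogate significance thresholds for conditional Granger causality
#'
#' Builds the null distribution of the CGC estimator by phase randomization:
#' for each surrogate, the Fourier phases of every channel-trial record are
#' rearranged independently (conjugate-symmetric, so the record stays real
#' and its amplitude spectrum — hence autocorrelation — is untouched), which
#' destroys systematic cross-channel causal structure. The full pipeline
#' (cross-spectral estimation, factorization, conditional causality) is
#' re-run per surrogate and the threshold is the chosen percentile across
#' surrogates, per pair and frequency.
#'
#' @param trials an `esconn_trialset`.
#' @param n_surr number of surrogates (>= 20; the study protocol used 200).
#' @param seed integer seed.
#' @param prob percentile defining the threshold (default 0.95).
#' @param window_ms,nw,n_tapers,nfft,channels passed to [estimate_csd()].
#' @param tol,max_iter passed to the factorization.
#' @return List with `threshold` (source x target x n_freqs), `freqs`,
#'   `n_surr`, `channel_names`.
#' @export
surrogate_threshold <- function(trials, n_surr = 200, seed = 1, prob = 0.95,
                                window_ms = c(70, 200), nw = 2, n_tapers = 3,
                                nfft = NULL, channels = NULL,
                                tol = 1e-9, max_iter = 500) {
  if (n_surr < 20) stop("n_surr must be >= 20")
  set.seed(seed)
  csd0 <- estimate_csd(trials, window_ms, nw, n_tapers, nfft, channels)
  m <- dim(csd0$S)[1]; nf <- length(csd0$freqs)
  vals <- array(NA_real_, dim = c(n_surr, m, m, nf))
  for (s in seq_len(n_surr)) {
    surr <- phase_randomize_trials(trials)
    csd <- estimate_csd(surr, window_ms, nw, n_tapers, nfft, channels)
    vals[s, , , ] <- cgc_all_pairs(csd, tol, max_iter)$cgc
  }
  thr <- apply(vals, c(2, 3, 4), function(v)
    if (all(is.na(v))) NA_real_ else stats::quantile(v, prob, names = FALSE))
  dimnames(thr) <- list(csd0$channel_names, csd0$channel_names, NULL)
  list(threshold = thr, freqs = csd0$freqs, n_surr = n_surr,
       channel_names = csd0$channel_names)
}

#' Summarize a causality result at an evaluation frequency
#'
#' Selects the frequency bin nearest the evaluation frequency (the measure
#' peaks in the alpha range, around 8 Hz, reflecting the late evoked
#' component), averages channel-level causality within ROI-group pairs,
#' applies the surrogate significance mask, and reports per-group in/out
#' degrees (sums of significant inflow and outflow).
#'
#' @param result an `esconn_cgc` from [cgc_all_pairs()].
#' @param groups character vector of group labels, one per channel.
#' @param threshold surrogate threshold array from [surrogate_threshold()]
#'   (optional; without it every edge is reported unmasked).
#' @param eval_freq evaluation frequency in Hz (default 8).
#' @return List with `eval_freq_used`, `group_cgc` (group x group mean
#'   causality), `significant` (logical mask), `in_degree`, `out_degree`,
#'   `edges` (data.frame: source, target, cgc, threshold, significant).
#' @export
summarize_network <- function(result, groups, threshold = NULL, eval_freq = 8) {
  stopifnot(inherits(result, "esconn_cgc"))
  fi <- nearest_index(result$freqs, eval_freq)
  C <- result$cgc[, , fi]
  thr <- if (is.null(threshold)) NULL else threshold[, , fi]
  groups <- as.character(groups)
  gl <- unique(groups)
  empty <- vapply(gl, function(g) sum(groups == g) == 0, logical(1))
  gl <- gl[!empty]
  k <- length(gl)
  gc_mat <- matrix(NA_real_, k, k, dimnames = list(gl, gl))
  th_mat <- matrix(NA_real_, k, k, dimnames = list(gl, gl))
  for (a in seq_len(k)) for (b in seq_len(k)) {
    ia <- which(groups == gl[a]); ib <- which(groups == gl[b])
    vals <- C[ia, ib, drop = FALSE]
    if (a == b) { vals <- vals[row(vals) != col(vals)] } # drop self-edges
    if (length(vals) == 0 || all(is.na(vals))) next
    gc_mat[a, b] <- mean(vals, na.rm = TRUE)
    if (!is.null(thr)) {
      tv <- thr[ia, ib, drop = FALSE]
      if (a == b) tv <- tv[row(tv) != col(tv)]
      th_mat[a, b] <- mean(tv, na.rm = TRUE)
    }
  }
  sig <- if (is.null(thr)) !is.na(gc_mat) else (!is.na(gc_mat) & gc_mat > th_mat)
  masked <- gc_mat; masked[!sig] <- 0
  diag(masked) <- 0
  edges <- expand.grid(source = gl, target = gl, stringsAsFactors = FALSE)
  edges <- edges[edges$source != edges$target, ]
  edges$cgc <- gc_mat[cbind(edges$source, edges$target)]
  edges$threshold <- th_mat[cbind(edges$source, edges$target)]
  edges$significant <- sig[cbind(edges$source, edges$target)]
  list(eval_freq_used = result$freqs[fi], group_cgc = gc_mat,
       significant = sig, in_degree = colSums(masked, na.rm = TRUE),
       out_degree = rowSums(masked, na.rm = TRUE), edges = edges)
}
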