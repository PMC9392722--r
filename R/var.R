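#' Specify a vector-autoregressive (VAR) process
#'
#' Container for a stationary VAR(p) model `x_t = sum_k A_k x_{t-k} + e_t`
#' with innovation covariance `Sigma`. Used as a ground-truth generator whose
#' spectral matrix and Granger causality are known in closed form, making it
#' the validation oracle for the nonparametric spectral pipeline.
#'
#' @param A coefficient array, `n_channels x n_channels x order` (a matrix is
#'   taken as order 1). `A[i, j, k]` is the influence of channel j at lag k on
#'   channel i.
#' @param Sigma innovation covariance, symmetric positive-definite.
#' @return An object of class `esconn_var_spec`.
#' @export
var_spec <- function(A, Sigma = NULL) {
  if (is.matrix(A)) A <- array(A, dim = c(dim(A), 1L))
  stopifnot(length(dim(A)) == 3, dim(A)[1] == dim(A)[2])
  m <- dim(A)[1]; p <- dim(A)[3]
  if (is.null(Sigma)) Sigma <- diag(m)
  if (!is_spd(Sigma)) stop("Sigma must be symmetric positive-definite")
  ## Companion matrix stationarity check
  comp <- matrix(0, m * p, m * p)
  for (k in seq_len(p)) comp[1:m, ((k - 1) * m + 1):(k * m)] <- A[, , k]
  if (p > 1) comp[(m + 1):(m * p), 1:(m * (p - 1))] <- diag(m * (p - 1))
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (rho >= 1)
    stop("VAR is non-stationary: companion spectral radius ", round(rho, 4),
         " >= 1")
  structure(list(A = A, Sigma = Sigma, n_channels = m, order = p,
                 spectral_radius = rho),
            class = "esconn_var_spec")
}

#' Simulate trials from a VAR process
#'
#' Draws independent trials from a stationary VAR specification after a
#' burn-in period, packaged as a trial set so the spectral pipeline can
#' consume them directly.
#'
#' @param spec an [var_spec()] object.
#' @param n_trials,n_samples trials and samples per trial.
#' @param fs nominal sampling rate (Hz) attached to the output.
#' @param seed integer seed.
#' @param burn_in samples discarded at the start of each trial.
#' @return An `esconn_trialset` with `t0_index = 1`.
#' @export
simulate_var <- function(spec, n_trials, n_samples, fs = 200, seed = 1,
                         burn_in = 500) {
  stopifnot(inherits(spec, "esconn_var_spec"))
  set.seed(seed)
  m <- spec$n_channels; p <- spec$order
  L <- chol(spec$Sigma)
  total <- n_samples + burn_in
  data <- array(0, dim = c(m, n_trials, n_samples))
  for (tr in seq_len(n_trials)) {
    e <- matrix(stats::rnorm(total * m), total, m) %*% L
    x <- matrix(0, total, m)
    for (t in (p + 1):total) {
      acc <- e[t, ]
      for (k in seq_len(p)) acc <- acc + spec$A[, , k] %*% x[t - k, ]
      x[t, ] <- acc
    }
    data[, tr, ] <- t(x[(burn_in + 1):total, , drop = FALSE])
  }
  channels <- data.frame(name = sprintf("ch%02d", seq_len(m)),
                         roi = sprintf("ch%02d", seq_len(m)),
                         roi_group = "other", hemisphere = "R",
                         in_soz = FALSE, in_white_matter = FALSE,
                         stringsAsFactors = FALSE)
  structure(list(data = data, fs = fs, t0_index = 1L, channels = channels,
                 stim_group = NA_character_, run_id = "var-sim",
                 ground_truth = spec, seed = seed),
            class = "esconn_trialset")
}

#' Analytic spectral matrix of a VAR process
#'
#' `S(f) = H(f) Sigma H(f)^*` with transfer function
#' `H(f) = (I - sum_k A_k e^{-2*pi*i*f*k/fs})^{-1}`.
#'
#' @param spec an [var_spec()] object.
#' @param freqs frequencies (Hz) at which to evaluate.
#' @param fs sampling rate (Hz).
#' @return List with `S` (ch x ch x n_freqs, complex), `H`, `Sigma`, `freqs`.
#' @export
var_spectrum <- function(spec, freqs, fs = 200) {
  stopifnot(inherits(spec, "esconn_var_spec"))
  m <- spec$n_channels; p <- spec$order
  nf <- length(freqs)
  S <- array(complex(real = 0), dim = c(m, m, nf))
  H <- array(complex(real = 0), dim = c(m, m, nf))
  for (i in seq_len(nf)) {
    z <- exp(-2i * pi * freqs[i] / fs)
    Af <- diag(m) + 0i
    for (k in seq_len(p)) Af <- Af - spec$A[, , k] * z^k
    Hf <- solve(Af)
    H[, , i] <- Hf
    S[, , i] <- Hf %*% spec$Sigma %*% Conj(t(Hf))
  }
  list(S = S, H = H, Sigma = spec$Sigma, freqs = freqs)
}

#' Autocovariance of a VAR process (Yule-Walker)
#'
#' Solves the discrete Lyapunov equation of the companion form for the
#' stationary autocovariance sequence `Gamma_k = cov(x_t, x_{t-k})`.
#'
#' @param spec an [var_spec()] object.
#' @param max_lag largest lag returned.
#' @return Array `n_channels x n_channels x (max_lag + 1)`; slice k+1 is lag k.
#' @export
var_autocov <- function(spec, max_lag = 10) {
  m <- spec$n_channels; p <- spec$order
  mp <- m * p
  comp <- matrix(0, mp, mp)
  for (k in seq_len(p)) comp[1:m, ((k - 1) * m + 1):(k * m)] <- spec$A[, , k]
  if (p > 1) comp[(m + 1):mp, 1:(m * (p - 1))] <- diag(m * (p - 1))
  Q <- matrix(0, mp, mp); Q[1:m, 1:m] <- spec$Sigma
  ## vec(G) = (I - comp (x) comp)^{-1} vec(Q)
  G <- matrix(solve(diag(mp^2) - kronecker(comp, comp), as.vector(Q)), mp, mp)
  out <- array(0, dim = c(m, m, max_lag + 1))
  ## G holds cov of the stacked state: blocks are Gamma_{i-j}
  for (k in 0:min(max_lag, p - 1))
    out[, , k + 1] <- G[1:m, (k * m + 1):((k + 1) * m)]
  if (max_lag >= p) {
    for (k in p:max_lag) {
      acc <- matrix(0, m, m)
      for (j in seq_len(p)) acc <- acc + spec$A[, , j] %*% out[, , k - j + 1]
      out[, , k + 1] <- acc
    }
  }
  out
}

#' Least-squares VAR fit
#'
#' Ordinary least-squares estimation of VAR(p) coefficients and innovation
#' covariance from one or more trials. Used as the independent, time-domain
#' route to Granger causality against which the spectral estimator is tested.
#'
#' @param data matrix (samples x channels) or an `esconn_trialset`.
#' @param order model order p.
#' @param channels optional channel subset (indices).
#' @return An `esconn_var_spec` with the fitted coefficients (stationarity is
#'   not enforced on the fit) plus `$df_resid`.
#' @export
fit_var <- function(data, order, channels = NULL) {
  xs <- if (inherits(data, "esconn_trialset")) {
    lapply(seq_len(dim(data$data)[2]), function(tr) t(data$data[, tr, ]))
  } else list(data)
  if (!is.null(channels)) xs <- lapply(xs, function(x) x[, channels, drop = FALSE])
  m <- ncol(xs[[1]]); p <- order
  X <- NULL; Y <- NULL
  for (x in xs) {
    n <- nrow(x)
    Yt <- x[(p + 1):n, , drop = FALSE]
    Xt <- do.call(cbind, lapply(seq_len(p), function(k)
      x[(p + 1 - k):(n - k), , drop = FALSE]))
    X <- rbind(X, Xt); Y <- rbind(Y, Yt)
  }
  B <- qr.solve(X, Y)                     # (m*p) x m
  E <- Y - X %*% B
  df <- nrow(Y) - ncol(X)
  Sigma <- crossprod(E) / df
  A <- array(0, dim = c(m, m, p))
  for (k in seq_len(p)) A[, , k] <- t(B[((k - 1) * m + 1):(k * m), , drop = FALSE])
  out <- list(A = A, Sigma = symmetrize(Sigma), n_channels = m, order = p,
              spectral_radius = NA_real_, df_resid = df)
  class(out) <- "esconn_var_spec"
  out
}

#' Time-domain (conditional) Geweke Granger causality from data
#'
#' Classic log-variance-ratio Granger causality computed by fitting nested
#' VAR regressions by least squares: the full model predicts the target from
#' past values of target, source and conditioning channels; the reduced model
#' omits the source. `F = log(var_reduced / var_full)` for the target
#' innovation. This is the model-based oracle the spectral nonparametric
#' estimator is validated against.
#'
#' @param data matrix (samples x channels) or `esconn_trialset`.
#' @param source,target channel indices.
#' @param cond conditioning channel indices (default: all others).
#' @param order VAR order for both fits.
#' @return Scalar Geweke causality (>= 0 up to estimation noise).
#' @export
geweke_gc_time <- function(data, source, target, cond = NULL, order = 5) {
  xs <- if (inherits(data, "esconn_trialset")) {
    lapply(seq_len(dim(data$data)[2]), function(tr) t(data$data[, tr, ]))
  } else list(data)
  m <- ncol(xs[[1]])
  if (is.null(cond)) cond <- setdiff(seq_len(m), c(source, target))
  full_set <- c(target, source, cond)
  red_set <- c(target, cond)
  ## residual variance of the target from a least-squares VAR fit on `set`
  ## (target is always the first column of the subset)
  subfit <- function(set) {
    X <- NULL; Y <- NULL; p <- order
    for (x in xs) {
      xsub <- x[, set, drop = FALSE]
      n <- nrow(xsub)
      Y <- rbind(Y, xsub[(p + 1):n, 1, drop = FALSE])
      X <- rbind(X, do.call(cbind, lapply(seq_len(p), function(k)
        xsub[(p + 1 - k):(n - k), , drop = FALSE])))
    }
    e <- Y - X %*% qr.solve(X, Y)
    sum(e^2) / (nrow(Y) - ncol(X))
  }
  log(subfit(red_set) / subfit(full_set))
}
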