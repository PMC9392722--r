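## Region-level block-design stimulation-fMRI analysis: flexible-shape
## (spline-basis) deconvolution of the block response, and the censoring,
## scaling and residual bookkeeping around it.

#' Censor mask for a BOLD run
#'
#' Frames with frame-wise displacement above the threshold and the frame
#' immediately preceding each are censored; the first `n_discard` frames of
#' the run are always discarded.
#'
#' @param run an `esconn_bold_run`.
#' @param fd_threshold censoring threshold in mm (default 0.9).
#' @param n_discard leading frames discarded (default 2).
#' @return Logical vector, `TRUE` = frame usable.
#' @export
censor_mask <- function(run, fd_threshold = 0.9, n_discard = 2) {
  bad <- run$fd > fd_threshold
  bad <- bad | c(bad[-1], FALSE)        # frame before a high-motion frame
  if (n_discard > 0) bad[seq_len(min(n_discard, length(bad)))] <- TRUE
  !bad
}

#' Spline response basis for deconvolution
#'
#' Cardinal natural cubic-spline basis on `n_basis` evenly spaced knots over
#' the peristimulus window: basis function j is the natural spline that is 1
#' at knot j and 0 at the others. The estimated coefficients are therefore
#' the response values at the knots, and the response shape between knots is
#' the natural-spline interpolant — a variable-shape regression that makes
#' no assumption about the haemodynamic form.
#'
#' @param tr repetition time (s).
#' @param window peristimulus window in seconds relative to block onset.
#' @param n_basis number of knots / basis functions (study protocol: 14).
#' @return List with `knots` (s), `lags` (frame-aligned lag times, s) and
#'   `B` (length(lags) x n_basis cardinal basis evaluated at the lags).
#' @export
spline_response_basis <- function(tr = 3, window = c(-3, 36), n_basis = 14) {
  knots <- seq(window[1], window[2], length.out = n_basis)
  lags <- seq(ceiling(window[1] / tr), floor(window[2] / tr)) * tr
  B <- vapply(seq_len(n_basis), function(j) {
    e <- numeric(n_basis); e[j] <- 1
    stats::spline(knots, e, xout = lags, method = "natural")$y
  }, numeric(length(lags)))
  colnames(B) <- sprintf("basis%02d", seq_len(n_basis))
  list(knots = knots, lags = lags, B = B)
}

## Natural-spline interpolant of knot coefficients on an arbitrary grid.
eval_response <- function(basis, betas, t_out) {
  stats::spline(basis$knots, betas, xout = t_out, method = "natural")$y
}

#' Deconvolve the block response from a BOLD run
#'
#' Least-squares fit, per ROI, of a spline response basis placed at every
#' block onset, plus optional nuisance regressors and an intercept. The
#' series is first scaled to mean 100 per ROI; the fit uses only frames
#' surviving the censor mask; residuals (observed minus fitted) are
#' computed on all frames. ROIs whose series is flat (signal dropout) get
#' `NA` betas.
#'
#' @param run an `esconn_bold_run`.
#' @param window peristimulus window (s) of the response basis.
#' @param n_basis basis dimension (default 14).
#' @param nuisance optional matrix (frames x q) of nuisance regressors.
#' @param fd_threshold,n_discard censoring parameters (see [censor_mask()]).
#' @return An `esconn_deconv`: list with `betas` (ROI x n_basis), `fitted`
#'   and `residuals` (ROI x frames), `response` (ROI x lags, the fitted
#'   response shape), `lags`, `basis`, `mask`, `run`.
#' @export
fir_deconvolve <- function(run, window = c(-3, 36), n_basis = 14,
                           nuisance = NULL, fd_threshold = 0.9,
                           n_discard = 2) {
  stopifnot(inherits(run, "esconn_bold_run"))
  y <- run$series
  n_roi <- nrow(y); n_frames <- ncol(y)
  ## per-ROI scaling to mean 100
  mu <- rowMeans(y)
  dropout <- !is.finite(mu) | mu == 0 | apply(y, 1, stats::sd) == 0
  ysc <- y
  ysc[!dropout, ] <- y[!dropout, , drop = FALSE] * (100 / mu[!dropout])

  bas <- spline_response_basis(run$tr, window, n_basis)
  lag_frames <- round(bas$lags / run$tr)
  X <- matrix(0, n_frames, n_basis)
  for (o in run$onsets) {
    rows <- o + lag_frames
    ok <- rows >= 1 & rows <= n_frames
    X[rows[ok], ] <- X[rows[ok], ] + bas$B[ok, , drop = FALSE]
  }
  Xfull <- cbind(intercept = 1, X)
  if (!is.null(nuisance)) Xfull <- cbind(Xfull, as.matrix(nuisance))
  mask <- censor_mask(run, fd_threshold, n_discard)
  Xm <- Xfull[mask, , drop = FALSE]
  qrX <- qr(Xm)
  if (qrX$rank < ncol(Xm)) {
    dropped <- colnames(Xm)[qrX$pivot[(qrX$rank + 1):ncol(Xm)]]
    stop("design matrix rank-deficient after censoring; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  betas <- matrix(NA_real_, n_roi, n_basis,
                  dimnames = list(rownames(y), NULL))
  fitted <- matrix(NA_real_, n_roi, n_frames, dimnames = dimnames(y))
  resid <- matrix(NA_real_, n_roi, n_frames, dimnames = dimnames(y))
  for (r in seq_len(n_roi)) {
    if (dropout[r]) next
    coefs <- qr.coef(qrX, ysc[r, mask])
    coefs[is.na(coefs)] <- 0
    betas[r, ] <- coefs[1 + seq_len(n_basis)]
    fitted[r, ] <- as.numeric(Xfull %*% coefs)
    resid[r, ] <- ysc[r, ] - fitted[r, ]
  }
  structure(list(betas = betas, fitted = fitted, residuals = resid,
                 response = betas %*% t(bas$B), lags = bas$lags,
                 basis = bas, mask = mask, dropout = dropout, run = run),
            class = "esconn_deconv")
}

#' Mean deconvolved response per ROI
#'
#' Average of the spline-interpolated response shape over a post-onset
#' interval (protocol: 3 to 30 s), evaluated on a fine grid. ROIs with
#' signal dropout propagate `NA`.
#'
#' @param deconv an `esconn_deconv`.
#' @param interval interval in seconds, within the basis window.
#' @param dt evaluation grid step in seconds.
#' @return Named numeric vector, one mean beta per ROI.
#' @export
mean_beta <- function(deconv, interval = c(3, 30), dt = 0.5) {
  stopifnot(inherits(deconv, "esconn_deconv"))
  kn <- deconv$basis$knots
  if (interval[1] < kn[1] || interval[2] > kn[length(kn)])
    stop("interval outside the response-basis window")
  grid <- seq(interval[1], interval[2], by = dt)
  apply(deconv$betas, 1, function(b) {
    if (anyNA(b)) return(NA_real_)
    mean(eval_response(deconv$basis, b, grid))
  })
}
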