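#' Ground truth for synthetic block-design BOLD runs
#'
#' Defines the generative model for region-level stimulation-fMRI runs: a
#' block regressor convolved with a canonical haemodynamic kernel scaled by a
#' per-ROI amplitude, plus correlated Gaussian noise drawn from the inverse of
#' a ground-truth precision matrix, plus occasional motion spikes that also
#' appear in the frame-wise displacement (FD) trace.
#'
#' @param precision ROI x ROI precision (inverse covariance) matrix,
#'   symmetric positive-definite. Its off-diagonal entries fix the true
#'   partial correlations `-P_ij / sqrt(P_ii P_jj)`.
#' @param amplitudes matrix (ROI x stimulation groups, columns named) of
#'   block-response amplitudes in signal units (series baseline is 100).
#' @param tr repetition time in seconds (protocol value 3 s).
#' @param frames_on,frames_off frames per stimulation-ON and OFF period
#'   (protocol: 10 TRs ON followed by 30 s OFF).
#' @param n_cycles number of ON/OFF cycles per run.
#' @param lead_frames frames preceding the first block (the first two frames
#'   of a run are conventionally discarded downstream).
#' @param motion_spike_prob per-frame probability of a motion event.
#' @param motion_spike_mm FD magnitude of a motion event (mm); events exceed
#'   the 0.9 mm censoring threshold by default.
#' @param noise_sd overall scale applied to the correlated noise.
#' @return An object of class `esconn_bold_gt`.
#' @export
bold_ground_truth <- function(precision, amplitudes, tr = 3,
                              frames_on = 10, frames_off = 10, n_cycles = 5,
                              lead_frames = 4, motion_spike_prob = 0.02,
                              motion_spike_mm = 1.5, noise_sd = 1) {
  if (!is_spd(precision)) stop("precision matrix must be symmetric positive-definite")
  amplitudes <- as.matrix(amplitudes)
  if (nrow(amplitudes) != nrow(precision))
    stop("amplitudes must have one row per ROI")
  if (is.null(colnames(amplitudes)))
    colnames(amplitudes) <- c("medial", "lateral")[seq_len(ncol(amplitudes))]
  structure(list(precision = precision, amplitudes = amplitudes, tr = tr,
                 frames_on = frames_on, frames_off = frames_off,
                 n_cycles = n_cycles, lead_frames = lead_frames,
                 motion_spike_prob = motion_spike_prob,
                 motion_spike_mm = motion_spike_mm, noise_sd = noise_sd),
            class = "esconn_bold_gt")
}

#' True partial correlations implied by a precision matrix
#'
#' @param precision symmetric positive-definite matrix.
#' @return Matrix of partial correlations `-P_ij / sqrt(P_ii P_jj)` with unit
#'   diagonal.
#' @export
partial_cor_from_precision <- function(precision) {
  d <- 1 / sqrt(diag(precision))
  pc <- -precision * outer(d, d)
  diag(pc) <- 1
  pc
}

#' Canonical double-gamma haemodynamic kernel
#'
#' @param t time in seconds (>= 0).
#' @param peak1,peak2 peaks (s) of the response and undershoot gamma terms.
#' @param ratio undershoot amplitude relative to the response.
#' @return Kernel values, scaled to unit maximum.
#' @export
hrf_double_gamma <- function(t, peak1 = 6, peak2 = 16, ratio = 1/6) {
  h <- stats::dgamma(t, shape = peak1, rate = 1) -
    ratio * stats::dgamma(t, shape = peak2, rate = 1)
  h / max(h)
}

#' Simulate region-level block-design stimulation-fMRI runs
#'
#' Each run is `series = block (*) kernel * amplitude + correlated noise +
#' motion spikes` around a baseline of 100, with an FD trace whose spikes are
#' co-located with the injected motion events.
#'
#' @param gt an [bold_ground_truth()] object.
#' @param n_runs number of runs to generate.
#' @param stim_group column of `gt$amplitudes` to use (name); recycled over
#'   runs if a vector.
#' @param seed integer seed.
#' @return A list of `esconn_bold_run` objects, each a list with `series`
#'   (ROI x frames), `tr`, `onsets` (frame index of each ON-block start,
#'   1-based), `frames_on`, `frames_off`, `fd`, `stim_group`, `run_id`,
#'   `ground_truth`, `seed`.
#' @export
simulate_bold <- function(gt, n_runs = 1, stim_group = colnames(gt$amplitudes)[1],
                          seed = 1) {
  stopifnot(inherits(gt, "esconn_bold_gt"))
  set.seed(seed)
  stim_group <- rep_len(stim_group, n_runs)
  n_roi <- nrow(gt$precision)
  cyc <- gt$frames_on + gt$frames_off
  n_frames <- gt$lead_frames + gt$n_cycles * cyc
  onsets <- gt$lead_frames + (0:(gt$n_cycles - 1)) * cyc + 1L
  ## block regressor convolved with the canonical kernel, sampled at TR
  block <- numeric(n_frames)
  for (o in onsets) block[o:(o + gt$frames_on - 1)] <- 1
  klen <- ceiling(32 / gt$tr)
  kern <- hrf_double_gamma((0:klen) * gt$tr)
  resp <- stats::convolve(block, rev(kern), type = "open")[seq_len(n_frames)]
  Sigma_noise <- solve(gt$precision)
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    amp <- gt$amplitudes[, stim_group[r]]
    signal <- outer(amp, resp)                      # ROI x frames
    noise <- if (gt$noise_sd > 0)
      t(MASS::mvrnorm(n_frames, rep(0, n_roi), Sigma_noise)) * gt$noise_sd
    else matrix(0, n_roi, n_frames)
    series <- 100 + signal + noise
    fd <- abs(stats::rnorm(n_frames, 0.1, 0.05))
    spikes <- stats::runif(n_frames) < gt$motion_spike_prob
    if (any(spikes)) {
      fd[spikes] <- gt$motion_spike_mm
      series[, spikes] <- series[, spikes] +
        matrix(stats::rnorm(n_roi * sum(spikes), 0, 5), n_roi)
    }
    rownames(series) <- rownames(gt$precision) %||% sprintf("roi%02d", seq_len(n_roi))
    runs[[r]] <- structure(
      list(series = series, tr = gt$tr, onsets = onsets,
           frames_on = gt$frames_on, frames_off = gt$frames_off,
           fd = fd, stim_group = stim_group[r],
           run_id = sprintf("bold-run-%03d", r),
           ground_truth = gt, seed = seed),
      class = "esconn_bold_run")
  }
  runs
}
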