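#' Ground truth for synthetic evoked-potential trials
#'
#' Defines, per (ROI group, stimulation group) cell, the two evoked components
#' that the generator injects: an early component (10-30 ms window, either
#' polarity) and a late positive component (70-200 ms window), on a 1/f
#' background with occasional artifact trials.
#'
#' @param roi_group,stim_group character vectors (recycled against each other)
#'   naming the cells.
#' @param early_latency_ms early-component peak latency, must lie in [10, 30).
#' @param early_amplitude_sd signed early amplitude in baseline-SD units
#'   (negative sign gives an N-type component).
#' @param late_latency_ms late-component peak latency, must lie in [70, 200).
#' @param late_amplitude_sd late amplitude in baseline-SD units; non-negative
#'   because the late component is defined as positive.
#' @param early_width_ms,late_width_ms Gaussian widths (SD) of the two bumps.
#' @param noise_exponent spectral slope of the 1/f^alpha background.
#' @param artifact_rate fraction of channel-trials carrying an injected
#'   artifact (amplifier-saturation plateau or large spike).
#' @return A data.frame of class `esconn_ep_gt`, one row per cell.
#' @seealso [default_ep_ground_truth()], [simulate_ep_trials()]
#' @export
ep_ground_truth <- function(roi_group, stim_group,
                            early_latency_ms, early_amplitude_sd,
                            late_latency_ms, late_amplitude_sd,
                            early_width_ms = 4, late_width_ms = 40,
                            noise_exponent = 1, artifact_rate = 0) {
  gt <- data.frame(roi_group = roi_group, stim_group = stim_group,
                   early_latency_ms = early_latency_ms,
                   early_amplitude_sd = early_amplitude_sd,
                   late_latency_ms = late_latency_ms,
                   late_amplitude_sd = late_amplitude_sd,
                   early_width_ms = early_width_ms,
                   late_width_ms = late_width_ms,
                   noise_exponent = noise_exponent,
                   artifact_rate = artifact_rate,
                   stringsAsFactors = FALSE)
  if (any(gt$early_latency_ms < 10 | gt$early_latency_ms >= 30))
    stop("early_latency_ms must lie inside the early window [10, 30) ms")
  if (any(gt$late_latency_ms < 70 | gt$late_latency_ms >= 200))
    stop("late_latency_ms must lie inside the late window [70, 200) ms")
  if (any(gt$late_amplitude_sd < 0))
    stop("late_amplitude_sd must be non-negative (late component is positive)")
  if (any(gt$artifact_rate < 0 | gt$artifact_rate > 1))
    stop("artifact_rate must be a fraction in [0, 1]")
  class(gt) <- c("esconn_ep_gt", "data.frame")
  gt
}

#' Default evoked-potential ground truth
#'
#' The study conditions the generator emulates: six cortical ROI groups by two
#' amygdala stimulation groups. Early latencies are shortest in orbitofrontal
#' and cingulate cortex and longest in parietal cortex; the same ordering
#' holds for the late component. Lateral-group stimulation drives larger early
#' responses, medial-group stimulation larger late responses.
#'
#' @param artifact_rate fraction of artifact trials (default 0.05).
#' @param noise_exponent 1/f slope of the background (default 1).
#' @return An `esconn_ep_gt` data.frame with 12 rows.
#' @export
default_ep_ground_truth <- function(artifact_rate = 0.05, noise_exponent = 1) {
  groups <- ROI_GROUPS                   # OF, lPFC, SM, PL, TL, CC
  early_lat <- c(OF = 17.0, lPFC = 18.5, SM = 20.0, PL = 20.8,
                 TL = 19.0, CC = 16.6)
  late_lat  <- c(OF = 129, lPFC = 148, SM = 155, PL = 153,
                 TL = 157, CC = 143.3)
  ## Sign of the early component varies by region; magnitude by stim group.
  early_sign <- c(OF = -1, lPFC = 1, SM = 1, PL = 1, TL = -1, CC = -1)
  grid <- expand.grid(roi_group = groups,
                      stim_group = c("medial", "lateral"),
                      stringsAsFactors = FALSE)
  early_amp <- ifelse(grid$stim_group == "lateral", 8, 4) *
    early_sign[grid$roi_group]
  late_amp <- ifelse(grid$stim_group == "medial", 6, 3)
  ## Medial stimulation arrives slightly later in cingulate cortex.
  elat <- early_lat[grid$roi_group] +
    ifelse(grid$stim_group == "medial" & grid$roi_group == "CC", 1.5, 0)
  ep_ground_truth(grid$roi_group, grid$stim_group,
                  early_latency_ms = unname(elat),
                  early_amplitude_sd = unname(early_amp),
                  late_latency_ms = unname(late_lat[grid$roi_group]),
                  late_amplitude_sd = late_amp,
                  noise_exponent = noise_exponent,
                  artifact_rate = artifact_rate)
}

#' Simulate a multi-run evoked-potential study
#'
#' Convenience wrapper generating several stimulation runs per stimulation
#' group under one ground truth, running the first-order pipeline (trial
#' screening, averaging, feature extraction, significance) on each, and
#' pooling the per-channel features.
#'
#' @param gt ground truth (default [default_ep_ground_truth()]).
#' @param n_runs_per_group runs per stimulation group.
#' @param n_trials,fs,channels_per_group,noise_sd passed to
#'   [simulate_ep_trials()].
#' @param seed master seed; per-run seeds are derived from it.
#' @return Pooled `esconn_ep_features` data.frame with significance columns.
#' @export
simulate_ep_study <- function(gt = default_ep_ground_truth(),
                              n_runs_per_group = 6, n_trials = 60, fs = 2000,
                              channels_per_group = 4, noise_sd = 1,
                              seed = 1) {
  feats <- list()
  for (sg in unique(gt$stim_group)) {
    for (r in seq_len(n_runs_per_group)) {
      run_id <- sprintf("%s-%02d", sg, r)
      ts <- simulate_ep_trials(gt, n_trials = n_trials, fs = fs,
                               seed = derive_seed(seed, run_id),
                               stim_group = sg,
                               channels_per_group = channels_per_group,
                               noise_sd = noise_sd, run_id = run_id)
      ts <- reject_trials(ts)
      ep <- average_normalize(ts)
      f <- extract_features(ep)
      f <- significance_test(ep, f)
      feats[[run_id]] <- f
    }
  }
  out <- do.call(rbind, feats)
  rownames(out) <- NULL
  class(out) <- c("esconn_ep_features", "data.frame")
  out
}

gaussian_bump <- function(t_ms, latency_ms, width_ms, amplitude) {
  amplitude * exp(-0.5 * ((t_ms - latency_ms) / width_ms)^2)
}

#' Simulate stimulation-locked evoked-potential trials
#'
#' Generates a channels x trials x time array spanning [-1000, +1000) ms
#' around stimulation onset. Each channel belongs to one ground-truth cell
#' and carries two smooth Gaussian components on 1/f^alpha background noise
#' of unit SD; a fraction of channel-trials receive an injected artifact
#' (saturation plateau or a >50 SD spike), mirroring the two rejection
#' classes of the trial-screening rule.
#'
#' @param gt an `esconn_ep_gt` ground truth; only rows matching `stim_group`
#'   are used.
#' @param n_trials trials per channel (>= 1; the experimental protocol used
#'   60 pulses per run).
#' @param fs sampling rate in Hz (>= 1000).
#' @param seed integer seed; recorded in the output.
#' @param stim_group which stimulation group to simulate (default the first
#'   present in `gt`).
#' @param channels_per_group number of channels per ROI-group cell.
#' @param noise_sd baseline noise SD in "volts" (0 gives noiseless trials).
#' @param run_id identifier stored with the output.
#' @return An `esconn_trialset`: list with `data` (ch x trial x time), `fs`,
#'   `t0_index`, `channels` annotation table, `stim_group`, `run_id`,
#'   `ground_truth` (including the injected artifact bookkeeping in
#'   `attr(, "artifact_trials")`) and `seed`.
#' @export
simulate_ep_trials <- function(gt, n_trials = 60, fs = 8000, seed = 1,
                               stim_group = NULL, channels_per_group = 1,
                               noise_sd = 1, run_id = "sim-run") {
  stopifnot(inherits(gt, "esconn_ep_gt"))
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (fs < 1000) stop("fs must be >= 1000 Hz")
  if (is.null(stim_group)) stim_group <- gt$stim_group[1]
  gt <- gt[gt$stim_group == stim_group, , drop = FALSE]
  if (nrow(gt) == 0) stop("no ground-truth rows for stim_group '", stim_group, "'")
  set.seed(seed)

  n <- as.integer(2 * fs)                       # [-1000, +1000) ms
  t0 <- as.integer(fs) + 1L                     # onset sample
  t_ms <- (seq_len(n) - t0) / fs * 1000
  ch_rows <- rep(seq_len(nrow(gt)), each = channels_per_group)
  n_ch <- length(ch_rows)

  data <- array(0, dim = c(n_ch, n_trials, n))
  artifacts <- matrix(FALSE, n_ch, n_trials)
  spike_win <- which(t_ms >= 8 & t_ms <= 1000)

  for (c in seq_len(n_ch)) {
    g <- gt[ch_rows[c], ]
    sig <- gaussian_bump(t_ms, g$early_latency_ms, g$early_width_ms,
                         g$early_amplitude_sd) +
           gaussian_bump(t_ms, g$late_latency_ms, g$late_width_ms,
                         g$late_amplitude_sd)
    sig[t_ms < 0] <- 0                          # causal response
    amp_scale <- if (noise_sd > 0) noise_sd else 1  # volts per single-trial SD
    for (tr in seq_len(n_trials)) {
      noise <- if (noise_sd > 0)
        noise_one_over_f(n, g$noise_exponent) * noise_sd else numeric(n)
      x <- sig * amp_scale + noise
      if (stats::runif(1) < g$artifact_rate) {
        artifacts[c, tr] <- TRUE
        amp <- 100 * max(noise_sd, 1)   # far above the 50 SD rejection rule
        if (stats::runif(1) < 0.5) {            # saturation plateau
          i0 <- sample(spike_win[spike_win + floor(0.05 * fs) <= n], 1)
          x[i0:(i0 + floor(0.05 * fs))] <- amp
        } else {                                # isolated large spike
          x[sample(spike_win, 1)] <- amp * sample(c(-1, 1), 1)
        }
      }
      data[c, tr, ] <- x
    }
  }

  channels <- data.frame(
    name = sprintf("ch%02d", seq_len(n_ch)),
    roi = gt$roi_group[ch_rows],
    roi_group = gt$roi_group[ch_rows],
    hemisphere = "R",
    in_soz = FALSE,
    in_white_matter = FALSE,
    stringsAsFactors = FALSE)

  gt_out <- gt
  attr(gt_out, "artifact_trials") <- artifacts
  structure(list(data = data, fs = fs, t0_index = t0, channels = channels,
                 stim_group = stim_group, run_id = run_id,
                 ground_truth = gt_out, seed = seed),
            class = "esconn_trialset")
}
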