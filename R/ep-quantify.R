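## First-order quantification of stimulation-evoked potentials:
## trial screening, averaging/normalization, band-pass, component extraction,
## baseline-percentile significance and group statistics.

EARLY_WINDOW <- c(10, 30)    # ms, half-open [10, 30)
LATE_WINDOW  <- c(70, 200)   # ms, half-open [70, 200)

#' Screen trials for artifacts and exclude invalid channels
#'
#' Per channel and trial, the baseline standard deviation is computed over
#' [-100, -10) ms before onset. A trial is rejected when its absolute
#' amplitude exceeds 10 baseline SD at 8 ms after onset (the tail of the
#' stimulus artifact) or 50 baseline SD anywhere in [8, 1000] ms (amplifier
#' saturation, cable movement, interictal spikes). Channels flagged as lying
#' in the seizure onset zone or in white matter are excluded from analysis
#' entirely; channels whose baseline SD is zero on any trial are marked
#' invalid rather than passed through.
#'
#' @param trials an `esconn_trialset`.
#' @param at_ms time point of the stimulus-artifact amplitude check (8 ms).
#' @param k_at,k_any SD multipliers for the two rules (10 and 50).
#' @return The trial set with a logical `rejected` matrix (channels x trials),
#'   a per-channel `channel_status` vector (`"ok"`, `"excluded"`,
#'   `"invalid"`), and a `rejection_report` data.frame attached.
#' @export
reject_trials <- function(trials, at_ms = 8, k_at = 10, k_any = 50) {
  stopifnot(inherits(trials, "esconn_trialset"))
  d <- dim(trials$data); n_ch <- d[1]; n_tr <- d[2]; n <- d[3]
  fs <- trials$fs; t0 <- trials$t0_index
  base_idx <- window_indices(c(-100, -10), fs, t0, n)
  i_at <- time_to_index(at_ms, fs, t0)
  scan_idx <- window_indices(c(at_ms, 1000 + 1000 / fs), fs, t0, n)

  rejected <- matrix(FALSE, n_ch, n_tr)
  status <- rep("ok", n_ch)
  soz_wm <- trials$channels$in_soz | trials$channels$in_white_matter
  status[soz_wm] <- "excluded"
  for (c in seq_len(n_ch)) {
    if (status[c] == "excluded") next
    for (tr in seq_len(n_tr)) {
      x <- trials$data[c, tr, ]
      s <- stats::sd(x[base_idx])
      if (!is.finite(s) || s == 0) { status[c] <- "invalid"; break }
      if (abs(x[i_at]) > k_at * s || max(abs(x[scan_idx])) > k_any * s)
        rejected[c, tr] <- TRUE
    }
  }
  report <- data.frame(name = trials$channels$name, status = status,
                       n_trials = n_tr, n_rejected = rowSums(rejected),
                       stringsAsFactors = FALSE)
  trials$rejected <- rejected
  trials$channel_status <- status
  trials$rejection_report <- report
  trials
}

#' Average retained trials and normalize to baseline SD units
#'
#' Per-channel mean over retained trials, divided by the standard deviation
#' of the mean trace within the [-100, -10) ms baseline window. A channel
#' with all trials rejected, or with a flat (constant) mean trace, is marked
#' absent with an explicit reason. A channel with zero baseline SD but a
#' non-constant trace (the noiseless synthetic regime) is left unscaled.
#'
#' @param trials an `esconn_trialset`, ideally after [reject_trials()].
#' @return An `esconn_ep`: list with `traces` (channels x samples, SD units),
#'   `fs`, `t0_index`, `channels`, `n_trials_used`, `baseline_sd` (volts),
#'   `absent` (logical) + `absent_reason`, `stim_group`, `run_id`.
#' @export
average_normalize <- function(trials) {
  stopifnot(inherits(trials, "esconn_trialset"))
  d <- dim(trials$data); n_ch <- d[1]; n_tr <- d[2]; n <- d[3]
  rejected <- trials$rejected %||% matrix(FALSE, n_ch, n_tr)
  status <- trials$channel_status %||% rep("ok", n_ch)
  base_idx <- window_indices(c(-100, -10), trials$fs, trials$t0_index, n)

  traces <- matrix(NA_real_, n_ch, n)
  n_used <- integer(n_ch)
  base_sd <- rep(NA_real_, n_ch)
  absent <- logical(n_ch)
  reason <- rep(NA_character_, n_ch)
  for (c in seq_len(n_ch)) {
    if (status[c] != "ok") {
      absent[c] <- TRUE; reason[c] <- paste0("channel ", status[c]); next
    }
    keep <- which(!rejected[c, ])
    n_used[c] <- length(keep)
    if (length(keep) == 0) {
      absent[c] <- TRUE; reason[c] <- "all trials rejected"; next
    }
    m <- if (length(keep) == 1) trials$data[c, keep, ]
         else colMeans(trials$data[c, keep, , drop = FALSE][1, , ])
    s <- stats::sd(m[base_idx])
    base_sd[c] <- s
    if (max(m) == min(m)) {
      absent[c] <- TRUE; reason[c] <- "flat channel"; next
    }
    traces[c, ] <- if (s > 0) m / s else m
  }
  structure(list(traces = traces, fs = trials$fs, t0_index = trials$t0_index,
                 channels = trials$channels, n_trials_used = n_used,
                 baseline_sd = base_sd, absent = absent,
                 absent_reason = reason, stim_group = trials$stim_group,
                 run_id = trials$run_id),
            class = "esconn_ep")
}

#' Zero-phase band-pass for the early component
#'
#' Forward-backward (zero group delay) application of a 2nd-order Butterworth
#' band-pass designed so the composed response is -6 dB at 2 Hz and 200 Hz.
#' Applied before computing range values in the early window to suppress
#' baseline drift from the late response.
#'
#' @param ep an `esconn_ep` (or a numeric matrix channels x samples plus `fs`).
#' @param band single-pass -3 dB band edges in Hz.
#' @param fs sampling rate, taken from `ep` if it is an `esconn_ep`.
#' @return Object of the same shape with filtered traces.
#' @export
bandpass_early <- function(ep, band = c(2, 200), fs = NULL) {
  is_ep <- inherits(ep, "esconn_ep")
  x <- if (is_ep) ep$traces else as.matrix(ep)
  fs <- if (is_ep) ep$fs else fs
  if (is.null(fs) || fs <= 2 * band[2])
    stop("fs must exceed twice the upper band edge (", 2 * band[2], " Hz)")
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  y <- x
  for (c in seq_len(nrow(x))) {
    if (anyNA(x[c, ])) next
    y[c, ] <- signal::filtfilt(bf, x[c, ])
  }
  if (is_ep) { ep$traces <- y; ep$filtered_band <- band; ep } else y
}

## Local extrema of a vector: list of (index, sign); prominence relative to
## the flanking minima/maxima within the window.
local_extrema <- function(x) {
  dx <- diff(x)
  s <- sign(dx)
  idx <- which(s[-1] != 0 & s[-length(s)] != 0 & s[-1] != s[-length(s)]) + 1L
  if (length(idx) == 0) return(data.frame(index = integer(), sign = integer(),
                                          prominence = numeric()))
  sgn <- ifelse(x[idx] > x[idx - 1L], 1L, -1L)
  prom <- vapply(seq_along(idx), function(k) {
    i <- idx[k]
    if (sgn[k] > 0) {
      left <- min(x[1:i]); right <- min(x[i:length(x)])
      x[i] - max(left, right)
    } else {
      left <- max(x[1:i]); right <- max(x[i:length(x)])
      min(left, right) - x[i]
    }
  }, numeric(1))
  data.frame(index = idx, sign = sgn, prominence = prom)
}

#' Extract per-channel evoked-potential features
#'
#' For each channel and window (early [10, 30) ms, late [70, 200) ms):
#' the range value (max minus min, in baseline-SD units), the component peak
#' latency, its polarity, and the trend (last minus first sample in the
#' window). The early window is measured on the band-passed trace; the late
#' window on the unfiltered normalized trace. The early component is the
#' earliest local extremum with prominence above `min_prominence`, labelled
#' N or P by its sign; the late component is the largest positive local
#' maximum (P150). Channels without a qualifying extremum get polarity
#' `"absent"` and an `NA` latency.
#'
#' @param ep an `esconn_ep` from [average_normalize()].
#' @param min_prominence prominence (SD units) an extremum must exceed.
#' @param filter_early apply [bandpass_early()] for the early window.
#' @return An `esconn_ep_features` data.frame, one row per channel x window,
#'   with columns `name`, `roi`, `roi_group`, `window`, `range_value`,
#'   `peak_latency_ms`, `polarity`, `trend_value`, `stim_group`, `run_id`.
#' @export
extract_features <- function(ep, min_prominence = 1, filter_early = TRUE) {
  stopifnot(inherits(ep, "esconn_ep"))
  n <- ncol(ep$traces)
  t_ms <- (seq_len(n) - ep$t0_index) / ep$fs * 1000
  filt <- if (filter_early) bandpass_early(ep)$traces else ep$traces
  win_list <- list(early = EARLY_WINDOW, late = LATE_WINDOW)
  rows <- list()
  for (c in seq_len(nrow(ep$traces))) {
    for (w in names(win_list)) {
      win <- win_list[[w]]
      trace <- if (w == "early") filt[c, ] else ep$traces[c, ]
      if (ep$absent[c] || anyNA(trace)) {
        rows[[length(rows) + 1]] <- data.frame(
          name = ep$channels$name[c], roi = ep$channels$roi[c],
          roi_group = ep$channels$roi_group[c], window = w,
          range_value = NA_real_, peak_latency_ms = NA_real_,
          polarity = "absent", trend_value = NA_real_,
          stringsAsFactors = FALSE)
        next
      }
      idx <- window_indices(win, ep$fs, ep$t0_index, n)
      seg <- trace[idx]
      rng <- max(seg) - min(seg)
      trend <- seg[length(seg)] - seg[1]
      ext <- local_extrema(seg)
      ext <- ext[ext$prominence > min_prominence, , drop = FALSE]
      if (w == "late") ext <- ext[ext$sign > 0, , drop = FALSE]  # P150: positive peak
      if (nrow(ext) == 0) {
        lat <- NA_real_; pol <- "absent"
      } else if (w == "early") {
        k <- which.min(ext$index)              # earliest qualifying extremum
        lat <- t_ms[idx[ext$index[k]]]
        pol <- if (ext$sign[k] > 0) "P" else "N"
      } else {
        k <- which.max(seg[ext$index])         # largest positive peak
        lat <- t_ms[idx[ext$index[k]]]
        pol <- "P"
      }
      rows[[length(rows) + 1]] <- data.frame(
        name = ep$channels$name[c], roi = ep$channels$roi[c],
        roi_group = ep$channels$roi_group[c], window = w,
        range_value = rng, peak_latency_ms = lat, polarity = pol,
        trend_value = trend, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$stim_group <- ep$stim_group
  out$run_id <- ep$run_id
  class(out) <- c("esconn_ep_features", "data.frame")
  out
}

## Gaussian surrogate of a series: Fourier amplitudes drawn as complex
## normals scaled by the series' amplitude spectrum (conjugate-symmetric, so
## the output is real). Unlike plain phase randomization this restores the
## power variability a fresh realization of the process would have, which
## matters for the tail of the range null.
gaussian_surrogate <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  half <- (n - 1) %/% 2
  eps <- rep(1 + 0i, n)
  eps[2:(half + 1)] <- complex(real = stats::rnorm(half),
                               imaginary = stats::rnorm(half)) / sqrt(2)
  eps[n:(n - half + 1)] <- Conj(eps[2:(half + 1)])
  eps[1] <- stats::rnorm(1)
  if (n %% 2 == 0) eps[half + 2] <- stats::rnorm(1)
  Re(stats::fft(X * eps, inverse = TRUE)) / n
}

#' Baseline-calibrated significance of evoked responses
#'
#' Thresholds the post-stimulus range value against the 95th percentile of
#' its null distribution estimated from the [-1000, -10) ms pre-stimulus
#' baseline. The early-window null uses the band-passed trace, matching the
#' statistic being thresholded.
#'
#' Two null constructions are provided. `"surrogate"` (default) draws
#' Gaussian surrogates of the baseline — Fourier amplitudes resampled as
#' complex normals scaled by the baseline amplitude spectrum — and pools
#' range values over windows tiled across every surrogate; because each
#' surrogate is an independent realization given the baseline spectrum,
#' this estimates the marginal range quantile without the severe
#' small-sample bias of tiling the single observed baseline. `"tiled"`
#' pools ranges over windows slid along the observed baseline only; it is
#' cheaper but anti-conservative for the 130 ms late window, for which the
#' baseline holds fewer than eight independent windows.
#'
#' @param ep an `esconn_ep`; requires at least 990 ms of pre-stimulus
#'   baseline.
#' @param features output of [extract_features()] for the same EP.
#' @param prob percentile defining the threshold (default 0.95).
#' @param method `"surrogate"` or `"tiled"`.
#' @param n_surr surrogate realizations per channel (surrogate method).
#' @param step_ms tile step in ms (tiled method).
#' @param filter_early must match the `filter_early` used for the features.
#' @param seed seed for the surrogate draws.
#' @return `features` with `threshold` and `is_significant` columns added.
#' @export
significance_test <- function(ep, features, prob = 0.95,
                              method = c("surrogate", "tiled"),
                              n_surr = 30, step_ms = 10,
                              filter_early = TRUE, seed = 1) {
  stopifnot(inherits(ep, "esconn_ep"))
  method <- match.arg(method)
  n <- ncol(ep$traces)
  pre_ms <- (ep$t0_index - 1) / ep$fs * 1000
  if (pre_ms < 990) stop("at least 990 ms of pre-stimulus baseline required, got ",
                         round(pre_ms), " ms")
  filt <- if (filter_early) bandpass_early(ep)$traces else ep$traces
  win_list <- list(early = EARLY_WINDOW, late = LATE_WINDOW)
  features$threshold <- NA_real_
  features$is_significant <- NA
  base_idx <- window_indices(c(-1000, -10), ep$fs, ep$t0_index, n)
  set.seed(seed)
  for (c in seq_len(nrow(ep$traces))) {
    if (ep$absent[c]) next
    for (w in names(win_list)) {
      sel <- features$window == w & features$name == ep$channels$name[c]
      if (!any(sel)) next
      len_ms <- diff(win_list[[w]])
      trace <- if (w == "early") filt[c, ] else ep$traces[c, ]
      len <- max(2L, round(len_ms / 1000 * ep$fs))
      null_ranges <- if (method == "surrogate") {
        base <- trace[base_idx]
        starts <- seq(1, length(base) - len + 1, by = max(1L, len %/% 2))
        unlist(lapply(seq_len(n_surr), function(s) {
          b <- gaussian_surrogate(base)
          vapply(starts, function(i0) {
            seg <- b[i0:(i0 + len - 1)]; max(seg) - min(seg)
          }, numeric(1))
        }))
      } else {
        starts <- seq(-1000, -10 - len_ms, by = step_ms)
        vapply(starts, function(s) {
          idx <- window_indices(c(s, s + len_ms), ep$fs, ep$t0_index, n)
          max(trace[idx]) - min(trace[idx])
        }, numeric(1))
      }
      thr <- stats::quantile(null_ranges, prob, names = FALSE)
      features$threshold[sel] <- thr
      features$is_significant[sel] <- features$range_value[sel] > thr
    }
  }
  features
}

#' Per-ROI group contrast of response magnitude
#'
#' Two-sided t-test on range values per ROI between two groups (stimulation
#' site, or any binary label such as a clinical condition), with Bonferroni
#' correction across the ROIs tested. In `mode = "effect_size"` no test is
#' performed and only the mean difference and its standard error are
#' reported (the descriptive mode used for under-powered factors such as sex
#' and hemisphere).
#'
#' @param features a (row-bound) `esconn_ep_features` table across runs.
#' @param group_col column holding the binary grouping (default
#'   `"stim_group"`).
#' @param window which window's range values to compare.
#' @param by ROI column to stratify on (`"roi"` or `"roi_group"`).
#' @param mode `"test"` or `"effect_size"`.
#' @return Data.frame with one row per ROI: group means, mean difference,
#'   SE, and for `mode = "test"` the t statistic, df, raw and
#'   Bonferroni-corrected p-values (`p_corrected = min(1, m * p)`).
#' @export
roi_contrast <- function(features, group_col = "stim_group", window = "early",
                         by = "roi", mode = c("test", "effect_size")) {
  mode <- match.arg(mode)
  f <- features[features$window == window & !is.na(features$range_value), ]
  groups <- sort(unique(f[[group_col]]))
  if (length(groups) != 2) stop("grouping column must have exactly 2 levels")
  rois <- unique(f[[by]])
  rows <- list()
  for (r in rois) {
    x <- f$range_value[f[[by]] == r & f[[group_col]] == groups[1]]
    y <- f$range_value[f[[by]] == r & f[[group_col]] == groups[2]]
    diff_mean <- mean(x) - mean(y)
    se <- sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
    row <- data.frame(roi = r, n1 = length(x), n2 = length(y),
                      mean1 = mean(x), mean2 = mean(y),
                      effect = diff_mean, se = se,
                      stringsAsFactors = FALSE)
    if (mode == "test") {
      if (length(x) < 2 || length(y) < 2) {
        row$t <- NA_real_; row$df <- NA_real_; row$p <- NA_real_
        row$testable <- FALSE
      } else {
        tt <- stats::t.test(x, y)
        row$t <- unname(tt$statistic); row$df <- unname(tt$parameter)
        row$p <- tt$p.value; row$testable <- TRUE
      }
    }
    rows[[length(rows) + 1]] <- row
  }
  out <- do.call(rbind, rows)
  if (mode == "test") {
    m <- sum(out$testable)                 # Bonferroni factor = ROIs tested
    out$p_corrected <- pmin(1, m * out$p)
    out$significant <- !is.na(out$p_corrected) & out$p_corrected < 0.05
  }
  out
}

#' Group comparison of component latencies
#'
#' One-way ANOVA of peak latencies over the ROI groups, followed by Tukey
#' HSD pairwise comparisons. Empty or singleton groups are dropped with a
#' warning; fewer than two usable groups is an error.
#'
#' @param features `esconn_ep_features` rows (typically one window).
#' @param window which window's latencies to analyse.
#' @param group_col grouping column (default `"roi_group"`).
#' @return List with `anova` (data.frame: F, df1, df2, p), `group_means`,
#'   and `tukey` (pairwise table from [stats::TukeyHSD()]).
#' @export
latency_group_stats <- function(features, window = "early",
                                group_col = "roi_group") {
  f <- features[features$window == window & !is.na(features$peak_latency_ms), ]
  f$grp <- factor(f[[group_col]])
  counts <- table(f$grp)
  drop <- names(counts)[counts < 2]
  if (length(drop) > 0) {
    warning("dropping groups with < 2 latencies: ", paste(drop, collapse = ", "))
    f <- f[!(f$grp %in% drop), ]
    f$grp <- droplevels(f$grp)
  }
  if (nlevels(f$grp) < 2) stop("need at least 2 groups with >= 2 latencies each")
  fit <- stats::aov(peak_latency_ms ~ grp, data = f)
  s <- summary(fit)[[1]]
  anova_tab <- data.frame(F = s$`F value`[1], df1 = s$Df[1], df2 = s$Df[2],
                          p = s$`Pr(>F)`[1])
  gm <- stats::aggregate(peak_latency_ms ~ grp, f, function(v)
    c(mean = mean(v), se = stats::sd(v) / sqrt(length(v)), n = length(v)))
  group_means <- data.frame(group = gm$grp,
                            mean = gm$peak_latency_ms[, "mean"],
                            se = gm$peak_latency_ms[, "se"],
                            n = gm$peak_latency_ms[, "n"])
  tk <- stats::TukeyHSD(fit)$grp
  tukey <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL)
  list(anova = anova_tab, group_means = group_means, tukey = tukey)
}
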