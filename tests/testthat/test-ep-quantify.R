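test_that("trial screening applies both amplitude rules as stated", {
  fs <- 1000
  n <- as.integer(2 * fs)
  t0 <- fs + 1L
  set.seed(1)
  base <- array(rnorm(3 * n), dim = c(1, 3, n))
  ## make each trial's baseline SD exactly 1 so the rules are deterministic
  bidx <- (t0 - round(0.1 * fs)):(t0 - round(0.01 * fs) - 1)
  for (tr in 1:3) base[1, tr, ] <- base[1, tr, ] / sd(base[1, tr, bidx])
  i8 <- t0 + as.integer(0.008 * fs)
  i500 <- t0 + as.integer(0.5 * fs)
  data <- base
  data[1, 1, i8] <- 11        # > 10 SD at 8 ms -> rejected
  data[1, 2, i500] <- 49      # 49 SD at 500 ms, below 50 -> retained
  data[1, 2, i8] <- 9         # and below 10 at 8 ms
  data[1, 3, i500] <- 55      # > 50 SD -> rejected
  ts <- make_trialset(data, fs, t0)
  out <- reject_trials(ts)
  expect_equal(unname(out$rejected[1, ]), c(TRUE, FALSE, TRUE))
})

test_that("seizure-onset-zone and white-matter channels are excluded and
          zero-baseline channels flagged invalid", {
  fs <- 1000; n <- 2 * fs; t0 <- fs + 1L
  set.seed(2)
  data <- array(rnorm(3 * 3 * n), dim = c(3, 3, n))
  data[3, , ] <- 0                                  # dead channel
  ts <- make_trialset(data, fs, t0, in_soz = c(TRUE, FALSE, FALSE))
  out <- reject_trials(ts)
  expect_equal(out$channel_status, c("excluded", "ok", "invalid"))
  ep <- average_normalize(out)
  expect_true(ep$absent[1] && ep$absent[3])
  expect_match(ep$absent_reason[3], "invalid")
})

test_that("screening is monotone in its thresholds", {
  gt <- ep_ground_truth("OF", "lateral", 15, 8, 150, 5, artifact_rate = 0.3)
  ts <- simulate_ep_trials(gt, n_trials = 40, fs = 1000, seed = 8)
  strict <- reject_trials(ts, k_at = 5, k_any = 25)
  loose <- reject_trials(ts, k_at = 20, k_any = 100)
  expect_true(all(loose$rejected <= strict$rejected))
})

test_that("normalization yields unit baseline SD and is idempotent", {
  fs <- 1000; n <- 2 * fs; t0 <- fs + 1L
  set.seed(3)
  data <- array(rnorm(2 * 30 * n, sd = 3.7), dim = c(2, 30, n))
  ts <- make_trialset(data, fs, t0)
  ep <- average_normalize(ts)
  base_idx <- (t0 - round(0.1 * fs)):(t0 - round(0.01 * fs) - 1)
  for (c in 1:2) {
    expect_equal(sd(ep$traces[c, base_idx]), 1, tolerance = 1e-6)
  }
  ## injected bump of amplitude A volts with baseline SD s -> peak ~ A / s
  amp <- 5
  data2 <- data
  bump <- amp * exp(-0.5 * ((seq_len(n) - (t0 + 100)) / 20)^2)
  for (tr in 1:30) data2[1, tr, ] <- data2[1, tr, ] + bump
  ts2 <- make_trialset(data2, fs, t0)
  ep2 <- average_normalize(ts2)
  s <- ep2$baseline_sd[1]
  ## trace value at the bump centre = A/s up to the +-1 SD noise floor
  expect_equal(ep2$traces[1, t0 + 100], amp / s, tolerance = 0.4)
  expect_gt(amp / s, 5)               # bump dominates the noise
})

test_that("flat channels are reported absent with a reason", {
  fs <- 1000; n <- 2 * fs
  data <- array(0, dim = c(1, 3, n))
  ts <- make_trialset(data, fs, fs + 1L)
  ep <- average_normalize(ts)
  expect_true(ep$absent[1])
  expect_match(ep$absent_reason[1], "flat")
})

test_that("the composed band-pass hits -6 dB at both edges and is zero-phase", {
  g <- bandpass_gain_db(c(2, 200), fs = 8000)
  expect_equal(g, c(-6.0206, -6.0206), tolerance = 0.1)
  expect_lt(abs(bandpass_gain_db(30, fs = 8000)), 0.5)   # passband flat
  ## symmetric pulse stays symmetric under forward-backward filtering
  fs <- 2000; n <- 4000
  x <- exp(-0.5 * ((seq_len(n) - 2000) / 40)^2)
  y <- bandpass_early(matrix(x, 1), fs = fs)[1, ]
  ## mirror about the pulse centre (sample 2000): y[j] == y[4000 - j]
  j <- 1:1799
  expect_lt(max(abs(y[j] - y[4000 - j])), 1e-4)
  expect_error(bandpass_early(matrix(x, 1), fs = 300), "fs must exceed")
})

test_that("range values obey offset invariance and amplitude linearity", {
  fs <- 2000; n <- 2.5 * fs; t0 <- fs + 1L
  t_ms <- (seq_len(n) - t0) / fs * 1000
  ## full sine cycle of amplitude 1 inside the late window -> range 2
  x <- ifelse(t_ms >= 70 & t_ms < 200,
              sin(2 * pi * (t_ms - 70) / 130), 0)
  ep <- make_ep(matrix(x, 1), fs, t0)
  f <- extract_features(ep, filter_early = FALSE)
  expect_equal(f$range_value[f$window == "late"], 2, tolerance = 1e-6)
  ## offset leaves range unchanged, scaling scales it
  f_off <- extract_features(make_ep(matrix(x + 100, 1), fs, t0),
                            filter_early = FALSE)
  f_sc <- extract_features(make_ep(matrix(3 * x, 1), fs, t0),
                           filter_early = FALSE)
  expect_equal(f_off$range_value, f$range_value, tolerance = 1e-9)
  expect_equal(f_sc$range_value, 3 * f$range_value, tolerance = 1e-9)
})

test_that("component polarity and latency follow the earliest prominent peak", {
  gt <- ep_ground_truth("OF", "lateral", 15, -8, 150, 5)   # N-type early
  ts <- simulate_ep_trials(gt, n_trials = 3, fs = 2000, seed = 4,
                           noise_sd = 0)
  f <- extract_features(average_normalize(ts))
  fe <- f[f$window == "early", ]
  fl <- f[f$window == "late", ]
  expect_equal(fe$polarity, "N")
  expect_equal(fe$peak_latency_ms, 15, tolerance = 0.5)
  expect_equal(fl$polarity, "P")
  expect_equal(fl$peak_latency_ms, 150, tolerance = 1)
  ## a flat trace has no component
  epf <- make_ep(matrix(rnorm(5000, sd = 1e-12), 1), fs = 2000)
  ff <- extract_features(epf, filter_early = FALSE)
  expect_true(all(ff$polarity == "absent"))
  expect_true(all(is.na(ff$peak_latency_ms)))
})

test_that("latency is recovered within half a millisecond at study SNR", {
  gt <- ep_ground_truth("OF", "lateral", 15, 8, 150, 5)
  errs <- vapply(1:20, function(s) {
    ts <- simulate_ep_trials(gt, n_trials = 60, fs = 2000, seed = 100 + s)
    ts <- reject_trials(ts)
    f <- extract_features(average_normalize(ts))
    f$peak_latency_ms[f$window == "early"] - 15
  }, numeric(1))
  expect_lt(max(abs(errs)), 0.5)
  expect_lt(abs(mean(errs)), 0.2)         # unbiased at the sample grid
})

test_that("baseline-percentile significance is calibrated at 5 percent", {
  fs <- 1000
  n <- as.integer(1.25 * fs)
  t0 <- fs + 1L
  set.seed(42)
  n_ch <- 300
  traces <- matrix(rnorm(n_ch * n), n_ch, n)
  ep <- make_ep(traces, fs, t0)
  f <- extract_features(ep, filter_early = FALSE)
  f <- significance_test(ep, f, filter_early = FALSE, seed = 5)
  for (w in c("early", "late")) {
    rate <- mean(f$is_significant[f$window == w])
    expect_gt(rate, 0.02)
    expect_lt(rate, 0.10)
  }
  ## a zero-range trace can never be significant
  epz <- make_ep(matrix(c(rnorm(n - 300), numeric(300)), 1), fs, t0)
  fz <- extract_features(epz, filter_early = FALSE)
  fz <- significance_test(epz, fz, filter_early = FALSE)
  expect_false(any(fz$is_significant[fz$range_value == 0]))
  ## insufficient baseline is an error
  eps <- make_ep(matrix(rnorm(600), 1), fs, t0_index = 400L)
  fe <- extract_features(eps, filter_early = FALSE)
  expect_error(significance_test(eps, fe), "baseline")
})

test_that("an injected strong component is declared significant", {
  gt <- ep_ground_truth("OF", "lateral", 15, 8, 150, 6)
  ts <- simulate_ep_trials(gt, n_trials = 60, fs = 1000, seed = 12)
  ts <- reject_trials(ts)
  ep <- average_normalize(ts)
  f <- significance_test(ep, extract_features(ep))
  expect_true(all(f$is_significant))
})

test_that("ROI contrasts use two-sided t-tests with Bonferroni correction", {
  set.seed(6)
  mk <- function(roi, grp, vals) data.frame(
    name = seq_along(vals), roi = roi, roi_group = roi, window = "early",
    range_value = vals, peak_latency_ms = 15, polarity = "P",
    trend_value = 0, stim_group = grp, run_id = paste0(grp, seq_along(vals)))
  ## identical samples -> t = 0, corrected p = 1
  same <- rbind(mk("A", "medial", c(1, 2, 3, 4)),
                mk("A", "lateral", c(1, 2, 3, 4)))
  r <- roi_contrast(same)
  expect_equal(r$t, 0)
  expect_equal(r$p_corrected, 1)
  ## Bonferroni: corrected p = min(1, m * p)
  rois <- LETTERS[1:10]
  f <- do.call(rbind, lapply(rois, function(rr) rbind(
    mk(rr, "medial", rnorm(8)), mk(rr, "lateral", rnorm(8)))))
  f$range_value[f$roi == "C" & f$stim_group == "medial"] <-
    f$range_value[f$roi == "C" & f$stim_group == "medial"] + 3
  r <- roi_contrast(f)
  expect_equal(r$p_corrected, pmin(1, sum(r$testable) * r$p))
  expect_true(r$significant[r$roi == "C"])
  expect_equal(sum(r$significant), 1)     # only the injected ROI survives
  ## effect-size mode reports no test
  r2 <- roi_contrast(f, mode = "effect_size")
  expect_false("p" %in% names(r2))
  expect_true(all(c("effect", "se") %in% names(r2)))
})

test_that("latency group statistics recover an injected ordering", {
  set.seed(7)
  lat_means <- c(OF = 15, lPFC = 17, TL = 19, PL = 21)
  f <- do.call(rbind, lapply(names(lat_means), function(g) data.frame(
    name = 1:25, roi = g, roi_group = g, window = "early",
    range_value = 5, peak_latency_ms = rnorm(25, lat_means[g], 1),
    polarity = "P", trend_value = 0, stim_group = "lateral",
    run_id = "r1")))
  st <- latency_group_stats(f)
  expect_lt(st$anova$p, 1e-6)
  ord <- as.character(st$group_means$group[order(st$group_means$mean)])
  expect_equal(ord, names(lat_means))
  ## one group only -> error
  expect_error(latency_group_stats(f[f$roi_group == "OF", ]),
               "at least 2 groups")
})

test_that("stimulus safety arithmetic matches the waveform parameters", {
  expect_equal(stim_charge_per_phase(9, 0.2), 1.8)
  expect_equal(stim_pulse_duration(0.2, 2), 0.4)
  expect_equal(stim_charge_density(1.8, 0.0796), 22.6, tolerance = 0.01)
})
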