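test_that("Slepian tapers are orthonormal and band-concentrated", {
  tp <- dpss_tapers(256, nw = 2, k = 3)
  expect_equal(dim(tp), c(256L, 3L))
  expect_equal(crossprod(tp), diag(3), tolerance = 1e-8, ignore_attr = TRUE)
  ## the leading taper concentrates its energy inside |f| <= W
  spec <- abs(fft(c(tp[, 1], numeric(768))))^2
  W <- 2 / 256
  inband <- sum(spec[1:ceiling(W * 1024 + 1)])
  expect_gt(inband / (sum(spec) / 2), 0.99)
})

test_that("cross-spectra of independent white channels are flat and diagonal", {
  set.seed(1)
  data <- array(rnorm(3 * 40 * 300), dim = c(3, 40, 300))
  ts <- make_trialset(data, fs = 200, t0_index = 1)
  csd <- estimate_csd(ts, window_ms = NULL, nfft = 512)
  ## Hermitian at every frequency
  for (f in c(1, 100, 257))
    expect_equal(csd$S[, , f], Conj(t(csd$S[, , f])), tolerance = 1e-12)
  ## coherence between independent channels is small, auto-spectra flat
  mid <- 20:230
  coh <- Mod(csd$S[1, 2, mid])^2 /
    (Re(csd$S[1, 1, mid]) * Re(csd$S[2, 2, mid]))
  expect_lt(mean(coh), 0.05)
  auto <- Re(csd$S[1, 1, mid])
  expect_lt(sd(auto) / mean(auto), 0.35)
})

test_that("the estimated spectrum matches the analytic VAR spectrum", {
  spec <- coupled_var2()
  ts <- simulate_var(spec, n_trials = 60, n_samples = 1000, fs = 200,
                     seed = 13)
  csd <- estimate_csd(ts, window_ms = NULL, nfft = 2048)
  an <- var_spectrum(spec, csd$freqs, fs = 200)
  ## band-average both spectra (the analytic curve is smooth, the multitaper
  ## estimate fluctuates ~1/sqrt(trials x tapers) per bin), then compare
  ## after removing the common scale factor
  band_avg <- function(S, centres, hw = 24) {
    vapply(centres, function(f) apply(S[, , (f - hw):(f + hw)], c(1, 2), mean),
           matrix(0i, 2, 2))
  }
  mid <- seq(30, 990, by = 40)
  Sb <- band_avg(csd$S, mid)
  Ab <- band_avg(an$S, mid)
  sc <- mean(Re(Sb[1, 1, ]) / Re(Ab[1, 1, ]))
  relerr <- vapply(seq_along(mid), function(k)
    sqrt(sum(Mod(Sb[, , k] / sc - Ab[, , k])^2)) /
      sqrt(sum(Mod(Ab[, , k])^2)), numeric(1))
  expect_lt(stats::median(relerr), 0.05)
  expect_lt(max(relerr), 0.15)
})

test_that("Wilson factorization recovers closed-form and VAR factors", {
  ## scalar constant spectrum S(f) = sigma^2 -> H = 1, Sigma = sigma^2
  nfft <- 128; nf <- nfft / 2 + 1
  csd1 <- structure(list(
    S = array(4 + 0i, dim = c(1, 1, nf)),
    freqs = (0:(nf - 1)) * 100 / nfft, fs = 100, nfft = nfft,
    n_trials = 1, n_tapers = 1, window_ms = NULL, channel_names = "a"),
    class = "esconn_csd")
  sf1 <- wilson_factorize(csd1)
  expect_equal(sf1$Sigma[1, 1], 4, tolerance = 1e-8)
  expect_lt(max(Mod(sf1$H - 1)), 1e-6)
  ## an exactly lag-limited spectrum factorizes to machine precision
  B0 <- matrix(c(1, 0.3, 0, 0.8), 2, 2)
  B1 <- matrix(c(0.5, -0.2, 0.1, 0.4), 2, 2)
  nfft <- 256; nf <- nfft / 2 + 1
  S <- array(0i, dim = c(2, 2, nf))
  for (f in 1:nf) {
    z <- exp(-2i * pi * (f - 1) / nfft)
    P <- B0 + B1 * z
    S[, , f] <- P %*% Conj(t(P))
  }
  csd2 <- structure(list(S = S, freqs = (0:(nf - 1)) * 100 / nfft, fs = 100,
                         nfft = nfft, n_trials = 1, n_tapers = 1,
                         window_ms = NULL, channel_names = c("a", "b")),
                    class = "esconn_csd")
  sf2 <- wilson_factorize(csd2, tol = 1e-12)
  expect_lt(sf2$rel_error, 1e-6)            # reconstruction invariant
  expect_equal(sf2$Sigma, B0 %*% t(B0), tolerance = 1e-6)
  ## innovation covariance of an estimated VAR spectrum within a few percent
  spec <- coupled_var2()
  ts <- simulate_var(spec, n_trials = 80, n_samples = 1000, fs = 200,
                     seed = 14)
  csd <- estimate_csd(ts, window_ms = NULL, nfft = 2048)
  sf <- wilson_factorize(csd)
  sc <- sf$Sigma[1, 1] / spec$Sigma[1, 1]
  expect_equal(sf$Sigma / sc, spec$Sigma, tolerance = 0.06)
})

test_that("spectral causality matches the time-domain Geweke oracle", {
  spec <- coupled_var2()
  ts <- simulate_var(spec, n_trials = 60, n_samples = 1000, fs = 200,
                     seed = 15)
  csd <- estimate_csd(ts, window_ms = NULL, nfft = 2048)
  g_xy <- conditional_gc(csd, source = 1, target = 2, cond = integer(0))
  g_yx <- conditional_gc(csd, source = 2, target = 1, cond = integer(0))
  expect_true(all(g_xy$f >= 0))
  ## no reverse coupling: y -> x indistinguishable from zero
  expect_lt(mean(g_yx$f), 0.02)
  ## Geweke integral identity: mean over frequency = time-domain value
  td <- geweke_gc_time(ts, source = 1, target = 2, cond = integer(0),
                       order = 6)
  expect_equal(mean(g_xy$f), td, tolerance = 0.1)
})

test_that("independent channels and relabelings behave as required", {
  set.seed(16)
  data <- array(rnorm(3 * 50 * 400), dim = c(3, 50, 400))
  ts <- make_trialset(data, fs = 200, t0_index = 1)
  csd <- estimate_csd(ts, window_ms = NULL, nfft = 1024)
  r <- cgc_all_pairs(csd)
  expect_true(all(r$cgc >= 0, na.rm = TRUE))
  expect_true(all(is.na(r$cgc[cbind(1:3, 1:3, 1)])))
  expect_lt(max(apply(r$cgc, c(1, 2), mean)[!diag(3)]), 0.05)
  ## permutation equivariance: relabeling channels permutes the result
  perm <- c(2, 3, 1)
  csd_p <- csd
  csd_p$S <- csd$S[perm, perm, , drop = FALSE]
  csd_p$channel_names <- csd$channel_names[perm]
  r_p <- cgc_all_pairs(csd_p)
  expect_equal(r_p$cgc, r$cgc[perm, perm, , drop = FALSE],
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a chain system yields no conditional causality for the skip edge", {
  spec <- chain_var()
  ts <- simulate_var(spec, n_trials = 60, n_samples = 400, fs = 200,
                     seed = 17)
  csd <- estimate_csd(ts, window_ms = NULL, nfft = 1024)
  g_cond <- conditional_gc(csd, source = 1, target = 3, cond = 2)
  g_pair <- conditional_gc(csd, source = 1, target = 3, cond = integer(0))
  ## pairwise sees the mediated influence, conditional removes it
  expect_gt(mean(g_pair$f), 5 * mean(g_cond$f))
  td_cond <- geweke_gc_time(ts, 1, 3, 2, order = 6)
  td_pair <- geweke_gc_time(ts, 1, 3, integer(0), order = 6)
  expect_equal(mean(g_pair$f), td_pair, tolerance = 0.12)
  expect_lt(mean(g_cond$f), 0.02)
  expect_lt(td_cond, 0.02)
})

test_that("phase randomization preserves amplitude spectra and seeds", {
  set.seed(18)
  data <- array(rnorm(2 * 4 * 256), dim = c(2, 4, 256))
  ts <- make_trialset(data, fs = 200, t0_index = 1)
  surr <- esconn:::phase_randomize_trials(ts)
  for (c in 1:2) for (tr in 1:4) {
    a0 <- Mod(fft(ts$data[c, tr, ]))
    a1 <- Mod(fft(surr$data[c, tr, ]))
    expect_equal(a1, a0, tolerance = 1e-9)
    expect_false(isTRUE(all.equal(surr$data[c, tr, ], ts$data[c, tr, ])))
  }
  thr1 <- surrogate_threshold(ts, n_surr = 20, seed = 4, window_ms = NULL,
                              nfft = 512)
  thr2 <- surrogate_threshold(ts, n_surr = 20, seed = 4, window_ms = NULL,
                              nfft = 512)
  expect_identical(thr1$threshold, thr2$threshold)
  expect_error(surrogate_threshold(ts, n_surr = 5), "n_surr")
})

test_that("network summaries aggregate by ROI group at the nearest bin", {
  ## synthetic causality result: uniform value c over 3 groups of channels
  nm <- sprintf("ch%02d", 1:6)
  groups <- rep(c("A", "B", "C"), each = 2)
  freqs <- seq(0, 100, by = 4)
  cval <- 0.3
  cgc <- array(cval, dim = c(6, 6, length(freqs)),
               dimnames = list(nm, nm, NULL))
  for (f in seq_along(freqs)) diag(cgc[, , f]) <- NA
  res <- structure(list(cgc = cgc, freqs = freqs, channel_names = nm),
                   class = "esconn_cgc")
  s <- summarize_network(res, groups, eval_freq = 8)
  expect_equal(s$eval_freq_used, 8)          # exact bin present
  expect_true(all(abs(s$group_cgc - cval) < 1e-12))
  ## all-significant uniform network: in-degree = (k-1) * c
  expect_equal(unname(s$in_degree), rep((3 - 1) * cval, 3), tolerance = 1e-12)
  ## eval frequency between bins resolves to the nearest bin
  s2 <- summarize_network(res, groups, eval_freq = 9.4)
  expect_equal(s2$eval_freq_used, 8)
  ## significance mask zeroes sub-threshold edges
  thr <- array(0.5, dim = c(6, 6, length(freqs)))
  s3 <- summarize_network(res, groups, threshold = thr, eval_freq = 8)
  expect_false(any(s3$significant))
  expect_equal(unname(s3$in_degree), rep(0, 3))
})

test_that("an injected group-level coupling is the sole significant edge", {
  ## 4 channels in 2 groups; coupling only from group A (ch 1-2) to B (ch 3)
  A <- array(0, dim = c(4, 4, 1))
  diag(A[, , 1]) <- 0.4
  A[3, 1, 1] <- 0.45
  A[3, 2, 1] <- 0.45
  spec <- var_spec(A, diag(4))
  ts <- simulate_var(spec, n_trials = 40, n_samples = 260, fs = 200,
                     seed = 19)
  csd <- estimate_csd(ts, window_ms = NULL, nfft = 512)
  r <- cgc_all_pairs(csd)
  thr <- surrogate_threshold(ts, n_surr = 20, seed = 20, window_ms = NULL,
                             nfft = 512)
  s <- summarize_network(r, rep(c("A", "B"), each = 2),
                         threshold = thr$threshold, eval_freq = 8)
  expect_true(s$significant["A", "B"])
  expect_false(s$significant["B", "A"])
})
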