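test_that("censoring removes high-motion frames, their predecessors and the
          first two frames", {
  P <- block_precision(1, 3)
  gt <- bold_ground_truth(P, bold_amplitudes(3), n_cycles = 2,
                          motion_spike_prob = 0)
  run <- simulate_bold(gt, 1, "medial", seed = 1)[[1]]
  run$fd[10] <- 1.2
  m <- censor_mask(run)
  expect_false(any(m[c(1, 2, 9, 10)]))
  expect_true(all(m[-c(1, 2, 9, 10)]))
})

test_that("deconvolution is exact on noiseless data in the basis span and
          linear in amplitude", {
  P <- block_precision(3, 3)
  n_roi <- nrow(P)
  gt <- bold_ground_truth(P, bold_amplitudes(n_roi), n_cycles = 5,
                          motion_spike_prob = 0, noise_sd = 0)
  run <- simulate_bold(gt, 1, "medial", seed = 1)[[1]]
  bas <- spline_response_basis(run$tr)
  set.seed(2)
  beta_true <- matrix(rnorm(n_roi * 14), n_roi, 14)
  resp <- beta_true %*% t(bas$B)
  lagf <- round(bas$lags / run$tr)
  ser <- matrix(0, n_roi, ncol(run$series))
  for (o in run$onsets) {
    rows <- o + lagf; ok <- rows >= 1 & rows <= ncol(ser)
    ser[, rows[ok]] <- ser[, rows[ok]] + resp[, ok]
  }
  ser <- ser - rowMeans(ser)    # keep the series mean at exactly 100, so
                                # the mean-100 scaling is the identity
  run$series <- 100 + ser
  run$fd <- rep(0.05, ncol(ser))
  dec <- fir_deconvolve(run)
  expect_lt(max(abs(dec$residuals)), 1e-8)
  expect_equal(unname(dec$betas), unname(beta_true), tolerance = 1e-6)
  ## linearity of least squares: doubling the response doubles mean beta
  run2 <- run; run2$series <- 100 + 2 * ser
  dec2 <- fir_deconvolve(run2)
  mb1 <- mean_beta(dec); mb2 <- mean_beta(dec2)
  expect_equal(unname(mb2), unname(2 * mb1), tolerance = 1e-6)
})

test_that("zero-amplitude regions give near-zero betas and dropout gives NA", {
  P <- block_precision(2, 3)
  n_roi <- nrow(P)
  amps <- bold_amplitudes(n_roi, 0, 0)
  gt <- bold_ground_truth(P, amps, n_cycles = 6, motion_spike_prob = 0)
  run <- simulate_bold(gt, 1, "medial", seed = 3)[[1]]
  run$series[4, ] <- 0                      # electrode signal dropout
  dec <- fir_deconvolve(run)
  expect_true(all(is.na(dec$betas[4, ])))
  mb <- mean_beta(dec)
  expect_true(is.na(mb[4]))
  se <- apply(dec$betas[-4, ], 2, sd)
  expect_true(all(abs(colMeans(dec$betas[-4, ])) < 3 * se / sqrt(n_roi - 1) + 1))
  ## flat response c over the window -> mean beta = c
  runf <- run
  runf$series <- matrix(100, n_roi, ncol(run$series))
  runf$series[1, ] <- 100
  decf <- fir_deconvolve(run)
  bb <- decf$betas[1, ]
  decf$betas[1, ] <- 7
  expect_equal(unname(mean_beta(decf)[1]), 7, tolerance = 1e-8)
  expect_error(mean_beta(dec, interval = c(3, 60)), "window")
})

test_that("partial correlations recover the planted precision structure", {
  P <- block_precision(3, 3, 0.25)
  gt <- bold_ground_truth(P, bold_amplitudes(nrow(P), 0, 0), n_cycles = 500,
                          motion_spike_prob = 0)
  run <- simulate_bold(gt, 1, "medial", seed = 4)[[1]]
  dec <- fir_deconvolve(run)
  net <- residual_network(dec, condition = "all", band = NULL,
                          shrink = "none")
  expect_gte(net$n_frames_used, 9000)
  pc_true <- partial_cor_from_precision(P)
  offerr <- abs(net$pcor - pc_true)[!diag(nrow(P))]
  ## sampling error ~ 1/sqrt(frames) = 0.01 per edge at this run length
  expect_lt(mean(offerr), 0.012)
  expect_lt(max(offerr), 0.035)
  expect_true(isSymmetric(net$z, tol = 1e-10))
  expect_true(all(diag(net$z) == 0))
  ## rho = 0 maps to z = 0 exactly under the Fisher transform
  expect_equal(atanh(0), 0)
  idx <- which(pc_true == 0 & upper.tri(pc_true))
  expect_lt(max(abs(net$z[idx])), 0.05)
})

test_that("independent regions give Fisher-z values on the null scale", {
  n_roi <- 8
  P <- diag(n_roi)
  rownames(P) <- colnames(P) <- sprintf("roi%02d", 1:n_roi)
  gt <- bold_ground_truth(P, bold_amplitudes(n_roi, 0, 0), n_cycles = 30,
                          motion_spike_prob = 0)
  zs <- unlist(lapply(1:6, function(r) {
    run <- simulate_bold(gt, 1, "medial", seed = 40 + r)[[1]]
    dec <- fir_deconvolve(run)
    net <- residual_network(dec, condition = "all", band = NULL,
                            shrink = "none")
    net$z[upper.tri(net$z)]
  }))
  n_frames <- 30 * 20 + 4 - 2
  null_sd <- 1 / sqrt(n_frames - (n_roi - 2) - 3)
  ## deconvolution regressors absorb a few more degrees of freedom
  expect_equal(sd(zs), null_sd, tolerance = 0.25)
  expect_lt(abs(mean(zs)), 3 * null_sd / sqrt(length(zs)) + 0.01)
})

test_that("the stated 0.1-1 Hz band is clipped to Nyquist with a warning", {
  P <- diag(4); rownames(P) <- colnames(P) <- paste0("r", 1:4)
  gt <- bold_ground_truth(P, bold_amplitudes(4, 0, 0), n_cycles = 20,
                          motion_spike_prob = 0)
  run <- simulate_bold(gt, 1, "medial", seed = 5)[[1]]
  dec <- fir_deconvolve(run)
  expect_warning(residual_network(dec, condition = "all"), "Nyquist")
})

test_that("ON and OFF frame labels respect the haemodynamic shift", {
  P <- diag(3); rownames(P) <- colnames(P) <- paste0("r", 1:3)
  gt <- bold_ground_truth(P, bold_amplitudes(3), n_cycles = 2,
                          lead_frames = 4, motion_spike_prob = 0)
  run <- simulate_bold(gt, 1, "medial", seed = 6)[[1]]
  lab0 <- esconn:::condition_frames(run, shift = 0)
  lab1 <- esconn:::condition_frames(run, shift = 1)
  expect_equal(which(lab0 == "ON")[1], run$onsets[1])
  expect_equal(which(lab1 == "ON")[1], run$onsets[1] + 1)
  expect_equal(sum(lab0 == "ON"), 2 * run$frames_on)
})

test_that("edge contrasts are antisymmetric, calibrated and powered", {
  P <- diag(6); rownames(P) <- colnames(P) <- paste0("r", 1:6)
  gt <- bold_ground_truth(P, bold_amplitudes(6, 0, 0), n_cycles = 12,
                          motion_spike_prob = 0)
  make_nets <- function(seeds) lapply(seeds, function(s) {
    run <- simulate_bold(gt, 1, "medial", seed = s)[[1]]
    residual_network(fir_deconvolve(run), condition = "all", band = NULL)
  })
  nets_a <- make_nets(1:6)
  nets_b <- make_nets(101:106)
  con <- edge_contrast(nets_a, nets_b)
  con_rev <- edge_contrast(nets_b, nets_a)
  expect_equal(con$t, -con_rev$t, tolerance = 1e-10)
  ## null data: no (or almost no) significant edges at FDR 0.05
  expect_lte(mean(con$significant[upper.tri(con$significant)]), 0.05)
  ## a planted difference on one edge is detected
  nets_c <- lapply(nets_b, function(nt) {
    nt$z[1, 2] <- nt$z[2, 1] <- nt$z[1, 2] + 1.5
    nt
  })
  con2 <- edge_contrast(nets_a, nets_c)
  expect_true(con2$significant[1, 2])
  expect_equal(sum(con2$significant[upper.tri(con2$significant)]), 1)
  expect_error(edge_contrast(nets_a[1], nets_b), "at least 2 runs")
})

test_that("consensus communities recover planted blocks exactly", {
  P <- block_precision(3, 4, 0.2)
  pc <- partial_cor_from_precision(P)
  z <- atanh(pc * (1 - diag(nrow(P))))
  ## weak inter-block edges must not merge blocks
  set.seed(7)
  noise <- matrix(rnorm(nrow(P)^2, 0, 0.005), nrow(P))
  z <- z + (noise + t(noise)) / 2
  diag(z) <- 0
  cc <- community_consensus(z, n_runs = 60, seed = 8)
  truth <- rep(1:3, each = 4)
  expect_equal(cc$n_communities, 3)
  expect_equal(mclust::adjustedRandIndex(cc$membership, truth), 1)
  ## determinism under a fixed seed
  cc2 <- community_consensus(z, n_runs = 60, seed = 8)
  expect_identical(cc$membership, cc2$membership)
  ## a complete uniform graph is one community; an empty graph is singletons
  u <- matrix(0.5, 6, 6); diag(u) <- 0
  expect_equal(community_consensus(u, n_runs = 20, seed = 1)$n_communities, 1)
  e <- matrix(0, 5, 5)
  expect_equal(community_consensus(e, n_runs = 20, seed = 1)$n_communities, 5)
})

test_that("SMOTE balances classes on segments between minority neighbors", {
  set.seed(9)
  x <- matrix(rnorm(30 * 4), 30, 4)
  y <- rep(c("a", "b"), c(20, 10))
  bal <- smote_balance(x, y, k = 3, seed = 2)
  expect_equal(unname(table(bal$y)["a"]), unname(table(bal$y)["b"]))
  expect_equal(sum(bal$synthetic), 10)
  ## each synthetic point lies on a segment between its two parents
  mi <- which(y == "b")
  for (s in which(bal$synthetic)) {
    p <- bal$parents[s - 30, ]
    d_ab <- sqrt(sum((x[p[1], ] - x[p[2], ])^2))
    d_s <- sqrt(sum((bal$x[s, ] - x[p[1], ])^2)) +
      sqrt(sum((bal$x[s, ] - x[p[2], ])^2))
    expect_equal(d_s, d_ab, tolerance = 1e-8)
    expect_true(all(p %in% mi))
  }
})

test_that("run classification finds planted signal with honest nulls", {
  set.seed(10)
  n_roi <- 10
  lab <- rep(c("medial", "lateral"), c(26, 13))
  x <- matrix(rnorm(39 * n_roi), 39, n_roi,
              dimnames = list(NULL, sprintf("roi%02d", 1:n_roi)))
  x[lab == "medial", 4] <- x[lab == "medial", 4] + 4
  x[5, 7] <- NA                              # dropout is imputed, not zeroed
  res <- run_classification(x, lab, n_shuffle = 25, seed = 3)
  expect_gt(res$oob_auc, 0.9)
  expect_lt(abs(mean(res$shuffled_auc) - 0.5), 0.12)
  sig <- res$importance$roi[res$importance$significant]
  expect_true("roi04" %in% sig)
  expect_lte(length(setdiff(sig, c("roi04"))), 1)
  expect_error(run_classification(x[c(1, 2, 27, 28), ],
                                  lab[c(1, 2, 27, 28)]), "3 runs")
})
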