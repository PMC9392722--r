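## Fixture builders shared across the suite. Everything is generated in
## code under fixed seeds; nothing is read from disk.

## A minimal evoked-potential object from a channels x samples matrix,
## with onset placed so that >= 1000 ms of baseline is available.
make_ep <- function(traces, fs, t0_index = NULL, roi_group = "other",
                    stim_group = "medial", run_id = "test-run") {
  traces <- as.matrix(traces)
  n_ch <- nrow(traces)
  if (is.null(t0_index)) t0_index <- as.integer(fs) + 1L
  channels <- data.frame(
    name = sprintf("ch%02d", seq_len(n_ch)),
    roi = rep_len(roi_group, n_ch),
    roi_group = rep_len(roi_group, n_ch),
    hemisphere = "R", in_soz = FALSE, in_white_matter = FALSE,
    stringsAsFactors = FALSE)
  structure(list(traces = traces, fs = fs, t0_index = t0_index,
                 channels = channels, n_trials_used = rep(1L, n_ch),
                 baseline_sd = rep(1, n_ch), absent = rep(FALSE, n_ch),
                 absent_reason = rep(NA_character_, n_ch),
                 stim_group = stim_group, run_id = run_id),
            class = "esconn_ep")
}

## A trial set built directly from an array (channels x trials x samples).
make_trialset <- function(data, fs, t0_index, stim_group = "medial",
                          in_soz = FALSE, in_white_matter = FALSE) {
  n_ch <- dim(data)[1]
  channels <- data.frame(
    name = sprintf("ch%02d", seq_len(n_ch)),
    roi = "other", roi_group = "other", hemisphere = "R",
    in_soz = rep_len(in_soz, n_ch),
    in_white_matter = rep_len(in_white_matter, n_ch),
    stringsAsFactors = FALSE)
  structure(list(data = data, fs = fs, t0_index = as.integer(t0_index),
                 channels = channels, stim_group = stim_group,
                 run_id = "test-run", ground_truth = NULL, seed = NA),
            class = "esconn_trialset")
}

## A stationary bivariate VAR(2) with coupling ch1 -> ch2 only.
coupled_var2 <- function(coupling = 0.5) {
  A <- array(0, dim = c(2, 2, 2))
  A[1, 1, 1] <- 0.55; A[1, 1, 2] <- -0.8
  A[2, 2, 1] <- 0.35; A[2, 2, 2] <- -0.5
  A[2, 1, 1] <- coupling
  var_spec(A, diag(c(1, 0.7)))
}

## A three-channel chain x -> y -> z, VAR(1).
chain_var <- function(coupling = 0.5) {
  A <- array(0, dim = c(3, 3, 1))
  diag(A[, , 1]) <- 0.5
  A[2, 1, 1] <- coupling
  A[3, 2, 1] <- coupling
  var_spec(A, diag(3))
}

## Block-structured precision matrix: `k` blocks of `size` ROIs with
## within-block partial correlation, none across blocks.
block_precision <- function(k = 3, size = 3, partial = 0.25) {
  n <- k * size
  P <- diag(n)
  for (b in seq_len(k)) {
    idx <- ((b - 1) * size + 1):(b * size)
    P[idx, idx][row(diag(size)) != col(diag(size))] <- -partial
  }
  rownames(P) <- colnames(P) <- sprintf("roi%02d", seq_len(n))
  P
}

## Default amplitudes for a BOLD ground truth on n ROIs.
bold_amplitudes <- function(n, medial = 2, lateral = 0.5) {
  cbind(medial = rep_len(medial, n), lateral = rep_len(lateral, n))
}
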