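#' @keywords internal
"_PACKAGE"

#' Derive a per-stage seed from a master seed
#'
#' One master seed deterministically spawns independent per-stage seeds, so
#' partial re-runs of a pipeline reproduce the same randomness stage by stage.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(master) * 48271 + h * 16807) %% (2^31 - 1))
}

## Map a time in ms (relative to stimulation onset) to a sample index.
## Sample mapping is floor(fs * t): windows [a, b) ms are half-open.
time_to_index <- function(t_ms, fs, t0_index) {
  t0_index + floor(fs * t_ms / 1000)
}

## Indices covering the half-open window [a, b) ms around onset.
window_indices <- function(window_ms, fs, t0_index, n) {
  i0 <- time_to_index(window_ms[1], fs, t0_index)
  i1 <- time_to_index(window_ms[2], fs, t0_index) - 1L
  i0 <- max(1L, i0); i1 <- min(n, i1)
  if (i1 < i0) stop("window [", window_ms[1], ", ", window_ms[2],
                    ") ms is empty at fs = ", fs)
  seq.int(i0, i1)
}

#' Generate 1/f^alpha Gaussian noise
#'
#' Spectrally shaped Gaussian noise: white noise is filtered in the frequency
#' domain with amplitude proportional to f^(-alpha/2), giving a power spectrum
#' proportional to 1/f^alpha. The output is standardized to unit variance.
#'
#' @param n number of samples.
#' @param alpha spectral slope (0 = white, 1 = pink, 2 = brown).
#' @return Numeric vector of length `n` with mean ~0 and SD 1.
#' @export
noise_one_over_f <- function(n, alpha = 1) {
  if (alpha == 0) return(stats::rnorm(n))
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- c(1, seq_len(n - 1))            # avoid division by zero at DC
  f <- pmin(f, n - f + 1)              # fold to two-sided frequency magnitude
  shape <- f^(-alpha / 2)
  shape[1] <- 0                        # remove DC
  y <- Re(stats::fft(X * shape, inverse = TRUE)) / n
  as.numeric(scale(y))
}

## Nearest index of `x` in grid `g`.
nearest_index <- function(g, x) which.min(abs(g - x))

## Numerically symmetrize a matrix.
symmetrize <- function(m) (m + t(m)) / 2

## Check symmetric positive definiteness via Cholesky.
is_spd <- function(m, tol = 1e-10) {
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) return(FALSE)
  ok <- tryCatch({ chol(m); TRUE }, error = function(e) FALSE)
  ok
}

## The six cortical ROI groups used for latency and network summaries.
ROI_GROUPS <- c("OF", "lPFC", "SM", "PL", "TL", "CC")

#' @export
print.esconn_trialset <- function(x, ...) {
  d <- dim(x$data)
  cat("<TrialSet> ", d[1], " channels x ", d[2], " trials x ", d[3],
      " samples @ ", x$fs, " Hz\n", sep = "")
  cat("  onset at sample ", x$t0_index, "; stim_group = ",
      x$stim_group %||% "<none>", "; run_id = ", x$run_id %||% "<none>",
      "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
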