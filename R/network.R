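## Second-order BOLD connectivity: residual partial-correlation networks,
## ON/OFF and stimulation-site edge contrasts, and consensus communities.

## Ledoit-Wolf shrinkage of a sample covariance toward the scaled identity.
## Returns the shrunk covariance and the shrinkage weight.
lw_shrink <- function(x) {
  n <- nrow(x); p <- ncol(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  S <- crossprod(xc) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - mu * diag(p))^2)
  b2 <- 0
  for (i in seq_len(n)) {
    xi <- tcrossprod(xc[i, ])
    b2 <- b2 + sum((xi - S)^2)
  }
  b2 <- min(b2 / n^2, d2)
  lambda <- if (d2 > 0) b2 / d2 else 0
  list(cov = lambda * mu * diag(p) + (1 - lambda) * S, lambda = lambda)
}

## ON / OFF frame labels for a run, with a haemodynamic shift (frames).
condition_frames <- function(run, shift = 1) {
  n <- ncol(run$series)
  lab <- rep("OFF", n)
  for (o in run$onsets) {
    idx <- (o:(o + run$frames_on - 1)) + shift
    idx <- idx[idx >= 1 & idx <= n]
    lab[idx] <- "ON"
  }
  lab
}

#' Residual partial-correlation network of a run
#'
#' Takes the deconvolution residuals (the fluctuations not captured by the
#' stimulus-locked response, i.e. background connectivity), optionally
#' high-pass filters them, selects the frames of the requested stimulation
#' condition (with a one-frame haemodynamic shift by default), estimates the
#' partial correlations from the (shrinkage-regularized) inverse covariance
#' and Fisher-z transforms them.
#'
#' The protocol's stated 0.1-1 Hz band exceeds the Nyquist frequency of
#' TR = 3 s data (0.167 Hz); the realizable reading is a 0.1 Hz high-pass,
#' so the upper edge is clipped to Nyquist with a warning when necessary.
#'
#' @param deconv an `esconn_deconv` (or a plain ROI x frames residual matrix
#'   plus `tr`).
#' @param condition `"ON"`, `"OFF"` or `"all"`.
#' @param band filter band in Hz, `NULL` to skip filtering.
#' @param shift haemodynamic shift (frames) applied to the ON labels.
#' @param shrink `"auto"` (Ledoit-Wolf weight estimated from the data),
#'   `"none"`, or a numeric weight in \[0, 1\].
#' @param fd_threshold,n_discard censoring (frames failing it are excluded).
#' @param tr repetition time, needed only for a plain matrix input.
#' @return An `esconn_pcnet`: list with `z` (ROI x ROI Fisher-z partial
#'   correlations, zero diagonal), `pcor`, `condition`, `n_frames_used`,
#'   `shrinkage`, `run_id`, `stim_group`.
#' @export
residual_network <- function(deconv, condition = c("ON", "OFF", "all"),
                             band = c(0.1, 1), shift = 1, shrink = "auto",
                             fd_threshold = 0.9, n_discard = 2, tr = NULL) {
  condition <- match.arg(condition)
  if (inherits(deconv, "esconn_deconv")) {
    resid <- deconv$residuals
    run <- deconv$run
    mask <- deconv$mask
    tr <- run$tr
  } else {
    resid <- as.matrix(deconv)
    if (is.null(tr)) stop("tr required for a plain residual matrix")
    run <- NULL
    mask <- rep(TRUE, ncol(resid))
  }
  keep_roi <- apply(resid, 1, function(r) all(is.finite(r)))
  resid <- resid[keep_roi, , drop = FALSE]
  n_roi <- nrow(resid)
  x <- resid
  if (!is.null(band)) {
    nyq <- 1 / (2 * tr)
    if (band[2] > nyq) {
      warning("filter upper edge ", band[2], " Hz exceeds Nyquist (",
              signif(nyq, 3), " Hz) at TR = ", tr,
              " s; applying a ", band[1], " Hz high-pass instead")
      bf <- signal::butter(2, band[1] / nyq, type = "high")
    } else {
      bf <- signal::butter(2, band / nyq, type = "pass")
    }
    for (r in seq_len(n_roi)) x[r, ] <- signal::filtfilt(bf, x[r, ])
  }
  sel <- mask
  if (condition != "all") {
    if (is.null(run)) stop("condition selection needs a full deconvolution object")
    sel <- sel & (condition_frames(run, shift) == condition)
  }
  n_used <- sum(sel)
  if (n_used < 3) stop("fewer than 3 usable frames for condition ", condition)
  xm <- t(x[, sel, drop = FALSE])
  if (identical(shrink, "none")) shrink <- 0
  if (identical(shrink, "auto")) {
    sh <- lw_shrink(xm); Sig <- sh$cov; lambda <- sh$lambda
  } else {
    lambda <- as.numeric(shrink)
    S <- stats::cov(xm) * (n_used - 1) / n_used
    mu <- mean(diag(S))
    Sig <- lambda * mu * diag(n_roi) + (1 - lambda) * S
  }
  Om <- solve(Sig)
  d <- 1 / sqrt(diag(Om))
  pcor <- -Om * outer(d, d)
  diag(pcor) <- 0
  z <- atanh(pmax(pmin(pcor, 1 - 1e-12), -1 + 1e-12))
  rn <- rownames(resid) %||% sprintf("roi%02d", seq_len(n_roi))
  dimnames(z) <- dimnames(pcor) <- list(rn, rn)
  structure(list(z = z, pcor = pcor, condition = condition,
                 n_frames_used = n_used, shrinkage = lambda,
                 run_id = if (is.null(run)) NA_character_ else run$run_id,
                 stim_group = if (is.null(run)) NA_character_ else run$stim_group),
            class = "esconn_pcnet")
}

#' Edge-wise contrast between network conditions
#'
#' Per-edge two-sided t-test of Fisher-z partial correlations between two
#' sets of networks (stimulation ON vs OFF, or medial vs lateral site), with
#' Benjamini-Hochberg false-discovery-rate correction across all edges.
#'
#' @param nets_a,nets_b lists of `esconn_pcnet` objects (one per run), same
#'   ROI set.
#' @return List with matrices `t`, `p`, `q`, `diff` (mean z difference,
#'   a minus b), logical `significant` (q < `fdr`), and an `edges`
#'   data.frame of the significant edges with sign.
#' @param fdr FDR threshold (default 0.05).
#' @export
edge_contrast <- function(nets_a, nets_b, fdr = 0.05) {
  if (length(nets_a) < 2 || length(nets_b) < 2)
    stop("need at least 2 runs per level for an edge contrast")
  za <- simplify2array(lapply(nets_a, `[[`, "z"))
  zb <- simplify2array(lapply(nets_b, `[[`, "z"))
  n_roi <- dim(za)[1]
  rn <- dimnames(za)[[1]]
  tmat <- pmat <- dmat <- matrix(NA_real_, n_roi, n_roi,
                                 dimnames = list(rn, rn))
  ut <- which(upper.tri(tmat), arr.ind = TRUE)
  for (k in seq_len(nrow(ut))) {
    i <- ut[k, 1]; j <- ut[k, 2]
    va <- za[i, j, ]; vb <- zb[i, j, ]
    tt <- stats::t.test(va, vb)
    tmat[i, j] <- tmat[j, i] <- unname(tt$statistic)
    pmat[i, j] <- pmat[j, i] <- tt$p.value
    dmat[i, j] <- dmat[j, i] <- mean(va) - mean(vb)
  }
  qv <- stats::p.adjust(pmat[upper.tri(pmat)], method = "BH")
  qmat <- matrix(NA_real_, n_roi, n_roi, dimnames = list(rn, rn))
  qmat[upper.tri(qmat)] <- qv
  qmat[lower.tri(qmat)] <- t(qmat)[lower.tri(qmat)]
  sig <- !is.na(qmat) & qmat < fdr
  idx <- which(sig & upper.tri(sig), arr.ind = TRUE)
  edges <- data.frame(roi1 = rn[idx[, 1]], roi2 = rn[idx[, 2]],
                      diff_z = dmat[idx], t = tmat[idx], q = qmat[idx],
                      stringsAsFactors = FALSE)
  list(t = tmat, p = pmat, q = qmat, diff = dmat, significant = sig,
       edges = edges)
}

#' Consensus community detection on a partial-correlation network
#'
#' Repeated seeded runs of modularity-based Leiden community detection on
#' the positive-weight graph, followed by consensus clustering: the
#' co-assignment frequency matrix over runs is thresholded at 0.5 and
#' re-clustered once to give the final membership. Negative edges are
#' dropped (the negative-correlation network is analysed separately).
#'
#' @param z symmetric weight matrix (e.g. mean Fisher-z network).
#' @param resolution Leiden resolution parameter (default 1.0).
#' @param n_runs number of seeded detection runs (default 200).
#' @param seed integer seed.
#' @param consensus_threshold co-assignment frequency threshold.
#' @return List with `membership` (named integer vector), `coassignment`
#'   matrix, `n_communities`.
#' @export
community_consensus <- function(z, resolution = 1.0, n_runs = 200, seed = 1,
                                consensus_threshold = 0.5) {
  w <- symmetrize(as.matrix(z))   # guard against floating-point asymmetry
  w[w < 0] <- 0
  diag(w) <- 0
  n <- nrow(w)
  rn <- rownames(w) %||% sprintf("roi%02d", seq_len(n))
  if (all(w == 0)) {
    membership <- stats::setNames(seq_len(n), rn)
    return(list(membership = membership,
                coassignment = diag(n), n_communities = n))
  }
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  co <- matrix(0, n, n)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(seeds[r])
    cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 3)
    mem <- igraph::membership(cl)
    co <- co + outer(mem, mem, "==")
  }
  co <- co / n_runs
  cw <- co
  cw[cw < consensus_threshold] <- 0
  diag(cw) <- 0
  if (all(cw == 0)) {
    membership <- stats::setNames(seq_len(n), rn)
  } else {
    gc2 <- igraph::graph_from_adjacency_matrix(cw, mode = "undirected",
                                               weighted = TRUE)
    set.seed(seeds[1])
    cl2 <- igraph::cluster_leiden(gc2, objective_function = "modularity",
                                  resolution = resolution, n_iterations = 3)
    membership <- stats::setNames(as.integer(igraph::membership(cl2)), rn)
  }
  dimnames(co) <- list(rn, rn)
  list(membership = membership, coassignment = co,
       n_communities = length(unique(membership)))
}
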