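## Run-level stimulation-site classification from mean BOLD responses:
## minority oversampling, a random-forest ensemble scored out-of-bag, and a
## shuffled-label importance threshold.

#' Synthetic minority oversampling (SMOTE)
#'
#' Balances a two-class dataset by interpolating new minority samples on
#' segments between each minority sample and one of its k nearest minority
#' neighbors. When the minority class has fewer than `k + 1` samples the
#' neighbor count is reduced (with a message).
#'
#' @param x numeric feature matrix.
#' @param y binary labels (factor or character).
#' @param k number of nearest neighbors (default 5).
#' @param seed integer seed.
#' @return List with balanced `x`, `y`, and `synthetic` (logical marker of
#'   generated rows).
#' @export
smote_balance <- function(x, y, k = 5, seed = 1) {
  x <- as.matrix(x); y <- as.factor(y)
  stopifnot(nlevels(y) == 2)
  set.seed(seed)
  tab <- table(y)
  if (tab[1] == tab[2])
    return(list(x = x, y = y, synthetic = rep(FALSE, nrow(x))))
  minority <- names(tab)[which.min(tab)]
  mi <- which(y == minority)
  need <- max(tab) - min(tab)
  if (length(mi) < 2) stop("minority class needs at least 2 samples")
  k_use <- min(k, length(mi) - 1)
  if (k_use < k) message("SMOTE: reducing neighbor count to ", k_use)
  dmin <- as.matrix(stats::dist(x[mi, , drop = FALSE]))
  nn <- t(apply(dmin, 1, function(r) order(r)[2:(k_use + 1)]))
  newx <- matrix(NA_real_, need, ncol(x), dimnames = list(NULL, colnames(x)))
  parents <- matrix(NA_integer_, need, 2)
  base_pick <- sample(rep_len(seq_along(mi), need))
  for (s in seq_len(need)) {
    i <- base_pick[s]
    j <- nn[i, sample.int(k_use, 1)]
    u <- stats::runif(1)
    newx[s, ] <- x[mi[i], ] + u * (x[mi[j], ] - x[mi[i], ])
    parents[s, ] <- c(mi[i], mi[j])      # original-row indices
  }
  list(x = rbind(x, newx),
       y = factor(c(as.character(y), rep(minority, need)), levels(y)),
       synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, need)),
       parents = parents)
}

#' Classify stimulation site from run-level mean responses
#'
#' Random-forest classification of medial vs lateral stimulation from the
#' per-run table of ROI mean betas. The class imbalance is corrected with
#' SMOTE before fitting; performance is the out-of-bag area under the ROC
#' curve. The same protocol is repeated on label-shuffled copies, and ROIs
#' whose permutation importance exceeds the shuffled mean plus
#' `importance_sd_mult` standard deviations are flagged as informative.
#' Missing ROI values (electrode signal dropout) are median-imputed within
#' class, with a missingness indicator column appended per affected ROI.
#'
#' @param betas matrix runs x ROIs of mean beta values (may contain `NA`).
#' @param labels stimulation-site label per run (2 levels, >= 3 runs each).
#' @param n_trees forest size (default 250).
#' @param n_shuffle label-shuffled replicates (protocol: 100).
#' @param importance_sd_mult SD multiplier of the importance threshold.
#' @param seed integer seed.
#' @param smote_k SMOTE neighbor count.
#' @return List with `oob_auc`, `shuffled_auc` (vector), `importance`
#'   data.frame (`roi`, `importance`, `shuffled_mean`, `shuffled_sd`,
#'   `threshold`, `significant`), and `model`.
#' @export
run_classification <- function(betas, labels, n_trees = 250, n_shuffle = 100,
                               importance_sd_mult = 5, seed = 1,
                               smote_k = 5) {
  betas <- as.matrix(betas)
  y <- as.factor(labels)
  stopifnot(nlevels(y) == 2)
  if (min(table(y)) < 3) stop("need at least 3 runs per class")
  if (is.null(colnames(betas)))
    colnames(betas) <- sprintf("roi%02d", seq_len(ncol(betas)))
  ## within-class median imputation + missingness indicators
  x <- betas
  na_cols <- which(colSums(is.na(x)) > 0)
  for (j in na_cols) {
    for (lv in levels(y)) {
      sel <- y == lv & is.na(x[, j])
      if (any(sel)) {
        med <- stats::median(x[y == lv, j], na.rm = TRUE)
        if (!is.finite(med)) med <- stats::median(x[, j], na.rm = TRUE)
        x[sel, j] <- med
      }
    }
  }
  if (length(na_cols) > 0) {
    ind <- 1 * is.na(betas[, na_cols, drop = FALSE])
    colnames(ind) <- paste0(colnames(betas)[na_cols], "_missing")
    x <- cbind(x, ind)
  }

  ## Out-of-bag AUC free of oversampling leakage: a tree contributes to a
  ## sample's vote only if neither the sample nor any synthetic sample
  ## interpolated from it was in that tree's bootstrap.
  fit_once <- function(lab, sd) {
    bal <- smote_balance(x, lab, k = smote_k, seed = sd)
    set.seed(sd)
    rf <- randomForest::randomForest(bal$x, bal$y, ntree = n_trees,
                                     importance = TRUE, keep.inbag = TRUE)
    n_orig <- nrow(x)
    related <- lapply(seq_len(n_orig), function(i) {
      kin <- if (is.null(bal$parents)) integer(0)
             else n_orig + which(bal$parents[, 1] == i | bal$parents[, 2] == i)
      c(i, kin)
    })
    tree_pred <- predict(rf, bal$x[seq_len(n_orig), , drop = FALSE],
                         predict.all = TRUE)$individual
    pos <- levels(bal$y)[2]
    votes <- vapply(seq_len(n_orig), function(i) {
      ok <- colSums(rf$inbag[related[[i]], , drop = FALSE]) == 0
      if (!any(ok)) return(NA_real_)
      mean(tree_pred[i, ok] == pos)
    }, numeric(1))
    keep <- !is.na(votes)
    auc <- as.numeric(pROC::auc(pROC::roc(
      response = factor(lab[keep], levels(bal$y)), predictor = votes[keep],
      levels = levels(bal$y), direction = "<", quiet = TRUE)))
    imp <- randomForest::importance(rf, type = 1)[, 1]
    list(auc = auc, importance = imp, model = rf)
  }
  actual <- fit_once(y, derive_seed(seed, "rf-actual"))
  set.seed(derive_seed(seed, "rf-shuffle"))
  shuffled <- lapply(seq_len(n_shuffle), function(s)
    fit_once(sample(y), derive_seed(seed, paste0("rf-sh", s))))
  sh_auc <- vapply(shuffled, `[[`, numeric(1), "auc")
  sh_imp <- do.call(rbind, lapply(shuffled, `[[`, "importance"))
  imp_tab <- data.frame(
    roi = names(actual$importance),
    importance = unname(actual$importance),
    shuffled_mean = colMeans(sh_imp),
    shuffled_sd = apply(sh_imp, 2, stats::sd),
    stringsAsFactors = FALSE, row.names = NULL)
  imp_tab$threshold <- imp_tab$shuffled_mean +
    importance_sd_mult * imp_tab$shuffled_sd
  imp_tab$significant <- imp_tab$importance > imp_tab$threshold
  list(oob_auc = actual$auc, shuffled_auc = sh_auc, importance = imp_tab,
       model = actual$model)
}
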