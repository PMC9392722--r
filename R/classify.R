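## Stimulation-site decoding from evoked-potential features and waveform
## embeddings, with a gradient-boosted tree-ensemble classifier.

## One-hot encode a categorical column against its full level set.
one_hot <- function(x, levels = sort(unique(x))) {
  m <- matrix(0L, length(x), length(levels),
              dimnames = list(NULL, paste0("roi_", levels)))
  m[cbind(seq_along(x), match(x, levels))] <- 1L
  m
}

## Gradient-boosted decision trees (binary or multiclass).
## Hyperparameters follow the published configuration: tree depth 14,
## 200 boosting iterations, log-loss, learning rate 0.03.
gbt_fit <- function(x, y, depth = 14, nrounds = 200, eta = 0.03,
                    nthread = 1) {
  y <- as.factor(y)
  k <- nlevels(y)
  params <- if (k == 2) {
    list(max_depth = depth, eta = eta, objective = "binary:logistic",
         nthread = nthread)
  } else {
    list(max_depth = depth, eta = eta, objective = "multi:softprob",
         num_class = k, nthread = nthread)
  }
  dm <- xgboost::xgb.DMatrix(as.matrix(x),
                             label = as.integer(y) - 1L, nthread = nthread)
  fit <- xgboost::xgb.train(params = params, data = dm, nrounds = nrounds,
                            verbose = 0)
  list(fit = fit, levels = levels(y), k = k)
}

gbt_predict <- function(model, x) {
  p <- predict(model$fit,
               xgboost::xgb.DMatrix(as.matrix(x), nthread = 1))
  if (model$k == 2) {
    model$levels[1L + (p > 0.5)]
  } else {
    pm <- if (is.matrix(p)) p else matrix(p, ncol = model$k, byrow = TRUE)
    model$levels[max.col(pm)]
  }
}

## Stratified k-fold assignment; with `groups`, whole groups (runs) are
## assigned to folds, stratified by the group's label, so channels of one
## run never straddle a train/test split.
make_folds <- function(labels, k = 10, groups = NULL, seed = 1) {
  set.seed(seed)
  n <- length(labels)
  fold <- integer(n)
  if (is.null(groups)) {
    for (lv in unique(labels)) {
      idx <- sample(which(labels == lv))
      fold[idx] <- rep_len(sample(k), length(idx))
    }
  } else {
    gs <- unique(groups)
    glab <- labels[match(gs, groups)]
    gfold <- integer(length(gs))
    for (lv in unique(glab)) {
      gi <- sample(which(glab == lv))
      gfold[gi] <- rep_len(sample(k), length(gi))
    }
    fold <- gfold[match(groups, gs)]
  }
  ## degenerate single-class folds: re-split without grouping
  for (f in unique(fold)) {
    tr_lab <- labels[fold != f]
    if (length(unique(tr_lab)) < 2)
      return(make_folds(labels, k, groups = NULL, seed = seed + 1))
  }
  fold
}

cv_accuracy <- function(x, labels, folds, depth = 14, nrounds = 200,
                        eta = 0.03) {
  accs <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f; te <- !tr
    model <- gbt_fit(x[tr, , drop = FALSE], labels[tr], depth, nrounds, eta)
    mean(gbt_predict(model, x[te, , drop = FALSE]) == labels[te])
  }, numeric(1))
  c(mean = mean(accs), se = stats::sd(accs) / sqrt(length(accs)))
}

#' Pivot evoked-potential features into a classification table
#'
#' One row per channel per run, with early/late range, latency and trend as
#' columns plus the categorical ROI and the stimulation-site label. Channels
#' from the seizure onset zone or white matter never reach this table (they
#' are excluded upstream); rows with missing values are dropped.
#'
#' @param features an `esconn_ep_features` table (possibly row-bound over
#'   runs), with significance columns if filtering is wanted.
#' @param significant_only keep only channels whose both windows are
#'   significant.
#' @return Data.frame with columns `range_early`, `range_late`, `lat_early`,
#'   `lat_late`, `trend_early`, `trend_late`, `roi`, `stim_group`, `run_id`.
#' @export
ep_feature_table <- function(features, significant_only = FALSE) {
  if (significant_only && "is_significant" %in% names(features))
    features <- features[features$is_significant %in% TRUE, ]
  e <- features[features$window == "early", ]
  l <- features[features$window == "late", ]
  key_e <- paste(e$run_id, e$name)
  key_l <- paste(l$run_id, l$name)
  l <- l[match(key_e, key_l), ]
  out <- data.frame(range_early = e$range_value, range_late = l$range_value,
                    lat_early = e$peak_latency_ms,
                    lat_late = l$peak_latency_ms,
                    trend_early = e$trend_value, trend_late = l$trend_value,
                    roi = e$roi, stim_group = e$stim_group,
                    run_id = e$run_id, stringsAsFactors = FALSE)
  out[stats::complete.cases(out), ]
}

#' Sequential-feature stimulation-site decoding
#'
#' Adds features to a gradient-boosted tree classifier in a declared order
#' and reports k-fold cross-validated accuracy (mean and SE over folds) per
#' feature count, together with the identical protocol run on label-shuffled
#' copies of the data (the empirical chance level).
#'
#' @param table a feature table from [ep_feature_table()].
#' @param feature_order order in which features enter; the default starts
#'   with the five features reported to carry most information (ranges,
#'   latencies, ROI) followed by the trends.
#' @param folds number of CV folds.
#' @param seed integer seed.
#' @param grouping `"run"` (default) assigns whole runs to folds so channels
#'   of one stimulation run never leak across the split; `"none"` stratifies
#'   channels directly.
#' @param n_shuffle label-shuffled replicates per feature count.
#' @param depth,nrounds,eta classifier hyperparameters.
#' @return List with `curve` and `shuffled` data.frames
#'   (`n_features`, `feature_added`, `accuracy`, `se`).
#' @export
sequential_feature_classification <- function(
    table, feature_order = c("range_early", "range_late", "lat_early",
                             "lat_late", "roi", "trend_early", "trend_late"),
    folds = 10, seed = 1, grouping = c("run", "none"), n_shuffle = 1,
    depth = 14, nrounds = 200, eta = 0.03) {
  grouping <- match.arg(grouping)
  labels <- table$stim_group
  if (length(unique(labels)) != 2) stop("stim_group must have 2 levels")
  groups <- if (grouping == "run") table$run_id else NULL
  fold <- make_folds(labels, folds, groups, seed)
  roi_levels <- sort(unique(table$roi))
  build_x <- function(feats) {
    cols <- list()
    for (f in feats) {
      if (f == "roi") cols[[f]] <- one_hot(table$roi, roi_levels)
      else cols[[f]] <- matrix(table[[f]], dimnames = list(NULL, f))
    }
    do.call(cbind, cols)
  }
  curve <- NULL; shuffled <- NULL
  set.seed(derive_seed(seed, "shuffle"))
  shuffle_labs <- replicate(n_shuffle, sample(labels), simplify = FALSE)
  for (i in seq_along(feature_order)) {
    x <- build_x(feature_order[seq_len(i)])
    acc <- cv_accuracy(x, labels, fold, depth, nrounds, eta)
    curve <- rbind(curve, data.frame(
      n_features = i, feature_added = feature_order[i],
      accuracy = acc["mean"], se = acc["se"]))
    sh <- vapply(shuffle_labs, function(sl)
      cv_accuracy(x, sl, make_folds(sl, folds, groups, seed), depth,
                  nrounds, eta)["mean"], numeric(1))
    shuffled <- rbind(shuffled, data.frame(
      n_features = i, feature_added = feature_order[i],
      accuracy = mean(sh), se = stats::sd(sh) / sqrt(length(sh))))
  }
  rownames(curve) <- rownames(shuffled) <- NULL
  list(curve = curve, shuffled = shuffled)
}

#' Stimulation-site decoding from waveform embeddings
#'
#' Cross-validated classification of the stimulation site from embedding
#' coordinates, per requested dimensionality, optionally adding the
#' categorical ROI as an input feature.
#'
#' @param x waveform matrix (rows = channels) or a precomputed
#'   `esconn_embedding` (then `dims` must equal its width).
#' @param labels binary stimulation-site labels.
#' @param dims embedding dimensionalities to evaluate.
#' @param roi optional ROI labels; when given, accuracy is also computed
#'   with ROI one-hot columns appended.
#' @param folds,seed,run_id,grouping CV protocol, as in
#'   [sequential_feature_classification()].
#' @param n_shuffle label-shuffled replicates.
#' @param ... passed to [embed_waveforms()].
#' @return Data.frame: `dim`, `with_roi`, `accuracy`, `se`,
#'   `shuffled_accuracy`.
#' @export
embedding_classification <- function(x, labels, dims = c(2, 5, 10),
                                     roi = NULL, folds = 10, seed = 1,
                                     run_id = NULL,
                                     grouping = c("run", "none"),
                                     n_shuffle = 1, ...) {
  grouping <- match.arg(grouping)
  groups <- if (grouping == "run" && !is.null(run_id)) run_id else NULL
  out <- NULL
  set.seed(derive_seed(seed, "emb-shuffle"))
  shuffle_labs <- replicate(n_shuffle, sample(labels), simplify = FALSE)
  for (d in dims) {
    emb <- if (inherits(x, "esconn_embedding")) x
           else embed_waveforms(x, d = d, seed = derive_seed(seed, paste0("emb", d)), ...)
    coords <- emb$coordinates[, seq_len(min(d, ncol(emb$coordinates))),
                              drop = FALSE]
    variants <- list(list(with_roi = FALSE, x = coords))
    if (!is.null(roi))
      variants <- c(variants, list(list(with_roi = TRUE,
                                        x = cbind(coords, one_hot(roi)))))
    for (v in variants) {
      fold <- make_folds(labels, folds, groups, seed)
      acc <- cv_accuracy(v$x, labels, fold)
      sh <- vapply(shuffle_labs, function(sl)
        cv_accuracy(v$x, sl, make_folds(sl, folds, groups, seed))["mean"],
        numeric(1))
      out <- rbind(out, data.frame(dim = d, with_roi = v$with_roi,
                                   accuracy = acc["mean"], se = acc["se"],
                                   shuffled_accuracy = mean(sh)))
    }
  }
  rownames(out) <- NULL
  out
}

#' Latency-group decision map in a 2-D embedding
#'
#' Fits the tree-ensemble classifier to 2-D embedded points labelled by
#' latency group (e.g. frontal = OF + lPFC + CC, parietal + sensorimotor,
#' temporal), evaluates the decision boundary on a `grid_n` x `grid_n` grid
#' spanning the embedding bounding box with a margin, and reports per-group
#' accuracy as the fraction of that group's points classified correctly.
#'
#' @param coords 2-column matrix of embedded points.
#' @param groups group label per point (>= 3 non-empty groups typical).
#' @param grid_n grid resolution per axis (default 400).
#' @param margin bounding-box margin as a fraction of the range.
#' @param seed integer seed.
#' @param depth,nrounds,eta classifier hyperparameters.
#' @return List with `grid` (data.frame x, y, predicted), `grid_matrix`
#'   (`grid_n` x `grid_n` factor matrix), `per_group_accuracy`, `model`.
#' @export
latency_group_map <- function(coords, groups, grid_n = 400, margin = 0.05,
                              seed = 1, depth = 14, nrounds = 200,
                              eta = 0.03) {
  coords <- as.matrix(coords)
  stopifnot(ncol(coords) == 2)
  groups <- as.character(groups)
  tab <- table(groups)
  if (any(tab == 0) || length(tab) < 2) stop("all groups must be non-empty")
  set.seed(seed)
  model <- gbt_fit(coords, groups, depth, nrounds, eta)
  rx <- range(coords[, 1]); ry <- range(coords[, 2])
  mx <- diff(rx) * margin; my <- diff(ry) * margin
  gx <- seq(rx[1] - mx, rx[2] + mx, length.out = grid_n)
  gy <- seq(ry[1] - my, ry[2] + my, length.out = grid_n)
  grid <- as.matrix(expand.grid(x = gx, y = gy))
  pred <- gbt_predict(model, grid)
  fitted <- gbt_predict(model, coords)
  acc <- vapply(names(tab), function(g)
    mean(fitted[groups == g] == g), numeric(1))
  list(grid = data.frame(x = grid[, 1], y = grid[, 2], predicted = pred),
       grid_matrix = matrix(pred, grid_n, grid_n),
       per_group_accuracy = acc, model = model)
}
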