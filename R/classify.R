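# validation metrics for a binary confusion -----------------------------------

confusion_metrics <- function(truth, pred, positive) {
  tp <- sum(truth == positive & pred == positive)
  tn <- sum(truth != positive & pred != positive)
  fp <- sum(truth != positive & pred == positive)
  fn <- sum(truth == positive & pred != positive)
  n <- tp + tn + fp + fn
  acc <- (tp + tn) / n
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) NA_real_ else
    2 * prec * rec / (prec + rec)
  pe <- ((tp + fp) * (tp + fn) + (tn + fn) * (tn + fp)) / n^2
  kappa <- if (pe < 1) (acc - pe) / (1 - pe) else 0
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (denom > 0) (tp * tn - fp * fn) / denom else 0
  c(accuracy = acc, precision = prec, recall = rec, f1 = f1,
    kappa = kappa, mcc = mcc)
}

#' Balance classes and split into training and validation sets
#'
#' The majority class is downsampled without replacement to the minority
#' count (seeded), then a stratified split at the given ratio is drawn.
#'
#' @param x feature matrix or data frame (rows = clips or steps).
#' @param labels two-class factor (or coercible).
#' @param ratio training fraction: 0.7 for the clip model, 0.6 for gait.
#' @param seed integer seed.
#' @return list with `train_x`, `train_y`, `valid_x`, `valid_y`,
#'   `balance_counts`, and the row indices used (`train_idx`, `valid_idx`,
#'   relative to `x`).
#' @export
balance_and_split <- function(x, labels, ratio = 0.7, seed = 1L) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L) stop("exactly two classes are required")
  set.seed(as.integer(seed))
  by_class <- split(seq_along(labels), labels)
  n_min <- min(lengths(by_class))
  kept <- lapply(by_class, function(idx) {
    if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
  })
  train_idx <- valid_idx <- integer(0)
  for (idx in kept) {
    n_tr <- round(ratio * length(idx))
    tr <- sort(sample(idx, n_tr))
    train_idx <- c(train_idx, tr)
    valid_idx <- c(valid_idx, setdiff(idx, tr))
  }
  train_idx <- sort(train_idx); valid_idx <- sort(valid_idx)
  list(train_x = x[train_idx, , drop = FALSE], train_y = labels[train_idx],
       valid_x = x[valid_idx, , drop = FALSE], valid_y = labels[valid_idx],
       balance_counts = lengths(kept),
       train_idx = train_idx, valid_idx = valid_idx)
}

as_feature_matrix <- function(x, feature_cols = NULL) {
  if (is.data.frame(x)) {
    if (is.null(feature_cols)) {
      feature_cols <- attr(x, "feature_cols")
      if (is.null(feature_cols)) {
        feature_cols <- setdiff(names(x)[vapply(x, is.numeric, TRUE)],
                                kin_metadata_cols())
      }
    }
    x <- as.matrix(x[, feature_cols, drop = FALSE])
  }
  storage.mode(x) <- "double"
  x
}

xgb_fit <- function(x, y01, nrounds, seed, max_depth = 6, eta = 0.3) {
  dtrain <- xgboost::xgb.DMatrix(data = x, label = y01)
  set.seed(as.integer(seed))
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1, seed = as.integer(seed)),
    data = dtrain, nrounds = nrounds, verbose = 0)
}

#' Select the most impactful features
#'
#' Drops near-zero-variance features, removes high-collinearity duplicates
#' (|r| > `cor_cutoff`, keeping the first of each pair), ranks the
#' remaining features by mean absolute additive attribution from a
#' preliminary gradient-boosted ensemble, and returns the top `k` names.
#'
#' @param x feature matrix or table.
#' @param labels two-class factor.
#' @param k number of features to keep (30 for clips, 20 for gait).
#' @param seed integer seed.
#' @param cor_cutoff collinearity threshold (default 0.95).
#' @return character vector of `k` feature names, ranked.
#' @export
select_features <- function(x, labels, k = 30L, seed = 1L,
                            cor_cutoff = 0.95) {
  x <- as_feature_matrix(x)
  labels <- droplevels(as.factor(labels))
  ok <- colSums(is.na(x)) < nrow(x) &
    apply(x, 2L, function(v) isTRUE(stats::var(v, na.rm = TRUE) > 1e-12))
  x <- x[, ok, drop = FALSE]
  cm <- abs(suppressWarnings(stats::cor(x, use = "pairwise.complete.obs")))
  cm[is.na(cm)] <- 0
  keep <- logical(ncol(x))
  for (j in seq_len(ncol(x))) {
    keep[j] <- !any(cm[j, which(keep)] > cor_cutoff)
  }
  x <- x[, keep, drop = FALSE]
  if (ncol(x) < k) stop("fewer than k eligible features after filtering")
  y01 <- as.integer(labels == levels(labels)[2])
  bst <- xgb_fit(x, y01, nrounds = 50, seed = seed)
  contrib <- stats::predict(bst, xgboost::xgb.DMatrix(x), predcontrib = TRUE)
  imp <- colMeans(abs(contrib[, colnames(x), drop = FALSE]))
  names(sort(imp, decreasing = TRUE))[seq_len(k)]
}

#' Fit the clip-level PD classifier
#'
#' Balances the two classes, splits 7:3 into training and validation,
#' selects the 30 most impactful features and fits a gradient-boosted
#' decision-tree ensemble. The returned model scores clips as non-PD or PD
#' and underlies the AI-predicted PD score (APS).
#'
#' @param features clip feature table (from [assemble_feature_table()] /
#'   [featurize_sessions()]) or matrix.
#' @param labels two-class factor; the second level is the PD (positive)
#'   class.
#' @param k number of selected features (default 30).
#' @param ratio training fraction (default 0.7).
#' @param seed integer seed.
#' @param nrounds boosting rounds (default 100).
#' @param max_depth,eta tree depth and learning rate.
#' @return object of class `pd_model`: the fitted ensemble, selected
#'   feature names, class levels, split/seed metadata and validation
#'   metrics (accuracy, precision, recall, F1, kappa, MCC).
#' @export
fit_clip_classifier <- function(features, labels, k = 30L, ratio = 0.7,
                                seed = 1L, nrounds = 100L, max_depth = 6,
                                eta = 0.3) {
  x <- as_feature_matrix(features)
  labels <- droplevels(as.factor(labels))
  sp <- balance_and_split(x, labels, ratio = ratio, seed = seed)
  sel <- select_features(sp$train_x, sp$train_y, k = k, seed = seed)
  y01 <- as.integer(sp$train_y == levels(labels)[2])
  bst <- xgb_fit(sp$train_x[, sel, drop = FALSE], y01, nrounds = nrounds,
                 seed = seed, max_depth = max_depth, eta = eta)
  prob <- stats::predict(bst,
                         xgboost::xgb.DMatrix(sp$valid_x[, sel, drop = FALSE]))
  pred <- levels(labels)[1 + (prob > 0.5)]
  metrics <- confusion_metrics(as.character(sp$valid_y), pred,
                               positive = levels(labels)[2])
  structure(list(engine = "xgboost", task = "clip", model = bst,
                 features = sel, classes = levels(labels),
                 seed = as.integer(seed), ratio = ratio,
                 balance_counts = sp$balance_counts, metrics = metrics,
                 n_train = length(sp$train_y), n_valid = length(sp$valid_y)),
            class = "pd_model")
}

#' Fit the per-stride gait classifier
#'
#' Selects the 20 most impactful gait features and fits a randomised-tree
#' (extremely randomised trees) ensemble on a balanced 6:4 split of
#' per-stride feature records. Underlies the PD gait score.
#'
#' @param features per-stride 28-feature records (from
#'   [gait_feature_table()]) or matrix.
#' @param labels two-class factor; second level = PD.
#' @param k selected features (default 20).
#' @param ratio training fraction (default 0.6).
#' @param seed integer seed.
#' @param num_trees ensemble size (default 500).
#' @return a `pd_model` (engine `"ranger"`, task `"gait"`).
#' @export
fit_gait_classifier <- function(features, labels, k = 20L, ratio = 0.6,
                                seed = 1L, num_trees = 500L) {
  x <- as_feature_matrix(features)
  labels <- droplevels(as.factor(labels))
  sp <- balance_and_split(x, labels, ratio = ratio, seed = seed)
  sel <- select_features(sp$train_x, sp$train_y, k = k, seed = seed)
  # randomised-tree forests cannot accept missing values: impute training
  # column medians (stored on the model for prediction time)
  medians <- apply(sp$train_x[, sel, drop = FALSE], 2L, stats::median,
                   na.rm = TRUE)
  impute <- function(m) {
    for (j in seq_along(sel)) {
      bad <- is.na(m[, j])
      if (any(bad)) m[bad, j] <- medians[j]
    }
    m
  }
  df <- as.data.frame(impute(sp$train_x[, sel, drop = FALSE]))
  df$.class <- sp$train_y
  rf <- ranger::ranger(
    dependent.variable.name = ".class", data = df, probability = TRUE,
    num.trees = num_trees, splitrule = "extratrees", num.random.splits = 1,
    replace = FALSE, sample.fraction = 1, seed = as.integer(seed),
    num.threads = 1)
  prob <- stats::predict(
    rf, data = as.data.frame(impute(sp$valid_x[, sel, drop = FALSE])))$predictions
  pred <- colnames(prob)[max.col(prob, ties.method = "first")]
  metrics <- confusion_metrics(as.character(sp$valid_y), pred,
                               positive = levels(labels)[2])
  structure(list(engine = "ranger", task = "gait", model = rf,
                 features = sel, classes = levels(labels), medians = medians,
                 seed = as.integer(seed), ratio = ratio,
                 balance_counts = sp$balance_counts, metrics = metrics,
                 n_train = length(sp$train_y), n_valid = length(sp$valid_y)),
            class = "pd_model")
}

#' @export
print.pd_model <- function(x, ...) {
  cat(sprintf("<pd_model> %s classifier (%s), %d selected features\n",
              x$task, x$engine, length(x$features)))
  cat(sprintf("  classes: %s (positive: %s)\n",
              paste(x$classes, collapse = " vs "), x$classes[2]))
  cat(sprintf("  train/validation: %d/%d (ratio %.1f), seed %d\n",
              x$n_train, x$n_valid, x$ratio, x$seed))
  cat("  validation metrics:\n")
  print(round(x$metrics, 3))
  invisible(x)
}

#' @export
summary.pd_model <- function(object, ...) {
  print(object)
  cat("  selected features:\n")
  cat(paste0("    ", object$features, collapse = "\n"), "\n")
  invisible(object)
}

#' Predict method for PD classifiers
#'
#' @param object a `pd_model`.
#' @param newdata feature table or matrix containing the model's features.
#' @param type `"class"` (default), `"prob"` (probability of the positive
#'   class) or `"margin"` (log-odds; xgboost engine only).
#' @param ... unused.
#' @return vector of predictions.
#' @export
predict.pd_model <- function(object, newdata,
                             type = c("class", "prob", "margin"), ...) {
  type <- match.arg(type)
  x <- as_feature_matrix(newdata, feature_cols = object$features)
  x <- x[, object$features, drop = FALSE]
  if (object$engine == "xgboost") {
    dm <- xgboost::xgb.DMatrix(x)
    if (type == "margin") {
      return(stats::predict(object$model, dm, outputmargin = TRUE))
    }
    prob <- stats::predict(object$model, dm)
  } else {
    if (type == "margin") stop("margin predictions require the xgboost engine")
    if (!is.null(object$medians)) {
      for (j in seq_len(ncol(x))) {
        bad <- is.na(x[, j])
        if (any(bad)) x[bad, j] <- object$medians[colnames(x)[j]]
      }
    }
    pr <- stats::predict(object$model, data = as.data.frame(x))$predictions
    prob <- pr[, object$classes[2]]
  }
  if (type == "prob") return(prob)
  object$classes[1 + (prob > 0.5)]
}

#' AI-predicted PD score (APS) for one mouse
#'
#' The percentage of a mouse's motion clips classified as PD, with the
#' health-status bins: APS in [0, 25) non-PD, [25, 75) mild PD, and 75 and
#' above severe PD.
#'
#' @param object a clip `pd_model`.
#' @param clips feature rows of one mouse's clips.
#' @return object of class `aps_result`: list with `aps` (percent), `status`
#'   (`"NP"`, `"mild"`, `"severe"`), `n_clips`.
#' @export
score_aps <- function(object, clips) {
  if (!nrow(as_feature_matrix(clips, object$features))) {
    stop("at least one clip is required")
  }
  pred <- predict(object, clips)
  aps <- 100 * mean(pred == object$classes[2])
  status <- if (aps < 25) "NP" else if (aps < 75) "mild" else "severe"
  structure(list(aps = aps, status = status,
                 n_clips = length(pred)), class = "aps_result")
}

#' @export
print.aps_result <- function(x, ...) {
  cat(sprintf("APS %.1f%% (%s) from %d clips\n", x$aps, x$status, x$n_clips))
  invisible(x)
}

#' PD gait score for one mouse
#'
#' The percentage of a mouse's steps classified as PD-characteristic.
#'
#' @param object a gait `pd_model`.
#' @param steps per-stride feature rows of one mouse.
#' @return percentage between 0 and 100.
#' @export
score_gait <- function(object, steps) {
  pred <- predict(object, steps)
  100 * mean(pred == object$classes[2])
}

#' Additive feature attributions (SHAP)
#'
#' Exact per-tree additive attributions in log-odds for each clip: the base
#' value plus the per-feature attributions reproduces the model margin. A
#' global ranking by mean absolute attribution is included.
#'
#' @param object a `pd_model` with the xgboost engine.
#' @param newdata feature rows to explain.
#' @return object of class `attribution_table`: list with `contrib`
#'   (clips x features, log-odds), `base` (per-clip base value), `margin`
#'   (model output), `ranking` (features by mean |attribution|).
#' @export
attribute <- function(object, newdata) {
  if (!inherits(object, "pd_model") || object$engine != "xgboost") {
    stop("additive attribution requires a tree-ensemble (xgboost) pd_model")
  }
  x <- as_feature_matrix(newdata, feature_cols = object$features)
  x <- x[, object$features, drop = FALSE]
  dm <- xgboost::xgb.DMatrix(x)
  contrib <- stats::predict(object$model, dm, predcontrib = TRUE)
  bias_col <- setdiff(colnames(contrib), object$features)
  base <- contrib[, bias_col[1]]
  contrib <- contrib[, object$features, drop = FALSE]
  margin <- stats::predict(object$model, dm, outputmargin = TRUE)
  rk <- sort(colMeans(abs(contrib)), decreasing = TRUE)
  structure(list(contrib = contrib, base = base, margin = margin,
                 ranking = rk), class = "attribution_table")
}

#' @export
print.attribution_table <- function(x, n = 10L, ...) {
  cat(sprintf("<attribution_table> %d clips x %d features (log-odds)\n",
              nrow(x$contrib), ncol(x$contrib)))
  cat("  top features by mean |attribution|:\n")
  print(round(utils::head(x$ranking, n), 4))
  invisible(x)
}
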