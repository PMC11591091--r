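#' Stacked-classifier configuration
#'
#' Hyperparameters of the three-class stacking pipeline. Base learners:
#' gradient-boosted trees (xgboost), an RBF support-vector classifier with
#' pairwise-coupling probability calibration (e1071), and extremely
#' randomized trees (ranger with `splitrule = "extratrees"`, no bootstrap).
#' Meta learner: k-nearest neighbours on the bases' out-of-fold class
#' probabilities.
#'
#' @param bases character subset of `c("xgb", "svc", "et")`; empty means the
#'   meta learner runs directly on the input features.
#' @param xgb,svc,et per-learner hyperparameter lists.
#' @param knn_k meta-learner neighbour count (default 5).
#' @param inner_K internal folds for out-of-fold meta features (default 5).
#' @param smote apply SMOTE oversampling to each training set (default TRUE).
#' @param smote_k SMOTE neighbour count (default 5).
#' @return list of class `stack_config`.
#' @export
stack_config <- function(bases = c("xgb", "svc", "et"),
                         xgb = list(nrounds = 80, max_depth = 3, eta = 0.3),
                         svc = list(cost = 1),
                         et = list(num.trees = 200),
                         knn_k = 5, inner_K = 5, smote = TRUE, smote_k = 5) {
  stopifnot(all(bases %in% c("xgb", "svc", "et")))
  structure(list(bases = bases, xgb = xgb, svc = svc, et = et, knn_k = knn_k,
                 inner_K = inner_K, smote = smote, smote_k = smote_k),
            class = "stack_config")
}

fit_base <- function(name, X, y, config, seed) {
  set.seed(dk_child_seed(seed, name))
  nc <- nlevels(y)
  if (name == "xgb") {
    d <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L)
    params <- c(list(objective = "multi:softprob", num_class = nc,
                     nthread = 1, seed = dk_child_seed(seed, "xgbp")),
                config$xgb[setdiff(names(config$xgb), "nrounds")])
    m <- xgboost::xgb.train(params = params, data = d,
                            nrounds = config$xgb$nrounds %||% 80, verbose = 0)
    return(list(kind = "xgb", model = m, levels = levels(y)))
  }
  if (name == "svc") {
    m <- e1071::svm(x = X, y = y, probability = TRUE, kernel = "radial",
                    cost = config$svc$cost %||% 1)
    return(list(kind = "svc", model = m, levels = levels(y)))
  }
  if (name == "et") {
    m <- ranger::ranger(x = X, y = y, probability = TRUE,
                        splitrule = "extratrees", replace = FALSE,
                        sample.fraction = 1,
                        num.trees = config$et$num.trees %||% 200,
                        num.threads = 1,
                        seed = dk_child_seed(seed, "etseed"))
    return(list(kind = "et", model = m, levels = levels(y)))
  }
  dk_stop("dk_input_error", "unknown base learner: %s", name)
}

predict_base <- function(base, X) {
  lv <- base$levels
  if (base$kind == "xgb") {
    p <- predict(base$model, xgboost::xgb.DMatrix(X))
    colnames(p) <- lv
    return(p)
  }
  if (base$kind == "svc") {
    pr <- predict(base$model, X, probability = TRUE)
    p <- attr(pr, "probabilities")
    return(p[, lv, drop = FALSE])
  }
  p <- predict(base$model, data = X, num.threads = 1)$predictions
  p[, lv, drop = FALSE]
}

#' Fit the stacked three-class model
#'
#' Protocol: (1) impute (training medians) and standardize features; (2) for
#' each internal stratified fold, oversample the in-fold training part with
#' SMOTE (validation rows are never oversampling inputs), fit the base
#' learners, and predict class probabilities on the held-out part — the
#' out-of-fold probabilities (3 bases x 3 classes) become the meta features;
#' (3) refit the bases on the full (oversampled) training data; (4) fit the
#' k-nearest-neighbour meta learner on the out-of-fold meta features.
#' Deterministic given data and seed.
#'
#' @param X samples x features numeric matrix.
#' @param y class labels (coerced to factor); at least two classes, each with
#'   at least 2 members per internal training fold after oversampling.
#' @param config a [stack_config()].
#' @param seed integer seed.
#' @return object of class `stacked_model`.
#' @export
fit_stacked <- function(X, y, config = stack_config(), seed = 1) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  y <- droplevels(factor(y))
  if (nlevels(y) < 2)
    dk_stop("dk_input_error", "training data contains a single class")
  if (any(table(y) < 2))
    dk_stop("dk_fold_error", "every class needs at least 2 training samples")
  imp <- fit_imputer(X)
  Xi <- apply_imputer(imp, X)
  ctr <- colMeans(Xi)
  scl <- apply(Xi, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  Xs <- scale(Xi, center = ctr, scale = scl)

  smote_sources <- integer(0)
  train_set <- function(idx, stream) {
    if (config$smote) {
      sm <- smote_oversample(Xs[idx, , drop = FALSE], y[idx],
                             k_neighbors = config$smote_k,
                             seed = dk_child_seed(seed, stream))
      smote_sources <<- union(smote_sources, idx[sm$source_idx])
      list(X = sm$X, y = sm$y)
    } else list(X = Xs[idx, , drop = FALSE], y = y[idx])
  }

  if (length(config$bases) > 0) {
    inner_K <- min(config$inner_K, min(table(y)))
    if (inner_K < 2)
      dk_stop("dk_fold_error", "degenerate fold: a class has fewer than 2 members")
    plan <- stratified_folds(y, inner_K, dk_child_seed(seed, "inner"))
    Z <- matrix(NA_real_, nrow(Xs), 0)
    probs_oof <- lapply(config$bases, function(b)
      matrix(NA_real_, nrow(Xs), nlevels(y)))
    names(probs_oof) <- config$bases
    for (k in seq_len(inner_K)) {
      hold <- plan$folds[[k]]
      tr <- setdiff(seq_len(nrow(Xs)), hold)
      ts <- train_set(tr, paste0("in", k))
      for (b in config$bases) {
        fit <- fit_base(b, ts$X, ts$y, config, dk_child_seed(seed, paste0(b, k)))
        probs_oof[[b]][hold, ] <- predict_base(fit, Xs[hold, , drop = FALSE])
      }
    }
    Z <- do.call(cbind, probs_oof)
    colnames(Z) <- unlist(lapply(config$bases, function(b)
      paste0(b, ".", levels(y))))
    full <- train_set(seq_len(nrow(Xs)), "full")
    bases <- lapply(config$bases, function(b)
      fit_base(b, full$X, full$y, config, dk_child_seed(seed, paste0(b, "F"))))
    names(bases) <- config$bases
    meta <- caret::knn3(Z, y, k = min(config$knn_k, nrow(Z) - 1))
  } else {
    full <- train_set(seq_len(nrow(Xs)), "full")
    bases <- list()
    Z <- NULL
    meta <- caret::knn3(full$X, full$y, k = min(config$knn_k, nrow(full$X) - 1))
  }
  structure(list(bases = bases, meta = meta, config = config, seed = seed,
                 levels = levels(y), imputer = imp, center = ctr, scale = scl,
                 oof_features = Z, smote_sources = sort(smote_sources),
                 n_train = nrow(X)),
            class = "stacked_model")
}

#' Predict from a stacked model
#'
#' @param object a fitted `stacked_model`.
#' @param newdata samples x features matrix on the original feature scale.
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @return factor of classes or a samples x classes probability matrix.
#' @export
predict.stacked_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$center))
    dk_stop("dk_input_error", "feature count mismatch: model expects %d, got %d",
            length(object$center), ncol(X))
  colnames(X) <- names(object$center)
  Xs <- scale(apply_imputer(object$imputer, X),
              center = object$center, scale = object$scale)
  if (length(object$bases) > 0) {
    Z <- do.call(cbind, lapply(object$bases, function(b) predict_base(b, Xs)))
    prob <- predict(object$meta, Z, type = "prob")
  } else {
    prob <- predict(object$meta, Xs, type = "prob")
  }
  colnames(prob) <- object$levels
  if (type == "prob") return(prob)
  factor(object$levels[max.col(prob, ties.method = "first")],
         levels = object$levels)
}

#' @export
print.stacked_model <- function(x, ...) {
  cat(sprintf("<stacked_model> bases: %s; meta: %d-NN; classes: %s; n = %d\n",
              if (length(x$bases)) paste(names(x$bases), collapse = "+") else "(none)",
              x$config$knn_k, paste(x$levels, collapse = "/"), x$n_train))
  invisible(x)
}

#' Cross-validated evaluation of the stacking pipeline
#'
#' Outer stratified K-fold cross-validation: each fold's model is trained
#' from scratch on the remaining folds (SMOTE and the out-of-fold stacking
#' protocol run inside the training set only) and evaluated on the held-out
#' fold. Reports per-fold accuracy and macro metrics with mean and sd, the
#' pooled confusion matrix over all held-out predictions, the pooled
#' macro-averaged one-vs-rest ROC, and a SMOTE leakage audit asserting that
#' no held-out index ever entered oversampling.
#'
#' @param X samples x features matrix.
#' @param y class labels.
#' @param plan optional [stratified_folds()] plan (default: K = 5 folds from
#'   `seed`).
#' @param config a [stack_config()].
#' @param seed integer seed.
#' @return object of class `stack_eval`: `per_fold` (data frame), `mean`,
#'   `sd`, `confusion` (pooled), `metrics` (pooled), `roc`, `auc`,
#'   `oof_prob`, `leakage_ok`.
#' @export
evaluate_stacked <- function(X, y, plan = NULL, config = stack_config(),
                             seed = 1) {
  X <- as.matrix(X)
  y <- factor(y)
  if (is.null(plan)) plan <- stratified_folds(y, 5, seed)
  prob_oof <- matrix(NA_real_, nrow(X), nlevels(y),
                     dimnames = list(NULL, levels(y)))
  pred_oof <- rep(NA_character_, nrow(X))
  per_fold <- data.frame()
  leakage_ok <- TRUE
  for (k in seq_len(plan$K)) {
    hold <- plan$folds[[k]]
    tr <- setdiff(seq_len(nrow(X)), hold)
    model <- fit_stacked(X[tr, , drop = FALSE], y[tr], config,
                         dk_child_seed(seed, paste0("outer", k)))
    leaked <- intersect(tr[model$smote_sources], hold)
    if (length(leaked) > 0) leakage_ok <- FALSE
    prob <- predict(model, X[hold, , drop = FALSE], type = "prob")
    prob_oof[hold, ] <- prob
    pred <- levels(y)[max.col(prob, ties.method = "first")]
    pred_oof[hold] <- pred
    mt <- classification_metrics(confusion_matrix(y[hold], pred,
                                                  levels = levels(y)))
    rc <- macro_roc(prob, y[hold])
    per_fold <- rbind(per_fold, data.frame(
      fold = k, accuracy = mt$accuracy, macro_precision = mt$macro_precision,
      macro_recall = mt$macro_recall, macro_f1 = mt$macro_f1, auc = rc$auc))
  }
  pooled_cm <- confusion_matrix(y, pred_oof, levels = levels(y))
  pooled <- classification_metrics(pooled_cm)
  roc <- macro_roc(prob_oof, y)
  cols <- c("accuracy", "macro_precision", "macro_recall", "macro_f1", "auc")
  structure(list(per_fold = per_fold,
                 mean = colMeans(per_fold[cols]),
                 sd = apply(per_fold[cols], 2, stats::sd),
                 confusion = pooled_cm, metrics = pooled,
                 roc = roc, auc = roc$auc, oof_prob = prob_oof,
                 leakage_ok = leakage_ok, plan = plan, config = config,
                 seed = seed),
            class = "stack_eval")
}

#' @export
print.stack_eval <- function(x, ...) {
  cat(sprintf("<stack_eval> K = %d folds\n", x$plan$K))
  for (m in names(x$mean))
    cat(sprintf("  %-16s %.4f +/- %.4f\n", m, x$mean[m], x$sd[m]))
  cat(sprintf("  pooled macro AUC  %.4f\n", x$auc))
  cat(sprintf("  SMOTE leakage audit: %s\n",
              if (x$leakage_ok) "clean" else "LEAKED"))
  invisible(x)
}

#' @export
summary.stacked_model <- function(object, ...) {
  cat(sprintf("Stacked three-class model (seed %d)\n", object$seed))
  print(object)
  if (!is.null(object$oof_features))
    cat(sprintf("  meta feature dimension: %d (= %d bases x %d classes)\n",
                ncol(object$oof_features), length(object$bases),
                length(object$levels)))
  invisible(object)
}
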