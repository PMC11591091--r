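# shared fixtures and independent oracles

fixture_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) {
      ed <- system.file("extdata", package = "diabkit")
      db <<- load_nutrition_db(file.path(ed, "ingredients.csv"),
                               file.path(ed, "packaged.csv"),
                               file.path(ed, "dishes.csv"),
                               file.path(ed, "units.csv"))
    }
    db
  }
})

# independent dynamic-programming Levenshtein distance (oracle for match_food)
dp_edit_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  m <- length(ca); n <- length(cb)
  d <- matrix(0, m + 1, n + 1)
  d[, 1] <- 0:m; d[1, ] <- 0:n
  for (i in seq_len(m)) for (j in seq_len(n))
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1, d[i + 1, j] + 1,
                           d[i, j] + (ca[i] != cb[j]))
  d[m + 1, n + 1]
}

# brute-force contingency oracle: expand a confusion matrix to label vectors
# and count TP/FP/FN per class by looping over samples
brute_metrics <- function(cm) {
  classes <- rownames(cm)
  y_true <- character(0); y_pred <- character(0)
  for (i in seq_len(nrow(cm))) for (j in seq_len(ncol(cm))) {
    y_true <- c(y_true, rep(classes[i], cm[i, j]))
    y_pred <- c(y_pred, rep(classes[j], cm[i, j]))
  }
  tp <- fp <- fn <- stats::setNames(numeric(length(classes)), classes)
  for (s in seq_along(y_true)) {
    if (y_true[s] == y_pred[s]) tp[y_true[s]] <- tp[y_true[s]] + 1
    else {
      fn[y_true[s]] <- fn[y_true[s]] + 1
      fp[y_pred[s]] <- fp[y_pred[s]] + 1
    }
  }
  prec <- tp / (tp + fp); prec[tp + fp == 0] <- 0
  rec <- tp / (tp + fn)
  mp <- mean(prec); mr <- mean(rec)
  list(accuracy = sum(tp) / length(y_true), macro_precision = mp,
       macro_recall = mr, macro_f1 = 2 * mp * mr / (mp + mr),
       tp = tp, fp = fp, fn = fn)
}

# random 3-class confusion matrix with every true class represented
random_confusion <- function(seed) {
  set.seed(seed)
  cm <- matrix(rpois(9, 6), 3, 3, dimnames = list(0:2, 0:2))
  diag(cm) <- diag(cm) + 1         # ensure nonzero rows
  cm
}

# three well-separated gaussian blobs for classifier sanity checks
make_blobs <- function(n_per = 50, p = 4, sep = 6, seed = 1) {
  set.seed(seed)
  centers <- matrix(0, 3, p)
  centers[2, 1] <- sep; centers[3, 2] <- sep
  X <- do.call(rbind, lapply(1:3, function(cidx)
    matrix(rnorm(n_per * p), n_per, p) + centers[rep(cidx, n_per), ]))
  list(X = X, y = factor(rep(0:2, each = n_per)))
}

fast_config <- function(...) {
  stack_config(xgb = list(nrounds = 30, max_depth = 3, eta = 0.3),
               et = list(num.trees = 80), inner_K = 3, ...)
}
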