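#' Multi-feature food-weight regression
#'
#' Maps identified food type, shooting tilt angle, shooting distance and
#' projected area to food weight with an L1-penalized (LASSO) linear model.
#' Food type enters as an indicator block; an optional `area x type`
#' interaction block allows per-type areal densities. Features are
#' standardized before penalization; the intercept is never penalized.
#'
#' @param data data frame with columns `type_id`, `alpha`, `distance`,
#'   `area`, `weight`; at least 2 samples per type.
#' @param lambda L1 penalty. `0` fits ordinary least squares; `NULL`
#'   (default) selects lambda by internal 5-fold cross-validation.
#' @param seed integer seed (CV fold assignment).
#' @param interactions include the `area x type` interaction block
#'   (default `FALSE`).
#' @return object of class `weight_model`.
#' @export
fit_weight_model <- function(data, lambda = NULL, seed = 1,
                             interactions = FALSE) {
  req <- c("type_id", "alpha", "distance", "area", "weight")
  stopifnot(all(req %in% names(data)))
  tab <- table(data$type_id)
  if (any(tab < 2))
    dk_stop("dk_input_error", "need >= 2 samples per food type (type %s has %d)",
            names(tab)[which.min(tab)], min(tab))
  types <- sort(unique(data$type_id))
  X <- weight_design(data, types, interactions)
  y <- data$weight

  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  keep <- sdev > 1e-12
  if (!all(keep))
    warning(sprintf("dropping constant column(s): %s",
                    paste(colnames(X)[!keep], collapse = ", ")))
  Xs <- scale(X[, keep, drop = FALSE], center = mu[keep], scale = sdev[keep])

  if (!is.null(lambda) && lambda == 0) {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Xs), y)
    b <- fit$coefficients
    b[is.na(b)] <- 0
    beta_std <- b[-1]
    intercept_std <- b[1]
  } else {
    if (is.null(lambda)) {
      set.seed(dk_child_seed(seed, "wcv"))
      foldid <- sample(rep_len(1:5, nrow(Xs)))
      cv <- glmnet::cv.glmnet(Xs, y, alpha = 1, foldid = foldid,
                              standardize = FALSE)
      lambda <- cv$lambda.min
    }
    fit <- glmnet::glmnet(Xs, y, alpha = 1, lambda = lambda,
                          standardize = FALSE, thresh = 1e-9, maxit = 1e6)
    beta_std <- as.numeric(fit$beta)
    names(beta_std) <- rownames(fit$beta)
    intercept_std <- as.numeric(fit$a0)
  }
  # back-transform to the original feature scale
  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  beta[names(beta_std)] <- beta_std / sdev[keep]
  intercept <- intercept_std - sum(beta * mu)
  structure(list(coefficients = c(`(Intercept)` = unname(intercept), beta),
                 lambda = lambda %||% 0, types = types,
                 interactions = interactions, dropped = colnames(X)[!keep],
                 fitted = TRUE),
            class = "weight_model")
}

weight_design <- function(data, types, interactions) {
  n <- nrow(data)
  ind <- matrix(0, n, length(types),
                dimnames = list(NULL, paste0("type", types)))
  ti <- match(data$type_id, types)
  if (anyNA(ti))
    dk_stop("dk_unknown_type", "unseen food type(s): %s",
            paste(unique(data$type_id[is.na(ti)]), collapse = ", "))
  ind[cbind(seq_len(n), ti)] <- 1
  X <- cbind(ind, alpha = data$alpha, distance = data$distance,
             area = data$area)
  if (interactions) {
    inter <- ind * data$area
    colnames(inter) <- paste0("area:type", types)
    X <- cbind(X, inter)
  }
  X
}

#' @export
coef.weight_model <- function(object, ...) object$coefficients

#' @export
print.weight_model <- function(x, ...) {
  nz <- sum(abs(x$coefficients[-1]) > 1e-12)
  cat(sprintf("<weight_model> lambda = %.4g, %d/%d nonzero coefficients, %d food types\n",
              x$lambda, nz, length(x$coefficients) - 1, length(x$types)))
  invisible(x)
}

#' Predict food weight
#'
#' Linear prediction on the fitted coefficients, clamped at zero.
#'
#' @param object a fitted `weight_model`.
#' @param newdata data frame with `type_id`, `alpha`, `distance`, `area`.
#' @param ... unused.
#' @return numeric vector of predicted weights (g), `>= 0`.
#' @export
predict.weight_model <- function(object, newdata, ...) {
  if (!isTRUE(object$fitted)) dk_stop("dk_input_error", "model not fitted")
  X <- weight_design(newdata, object$types, object$interactions)
  b <- object$coefficients
  pred <- as.numeric(b[1] + X %*% b[colnames(X)])
  pmax(pred, 0)
}

#' @rdname predict.weight_model
#' @param model a fitted `weight_model`.
#' @param type_id,alpha,distance,area scalar or vector features.
#' @export
predict_weight <- function(model, type_id, alpha, distance, area) {
  predict(model, data.frame(type_id = type_id, alpha = alpha,
                            distance = distance, area = area))
}

#' Mean absolute error of a weight model
#'
#' @param model a fitted `weight_model`.
#' @param data evaluation data with a `weight` column.
#' @return list with `mae` (g) and `per_type` (named vector of per-type MAE).
#' @export
evaluate_mae <- function(model, data) {
  pred <- predict(model, data)
  err <- abs(pred - data$weight)
  list(mae = mean(err),
       per_type = tapply(err, data$type_id, mean))
}

#' Cross-validated weight-model MAE
#'
#' K-fold cross-validation (folds stratified over food type) of the held-out
#' mean absolute error.
#'
#' @inheritParams fit_weight_model
#' @param K number of folds (default 5).
#' @return list with `mae` (mean over folds), `per_fold`.
#' @export
cv_weight_mae <- function(data, lambda = NULL, K = 5, seed = 1,
                          interactions = FALSE) {
  plan <- stratified_folds(factor(data$type_id), K, seed)
  per_fold <- vapply(plan$folds, function(idx) {
    fit <- fit_weight_model(data[-idx, , drop = FALSE], lambda = lambda,
                            seed = seed, interactions = interactions)
    evaluate_mae(fit, data[idx, , drop = FALSE])$mae
  }, numeric(1))
  list(mae = mean(per_fold), per_fold = per_fold)
}
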