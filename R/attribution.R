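#' Shapley-style feature attribution by permutation sampling
#'
#' Model-agnostic coalition-sampling estimator of per-feature, per-class
#' contributions to the model's predicted class probabilities. For each
#' sampled feature permutation and background row `z`, features are switched
#' one by one from `z` to the explained sample `x`; the prediction change
#' when feature `j` switches is its marginal contribution in that coalition
#' order, and the Shapley value is the average over permutations. Background
#' rows are cycled deterministically, so per-sample additivity
#' (`base + sum(contributions) = prediction`) holds exactly by telescoping,
#' and for additive models the estimate converges to the closed form
#' `beta_j (x_j - mean(background_j))` as `nsim` covers the background.
#'
#' The estimator works identically for any predictor exposing class
#' probabilities, which is what makes it applicable to the heterogeneous
#' stacked ensemble.
#'
#' @param model a fitted [fit_stacked()] model, or a function mapping a
#'   feature matrix to a samples x classes probability (or single-output)
#'   matrix.
#' @param X samples x features matrix of rows to explain.
#' @param background background feature matrix (non-empty); defaults in
#'   [attribute_stacked()] follow the training distribution.
#' @param nsim number of sampled permutations (default `4 *
#'   nrow(background)`, an exact multiple of the background size).
#' @param seed integer seed.
#' @return object of class `attribution_report`: `phi` (samples x features x
#'   classes array), `base` (samples x classes), `fx` (model output at `X`),
#'   `nsim`, `tolerance` (Monte-Carlo standard error summary).
#' @export
shapley_attribution <- function(model, X, background, nsim = NULL, seed = 1) {
  f <- if (is.function(model)) model
       else if (inherits(model, "stacked_model"))
         function(M) predict(model, M, type = "prob")
       else dk_stop("dk_input_error", "model must be a function or a stacked_model")
  X <- as.matrix(X)
  background <- as.matrix(background)
  if (nrow(background) == 0)
    dk_stop("dk_input_error", "background sample must be non-empty")
  if (ncol(background) != ncol(X))
    dk_stop("dk_input_error", "feature count mismatch between X and background")
  if (inherits(model, "stacked_model") && ncol(X) != length(model$center))
    dk_stop("dk_input_error", "feature count mismatch with the model")
  n <- nrow(X); p <- ncol(X); B <- nrow(background)
  if (is.null(nsim)) nsim <- 4L * B
  out0 <- f(X)
  if (is.null(dim(out0))) out0 <- matrix(out0, ncol = 1)
  C <- ncol(out0)
  phi <- array(0, dim = c(n, p, C),
               dimnames = list(rownames(X), colnames(X), colnames(out0)))
  base <- matrix(0, n, C)
  set.seed(dk_child_seed(seed, "shap"))
  draws <- array(0, dim = c(n, p, C))   # running mean squares for tolerance
  perm <- NULL
  for (m in seq_len(nsim)) {
    # antithetic pairs: every second permutation reverses the previous one,
    # which symmetrizes credit between duplicated features and cuts variance
    perm <- if (m %% 2L == 1L) sample.int(p) else rev(perm)
    pair <- (m + 1L) %/% 2L
    zidx <- ((seq_len(n) + pair - 2L) %% B) + 1L   # cycle background rows
    cur <- background[zidx, , drop = FALSE]
    blocks <- vector("list", p + 1L)
    blocks[[1L]] <- cur
    for (j in seq_len(p)) {
      cur[, perm[j]] <- X[, perm[j]]
      blocks[[j + 1L]] <- cur
    }
    Fv <- f(do.call(rbind, blocks))
    if (is.null(dim(Fv))) Fv <- matrix(Fv, ncol = 1)
    for (j in seq_len(p)) {
      d <- Fv[(j * n) + seq_len(n), , drop = FALSE] -
           Fv[((j - 1L) * n) + seq_len(n), , drop = FALSE]
      phi[, perm[j], ] <- phi[, perm[j], ] + d
      draws[, perm[j], ] <- draws[, perm[j], ] + d^2
    }
    base <- base + Fv[seq_len(n), , drop = FALSE]
  }
  phi <- phi / nsim
  base <- base / nsim
  se <- sqrt(pmax(draws / nsim - phi^2, 0) / nsim)
  structure(list(phi = phi, base = base, fx = out0, nsim = nsim, seed = seed,
                 tolerance = max(se)),
            class = "attribution_report")
}

#' Attribute a stacked model on cohort data
#'
#' Convenience wrapper: background defaults to an evenly spaced subsample of
#' `X` (50 rows), explaining all rows of `X`.
#'
#' @param model a fitted `stacked_model`.
#' @param X feature matrix (typically the training matrix).
#' @param background_size background subsample size (default 50).
#' @param nsim permutations (default `2 * background_size`).
#' @param seed integer seed.
#' @return an `attribution_report`.
#' @export
attribute_stacked <- function(model, X, background_size = 50, nsim = NULL,
                              seed = 1) {
  X <- as.matrix(X)
  bs <- min(background_size, nrow(X))
  bg <- X[unique(round(seq(1, nrow(X), length.out = bs))), , drop = FALSE]
  shapley_attribution(model, X, bg, nsim = nsim %||% 2L * nrow(bg), seed = seed)
}

#' @export
print.attribution_report <- function(x, ...) {
  d <- dim(x$phi)
  cat(sprintf("<attribution_report> %d samples x %d features x %d classes, %d permutations (max MC se %.2g)\n",
              d[1], d[2], d[3], x$nsim, x$tolerance))
  invisible(x)
}

#' Summarize an attribution report
#'
#' Global ranking by the mean over samples and classes of the absolute
#' contribution; per-class rankings by the mean absolute contribution within
#' each class output; and a sign summary — the fraction of positive
#' contributions among samples whose feature value lies above the feature
#' median (requires the explained matrix).
#'
#' @param report an `attribution_report`.
#' @param top_n number of features to keep in each ranking (default 15).
#' @param X optional explained feature matrix for the sign summary.
#' @return list with `global` (data frame `feature`, `mean_abs`), `per_class`
#'   (list of data frames) and optionally `sign` (feature x class fraction of
#'   positive contributions at high feature value).
#' @export
summarize_attribution <- function(report, top_n = 15, X = NULL) {
  phi <- report$phi
  feats <- dimnames(phi)[[2]] %||% paste0("f", seq_len(dim(phi)[2]))
  global_imp <- apply(abs(phi), 2, mean)
  ord <- order(-global_imp, feats)
  global <- data.frame(feature = feats[ord],
                       mean_abs = unname(global_imp[ord]))[seq_len(min(top_n, length(feats))), ]
  per_class <- lapply(seq_len(dim(phi)[3]), function(cidx) {
    imp <- apply(abs(phi[, , cidx, drop = FALSE]), 2, mean)
    o <- order(-imp, feats)
    data.frame(feature = feats[o],
               mean_abs = unname(imp[o]))[seq_len(min(top_n, length(feats))), ]
  })
  names(per_class) <- dimnames(phi)[[3]] %||% paste0("class", seq_len(dim(phi)[3]))
  out <- list(global = global, per_class = per_class)
  if (!is.null(X)) {
    X <- as.matrix(X)
    sign_frac <- matrix(NA_real_, length(feats), dim(phi)[3],
                        dimnames = list(feats, names(per_class)))
    for (j in seq_along(feats)) {
      hi <- X[, j] > stats::median(X[, j])
      if (any(hi))
        for (cidx in seq_len(dim(phi)[3]))
          sign_frac[j, cidx] <- mean(phi[hi, j, cidx] > 0)
    }
    out$sign <- sign_frac
  }
  out
}
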