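#' SMOTE minority oversampling
#'
#' Brings every class up to the majority-class count by interpolation: each
#' synthetic sample is `x + lambda * (x_nn - x)` with `lambda ~ U[0, 1]` and
#' `x_nn` one of the `k_neighbors` nearest same-class neighbours of a
#' minority point `x` (Euclidean distance). Original rows are preserved
#' verbatim; synthetic rows are appended.
#'
#' @param X numeric matrix (samples x features).
#' @param y class labels (factor or vector), length `nrow(X)`.
#' @param k_neighbors number of same-class neighbours to interpolate towards
#'   (default 5); every minority class must have more than `k_neighbors`
#'   members.
#' @param seed integer seed.
#' @return list with `X`, `y` (originals first, synthetics appended),
#'   `n_original`, and `source_idx` — for each output row, the row index in
#'   the input it derives from (synthetic rows point at their base point),
#'   enabling leakage audits.
#' @export
smote_oversample <- function(X, y, k_neighbors = 5, seed = 1) {
  y <- factor(y)
  X <- as.matrix(X)
  counts <- table(y)
  n_max <- max(counts)
  small <- names(counts)[counts <= k_neighbors & counts < n_max]
  if (length(small) > 0)
    dk_stop("dk_input_error",
            "class '%s' has %d members, not more than k_neighbors = %d; use a smaller k",
            small[1], counts[small[1]], k_neighbors)
  set.seed(dk_child_seed(seed, "smote"))
  newX <- list(); newy <- list(); src <- list()
  for (cl in names(counts)) {
    need <- n_max - counts[[cl]]
    if (need == 0) next
    idx <- which(y == cl)
    Xc <- X[idx, , drop = FALSE]
    d <- as.matrix(stats::dist(Xc))
    diag(d) <- Inf
    nn <- do.call(rbind, lapply(seq_len(nrow(d)), function(i)
      order(d[i, ])[seq_len(k_neighbors)]))
    base <- rep_len(seq_along(idx), need)
    pick <- nn[cbind(base, sample.int(k_neighbors, need, replace = TRUE))]
    lam <- stats::runif(need)
    syn <- Xc[base, , drop = FALSE] +
      lam * (Xc[pick, , drop = FALSE] - Xc[base, , drop = FALSE])
    newX[[cl]] <- syn
    newy[[cl]] <- rep(cl, need)
    src[[cl]] <- idx[base]
  }
  Xout <- rbind(X, do.call(rbind, newX))
  yout <- factor(c(as.character(y), unlist(newy)), levels = levels(y))
  rownames(Xout) <- NULL
  list(X = Xout, y = yout, n_original = nrow(X),
       source_idx = c(seq_len(nrow(X)), unlist(src, use.names = FALSE)))
}

#' Stratified K-fold plan
#'
#' Partitions the samples into `K` folds so that each fold's class counts
#' differ from exact proportional allocation by at most one. Deterministic
#' given the seed.
#'
#' @param y class labels.
#' @param K number of folds.
#' @param seed integer seed.
#' @return object of class `fold_plan`: list with `folds` (list of index
#'   vectors), `K`, `seed`, `class_counts` (K x classes matrix).
#' @export
stratified_folds <- function(y, K, seed = 1) {
  y <- factor(y)
  if (K < 2 || K > length(y)) dk_stop("dk_input_error", "K must be in [2, n]")
  set.seed(dk_child_seed(seed, "folds"))
  folds <- vector("list", K)
  for (cl in levels(y)) {
    idx <- sample(which(y == cl))
    off <- sample.int(K, 1)                     # rotate which folds get extras
    fold_of <- (rep_len(seq_len(K), length(idx)) + off - 1) %% K + 1
    for (k in seq_len(K)) folds[[k]] <- c(folds[[k]], idx[fold_of == k])
  }
  folds <- lapply(folds, sort)
  cc <- t(vapply(folds, function(f) as.integer(table(y[f])),
                 integer(nlevels(y))))
  colnames(cc) <- levels(y)
  structure(list(folds = folds, K = K, seed = seed, class_counts = cc,
                 n = length(y)), class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> K = %d, n = %d (seed %d)\n", x$K, x$n, x$seed))
  print(x$class_counts)
  invisible(x)
}
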