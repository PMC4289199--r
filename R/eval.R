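#' Jackknife (leave-one-out) evaluation of a linear SVM
#'
#' For each sample, trains a linear-kernel SVM on the remaining `n - 1`
#' samples (optionally restricted to a feature subset) and predicts the
#' held-out sample at decision threshold 0. Returns the aggregated
#' confusion counts together with the `n` signed decision values, from
#' which ROC/AUC can be computed.
#'
#' With `nested = TRUE` the feature ranking is recomputed inside every
#' fold (on the `n - 1` training samples) and its top `N` features are
#' used for that fold, giving a selection-leakage-free estimate; the
#' default mirrors the common protocol of ranking once on the full data
#' before cross-validation.
#'
#' If a training fold loses a class entirely (only possible when a class
#' has a single sample), that fold's prediction falls back to the
#' majority class of the fold, with a message.
#'
#' @param x feature matrix (n x D), `n >= 3`.
#' @param y labels, +1 / -1, both classes present.
#' @param C SVM regularization parameter.
#' @param features optional character vector of feature (column) names to
#'   restrict the model to. Ignored when `nested = TRUE`.
#' @param nested re-rank features within each fold. Default `FALSE`.
#' @param N top-feature count used per fold when `nested = TRUE`.
#' @param rank_method `"rfe"` or `"fscore"`; the per-fold ranker for
#'   `nested = TRUE`.
#' @param scale standardize features inside each SVM fit. Default
#'   `FALSE`.
#' @return list with `counts` (a [confusion_counts()] object),
#'   `decisions` (n signed decision values) and `predictions` (+1/-1).
#' @export
jackknife_evaluate <- function(x, y, C = 1, features = NULL,
                               nested = FALSE, N = NULL,
                               rank_method = c("rfe", "fscore"),
                               scale = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3L) stop("Jackknife needs at least 3 samples", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("Both classes must be present", call. = FALSE)
  }
  rank_method <- match.arg(rank_method)
  if (!nested && !is.null(features)) {
    missing <- setdiff(features, colnames(x))
    if (length(missing)) {
      stop("Unknown feature(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    x_use <- x[, features, drop = FALSE]
  } else {
    x_use <- x
  }
  decisions <- numeric(n)
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      message("Fold ", i, " lost a class; predicting fold majority")
      maj <- if (sum(ytr == 1) >= sum(ytr == -1)) 1 else -1
      decisions[i] <- maj * .Machine$double.eps
      next
    }
    if (nested) {
      xtr <- x[-i, , drop = FALSE]
      rk <- if (rank_method == "rfe") rfe_rank(xtr, ytr, C = C,
                                               scale = scale)
            else fscore_rank(xtr, ytr)
      Nf <- if (is.null(N)) ncol(x) else min(N, ncol(x))
      feats <- select_top(rk, Nf)
      fit <- fit_linear_svm(xtr[, feats, drop = FALSE], ytr, C = C,
                            scale = scale)
      decisions[i] <- decision_values(fit, x[i, feats, drop = FALSE])
    } else {
      fit <- fit_linear_svm(x_use[-i, , drop = FALSE], ytr, C = C,
                            scale = scale)
      decisions[i] <- decision_values(fit, x_use[i, , drop = FALSE])
    }
  }
  predictions <- ifelse(decisions >= 0, 1, -1)
  list(counts = confusion_counts(y, predictions),
       decisions = decisions,
       predictions = predictions)
}

#' Grid search over C and the retained feature dimension
#'
#' For every pair (C, N) on the grid, evaluates the jackknife accuracy
#' of a linear SVM restricted to the top-N features of `ranking`, and
#' returns the maximizer together with the full accuracy surface. Ties
#' on accuracy prefer the smaller N (parsimony), then the smaller C.
#'
#' @param x feature matrix.
#' @param y labels, +1 / -1.
#' @param ranking a `"ranking_list"` covering the columns of `x`.
#' @param C_grid positive reals; duplicates are removed. Default powers
#'   of two `2^(-5..15)`.
#' @param N_grid positive integers `<= ncol(x)`; duplicates removed.
#'   Default `1:min(200, D)`.
#' @param scale standardize features inside each SVM fit.
#' @return list with `C`, `Dim` (best N), `acc` (their jackknife
#'   accuracy) and `surface` (data.frame of C, N, accuracy).
#' @export
grid_search <- function(x, y, ranking, C_grid = 2^(-5:15),
                        N_grid = NULL, scale = FALSE) {
  x <- as.matrix(x)
  D <- ncol(x)
  if (!all(ranking$feature %in% colnames(x)) || nrow(ranking) != D) {
    stop("Ranking does not cover the feature matrix columns",
         call. = FALSE)
  }
  C_grid <- sort(unique(as.numeric(C_grid)))
  if (any(C_grid <= 0)) stop("C grid must be positive", call. = FALSE)
  if (is.null(N_grid)) N_grid <- seq_len(min(200L, D))
  N_grid <- sort(unique(as.integer(N_grid)))
  if (any(N_grid < 1L) || any(N_grid > D)) {
    stop("N grid must lie in 1..", D, call. = FALSE)
  }
  grid <- expand.grid(N = N_grid, C = C_grid)
  acc <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    feats <- select_top(ranking, grid$N[r])
    jk <- jackknife_evaluate(x, y, C = grid$C[r], features = feats,
                             scale = scale)
    acc[r] <- metrics_from_counts(jk$counts)$Acc
  }
  # argmax with ties -> smaller N, then smaller C
  best <- order(-acc, grid$N, grid$C)[1L]
  list(C = grid$C[best], Dim = grid$N[best], acc = acc[best],
       surface = data.frame(C = grid$C, N = grid$N, accuracy = acc))
}

#' Feature-selection stability across a random half-split
#'
#' Randomly splits the samples into two halves (each keeping both
#' classes), runs SVM-RFE on each half and on the full set, and reports
#' the pairwise overlaps of the three top-N feature lists, broken down
#' by feature family (k-mer tiers vs PseDNC) when a feature layout is
#' attached to `x`.
#'
#' @param x feature matrix with (optionally) a `"layout"` attribute from
#'   [encode_dataset()].
#' @param y labels, +1 / -1.
#' @param C SVM regularization parameter used by RFE.
#' @param N size of the top lists compared.
#' @param seed integer seed for the random split.
#' @param split optional logical vector assigning samples to the first
#'   half, overriding the random split (both halves must keep both
#'   classes).
#' @return list with `top_full`, `top_s1`, `top_s2` (character vectors),
#'   `common` (features in all three), and `by_block` (data.frame
#'   counting three-way common features per block).
#' @export
feature_overlap <- function(x, y, C = 1, N = 20L, seed = 1L,
                            split = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (is.null(split)) {
    set.seed(as.integer(seed))
    repeat {
      half <- sample(n, floor(n / 2))
      s1 <- seq_len(n) %in% half
      if (length(unique(y[s1])) == 2L &&
          length(unique(y[!s1])) == 2L) break
    }
  } else {
    stopifnot(is.logical(split), length(split) == n)
    s1 <- split
    if (length(unique(y[s1])) < 2L || length(unique(y[!s1])) < 2L) {
      stop("Both halves must contain both classes", call. = FALSE)
    }
  }
  N <- min(as.integer(N), ncol(x))
  top_full <- select_top(rfe_rank(x, y, C = C), N)
  top_s1 <- select_top(rfe_rank(x[s1, , drop = FALSE], y[s1], C = C), N)
  top_s2 <- select_top(rfe_rank(x[!s1, , drop = FALSE], y[!s1], C = C), N)
  common <- Reduce(intersect, list(top_full, top_s1, top_s2))
  lay <- attr(x, "layout")
  by_block <- NULL
  if (!is.null(lay)) {
    by_block <- data.frame(
      block = names(lay$blocks),
      common = vapply(lay$blocks,
                      function(b) length(intersect(common, b)),
                      integer(1)),
      row.names = NULL)
  }
  list(top_full = top_full, top_s1 = top_s1, top_s2 = top_s2,
       common = common, by_block = by_block)
}
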