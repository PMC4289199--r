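#' Rank features by SVM-RFE (recursive feature elimination)
#'
#' Iteratively fits a linear-kernel SVM on the surviving features and
#' eliminates the single feature with the smallest squared weight, until
#' none remain. The ranking is the reverse elimination order: the
#' last-surviving feature has rank 1. Ties on the squared weight are
#' broken by eliminating the feature with the larger column index, so
#' earlier-defined features survive longer and the ranking is
#' deterministic.
#'
#' One feature is removed per iteration by default; `chunk > 1` removes
#' that many per iteration (faster, coarser) while keeping the final
#' ranking a full permutation of the features.
#'
#' @param x numeric feature matrix (n x D).
#' @param y labels, +1 / -1.
#' @param C SVM regularization parameter used for every refit. Default 1.
#' @param chunk features eliminated per iteration. Default 1.
#' @param scale standardize features inside each SVM fit. Default
#'   `FALSE`.
#' @return object of class `"ranking_list"`: a data.frame with columns
#'   `rank`, `feature`, `elimination_step` (1 = eliminated first) and
#'   `criterion` (squared weight at elimination time, or the surviving
#'   weight for rank 1).
#' @examples
#' set.seed(1)
#' x <- cbind(signal = rep(c(-1, 1), each = 10) + rnorm(20, sd = 0.1),
#'            noise  = rnorm(20))
#' rfe_rank(x, rep(c(-1, 1), each = 10), C = 10)
#' @export
rfe_rank <- function(x, y, C = 1, chunk = 1L, scale = FALSE) {
  x <- as.matrix(x)
  D <- ncol(x)
  if (D < 1L) stop("Need at least one feature", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(D))
  chunk <- max(1L, as.integer(chunk))
  surviving <- seq_len(D)
  elim_order <- integer(0)
  elim_crit <- numeric(0)
  while (length(surviving) > 0L) {
    if (length(surviving) == 1L) {
      fit <- NULL
      w2 <- NA_real_
      elim_order <- c(elim_order, surviving)
      elim_crit <- c(elim_crit, last_crit(x, y, C, surviving, scale))
      break
    }
    fit <- fit_linear_svm(x[, surviving, drop = FALSE], y, C = C,
                          scale = scale)
    w2 <- fit$w^2
    n_drop <- min(chunk, length(surviving) - 1L)
    drop_local <- integer(n_drop)
    crit <- numeric(n_drop)
    remaining <- seq_along(surviving)
    for (d in seq_len(n_drop)) {
      m <- min(w2[remaining])
      # tie: eliminate the largest column index among the minima
      cand <- remaining[w2[remaining] == m]
      pick <- max(cand)
      drop_local[d] <- pick
      crit[d] <- w2[pick]
      remaining <- setdiff(remaining, pick)
    }
    elim_order <- c(elim_order, surviving[drop_local])
    elim_crit <- c(elim_crit, crit)
    surviving <- surviving[-drop_local]
  }
  ranking_list(colnames(x), elim_order, elim_crit)
}

# criterion recorded for the final surviving feature: its squared weight
# in a univariate fit (purely informational)
last_crit <- function(x, y, C, idx, scale) {
  fit <- tryCatch(
    fit_linear_svm(x[, idx, drop = FALSE], y, C = C, scale = scale),
    error = function(e) NULL)
  if (is.null(fit)) NA_real_ else unname(fit$w^2)
}

# Assemble a ranking_list from elimination order over feature names.
ranking_list <- function(features, elim_order, criterion) {
  D <- length(features)
  stopifnot(length(elim_order) == D, setequal(elim_order, seq_len(D)))
  rank_of <- integer(D)
  rank_of[elim_order] <- D:1  # eliminated first = worst rank
  step_of <- integer(D)
  step_of[elim_order] <- seq_len(D)
  crit_of <- numeric(D)
  crit_of[elim_order] <- criterion
  ord <- order(rank_of)
  out <- data.frame(rank = rank_of[ord],
                    feature = features[ord],
                    elimination_step = step_of[ord],
                    criterion = crit_of[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranking_list", "data.frame")
  out
}

#' Rank features by two-class F-score
#'
#' The filter baseline to SVM-RFE: for feature i with class means
#' \eqn{\bar x_i^+,\ \bar x_i^-}, overall mean \eqn{\bar x_i} and
#' within-class variances, the F-score is
#' \deqn{F_i = \frac{(\bar x_i^+ - \bar x_i)^2 + (\bar x_i^- - \bar
#'   x_i)^2}{\frac{1}{n^+ - 1}\sum (x^+ - \bar x_i^+)^2 +
#'   \frac{1}{n^- - 1}\sum (x^- - \bar x_i^-)^2}.}
#' Features are ranked by descending F-score; ties keep the original
#' column order. A feature with zero within-class variance in both
#' classes but distinct class means is maximally discriminative and is
#' ranked first (infinite F-score, with a message).
#'
#' @param x numeric feature matrix (n x D).
#' @param y labels, +1 / -1; each class needs at least 2 samples.
#' @return a `"ranking_list"` data.frame as in [rfe_rank()], with
#'   `criterion` holding the F-score and `elimination_step` the reverse
#'   rank for symmetry with RFE output.
#' @export
fscore_rank <- function(x, y) {
  x <- as.matrix(x)
  D <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(D))
  pos <- y == 1
  neg <- y == -1
  if (sum(pos) < 2L || sum(neg) < 2L) {
    stop("Each class needs at least 2 samples for F-score", call. = FALSE)
  }
  mp <- colMeans(x[pos, , drop = FALSE])
  mn <- colMeans(x[neg, , drop = FALSE])
  m <- colMeans(x)
  vp <- apply(x[pos, , drop = FALSE], 2L, stats::var)
  vn <- apply(x[neg, , drop = FALSE], 2L, stats::var)
  num <- (mp - m)^2 + (mn - m)^2
  den <- vp + vn
  f <- ifelse(den == 0 & num == 0, 0,
              ifelse(den == 0, Inf, num / den))
  if (any(is.infinite(f))) {
    message(sum(is.infinite(f)),
            " feature(s) with zero within-class variance ranked first")
  }
  ord <- order(-f, seq_len(D))  # descending score, ties by column order
  out <- data.frame(rank = seq_len(D),
                    feature = colnames(x)[ord],
                    elimination_step = D:1,
                    criterion = f[ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("ranking_list", "data.frame")
  out
}

#' Top-N features of a ranking
#'
#' @param ranking a `"ranking_list"` from [rfe_rank()] or
#'   [fscore_rank()].
#' @param N number of features to keep, `1 <= N <= D`.
#' @return character vector of the N best-ranked feature names, best
#'   first.
#' @export
select_top <- function(ranking, N) {
  N <- as.integer(N)
  D <- nrow(ranking)
  if (N < 1L || N > D) {
    stop("N must satisfy 1 <= N <= ", D, call. = FALSE)
  }
  ranking$feature[order(ranking$rank)][seq_len(N)]
}

#' @export
print.ranking_list <- function(x, n = 10L, ...) {
  cat("Feature ranking (", nrow(x), " features), top ", min(n, nrow(x)),
      ":\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), n), row.names = FALSE)
  invisible(x)
}

#' Write / read a ranking list as TSV
#'
#' Columns: rank, feature, elimination_step, criterion.
#'
#' @param ranking a `"ranking_list"`.
#' @param path file path.
#' @return `path` invisibly (write); a `"ranking_list"` (read).
#' @export
write_ranking_tsv <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranking_tsv
#' @export
read_ranking_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("rank", "feature", "elimination_step", "criterion")
  if (!all(needed %in% names(out))) {
    stop("Ranking TSV must have columns: ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  class(out) <- c("ranking_list", "data.frame")
  out
}
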