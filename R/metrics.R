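#' Confusion counts for a hotspot/coldspot prediction
#'
#' Summarizes a two-class prediction as the four counts the performance
#' metrics are defined on: the number of hotspot (+1) and coldspot (-1)
#' samples, and how many of each were misclassified.
#'
#' @param truth true labels, +1 / -1.
#' @param pred predicted labels, +1 / -1.
#' @return object of class `"confusion_counts"`: list with `N_plus`,
#'   `N_minus`, `N_plus_mis`, `N_minus_mis`.
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred),
            all(truth %in% c(-1, 1)), all(pred %in% c(-1, 1)))
  out <- list(N_plus = sum(truth == 1),
              N_minus = sum(truth == -1),
              N_plus_mis = sum(truth == 1 & pred == -1),
              N_minus_mis = sum(truth == -1 & pred == 1))
  class(out) <- "confusion_counts"
  out
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("hotspots:  ", x$N_plus, " (", x$N_plus_mis, " misclassified)\n",
      "coldspots: ", x$N_minus, " (", x$N_minus_mis, " misclassified)\n",
      sep = "")
  invisible(x)
}

#' Sensitivity, specificity, accuracy and MCC from confusion counts
#'
#' \deqn{Sn = 1 - N^+_{mis}/N^+, \quad Sp = 1 - N^-_{mis}/N^-,}
#' \deqn{Acc = 1 - (N^+_{mis} + N^-_{mis})/(N^+ + N^-),}
#' and the Matthews correlation coefficient in its contingency form
#' (TP = hotspots correctly predicted, etc.). When any MCC marginal is
#' zero the coefficient is undefined; the conventional value 0 is
#' returned with a message.
#'
#' @param counts a `"confusion_counts"` object, or a list with fields
#'   `N_plus`, `N_minus`, `N_plus_mis`, `N_minus_mis`.
#' @return named list with `Sn`, `Sp`, `Acc`, `MCC`.
#' @examples
#' metrics_from_counts(list(N_plus = 10, N_minus = 10,
#'                          N_plus_mis = 2, N_minus_mis = 1))
#' @export
metrics_from_counts <- function(counts) {
  np <- counts$N_plus; nn <- counts$N_minus
  fp_n <- counts$N_minus_mis  # coldspots called hotspot
  fn_n <- counts$N_plus_mis   # hotspots called coldspot
  if (is.null(np) || is.null(nn) || np <= 0 || nn <= 0) {
    stop("Both classes must have at least one sample", call. = FALSE)
  }
  if (fn_n < 0 || fn_n > np || fp_n < 0 || fp_n > nn) {
    stop("Misclassification counts out of range", call. = FALSE)
  }
  tp <- np - fn_n
  tn <- nn - fp_n
  sn <- 1 - fn_n / np
  sp <- 1 - fp_n / nn
  acc <- 1 - (fn_n + fp_n) / (np + nn)
  den2 <- (tp + fp_n) * (tp + fn_n) * (tn + fp_n) * (tn + fn_n)
  if (den2 == 0) {
    message("MCC denominator is zero (degenerate margin); returning 0")
    mcc <- 0
  } else {
    mcc <- (tp * tn - fp_n * fn_n) / sqrt(den2)
  }
  list(Sn = sn, Sp = sp, Acc = acc, MCC = mcc)
}

#' ROC curve and AUC from decision values
#'
#' Builds the ROC curve by sweeping a threshold over the signed decision
#' values, stepping through tied values simultaneously, and computes the
#' area under it by the trapezoid rule. This equals the normalized
#' Mann-Whitney U statistic: the probability that a random hotspot
#' receives a higher decision value than a random coldspot, counting
#' ties as 1/2.
#'
#' @param labels true labels, +1 / -1, both classes present.
#' @param scores finite numeric decision values, higher = more
#'   hotspot-like.
#' @return list with `roc` (data.frame of `fpr`, `tpr` from (0,0) to
#'   (1,1)) and `auc`.
#' @examples
#' roc_auc(c(1, 1, -1, -1), c(0.9, 0.2, 0.4, -1))
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores),
            all(labels %in% c(-1, 1)))
  if (!all(is.finite(scores))) {
    stop("Decision values must be finite", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("Both classes must be present", call. = FALSE)
  }
  if (length(unique(scores)) == 1L) {
    warning("Constant decision values: AUC is 0.5 by convention",
            call. = FALSE)
  }
  np <- sum(labels == 1)
  nn <- sum(labels == -1)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # group tied scores: one ROC step per distinct threshold
  grp <- cumsum(!duplicated(s))
  tp_inc <- tapply(l == 1, grp, sum)
  fp_inc <- tapply(l == -1, grp, sum)
  tpr <- c(0, cumsum(tp_inc) / np)
  fpr <- c(0, cumsum(fp_inc) / nn)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
  list(roc = data.frame(fpr = as.numeric(fpr), tpr = as.numeric(tpr)),
       auc = as.numeric(auc))
}
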