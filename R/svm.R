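#' Fit a soft-margin linear-kernel SVM
#'
#' Thin wrapper around the LIBSVM implementation in \pkg{e1071} exposing
#' the primal weight vector and bias of the linear decision function
#' `f(x) = x . w + b`, oriented so that `f > 0` predicts the positive
#' (+1, hotspot) class. Features are not rescaled by default: PseNAC
#' features already live on comparable [0, 1]-scale ranges, and rescaling
#' would silently change the SVM-RFE elimination criterion. Set
#' `scale = TRUE` to standardize columns first.
#'
#' @param x numeric feature matrix (n samples x D features).
#' @param y labels, +1 / -1, both classes present.
#' @param C regularization parameter (LIBSVM `cost`). Default 1.
#' @param scale standardize columns before fitting. Default `FALSE`.
#' @return object of class `"linear_svm"`: list with `w` (named weight
#'   vector on the input scale of the decision function), `b` (bias),
#'   `C`, and the scaling parameters when `scale = TRUE`. Use
#'   [decision_values()] or `predict()` on new data.
#' @examples
#' x <- matrix(c(-1, 1), ncol = 1)
#' m <- fit_linear_svm(x, c(-1, 1), C = 100)
#' decision_values(m, x)
#' @export
fit_linear_svm <- function(x, y, C = 1, scale = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("Non-finite feature values", call. = FALSE)
  if (!all(y %in% c(-1, 1))) stop("Labels must be +1/-1", call. = FALSE)
  if (length(unique(y)) < 2L) {
    stop("Both classes must be present to fit an SVM", call. = FALSE)
  }
  if (nrow(x) != length(y)) stop("nrow(x) != length(y)", call. = FALSE)
  fit <- e1071::svm(x, factor(y, levels = c("1", "-1")),
                    kernel = "linear", cost = C, scale = scale)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  obj <- structure(
    list(w = w, b = b, C = C,
         x_center = fit$x.scale$`scaled:center`,
         x_scale = fit$x.scale$`scaled:scale`),
    class = "linear_svm")
  # orient the plane so positive decision values mean class +1,
  # whichever internal label order LIBSVM picked
  fitted_lab <- ifelse(fit$fitted == "1", 1, -1)
  raw <- decision_values(obj, x)
  if (mean((raw >= 0) == (fitted_lab == 1)) < 0.5) {
    obj$w <- -obj$w
    obj$b <- -obj$b
  }
  if (is.null(names(obj$w)) && !is.null(colnames(x))) {
    names(obj$w) <- colnames(x)
  }
  obj
}

#' Signed decision values of a fitted linear SVM
#'
#' @param object a `"linear_svm"` fit.
#' @param newx feature matrix with the same columns the model was
#'   trained on.
#' @return numeric vector `newx . w + b`; positive values predict the
#'   +1 (hotspot) class.
#' @export
decision_values <- function(object, newx) {
  newx <- as.matrix(newx)
  if (!is.null(object$x_center)) {
    newx <- sweep(newx, 2L, object$x_center, "-")
    newx <- sweep(newx, 2L, object$x_scale, "/")
  }
  drop(newx %*% object$w) + object$b
}

#' @export
print.linear_svm <- function(x, ...) {
  cat("Linear-kernel SVM: ", length(x$w), " features, C = ", x$C,
      "\n", sep = "")
  invisible(x)
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  ifelse(decision_values(object, newdata) >= 0, 1, -1)
}

#' @export
coef.linear_svm <- function(object, ...) {
  c(`(bias)` = object$b, object$w)
}
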