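#' Fit a recombination hot/cold-spot classifier
#'
#' Runs the full pipeline on two labeled sequence sets: PseNAC encoding
#' (k-mer tiers 1..`k_max` plus PseDNC with `omega` coupling factors),
#' feature ranking (SVM-RFE by default, F-score as baseline), grid
#' search over the SVM regularization parameter C and the retained
#' top-feature dimension under jackknife (leave-one-out)
#' cross-validation, and a final linear SVM trained on the full data at
#' the selected (C, Dim). Jackknife Sn/Sp/Acc/MCC and ROC/AUC at the
#' optimum are reported.
#'
#' By default the ranking is computed once on the full dataset and the
#' grid search reuses it for every fold, which mirrors the usual
#' protocol of this method family but lets feature selection see the
#' held-out samples; `nested = TRUE` re-ranks within every jackknife
#' fold at the selected dimension for a selection-leakage-free estimate
#' of the final performance (at considerable extra cost).
#'
#' @param hot,cold sequences of each class: named character vectors
#'   (e.g. from [read_fasta()]) or paths to FASTA files.
#' @param k_max highest k-mer tier. Default 5.
#' @param omega number of PseDNC coupling factors; capped by the
#'   shortest sequence at `L_min - 2`. Default 10.
#' @param w PseDNC pseudo-component weight. Default 0.05.
#' @param table dinucleotide property matrix. Default
#'   [dinuc_properties()].
#' @param rank_method `"rfe"` (default) or `"fscore"`.
#' @param C_grid candidate regularization parameters. Default
#'   `2^(-5:15)`.
#' @param N_grid candidate top-feature dimensions. Default
#'   `1:min(200, D)`.
#' @param rfe_C the C used while ranking (the grid-searched C is not
#'   known yet at ranking time). Default 1.
#' @param nested re-rank inside each jackknife fold at the selected
#'   dimension and report leakage-free metrics. Default `FALSE`.
#' @param scale standardize features inside each SVM fit. Default
#'   `FALSE`.
#' @return object of class `"recspot"`; see Details. Key components:
#'   `ranking`, `C`, `Dim`, `features`, `metrics` (Sn/Sp/Acc/MCC),
#'   `roc`, `auc`, `surface`, `model` (the final full-data
#'   `"linear_svm"`), `decisions` (jackknife decision values).
#' @examples
#' \donttest{
#' d <- generate_dataset(synthetic_config(n_hot = 15, n_cold = 15,
#'                                        length_range = c(100, 150)))
#' fit <- recspot(d$sequences[d$labels == 1], d$sequences[d$labels == -1],
#'                k_max = 2, omega = 2, C_grid = c(1, 32),
#'                N_grid = c(5, 10, 20))
#' fit
#' }
#' @export
recspot <- function(hot, cold, k_max = 5L, omega = 10L, w = 0.05,
                    table = dinuc_properties(),
                    rank_method = c("rfe", "fscore"),
                    C_grid = 2^(-5:15), N_grid = NULL, rfe_C = 1,
                    nested = FALSE, scale = FALSE) {
  rank_method <- match.arg(rank_method)
  if (is.character(hot) && length(hot) == 1L && file.exists(hot)) {
    hot <- read_fasta(hot)
  }
  if (is.character(cold) && length(cold) == 1L && file.exists(cold)) {
    cold <- read_fasta(cold)
  }
  if (length(hot) == 0L || length(cold) == 0L) {
    stop("Both classes need at least one sequence", call. = FALSE)
  }
  if (is.null(names(hot))) names(hot) <- paste0("hot_", seq_along(hot))
  if (is.null(names(cold))) names(cold) <- paste0("cold_", seq_along(cold))
  seqs <- c(hot, cold)
  y <- c(rep(1, length(hot)), rep(-1, length(cold)))
  x <- encode_dataset(seqs, k_max = k_max, omega = omega, w = w,
                      table = table)
  layout <- attr(x, "layout")

  ranking <- if (rank_method == "rfe") {
    rfe_rank(x, y, C = rfe_C, scale = scale)
  } else {
    fscore_rank(x, y)
  }

  gs <- grid_search(x, y, ranking, C_grid = C_grid, N_grid = N_grid,
                    scale = scale)
  features <- select_top(ranking, gs$Dim)

  jk <- jackknife_evaluate(x, y, C = gs$C, features = features,
                           nested = nested, N = gs$Dim,
                           rank_method = rank_method, scale = scale)
  metrics <- metrics_from_counts(jk$counts)
  roc <- roc_auc(y, jk$decisions)

  model <- fit_linear_svm(x[, features, drop = FALSE], y, C = gs$C,
                          scale = scale)

  structure(list(
    call = match.call(),
    n_hot = length(hot), n_cold = length(cold),
    encoder = list(k_max = as.integer(k_max), omega = as.integer(omega),
                   w = w, table = table),
    layout = layout,
    rank_method = rank_method, rfe_C = rfe_C, nested = nested,
    scale = scale,
    ranking = ranking,
    C = gs$C, Dim = gs$Dim, surface = gs$surface,
    features = features,
    counts = jk$counts, metrics = metrics,
    decisions = jk$decisions, labels = y, ids = names(seqs),
    roc = roc$roc, auc = roc$auc,
    model = model), class = "recspot")
}

#' @export
print.recspot <- function(x, ...) {
  cat("Recombination spot classifier (PseNAC + SVM-RFE + linear SVM)\n")
  cat(sprintf("  samples: %d hotspots, %d coldspots; %d features (k_max = %d, omega = %d)\n",
              x$n_hot, x$n_cold, x$layout$dim, x$encoder$k_max,
              x$encoder$omega))
  cat(sprintf("  selected: C = %g, Dim = %d (%s ranking%s)\n",
              x$C, x$Dim, x$rank_method,
              if (x$nested) ", nested" else ""))
  m <- x$metrics
  cat(sprintf("  jackknife: Sn = %.4f  Sp = %.4f  Acc = %.4f  MCC = %.4f  AUC = %.4f\n",
              m$Sn, m$Sp, m$Acc, m$MCC, x$auc))
  invisible(x)
}

#' @export
summary.recspot <- function(object, top = 10L, ...) {
  print(object)
  cat("\nTop-ranked features:\n")
  print(utils::head(as.data.frame(object$ranking), top),
        row.names = FALSE)
  blocks <- vapply(object$layout$blocks, function(b) {
    length(intersect(object$features, b))
  }, integer(1))
  cat("\nSelected features by block:\n")
  print(data.frame(block = names(blocks), selected = unname(blocks)),
        row.names = FALSE)
  invisible(object)
}

#' @export
coef.recspot <- function(object, ...) {
  coef(object$model)
}

#' Predict recombination spot class for new sequences
#'
#' Encodes new sequences with the parameters stored in the fitted model
#' and applies the final linear SVM. Sequences shorter than the model's
#' `omega + 2` (or `k_max`) cannot be encoded and yield `NA` rows with a
#' warning.
#'
#' @param object a fitted [recspot()] model.
#' @param newdata named character vector of DNA sequences or a FASTA
#'   path.
#' @param ... unused.
#' @return data.frame with `id`, `decision` (signed decision value) and
#'   `class` (`"hotspot"` / `"coldspot"`).
#' @export
predict.recspot <- function(object, newdata, ...) {
  if (is.character(newdata) && length(newdata) == 1L &&
      file.exists(newdata)) {
    newdata <- read_fasta(newdata)
  }
  if (length(newdata) == 0L) stop("No sequences to predict",
                                  call. = FALSE)
  if (is.null(names(newdata))) {
    names(newdata) <- paste0("seq", seq_along(newdata))
  }
  enc <- object$encoder
  if (is.na(enc$k_max) || is.na(enc$omega)) {
    stop("Model lacks encoder parameters; cannot encode raw sequences",
         call. = FALSE)
  }
  min_len <- max(enc$k_max, enc$omega + 2L)
  ok <- nchar(newdata) >= min_len
  if (!all(ok)) {
    warning(sum(!ok), " sequence(s) shorter than ", min_len,
            " nt cannot be encoded: ",
            paste(names(newdata)[!ok], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(id = names(newdata),
                    decision = NA_real_,
                    class = NA_character_,
                    stringsAsFactors = FALSE)
  if (any(ok)) {
    x <- encode_dataset(newdata[ok], k_max = enc$k_max,
                        omega = enc$omega, w = enc$w, table = enc$table)
    d <- decision_values(object$model,
                         x[, object$features, drop = FALSE])
    out$decision[ok] <- d
    out$class[ok] <- ifelse(d >= 0, "hotspot", "coldspot")
  }
  out
}

#' Plot a fitted recombination spot classifier
#'
#' `type = "surface"` draws the jackknife accuracy against the retained
#' top-feature dimension, one line per C on the grid (the top-N sweep);
#' `type = "roc"` draws the jackknife ROC curve with its AUC.
#'
#' @param x a fitted [recspot()] model.
#' @param type `"surface"` or `"roc"`.
#' @param ... passed to [graphics::plot()].
#' @return `x` invisibly.
#' @export
plot.recspot <- function(x, type = c("surface", "roc"), ...) {
  type <- match.arg(type)
  if (type == "surface") {
    s <- x$surface
    cs <- sort(unique(s$C))
    graphics::plot(range(s$N), range(s$accuracy), type = "n",
                   xlab = "top-N feature dimension",
                   ylab = "jackknife accuracy", ...)
    for (i in seq_along(cs)) {
      sub <- s[s$C == cs[i], ]
      graphics::lines(sub$N, sub$accuracy, col = i, lty = 1)
    }
    graphics::abline(v = x$Dim, lty = 3)
    graphics::legend("bottomright", legend = paste0("C = ", cs),
                     col = seq_along(cs), lty = 1, cex = 0.8)
  } else {
    graphics::plot(x$roc$fpr, x$roc$tpr, type = "l",
                   xlab = "false positive rate",
                   ylab = "true positive rate",
                   main = sprintf("Jackknife ROC (AUC = %.3f)", x$auc),
                   ...)
    graphics::abline(0, 1, lty = 3)
  }
  invisible(x)
}

#' Save / load a fitted model as JSON
#'
#' Persists everything needed to reproduce predictions without
#' retraining: SVM weights, bias, C, the selected feature names and the
#' encoder parameters (including the property table).
#'
#' @param object a fitted [recspot()] model.
#' @param path JSON file path.
#' @return `path` invisibly (save); a reduced `"recspot"` object
#'   sufficient for [predict.recspot()] (load).
#' @export
save_model_json <- function(object, path) {
  stopifnot(inherits(object, "recspot"))
  tab <- object$encoder$table
  payload <- list(
    format = "recspot-model",
    version = 1L,
    weights = as.list(object$model$w),
    bias = object$model$b,
    C = object$C, Dim = object$Dim,
    features = object$features,
    scaled = object$scale,
    x_center = object$model$x_center,
    x_scale = object$model$x_scale,
    encoder = list(k_max = object$encoder$k_max,
                   omega = object$encoder$omega,
                   w = object$encoder$w,
                   table = list(dinucleotide = rownames(tab),
                                values = as.data.frame(tab))),
    metrics = object$metrics, auc = object$auc)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_model_json
#' @export
load_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "recspot-model")) {
    stop("Not a recspot model file: ", path, call. = FALSE)
  }
  tab <- as.matrix(p$encoder$table$values)
  rownames(tab) <- p$encoder$table$dinucleotide
  w <- unlist(p$weights)
  norm_null <- function(v) if (length(v)) unlist(v) else NULL
  model <- structure(list(w = w, b = p$bias, C = p$C,
                          x_center = norm_null(p$x_center),
                          x_scale = norm_null(p$x_scale)),
                     class = "linear_svm")
  structure(list(
    encoder = list(k_max = as.integer(p$encoder$k_max),
                   omega = as.integer(p$encoder$omega),
                   w = p$encoder$w, table = tab),
    C = p$C, Dim = as.integer(p$Dim),
    features = p$features,
    metrics = p$metrics, auc = p$auc,
    model = model), class = "recspot")
}
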