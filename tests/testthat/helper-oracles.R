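# Independent reference implementations used as oracles. These stay
# deliberately naive (explicit loops, no shared code with the package
# internals beyond exported primitives they are meant to check against).

# Brute-force overlapping k-mer frequencies by explicit substring scan.
oracle_kmer_freq <- function(seq, k) {
  L <- nchar(seq)
  kmers <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                  stringsAsFactors = FALSE),
                      1, function(r) paste(rev(r), collapse = "")))
  counts <- setNames(numeric(length(kmers)), kmers)
  for (i in 1:(L - k + 1)) {
    m <- substr(seq, i, i + k - 1)
    counts[m] <- counts[m] + 1
  }
  counts / (L - k + 1)
}

# Coupling factor by explicit loop over positions, using the exported
# single-pair delta().
oracle_corr_factor <- function(seq, j, table = dinuc_properties()) {
  L <- nchar(seq)
  total <- 0
  for (i in 1:(L - j - 1)) {
    d1 <- substr(seq, i, i + 1)
    d2 <- substr(seq, i + j, i + j + 1)
    total <- total + delta(d1, d2, table)
  }
  total / (L - j - 1)
}

# PseDNC by direct composition of the published formulas.
oracle_psednc <- function(seq, omega, w, table = dinuc_properties()) {
  f <- oracle_kmer_freq(seq, 2)
  g <- vapply(seq_len(omega), oracle_corr_factor, numeric(1),
              seq = seq, table = table)
  c(f, w * g) / (sum(f) + w * sum(g))
}

# Linear soft-margin SVM via the dual QP, solved with kernlab's
# interior-point solver. Only for tiny n.
oracle_dual_svm <- function(x, y, C) {
  n <- nrow(x)
  K <- x %*% t(x)
  H <- (y %*% t(y)) * K
  ridge <- 1e-6 * max(diag(H))
  sol <- kernlab::ipop(c = rep(-1, n), H = H + diag(ridge, n),
                       A = t(y), b = 0, l = rep(0, n), u = rep(C, n),
                       r = 0, sigf = 7, maxiter = 400)
  a <- kernlab::primal(sol)
  w <- colSums(a * y * x)
  sv <- which(a > 1e-6 * C & a < C * (1 - 1e-6))
  if (length(sv)) {
    b <- mean(y[sv] - x[sv, , drop = FALSE] %*% w)
    b_lo <- b_hi <- b
  } else {
    # all alphas at bounds: any bias inside the KKT bracket is optimal
    g <- y - x %*% w
    b_lo <- max(g[y == -1])
    b_hi <- min(g[y == 1])
    b <- mean(c(b_lo, b_hi))
  }
  list(w = w, b = b, b_lo = min(b_lo, b_hi), b_hi = max(b_lo, b_hi))
}

# Step-by-step reference of the eliminate-one SVM-RFE loop. Uses
# fit_linear_svm for the per-step fit (the quantity under test is the
# elimination bookkeeping, checked independently of rfe_rank's code
# path) and re-derives the ranking by explicit list surgery.
oracle_rfe <- function(x, y, C) {
  feats <- colnames(x)
  alive <- feats
  order_out <- character(0)
  while (length(alive) > 1) {
    fit <- fit_linear_svm(x[, alive, drop = FALSE], y, C = C)
    w2 <- fit$w^2
    worst <- which(w2 == min(w2))
    pick <- alive[max(worst)]  # tie: drop the later-defined feature
    order_out <- c(order_out, pick)
    alive <- setdiff(alive, pick)
  }
  rev(c(order_out, alive))  # best first
}

# AUC as the exhaustive concordant-pair fraction (ties count 1/2).
oracle_auc_pairs <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == -1]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# MCC from an explicitly assembled 2x2 contingency table.
oracle_mcc <- function(tp, fn, tn, fp) {
  num <- tp * tn - fp * fn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else num / den
}

# Random A/C/G/T sequence.
random_seq <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# Small labeled matrix with planted class separation in chosen columns.
make_separable <- function(n_per_class = 6, D = 4, informative = 1:2,
                           gap = 3, sd = 0.3) {
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * D, sd = 1), n, D)
  y <- rep(c(1, -1), each = n_per_class)
  for (j in informative) {
    x[, j] <- y * gap / 2 + rnorm(n, sd = sd)
  }
  colnames(x) <- paste0("f", seq_len(D))
  list(x = x, y = y)
}
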