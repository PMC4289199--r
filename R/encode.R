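#' Overlapping k-mer frequencies of a DNA sequence
#'
#' Counts every overlapping window of length `k` and normalizes by the
#' number of windows, `L - k + 1`, so the vector sums to one. Entries are
#' ordered lexicographically with A < C < G < T. `k = 1` gives the
#' nucleic acid composition (NAC); `k = 2` the dinucleotide composition;
#' higher `k` the higher frequency tiers.
#'
#' @param seq a single DNA sequence string (A/C/G/T).
#' @param k word length, `1 <= k <= nchar(seq)`.
#' @return numeric vector of length `4^k`, named by k-mer.
#' @examples
#' kmer_frequencies("ACGT", 1)
#' kmer_frequencies("AAAA", 2)
#' @export
kmer_frequencies <- function(seq, k) {
  stopifnot(length(seq) == 1L, is.character(seq))
  seq <- toupper(seq)
  check_dna(seq)
  L <- nchar(seq)
  k <- as.integer(k)
  if (k < 1L || k > L) {
    stop("k must satisfy 1 <= k <= sequence length (L = ", L, ")",
         call. = FALSE)
  }
  kmers <- all_kmers(k)
  windows <- substring(seq, 1:(L - k + 1L), k:L)
  counts <- tabulate(match(windows, kmers), nbins = length(kmers))
  out <- counts / (L - k + 1L)
  names(out) <- kmers
  out
}

#' Sequence-order correlation factor at a given lag
#'
#' The rank-`j` coupling factor of pseudo dinucleotide composition: the
#' average physicochemical dissimilarity [delta()] between dinucleotides
#' `j` positions apart,
#' \deqn{g_j = \frac{1}{L-j-1} \sum_{i=1}^{L-j-1}
#'   \Delta(R_i R_{i+1},\; R_{i+j} R_{i+j+1}).}
#' `g_1` couples each dinucleotide to its immediate successor, `g_2` to
#' the next one along, and so forth.
#'
#' @param seq a single DNA sequence string.
#' @param j lag (coupling rank), `1 <= j <= nchar(seq) - 2`.
#' @param table property matrix from [dinuc_properties()].
#' @return non-negative scalar.
#' @examples
#' correlation_factor("ACGTACGT", 1)
#' @export
correlation_factor <- function(seq, j, table = dinuc_properties()) {
  seq <- toupper(seq)
  check_dna(seq)
  L <- nchar(seq)
  j <- as.integer(j)
  if (j < 1L || j > L - 2L) {
    stop("lag j must satisfy 1 <= j <= L - 2 (L = ", L, ")",
         call. = FALSE)
  }
  dm <- delta_matrix(table)
  di <- dinuc_index(seq)
  idx <- 1:(L - j - 1L)
  mean(dm[cbind(di[idx], di[idx + j])])
}

# Integer codes (1..16) of the L-1 overlapping dinucleotides of seq.
dinuc_index <- function(seq) {
  base <- match(strsplit(seq, "", fixed = TRUE)[[1L]],
                c("A", "C", "G", "T"))
  L <- length(base)
  (base[-L] - 1L) * 4L + base[-1L]
}

#' Pseudo dinucleotide composition (PseDNC) vector
#'
#' Augments the 16 dinucleotide frequencies with `omega` sequence-order
#' coupling factors, jointly normalized so the full vector sums to one:
#' \deqn{d_m = \frac{f_m}{\sum_{m'} f_{m'} + w \sum_{j=1}^{\omega} g_j},
#'   \quad m = 1..16,}
#' \deqn{d_{16+j} = \frac{w\, g_j}{\sum_{m'} f_{m'} +
#'   w \sum_{j=1}^{\omega} g_j}, \quad j = 1..\omega.}
#' With `w = 0` this reduces exactly to the dinucleotide composition with
#' zero pseudo-components.
#'
#' @param seq a single DNA sequence string, length at least `omega + 2`.
#' @param omega highest coupling rank (number of pseudo-components).
#' @param w weight of the pseudo-components relative to the dinucleotide
#'   frequencies. Default 0.05.
#' @param table property matrix from [dinuc_properties()].
#' @return numeric vector of length `16 + omega`, names `AA..TT` then
#'   `lambda.1..lambda.omega`.
#' @examples
#' psednc_vector("ACGTACGTACGT", omega = 3)
#' @export
psednc_vector <- function(seq, omega, w = 0.05,
                          table = dinuc_properties()) {
  seq <- toupper(seq)
  check_dna(seq)
  L <- nchar(seq)
  omega <- as.integer(omega)
  if (omega < 1L) stop("omega must be a positive integer", call. = FALSE)
  if (w < 0) stop("w must be non-negative", call. = FALSE)
  if (L < omega + 2L) {
    stop("Sequence length L = ", L, " is below omega + 2 = ", omega + 2L,
         call. = FALSE)
  }
  f <- kmer_frequencies(seq, 2L)
  dm <- delta_matrix(table)
  di <- dinuc_index(seq)
  g <- vapply(seq_len(omega), function(j) {
    idx <- 1:(L - j - 1L)
    mean(dm[cbind(di[idx], di[idx + j])])
  }, numeric(1))
  denom <- sum(f) + w * sum(g)
  out <- c(f, w * g) / denom
  names(out) <- c(names(f), paste0("lambda.", seq_len(omega)))
  out
}

#' Feature layout of the merged PseNAC vector
#'
#' Describes the fixed block structure of an encoded feature vector:
#' k-mer frequency tiers 1..`k_max` (each tier `k` contributing `4^k`
#' features in lexicographic order), followed by the PseDNC block
#' (16 dinucleotide components plus `omega` pseudo-components ordered by
#' increasing lag). Feature names are prefixed by block
#' (`"kmer1:A"`, `"kmer2:AA"`, ..., `"pse:AA"`, `"pse:lambda.1"`) so
#' downstream rankings stay interpretable.
#'
#' @param k_max highest k-mer tier. Default 5.
#' @param omega number of PseDNC pseudo-components. Default 10.
#' @return object of class `"feature_layout"`: a list with `blocks`
#'   (named list of character vectors of feature names), `names` (all
#'   feature names in order) and `dim` (total dimension).
#' @examples
#' lay <- feature_layout(k_max = 2, omega = 1)
#' lay$dim # 4 + 16 + 16 + 1 = 37
#' @export
feature_layout <- function(k_max = 5L, omega = 10L) {
  k_max <- as.integer(k_max)
  omega <- as.integer(omega)
  if (k_max < 1L) stop("k_max must be >= 1", call. = FALSE)
  if (omega < 1L) stop("omega must be >= 1", call. = FALSE)
  blocks <- lapply(seq_len(k_max), function(k) {
    paste0("kmer", k, ":", all_kmers(k))
  })
  names(blocks) <- paste0("kmer", seq_len(k_max))
  blocks$pse <- paste0("pse:", c(all_kmers(2L),
                                 paste0("lambda.", seq_len(omega))))
  nm <- unlist(blocks, use.names = FALSE)
  structure(list(blocks = blocks, names = nm, dim = length(nm),
                 k_max = k_max, omega = omega),
            class = "feature_layout")
}

#' @export
print.feature_layout <- function(x, ...) {
  cat("PseNAC feature layout: ", x$dim, " features\n", sep = "")
  for (b in names(x$blocks)) {
    cat("  ", b, ": ", length(x$blocks[[b]]), " features\n", sep = "")
  }
  invisible(x)
}

#' Encode one DNA sequence as a PseNAC feature vector
#'
#' Concatenates the k-mer frequency tiers `k = 1..k_max` with the PseDNC
#' vector of [psednc_vector()]. The result has dimension
#' `sum(4^(1:k_max)) + 16 + omega`.
#'
#' @inheritParams psednc_vector
#' @param k_max highest k-mer tier. Default 5.
#' @return named numeric vector with names from [feature_layout()].
#' @examples
#' v <- encode_psenac("ACGTACGTACGTACGT", k_max = 2, omega = 2)
#' length(v) # 4 + 16 + 16 + 2 = 38
#' @export
encode_psenac <- function(seq, k_max = 5L, omega = 10L, w = 0.05,
                          table = dinuc_properties()) {
  seq <- toupper(seq)
  check_dna(seq)
  L <- nchar(seq)
  k_max <- as.integer(k_max)
  if (k_max < 1L) stop("k_max must be >= 1", call. = FALSE)
  if (L < k_max) {
    stop("Sequence length L = ", L, " is below k_max = ", k_max,
         call. = FALSE)
  }
  tiers <- unlist(lapply(seq_len(k_max), kmer_frequencies, seq = seq))
  pse <- psednc_vector(seq, omega = omega, w = w, table = table)
  lay <- feature_layout(k_max, omega)
  out <- c(tiers, pse)
  names(out) <- lay$names
  out
}

#' Encode a set of DNA sequences as a PseNAC feature matrix
#'
#' Applies [encode_psenac()] to every sequence and stacks the results.
#' The PseDNC rank cap is validated against the shortest sequence in the
#' set: `omega` may not exceed `min(length) - 2`, so every coupling
#' factor has at least one term for every sequence.
#'
#' @param seqs named character vector of DNA sequences (e.g. from
#'   [read_fasta()]).
#' @inheritParams encode_psenac
#' @return numeric matrix, one row per sequence (rownames = sequence
#'   ids, colnames = feature names), with the [feature_layout()] attached
#'   as attribute `"layout"`.
#' @examples
#' seqs <- c(s1 = "ACGTACGTACGTACGT", s2 = "AAAACCCCGGGGTTTT")
#' m <- encode_dataset(seqs, k_max = 2, omega = 2)
#' dim(m)
#' @export
encode_dataset <- function(seqs, k_max = 5L, omega = 10L, w = 0.05,
                           table = dinuc_properties()) {
  if (length(seqs) == 0L) stop("No sequences to encode", call. = FALSE)
  if (is.null(names(seqs)) || any(names(seqs) == "")) {
    names(seqs) <- paste0("seq", seq_along(seqs))
  }
  omega <- as.integer(omega)
  lens <- nchar(seqs)
  L_min <- min(lens)
  if (omega > L_min - 2L) {
    short <- names(seqs)[which.min(lens)]
    stop("omega = ", omega, " exceeds L_min - 2 = ", L_min - 2L,
         " (shortest sequence: '", short, "', length ", L_min, ")",
         call. = FALSE)
  }
  lay <- feature_layout(k_max, omega)
  rows <- t(vapply(seqs, encode_psenac, numeric(lay$dim),
                   k_max = k_max, omega = omega, w = w, table = table))
  dimnames(rows) <- list(names(seqs), lay$names)
  attr(rows, "layout") <- lay
  rows
}

#' Write / read a feature matrix as TSV
#'
#' The TSV has a header row of feature names and the sequence id in the
#' first column; an optional `label` column (+1 hotspot / -1 coldspot)
#' follows the id when labels are supplied.
#'
#' @param x feature matrix from [encode_dataset()].
#' @param path output path.
#' @param labels optional numeric labels (+1/-1), one per row.
#' @return `path` invisibly (write); list with `x` (matrix) and `labels`
#'   (numeric or NULL) (read).
#' @export
write_feature_tsv <- function(x, path, labels = NULL) {
  df <- data.frame(id = rownames(x), check.names = FALSE)
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(x))
    df$label <- labels
  }
  df <- cbind(df, as.data.frame(x, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_tsv
#' @export
read_feature_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("Feature TSV lacks an 'id' column",
                                 call. = FALSE)
  labels <- NULL
  drop <- "id"
  if ("label" %in% names(df)) {
    labels <- df$label
    drop <- c(drop, "label")
  }
  x <- as.matrix(df[, setdiff(names(df), drop), drop = FALSE])
  rownames(x) <- df$id
  list(x = x, labels = labels)
}
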