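#' Normalized dinucleotide structural property table
#'
#' Returns the packaged table of six normalized DNA dinucleotide structural
#' properties (twist, tilt, roll, shift, slide, rise) for all 16
#' dinucleotides, or reads a user-supplied table of the same shape. These
#' constants drive the physicochemical dissimilarity [delta()] underlying
#' the PseDNC sequence-order coupling factors.
#'
#' The packaged values are symmetric under reverse complementation (the
#' row for `AC` equals the row for `GT`, and so on), which the coupling
#' factors inherit.
#'
#' @param path optional path to a tab-separated table with a
#'   `dinucleotide` column followed by six numeric property columns. When
#'   `NULL` (default) the packaged constants are returned.
#' @return a 16 x 6 numeric matrix with dinucleotide rownames (A < C < G
#'   < T lexicographic order) and property colnames.
#' @examples
#' tab <- dinuc_properties()
#' tab["CG", ]
#' @export
dinuc_properties <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dinucleotide_properties.tsv",
                        package = "recspot", mustWork = TRUE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  expected <- c("dinucleotide", "twist", "tilt", "roll", "shift",
                "slide", "rise")
  if (!identical(names(df), expected)) {
    stop("Property table must have columns: ",
         paste(expected, collapse = ", "), call. = FALSE)
  }
  tab <- as.matrix(df[, -1L])
  rownames(tab) <- toupper(df$dinucleotide)
  dn <- all_kmers(2L)
  if (!setequal(rownames(tab), dn) || nrow(tab) != 16L) {
    stop("Property table must contain exactly the 16 dinucleotides",
         call. = FALSE)
  }
  tab <- tab[dn, , drop = FALSE]
  storage.mode(tab) <- "double"
  if (anyNA(tab)) stop("Property table contains missing values",
                       call. = FALSE)
  tab
}

#' Physicochemical dissimilarity between two dinucleotides
#'
#' The coupling-mode dissimilarity used by the PseDNC correlation factors:
#' the mean squared difference over the J = 6 normalized structural
#' properties,
#' \deqn{\Delta(d_1, d_2) = \frac{1}{J}\sum_{u=1}^{J}
#'   \left(V_u(d_1) - V_u(d_2)\right)^2.}
#' It is symmetric and zero for identical arguments; on the packaged
#' table it is also zero for reverse-complement-equivalent rows.
#'
#' @param d1,d2 dinucleotide strings, e.g. `"AC"`.
#' @param table property matrix from [dinuc_properties()].
#' @return non-negative scalar.
#' @examples
#' delta("AA", "CG")
#' delta("AC", "GT") # 0: packaged rows are identical
#' @export
delta <- function(d1, d2, table = dinuc_properties()) {
  d1 <- toupper(d1); d2 <- toupper(d2)
  missing <- setdiff(c(d1, d2), rownames(table))
  if (length(missing)) {
    stop("Unknown dinucleotide(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  mean((table[d1, ] - table[d2, ])^2)
}

# 16 x 16 matrix of delta values, precomputed once per encoding run.
delta_matrix <- function(table) {
  dn <- rownames(table)
  J <- ncol(table)
  g <- table %*% t(table)
  sq <- rowSums(table^2)
  m <- (outer(sq, sq, "+") - 2 * g) / J
  dimnames(m) <- list(dn, dn)
  # clamp tiny negative round-off on the diagonal
  m[m < 0] <- 0
  m
}

# All k-mers over A<C<G<T in lexicographic order.
all_kmers <- function(k) {
  bases <- c("A", "C", "G", "T")
  if (k == 1L) return(bases)
  grid <- expand.grid(rep(list(bases), k), stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest; reverse columns for
  # lexicographic order with the leftmost position most significant
  do.call(paste0, rev(grid))
}

revcomp <- function(d) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(d, "", fixed = TRUE),
         function(ch) paste(rev(unname(comp[ch])), collapse = ""),
         character(1))
}
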