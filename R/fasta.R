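#' Read DNA sequences from a FASTA file
#'
#' Reads a (possibly line-wrapped) multi-record FASTA file and returns the
#' sequences as an uppercase named character vector over the strict
#' A/C/G/T alphabet. Record identifiers are taken from the header line up
#' to the first whitespace.
#'
#' Records containing any character outside A/C/G/T (after case folding)
#' are rejected with an error naming the record and the offending
#' character, because silently dropping or recoding ambiguous bases would
#' corrupt the normalization of the downstream frequency features. With
#' `skip_invalid = TRUE` such records are dropped with a warning instead.
#'
#' @param path path to a FASTA file.
#' @param skip_invalid drop records with non-ACGT characters (with a
#'   warning) instead of failing. Default `FALSE`.
#' @return named character vector of uppercase sequences; names are the
#'   record identifiers.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1", "ACGTac", ">s2", "GGGTTT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path, skip_invalid = FALSE) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("FASTA file contains no records: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  bad <- vapply(seqs, function(s) {
    chars <- unique(strsplit(s, "", fixed = TRUE)[[1L]])
    offending <- setdiff(chars, c("A", "C", "G", "T"))
    if (length(offending)) offending[1L] else NA_character_
  }, character(1))
  invalid <- !is.na(bad)
  if (any(invalid)) {
    msg <- sprintf("record '%s' contains invalid character '%s'",
                   ids[invalid], bad[invalid])
    if (skip_invalid) {
      warning("Dropping ", sum(invalid), " record(s) with non-ACGT ",
              "characters: ", paste(msg, collapse = "; "), call. = FALSE)
      seqs <- seqs[!invalid]
      if (length(seqs) == 0L) {
        stop("All records were dropped as invalid: ", path, call. = FALSE)
      }
    } else {
      stop("Non-ACGT characters in FASTA input: ",
           paste(msg, collapse = "; "), call. = FALSE)
    }
  }
  seqs
}

#' Write DNA sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @param width line width for wrapping. Default 70.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), length(seqs) > 0L, !is.null(names(seqs)))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Validate one sequence string; used by encoders on direct (non-FASTA)
# character input.
check_dna <- function(seq, id = "<sequence>") {
  chars <- unique(strsplit(seq, "", fixed = TRUE)[[1L]])
  offending <- setdiff(chars, c("A", "C", "G", "T"))
  if (length(offending)) {
    stop("Sequence '", id, "' contains invalid character '",
         offending[1L], "'", call. = FALSE)
  }
  invisible(seq)
}
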