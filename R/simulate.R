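#' Configuration for synthetic hot/cold sequence datasets
#'
#' Describes a two-class sequence simulation with a planted
#' dinucleotide-composition signal. Coldspot sequences are i.i.d. draws
#' from the background base composition. Hotspot sequences are drawn
#' from a first-order Markov chain whose transition matrix up-weights
#' the dinucleotides making up the planted k-mers by their enrichment
#' factors, and optionally tilts the chain toward G/C ("GC shift"),
#' before row renormalization. A dinucleotide-level signal is the
#' natural planted effect here because every feature family the encoder
#' computes -- k-mer tiers and PseDNC coupling factors alike -- responds
#' to dinucleotide statistics, so the signal is detectable by the method
#' without being trivially separable.
#'
#' Default class sizes mirror the 490 hotspot / 591 coldspot balance of
#' the benchmark this method family is usually evaluated on, and default
#' lengths span 1,000-2,500 nt, the typical extent of a recombination
#' region.
#'
#' @param n_hot,n_cold class sizes. Defaults 490 and 591.
#' @param length_range integer vector `c(min_nt, max_nt)`; lengths are
#'   uniform on this range. Default `c(1000, 2500)`; minimum 12 nt.
#' @param background base probabilities for A, C, G, T; must sum to 1.
#'   Default uniform.
#' @param planted named numeric vector of enrichment factors, names are
#'   the planted k-mers (e.g. `c(CG = 3)`); factors must be positive.
#'   Factor 1 plants nothing. Default `c(CG = 3)`.
#' @param gc_shift additive tilt of the hot-class G+C weight; 0 for
#'   none. Default 0.
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @return object of class `"synthetic_config"` (a list of the above).
#' @export
synthetic_config <- function(n_hot = 490L, n_cold = 591L,
                             length_range = c(1000L, 2500L),
                             background = c(A = 0.25, C = 0.25,
                                            G = 0.25, T = 0.25),
                             planted = c(CG = 3),
                             gc_shift = 0, seed = 1L) {
  stopifnot(n_hot >= 1L, n_cold >= 1L, length(length_range) == 2L)
  length_range <- as.integer(length_range)
  if (length_range[1L] < 12L || length_range[2L] < length_range[1L]) {
    stop("length_range must satisfy 12 <= min <= max", call. = FALSE)
  }
  background <- background[c("A", "C", "G", "T")]
  if (anyNA(background) || abs(sum(background) - 1) > 1e-8 ||
      any(background < 0)) {
    stop("background must be probabilities for A, C, G, T summing to 1",
         call. = FALSE)
  }
  if (length(planted)) {
    if (is.null(names(planted)) ||
        !all(grepl("^[ACGT]+$", names(planted))) ||
        any(nchar(names(planted)) < 2L)) {
      stop("planted k-mers must be named A/C/G/T strings of length >= 2",
           call. = FALSE)
    }
    if (any(planted <= 0)) {
      stop("enrichment factors must be positive", call. = FALSE)
    }
  }
  if (abs(gc_shift) >= 1) stop("|gc_shift| must be < 1", call. = FALSE)
  structure(list(n_hot = as.integer(n_hot), n_cold = as.integer(n_cold),
                 length_range = length_range, background = background,
                 planted = planted, gc_shift = gc_shift,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Hot-class transition matrix: background composition up-weighted on the
# planted dinucleotides, tilted by gc_shift, rows renormalized.
hot_transition_matrix <- function(config) {
  bases <- c("A", "C", "G", "T")
  tm <- matrix(rep(config$background, each = 4L), 4L, 4L,
               dimnames = list(bases, bases))
  for (m in names(config$planted)) {
    fac <- config$planted[[m]]
    ch <- strsplit(m, "", fixed = TRUE)[[1L]]
    for (i in seq_len(length(ch) - 1L)) {
      tm[ch[i], ch[i + 1L]] <- tm[ch[i], ch[i + 1L]] * fac
    }
  }
  gc_mult <- c(A = 1 - config$gc_shift, C = 1 + config$gc_shift,
               G = 1 + config$gc_shift, T = 1 - config$gc_shift)
  tm <- sweep(tm, 2L, gc_mult, "*")
  rs <- rowSums(tm)
  if (any(rs <= 0) || !all(is.finite(rs))) {
    stop("Hot-class transition matrix has an unnormalizable row",
         call. = FALSE)
  }
  tm / rs
}

#' Generate a labeled synthetic hot/cold sequence dataset
#'
#' Draws `n_cold` coldspot sequences i.i.d. from the background
#' composition and `n_hot` hotspot sequences from the planted-signal
#' Markov chain of the configuration (see [synthetic_config()]).
#' Deterministic given `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @return list with `sequences` (named character vector, hot records
#'   first, ids `hot_1.. / cold_1..`), `labels` (+1 hot, -1 cold) and
#'   `config`.
#' @examples
#' d <- generate_dataset(synthetic_config(n_hot = 3, n_cold = 3,
#'                                        length_range = c(50, 60)))
#' nchar(d$sequences)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  bases <- c("A", "C", "G", "T")
  set.seed(config$seed)
  tm <- hot_transition_matrix(config)
  lens_hot <- sample(config$length_range[1L]:config$length_range[2L],
                     config$n_hot, replace = TRUE)
  lens_cold <- sample(config$length_range[1L]:config$length_range[2L],
                      config$n_cold, replace = TRUE)
  # step all hot-class chains in parallel: one vectorized draw per
  # position rather than one per (sequence, position)
  cum_tm <- t(apply(tm, 1L, cumsum))
  n_hot <- config$n_hot
  max_L <- max(lens_hot)
  states <- matrix(0L, n_hot, max_L)
  states[, 1L] <- sample.int(4L, n_hot, replace = TRUE,
                             prob = config$background)
  if (max_L > 1L) {
    for (i in 2:max_L) {
      u <- stats::runif(n_hot)
      prev <- states[, i - 1L]
      states[, i] <- 1L + (u > cum_tm[prev, 1L]) +
        (u > cum_tm[prev, 2L]) + (u > cum_tm[prev, 3L])
    }
  }
  hot <- vapply(seq_len(n_hot), function(r) {
    paste(bases[states[r, seq_len(lens_hot[r])]], collapse = "")
  }, character(1))
  cold <- vapply(lens_cold, function(L) {
    paste(sample(bases, L, replace = TRUE, prob = config$background),
          collapse = "")
  }, character(1))
  sequences <- c(hot, cold)
  names(sequences) <- c(paste0("hot_", seq_len(config$n_hot)),
                        paste0("cold_", seq_len(config$n_cold)))
  list(sequences = sequences,
       labels = c(rep(1, config$n_hot), rep(-1, config$n_cold)),
       config = config)
}

#' Write a synthetic dataset to disk
#'
#' Emits `hot.fasta`, `cold.fasta`, a `labels.tsv` (id, label) and a
#' `config.json` sidecar recording the full configuration including the
#' seed.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir` invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hot <- dataset$sequences[dataset$labels == 1]
  cold <- dataset$sequences[dataset$labels == -1]
  write_fasta(hot, file.path(dir, "hot.fasta"))
  write_fasta(cold, file.path(dir, "cold.fasta"))
  utils::write.table(
    data.frame(id = names(dataset$sequences), label = dataset$labels),
    file.path(dir, "labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- unclass(dataset$config)
  cfg$background <- as.list(cfg$background)
  cfg$planted <- as.list(cfg$planted)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
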