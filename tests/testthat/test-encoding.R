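test_that("k-mer frequencies match direct counting", {
  expect_equal(kmer_frequencies("ACGT", 1),
               c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  f2 <- kmer_frequencies("AAAA", 2)
  expect_equal(unname(f2["AA"]), 1)
  expect_equal(sum(f2), 1)
  expect_equal(sum(f2 != 0), 1L)
  # overlapping windows of ACGTACGT at k = 3: ACG x2, CGT x2, GTA, TAC
  f3 <- kmer_frequencies("ACGTACGT", 3)
  expect_equal(unname(f3[c("ACG", "CGT", "GTA", "TAC")]),
               c(2, 2, 1, 1) / 6)
  expect_equal(f3, oracle_kmer_freq("ACGTACGT", 3))
  expect_error(kmer_frequencies("ACG", 4), "k must satisfy")
})

test_that("k-mer blocks are simplex-normalized for random sequences", {
  set.seed(42)
  for (rep in 1:5) {
    s <- random_seq(sample(30:200, 1))
    for (k in 1:5) {
      f <- kmer_frequencies(s, k)
      expect_true(all(f >= 0))
      expect_equal(sum(f), 1, tolerance = 1e-9)
      expect_equal(f, oracle_kmer_freq(s, k))
    }
  }
})

test_that("delta is the mean squared property difference, symmetric, with
           reverse-complement degeneracy of the packaged table", {
  expect_equal(delta("AA", "AA"), 0)
  expect_equal(delta("AC", "GT"), 0)  # identical packaged rows
  expect_equal(delta("AA", "CG"), 2.3379)
  dn <- rownames(dinuc_properties())
  tab <- dinuc_properties()
  for (a in dn) for (b in dn) {
    expect_identical(delta(a, b, tab), delta(b, a, tab))
    rc <- function(d) chartr("ACGT", "TGCA",
                             paste(rev(strsplit(d, "")[[1]]),
                                   collapse = ""))
    expect_equal(delta(a, b, tab), delta(rc(b), rc(a), tab))
  }
  expect_error(delta("AN", "AA"), "Unknown dinucleotide")
})

test_that("correlation factors match the position-loop oracle", {
  expect_equal(correlation_factor("AAAA", 1), 0)
  expect_equal(correlation_factor("AAAA", 2), 0)
  for (j in 1:3) {
    expect_equal(correlation_factor("ACGTACGT", j),
                 oracle_corr_factor("ACGTACGT", j))
  }
  set.seed(7)
  s <- random_seq(60)
  for (j in c(1, 5, 10)) {
    expect_equal(correlation_factor(s, j), oracle_corr_factor(s, j))
  }
  expect_error(correlation_factor("ACGT", 3), "lag j")
})

test_that("PseDNC vectors are normalized and reduce correctly in limits", {
  # homopolymer: every coupling factor vanishes, all mass on AA
  v <- psednc_vector(strrep("A", 30), omega = 2, w = 0.05)
  expect_equal(unname(v["AA"]), 1)
  expect_equal(sum(v), 1)
  expect_equal(unname(v[c("lambda.1", "lambda.2")]), c(0, 0))
  # w = 0: exactly the dinucleotide composition plus zero pseudo-entries
  s <- "ACGTACGTACGTGGCC"
  v0 <- psednc_vector(s, omega = 3, w = 0)
  expect_equal(v0[1:16], kmer_frequencies(s, 2))
  expect_equal(unname(v0[17:19]), c(0, 0, 0))
  # compositional oracle
  expect_equal(unname(psednc_vector("ACGTACGTACGT", omega = 3, w = 0.05)),
               unname(oracle_psednc("ACGTACGTACGT", omega = 3, w = 0.05)))
  expect_error(psednc_vector("ACGT", omega = 5), "omega")
})

test_that("PseDNC normalization holds across omega and w", {
  set.seed(11)
  for (rep in 1:3) {
    s <- random_seq(sample(40:120, 1))
    for (omega in c(1, 4, 10)) {
      for (w in c(0, 0.05, 0.5)) {
        v <- psednc_vector(s, omega = omega, w = w)
        expect_length(v, 16 + omega)
        expect_true(all(v >= 0))
        expect_equal(sum(v), 1, tolerance = 1e-9)
      }
    }
  }
})

test_that("merged PseNAC vectors have the documented block structure", {
  lay <- feature_layout(k_max = 2, omega = 1)
  expect_equal(lay$dim, 4 + 16 + 16 + 1)
  expect_equal(feature_layout(5, 10)$dim, 4 + 16 + 64 + 256 + 1024 + 16 + 10)
  expect_identical(lay$blocks$kmer1, paste0("kmer1:", c("A", "C", "G", "T")))
  expect_identical(lay$blocks$kmer2[1:3],
                   c("kmer2:AA", "kmer2:AC", "kmer2:AG"))
  v <- encode_psenac("ACGTACGTACGTACGT", k_max = 2, omega = 2, w = 0)
  expect_length(v, 38)
  # with w = 0 the first 20 entries are exactly the two k-mer tiers
  expect_equal(unname(v[1:4]), unname(kmer_frequencies("ACGTACGTACGTACGT", 1)))
  expect_equal(unname(v[5:20]), unname(kmer_frequencies("ACGTACGTACGTACGT", 2)))
  expect_error(feature_layout(2, 0), "omega")
})

test_that("dataset encoding is deterministic and enforces the omega cap", {
  seqs <- c(a = "ACGTACGTACGTACGT", b = "ACGTACGTACGTACGT",
            c = "AAAACCCCGGGGTTTT")
  m <- encode_dataset(seqs, k_max = 2, omega = 3)
  expect_equal(m["a", ], m["b", ])  # identical sequences, identical rows
  expect_identical(rownames(m), c("a", "b", "c"))
  expect_s3_class(attr(m, "layout"), "feature_layout")
  expect_error(encode_dataset(character(0)), "No sequences")
  short <- c(long = strrep("ACGT", 10), tiny = "ACGTACG")
  expect_error(encode_dataset(short, k_max = 2, omega = 6), "tiny")
})

test_that("encoding ignores ids and FASTA line wrapping", {
  set.seed(3)
  s <- random_seq(150)
  fa1 <- withr::local_tempfile(fileext = ".fasta")
  fa2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(c(first = s), fa1, width = 60)
  write_fasta(c(other_name = s), fa2, width = 9)
  m1 <- encode_dataset(read_fasta(fa1), k_max = 3, omega = 5)
  m2 <- encode_dataset(read_fasta(fa2), k_max = 3, omega = 5)
  expect_equal(unname(m1[1, ]), unname(m2[1, ]))
})

test_that("feature matrix TSV round-trips with labels", {
  seqs <- c(a = strrep("ACGT", 8), b = strrep("AACG", 8))
  m <- encode_dataset(seqs, k_max = 2, omega = 2)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(m, f, labels = c(1, -1))
  back <- read_feature_tsv(f)
  expect_equal(back$labels, c(1, -1))
  expect_equal(unname(back$x), unname(m[, ]), tolerance = 1e-12)
  expect_identical(colnames(back$x), colnames(m))
})
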