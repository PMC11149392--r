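# Reference affine-gap alignment score: a plain-R three-state forward DP
# over full matrices, written independently of the package's banded C++
# implementation.
brute_force_align_score <- function(a, b, match = 2, mismatch = -3,
                                    open = 5, ext = 2) {
  av <- strsplit(a, "")[[1L]]; bv <- strsplit(b, "")[[1L]]
  n <- length(av); m <- length(bv)
  M <- matrix(-Inf, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -open - ext * i
  for (j in seq_len(m)) Y[1, j + 1] <- -open - ext * j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

test_that("HSP table enforces the alignment-statistics invariants", {
  row <- data.frame(qgene = "0", qiso = "0", sgene = "602", siso = "0",
                    bitscore = 1851, nident = 1073, length = 1114, gaps = 3)
  h <- hsp_table(row, "a", "b")
  expect_equal(nrow(h), 1L)
  expect_true(h$nident <= h$length - h$gaps)

  bad <- row; bad$nident <- 1200
  expect_error(hsp_table(bad, "a", "b"), "nident <= length - gaps")
  expect_error(hsp_table(row, "a", "a"), "must differ")
})

test_that("HSP tables round-trip through TSV with field mapping intact", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("qgene\tqiso\tsgene\tsiso\tbitscore\tnident\tlength\tgaps",
               "0\t0\t602\t0\t1851\t1073\t1114\t3"), p)
  h <- read_hsp_table(p, "a", "b")
  expect_equal(h$qgene, "0")
  expect_equal(h$sgene, "602")
  expect_equal(h$bitscore, 1851)
  expect_equal(h$nident, 1073)
  expect_equal(h$length, 1114)
  expect_equal(h$gaps, 3)

  # header-only file gives an empty table
  writeLines("qgene\tqiso\tsgene\tsiso\tbitscore\tnident\tlength\tgaps", p)
  expect_equal(nrow(read_hsp_table(p, "a", "b")), 0L)

  # invariant violations and non-numeric fields are rejected
  writeLines(c("qgene\tqiso\tsgene\tsiso\tbitscore\tnident\tlength\tgaps",
               "0\t0\t1\t0\t100\t600\t500\t0"), p)
  expect_error(read_hsp_table(p, "a", "b"), "nident")
  writeLines(c("qgene\tqiso\tsgene\tsiso\tbitscore\tnident\tlength\tgaps",
               "0\t0\t1\t0\txyz\t400\t500\t0"), p)
  expect_error(read_hsp_table(p, "a", "b"), "non-numeric")
})

test_that("built-in aligner reads exact statistics off the global alignment", {
  set.seed(21)
  s200 <- random_dna(200)
  t1 <- tiny_transcriptome(c("0.0" = s200), "a")
  t2 <- tiny_transcriptome(c("0.0" = s200), "b")
  h <- builtin_reciprocal(t1, t2)
  expect_equal(nrow(h$forward), 1L)
  expect_equal(h$forward$nident, 200)
  expect_equal(h$forward$length, 200)
  expect_equal(h$forward$gaps, 0)
  # reverse is the mirror
  expect_equal(h$reverse$nident, h$forward$nident)

  # unrelated sequences yield no HSP
  t3 <- tiny_transcriptome(c("0.0" = random_dna(300)), "c")
  t4 <- tiny_transcriptome(c("0.0" = random_dna(300)), "d")
  h2 <- builtin_reciprocal(t3, t4)
  expect_equal(nrow(h2$forward), 0L)
  expect_equal(nrow(h2$reverse), 0L)

  # 100 bp vs the same with a 5 bp deletion: lambda 100, gamma 5, iota 95
  a <- random_dna(100)
  b <- paste0(substr(a, 1, 40), substr(a, 46, 100))
  t5 <- tiny_transcriptome(c("0.0" = a), "e")
  t6 <- tiny_transcriptome(c("0.0" = b), "f")
  h3 <- builtin_reciprocal(t5, t6)
  expect_equal(h3$forward$length, 100)
  expect_equal(h3$forward$gaps, 5)
  expect_equal(h3$forward$nident, 95)
})

test_that("alignment scores match a brute-force DP on small cases", {
  set.seed(31)
  for (r in 1:25) {
    a <- random_dna(sample(4:12, 1))
    b <- if (r %% 2 == 0) random_dna(sample(4:12, 1)) else {
      v <- strsplit(a, "")[[1L]]
      v <- v[-sample(seq_along(v), min(3, length(v) - 1))]
      paste(v, collapse = "")
    }
    g <- orthoclique:::.gotoh_align_stats(a, b)
    expect_equal(g$score, brute_force_align_score(a, b), tolerance = 1e-12)
  }
})

test_that("alignment scores match Biostrings pairwiseAlignment on random pairs", {
  set.seed(41)
  sub <- matrix(-3, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                          c("A", "C", "G", "T", "N")))
  diag(sub) <- 2; sub["N", ] <- 0; sub[, "N"] <- 0
  for (r in 1:20) {
    a <- random_dna(sample(30:250, 1))
    b <- if (r %% 4 == 0) random_dna(sample(30:250, 1)) else {
      x <- mutate_seq(a, runif(1, 0, 0.3))
      if (r %% 3 == 0) x <- paste0(substr(x, 1, 20), substr(x, sample(22:28, 1), nchar(x)))
      x
    }
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = sub, gapOpening = 5, gapExtension = 2)
    g <- orthoclique:::.gotoh_align_stats(a, b)
    expect_equal(g$score, BiocGenerics::score(aln), tolerance = 1e-9)
  }
})

test_that("external BLASTn produces reciprocal HSP tables that pass the cutoff", {
  set.seed(51)
  seqs <- c("0.0" = random_dna(500), "1.0" = random_dna(400))
  t1 <- tiny_transcriptome(seqs, "a")
  t2 <- tiny_transcriptome(seqs, "b")
  wd <- tempfile("bl")
  h <- blastn_reciprocal(t1, t2, workdir = wd)
  expect_true(file.exists(file.path(wd, "a__vs__b.tsv")))
  self <- h$forward[h$forward$qgene == "0" & h$forward$sgene == "0", ]
  expect_equal(self$nident[1], 500)
  expect_equal(self$length[1], 500)
  expect_equal(self$gaps[1], 0)
  expect_true(all(h$forward$evalue <= 1e-99))

  # non-homologous inputs at the stringent cutoff: both tables empty
  t3 <- tiny_transcriptome(c("0.0" = random_dna(300)), "c")
  t4 <- tiny_transcriptome(c("0.0" = random_dna(300)), "d")
  h2 <- blastn_reciprocal(t3, t4)
  expect_equal(nrow(h2$forward), 0L)
  expect_equal(nrow(h2$reverse), 0L)

  # one substitution in 500 bp, checked against the global-alignment oracle
  a <- random_dna(500)
  v <- strsplit(a, "")[[1L]]
  v[250] <- setdiff(c("A", "C", "G", "T"), v[250])[1L]
  b <- paste(v, collapse = "")
  h3 <- blastn_reciprocal(tiny_transcriptome(c("0.0" = a), "e"),
                          tiny_transcriptome(c("0.0" = b), "f"))
  expect_equal(h3$forward$nident[1], 499)
  expect_equal(h3$forward$length[1], 500)
  g <- orthoclique:::.gotoh_align_stats(a, b)
  expect_equal(g$nident, 499)
  expect_equal(g$length, 500)
})

test_that("missing executables are reported by name", {
  expect_error(orthoclique:::run_tool("definitely-not-a-real-binary", "x"),
               "definitely-not-a-real-binary")
})
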