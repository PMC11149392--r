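mt_rows <- function(nident, length, gaps) {
  k <- length(nident)
  gene_match_table(data.frame(
    s1gene = as.character(seq_len(k)), s1iso = rep("0", k),
    s2gene = as.character(seq_len(k)), s2iso = rep("0", k),
    bitscore = rep(100, k), nident = nident, length = length, gaps = gaps),
    "a", "b")
}

test_that("similarity is summed identities over summed aligned bases", {
  one <- mt_rows(100, 100, 0)
  expect_identical(pair_similarity(one)$S, 1)
  expect_identical(pair_similarity(one)$D, 0)

  two <- mt_rows(c(90, 95), c(100, 100), c(0, 5))
  ps <- pair_similarity(two)
  expect_equal(ps$S, 185 / 195, tolerance = 1e-15)
  expect_equal(ps$D, 1 - 185 / 195, tolerance = 1e-15)
  expect_equal(ps$sum_ident, 185)
  expect_equal(ps$row_count, 2L)

  empty <- mt_rows(numeric(), numeric(), numeric())
  expect_error(pair_similarity(empty), "no comparable orthologs")
})

test_that("two-sample direct distance detects a single substitution", {
  set.seed(101)
  seqs <- setNames(vapply(1:10, function(i) random_dna(500), ""),
                   paste0(0:9, ".0"))
  t1 <- tiny_transcriptome(seqs, "a")
  mut <- seqs
  v <- strsplit(mut[[1]], "")[[1L]]
  v[100] <- setdiff(c("A", "C", "G", "T"), v[100])[1L]
  mut[[1]] <- paste(v, collapse = "")
  t2 <- tiny_transcriptome(mut, "b")
  D <- distance_matrix(list(t1, t2), n = 10, mode = "two_sample_direct",
                       aligner = "builtin")
  expect_equal(D["a", "b"], 1 - 4999 / 5000, tolerance = 1e-12)
  expect_equal(diag(D), c(a = 0, b = 0))
})

test_that("clone transcriptomes are at distance zero with zero diagonal", {
  set.seed(111)
  seqs <- setNames(vapply(1:8, function(i) random_dna(300), ""),
                   paste0(0:7, ".0"))
  clones <- lapply(c("c1", "c2", "c3"), function(id) tiny_transcriptome(seqs, id))
  D <- distance_matrix(clones, n = 8, aligner = "builtin")
  expect_true(all(D == 0))
  expect_equal(attr(D, "components")$n_ideal, 8L)
  expect_equal(attr(D, "metadata")$mode, "ideal_filtered")
})

test_that("genes missing an edge to any sample are excluded by ideal filtering", {
  set.seed(121)
  shared <- setNames(vapply(1:5, function(i) random_dna(300), ""),
                     paste0(0:4, ".0"))
  # gene 9 exists only in samples a and b
  ab_only <- c(shared, setNames(random_dna(300), "9.0"))
  t1 <- tiny_transcriptome(ab_only, "a")
  t2 <- tiny_transcriptome(ab_only, "b")
  t3 <- tiny_transcriptome(shared, "c")
  D <- distance_matrix(list(t1, t2, t3), n = 10, aligner = "builtin")
  expect_equal(attr(D, "components")$n_ideal, 5L)
  stats <- attr(D, "pair_stats")
  ab <- stats[[which(vapply(stats, function(x)
    x$sample1 == "a" && x$sample2 == "b", TRUE))]]
  # 5 genes, each contributing its tied forward and reverse rows; the
  # pair-only gene 9 does not contribute
  expect_equal(ab$row_count, 10L)
  expect_true(all(D == 0))
})

test_that("pipeline errors on pairs with no comparable orthologs", {
  set.seed(131)
  t1 <- tiny_transcriptome(c("0.0" = random_dna(300)), "a")
  t2 <- tiny_transcriptome(c("0.0" = random_dna(300)), "b")
  expect_error(distance_matrix(list(t1, t2), n = 1, aligner = "builtin"),
               "a / b")
})

test_that("orientation asymmetry is bounded on simulated data", {
  sim <- simulate_transcriptomes(sim_config(n_taxa = 4, n_transcripts = 60,
                                            seed = 7))
  D12 <- distance_matrix(sim$transcriptomes, n = 60, aligner = "builtin")
  D21 <- distance_matrix(rev(sim$transcriptomes), n = 60, aligner = "builtin")
  D21 <- D21[rownames(D12), colnames(D12)]
  gap <- abs(D12 - D21)
  expect_lt(max(gap), 10 * mean(D12[upper.tri(D12)]))
  # symmetrize = "mean" averages the two orientations
  Dm <- distance_matrix(sim$transcriptomes, n = 60, aligner = "builtin",
                        symmetrize = "mean")
  expect_true(all(abs(Dm - t(Dm)) < 1e-15))
})

test_that("k-mer Jaccard baseline matches hand/oracle computations", {
  set.seed(141)
  seqs <- setNames(vapply(1:4, function(i) random_dna(120), ""),
                   paste0(0:3, ".0"))
  same <- lapply(c("a", "b", "c"), function(id) tiny_transcriptome(seqs, id))
  D0 <- kmer_jaccard_matrix(same, k = 21)
  expect_true(all(D0 == 0))

  # hand example: 3 samples, short sequences, k = 3; oracle by enumeration
  s1 <- tiny_transcriptome(c("0.0" = "ACGTACGT"), "x")
  s2 <- tiny_transcriptome(c("0.0" = "ACGTAAAA"), "y")
  s3 <- tiny_transcriptome(c("0.0" = "CGTACGTT"), "z")
  D <- kmer_jaccard_matrix(list(s1, s2, s3), k = 3)
  want <- naive_jaccard(list("ACGTACGT", "ACGTAAAA", "CGTACGTT"), 3)
  expect_equal(unname(D), want, tolerance = 1e-15, ignore_attr = TRUE)

  # pairwise-disjoint k-mer universes degrade to distance 1 with a warning
  d1 <- tiny_transcriptome(c("0.0" = "AAAAAAAA"), "p")
  d2 <- tiny_transcriptome(c("0.0" = "CCCCCCCC"), "q")
  d3 <- tiny_transcriptome(c("0.0" = "ACACACAC"), "r")
  expect_warning(Dd <- kmer_jaccard_matrix(list(d1, d2, d3), k = 5),
                 "distance is reported as 1")
  expect_true(all(Dd[upper.tri(Dd)] == 1))

  expect_error(kmer_jaccard_matrix(list(s1, s2), k = 100), "longer than every")
})

test_that("k-mers are canonicalized over strands", {
  fwd <- tiny_transcriptome(c("0.0" = "ACGTTGCAGT"), "f")
  rc <- tiny_transcriptome(c("0.0" = "ACTGCAACGT"), "r")  # reverse complement
  other <- tiny_transcriptome(c("0.0" = "ACGTTGCAGA"), "o")
  D <- kmer_jaccard_matrix(list(fwd, rc, other), k = 5)
  expect_equal(D["f", "r"], 0)
})

test_that("hybrid mode filters to ideal genes before the Jaccard stage", {
  set.seed(151)
  seqs <- setNames(vapply(1:6, function(i) random_dna(250), ""),
                   paste0(0:5, ".0"))
  clones <- lapply(c("a", "b", "c"), function(id) tiny_transcriptome(seqs, id))
  Dh <- hybrid_ideal_then_jaccard(clones, n = 6, k = 21, aligner = "builtin")
  expect_true(all(Dh == 0))
  # all genes ideal: equals the plain Jaccard matrix on the full input
  Dj <- kmer_jaccard_matrix(clones, k = 21)
  expect_equal(unname(Dh), unname(Dj), ignore_attr = TRUE)
  # a gene family confined to one pair is excluded from the k-mer universe
  extra <- c(seqs, setNames(random_dna(250), "9.0"))
  mixed <- list(tiny_transcriptome(extra, "a"), tiny_transcriptome(extra, "b"),
                tiny_transcriptome(seqs, "c"))
  Dm <- hybrid_ideal_then_jaccard(mixed, n = 10, k = 21, aligner = "builtin")
  expect_true(all(Dm == 0))  # the ab-only gene no longer separates c
})

test_that("distance matrices serialize to TSV and PHYLIP", {
  D <- matrix(c(0, 0.1, 0.1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  attr(D, "metadata") <- list(n = 10, mode = "two_sample_direct")
  prefix <- tempfile("dm")
  paths <- write_distance_matrix(D, prefix)
  expect_true(all(file.exists(paths)))
  back <- as.matrix(read.table(paths[["tsv"]], header = TRUE, sep = "\t",
                               row.names = 1, check.names = FALSE))
  expect_equal(unname(back), unname(D), tolerance = 1e-12, ignore_attr = TRUE)
  phylip <- readLines(paths[["phylip"]])
  expect_match(phylip[1], "^\\s*2$")
})
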