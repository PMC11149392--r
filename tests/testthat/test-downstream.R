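dm <- function(m, ids) {
  dimnames(m) <- list(ids, ids)
  m
}

test_that("neighbor joining recovers an additive four-taxon tree", {
  # tree ((A:1,B:2):1,(C:3,D:4)): additive distances below
  D <- dm(matrix(c(0, 3, 5, 6,
                   3, 0, 6, 7,
                   5, 6, 0, 7,
                   6, 7, 7, 0), 4, 4, byrow = TRUE), c("A", "B", "C", "D"))
  # verify the input satisfies the four-point condition for split AB|CD
  sums <- c(D["A", "B"] + D["C", "D"], D["A", "C"] + D["B", "D"],
            D["A", "D"] + D["B", "C"])
  expect_lt(sums[1], sums[2])
  expect_equal(sums[2], sums[3])

  tr <- neighbor_joining(D)
  truth <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:4);")
  expect_equal(robinson_foulds(tr, truth), 0L)
  # additive input: path lengths reproduce the input distances
  cophen <- ape::cophenetic.phylo(tr)[c("A", "B", "C", "D"),
                                      c("A", "B", "C", "D")]
  expect_equal(unname(cophen), unname(D), tolerance = 1e-9)
})

test_that("neighbor joining handles 2 and 3 samples", {
  D2 <- dm(matrix(c(0, 0.4, 0.4, 0), 2, 2), c("x", "y"))
  t2 <- neighbor_joining(D2)
  expect_equal(length(t2$tip.label), 2L)
  expect_equal(sum(t2$edge.length), 0.4, tolerance = 1e-12)

  D3 <- dm(matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3, 3), c("x", "y", "z"))
  t3 <- neighbor_joining(D3)
  expect_equal(length(t3$tip.label), 3L)
  expect_equal(sum(t3$edge.length), 3, tolerance = 1e-12)

  expect_error(neighbor_joining(matrix(0, 2, 3)), "square")
})

test_that("neighbor joining agrees with the reference implementation", {
  set.seed(161)
  for (r in 1:10) {
    s <- sample(4:8, 1)
    # random tree-derived (nearly additive) distances plus small noise
    tr <- ape::rtree(s, br = function(n) runif(n, 0.5, 2))
    D <- ape::cophenetic.phylo(tr)
    D <- D + matrix(runif(s * s, 0, 0.01), s, s)
    D <- (D + t(D)) / 2
    diag(D) <- 0
    mine <- neighbor_joining(D)
    ref <- ape::nj(as.dist(D))
    expect_equal(as.numeric(phangorn::RF.dist(ape::unroot(mine),
                                              ape::unroot(ref))), 0)
  }
})

test_that("PCoA recovers Euclidean configurations and collinear spacings", {
  # all-zero matrix: all coordinates zero
  Z <- dm(matrix(0, 3, 3), c("a", "b", "c"))
  p0 <- pcoa(Z, dims = 2)
  expect_true(all(p0$points == 0))

  # collinear points 0, 1, 2: first axis recovers the spacing
  C3 <- dm(matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3), c("p", "q", "r"))
  p1 <- pcoa(C3, dims = 2)
  ax1 <- p1$points[, 1L]
  expect_equal(abs(diff(ax1)), c(1, 1), tolerance = 1e-9,
               ignore_attr = TRUE)

  # random Euclidean input: returned coordinates reproduce the distances
  set.seed(171)
  X <- matrix(rnorm(6 * 3), 6, 3)
  D <- as.matrix(dist(X))
  p2 <- pcoa(dm(D, paste0("s", 1:6)), dims = 5)
  back <- as.matrix(dist(p2$points))
  expect_equal(unname(back), unname(D), tolerance = 1e-9)
  expect_equal(p2$n_negative, 0L)

  # agreement with classical scaling in stats::cmdscale
  ref <- stats::cmdscale(D, k = 2)
  expect_equal(abs(unname(p2$points[, 1:2])), abs(unname(ref)),
               tolerance = 1e-9)

  expect_warning(pcoa(C3, dims = 5), "clamped")
})

test_that("Robinson-Foulds distance counts symmetric split differences", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(robinson_foulds(t1, t1), 0L)
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(robinson_foulds(t1, t2), 2L)

  # caterpillar vs balanced 6-leaf trees, value from exhaustive split listing:
  # caterpillar splits {AB, ABC, ABCD}, balanced {AB, CD, EF}; ABCD and EF
  # are complementary, so two splits are shared and two differ
  cat6 <- ape::read.tree(text = "(((((A,B),C),D),E),F);")
  bal6 <- ape::read.tree(text = "((A,B),(C,D),(E,F));")
  expect_equal(robinson_foulds(cat6, bal6), 2L)
  expect_equal(as.numeric(phangorn::RF.dist(ape::unroot(cat6),
                                            ape::unroot(bal6))), 2)

  expect_error(robinson_foulds(t1, ape::read.tree(text = "((A,B),(C,E));")),
               "identical leaf label sets")
})

test_that("Robinson-Foulds agrees with the reference on random trees", {
  set.seed(181)
  for (r in 1:15) {
    s <- sample(4:10, 1)
    ta <- ape::rtree(s)
    tb <- ape::rtree(s)
    tb$tip.label <- sample(ta$tip.label)
    expect_equal(robinson_foulds(ta, tb),
                 as.numeric(phangorn::RF.dist(ape::unroot(ta),
                                              ape::unroot(tb))))
  }
})

test_that("prefix sweeps produce nested subsets with non-increasing ideal counts", {
  sim <- simulate_transcriptomes(sim_config(n_taxa = 5, n_transcripts = 60,
                                            seed = 47))
  sw <- sweep_components(sim$transcriptomes, n_values = 60,
                         subset_strategy = "prefix",
                         permutation = seq_along(sim$transcriptomes),
                         aligner = "builtin")
  expect_equal(sw$s, 2:5)
  expect_true(all(diff(sw$n_ideal) <= 0))
  expect_true(all(sw$n_ideal <= sw$n_large))
  # each subset extends the previous one
  subsets <- strsplit(sw$subset, ",")
  for (i in seq_len(length(subsets) - 1L)) {
    expect_true(all(subsets[[i]] %in% subsets[[i + 1L]]))
  }
  expect_error(sweep_components(sim$transcriptomes, 60,
                                subset_strategy = "prefix",
                                permutation = 1:9),
               "prefix")
})

test_that("all and fair sweep strategies cover the requested cells", {
  sim <- simulate_transcriptomes(sim_config(n_taxa = 4, n_transcripts = 40,
                                            seed = 53))
  one <- sweep_components(sim$transcriptomes, n_values = 40,
                          subset_strategy = "all", aligner = "builtin")
  expect_equal(nrow(one), 1L)
  expect_equal(one$s, 4L)

  fair <- sweep_components(sim$transcriptomes, n_values = 40,
                           subset_strategy = "fair",
                           max_trials_per_size = 2L, seed = 9,
                           aligner = "builtin")
  expect_true(all(fair$s %in% 2:4))
  expect_true(all(table(fair$s) <= 2L))
  # subsets of each size are distinct
  for (sz in unique(fair$s)) {
    expect_false(anyDuplicated(fair$subset[fair$s == sz]) > 0)
  }
  expect_error(sweep_components(sim$transcriptomes, 40,
                                subset_strategy = "fair"),
               "time_budget")
})
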