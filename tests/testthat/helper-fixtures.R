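# Fixtures and independent oracles shared across test files. Everything is
# generated in code; no binary fixtures.

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Point-mutate a sequence at per-site probability p (substitutions only).
mutate_seq <- function(s, p) {
  v <- strsplit(s, "")[[1L]]
  hit <- stats::runif(length(v)) < p
  if (any(hit)) {
    v[hit] <- vapply(v[hit], function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  }
  paste(v, collapse = "")
}

# A tiny transcriptome from a named character vector of sequences
# ("gene/isotig" names like "0.0", "0.1", "3.0"); coverage defaults to 10.
tiny_transcriptome <- function(seqs, sample, coverage = NULL) {
  gi <- strsplit(names(seqs), ".", fixed = TRUE)
  genes <- vapply(gi, `[`, "", 1L)
  isos <- vapply(gi, `[`, "", 2L)
  if (is.null(coverage)) coverage <- rep(10, length(seqs))
  transcriptome(data.frame(
    record_id = sprintf("NODE_%d_length_%d_cov_%f_g%s_i%s",
                        seq_along(seqs), nchar(seqs), coverage, genes, isos),
    gene_id = genes, isotig_id = isos, kmer_coverage = coverage,
    sequence = unname(seqs), stringsAsFactors = FALSE), sample)
}

# Random HSP table over small gene/isotig universes, for oracle comparisons.
random_hsp_table <- function(qs, ss, n_rows, n_genes = 6L, n_isos = 2L) {
  if (n_rows == 0L) {
    return(hsp_table(data.frame(qgene = character(), qiso = character(),
                                sgene = character(), siso = character(),
                                bitscore = numeric(), nident = numeric(),
                                length = numeric(), gaps = numeric()), qs, ss))
  }
  len <- sample(50:500, n_rows, replace = TRUE)
  gaps <- pmin(sample(0:20, n_rows, replace = TRUE), len - 1L)
  nident <- floor((len - gaps) * stats::runif(n_rows, 0.5, 1))
  hsp_table(data.frame(
    qgene = as.character(sample.int(n_genes, n_rows, replace = TRUE) - 1L),
    qiso = as.character(sample.int(n_isos, n_rows, replace = TRUE) - 1L),
    sgene = as.character(sample.int(n_genes, n_rows, replace = TRUE) - 1L),
    siso = as.character(sample.int(n_isos, n_rows, replace = TRUE) - 1L),
    bitscore = round(stats::runif(n_rows, 1, 1000),
                     sample(0:1, n_rows, replace = TRUE)),  # some exact ties
    nident = nident, length = len, gaps = gaps,
    stringsAsFactors = FALSE), qs, ss)
}

# Literal brute-force reduction of a forward/reverse HSP table pair:
# enumerates every (s1gene, s2gene) pair and applies the definitions
# directly, with no shared code with the production pipeline.
brute_force_match_table <- function(forward, reverse, N = 1L) {
  top_n <- function(df, N) {
    keep <- rep(FALSE, nrow(df))
    for (g in unique(df$qgene)) {
      idx <- which(df$qgene == g)
      b <- sort(df$bitscore[idx], decreasing = TRUE)
      thr <- b[min(N, length(b))]
      keep[idx[df$bitscore[idx] >= thr]] <- TRUE
    }
    df[keep, , drop = FALSE]
  }
  f <- top_n(as.data.frame(forward), N)
  r <- top_n(as.data.frame(reverse), N)
  f2 <- data.frame(s1gene = f$qgene, s1iso = f$qiso, s2gene = f$sgene,
                   s2iso = f$siso, bitscore = f$bitscore, nident = f$nident,
                   length = f$length, gaps = f$gaps)
  r2 <- data.frame(s1gene = r$sgene, s1iso = r$siso, s2gene = r$qgene,
                   s2iso = r$qiso, bitscore = r$bitscore, nident = r$nident,
                   length = r$length, gaps = r$gaps)
  out <- NULL
  for (g1 in unique(c(f2$s1gene, r2$s1gene))) {
    for (g2 in unique(c(f2$s2gene, r2$s2gene))) {
      in_f <- f2[f2$s1gene == g1 & f2$s2gene == g2, , drop = FALSE]
      in_r <- r2[r2$s1gene == g1 & r2$s2gene == g2, , drop = FALSE]
      if (nrow(in_f) > 0L && nrow(in_r) > 0L) {
        both <- rbind(in_f, in_r)
        out <- rbind(out, both[both$bitscore == max(both$bitscore), , drop = FALSE])
      }
    }
  }
  if (is.null(out) || nrow(out) == 0L) {
    return(data.frame(s1gene = character(), s1iso = character(),
                      s2gene = character(), s2iso = character(),
                      bitscore = numeric(), nident = numeric(),
                      length = numeric(), gaps = numeric()))
  }
  best <- NULL
  for (g1 in unique(out$s1gene)) {
    rows <- out[out$s1gene == g1, , drop = FALSE]
    best <- rbind(best, rows[rows$bitscore == max(rows$bitscore), , drop = FALSE])
  }
  best
}

# Canonical form for comparing match tables regardless of row order.
canonical_rows <- function(df) {
  df <- as.data.frame(df)[, c("s1gene", "s1iso", "s2gene", "s2iso",
                              "bitscore", "nident", "length", "gaps")]
  df <- df[do.call(order, df), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Random graph over (sample, gene) vertices with no intra-sample edges,
# returned as match tables (one per sample pair) for build_match_graph.
random_match_tables <- function(n_samples, genes_per_sample, edge_prob) {
  ids <- paste0("S", seq_len(n_samples))
  tables <- list()
  for (i in seq_len(n_samples - 1L)) {
    for (j in (i + 1L):n_samples) {
      pairs <- expand.grid(g1 = seq_len(genes_per_sample) - 1L,
                           g2 = seq_len(genes_per_sample) - 1L)
      pairs <- pairs[stats::runif(nrow(pairs)) < edge_prob, , drop = FALSE]
      np <- nrow(pairs)
      rows <- data.frame(s1gene = as.character(pairs$g1), s1iso = rep("0", np),
                         s2gene = as.character(pairs$g2), s2iso = rep("0", np),
                         bitscore = rep(100, np), nident = rep(90, np),
                         length = rep(100, np), gaps = rep(0, np),
                         stringsAsFactors = FALSE)
      tables[[length(tables) + 1L]] <- gene_match_table(rows, ids[i], ids[j])
    }
  }
  list(tables = tables, sample_ids = ids)
}

# Naive component classifier: adjacency-matrix reachability plus an
# all-pairs completeness probe (the spec's test oracle for classify).
naive_classify <- function(tables, sample_ids) {
  verts <- character()
  edges <- list()
  for (t in tables) {
    df <- as.data.frame(t)
    if (nrow(df) == 0L) next
    v1 <- paste(attr(t, "sample1"), df$s1gene, sep = "\t")
    v2 <- paste(attr(t, "sample2"), df$s2gene, sep = "\t")
    verts <- c(verts, v1, v2)
    edges[[length(edges) + 1L]] <- cbind(v1, v2)
  }
  verts <- sort(unique(verts))
  nv <- length(verts)
  if (nv == 0L) {
    return(list(n_small = 0L, n_large = 0L, n_ideal = 0L))
  }
  A <- matrix(FALSE, nv, nv, dimnames = list(verts, verts))
  for (e in edges) {
    A[cbind(e[, 1L], e[, 2L])] <- TRUE
    A[cbind(e[, 2L], e[, 1L])] <- TRUE
  }
  # reachability by repeated boolean multiplication
  R <- A | diag(nv)
  repeat {
    R2 <- (R %*% R) > 0
    if (identical(R2, R)) break
    R <- R2
  }
  comp_of <- match(apply(R, 1L, function(r) paste(which(r), collapse = ",")),
                   unique(apply(R, 1L, function(r) paste(which(r), collapse = ","))))
  s <- length(sample_ids)
  n_small <- n_large <- n_ideal <- 0L
  for (cid in unique(comp_of)) {
    members <- which(comp_of == cid)
    size <- length(members)
    if (size < s) { n_small <- n_small + 1L; next }
    n_large <- n_large + 1L
    complete <- all(A[members, members][upper.tri(diag(size))])
    samples <- sub("\t.*", "", verts[members])
    if (size == s && complete) {
      # the one-gene-per-sample equivalence must hold by construction
      stopifnot(setequal(samples, sample_ids), !anyDuplicated(samples))
      n_ideal <- n_ideal + 1L
    }
  }
  list(n_small = n_small, n_large = n_large, n_ideal = n_ideal)
}

# Exhaustive k-mer Jaccard oracle (no canonicalization shortcuts: builds
# both strands explicitly via chartr-based reverse complement).
naive_jaccard <- function(seq_sets, k) {
  rc <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1L]]), collapse = ""))
  kset <- function(seqs) {
    out <- character()
    for (s in seqs) {
      if (nchar(s) < k) next
      for (i in seq_len(nchar(s) - k + 1L)) {
        km <- substr(s, i, i + k - 1L)
        out <- c(out, min(km, rc(km)))
      }
    }
    unique(out)
  }
  sets <- lapply(seq_sets, kset)
  counts <- table(unlist(sets))
  V <- names(counts)[counts >= 2L]
  sets <- lapply(sets, intersect, V)
  n <- length(sets)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      u <- length(union(sets[[i]], sets[[j]]))
      D[i, j] <- D[j, i] <- if (u == 0L) 1 else
        1 - length(intersect(sets[[i]], sets[[j]])) / u
    }
  }
  D
}
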