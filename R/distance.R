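# Similarity/distance statistic and whole-matrix assembly, plus the k-mer
# Jaccard baseline and the hybrid (ideal-filter then Jaccard) mode.

#' Similarity and distance for one gene match table
#'
#' The similarity between two samples is the ratio of summed identical bases
#' to summed aligned bases over all retained match rows,
#' `S = sum(nident) / (sum(length) - sum(gaps))`, and the distance is
#' `D = 1 - S`. Both are dimensionless ratios of base pairs.
#'
#' @param t a [gene_match_table]; must be non-empty (with no comparable
#'   orthologs the statistic is undefined and an error is raised, never 0).
#' @return List with `S`, `D`, and the aggregates `sum_ident`, `sum_length`,
#'   `sum_gaps`, `row_count`.
#' @export
pair_similarity <- function(t) {
  stopifnot(inherits(t, "gene_match_table"))
  if (nrow(t) == 0L) {
    stop("no comparable orthologs between '", attr(t, "sample1"), "' and '",
         attr(t, "sample2"), "': similarity is undefined for an empty match table")
  }
  sum_ident <- sum(t$nident)
  sum_length <- sum(t$length)
  sum_gaps <- sum(t$gaps)
  S <- sum_ident / (sum_length - sum_gaps)
  list(S = S, D = 1 - S, sum_ident = sum_ident, sum_length = sum_length,
       sum_gaps = sum_gaps, row_count = nrow(t))
}

# All unordered sample pairs in input order: sample i (i < j) takes the
# sample-1 role for entry (i, j).
sample_pairs <- function(sample_ids) {
  pr <- utils::combn(length(sample_ids), 2L)
  data.frame(i = pr[1L, ], j = pr[2L, ])
}

# Compute gene match tables for every unordered pair of (already top-n
# selected) transcriptomes.
all_match_tables <- function(selected, N = 1L, aligner = "builtin",
                             evalue_cutoff = 1e-99, min_identity_fraction = 0.7,
                             dedupe_ties = FALSE, workdir = NULL,
                             seed_filter = TRUE, seed_k = 12L, ...) {
  ids <- vapply(selected, sample_id, "")
  pairs <- sample_pairs(ids)
  # per-sample seed indexes are reused across all pairs
  indexes <- if (aligner == "builtin" && isTRUE(seed_filter)) {
    lapply(selected, seed_kmer_index, k = as.integer(seed_k))
  } else {
    vector("list", length(selected))
  }
  tables <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    h <- if (aligner == "blastn") {
      pair_hsps(selected[[i]], selected[[j]], aligner = "blastn",
                evalue_cutoff = evalue_cutoff, workdir = workdir)
    } else {
      builtin_reciprocal(selected[[i]], selected[[j]],
                         min_identity_fraction = min_identity_fraction,
                         seed_filter = seed_filter, seed_k = seed_k,
                         seed_index = list(indexes[[i]], indexes[[j]]), ...)
    }
    tables[[r]] <- match_table(h$forward, h$reverse, N = N,
                               dedupe_ties = dedupe_ties)
  }
  tables
}

#' Pairwise distance matrix for a set of transcriptomes
#'
#' Orchestrates the full method: per-sample top-n gene selection, reciprocal
#' HSP generation, reduction to gene match tables, and (for three or more
#' samples by default) gene-matches-graph construction with ideal-component
#' filtering, so every retained gene has exactly one ortholog in every
#' sample. Entry (i, j) with i earlier in the input order is computed with
#' sample i in the sample-1 role; the diagonal is 0 by convention.
#'
#' @param samples list of [transcriptome] objects (at least two, distinct
#'   sample ids); their order fixes the matrix order and pair orientation.
#' @param n number of top genes selected per sample by k-mer coverage.
#' @param N top HSPs retained per query gene.
#' @param evalue_cutoff BLAST e-value cutoff (blastn aligner).
#' @param mode `"auto"` (ideal filtering for s >= 3, direct for s = 2),
#'   `"ideal_filtered"`, or `"two_sample_direct"` (exactly 2 samples).
#' @param aligner `"builtin"` or `"blastn"`.
#' @param min_identity_fraction identity threshold for the builtin aligner.
#' @param dedupe_ties collapse tied match rows (see [match_table()]).
#' @param symmetrize `"none"` (default) or `"mean"`: with `"mean"` each
#'   unordered pair is computed in both orientations and averaged.
#' @param workdir directory for BLAST intermediates (blastn aligner).
#' @param ... further arguments to [builtin_reciprocal()].
#' @return A square numeric matrix of distances in `[0, 1]` with sample ids
#'   as dimnames and attributes `components` (component counts; `NULL` in
#'   direct mode), `pair_stats` (per-pair aggregates), and `metadata`.
#' @export
distance_matrix <- function(samples, n = 50000L, N = 1L, evalue_cutoff = 1e-99,
                            mode = c("auto", "ideal_filtered", "two_sample_direct"),
                            aligner = c("builtin", "blastn"),
                            min_identity_fraction = 0.7, dedupe_ties = FALSE,
                            symmetrize = c("none", "mean"), workdir = NULL, ...) {
  mode <- match.arg(mode)
  aligner <- match.arg(aligner)
  symmetrize <- match.arg(symmetrize)
  stopifnot(is.list(samples), length(samples) >= 2L)
  ids <- vapply(samples, sample_id, "")
  if (anyDuplicated(ids)) stop("sample ids must be distinct")
  s <- length(ids)
  if (mode == "auto") mode <- if (s == 2L) "two_sample_direct" else "ideal_filtered"
  if (mode == "two_sample_direct" && s != 2L) {
    stop("mode 'two_sample_direct' requires exactly 2 samples")
  }

  selected <- lapply(samples, select_top_genes, n = n)
  tables <- all_match_tables(selected, N = N, aligner = aligner,
                             evalue_cutoff = evalue_cutoff,
                             min_identity_fraction = min_identity_fraction,
                             dedupe_ties = dedupe_ties, workdir = workdir, ...)
  components <- NULL
  if (mode == "ideal_filtered") {
    g <- build_match_graph(tables, ids)
    cls <- classify_components(g)
    pairs_ideal <- ideal_gene_pairs(g, cls)
    tables <- lapply(tables, filter_to_ideal, pairs = pairs_ideal)
    components <- cls[c("n_small", "n_large", "n_ideal", "n_large_nonideal")]
  }

  pairs <- sample_pairs(ids)
  empty <- vapply(tables, nrow, 0L) == 0L
  if (any(empty)) {
    bad <- pairs[empty, , drop = FALSE]
    stop("no comparable orthologs for sample pair(s): ",
         paste(paste(ids[bad$i], ids[bad$j], sep = " / "), collapse = "; "))
  }

  D <- matrix(0, s, s, dimnames = list(ids, ids))
  stats <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    ps <- pair_similarity(tables[[r]])
    d <- ps$D
    if (symmetrize == "mean") {
      # recompute with roles swapped and average both orientations
      i <- pairs$i[r]; j <- pairs$j[r]
      h <- pair_hsps(selected[[j]], selected[[i]], aligner = aligner,
                     evalue_cutoff = evalue_cutoff,
                     min_identity_fraction = min_identity_fraction,
                     workdir = workdir, ...)
      t_rev <- match_table(h$forward, h$reverse, N = N, dedupe_ties = dedupe_ties)
      if (mode == "ideal_filtered") t_rev <- filter_to_ideal(t_rev, pairs_ideal)
      d <- mean(c(d, pair_similarity(t_rev)$D))
    }
    D[pairs$i[r], pairs$j[r]] <- d
    D[pairs$j[r], pairs$i[r]] <- d
    stats[[r]] <- c(list(sample1 = ids[pairs$i[r]], sample2 = ids[pairs$j[r]]), ps)
  }
  structure(D,
            components = components,
            pair_stats = stats,
            metadata = list(n = n, N = N, evalue_cutoff = evalue_cutoff,
                            mode = mode, aligner = aligner,
                            min_identity_fraction = min_identity_fraction,
                            symmetrize = symmetrize))
}

#' Gene matches graph component counts for a set of transcriptomes
#'
#' Runs the pipeline through graph construction and classification without
#' computing distances (usable even when no ideal components remain).
#'
#' @inheritParams distance_matrix
#' @return List with `n_small`, `n_large`, `n_ideal`, `n_large_nonideal`.
#' @export
component_counts <- function(samples, n = 50000L, N = 1L, evalue_cutoff = 1e-99,
                             aligner = c("builtin", "blastn"),
                             min_identity_fraction = 0.7, workdir = NULL, ...) {
  aligner <- match.arg(aligner)
  ids <- vapply(samples, sample_id, "")
  selected <- lapply(samples, select_top_genes, n = n)
  tables <- all_match_tables(selected, N = N, aligner = aligner,
                             evalue_cutoff = evalue_cutoff,
                             min_identity_fraction = min_identity_fraction,
                             workdir = workdir, ...)
  cls <- classify_components(build_match_graph(tables, ids))
  cls[c("n_small", "n_large", "n_ideal", "n_large_nonideal")]
}

# Canonical k-mer enumeration: each k-mer is represented by the
# lexicographic minimum of itself and its reverse complement, so strand does
# not matter.
canonical_kmers <- function(sequences, k) {
  n <- nchar(sequences)
  use <- n >= k
  if (!any(use)) return(character())
  seqs <- sequences[use]
  n <- n[use]
  idx <- rep.int(seq_along(seqs), n - k + 1L)
  starts <- unlist(lapply(n - k + 1L, seq_len), use.names = FALSE)
  km <- unique(substring(seqs[idx], starts, starts + k - 1L))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
  unique(pmin(km, rc))
}

#' Alignment-free k-mer Jaccard distance matrix
#'
#' The baseline distance: with `V` the set of canonical k-mers present in at
#' least two samples, the distance between samples i and j is one minus the
#' Jaccard similarity of their k-mer sets intersected with `V`. With only two
#' samples the filtered sets coincide and all distances are 0, so at least
#' three samples are needed for a non-degenerate result. Pairs whose filtered
#' union is empty get distance 1 with a warning.
#'
#' @param samples list of [transcriptome] objects.
#' @param k k-mer length (default 21); k-mers are canonicalized over strands.
#' @return Square distance matrix with `metadata` attribute.
#' @export
kmer_jaccard_matrix <- function(samples, k = 21L) {
  stopifnot(is.list(samples), length(samples) >= 2L, k >= 1L)
  k <- as.integer(k)
  ids <- vapply(samples, sample_id, "")
  if (anyDuplicated(ids)) stop("sample ids must be distinct")
  if (all(vapply(samples, function(t) all(nchar(t$sequence) < k), TRUE))) {
    stop("k = ", k, " is longer than every input sequence")
  }
  sets <- lapply(samples, function(t) canonical_kmers(t$sequence, k))
  counts <- table(unlist(lapply(sets, unique), use.names = FALSE))
  shared <- names(counts)[counts >= 2L]
  sets <- lapply(sets, intersect, shared)

  s <- length(ids)
  D <- matrix(0, s, s, dimnames = list(ids, ids))
  degenerate <- FALSE
  pr <- sample_pairs(ids)
  for (r in seq_len(nrow(pr))) {
    a <- sets[[pr$i[r]]]; b <- sets[[pr$j[r]]]
    u <- length(union(a, b))
    d <- if (u == 0L) { degenerate <- TRUE; 1 } else 1 - length(intersect(a, b)) / u
    D[pr$i[r], pr$j[r]] <- d
    D[pr$j[r], pr$i[r]] <- d
  }
  if (degenerate) {
    warning("some sample pairs share no k-mers with the filtered universe; ",
            "their distance is reported as 1")
  }
  structure(D, metadata = list(k = k, mode = "kmer_jaccard"))
}

#' Hybrid mode: ideal-component filtering, then k-mer Jaccard
#'
#' Restricts each sample's transcripts to genes lying in ideal components of
#' the gene matches graph, then computes the k-mer Jaccard matrix on the
#' restricted transcriptomes. This removes paralogous gene families from the
#' k-mer universe before the alignment-free comparison.
#'
#' @inheritParams distance_matrix
#' @param k k-mer length for the Jaccard stage.
#' @return Square distance matrix with `metadata` attribute.
#' @export
hybrid_ideal_then_jaccard <- function(samples, n = 50000L, N = 1L,
                                      evalue_cutoff = 1e-99, k = 21L,
                                      aligner = c("builtin", "blastn"),
                                      min_identity_fraction = 0.7,
                                      workdir = NULL, ...) {
  aligner <- match.arg(aligner)
  ids <- vapply(samples, sample_id, "")
  selected <- lapply(samples, select_top_genes, n = n)
  tables <- all_match_tables(selected, N = N, aligner = aligner,
                             evalue_cutoff = evalue_cutoff,
                             min_identity_fraction = min_identity_fraction,
                             workdir = workdir, ...)
  g <- build_match_graph(tables, ids)
  cls <- classify_components(g)
  if (cls$n_ideal == 0L) stop("no ideal components: hybrid mode has no genes to keep")
  keep <- split(igraph::V(g)$gene[cls$membership %in% which(cls$class == "ideal")],
                igraph::V(g)$sample[cls$membership %in% which(cls$class == "ideal")])
  restricted <- lapply(selected, function(t) {
    genes <- keep[[sample_id(t)]]
    df <- as.data.frame(t)[t$gene_id %in% genes, , drop = FALSE]
    transcriptome(df, sample_id(t))
  })
  out <- kmer_jaccard_matrix(restricted, k = k)
  meta <- attr(out, "metadata")
  meta$mode <- "hybrid_ideal_then_jaccard"
  meta$n <- n; meta$N <- N; meta$evalue_cutoff <- evalue_cutoff
  attr(out, "metadata") <- meta
  out
}

#' Write a distance matrix as TSV and PHYLIP
#'
#' @param D square distance matrix with dimnames.
#' @param prefix output prefix; writes `<prefix>.tsv` (square, header row and
#'   column), `<prefix>.phylip` (square PHYLIP), and `<prefix>_metadata.txt`.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_distance_matrix <- function(D, prefix) {
  tsv <- paste0(prefix, ".tsv")
  phy <- paste0(prefix, ".phylip")
  meta_path <- paste0(prefix, "_metadata.txt")
  utils::write.table(data.frame(sample = rownames(D), D, check.names = FALSE),
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  con <- file(phy, "w")
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D))) {
    writeLines(paste(formatC(rownames(D)[i], width = -10),
                     paste(sprintf("%.10f", D[i, ]), collapse = " ")), con)
  }
  close(con)
  meta <- attr(D, "metadata")
  if (is.null(meta)) meta <- list()
  writeLines(c(paste0("generated_by: orthoclique ",
                      as.character(utils::packageVersion("orthoclique"))),
               vapply(names(meta), function(nm) {
                 paste0(nm, ": ", paste(format(meta[[nm]]), collapse = " "))
               }, "")), meta_path)
  invisible(c(tsv = tsv, phylip = phy, metadata = meta_path))
}
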