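# Synthetic-data generator: a birth-death phylogeny with a known topology,
# random root transcripts, substitution-only HKY85 evolution along the tree,
# and per-taxon transcriptome FASTA emission with ground truth. This is the
# validation harness: if the method works, distances computed from the
# emitted transcriptomes must recover the generating tree.

#' Simulation configuration
#'
#' Defaults reproduce the validation design: a birth-death tree (birth rate
#' 1, death rate 0.5) grown until exactly 16 extant taxa, 50000 root
#' transcripts with bases drawn uniformly, and HKY85 evolution at rate 0.01
#' expected substitutions per site per unit branch length.
#'
#' @param birth_rate,death_rate birth-death rates per lineage per unit time.
#' @param n_taxa number of extant taxa to stop at.
#' @param n_transcripts number of simulated genes (one transcript each).
#' @param site_rate expected substitutions per site per unit branch length.
#' @param kappa HKY85 transition/transversion rate ratio.
#' @param base_freqs equilibrium base frequencies (A, C, G, T), summing to 1.
#' @param length_distribution transcript length sampler: `NULL` for the
#'   built-in log-normal (median 500 bp, sdlog 0.6, floor 200 bp, mimicking
#'   an assembled-transcriptome length spread), a numeric vector of lengths
#'   sampled uniformly, or a data frame with columns `length` and `weight`.
#' @param coverage_range range of synthetic per-isotig k-mer coverage values,
#'   drawn log-uniformly, so top-n gene selection is exercised downstream.
#' @param seed integer seed; all stages draw from named substreams derived
#'   from it, so each stage is independently reproducible.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(birth_rate = 1, death_rate = 0.5, n_taxa = 16L,
                       n_transcripts = 50000L, site_rate = 0.01, kappa = 3.0,
                       base_freqs = rep(0.25, 4), length_distribution = NULL,
                       coverage_range = c(1, 1000), seed = 1L) {
  stopifnot(birth_rate > 0, death_rate >= 0, n_taxa >= 2L, n_transcripts >= 1L,
            site_rate >= 0, kappa > 0, length(base_freqs) == 4L,
            all(is.finite(c(birth_rate, death_rate, site_rate, kappa, base_freqs))))
  if (abs(sum(base_freqs) - 1) > 1e-9) stop("base_freqs must sum to 1")
  structure(list(birth_rate = birth_rate, death_rate = death_rate,
                 n_taxa = as.integer(n_taxa),
                 n_transcripts = as.integer(n_transcripts),
                 site_rate = site_rate, kappa = kappa, base_freqs = base_freqs,
                 length_distribution = length_distribution,
                 coverage_range = coverage_range, seed = as.integer(seed)),
            class = "sim_config")
}

# Named substreams: each stage reseeds from a distinct derived seed (kept
# below 2^31) so stages are reproducible independently of one another.
substream_seed <- function(seed, stage) {
  offset <- c(tree = 1L, lengths = 2L, roots = 3L, evolution = 4L,
              coverage = 5L)[[stage]]
  as.integer((as.double(seed) + offset * 1000003) %% 2147483647)
}

#' Simulate a birth-death tree with a fixed number of extant taxa
#'
#' Forward simulation from a single lineage: lineages split at the birth rate
#' and die at the death rate; the process stops the first time the extant
#' lineage count reaches `n_taxa`. Extinct lineages are pruned and
#' unifurcations suppressed, so the returned tree has exactly `n_taxa` leaves
#' (labeled `T1`, `T2`, ... in order of lineage creation) with branch lengths
#' in time units. Runs that go fully extinct are retried up to `max_attempts`
#' times.
#'
#' @param config a [sim_config()] (fields `birth_rate`, `death_rate`,
#'   `n_taxa`, `seed` are used).
#' @param max_attempts retry cap for full-lineage extinction.
#' @return An `ape` "phylo" tree.
#' @export
simulate_birth_death_tree <- function(config, max_attempts = 1000L) {
  b <- config$birth_rate; d <- config$death_rate; n <- config$n_taxa
  set.seed(substream_seed(config$seed, "tree"))
  for (attempt in seq_len(max_attempts)) {
    parent <- NA_integer_; t_start <- 0; t_end <- NA_real_
    alive <- TRUE
    t <- 0
    repeat {
      n_alive <- sum(alive)
      if (n_alive == 0L || n_alive == n) break
      t <- t + stats::rexp(1L, n_alive * (b + d))
      lin <- which(alive)[sample.int(n_alive, 1L)]
      alive[lin] <- FALSE
      t_end[lin] <- t
      if (stats::runif(1L) < b / (b + d)) {
        parent <- c(parent, lin, lin)
        t_start <- c(t_start, t, t)
        t_end <- c(t_end, NA_real_, NA_real_)
        alive <- c(alive, TRUE, TRUE)
      }
    }
    if (sum(alive) != n) next  # extinction: retry
    t_end[alive] <- t

    labels <- rep(NA_character_, length(parent))
    labels[alive] <- paste0("T", seq_len(n))
    children <- split(seq_along(parent), factor(parent, levels = seq_along(parent)))
    # keep = lineage has at least one extant descendant
    keep <- alive
    for (i in rev(seq_along(parent))) {
      if (!is.na(parent[i]) && keep[i]) keep[parent[i]] <- TRUE
    }
    frag <- function(node, extra) {
      len <- t_end[node] - t_start[node] + extra
      kids <- children[[node]]
      kids <- kids[keep[kids]]
      if (length(kids) == 0L) return(paste0(labels[node], ":", format(len, digits = 12)))
      if (length(kids) == 1L) return(frag(kids, len))
      paste0("(", paste(vapply(kids, frag, "", extra = 0), collapse = ","),
             "):", format(len, digits = 12))
    }
    root <- 1L
    repeat {
      kids <- children[[root]]
      kids <- kids[keep[kids]]
      if (length(kids) != 1L) break
      root <- kids
    }
    kids <- children[[root]]
    kids <- kids[keep[kids]]
    newick <- if (length(kids) == 0L) {
      paste0("(", labels[root], ":0);")
    } else {
      paste0("(", paste(vapply(kids, frag, "", extra = 0), collapse = ","), ");")
    }
    return(ape::read.tree(text = newick))
  }
  stop("birth-death simulation went extinct in every attempt; ",
       "a death rate at or above the birth rate makes survival unlikely - ",
       "lower death_rate or raise max_attempts")
}

sample_lengths <- function(config, n) {
  ld <- config$length_distribution
  if (is.null(ld)) {
    return(pmax(200L, as.integer(round(stats::rlnorm(n, log(500), 0.6)))))
  }
  if (is.data.frame(ld)) {
    if (nrow(ld) == 0L) stop("empty length distribution")
    li <- sample.int(nrow(ld), n, replace = TRUE, prob = ld$weight)
    return(as.integer(ld$length[li]))
  }
  if (length(ld) == 0L) stop("empty length distribution")
  ld <- as.integer(ld)
  ld[sample.int(length(ld), n, replace = TRUE)]
}

#' Sample random root transcripts
#'
#' Lengths are drawn i.i.d. from the configured length distribution and bases
#' i.i.d. from the configured base frequencies (uniform by default).
#'
#' @param config a [sim_config()].
#' @return Character vector of `n_transcripts` DNA sequences.
#' @export
sample_root_transcripts <- function(config) {
  set.seed(substream_seed(config$seed, "lengths"))
  lens <- sample_lengths(config, config$n_transcripts)
  set.seed(substream_seed(config$seed, "roots"))
  bases <- sample(c("A", "C", "G", "T"), sum(lens), replace = TRUE,
                  prob = config$base_freqs)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  all <- paste(bases, collapse = "")
  substring(all, starts, ends)
}

# HKY85 rate matrix (rows/cols A, C, G, T), normalized to one expected
# substitution per site per unit time at equilibrium.
hky_rate_matrix <- function(kappa, base_freqs) {
  bases <- c("A", "C", "G", "T")
  R <- matrix(1, 4, 4, dimnames = list(bases, bases))
  R["A", "G"] <- R["G", "A"] <- kappa
  R["C", "T"] <- R["T", "C"] <- kappa
  Q <- R * rep(base_freqs, each = 4)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q / sum(base_freqs * -diag(Q))
}

# P(t) = exp(Qt) via eigendecomposition of the pi-symmetrized generator
# (numerically stable because the symmetrized matrix is real symmetric).
hky_transition_matrix <- function(Q, t, base_freqs) {
  sq <- sqrt(base_freqs)
  B <- diag(sq) %*% Q %*% diag(1 / sq)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  P <- diag(1 / sq) %*% e$vectors %*% diag(exp(e$values * t)) %*%
    t(e$vectors) %*% diag(sq)
  P[P < 0] <- 0
  P / rowSums(P)
}

mutate_sites <- function(seq_int, P) {
  u <- stats::runif(length(seq_int))
  out <- integer(length(seq_int))
  for (st in 1:4) {
    idx <- seq_int == st
    if (any(idx)) {
      out[idx] <- 1L + findInterval(u[idx], cumsum(P[st, ])[-4L])
    }
  }
  out
}

#' Evolve root transcripts along a tree under HKY85
#'
#' Substitution-only evolution (no indels): every site evolves independently,
#' and the expected number of substitutions per site along a branch equals
#' branch length times `site_rate`. Each root transcript yields exactly one
#' descendant transcript per leaf, so each ortholog set has one transcript
#' per taxon and lengths are preserved.
#'
#' @param tree an `ape` "phylo" tree with branch lengths in time units.
#' @param roots character vector of root transcript sequences.
#' @param config a [sim_config()] (`site_rate`, `kappa`, `base_freqs`, `seed`).
#' @return Named list, one element per leaf label, each a character vector of
#'   transcripts parallel to `roots`.
#' @export
evolve_hky85 <- function(tree, roots, config) {
  stopifnot(inherits(tree, "phylo"), length(roots) >= 1L)
  set.seed(substream_seed(config$seed, "evolution"))
  bases <- c("A", "C", "G", "T")
  lens <- nchar(roots)
  root_int <- match(strsplit(paste(roots, collapse = ""), "")[[1L]], bases)
  if (anyNA(root_int)) stop("root sequences must contain only A, C, G, T")

  Q <- hky_rate_matrix(config$kappa, config$base_freqs)
  n_tip <- length(tree$tip.label)
  root_node <- n_tip + 1L
  seqs <- vector("list", n_tip + tree$Nnode)
  seqs[[root_node]] <- root_int
  # parents before children: walk edges in preorder
  edge_order <- rev(ape::postorder(tree))
  for (e in edge_order) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    el <- tree$edge.length[e] * config$site_rate
    P <- if (el == 0) diag(4) else hky_transition_matrix(Q, el, config$base_freqs)
    seqs[[child]] <- mutate_sites(seqs[[par]], P)
  }

  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  out <- lapply(seq_len(n_tip), function(tip) {
    full <- paste(bases[seqs[[tip]]], collapse = "")
    substring(full, starts, ends)
  })
  names(out) <- tree$tip.label
  out
}

#' Simulate a set of related transcriptomes with known ground truth
#'
#' Runs the full generator: birth-death tree, random root transcripts, HKY85
#' evolution, and assembly of one [transcriptome] per taxon with rnaSPAdes
#' style headers (one isotig per gene, synthetic k-mer coverage drawn
#' log-uniformly) so the whole pipeline, including top-n gene selection and
#' header parsing, is exercised.
#'
#' What this emulates: samples related by a known phylogeny with realistic
#' transcript length spread and coverage values. What it does not emulate:
#' paralogy and homeology, alternative splicing, indels, sequencing error, or
#' assembly artifacts.
#'
#' @param config a [sim_config()].
#' @return List of class `sim_result` with elements `tree` ("phylo"),
#'   `transcriptomes` (named list of [transcriptome]), `ortholog_map` (data
#'   frame `gene_id`, `taxon`, `record_id`), and `config`.
#' @export
simulate_transcriptomes <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  tree <- simulate_birth_death_tree(config)
  roots <- sample_root_transcripts(config)
  leaves <- evolve_hky85(tree, roots, config)

  set.seed(substream_seed(config$seed, "coverage"))
  n_tr <- config$n_transcripts
  lo <- log(config$coverage_range[1L]); hi <- log(config$coverage_range[2L])
  maps <- vector("list", length(leaves))
  tx <- vector("list", length(leaves))
  for (i in seq_along(leaves)) {
    taxon <- names(leaves)[i]
    seqs <- leaves[[i]]
    cov <- exp(stats::runif(n_tr, lo, hi))
    rec <- sprintf("NODE_%d_length_%d_cov_%.6f_g%d_i0",
                   seq_len(n_tr), nchar(seqs), cov, seq_len(n_tr) - 1L)
    tx[[i]] <- transcriptome(
      data.frame(record_id = rec, gene_id = as.character(seq_len(n_tr) - 1L),
                 isotig_id = "0", kmer_coverage = cov, sequence = seqs,
                 stringsAsFactors = FALSE),
      sample_id = taxon)
    maps[[i]] <- data.frame(gene_id = as.character(seq_len(n_tr) - 1L),
                            taxon = taxon, record_id = rec,
                            stringsAsFactors = FALSE)
  }
  names(tx) <- names(leaves)
  structure(list(tree = tree, transcriptomes = tx,
                 ortholog_map = do.call(rbind, maps), config = config),
            class = "sim_result")
}

#' Write a simulation to disk
#'
#' Emits one FASTA per taxon (rnaSPAdes-style headers), the ground-truth tree
#' as newick, the ortholog map as TSV, and the configuration (seed included)
#' as a key-value text file.
#'
#' @param sim a `sim_result` from [simulate_transcriptomes()].
#' @param outdir output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "sim_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  fasta <- vapply(sim$transcriptomes, function(t) {
    p <- file.path(outdir, paste0(sample_id(t), ".fasta"))
    write_transcriptome(t, p)
    p
  }, "")
  tree_path <- file.path(outdir, "ground_truth.nwk")
  ape::write.tree(sim$tree, tree_path)
  map_path <- file.path(outdir, "ortholog_map.tsv")
  utils::write.table(sim$ortholog_map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cfg <- sim$config
  cfg_path <- file.path(outdir, "config.txt")
  scalar <- vapply(cfg, function(v) {
    if (is.null(v)) "default" else paste(format(v, digits = 12), collapse = " ")
  }, "")
  writeLines(paste0(names(cfg), ": ", scalar), cfg_path)
  invisible(list(fasta = fasta, tree = tree_path, ortholog_map = map_path,
                 config = cfg_path))
}
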