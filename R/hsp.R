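# HSP tables: high-scoring segment pairs between the selected genes of two
# samples, produced either by external BLASTn (production) or by a built-in
# desk-scale global aligner (testing, small inputs).

hsp_columns <- c("qgene", "qiso", "sgene", "siso",
                 "bitscore", "nident", "length", "gaps", "evalue")

#' Construct an HSP table
#'
#' One row per HSP (a BLAST "hit" may contain several HSPs). Columns follow
#' the reduction-pipeline schema: query/subject gene and isotig tokens,
#' bitscore, number of identical bases (iota), alignment length in columns
#' (lambda), and total gap characters (gamma). `gaps` counts gap characters,
#' not gap openings, so `length - gaps` is the number of aligned base pairs
#' and `nident <= length - gaps` must hold.
#'
#' @param rows data frame with columns `qgene`, `qiso`, `sgene`, `siso`,
#'   `bitscore`, `nident`, `length`, `gaps` and optionally `evalue`.
#' @param query_sample,subject_sample sample labels; must differ.
#' @return An object of class `hsp_table`.
#' @export
hsp_table <- function(rows, query_sample, subject_sample) {
  stopifnot(is.character(query_sample), is.character(subject_sample))
  if (identical(query_sample, subject_sample)) {
    stop("query_sample and subject_sample must differ")
  }
  rows <- as.data.frame(rows)
  if (!"evalue" %in% names(rows)) rows$evalue <- rep(NA_real_, nrow(rows))
  missing_cols <- setdiff(hsp_columns, names(rows))
  if (length(missing_cols) > 0L) {
    stop("HSP rows missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  rows <- rows[, hsp_columns]
  for (col in c("qgene", "qiso", "sgene", "siso")) rows[[col]] <- as.character(rows[[col]])
  for (col in c("bitscore", "nident", "length", "gaps", "evalue")) {
    rows[[col]] <- suppressWarnings(as.numeric(rows[[col]]))  # NA checked below
  }
  if (nrow(rows) > 0L) {
    num <- rows[, c("bitscore", "nident", "length", "gaps")]
    if (anyNA(num)) {
      stop("non-numeric value in HSP row ", which(rowSums(is.na(num)) > 0)[1L])
    }
    bad <- which(rows$gaps > rows$length | rows$nident > rows$length - rows$gaps)
    if (length(bad) > 0L) {
      stop("HSP row ", bad[1L], " violates nident <= length - gaps")
    }
    if (any(rows$bitscore <= 0)) stop("bitscore must be > 0")
    if (any(rows$length < 1) || any(rows$nident < 0) || any(rows$gaps < 0)) {
      stop("HSP rows must have length >= 1, nident >= 0, gaps >= 0")
    }
  }
  rownames(rows) <- NULL
  structure(rows, query_sample = query_sample, subject_sample = subject_sample,
            class = c("hsp_table", "data.frame"))
}

#' @export
print.hsp_table <- function(x, ...) {
  cat(sprintf("<hsp_table> %s vs %s: %d HSPs\n",
              attr(x, "query_sample"), attr(x, "subject_sample"), nrow(x)))
  invisible(x)
}

#' Read an HSP table from TSV
#'
#' @param path tab-separated file with header columns
#'   `qgene qiso sgene siso bitscore nident length gaps [evalue]`.
#' @param query_sample,subject_sample sample labels.
#' @return An [hsp_table].
#' @export
read_hsp_table <- function(path, query_sample, subject_sample) {
  if (!file.exists(path)) stop("HSP table file not found: ", path)
  rows <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE)
  hsp_table(rows, query_sample, subject_sample)
}

#' Write an HSP table to TSV
#' @param x an [hsp_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hsp_table <- function(x, path) {
  stopifnot(inherits(x, "hsp_table"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

blast_outfmt <- "6 qseqid sseqid bitscore nident length gaps evalue"

run_tool <- function(exe, args) {
  if (Sys.which(exe) == "") {
    stop("required executable '", exe, "' was not found on PATH")
  }
  out <- suppressWarnings(system2(exe, args, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop(exe, " exited with status ", status, ":\n", paste(out, collapse = "\n"))
  }
  out
}

# Map BLAST qseqid/sseqid back to (gene, isotig) tokens via the
# transcriptome's own record table.
blast_tsv_to_hsps <- function(path, tq, ts) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           col.names = c("qseqid", "sseqid", "bitscore",
                                         "nident", "length", "gaps", "evalue"),
                           colClasses = c("character", "character", rep("numeric", 5)))
  iq <- match(raw$qseqid, tq$record_id)
  is <- match(raw$sseqid, ts$record_id)
  if (anyNA(iq) || anyNA(is)) {
    stop("BLAST output names a sequence absent from the input transcriptomes")
  }
  data.frame(qgene = tq$gene_id[iq], qiso = tq$isotig_id[iq],
             sgene = ts$gene_id[is], siso = ts$isotig_id[is],
             bitscore = raw$bitscore, nident = raw$nident,
             length = raw$length, gaps = raw$gaps, evalue = raw$evalue,
             stringsAsFactors = FALSE)
}

#' Reciprocal BLASTn between two transcriptomes
#'
#' Runs external `makeblastdb` and `blastn` (BLAST+ defaults, i.e. megablast)
#' in both directions with only the e-value cutoff imposed; one table row per
#' HSP. Intermediate files are written under `workdir` with deterministic
#' names `<query>__vs__<subject>.tsv`.
#'
#' @param t1,t2 transcriptomes (typically after [select_top_genes()]).
#' @param evalue_cutoff BLAST e-value cutoff; the stringent default 1e-99
#'   keeps only unambiguously homologous alignments.
#' @param workdir directory for databases and tabular output.
#' @return List with elements `forward` (t1 as query) and `reverse` (t2 as
#'   query), both [hsp_table] objects.
#' @export
blastn_reciprocal <- function(t1, t2, evalue_cutoff = 1e-99,
                              workdir = tempfile("blastwork")) {
  stopifnot(inherits(t1, "transcriptome"), inherits(t2, "transcriptome"))
  stopifnot(is.numeric(evalue_cutoff), evalue_cutoff > 0)
  if (nrow(t1) == 0L || nrow(t2) == 0L) stop("both transcriptomes must be non-empty")
  s1 <- sample_id(t1); s2 <- sample_id(t2)
  if (identical(s1, s2)) stop("transcriptomes must have distinct sample ids")
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)

  fa <- function(t) {
    p <- file.path(workdir, paste0(sample_id(t), ".fa"))
    write_transcriptome(t, p)
    p
  }
  fa1 <- fa(t1); fa2 <- fa(t2)
  db <- function(p) {
    run_tool("makeblastdb", c("-in", p, "-dbtype", "nucl", "-out",
                              paste0(p, ".db"), "-logfile",
                              paste0(p, ".db.log")))
    paste0(p, ".db")
  }
  db1 <- db(fa1); db2 <- db(fa2)

  one_direction <- function(query_fa, db, out_name) {
    out <- file.path(workdir, out_name)
    run_tool("blastn", c("-query", query_fa, "-db", db,
                         "-evalue", format(evalue_cutoff, scientific = TRUE),
                         "-outfmt", shQuote(blast_outfmt), "-out", out))
    out
  }
  fwd_path <- one_direction(fa1, db2, paste0(s1, "__vs__", s2, ".tsv"))
  rev_path <- one_direction(fa2, db1, paste0(s2, "__vs__", s1, ".tsv"))

  fwd <- if (file.info(fwd_path)$size > 0) blast_tsv_to_hsps(fwd_path, t1, t2) else
    data.frame(qgene = character(), qiso = character(), sgene = character(),
               siso = character(), bitscore = numeric(), nident = numeric(),
               length = numeric(), gaps = numeric(), evalue = numeric())
  rev <- if (file.info(rev_path)$size > 0) blast_tsv_to_hsps(rev_path, t2, t1) else
    fwd[0, ]
  list(forward = hsp_table(fwd, s1, s2),
       reverse = hsp_table(rev, s2, s1))
}

# Per-sample k-mer index for alignment seeding, reusable across pairs.
seed_kmer_index <- function(t, k) {
  n <- nchar(t$sequence)
  idx <- rep.int(seq_len(nrow(t)), pmax(n - k + 1L, 0L))
  starts <- unlist(lapply(pmax(n - k + 1L, 0L), seq_len), use.names = FALSE)
  dt <- unique(data.table::data.table(
    idx = idx, kmer = substring(t$sequence[idx], starts, starts + k - 1L)))
  data.table::setkey(dt, kmer)
  dt
}

# Seed prefilter, mirroring BLAST's seed-and-extend strategy so the
# all-vs-all alignment stays tractable. A pair of isotigs becomes an
# alignment candidate when its count of shared exact k-mers reaches a
# length-scaled threshold: at identity q a fraction q^k of k-mers survives,
# so a pair at the reporting threshold `min_identity` is expected to share
# (Lmin - k + 1) * min_identity^k seeds; requiring half that (with an
# absolute floor of `min_hits`) retains pairs at or above the threshold
# while discarding chance seed matches between unrelated sequences. Pairs
# involving sequences too short for seeding bypass the filter entirely.
seed_candidates <- function(t1, t2, k, min_hits, min_identity,
                            index1 = NULL, index2 = NULL) {
  d1 <- if (is.null(index1)) seed_kmer_index(t1, k) else index1
  d2 <- if (is.null(index2)) seed_kmer_index(t2, k) else index2
  joined <- d1[d2, , nomatch = 0L, allow.cartesian = TRUE]
  hits <- joined[, .N, by = c("idx", "i.idx")]
  len1 <- nchar(t1$sequence); len2 <- nchar(t2$sequence)
  minlen <- pmin(len1[hits$idx], len2[hits$i.idx])
  thr <- pmax(min_hits, floor(0.5 * (minlen - k + 1L) * min_identity^k))
  cand <- as.data.frame(hits[hits$N >= thr, c("idx", "i.idx")])
  names(cand) <- c("i1", "i2")
  # short sequences bypass the seed filter entirely
  short1 <- which(len1 < 4L * k)
  short2 <- which(len2 < 4L * k)
  if (length(short1) > 0L || length(short2) > 0L) {
    extra <- rbind(
      if (length(short1)) expand.grid(i1 = short1, i2 = seq_len(nrow(t2))),
      if (length(short2)) expand.grid(i1 = seq_len(nrow(t1)), i2 = short2)
    )
    cand <- unique(rbind(cand, extra))
  }
  cand
}

#' Built-in pairwise HSP generation by global alignment
#'
#' A desk-scale alternative to BLASTn for small inputs (intended for up to
#' roughly a thousand isotigs per sample): every candidate isotig pair is
#' globally aligned (match +2, mismatch -3, gap open -5, gap extend -2, N
#' neutral) and pairs whose identity `nident/length` reaches
#' `min_identity_fraction` are emitted as HSPs with `nident`, `length`, and
#' `gaps` read off the alignment and bitscore equal to half the raw score.
#' Candidate pairs are found by exact k-mer seeding (see Details); global
#' alignment is symmetric, so the reverse table is the forward table with
#' roles swapped.
#'
#' @details The default identity threshold of 0.7 plays the role of BLAST's
#'   stringent e-value cutoff: it retains alignments only between sequences
#'   that are unambiguously homologous at desk scale. With `seed_filter =
#'   FALSE` every pair is aligned, which is exact but quadratic.
#'
#' @param t1,t2 transcriptomes with distinct sample ids.
#' @param min_identity_fraction minimum `nident/length` to report, in (0, 1].
#' @param seed_filter use exact k-mer seeding to restrict candidate pairs.
#' @param seed_k seed k-mer length.
#' @param min_seed_hits absolute floor on the shared-seed count required to
#'   become a candidate (the working threshold scales with sequence length;
#'   see the implementation notes on seeding).
#' @param seed_index optional precomputed per-sample k-mer indexes (internal
#'   reuse across pairs).
#' @return List with [hsp_table] elements `forward` and `reverse`.
#' @export
builtin_reciprocal <- function(t1, t2, min_identity_fraction = 0.7,
                               seed_filter = TRUE, seed_k = 12L,
                               min_seed_hits = 2L,
                               seed_index = list(NULL, NULL)) {
  stopifnot(inherits(t1, "transcriptome"), inherits(t2, "transcriptome"))
  stopifnot(min_identity_fraction > 0, min_identity_fraction <= 1)
  s1 <- sample_id(t1); s2 <- sample_id(t2)
  if (identical(s1, s2)) stop("transcriptomes must have distinct sample ids")

  cand <- if (seed_filter) {
    seed_candidates(t1, t2, as.integer(seed_k), as.integer(min_seed_hits),
                    min_identity_fraction,
                    index1 = seed_index[[1L]], index2 = seed_index[[2L]])
  } else {
    expand.grid(i1 = seq_len(nrow(t1)), i2 = seq_len(nrow(t2)))
  }

  empty <- data.frame(qgene = character(), qiso = character(),
                      sgene = character(), siso = character(),
                      bitscore = numeric(), nident = numeric(),
                      length = numeric(), gaps = numeric(), evalue = numeric())
  if (nrow(cand) == 0L) {
    return(list(forward = hsp_table(empty, s1, s2),
                reverse = hsp_table(empty, s2, s1)))
  }

  st <- .gotoh_align_stats(t1$sequence[cand$i1], t2$sequence[cand$i2])
  all <- cbind(cand, as.data.frame(st))
  keep <- all$nident / all$length >= min_identity_fraction & all$score > 0
  all <- all[keep, , drop = FALSE]
  if (nrow(all) == 0L) {
    return(list(forward = hsp_table(empty, s1, s2),
                reverse = hsp_table(empty, s2, s1)))
  }
  fwd <- data.frame(qgene = t1$gene_id[all$i1], qiso = t1$isotig_id[all$i1],
                    sgene = t2$gene_id[all$i2], siso = t2$isotig_id[all$i2],
                    bitscore = all$score / 2, nident = all$nident,
                    length = all$length, gaps = all$gaps, evalue = NA_real_,
                    stringsAsFactors = FALSE)
  rev <- data.frame(qgene = fwd$sgene, qiso = fwd$siso,
                    sgene = fwd$qgene, siso = fwd$qiso,
                    bitscore = fwd$bitscore, nident = fwd$nident,
                    length = fwd$length, gaps = fwd$gaps, evalue = NA_real_,
                    stringsAsFactors = FALSE)
  list(forward = hsp_table(fwd, s1, s2),
       reverse = hsp_table(rev, s2, s1))
}

# Dispatch between the two HSP engines.
pair_hsps <- function(t1, t2, aligner = c("builtin", "blastn"),
                      evalue_cutoff = 1e-99, min_identity_fraction = 0.7,
                      workdir = NULL, ...) {
  aligner <- match.arg(aligner)
  if (aligner == "blastn") {
    blastn_reciprocal(t1, t2, evalue_cutoff = evalue_cutoff,
                      workdir = if (is.null(workdir)) tempfile("blastwork") else workdir)
  } else {
    builtin_reciprocal(t1, t2, min_identity_fraction = min_identity_fraction, ...)
  }
}
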