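# Transcriptome container: one assembled RNA-seq sample, partitioned into
# genes ("isotig sets"), each isotig carrying a k-mer coverage value.

#' Construct a transcriptome object
#'
#' A transcriptome is a data frame with one row per isotig (assembled
#' transcript) and columns `record_id`, `gene_id`, `isotig_id`,
#' `kmer_coverage`, and `sequence`, carrying the sample identifier as an
#' attribute. Isotigs sharing a `gene_id` form an isotig set, i.e. a gene;
#' each isotig is assumed to be a splice or allelic variant of that gene.
#'
#' @param records data frame with columns `record_id`, `gene_id`,
#'   `isotig_id`, `kmer_coverage`, `sequence`. IDs are coerced to character;
#'   sequences are uppercased and must contain only A, C, G, T, N.
#' @param sample_id single character label for the sample.
#' @return An object of class `transcriptome`.
#' @export
transcriptome <- function(records, sample_id) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
  needed <- c("record_id", "gene_id", "isotig_id", "kmer_coverage", "sequence")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    stop("records is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  records <- as.data.frame(records)[, needed]
  records$record_id <- as.character(records$record_id)
  records$gene_id <- as.character(records$gene_id)
  records$isotig_id <- as.character(records$isotig_id)
  records$kmer_coverage <- as.numeric(records$kmer_coverage)
  records$sequence <- toupper(as.character(records$sequence))

  if (nrow(records) == 0L) stop("no records: transcriptome must contain at least one isotig")
  if (anyNA(records$kmer_coverage) || any(!is.finite(records$kmer_coverage)) ||
      any(records$kmer_coverage < 0)) {
    stop("kmer_coverage values must be finite and >= 0")
  }
  if (any(nchar(records$sequence) < 1L)) stop("every sequence must have length >= 1")
  bad <- grepl("[^ACGTN]", records$sequence)
  if (any(bad)) {
    stop("sequence for record '", records$record_id[which(bad)[1L]],
         "' contains characters outside {A,C,G,T,N}")
  }
  key <- paste(records$gene_id, records$isotig_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (gene_id, isotig_id) pair within sample '", sample_id,
         "': ", gsub("\r", "/", d))
  }
  rownames(records) <- NULL
  structure(records, sample_id = sample_id,
            class = c("transcriptome", "data.frame"))
}

#' @export
print.transcriptome <- function(x, ...) {
  cat(sprintf("<transcriptome> sample '%s': %d isotigs in %d genes\n",
              sample_id(x), nrow(x), length(unique(x$gene_id))))
  invisible(x)
}

#' Sample identifier of a transcriptome
#' @param x a `transcriptome`.
#' @return Character scalar.
#' @export
sample_id <- function(x) attr(x, "sample_id")

# Default header scheme: rnaSPAdes names its transcripts
# NODE_<i>_length_<L>_cov_<float>_g<int>_i<int>; the trailing _g/_i tokens
# give gene and isoform and the cov_ token the k-mer coverage.
parse_rnaspades_headers <- function(ids) {
  gi <- regmatches(ids, regexec("_g([0-9]+)_i([0-9]+)$", ids))
  cov <- regmatches(ids, regexec("_cov_([0-9]+\\.?[0-9]*(?:[eE][+-]?[0-9]+)?)", ids))
  ok <- lengths(gi) == 3L & lengths(cov) == 2L
  if (!all(ok)) {
    stop("header '", ids[which(!ok)[1L]],
         "' does not match the rnaSPAdes scheme (`..._cov_<float>_g<int>_i<int>`); ",
         "supply a mapping table instead")
  }
  data.frame(
    record_id = ids,
    gene_id = vapply(gi, `[`, "", 2L),
    isotig_id = vapply(gi, `[`, "", 3L),
    kmer_coverage = as.numeric(vapply(cov, `[`, "", 2L)),
    stringsAsFactors = FALSE
  )
}

#' Read a transcriptome from a FASTA file
#'
#' Record identifiers are resolved to (gene, isotig, coverage) either by the
#' rnaSPAdes naming convention (`..._cov_<float>_g<int>_i<int>`) or by a
#' user-supplied mapping table, so the method is not tied to one assembler.
#'
#' @param path FASTA file.
#' @param sample_id sample label; defaults to the file name without extension.
#' @param header_scheme `"rnaspades"` (default) or `"mapping_file"`.
#' @param mapping for `header_scheme = "mapping_file"`: a data frame or TSV
#'   path with columns `record_id`, `gene_id`, `isotig_id` and optionally
#'   `kmer_coverage` (defaults to 1.0). Every FASTA record must be covered.
#' @return A [transcriptome].
#' @export
read_transcriptome <- function(path, sample_id = NULL,
                               header_scheme = c("rnaspades", "mapping_file"),
                               mapping = NULL) {
  header_scheme <- match.arg(header_scheme)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  }
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) stop("malformed FASTA '", path, "': ",
                                            conditionMessage(e)))
  if (length(seqs) == 0L) stop("no records in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))  # first whitespace-delimited token

  if (header_scheme == "rnaspades") {
    meta <- parse_rnaspades_headers(ids)
  } else {
    if (is.null(mapping)) stop("header_scheme = 'mapping_file' requires a mapping")
    if (is.character(mapping)) {
      mapping <- utils::read.table(mapping, header = TRUE, sep = "\t",
                                   colClasses = "character")
    }
    mapping <- as.data.frame(mapping)
    for (col in c("record_id", "gene_id", "isotig_id")) {
      if (!col %in% names(mapping)) stop("mapping is missing column '", col, "'")
      mapping[[col]] <- as.character(mapping[[col]])
    }
    if (!"kmer_coverage" %in% names(mapping)) mapping$kmer_coverage <- 1.0
    mapping$kmer_coverage <- as.numeric(mapping$kmer_coverage)
    idx <- match(ids, mapping$record_id)
    if (anyNA(idx)) {
      stop("mapping does not cover record '", ids[which(is.na(idx))[1L]], "'")
    }
    meta <- data.frame(record_id = ids,
                       gene_id = mapping$gene_id[idx],
                       isotig_id = mapping$isotig_id[idx],
                       kmer_coverage = mapping$kmer_coverage[idx],
                       stringsAsFactors = FALSE)
  }
  meta$sequence <- as.character(seqs)
  transcriptome(meta, sample_id = sample_id)
}

#' Write a transcriptome to FASTA
#'
#' Original record identifiers are preserved as headers, so a written file
#' round-trips through [read_transcriptome()].
#'
#' @param x a `transcriptome`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_transcriptome <- function(x, path) {
  stopifnot(inherits(x, "transcriptome"))
  seqs <- Biostrings::DNAStringSet(x$sequence)
  names(seqs) <- x$record_id
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Per-gene k-mer coverage
#'
#' A gene's coverage is the maximum k-mer coverage among its isotigs.
#'
#' @param x a `transcriptome`.
#' @return Named numeric vector, one entry per gene.
#' @export
gene_coverage <- function(x) {
  stopifnot(inherits(x, "transcriptome"))
  if (nrow(x) == 0L) stop("transcriptome has no isotigs")
  cov <- tapply(x$kmer_coverage, x$gene_id, max)
  stats::setNames(as.numeric(cov), names(cov))
}

# Deterministic gene ordering for coverage ties: ascending gene_id,
# numerically when every id is a plain integer token, else lexicographically.
order_gene_ids <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) order(num) else order(ids)
}

#' Select the top n genes by k-mer coverage
#'
#' Keeps the `min(n, gene count)` genes with highest coverage, retaining all
#' isotigs of each selected gene. Coverage ties at the n-th rank are broken
#' by ascending gene ID so selections are reproducible and nested in n.
#'
#' @param x a `transcriptome`.
#' @param n positive integer number of genes to keep.
#' @return A `transcriptome` restricted to the selected genes.
#' @export
select_top_genes <- function(x, n) {
  stopifnot(inherits(x, "transcriptome"))
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("n must be a positive integer")
  }
  n <- as.integer(n)
  cov <- gene_coverage(x)
  ids <- names(cov)
  ord <- order(-cov[order_gene_ids(ids)])  # stable: ties already in id order
  ids_sorted <- ids[order_gene_ids(ids)][ord]
  keep <- ids_sorted[seq_len(min(n, length(ids_sorted)))]
  out <- x[x$gene_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, sample_id = sample_id(x),
            class = c("transcriptome", "data.frame"))
}

# DNAStringSet view of a transcriptome, named by record_id.
transcriptome_seqs <- function(x) {
  seqs <- Biostrings::DNAStringSet(x$sequence)
  names(seqs) <- x$record_id
  seqs
}
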