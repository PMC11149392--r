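# Reduction of a forward/reverse HSP table pair to the gene match table:
# top-N HSPs per query gene -> reorient columns -> keep reciprocal gene
# pairs -> best row per gene pair -> best row per sample-1 gene.

match_columns <- c("s1gene", "s1iso", "s2gene", "s2iso",
                   "bitscore", "nident", "length", "gaps")

#' Construct a gene match table
#'
#' The final per-pair table: each row maps a sample-1 gene to its most likely
#' ortholog in sample 2, carrying the alignment statistics of the best HSP.
#'
#' @param rows data frame with columns
#'   `s1gene s1iso s2gene s2iso bitscore nident length gaps`.
#' @param sample1,sample2 sample labels (sample 1 is the orientation role:
#'   the earlier sample in the user-given order).
#' @return Object of class `gene_match_table`.
#' @export
gene_match_table <- function(rows, sample1, sample2) {
  rows <- as.data.frame(rows)
  missing_cols <- setdiff(match_columns, names(rows))
  if (length(missing_cols) > 0L) {
    stop("match rows missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  rows <- rows[, match_columns]
  for (col in c("s1gene", "s1iso", "s2gene", "s2iso")) {
    rows[[col]] <- as.character(rows[[col]])
  }
  for (col in c("bitscore", "nident", "length", "gaps")) {
    rows[[col]] <- as.numeric(rows[[col]])
  }
  if (nrow(rows) > 0L) {
    bad <- which(rows$nident > rows$length - rows$gaps)
    if (length(bad) > 0L) stop("match row ", bad[1L], " violates nident <= length - gaps")
  }
  rownames(rows) <- NULL
  structure(rows, sample1 = sample1, sample2 = sample2,
            class = c("gene_match_table", "data.frame"))
}

#' @export
print.gene_match_table <- function(x, ...) {
  cat(sprintf("<gene_match_table> %s ~ %s: %d rows, %d sample-1 genes\n",
              attr(x, "sample1"), attr(x, "sample2"), nrow(x),
              length(unique(x$s1gene))))
  invisible(x)
}

#' Select the top N HSPs per query gene
#'
#' For each query gene ID, retains the N highest-bitscore HSPs plus any HSPs
#' tied with the N-th bitscore (ties are never broken arbitrarily).
#'
#' @param x an [hsp_table].
#' @param N positive integer; the default 1 keeps only best matches, which
#'   avoids matching non-orthologous genes.
#' @return An [hsp_table] with the surviving rows.
#' @export
select_top_hsps <- function(x, N = 1L) {
  stopifnot(inherits(x, "hsp_table"))
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1) {
    stop("N must be a positive integer")
  }
  N <- as.integer(N)
  if (nrow(x) == 0L) return(x)
  keep <- unlist(lapply(split(seq_len(nrow(x)), x$qgene), function(idx) {
    b <- x$bitscore[idx]
    thr <- sort(b, decreasing = TRUE)[min(N, length(b))]
    idx[b >= thr]
  }), use.names = FALSE)
  hsp_table(as.data.frame(x)[sort(keep), , drop = FALSE],
            attr(x, "query_sample"), attr(x, "subject_sample"))
}

# Reorient an HSP table so columns are (s1gene, s1iso, s2gene, s2iso) for a
# fixed role assignment: query_is_s1 says whether the table's query sample
# plays the sample-1 role.
reorient_hsps <- function(x, query_is_s1) {
  df <- as.data.frame(x)
  if (query_is_s1) {
    data.frame(s1gene = df$qgene, s1iso = df$qiso,
               s2gene = df$sgene, s2iso = df$siso,
               bitscore = df$bitscore, nident = df$nident,
               length = df$length, gaps = df$gaps, stringsAsFactors = FALSE)
  } else {
    data.frame(s1gene = df$sgene, s1iso = df$siso,
               s2gene = df$qgene, s2iso = df$qiso,
               bitscore = df$bitscore, nident = df$nident,
               length = df$length, gaps = df$gaps, stringsAsFactors = FALSE)
  }
}

#' Keep reciprocal gene pairs and merge both search directions
#'
#' Columns of both tables are renamed to sample-1/sample-2 roles, then rows
#' are retained only when their (sample-1 gene, sample-2 gene) pair occurs in
#' both directions, and the survivors from both tables are concatenated.
#' Every surviving gene pair therefore contributes at least two rows.
#'
#' @param forward,reverse [hsp_table] objects for the two search directions
#'   (forward's query sample is the sample-1 role).
#' @return Data frame of match rows (both directions concatenated).
#' @export
reciprocal_merge <- function(forward, reverse) {
  stopifnot(inherits(forward, "hsp_table"), inherits(reverse, "hsp_table"))
  if (!identical(attr(forward, "query_sample"), attr(reverse, "subject_sample")) ||
      !identical(attr(forward, "subject_sample"), attr(reverse, "query_sample"))) {
    stop("forward and reverse tables disagree on sample ids")
  }
  f <- reorient_hsps(forward, query_is_s1 = TRUE)
  r <- reorient_hsps(reverse, query_is_s1 = FALSE)
  fkey <- paste(f$s1gene, f$s2gene, sep = "\r")
  rkey <- paste(r$s1gene, r$s2gene, sep = "\r")
  both <- intersect(unique(fkey), unique(rkey))
  rbind(f[fkey %in% both, , drop = FALSE], r[rkey %in% both, , drop = FALSE])
}

# Rows attaining the maximum of `values` within each group; all ties kept.
max_rows_by <- function(values, group) {
  mx <- tapply(values, group, max)
  which(values >= mx[group] - 0)
}

#' Best row per (sample-1 gene, sample-2 gene) pair
#'
#' Retains, for each gene pair, the row(s) with the highest bitscore;
#' bitscore ties keep all tied rows.
#'
#' @param rows data frame of match rows (as from [reciprocal_merge()]).
#' @return Data frame of surviving match rows.
#' @export
best_per_gene_pair <- function(rows) {
  if (nrow(rows) == 0L) return(rows)
  key <- paste(rows$s1gene, rows$s2gene, sep = "\r")
  rows[max_rows_by(rows$bitscore, key), , drop = FALSE]
}

#' Best row per sample-1 gene
#'
#' Retains, for each sample-1 gene, the row(s) with the highest bitscore:
#' each surviving row is read as the most likely ortholog of that gene in
#' sample 2. Ties keep all tied rows.
#'
#' @param rows data frame of match rows already reduced per gene pair.
#' @param sample1,sample2 sample labels for the resulting table.
#' @return A [gene_match_table].
#' @export
best_per_s1_gene <- function(rows, sample1, sample2) {
  if (nrow(rows) == 0L) return(gene_match_table(rows, sample1, sample2))
  out <- rows[max_rows_by(rows$bitscore, rows$s1gene), , drop = FALSE]
  gene_match_table(out, sample1, sample2)
}

#' Full reduction of an HSP table pair to the gene match table
#'
#' Composes [select_top_hsps()] (on both directions), [reciprocal_merge()],
#' [best_per_gene_pair()], and [best_per_s1_gene()]. Rows are returned in a
#' canonical sort (by sample-1 gene, sample-2 gene, isotigs) so the result is
#' invariant to input row order.
#'
#' @param forward,reverse [hsp_table] objects; forward's query sample takes
#'   the sample-1 role.
#' @param N top HSPs retained per query gene before the reciprocal filter.
#' @param dedupe_ties if `TRUE`, tied rows for the same gene pair are
#'   collapsed to the single row with the lowest (s1iso, s2iso), so each pair
#'   contributes once to the similarity sums.
#' @return A [gene_match_table].
#' @export
match_table <- function(forward, reverse, N = 1L, dedupe_ties = FALSE) {
  s1 <- attr(forward, "query_sample")
  s2 <- attr(forward, "subject_sample")
  merged <- reciprocal_merge(select_top_hsps(forward, N),
                             select_top_hsps(reverse, N))
  reduced <- best_per_gene_pair(merged)
  out <- best_per_s1_gene(reduced, s1, s2)
  df <- as.data.frame(out)
  if (isTRUE(dedupe_ties) && nrow(df) > 0L) {
    key <- paste(df$s1gene, df$s2gene, sep = "\r")
    df <- df[order(key, df$s1iso, df$s2iso), , drop = FALSE]
    df <- df[!duplicated(paste(df$s1gene, df$s2gene, sep = "\r")), , drop = FALSE]
  }
  df <- df[order(df$s1gene, df$s2gene, df$s1iso, df$s2iso, -df$bitscore), ,
           drop = FALSE]
  gene_match_table(df, s1, s2)
}

#' Write a gene match table to TSV
#' @param x a [gene_match_table].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_match_table <- function(x, path) {
  stopifnot(inherits(x, "gene_match_table"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a gene match table from TSV
#' @param path TSV with the `s1gene s1iso s2gene s2iso bitscore nident length
#'   gaps` schema.
#' @param sample1,sample2 sample labels.
#' @return A [gene_match_table].
#' @export
read_match_table <- function(path, sample1, sample2) {
  if (!file.exists(path)) stop("match table file not found: ", path)
  rows <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = "character", check.names = FALSE)
  gene_match_table(rows, sample1, sample2)
}
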