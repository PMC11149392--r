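# Gene matches graph: one vertex per (sample, gene), one edge per gene pair
# occurring in the corresponding samples' match table. Components are
# classified as small (< s vertices), large (>= s), or ideal (a clique with
# exactly one gene from each of the s samples); only genes in ideal
# components enter the multi-sample distance computation.

vertex_key <- function(sample, gene) paste(sample, gene, sep = "\t")

#' Build the gene matches graph
#'
#' @param tables list of [gene_match_table] objects, exactly one per
#'   unordered pair of samples.
#' @param sample_ids ordered character vector of all sample ids.
#' @return An `igraph` graph with vertex attributes `sample` and `gene` and
#'   graph attributes `sample_ids` and `num_samples`.
#' @export
build_match_graph <- function(tables, sample_ids) {
  stopifnot(is.character(sample_ids), length(sample_ids) >= 2L,
            !anyDuplicated(sample_ids))
  s <- length(sample_ids)
  pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\t")
  want <- outer(sample_ids, sample_ids, pair_key)[upper.tri(diag(s))]
  got <- vapply(tables, function(t) {
    a <- attr(t, "sample1"); b <- attr(t, "sample2")
    if (!all(c(a, b) %in% sample_ids)) {
      stop("match table for samples '", a, "'/'", b,
           "' involves a sample not in sample_ids")
    }
    pair_key(a, b)
  }, "")
  if (anyDuplicated(got)) stop("duplicate match table for a sample pair")
  miss <- setdiff(want, got)
  if (length(miss) > 0L) {
    stop("missing match table for sample pair: ", gsub("\t", " / ", miss[1L]))
  }

  edges <- do.call(rbind, lapply(tables, function(t) {
    df <- as.data.frame(t)
    if (nrow(df) == 0L) return(NULL)
    unique(data.frame(v1 = vertex_key(attr(t, "sample1"), df$s1gene),
                      v2 = vertex_key(attr(t, "sample2"), df$s2gene),
                      stringsAsFactors = FALSE))
  }))
  if (is.null(edges) || nrow(edges) == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    verts <- sort(unique(c(edges$v1, edges$v2)))
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = verts))
    g <- igraph::simplify(g)
  }
  if (igraph::vcount(g) > 0) {
    parts <- strsplit(igraph::V(g)$name, "\t", fixed = TRUE)
    igraph::V(g)$sample <- vapply(parts, `[`, "", 1L)
    igraph::V(g)$gene <- vapply(parts, `[`, "", 2L)
  }
  g$sample_ids <- sample_ids
  g$num_samples <- s
  g
}

#' Classify connected components of a gene matches graph
#'
#' A component is small if it has fewer vertices than there are samples,
#' large if it has at least as many, and ideal if it is a complete subgraph
#' with exactly as many vertices as samples (equivalently, a clique with one
#' gene from each sample, since no edge joins two genes of one sample).
#' Large counts include ideal components; `n_large_nonideal` is reported for
#' convenience.
#'
#' @param g graph from [build_match_graph()].
#' @return List with `membership` (integer component id per vertex), `sizes`,
#'   `class` (factor per component: small/large/ideal), and counts `n_small`,
#'   `n_large`, `n_ideal`, `n_large_nonideal`.
#' @export
classify_components <- function(g) {
  s <- g$num_samples
  comp <- igraph::components(g)
  n_comp <- comp$no
  sizes <- comp$csize
  # completeness by edge-count equality: a component with v vertices is a
  # clique iff it has v(v-1)/2 edges
  ecount_by_comp <- rep(0, n_comp)
  if (igraph::ecount(g) > 0) {
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    tab <- table(comp$membership[ends[, 1L]])
    ecount_by_comp[as.integer(names(tab))] <- as.integer(tab)
  }
  cls <- ifelse(sizes < s, "small",
                ifelse(sizes == s & ecount_by_comp == s * (s - 1) / 2,
                       "ideal", "large"))
  counts <- list(
    n_small = sum(cls == "small"),
    n_large = sum(cls %in% c("large", "ideal")),
    n_ideal = sum(cls == "ideal"),
    n_large_nonideal = sum(cls == "large")
  )
  c(list(membership = comp$membership, sizes = sizes,
         class = factor(cls, levels = c("small", "large", "ideal"))),
    counts)
}

#' Gene pairs lying together in ideal components
#'
#' @param g graph from [build_match_graph()].
#' @param classification optional result of [classify_components()].
#' @return Data frame with columns `sample1`, `gene1`, `sample2`, `gene2`,
#'   one row per unordered vertex pair within an ideal component
#'   (`n_ideal * s(s-1)/2` rows in total). Within each row the two vertices
#'   are ordered by the graph's `sample_ids` order.
#' @export
ideal_gene_pairs <- function(g, classification = classify_components(g)) {
  cls <- classification
  ideal_ids <- which(cls$class == "ideal")
  if (length(ideal_ids) == 0L || igraph::vcount(g) == 0L) {
    return(data.frame(sample1 = character(), gene1 = character(),
                      sample2 = character(), gene2 = character(),
                      component = integer(), stringsAsFactors = FALSE))
  }
  samp <- igraph::V(g)$sample
  gene <- igraph::V(g)$gene
  rank <- match(samp, g$sample_ids)
  out <- lapply(ideal_ids, function(cid) {
    vs <- which(cls$membership == cid)
    vs <- vs[order(rank[vs])]
    pr <- utils::combn(seq_along(vs), 2L)
    data.frame(sample1 = samp[vs[pr[1L, ]]], gene1 = gene[vs[pr[1L, ]]],
               sample2 = samp[vs[pr[2L, ]]], gene2 = gene[vs[pr[2L, ]]],
               component = cid, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Restrict a gene match table to ideal-component gene pairs
#'
#' Keeps exactly the rows whose (sample-1 gene, sample-2 gene) pair appears
#' in some ideal component; surviving rows are unmodified.
#'
#' @param t a [gene_match_table].
#' @param pairs data frame from [ideal_gene_pairs()] computed on a graph
#'   built over match tables including `t`.
#' @return A filtered [gene_match_table].
#' @export
filter_to_ideal <- function(t, pairs) {
  stopifnot(inherits(t, "gene_match_table"))
  s1 <- attr(t, "sample1"); s2 <- attr(t, "sample2")
  rel <- pairs[(pairs$sample1 == s1 & pairs$sample2 == s2) |
                 (pairs$sample1 == s2 & pairs$sample2 == s1), , drop = FALSE]
  flip <- rel$sample1 == s2
  key_ok <- paste(ifelse(flip, rel$gene2, rel$gene1),
                  ifelse(flip, rel$gene1, rel$gene2), sep = "\r")
  df <- as.data.frame(t)
  keep <- paste(df$s1gene, df$s2gene, sep = "\r") %in% key_ok
  gene_match_table(df[keep, , drop = FALSE], s1, s2)
}

#' Export a gene matches graph
#'
#' Writes an edge-list TSV (`sample1 gene1 sample2 gene2`), a GraphML file,
#' and a component report TSV (`component_id size class members`).
#'
#' @param g graph from [build_match_graph()].
#' @param prefix output path prefix; files get suffixes `_edges.tsv`,
#'   `.graphml`, `_components.tsv`.
#' @param classification optional result of [classify_components()].
#' @return Named character vector of the written paths, invisibly.
#' @export
write_graph_exports <- function(g, prefix,
                                classification = classify_components(g)) {
  edge_path <- paste0(prefix, "_edges.tsv")
  graphml_path <- paste0(prefix, ".graphml")
  comp_path <- paste0(prefix, "_components.tsv")
  if (igraph::ecount(g) > 0) {
    ends <- igraph::ends(g, igraph::E(g), names = FALSE)
    edf <- data.frame(sample1 = igraph::V(g)$sample[ends[, 1L]],
                      gene1 = igraph::V(g)$gene[ends[, 1L]],
                      sample2 = igraph::V(g)$sample[ends[, 2L]],
                      gene2 = igraph::V(g)$gene[ends[, 2L]])
  } else {
    edf <- data.frame(sample1 = character(), gene1 = character(),
                      sample2 = character(), gene2 = character())
  }
  utils::write.table(edf, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  igraph::write_graph(g, graphml_path, format = "graphml")
  cls <- classification
  members <- vapply(seq_along(cls$sizes), function(cid) {
    vs <- which(cls$membership == cid)
    paste(igraph::V(g)$name[vs], collapse = ",")
  }, "")
  utils::write.table(
    data.frame(component_id = seq_along(cls$sizes), size = cls$sizes,
               class = as.character(cls$class), members = gsub("\t", ":", members)),
    comp_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(edges = edge_path, graphml = graphml_path, components = comp_path))
}
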