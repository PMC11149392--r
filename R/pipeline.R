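# End-to-end run orchestration: read inputs, run the distance pipeline, and
# write the full output bundle (selected genes, HSP tables, match tables,
# graph exports, component report, distance matrix, NJ tree, PCoA
# coordinates, manifest).

# Stable short hash of the run configuration, so resumed or repeated runs
# can be recognized; every output file name carries it.
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(config),
                   vapply(config, function(v) paste(format(v, digits = 15),
                                                    collapse = ","), ""),
                   sep = "="), tmp)
  substr(unname(tools::md5sum(tmp)), 1L, 8L)
}

#' Run configuration for the full pipeline
#'
#' Defaults follow the method's standard settings: the top `n = 50000` genes
#' per sample, `N = 1` best HSP per query gene, and a BLASTn e-value cutoff
#' of 1e-99.
#'
#' @param n top genes selected per sample by k-mer coverage.
#' @param N top HSPs per query gene.
#' @param evalue_cutoff BLASTn e-value cutoff.
#' @param mode distance mode; see [distance_matrix()].
#' @param aligner `"blastn"` or `"builtin"`.
#' @param min_identity_fraction identity threshold for the builtin aligner.
#' @param k k-mer length for the Jaccard baseline (if requested).
#' @param dedupe_ties collapse tied match rows; see [match_table()].
#' @param pcoa_dims axes to report from PCoA.
#' @param seed recorded in the manifest (the alignment pipeline itself is
#'   deterministic).
#' @return List of class `run_config`.
#' @export
run_config <- function(n = 50000L, N = 1L, evalue_cutoff = 1e-99,
                       mode = "auto", aligner = "blastn",
                       min_identity_fraction = 0.7, k = 21L,
                       dedupe_ties = FALSE, pcoa_dims = 2L, seed = 1L) {
  structure(list(n = as.integer(n), N = as.integer(N),
                 evalue_cutoff = evalue_cutoff, mode = mode,
                 aligner = aligner,
                 min_identity_fraction = min_identity_fraction,
                 k = as.integer(k), dedupe_ties = dedupe_ties,
                 pcoa_dims = as.integer(pcoa_dims), seed = as.integer(seed)),
            class = "run_config")
}

pipeline_stage <- function(stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop("[stage ", stage, "] ", conditionMessage(e), call. = FALSE)
  })
  message(sprintf("[%s] done in %.1fs", stage, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full distance pipeline on a set of FASTA files
#'
#' Reads per-sample transcriptome FASTAs, selects top genes, generates
#' reciprocal HSPs, reduces them to gene match tables, builds and classifies
#' the gene matches graph, computes the ideal-filtered distance matrix, and
#' derives a neighbor-joining tree and PCoA coordinates. All intermediate and
#' final artifacts are written under `output_dir`, with file names carrying a
#' hash of the configuration so outputs from different configurations never
#' mix.
#'
#' @param inputs character vector of at least two FASTA paths.
#' @param output_dir output directory (created if needed).
#' @param config a [run_config()].
#' @param header_scheme,mapping passed to [read_transcriptome()].
#' @return Invisibly, a list with the distance matrix, tree, PCoA result,
#'   component counts, and a named vector of output paths.
#' @export
run_pipeline <- function(inputs, output_dir, config = run_config(),
                         header_scheme = "rnaspades", mapping = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (length(inputs) < 2L) stop("[stage inputs] at least two input FASTAs are required")
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in) > 0L) {
    stop("[stage inputs] input path not found: ", missing_in[1L])
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  h <- config_hash(config)
  tag <- function(name) file.path(output_dir, paste0(h, "_", name))

  samples <- pipeline_stage("inputs", lapply(inputs, read_transcriptome,
                                             header_scheme = header_scheme,
                                             mapping = mapping))
  ids <- vapply(samples, sample_id, "")
  if (anyDuplicated(ids)) stop("[stage inputs] duplicate sample ids among inputs")

  selected <- pipeline_stage("select", {
    sel <- lapply(samples, select_top_genes, n = config$n)
    for (t in sel) write_transcriptome(t, tag(paste0("selected_", sample_id(t), ".fasta")))
    sel
  })

  tables <- pipeline_stage("match", {
    pairs <- sample_pairs(ids)
    tabs <- vector("list", nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      t1 <- selected[[pairs$i[r]]]; t2 <- selected[[pairs$j[r]]]
      hs <- pair_hsps(t1, t2, aligner = config$aligner,
                      evalue_cutoff = config$evalue_cutoff,
                      min_identity_fraction = config$min_identity_fraction,
                      workdir = file.path(output_dir, paste0(h, "_blastwork")))
      write_hsp_table(hs$forward, tag(paste0("hsp_", sample_id(t1), "__vs__",
                                             sample_id(t2), ".tsv")))
      write_hsp_table(hs$reverse, tag(paste0("hsp_", sample_id(t2), "__vs__",
                                             sample_id(t1), ".tsv")))
      tabs[[r]] <- match_table(hs$forward, hs$reverse, N = config$N,
                               dedupe_ties = config$dedupe_ties)
      write_match_table(tabs[[r]], tag(paste0("match_", sample_id(t1), "__",
                                              sample_id(t2), ".tsv")))
    }
    tabs
  })

  graph_out <- pipeline_stage("graph", {
    g <- build_match_graph(tables, ids)
    cls <- classify_components(g)
    write_graph_exports(g, tag("graph"), cls)
    list(g = g, cls = cls)
  })

  D <- pipeline_stage("dist", {
    mode <- config$mode
    if (mode == "auto") mode <- if (length(ids) == 2L) "two_sample_direct" else "ideal_filtered"
    use_tables <- tables
    if (mode == "ideal_filtered") {
      pairs_ideal <- ideal_gene_pairs(graph_out$g, graph_out$cls)
      use_tables <- lapply(tables, filter_to_ideal, pairs = pairs_ideal)
    }
    pairs <- sample_pairs(ids)
    empty <- vapply(use_tables, nrow, 0L) == 0L
    if (any(empty)) {
      bad <- pairs[empty, , drop = FALSE]
      stop("no comparable orthologs for sample pair(s): ",
           paste(paste(ids[bad$i], ids[bad$j], sep = " / "), collapse = "; "))
    }
    D <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (r in seq_len(nrow(pairs))) {
      d <- pair_similarity(use_tables[[r]])$D
      D[pairs$i[r], pairs$j[r]] <- d
      D[pairs$j[r], pairs$i[r]] <- d
    }
    attr(D, "metadata") <- list(n = config$n, N = config$N,
                                evalue_cutoff = config$evalue_cutoff,
                                mode = mode, aligner = config$aligner,
                                seed = config$seed)
    write_distance_matrix(D, tag("distances"))
    D
  })

  tree <- pipeline_stage("tree", {
    tr <- neighbor_joining(D)
    ape::write.tree(tr, tag("nj.nwk"))
    tr
  })

  ord <- pipeline_stage("pcoa", {
    if (length(ids) >= 3L) {
      p <- pcoa(D, dims = config$pcoa_dims)
      utils::write.table(data.frame(sample = rownames(p$points), p$points),
                         tag("pcoa.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      p
    } else NULL
  })

  manifest <- c(list(package_version =
                       as.character(utils::packageVersion("orthoclique")),
                     config_hash = h, inputs = inputs, sample_ids = ids,
                     components = graph_out$cls[c("n_small", "n_large",
                                                  "n_ideal", "n_large_nonideal")]),
                unclass(config))
  jsonlite::write_json(manifest, tag("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)

  invisible(list(distances = D, tree = tree, pcoa = ord,
                 components = graph_out$cls[c("n_small", "n_large", "n_ideal",
                                              "n_large_nonideal")],
                 output_dir = output_dir, config_hash = h))
}
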