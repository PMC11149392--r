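# Downstream analyses: neighbor-joining trees, principal coordinates
# analysis, Robinson-Foulds topology comparison, and the parameter sweeps
# over gene count n and sample count s. NJ and PCoA are implemented to their
# published definitions (with library implementations used as independent
# cross-checks in the test suite).

check_square_distance <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (is.null(rownames(D))) stop("distance matrix must carry sample ids as dimnames")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix must have a zero diagonal")
  invisible(D)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (Studier-Keppler Q criterion). The matrix is
#' symmetrized by averaging with its transpose before clustering, since the
#' pipeline's pairwise distances are computed in one orientation. Q-criterion
#' ties are broken deterministically by the lowest (row, column) index pair.
#' Negative branch-length estimates are retained as computed. For two samples
#' the tree is a single edge carrying the full distance.
#'
#' @param D square distance matrix with a zero diagonal and sample dimnames.
#' @return An unrooted `ape` "phylo" tree (basal trifurcation).
#' @export
neighbor_joining <- function(D) {
  check_square_distance(D)
  D <- (D + t(D)) / 2
  labels <- rownames(D)
  s <- nrow(D)
  if (s == 2L) {
    return(ape::read.tree(text = sprintf("(%s:%.12g,%s:%.12g);", labels[1L],
                                         D[1L, 2L] / 2, labels[2L], D[1L, 2L] / 2)))
  }
  frag <- labels
  d <- D
  nwk_num <- function(x) sprintf("%.12g", x)
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    Q <- (m - 2) * d - outer(r, r, `+`)
    diag(Q) <- Inf
    # lowest (i, j) among ties, column-major scan of the upper triangle
    Q[lower.tri(Q)] <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    i <- best[1L, 1L]; j <- best[1L, 2L]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    new_frag <- paste0("(", frag[i], ":", nwk_num(bi), ",",
                       frag[j], ":", nwk_num(bj), ")")
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
  }
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  newick <- paste0("(", frag[1L], ":", nwk_num(b1), ",",
                   frag[2L], ":", nwk_num(b2), ",",
                   frag[3L], ":", nwk_num(b3), ");")
  ape::read.tree(text = newick)
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and returns the top `dims`
#' axes ordered by eigenvalue. Axes with negative eigenvalues are dropped
#' (their count and magnitudes are reported); axes with zero eigenvalue yield
#' zero coordinates, so an all-zero matrix gives all-zero coordinates.
#'
#' @param D square symmetric distance matrix with a zero diagonal.
#' @param dims number of axes to return; values above `s - 1` are clamped
#'   with a warning.
#' @return List with `points` (samples x dims matrix), `eigenvalues` (all s),
#'   and `n_negative` (count of negative eigenvalues).
#' @export
pcoa <- function(D, dims = 2L) {
  check_square_distance(D)
  D <- (D + t(D)) / 2
  s <- nrow(D)
  if (dims > s - 1L) {
    warning("dims clamped to s - 1 = ", s - 1L)
    dims <- s - 1L
  }
  dims <- as.integer(max(dims, 1L))
  C <- diag(s) - matrix(1 / s, s, s)
  B <- -0.5 * C %*% (D^2) %*% C
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  vals <- e$values
  tol <- 1e-9 * max(1, abs(vals[1L]))
  usable <- which(vals > -tol)  # non-negative axes, already sorted by value
  take <- usable[seq_len(min(dims, length(usable)))]
  pts <- e$vectors[, take, drop = FALSE] %*% diag(sqrt(pmax(vals[take], 0)),
                                                  length(take))
  if (ncol(pts) < dims) {
    pts <- cbind(pts, matrix(0, s, dims - ncol(pts)))
  }
  dimnames(pts) <- list(rownames(D), paste0("Axis", seq_len(dims)))
  list(points = pts, eigenvalues = vals, n_negative = sum(vals < -tol))
}

# Non-trivial bipartitions of a tree as canonical strings: each internal
# edge splits the leaves; the side not containing the reference leaf is
# sorted and joined. Duplicate splits (e.g. around a rooted tree's root) are
# collapsed.
tree_bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  labels <- tree$tip.label
  ref <- sort(labels)[1L]
  below <- vector("list", n_tip + tree$Nnode)
  for (tip in seq_len(n_tip)) below[[tip]] <- labels[tip]
  for (e in ape::postorder(tree)) {
    par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    below[[par]] <- c(below[[par]], below[[child]])
  }
  splits <- character()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    if (child <= n_tip) next
    side <- below[[child]]
    if (ref %in% side) side <- setdiff(labels, side)
    if (length(side) < 2L || length(side) > n_tip - 2L) next
    splits <- c(splits, paste(sort(side), collapse = "|"))
  }
  unique(splits)
}

#' Robinson-Foulds distance between two trees
#'
#' Counts the non-trivial bipartitions present in exactly one of the two
#' trees; 0 means the trees are topologically identical.
#'
#' @param t1,t2 `ape` "phylo" trees over the same leaf label set.
#' @return Non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label) ||
      length(t1$tip.label) != length(t2$tip.label)) {
    stop("trees must have identical leaf label sets")
  }
  b1 <- tree_bipartitions(t1)
  b2 <- tree_bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

run_sweep_cell <- function(samples, subset_idx, n, ...) {
  ids <- vapply(samples, sample_id, "")
  elapsed <- system.time(
    counts <- component_counts(samples[subset_idx], n = n, ...)
  )[["elapsed"]]
  data.frame(n = n, s = length(subset_idx),
             subset = paste(ids[subset_idx], collapse = ","),
             n_small = counts$n_small, n_large = counts$n_large,
             n_ideal = counts$n_ideal,
             n_large_nonideal = counts$n_large_nonideal,
             elapsed = elapsed, stringsAsFactors = FALSE)
}

#' Sweep gene matches graph component counts over n and sample subsets
#'
#' For each requested gene count `n` and each sample subset, runs the
#' pipeline through component classification and records the component
#' counts.
#'
#' Subset strategies: `"all"` uses the full sample set once per `n`;
#' `"prefix"` uses the size-2 ... size-s prefixes of a given permutation, so
#' successive subsets are nested; `"fair"` draws subsets of each size 2..s
#' uniformly at random, allocating trials so the expected time spent on each
#' size is approximately equal (sizes whose accumulated runtime is lowest are
#' tried next, using observed running means), until a time budget or per-size
#' trial cap is exhausted.
#'
#' @param samples list of [transcriptome] objects.
#' @param n_values integer vector of top-gene counts to test.
#' @param subset_strategy `"all"`, `"prefix"`, or `"fair"`.
#' @param permutation for `"prefix"`: sample ids (or indices) in the desired
#'   order; sizes beyond the sample count are an error.
#' @param time_budget for `"fair"`: total seconds to spend.
#' @param max_trials_per_size for `"fair"`: per-size trial cap (alternative
#'   or complement to `time_budget`).
#' @param seed for `"fair"`: RNG seed for subset draws.
#' @param ... passed to [component_counts()] (aligner, thresholds, ...).
#' @return Data frame with columns `n`, `s`, `subset`, `n_small`, `n_large`,
#'   `n_ideal`, `n_large_nonideal`, `elapsed`.
#' @export
sweep_components <- function(samples, n_values,
                             subset_strategy = c("all", "prefix", "fair"),
                             permutation = NULL, time_budget = NULL,
                             max_trials_per_size = NULL, seed = 1L, ...) {
  subset_strategy <- match.arg(subset_strategy)
  ids <- vapply(samples, sample_id, "")
  s <- length(samples)
  records <- list()

  if (subset_strategy == "all") {
    for (n in n_values) {
      records[[length(records) + 1L]] <-
        run_sweep_cell(samples, seq_len(s), n, ...)
    }
  } else if (subset_strategy == "prefix") {
    if (is.null(permutation)) stop("prefix strategy requires a permutation")
    idx <- if (is.character(permutation)) match(permutation, ids) else as.integer(permutation)
    if (anyNA(idx) || length(idx) > s || anyDuplicated(idx)) {
      stop("permutation must be a subset-free ordering of the samples ",
           "(prefix size cannot exceed the sample count)")
    }
    for (n in n_values) {
      for (size in 2:length(idx)) {
        records[[length(records) + 1L]] <-
          run_sweep_cell(samples, idx[seq_len(size)], n, ...)
      }
    }
  } else {
    if (is.null(time_budget) && is.null(max_trials_per_size)) {
      stop("fair strategy requires a time_budget or max_trials_per_size")
    }
    set.seed(as.integer(seed))
    sizes <- 2:s
    spent <- stats::setNames(numeric(length(sizes)), sizes)
    trials <- stats::setNames(integer(length(sizes)), sizes)
    tried <- stats::setNames(vector("list", length(sizes)), sizes)
    total_subsets <- choose(s, sizes)
    start <- proc.time()[["elapsed"]]
    repeat {
      open <- which((is.null(max_trials_per_size) |
                       trials < max_trials_per_size) &
                      lengths(tried) < total_subsets)
      if (length(open) == 0L) break
      if (!is.null(time_budget) &&
          proc.time()[["elapsed"]] - start >= time_budget) break
      k <- open[which.min(spent[open])]
      size <- sizes[k]
      repeat {
        subset <- sort(sample.int(s, size))
        key <- paste(subset, collapse = ",")
        if (!key %in% tried[[k]]) break
      }
      tried[[k]] <- c(tried[[k]], key)
      for (n in n_values) {
        rec <- run_sweep_cell(samples, subset, n, ...)
        spent[k] <- spent[k] + rec$elapsed
        records[[length(records) + 1L]] <- rec
      }
      trials[k] <- trials[k] + 1L
    }
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}
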