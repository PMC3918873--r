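#' Intersect per-line downregulated gene sets into a core signature
#'
#' The core transcriptional program is the exact intersection of the
#' significantly downregulated sets across all cell lines. When DE results
#' are supplied the signature genes are ordered by mean log2 fold change
#' ascending (most downregulated first) and pairwise overlap counts and
#' fold-change correlations between lines are recorded.
#'
#' @param per_line_down named list (>= 2 entries) of downregulated gene id
#'   vectors, one per cell line.
#' @param de_results optional named list of `de_result` objects matching
#'   `per_line_down`, used for ordering and pairwise correlations.
#' @return An object of class `core_signature` with elements `gene_ids`,
#'   `per_line_down`, `pairwise` (overlap count matrix and, when DE results
#'   are given, a correlation matrix).
#' @export
intersect_down <- function(per_line_down, de_results = NULL) {
  if (!is.list(per_line_down) || length(per_line_down) < 2L)
    stop("need at least two gene sets", call. = FALSE)
  sets <- lapply(per_line_down, function(s) unique(as.character(s)))
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    names(sets) <- sprintf("line%d", seq_along(sets))
  core <- Reduce(intersect, sets)

  n <- length(sets)
  counts <- matrix(0L, n, n, dimnames = list(names(sets), names(sets)))
  for (i in seq_len(n)) for (j in seq_len(n))
    counts[i, j] <- length(intersect(sets[[i]], sets[[j]]))

  correlations <- NULL
  if (!is.null(de_results)) {
    stopifnot(length(de_results) == n)
    correlations <- matrix(NA_real_, n, n, dimnames = dimnames(counts))
    for (i in seq_len(n)) for (j in seq_len(n))
      correlations[i, j] <- suppressWarnings(
        overlap_correlation(de_results[[i]], de_results[[j]])$r)
    if (length(core) > 1L) {
      lfc <- sapply(de_results, function(d) d$log2fc[match(core, d$gene)])
      core <- core[order(rowMeans(as.matrix(lfc)))]
    }
  }

  structure(list(gene_ids = core, per_line_down = sets,
                 pairwise = list(counts = counts, correlations = correlations)),
            class = "core_signature")
}

#' @export
print.core_signature <- function(x, ...) {
  cat(sprintf("core_signature: %d genes common to %d cell lines\n",
              length(x$gene_ids), length(x$per_line_down)))
  invisible(x)
}

#' Fold-change correlation and shared-downregulation count for two lines
#'
#' Pearson correlation of per-gene log2 fold changes between two DE results,
#' computed by default over the union of either line's significant genes
#' (the regulated genes the comparison concerns); set `genes = "all"` to use
#' the whole shared gene universe.
#'
#' @param de_a,de_b `de_result` objects from [moderated_de()].
#' @param genes `"significant"` (default) or `"all"`.
#' @param fdr,fc significance thresholds passed to [call_significant()].
#' @return list with `r` (Pearson correlation, `NA` with a warning when
#'   fewer than 3 shared genes are available) and `shared_down`
#'   (`|downA` \eqn{\cap} `downB|`).
#' @export
overlap_correlation <- function(de_a, de_b, genes = c("significant", "all"),
                                fdr = 0.05, fc = 2) {
  genes <- match.arg(genes)
  sig_a <- call_significant(de_a, fdr, fc)
  sig_b <- call_significant(de_b, fdr, fc)
  shared_down <- length(intersect(sig_a$down, sig_b$down))

  universe <- intersect(de_a$gene, de_b$gene)
  if (length(universe) == 0L) stop("gene universes do not overlap", call. = FALSE)
  use <- if (genes == "significant") {
    intersect(universe, unique(c(unlist(sig_a), unlist(sig_b))))
  } else universe
  if (length(use) < 3L) {
    warning("fewer than 3 shared genes; correlation undefined")
    return(list(r = NA_real_, shared_down = shared_down, n_genes = length(use)))
  }
  r <- cor(de_a$log2fc[match(use, de_a$gene)],
           de_b$log2fc[match(use, de_b$gene)])
  list(r = r, shared_down = shared_down, n_genes = length(use))
}

#' Cluster genes by their cross-line fold-change profiles
#'
#' Agglomerative complete-linkage clustering on the Euclidean distance
#' between per-gene fold-change signatures; clusters are the connected
#' components after cutting the dendrogram at `cutoff`.
#'
#' @param log2fc_matrix genes x cell-lines numeric matrix.
#' @param cutoff dendrogram cut height (default 10).
#' @return Integer cluster labels named by gene.
#' @export
cluster_genes <- function(log2fc_matrix, cutoff = 10) {
  x <- as.matrix(log2fc_matrix)
  if (nrow(x) < 2L) stop("need at least two genes", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite values in fold-change matrix", call. = FALSE)
  hc <- hclust(dist(x, method = "euclidean"), method = "complete")
  cutree(hc, h = cutoff)
}
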