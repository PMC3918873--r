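#' Map a core signature onto a measured cohort matrix
#'
#' Restricts a cohort expression matrix to the signature genes that the
#' measurement platform covers. The platform map may be many-to-one or have
#' gaps; multiple measured rows per gene are averaged; signature genes with
#' no mapped measurement are dropped and reported.
#'
#' @param cohort genes x patients numeric matrix (row names are platform
#'   row ids).
#' @param signature a `core_signature` or character vector of gene ids.
#' @param platform_map data.frame with columns `gene_id`, `row_id`.
#' @return list with `matrix` (one row per mapped signature gene, named by
#'   gene), `mapped_genes` (count), `unmapped` (gene ids without
#'   measurement). Zero mapped genes is an error.
#' @export
extract_signature <- function(cohort, signature, platform_map) {
  genes <- if (inherits(signature, "core_signature")) signature$gene_ids else
    as.character(signature)
  stopifnot(all(c("gene_id", "row_id") %in% names(platform_map)))
  cohort <- as.matrix(cohort)
  rows <- lapply(genes, function(g) {
    ids <- platform_map$row_id[platform_map$gene_id == g]
    ids[ids %in% rownames(cohort)]
  })
  mapped <- lengths(rows) > 0
  if (!any(mapped)) stop("no signature gene maps to a measured row", call. = FALSE)
  out <- t(vapply(which(mapped), function(i) {
    colMeans(cohort[rows[[i]], , drop = FALSE])
  }, numeric(ncol(cohort))))
  dimnames(out) <- list(genes[mapped], colnames(cohort))
  list(matrix = out, mapped_genes = sum(mapped), unmapped = genes[!mapped])
}

#' Default platform fixture mapping a core signature onto cohort rows
#'
#' Deterministic fixture standing in for a measurement platform's probe
#' manifest (synthetic; no real platform is consulted): the named program
#' members come first, then the abstract core ids in order, and the first
#' `n_mapped` of them receive a measured row id; the remainder are left
#' unmeasured.
#'
#' @param core_gene_ids the signature gene ids (typically 26).
#' @param cohort_gene_ids measured row ids, one per mapped gene.
#' @param n_mapped how many signature genes the platform covers (default
#'   `length(cohort_gene_ids)`, conventionally 18).
#' @return data.frame with columns `gene_id`, `row_id`.
#' @export
default_platform_map <- function(core_gene_ids, cohort_gene_ids,
                                 n_mapped = length(cohort_gene_ids)) {
  named <- intersect(c("BCL2", "MYC", "IRF8"), core_gene_ids)
  ordered <- c(named, sort(setdiff(core_gene_ids, named)))
  if (n_mapped > length(ordered) || n_mapped > length(cohort_gene_ids))
    stop("n_mapped exceeds available genes or rows", call. = FALSE)
  data.frame(gene_id = ordered[seq_len(n_mapped)],
             row_id = cohort_gene_ids[seq_len(n_mapped)],
             stringsAsFactors = FALSE)
}

#' Classify cohort patients by hierarchical clustering of the signature
#'
#' Agglomerative complete-linkage clustering of patients on the Euclidean
#' distance between their signature profiles (per-gene z-scored by
#' default). The dendrogram can be cut into a requested number of groups
#' (`k`), at a height (`h`), or — the default — into the group count in
#' `2..max_k` that maximizes the relative gap between successive merge
#' heights, so well-separated subgroups are recovered without fixing their
#' number in advance. Group numbers follow dendrogram left-to-right order.
#'
#' @param sub_matrix genes x patients matrix (e.g. from
#'   [extract_signature()]).
#' @param k requested group count (optional).
#' @param h dendrogram cut height (optional).
#' @param zscore z-score each gene across patients before distances
#'   (default TRUE).
#' @param max_k largest group count considered in automatic mode
#'   (default 12).
#' @return Object of class `cohort_classification`: `groups` (integer
#'   labels named by patient), `k`, `hclust` (merge tree), `cut_mode`.
#' @export
classify_patients <- function(sub_matrix, k = NULL, h = NULL, zscore = TRUE,
                              max_k = 12) {
  x <- as.matrix(sub_matrix)
  if (ncol(x) < 2L) stop("need at least two patients", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite values in cohort matrix", call. = FALSE)
  if (zscore) {
    mu <- rowMeans(x)
    sdev <- apply(x, 1, sd)
    sdev[sdev == 0] <- 1
    x <- (x - mu) / sdev
  }
  hc <- hclust(dist(t(x), method = "euclidean"), method = "complete")

  cut_mode <- if (!is.null(k)) "k" else if (!is.null(h)) "height" else "auto"
  if (cut_mode == "auto") {
    heights <- hc$height
    n <- length(heights) + 1L
    ks <- seq(2L, min(max_k, n - 1L))
    ## cutting into k groups removes the k-1 tallest merges; score k by the
    ## relative gap between the heights just below and above that cut
    gap <- vapply(ks, function(kk) {
      heights[n - kk + 1L] / heights[n - kk]
    }, numeric(1))
    k <- ks[which.max(gap)]
  }
  raw <- if (cut_mode == "height") cutree(hc, h = h) else cutree(hc, k = k)

  ## renumber groups in dendrogram left-to-right order
  first_seen <- raw[hc$order]
  relabel <- stats::setNames(seq_along(unique(first_seen)), unique(first_seen))
  groups <- stats::setNames(as.integer(relabel[as.character(raw)]), names(raw))

  structure(list(groups = groups, k = length(unique(groups)), hclust = hc,
                 cut_mode = cut_mode),
            class = "cohort_classification")
}

#' @export
print.cohort_classification <- function(x, ...) {
  cat(sprintf("cohort_classification: %d patients in %d groups (%s cut)\n",
              length(x$groups), x$k, x$cut_mode))
  invisible(x)
}

#' Chi-square association between patient groups and clinical factors
#'
#' Pearson chi-square (no continuity correction) on the groups x levels
#' contingency table, per factor. Degenerate factors (a single level or a
#' single group) are flagged without a statistic; a warning is recorded
#' when any expected count falls below 5.
#'
#' @param groups integer/character group label per patient.
#' @param factors data.frame of categorical labels (one column per factor;
#'   a `patient_id` column is ignored).
#' @return Named list; per factor: `table`, `expected`, `chi2`, `df`, `p`,
#'   `degenerate`, `small_counts`.
#' @export
association_test <- function(groups, factors) {
  if (is.data.frame(factors))
    factors <- factors[, setdiff(names(factors), "patient_id"), drop = FALSE]
  stopifnot(nrow(factors) == length(groups))
  lapply(as.list(factors), function(f) {
    tab <- table(group = groups, level = f)
    if (nrow(tab) < 2L || ncol(tab) < 2L) {
      return(list(table = tab, expected = NULL, chi2 = NA_real_,
                  df = NA_integer_, p = NA_real_, degenerate = TRUE,
                  small_counts = FALSE))
    }
    fit <- suppressWarnings(chisq.test(tab, correct = FALSE))
    small <- any(fit$expected < 5)
    if (small)
      warning("some expected counts < 5; chi-square approximation may be poor",
              call. = FALSE)
    list(table = tab, expected = fit$expected,
         chi2 = unname(fit$statistic), df = unname(fit$parameter),
         p = unname(fit$p.value), degenerate = FALSE, small_counts = small)
  })
}

#' Adjusted agreement between recovered groups and planted archetypes
#'
#' Adjusted Rand index (chance-corrected partition agreement) via
#' [mclust::adjustedRandIndex()].
#'
#' @param groups recovered group labels.
#' @param truth planted archetype labels.
#' @return Adjusted Rand index in `[-1, 1]` (approximately 0 at chance).
#' @export
archetype_agreement <- function(groups, truth) {
  mclust::adjustedRandIndex(groups, truth)
}
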