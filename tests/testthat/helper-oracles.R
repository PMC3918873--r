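## Independent oracles and small fixture builders used across the suite.

## Benjamini-Hochberg step-up applied from its definition: q_(i) =
## min_{j >= i} p_(j) * n / j, capped at 1.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- p[o] * n / seq_len(n)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(n)
  q[o] <- pmin(q_sorted, 1)
  q
}

## Complete-linkage agglomeration by direct enumeration of all merges:
## repeatedly join the pair of clusters with the smallest maximum pairwise
## distance until that minimum exceeds the cutoff; returns the partition.
bf_complete_linkage <- function(x, cutoff) {
  d <- as.matrix(dist(x))
  clusters <- as.list(seq_len(nrow(d)))
  repeat {
    if (length(clusters) == 1L) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      dij <- max(d[clusters[[i]], clusters[[j]]])
      if (dij < best_d) { best_d <- dij; best <- c(i, j) }
    }
    if (best_d > cutoff) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(nrow(d))
  for (k in seq_along(clusters)) labels[clusters[[k]]] <- k
  labels
}

## Per-base coverage by direct accumulation, then binned mean depth.
bf_depth_bins <- function(intervals, binsize, chrom_len) {
  base <- numeric(chrom_len)
  for (i in seq_len(nrow(intervals))) {
    idx <- seq(intervals$start[i] + 1L, intervals$end[i])
    base[idx] <- base[idx] + 1
  }
  n_bins <- ceiling(chrom_len / binsize)
  vapply(seq_len(n_bins), function(b) {
    lo <- (b - 1L) * binsize + 1L
    hi <- min(b * binsize, chrom_len)
    sum(base[lo:hi]) / binsize
  }, numeric(1))
}

## all permutations of 1..n (n small) as a list of index vectors
combinat_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- combinat_permutations(n - 1L)
  out <- list()
  for (p in sub) for (k in 0:(n - 1L))
    out[[length(out) + 1L]] <- append(p, n, after = k)
  out
}

## two labelings describe the same partition? (canonical first-occurrence
## relabeling, so degenerate partitions compare cleanly)
same_partition <- function(a, b) {
  canon <- function(v) match(v, unique(v))
  identical(canon(as.vector(a)), canon(as.vector(b)))
}

## minimal read table
make_reads <- function(chrom, start, end, strand, mapq,
                       name = sprintf("r%03d", seq_along(start))) {
  data.frame(chrom = chrom, start = start, end = end, name = name,
             mapq = mapq, strand = strand, stringsAsFactors = FALSE)
}

## bundle with intensities given directly (already on the analysis scale)
make_bundle <- function(x, treatment, cell_line = "lineA") {
  n <- ncol(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("g%03d", seq_len(nrow(x)))
  samples <- data.frame(
    sample_id = sprintf("s%02d", seq_len(n)),
    cell_line = rep(cell_line, n),
    treatment = treatment,
    replicate = stats::ave(seq_len(n), treatment, FUN = seq_along),
    stringsAsFactors = FALSE)
  colnames(x) <- samples$sample_id
  expression_bundle(x, matrix(0.001, nrow(x), n,
                              dimnames = dimnames(x)),
                    samples,
                    data.frame(probe_id = rownames(x), gene_id = rownames(x),
                               stringsAsFactors = FALSE))
}

## small chip configuration for Monte-Carlo loops (geometry matches the
## default design at reduced depth and genome size)
small_chip_config <- function(seed, super_multiplier = 20) {
  chip_config(genome = c(chr1 = 15e6, chr2 = 15e6), n_enhancers = 120,
              n_super = 12, core_genes_with_se = 6,
              super_multiplier = super_multiplier,
              library_size_per_condition = 2e5, n_background_genes = 20,
              seed = seed)
}

chip_pipeline_rpm <- function(bundle, condition = "vehicle",
                              mapq_min = 10, fragment_len = 300) {
  filtered <- filter_reads(bundle$reads[[condition]], mapq_min, dedup = TRUE)
  frags <- extend_reads(filtered, fragment_len, bundle$genome)
  quantify_rpm(frags, bundle$regions, attr(filtered, "library_size"))
}

## full expression pipeline to per-line downregulated sets
expression_down_sets <- function(bundle, alpha = 0.01, fdr = 0.05, fc = 2) {
  b <- quantile_normalize(vst_transform(filter_probes(bundle, alpha)))
  lines <- unique(b$samples$cell_line)
  de <- lapply(lines, function(cl) moderated_de(b, cl))
  names(de) <- lines
  list(de = de,
       down = lapply(de, function(d) call_significant(d, fdr, fc)$down))
}
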