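## Aligned reads are handled as plain data.frames with columns
## chrom, start, end, name, mapq, strand (0-based half-open coordinates),
## the tagAlign-style representation the generators write as extended BED.

validate_reads <- function(reads) {
  required <- c("chrom", "start", "end", "strand", "mapq")
  if (!all(required %in% names(reads)))
    stop("reads need columns chrom, start, end, strand, mapq", call. = FALSE)
  if (nrow(reads) && any(reads$start >= reads$end))
    stop("read intervals must satisfy start < end", call. = FALSE)
  if (nrow(reads) && !all(reads$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  invisible(reads)
}

## strand-aware 5' position of each read
five_prime <- function(reads) {
  pos <- reads$start
  minus <- reads$strand == "-"
  pos[minus] <- reads$end[minus] - 1L
  pos
}

#' Filter aligned reads by mapping quality and PCR-duplicate status
#'
#' Retains reads with mapping quality strictly greater than `mapq_min`
#' (a read at exactly `mapq_min` is removed). With `dedup = TRUE`, at most
#' one read is kept per (chrom, 5' position, strand) key, the strand-aware
#' reading of "multiple reads mapping to identical genomic loci".
#'
#' @param reads read data.frame (see [read_bed()]).
#' @param mapq_min mapping-quality cutoff (default 10, strict `>`).
#' @param dedup remove duplicate loci (default TRUE).
#' @return Filtered reads; the retained read count (the RPM library size)
#'   is attached as attribute `library_size`.
#' @export
filter_reads <- function(reads, mapq_min = 10, dedup = TRUE) {
  validate_reads(reads)
  keep <- reads$mapq > mapq_min
  out <- reads[keep, , drop = FALSE]
  if (dedup && nrow(out)) {
    key <- data.table::data.table(chrom = out$chrom, pos = five_prime(out),
                                  strand = out$strand)
    out <- out[!duplicated(key), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "library_size") <- nrow(out)
  out
}

#' Extend reads along their strand to the fragment size
#'
#' A plus-strand read `[s, e)` becomes `[s, s + fragment_len)`; a
#' minus-strand read becomes `[e - fragment_len, e)`. Fragments are clipped
#' to `[0, chromosome length)`.
#'
#' @param reads read data.frame.
#' @param fragment_len estimated fragment size in bp (default 300); must be
#'   at least the read length.
#' @param genome named vector of chromosome lengths used for clipping
#'   (optional; without it only the zero bound is enforced).
#' @return data.frame of fragment intervals (`chrom`, `start`, `end`,
#'   `strand`).
#' @export
extend_reads <- function(reads, fragment_len = 300, genome = NULL) {
  validate_reads(reads)
  if (nrow(reads) && fragment_len < max(reads$end - reads$start))
    stop("fragment_len must be >= read length", call. = FALSE)
  plus <- reads$strand == "+"
  start <- ifelse(plus, reads$start, reads$end - fragment_len)
  end <- ifelse(plus, reads$start + fragment_len, reads$end)
  start <- pmax(start, 0)
  if (!is.null(genome)) {
    genome <- check_genome(genome)
    unknown <- setdiff(unique(reads$chrom), names(genome))
    if (length(unknown))
      stop(sprintf("reads on chromosomes absent from genome: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    end <- pmin(end, genome[reads$chrom])
  }
  data.frame(chrom = reads$chrom, start = as.numeric(start),
             end = as.numeric(end), strand = reads$strand,
             stringsAsFactors = FALSE)
}

#' Binned genome coverage from fragment intervals
#'
#' In `"fragments"` mode (default) a fragment increments every bin it
#' overlaps; in `"depth"` mode each bin records its mean per-base depth
#' (overlap bp / binsize), so that sum(bins) x binsize equals the total
#' fragment length, up to clipping at chromosome edges.
#'
#' @param intervals fragment data.frame from [extend_reads()].
#' @param binsize bin width in bp (>= 1).
#' @param genome named vector of chromosome lengths.
#' @param mode `"fragments"` or `"depth"`.
#' @param library_size retained read count to record on the track (defaults
#'   to the number of intervals).
#' @return A `coverage_track`: list of per-chromosome bin vectors plus
#'   `binsize`, `mode`, `library_size`, `genome`.
#' @export
coverage_track <- function(intervals, binsize, genome,
                           mode = c("fragments", "depth"),
                           library_size = NULL) {
  mode <- match.arg(mode)
  binsize <- check_count(binsize, "binsize", min = 1L)
  genome <- check_genome(genome)
  if (nrow(intervals)) {
    bad <- !(intervals$chrom %in% names(genome)) |
      intervals$start < 0 | intervals$end > genome[intervals$chrom]
    if (any(bad)) stop("interval outside genome", call. = FALSE)
  }
  bins <- lapply(names(genome), function(chr) {
    n_bins <- ceiling(genome[[chr]] / binsize)
    iv <- intervals[intervals$chrom == chr, , drop = FALSE]
    if (!nrow(iv)) return(numeric(n_bins))
    if (mode == "fragments") {
      first <- iv$start %/% binsize + 1L
      last <- (iv$end - 1L) %/% binsize + 1L
      as.numeric(IRanges::coverage(IRanges::IRanges(first, last), width = n_bins))
    } else {
      cov <- IRanges::coverage(IRanges::IRanges(iv$start + 1L, iv$end),
                               width = n_bins * binsize)
      starts <- seq(1L, n_bins * binsize, by = binsize)
      as.numeric(IRanges::viewSums(
        IRanges::Views(cov, starts, starts + binsize - 1L))) / binsize
    }
  })
  names(bins) <- names(genome)
  structure(list(bins = bins, binsize = binsize, mode = mode,
                 library_size = library_size %||% nrow(intervals),
                 genome = genome),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d chromosomes, binsize %d (%s mode), library %d\n",
              length(x$bins), x$binsize, x$mode, x$library_size))
  invisible(x)
}

#' TSS-centered coverage heatmap and mean profile
#'
#' Extracts, for every gene, the coverage bins in `[TSS - flank,
#' TSS + flank)` oriented 5' to 3' (minus-strand rows are reversed), and the
#' columnwise mean profile. Windows running off a chromosome are clipped
#' with zeros and the affected genes flagged.
#'
#' @param track a [coverage_track()] .
#' @param genes data.frame with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @param flank half-window in bp (default 5000); must be a multiple of the
#'   track binsize.
#' @param order_rows `"signal"` (default, decreasing total row signal) or
#'   `"input"`.
#' @return list with `heatmap` (genes x bins matrix), `mean_profile`,
#'   `positions` (bin-start offsets relative to the TSS) and
#'   `clipped_genes`.
#' @export
tss_matrix <- function(track, genes, flank = 5000, order_rows = c("signal", "input")) {
  stopifnot(inherits(track, "coverage_track"))
  order_rows <- match.arg(order_rows)
  bs <- track$binsize
  if (flank %% bs != 0) stop("flank must be a multiple of the track binsize", call. = FALSE)
  nb <- flank %/% bs
  cols <- 2L * nb
  mat <- matrix(0, nrow = nrow(genes), ncol = cols,
                dimnames = list(genes$gene_id,
                                as.character(seq(-flank, flank - bs, by = bs))))
  clipped <- character(0)
  for (i in seq_len(nrow(genes))) {
    chr <- genes$chrom[i]
    if (!chr %in% names(track$bins)) { clipped <- c(clipped, genes$gene_id[i]); next }
    v <- track$bins[[chr]]
    centre <- genes$tss[i] %/% bs + 1L
    idx <- seq(centre - nb, centre + nb - 1L)
    ok <- idx >= 1L & idx <= length(v)
    if (!all(ok)) clipped <- c(clipped, genes$gene_id[i])
    row <- numeric(cols)
    row[ok] <- v[idx[ok]]
    if (genes$strand[i] == "-") row <- rev(row)
    mat[i, ] <- row
  }
  if (order_rows == "signal") mat <- mat[order(-rowSums(mat)), , drop = FALSE]
  list(heatmap = mat, mean_profile = colMeans(mat),
       positions = seq(-flank, flank - bs, by = bs), clipped_genes = clipped)
}

#' Simplified local-Poisson peak caller
#'
#' Scores every bin against a Poisson background whose rate is the maximum
#' of the global track mean and a local sliding-window mean, corrects the
#' upper-tail p-values by Benjamini-Hochberg, and merges adjacent
#' significant bins separated by at most `merge_gap` non-significant bins.
#' A deliberately simple stand-in for a full model-based peak caller:
#' super-enhancer regions arrive as input in this pipeline, so the caller
#' only needs a calibrated background model.
#'
#' @param track a [coverage_track()] in fragments mode.
#' @param lambda_bg global background rate; `NULL` (default) estimates it as
#'   the genome-wide mean bin count.
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param local_halfwidth local window half-width in bins (default 10).
#' @param merge_gap maximum run of sub-threshold bins bridged when merging
#'   (default 1).
#' @return data.frame of peaks (`chrom`, `start`, `end`, `n_bins`, `min_q`);
#'   empty for an all-zero track.
#' @export
call_peaks <- function(track, lambda_bg = NULL, alpha = 0.05,
                       local_halfwidth = 10, merge_gap = 1) {
  stopifnot(inherits(track, "coverage_track"))
  counts <- unlist(track$bins, use.names = FALSE)
  if (!length(counts) || all(counts == 0))
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      n_bins = integer(0), min_q = numeric(0)))
  global <- lambda_bg %||% mean(counts)
  if (global <= 0) stop("lambda_bg must be positive", call. = FALSE)

  pvals <- lapply(track$bins, function(v) {
    if (!length(v)) return(numeric(0))
    w <- 2L * local_halfwidth + 1L
    local <- if (length(v) > 1L) {
      cs <- cumsum(c(0, v))
      lo <- pmax(seq_along(v) - local_halfwidth, 1L)
      hi <- pmin(seq_along(v) + local_halfwidth, length(v))
      (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    } else v
    lambda <- pmax(global, local)
    ppois(v - 1, lambda, lower.tail = FALSE)
  })
  q <- bh_adjust(unlist(pvals, use.names = FALSE))
  qs <- split(q, rep(names(track$bins), lengths(pvals)))

  peaks <- list()
  for (chr in names(track$bins)) {
    sig <- qs[[chr]] < alpha
    if (!any(sig)) next
    idx <- which(sig)
    gaps <- diff(idx)
    grp <- cumsum(c(1L, gaps > merge_gap + 1L))
    for (g in unique(grp)) {
      b <- idx[grp == g]
      peaks[[length(peaks) + 1L]] <- data.frame(
        chrom = chr,
        start = (min(b) - 1L) * track$binsize,
        end = min(max(b) * track$binsize, track$genome[[chr]]),
        n_bins = length(b),
        min_q = min(qs[[chr]][b]))
    }
  }
  if (!length(peaks))
    return(data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
                      n_bins = integer(0), min_q = numeric(0)))
  do.call(rbind, peaks)
}
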