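regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(regions$chrom,
                         IRanges::IRanges(regions$start + 1, regions$end))
}

#' Reads-per-million signal over enhancer regions
#'
#' Counts extended fragments overlapping each region and normalizes by the
#' retained library size: `rpm_i = overlaps_i * 1e6 / library_size`.
#'
#' @param fragments extended-fragment data.frame from [extend_reads()].
#' @param regions data.frame with `region_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param library_size retained read count after filtering; defaults to the
#'   `library_size` attribute carried by [filter_reads()] output if
#'   `fragments` still has it, else the fragment count.
#' @return Numeric RPM vector named by region id.
#' @export
quantify_rpm <- function(fragments, regions, library_size = NULL) {
  library_size <- library_size %||% attr(fragments, "library_size") %||% nrow(fragments)
  if (is.null(library_size) || library_size <= 0)
    stop("library size must be positive", call. = FALSE)
  gr_regions <- regions_to_granges(regions)
  counts <- if (nrow(fragments)) {
    gr_frag <- GenomicRanges::GRanges(fragments$chrom,
                                      IRanges::IRanges(fragments$start + 1, fragments$end))
    GenomicRanges::countOverlaps(gr_regions, gr_frag)
  } else rep(0L, nrow(regions))
  stats::setNames(counts * 1e6 / library_size, regions$region_id)
}

#' Call super-enhancers from the ranked-signal inflection
#'
#' Regions are sorted by increasing signal and both axes scaled to
#' `[0, 1]`; the cutoff sits at the first point where the tangent slope of
#' the scaled rank-signal curve exceeds 1 (the point where signal starts
#' growing faster than rank), and every region above it is flagged super.
#' With all signals equal the scaled curve never exceeds slope 1 and no
#' region is flagged. Flags are invariant under positive rescaling of the
#' signal.
#'
#' @param rpm numeric signal vector (>= 2 regions), typically from
#'   [quantify_rpm()] on the vehicle condition.
#' @return list with `cutoff_value` (signal of the lowest flagged region;
#'   `Inf` when nothing is flagged) and `is_super` (logical, input order).
#' @export
call_super_enhancers <- function(rpm) {
  n <- length(rpm)
  if (n < 2L) stop("need at least two regions", call. = FALSE)
  if (any(!is.finite(rpm) | rpm < 0))
    stop("signals must be finite and non-negative", call. = FALSE)
  ord <- order(rpm)
  y <- rpm[ord]
  ymax <- y[n]
  is_super <- rep(FALSE, n)
  if (ymax > 0) {
    ## scaled tangent slope of segment i: n * (y[i+1] - y[i]) / ymax
    gaps <- diff(y)
    cross <- which(n * gaps / ymax > 1)
    if (length(cross)) is_super[ord[seq(cross[1] + 1L, n)]] <- TRUE
  }
  list(cutoff_value = if (any(is_super)) min(rpm[is_super]) else Inf,
       is_super = is_super)
}

#' Stitch nearby enhancer regions before ranking
#'
#' Optionally merges enhancers separated by at most `distance` bp into
#' single regions (ids joined with `"+"`), the pre-ranking consolidation
#' some super-enhancer workflows apply. Off the default analysis path;
#' `distance = 0` merges only overlapping/adjacent regions.
#'
#' @param regions enhancer data.frame (`region_id`, `chrom`, `start`,
#'   `end`).
#' @param distance maximum gap to bridge, bp (default 12500).
#' @return data.frame of stitched regions in the same layout.
#' @export
stitch_regions <- function(regions, distance = 12500) {
  stopifnot(distance >= 0)
  gr <- regions_to_granges(regions)
  merged <- GenomicRanges::reduce(gr, min.gapwidth = distance + 1)
  hits <- GenomicRanges::findOverlaps(gr, merged)
  ids <- vapply(split(regions$region_id[S4Vectors::queryHits(hits)],
                      S4Vectors::subjectHits(hits)),
                paste, character(1), collapse = "+")
  data.frame(region_id = unname(ids[as.character(seq_along(merged))]),
             chrom = as.character(GenomicRanges::seqnames(merged)),
             start = GenomicRanges::start(merged) - 1,
             end = GenomicRanges::end(merged),
             stringsAsFactors = FALSE)
}

#' Assign genes to enhancer regions within a distance window
#'
#' A gene is assigned to a region when the distance from its TSS to the
#' nearest region edge is at most `window` bp (zero when the TSS lies
#' inside the region). Genes may be assigned to more than one region; all
#' assignments are recorded.
#'
#' @param regions enhancer data.frame (`region_id`, `chrom`, `start`,
#'   `end`).
#' @param genes gene annotation with `gene_id`, `chrom`, `tss` (0-based
#'   position).
#' @param window distance window in bp (default 50000).
#' @return data.frame of assignments (`region_id`, `gene_id`, `distance`).
#'   Genes on chromosomes absent from `regions` are skipped with a warning.
#' @export
assign_genes <- function(regions, genes, window = 50000) {
  stopifnot(window >= 0)
  unknown <- setdiff(unique(genes$chrom), unique(regions$chrom))
  if (length(unknown))
    warning(sprintf("genes on chromosomes without regions skipped: %s",
                    paste(unknown, collapse = ", ")))
  gr_tss <- GenomicRanges::GRanges(genes$chrom,
                                   IRanges::IRanges(genes$tss + 1, genes$tss + 1))
  expanded <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(pmax(regions$start - window, 0) + 1, regions$end + window))
  hits <- GenomicRanges::findOverlaps(gr_tss, expanded)
  gi <- S4Vectors::queryHits(hits)
  ri <- S4Vectors::subjectHits(hits)
  distance <- pmax(0, regions$start[ri] - genes$tss[gi],
                   genes$tss[gi] - (regions$end[ri] - 1))
  out <- data.frame(region_id = regions$region_id[ri],
                    gene_id = genes$gene_id[gi],
                    distance = distance, stringsAsFactors = FALSE)
  out <- out[order(ri, gi), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the full enhancer table
#'
#' Combines per-condition RPM, ranks by increasing signal in the reference
#' condition, super-enhancer flags called on that condition, and
#' semicolon-joined assigned genes.
#'
#' @param regions enhancer skeleton data.frame.
#' @param rpm_by_condition named list of RPM vectors (same region order).
#' @param genes gene annotation (see [assign_genes()]).
#' @param reference condition used for ranking and super-enhancer calling
#'   (default first entry, conventionally the vehicle arm).
#' @param window assignment window in bp (default 50000).
#' @return An `enhancer_table` data.frame with `rpm_<condition>` columns,
#'   `rank`, `is_super`, `assigned_genes`; the assignment data.frame is
#'   attached as attribute `assignments`.
#' @export
build_enhancer_table <- function(regions, rpm_by_condition, genes,
                                 reference = names(rpm_by_condition)[1],
                                 window = 50000) {
  stopifnot(is.list(rpm_by_condition), length(rpm_by_condition) >= 1,
            reference %in% names(rpm_by_condition))
  tab <- regions
  for (cond in names(rpm_by_condition))
    tab[[paste0("rpm_", cond)]] <- as.numeric(rpm_by_condition[[cond]])
  ref <- rpm_by_condition[[reference]]
  tab$rank <- rank(ref, ties.method = "first")
  se <- if (length(ref) >= 2L) call_super_enhancers(ref) else
    list(cutoff_value = Inf, is_super = rep(FALSE, length(ref)))
  tab$is_super <- se$is_super
  asn <- assign_genes(regions, genes, window)
  joined <- vapply(split(asn$gene_id, asn$region_id), paste,
                   character(1), collapse = ";")
  tab$assigned_genes <- unname(joined[match(tab$region_id, names(joined))])
  tab$assigned_genes[is.na(tab$assigned_genes)] <- ""
  attr(tab, "assignments") <- asn
  attr(tab, "cutoff_value") <- se$cutoff_value
  attr(tab, "reference") <- reference
  class(tab) <- c("enhancer_table", "data.frame")
  tab
}

#' Per-region signal change between two conditions
#'
#' Computes per-region `delta = rpm_b - rpm_a` and ratio, plus the
#' hockey-stick plot series (per condition: regions ranked by increasing
#' signal in that condition with their RPM).
#'
#' @param table an [build_enhancer_table()] result.
#' @param cond_a,cond_b condition names present in the table.
#' @return list with `delta_table` (region, both RPMs, `delta`, `ratio`,
#'   `is_super`, ordered by delta) and `plot_data` (long data.frame:
#'   `condition`, `rank`, `rpm`).
#' @export
condition_delta <- function(table, cond_a, cond_b) {
  ca <- paste0("rpm_", cond_a); cb <- paste0("rpm_", cond_b)
  if (!all(c(ca, cb) %in% names(table)))
    stop("condition not quantified in enhancer table", call. = FALSE)
  a <- table[[ca]]; b <- table[[cb]]
  delta <- data.frame(region_id = table$region_id, rpm_a = a, rpm_b = b,
                      delta = b - a,
                      ratio = ifelse(a > 0, b / a, NA_real_),
                      is_super = table$is_super, stringsAsFactors = FALSE)
  delta <- delta[order(delta$delta), , drop = FALSE]
  rownames(delta) <- NULL
  plot_data <- do.call(rbind, lapply(c(cond_a, cond_b), function(cond) {
    v <- table[[paste0("rpm_", cond)]]
    data.frame(condition = cond, rank = seq_along(v), rpm = sort(v),
               stringsAsFactors = FALSE)
  }))
  list(delta_table = delta, plot_data = plot_data)
}
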