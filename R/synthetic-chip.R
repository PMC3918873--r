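#' Design of the synthetic two-condition ChIP-seq bundle
#'
#' Describes the toy genome, enhancer complement and sequencing depths the
#' ChIP-seq generator emulates: a heavy-tailed typical-enhancer signal
#' distribution, a designated super-enhancer subset with `super_multiplier`
#' times the typical scale, a planted link between `core_genes_with_se`
#' core-program genes and a nearby super-enhancer, and depletion of
#' super-enhancer reads in the treated (BET-inhibited) condition.
#'
#' Typical-enhancer signal weights are exponential draws winsorized at the
#' exponential's 95th percentile; super-enhancer weights are
#' `super_multiplier * (1 + Exp(1))` times the typical scale. The winsorized
#' background keeps the ranked-signal curve's inflection well defined (an
#' unbounded exponential tail is itself sparse enough at the top to mimic a
#' handful of super-enhancers), while preserving the hockey-stick shape.
#'
#' @param genome named vector of chromosome lengths; default four 30 Mb
#'   chromosomes.
#' @param n_enhancers total enhancer regions (default 500).
#' @param n_super designated super-enhancers among them (default 30).
#' @param core_genes_with_se core-program genes planted with a
#'   super-enhancer within 50 kb of their TSS (default 12).
#' @param typical_rpm_scale scale of the typical-enhancer signal weights
#'   (default 1; the super-enhancer calling geometry is invariant to it).
#' @param super_multiplier super-enhancer over typical signal ratio
#'   (default 20).
#' @param library_size_per_condition sequenced reads per condition
#'   (default 2e6).
#' @param fragment_len fragment size reads are later extended to
#'   (default 300).
#' @param ibet_se_depletion fraction of super-enhancer reads *retained* in
#'   the treated condition (default 0.3, i.e. a 70% loss).
#' @param seed integer seed.
#' @param read_len sequenced read length (default 36).
#' @param enhancer_width,super_width region widths in bp (defaults 2 kb and
#'   20 kb).
#' @param background_read_fraction fraction of the library scattered
#'   uniformly over the genome rather than at enhancers (default 0.5).
#' @param n_background_genes non-core genes in the annotation (default 174).
#' @return An object of class `chip_config`.
#' @export
chip_config <- function(genome = c(chr1 = 30e6, chr2 = 30e6, chr3 = 30e6, chr4 = 30e6),
                        n_enhancers = 500,
                        n_super = 30,
                        core_genes_with_se = 12,
                        typical_rpm_scale = 1,
                        super_multiplier = 20,
                        library_size_per_condition = 2e6,
                        fragment_len = 300,
                        ibet_se_depletion = 0.3,
                        seed = 1L,
                        read_len = 36,
                        enhancer_width = 2000,
                        super_width = 20000,
                        background_read_fraction = 0.5,
                        n_background_genes = 174) {
  cfg <- list(
    genome = check_genome(genome),
    n_enhancers = check_count(n_enhancers, "n_enhancers", min = 1L),
    n_super = check_count(n_super, "n_super"),
    core_genes_with_se = check_count(core_genes_with_se, "core_genes_with_se"),
    typical_rpm_scale = check_real(typical_rpm_scale, "typical_rpm_scale"),
    super_multiplier = check_real(super_multiplier, "super_multiplier"),
    library_size_per_condition = check_count(library_size_per_condition,
                                             "library_size_per_condition"),
    fragment_len = check_count(fragment_len, "fragment_len", min = 1L),
    ibet_se_depletion = check_fraction(ibet_se_depletion, "ibet_se_depletion"),
    seed = check_count(seed, "seed"),
    read_len = check_count(read_len, "read_len", min = 1L),
    enhancer_width = check_count(enhancer_width, "enhancer_width", min = 1L),
    super_width = check_count(super_width, "super_width", min = 1L),
    background_read_fraction = check_fraction(background_read_fraction,
                                              "background_read_fraction"),
    n_background_genes = check_count(n_background_genes, "n_background_genes")
  )
  if (cfg$ibet_se_depletion == 0)
    stop("ibet_se_depletion must lie in (0, 1]", call. = FALSE)
  if (cfg$n_super > cfg$n_enhancers)
    stop("n_super must not exceed n_enhancers", call. = FALSE)
  structure(cfg, class = "chip_config")
}

## MAPQ alphabet with fixed weights, so the MAPQ>10 filter always has work
MAPQ_LEVELS <- c(0L, 10L, 30L, 60L)
MAPQ_WEIGHTS <- c(0.05, 0.10, 0.25, 0.60)

TILE_SIZE <- 150000

#' Generate a synthetic two-condition ChIP-seq bundle with planted truth
#'
#' Lays out genes and enhancers on non-adjacent 150 kb tiles of the toy
#' genome so that exactly `core_genes_with_se` core-program genes carry a
#' designated super-enhancer within 50 kb of their TSS and *no other
#' enhancer* falls within 50 kb of any core-gene TSS. Reads are drawn per
#' region with Poisson counts proportional to the planted signal weights
#' (treated-condition super-enhancer weights scaled by
#' `ibet_se_depletion`), plus a uniform genome-wide background; each read
#' carries a MAPQ score from \{0, 10, 30, 60\} with fixed weights.
#'
#' @param config a [chip_config()].
#' @param truth planted truth from [generate_expression_bundle()] (supplies
#'   `core_gene_ids`); `core_genes_with_se` must not exceed the core block.
#' @return list with `reads` (named list of vehicle/treated read
#'   data.frames), `regions` (enhancer skeleton: `region_id`, `chrom`,
#'   `start`, `end`), `genes` (annotation with strand-aware `tss`),
#'   `genome`, and `truth` extended with `se_region_ids` and
#'   `se_core_gene_ids`.
#' @export
generate_chip_bundle <- function(config = chip_config(),
                                 truth = list(core_gene_ids = core_gene_names(26))) {
  stopifnot(inherits(config, "chip_config"))
  core_ids <- truth$core_gene_ids
  if (config$core_genes_with_se > length(core_ids))
    stop("core_genes_with_se exceeds the core block size", call. = FALSE)
  with_seed(config$seed + 1L, {
    genome <- config$genome
    n_typical <- config$n_enhancers - config$n_super
    n_core <- length(core_ids)

    ## tile bookkeeping: one feature per 150 kb tile keeps every enhancer
    ## except the designated supers > 50 kb away from every core-gene TSS
    tiles <- do.call(rbind, lapply(names(genome), function(chr) {
      n <- floor(genome[[chr]] / TILE_SIZE)
      if (n < 1) stop("chromosome shorter than one tile", call. = FALSE)
      data.frame(chrom = chr, start = (seq_len(n) - 1L) * TILE_SIZE)
    }))
    needed <- n_core + (config$n_super - config$core_genes_with_se) +
      n_typical + config$n_background_genes
    if (needed > nrow(tiles))
      stop("genome too small for the requested regions (regions would overflow chromosome bounds)",
           call. = FALSE)
    tiles <- tiles[sample.int(nrow(tiles), needed), , drop = FALSE]
    take <- function(n) {
      out <- tiles[seq_len(n), , drop = FALSE]
      tiles <<- tiles[-seq_len(n), , drop = FALSE]
      out
    }

    gene_width <- 10000
    ## core genes; the first core_genes_with_se (after a seeded shuffle)
    ## receive a designated super-enhancer
    core_order <- sample(core_ids)
    core_tiles <- take(n_core)
    core_strand <- sample(c("+", "-"), n_core, replace = TRUE)
    core_start <- core_tiles$start + 70000
    core_genes <- data.frame(
      gene_id = core_order, chrom = core_tiles$chrom,
      start = core_start, end = core_start + gene_width,
      strand = core_strand, is_core = TRUE, stringsAsFactors = FALSE)

    bg_tiles <- take(config$n_background_genes)
    bg_strand <- sample(c("+", "-"), config$n_background_genes, replace = TRUE)
    bg_start <- bg_tiles$start + 70000
    bg_genes <- data.frame(
      gene_id = sprintf("BGGENE%03d", seq_len(config$n_background_genes)),
      chrom = bg_tiles$chrom, start = bg_start, end = bg_start + gene_width,
      strand = bg_strand, is_core = FALSE, stringsAsFactors = FALSE)

    genes <- rbind(core_genes, bg_genes)
    genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)

    ## designated super-enhancers: edge 2-20 kb downstream of the paired TSS
    se_core <- head(core_order, config$core_genes_with_se)
    se_core_rows <- match(se_core, genes$gene_id)
    se_offset <- round(runif(length(se_core), 2000, 20000))
    se1 <- data.frame(chrom = genes$chrom[se_core_rows],
                      start = genes$tss[se_core_rows] + se_offset,
                      end = genes$tss[se_core_rows] + se_offset + config$super_width)

    n_free_super <- config$n_super - config$core_genes_with_se
    free_tiles <- take(n_free_super)
    se2 <- data.frame(chrom = free_tiles$chrom,
                      start = free_tiles$start + 65000,
                      end = free_tiles$start + 65000 + config$super_width)

    typ_tiles <- take(n_typical)
    typ_start <- typ_tiles$start + 65000 + round(runif(n_typical, -30000, 30000))
    typ <- data.frame(chrom = typ_tiles$chrom, start = typ_start,
                      end = typ_start + config$enhancer_width)

    regions <- rbind(se1, se2, typ)
    regions <- data.frame(region_id = sprintf("ENH%04d", seq_len(nrow(regions))),
                          regions, stringsAsFactors = FALSE)
    is_super_truth <- seq_len(nrow(regions)) <= config$n_super
    if (any(regions$start < 0 | regions$end > genome[regions$chrom]))
      stop("generated region overflows chromosome bounds", call. = FALSE)

    ## signal weights
    cap <- stats::qexp(0.95)
    w_typ <- config$typical_rpm_scale * pmin(rexp(n_typical), cap)
    w_sup <- config$typical_rpm_scale * config$super_multiplier * (1 + rexp(config$n_super))
    weights <- c(w_sup, w_typ)

    simulate_condition <- function(weights) {
      lib <- config$library_size_per_condition
      enh_reads <- (1 - config$background_read_fraction) * lib
      expected <- if (sum(weights) > 0) enh_reads * weights / sum(weights) else 0 * weights
      counts <- rpois(length(weights), expected)
      reads <- vector("list", length(weights) + 1L)
      for (i in seq_along(weights)) {
        n <- counts[i]
        if (n == 0) next
        lo <- regions$start[i]
        hi <- regions$end[i] - config$read_len
        s <- floor(runif(n, lo, hi + 1))
        str <- sample(c("+", "-"), n, replace = TRUE)
        reads[[i]] <- data.frame(chrom = regions$chrom[i], start = s,
                                 end = s + config$read_len, strand = str,
                                 stringsAsFactors = FALSE)
      }
      n_bg <- rpois(1, config$background_read_fraction * lib)
      if (n_bg > 0) {
        chr <- sample(names(genome), n_bg, replace = TRUE,
                      prob = genome / sum(genome))
        s <- floor(runif(n_bg, 0, genome[chr] - config$read_len + 1))
        reads[[length(weights) + 1L]] <- data.frame(
          chrom = chr, start = s, end = s + config$read_len,
          strand = sample(c("+", "-"), n_bg, replace = TRUE),
          stringsAsFactors = FALSE)
      }
      out <- data.table::rbindlist(reads)
      if (nrow(out) == 0L)
        return(data.frame(chrom = character(0), start = numeric(0),
                          end = numeric(0), name = character(0),
                          mapq = integer(0), strand = character(0),
                          stringsAsFactors = FALSE))
      out <- as.data.frame(out)
      out$name <- sprintf("r%07d", seq_len(nrow(out)))
      out$mapq <- sample(MAPQ_LEVELS, nrow(out), replace = TRUE, prob = MAPQ_WEIGHTS)
      out[, c("chrom", "start", "end", "name", "mapq", "strand")]
    }

    vehicle <- simulate_condition(weights)
    w_treated <- weights
    w_treated[seq_len(config$n_super)] <- w_treated[seq_len(config$n_super)] *
      config$ibet_se_depletion
    treated <- simulate_condition(w_treated)

    truth$se_region_ids <- regions$region_id[is_super_truth]
    truth$se_core_gene_ids <- se_core
    list(reads = list(vehicle = vehicle, treated = treated),
         regions = regions[, c("region_id", "chrom", "start", "end")],
         genes = genes[, c("gene_id", "chrom", "start", "end", "strand", "tss", "is_core")],
         genome = genome,
         truth = truth)
  })
}
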