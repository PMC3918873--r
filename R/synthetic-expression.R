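#' Experimental design for the synthetic multi-cell-line microarray bundle
#'
#' Describes the treated-vs-vehicle microarray experiment the generator
#' emulates: `n_cell_lines` lines, each with `replicates_per_arm` vehicle and
#' `replicates_per_arm` treated replicates, a planted block of
#' `core_block_size` genes downregulated by `core_log2fc` in the treated arm
#' of *every* line, and `private_de_per_line` additional genes perturbed in
#' exactly one line each.
#'
#' @param n_cell_lines number of cell lines (default 4).
#' @param replicates_per_arm biological replicates per treatment arm
#'   (default 3).
#' @param n_genes number of genes / probes (one probe per gene; default
#'   10000).
#' @param core_block_size size of the planted common downregulated block
#'   (default 26).
#' @param core_log2fc planted log2 fold change (treated minus vehicle) of the
#'   core block; default -2.
#' @param core_sd per-gene, per-line standard deviation of the planted core
#'   effect around `core_log2fc` (default 0.25).
#' @param private_de_per_line genes perturbed in exactly one cell line each
#'   (default 300); perturbation magnitude matches `abs(core_log2fc)` with a
#'   random sign.
#' @param null_sd replicate noise standard deviation on the log2 scale
#'   (default 0.25).
#' @param undetected_fraction fraction of probes whose detection p-value
#'   exceeds 0.01 in all samples (default 0.05); drawn from unplanted genes.
#' @param seed integer seed fixing the output bit-exactly.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(n_cell_lines = 4,
                              replicates_per_arm = 3,
                              n_genes = 10000,
                              core_block_size = 26,
                              core_log2fc = -2.0,
                              core_sd = 0.25,
                              private_de_per_line = 300,
                              null_sd = 0.25,
                              undetected_fraction = 0.05,
                              seed = 1L) {
  cfg <- list(
    n_cell_lines = check_count(n_cell_lines, "n_cell_lines", min = 1L),
    replicates_per_arm = check_count(replicates_per_arm, "replicates_per_arm", min = 1L),
    n_genes = check_count(n_genes, "n_genes", min = 1L),
    core_block_size = check_count(core_block_size, "core_block_size"),
    core_log2fc = check_real(core_log2fc, "core_log2fc"),
    core_sd = check_real(core_sd, "core_sd"),
    private_de_per_line = check_count(private_de_per_line, "private_de_per_line"),
    null_sd = check_real(null_sd, "null_sd"),
    undetected_fraction = check_fraction(undetected_fraction, "undetected_fraction"),
    seed = check_count(seed, "seed")
  )
  if (cfg$core_block_size > cfg$n_genes)
    stop("core_block_size must not exceed n_genes", call. = FALSE)
  if (cfg$core_block_size + cfg$n_cell_lines * cfg$private_de_per_line > cfg$n_genes)
    stop("planted core and private blocks do not fit in n_genes", call. = FALSE)
  structure(cfg, class = "experiment_config")
}

## canonical planted core gene names: three named program members for
## documentation fidelity, the rest abstract ids
core_gene_names <- function(n) {
  named <- c("BCL2", "MYC", "IRF8")
  if (n <= length(named)) return(named[seq_len(n)])
  c(named, sprintf("CORE%02d", seq(length(named) + 1L, n)))
}

#' Generate a synthetic multi-cell-line expression bundle with planted truth
#'
#' Simulates probe intensities on the log2 scale as Gaussian draws around
#' per-probe baselines, then exponentiates, so that downstream
#' variance-stabilization and quantile-normalization steps are exercised
#' meaningfully. The planted core block is shifted by `core_log2fc` in the
#' treated arm of every cell line; private DE genes are shifted in exactly
#' one line. Core-gene baselines are drawn from the well-expressed range
#' (log2 intensity 9-11), consistent with the highly expressed regulators
#' the program contains.
#'
#' Detection p-values follow the generator contract: probes designated
#' undetected receive p ~ U(0.011, 1) in all samples, detected probes
#' p ~ U(0, 0.009), keeping both sides clear of the 0.01 decision boundary.
#'
#' @param config an [experiment_config()].
#' @return A list with elements `bundle` (an [expression_bundle()]) and
#'   `truth` (planted truth: `core_gene_ids`, `per_line_down_ids`,
#'   `undetected_probe_ids`).
#' @export
generate_expression_bundle <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  with_seed(config$seed, {
    n_g <- config$n_genes
    lines <- sprintf("line%d", seq_len(config$n_cell_lines))
    arms <- c("vehicle", "treated")
    reps <- seq_len(config$replicates_per_arm)

    samples <- expand.grid(replicate = reps, treatment = arms, cell_line = lines,
                           stringsAsFactors = FALSE)[, c("cell_line", "treatment", "replicate")]
    samples$sample_id <- with(samples, paste(cell_line, treatment, replicate, sep = "_"))

    gene_ids <- sprintf("GENE%05d", seq_len(n_g))
    core_idx <- sort(sample.int(n_g, config$core_block_size))
    gene_ids[core_idx] <- core_gene_names(config$core_block_size)

    remaining <- setdiff(seq_len(n_g), core_idx)
    private_idx <- lapply(seq_along(lines), function(i) {
      take <- remaining[seq_len(config$private_de_per_line) +
                          (i - 1L) * config$private_de_per_line]
      take
    })
    if (config$private_de_per_line == 0L) private_idx <- rep(list(integer(0)), length(lines))
    planted <- c(core_idx, unlist(private_idx))

    baseline <- rnorm(n_g, mean = 8, sd = 1.5)
    baseline[core_idx] <- runif(config$core_block_size, 9, 11)

    ## planted treatment effects are per gene x line, shared by all treated
    ## replicates of that line
    effect <- matrix(0, nrow = n_g, ncol = length(lines))
    for (li in seq_along(lines)) {
      if (length(core_idx))
        effect[core_idx, li] <- rnorm(length(core_idx),
                                      config$core_log2fc, config$core_sd)
      pi <- private_idx[[li]]
      if (length(pi))
        effect[pi, li] <- sample(c(-1, 1), length(pi), replace = TRUE) *
          rnorm(length(pi), abs(config$core_log2fc), config$core_sd)
    }

    log2_expr <- matrix(0, nrow = n_g, ncol = nrow(samples),
                        dimnames = list(gene_ids, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mu <- baseline
      if (samples$treatment[j] == "treated")
        mu <- mu + effect[, match(samples$cell_line[j], lines)]
      log2_expr[, j] <- mu + rnorm(n_g, 0, config$null_sd)
    }
    intensities <- 2^log2_expr

    n_undet <- round(config$undetected_fraction * n_g)
    undet_pool <- setdiff(seq_len(n_g), planted)
    if (n_undet > length(undet_pool))
      stop("undetected_fraction too large for the unplanted gene pool", call. = FALSE)
    undet_idx <- sort(sample(undet_pool, n_undet))
    detection_p <- matrix(runif(length(intensities), 0, 0.009),
                          nrow = n_g, dimnames = dimnames(intensities))
    if (n_undet)
      detection_p[undet_idx, ] <- runif(n_undet * ncol(detection_p), 0.011, 1)

    probe_ids <- sprintf("probe_%05d", seq_len(n_g))
    rownames(intensities) <- probe_ids
    rownames(detection_p) <- probe_ids
    probe_to_gene <- data.frame(probe_id = probe_ids, gene_id = gene_ids,
                                stringsAsFactors = FALSE)

    bundle <- expression_bundle(intensities, detection_p,
                                samples[, c("sample_id", "cell_line", "treatment", "replicate")],
                                probe_to_gene)
    truth <- list(
      core_gene_ids = gene_ids[core_idx],
      per_line_down_ids = stats::setNames(
        lapply(private_idx, function(ix) gene_ids[ix]), lines),
      undetected_probe_ids = probe_ids[undet_idx]
    )
    list(bundle = bundle, truth = truth)
  })
}
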