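#' Numeric parameters of the analysis pipeline
#'
#' Houses every stated analysis constant: the detection-p filter (0.01),
#' the significance gates (FDR < 5%, fold change > 2), the gene-cluster
#' dendrogram cutoff (10), the ChIP filters (MAPQ > 10), the fragment
#' extension (300 bp), the TSS flank (5 kb) and the enhancer-to-gene
#' assignment window (50 kb).
#'
#' @param detection_alpha detection p-value threshold.
#' @param fdr_threshold FDR gate for significance calls.
#' @param fc_threshold linear fold-change gate.
#' @param cluster_cutoff gene-cluster dendrogram cut height.
#' @param mapq_min MAPQ cutoff (strict `>`).
#' @param fragment_len fragment extension length, bp.
#' @param tss_flank TSS metaprofile half-window, bp.
#' @param assign_window enhancer-to-gene window, bp.
#' @param coverage_binsize coverage bin width, bp.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(detection_alpha = 0.01,
                            fdr_threshold = 0.05,
                            fc_threshold = 2.0,
                            cluster_cutoff = 10.0,
                            mapq_min = 10,
                            fragment_len = 300,
                            tss_flank = 5000,
                            assign_window = 50000,
                            coverage_binsize = 100) {
  cfg <- list(detection_alpha = check_fraction(detection_alpha, "detection_alpha"),
              fdr_threshold = check_fraction(fdr_threshold, "fdr_threshold"),
              fc_threshold = check_real(fc_threshold, "fc_threshold"),
              cluster_cutoff = check_real(cluster_cutoff, "cluster_cutoff"),
              mapq_min = check_count(mapq_min, "mapq_min"),
              fragment_len = check_count(fragment_len, "fragment_len", min = 1L),
              tss_flank = check_count(tss_flank, "tss_flank", min = 1L),
              assign_window = check_count(assign_window, "assign_window"),
              coverage_binsize = check_count(coverage_binsize, "coverage_binsize",
                                             min = 1L))
  if (any(unlist(cfg[c("fdr_threshold", "fc_threshold", "cluster_cutoff")]) <= 0))
    stop("thresholds must be positive", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Full run configuration
#'
#' Bundles the seeds and per-stage parameters of a pipeline run into one
#' serializable document. Unknown keys in any section are rejected.
#'
#' @param seed master seed; section seeds default to it.
#' @param experiment named list of [experiment_config()] overrides.
#' @param chip named list of [chip_config()] overrides.
#' @param cohort named list of [cohort_config()] overrides.
#' @param pipeline named list of [pipeline_config()] overrides.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L, experiment = list(), chip = list(),
                       cohort = list(), pipeline = list()) {
  build <- function(fn, overrides, seeded = TRUE) {
    allowed <- names(formals(fn))
    unknown <- setdiff(names(overrides), allowed)
    if (length(unknown))
      stop(sprintf("unknown configuration keys: %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    if (seeded && is.null(overrides$seed)) overrides$seed <- seed
    do.call(fn, overrides)
  }
  structure(list(seed = check_count(seed, "seed"),
                 experiment = build(experiment_config, experiment),
                 chip = build(chip_config, chip),
                 cohort = build(cohort_config, cohort),
                 pipeline = build(pipeline_config, pipeline, seeded = FALSE)),
            class = "run_config")
}

#' Write / read a run configuration as JSON
#'
#' The document round-trips losslessly; unknown keys are rejected on read.
#'
#' @param config a [run_config()].
#' @param path JSON file path.
#' @return `path` / the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  cohort <- unclass(config$cohort)
  cohort$label_schemes <- lapply(cohort$label_schemes, function(sch)
    lapply(sch, as.list))  # named vectors must serialize as JSON objects
  doc <- list(seed = config$seed,
              experiment = unclass(config$experiment),
              chip = c(list(genome = as.list(config$chip$genome)),
                       unclass(config$chip)[names(config$chip) != "genome"]),
              cohort = cohort,
              pipeline = unclass(config$pipeline))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  doc <- jsonlite::read_json(path)  # unsimplified: named vectors survive as lists
  top_unknown <- setdiff(names(doc), c("seed", "experiment", "chip", "cohort", "pipeline"))
  if (length(top_unknown))
    stop(sprintf("unknown configuration keys: %s", paste(top_unknown, collapse = ", ")),
         call. = FALSE)
  chip <- as.list(doc$chip %||% list())
  if (!is.null(chip$genome)) chip$genome <- unlist(chip$genome)
  cohort <- as.list(doc$cohort %||% list())
  if (!is.null(cohort$label_schemes))
    cohort$label_schemes <- lapply(cohort$label_schemes, function(sch)
      lapply(sch, unlist))
  run_config(seed = doc$seed %||% 1L,
             experiment = as.list(doc$experiment %||% list()),
             chip = chip,
             cohort = cohort,
             pipeline = as.list(doc$pipeline %||% list()))
}

log_stage <- function(stage, ...) {
  message(sprintf("[betcore] %s %s", stage,
                  paste(sprintf("%s=%s", names(list(...)), unlist(list(...))),
                        collapse = " ")))
}

#' Run the full pipeline into an output directory
#'
#' Executes the requested stages — `simulate`, `de`, `signature`, `chip`,
#' `superenh`, `classify` — writing each stage's outputs as plain-text
#' files plus a `manifest.json` recording parameters, the seed and MD5
#' checksums of every written file, so any figure-style output is
#' reproducible from the configuration alone. Stages log one structured
#' line each to standard error. Later stages require the in-memory results
#' of earlier ones and raise an error naming the missing stage otherwise.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param stages subset of stages to run, in pipeline order.
#' @return Invisibly, a list with the manifest and the in-memory stage
#'   results.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "de", "signature", "chip",
                                    "superenh", "classify")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pc <- config$pipeline
  state <- list()
  manifest <- list(package = as.character(utils::packageVersion("betcore")),
                   seed = config$seed, stages = list())
  outputs <- function(...) {
    files <- c(...)
    as.list(stats::setNames(unname(tools::md5sum(files)), basename(files)))
  }
  need <- function(what, stage) {
    if (is.null(state[[what]]))
      stop(sprintf("stage '%s' requires output of stage '%s'; run it first",
                   stage, what), call. = FALSE)
    state[[what]]
  }
  path <- function(...) file.path(out_dir, ...)

  if ("simulate" %in% stages) {
    log_stage("simulate", seed = config$seed)
    expr <- generate_expression_bundle(config$experiment)
    chip <- generate_chip_bundle(config$chip, expr$truth)
    cohort <- generate_cohort(config$cohort)
    files <- c(
      write_matrix(expr$bundle$intensities, path("expression.tsv"), "probe_id"),
      write_matrix(expr$bundle$detection_p, path("detection_p.tsv"), "probe_id"),
      new_tsv(expr$bundle$samples, path("samples.tsv")),
      new_tsv(expr$bundle$probe_to_gene, path("probe_to_gene.tsv")),
      write_bed(cbind(chip$reads$vehicle, condition = "vehicle"),
                path("reads_vehicle.bed")),
      write_bed(cbind(chip$reads$treated, condition = "treated"),
                path("reads_treated.bed")),
      write_bed(chip$regions[, c("chrom", "start", "end", "region_id")] |>
                  stats::setNames(c("chrom", "start", "end", "name")),
                path("enhancers.bed")),
      new_tsv(chip$genes, path("genes.tsv")),
      write_matrix(cohort$matrix, path("cohort.tsv"), "row_id"),
      new_tsv(cohort$labels, path("cohort_labels.tsv"))
    )
    truth <- c(chip$truth, cohort$truth)
    jsonlite::write_json(truth, path("truth.json"), auto_unbox = FALSE)
    files <- c(files, path("truth.json"))
    state$simulate <- list(expression = expr, chip = chip, cohort = cohort,
                           truth = truth)
    manifest$stages$simulate <- list(
      params = list(experiment = unclass(config$experiment)),
      outputs = outputs(files))
  }

  if ("de" %in% stages) {
    sim <- need("simulate", "de")
    bundle <- sim$expression$bundle |>
      filter_probes(pc$detection_alpha) |>
      vst_transform() |>
      quantile_normalize()
    lines <- unique(bundle$samples$cell_line)
    de <- lapply(lines, function(cl) moderated_de(bundle, cl))
    names(de) <- lines
    files <- character(0)
    for (cl in lines) {
      f <- path(sprintf("de_%s.tsv", cl))
      new_tsv(de[[cl]], f)
      v <- path(sprintf("volcano_%s.tsv", cl))
      sig <- call_significant(de[[cl]], pc$fdr_threshold, pc$fc_threshold)
      call <- ifelse(de[[cl]]$gene %in% sig$down, "down",
                     ifelse(de[[cl]]$gene %in% sig$up, "up", "ns"))
      new_tsv(data.frame(gene = de[[cl]]$gene, log2fc = de[[cl]]$log2fc,
                         neg_log10_q = -log10(pmax(de[[cl]]$q, 1e-300)),
                         call = call), v)
      files <- c(files, f, v)
    }
    log_stage("de", lines = length(lines), genes = nrow(de[[1]]))
    state$de <- de
    manifest$stages$de <- list(
      params = pc[c("detection_alpha", "fdr_threshold", "fc_threshold")],
      outputs = outputs(files))
  }

  if ("signature" %in% stages) {
    de <- need("de", "signature")
    down <- lapply(de, function(d)
      call_significant(d, pc$fdr_threshold, pc$fc_threshold)$down)
    sig <- intersect_down(down, de)
    log_stage("signature", size = length(sig$gene_ids))
    f1 <- path("core_signature.tsv")
    new_tsv(data.frame(gene = sig$gene_ids), f1)
    f2 <- path("core_signature.json")
    jsonlite::write_json(
      list(gene_ids = sig$gene_ids, per_line_down = sig$per_line_down,
           pairwise_counts = sig$pairwise$counts,
           pairwise_correlations = sig$pairwise$correlations),
      f2, auto_unbox = FALSE, digits = NA)
    state$signature <- sig
    manifest$stages$signature <- list(
      params = pc[c("fdr_threshold", "fc_threshold")],
      outputs = outputs(c(f1, f2)))
  }

  if ("chip" %in% stages) {
    sim <- need("simulate", "chip")
    chip <- sim$chip
    files <- character(0)
    tracks <- list(); frags <- list(); libs <- list()
    for (cond in names(chip$reads)) {
      filtered <- filter_reads(chip$reads[[cond]], pc$mapq_min, dedup = TRUE)
      libs[[cond]] <- attr(filtered, "library_size")
      frags[[cond]] <- extend_reads(filtered, pc$fragment_len, chip$genome)
      tracks[[cond]] <- coverage_track(frags[[cond]], pc$coverage_binsize,
                                       chip$genome, library_size = libs[[cond]])
      fb <- path(sprintf("coverage_%s.bedgraph", cond))
      write_bedgraph(tracks[[cond]], fb)
      peaks <- call_peaks(tracks[[cond]])
      fp <- path(sprintf("peaks_%s.bed", cond))
      if (nrow(peaks)) {
        write_bed(data.frame(chrom = peaks$chrom, start = peaks$start,
                             end = peaks$end,
                             name = sprintf("peak%04d", seq_len(nrow(peaks)))), fp)
      } else writeLines(character(0), fp)
      tm <- tss_matrix(tracks[[cond]], chip$genes, pc$tss_flank)
      fm <- path(sprintf("tss_matrix_%s.tsv", cond))
      write_matrix(tm$heatmap, fm, "gene_id")
      files <- c(files, fb, fp, fm)
      log_stage("chip", condition = cond, retained = libs[[cond]],
                peaks = nrow(peaks))
    }
    state$chip <- list(tracks = tracks, fragments = frags, libraries = libs,
                       bundle = chip)
    manifest$stages$chip <- list(
      params = pc[c("mapq_min", "fragment_len", "coverage_binsize", "tss_flank")],
      outputs = outputs(files))
  }

  if ("superenh" %in% stages) {
    ch <- need("chip", "superenh")
    chip <- ch$bundle
    rpm <- lapply(names(ch$fragments), function(cond)
      quantify_rpm(ch$fragments[[cond]], chip$regions, ch$libraries[[cond]]))
    names(rpm) <- names(ch$fragments)
    tab <- build_enhancer_table(chip$regions, rpm, chip$genes,
                                reference = "vehicle", window = pc$assign_window)
    delta <- condition_delta(tab, "vehicle", "treated")
    f1 <- path("enhancer_table.tsv")
    new_tsv(as.data.frame(tab), f1)
    f2 <- path("hockey_stick.tsv")
    new_tsv(delta$plot_data, f2)
    se_genes <- unique(unlist(strsplit(tab$assigned_genes[tab$is_super], ";")))
    core_with_se <- intersect(se_genes, sim_core_ids(state))
    log_stage("superenh", supers = sum(tab$is_super),
              core_genes_with_se = length(core_with_se))
    state$superenh <- list(table = tab, delta = delta,
                           core_genes_with_se = core_with_se)
    manifest$stages$superenh <- list(
      params = pc["assign_window"],
      outputs = outputs(c(f1, f2)))
  }

  if ("classify" %in% stages) {
    sim <- need("simulate", "classify")
    signature_genes <- if (!is.null(state$signature)) state$signature$gene_ids
      else sim$truth$core_gene_ids
    cohort <- sim$cohort
    pmap <- default_platform_map(signature_genes, rownames(cohort$matrix))
    extracted <- extract_signature(cohort$matrix, signature_genes, pmap)
    cls <- classify_patients(extracted$matrix)
    assoc <- association_test(cls$groups, cohort$labels)
    f1 <- path("classification.tsv")
    new_tsv(data.frame(patient_id = names(cls$groups), group = cls$groups), f1)
    f2 <- path("associations.json")
    jsonlite::write_json(
      lapply(assoc, function(a) list(chi2 = a$chi2, df = a$df, p = a$p,
                                     degenerate = a$degenerate)),
      f2, auto_unbox = TRUE, digits = NA)
    ## heatmap-ready matrix: patients in dendrogram order, genes by
    ## decreasing cross-patient variance
    ord_p <- cls$hclust$order
    ord_g <- order(-apply(extracted$matrix, 1, stats::var))
    f3 <- path("cohort_heatmap.tsv")
    write_matrix(extracted$matrix[ord_g, ord_p, drop = FALSE], f3, "gene_id")
    log_stage("classify", groups = cls$k, mapped_genes = extracted$mapped_genes)
    state$classify <- list(classification = cls, associations = assoc,
                           mapped_genes = extracted$mapped_genes)
    manifest$stages$classify <- list(
      params = list(mapped_genes = extracted$mapped_genes, k = cls$k),
      outputs = outputs(c(f1, f2, f3)))
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(manifest = manifest, state = state))
}

sim_core_ids <- function(state) {
  if (is.null(state$simulate)) character(0) else state$simulate$truth$core_gene_ids
}
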