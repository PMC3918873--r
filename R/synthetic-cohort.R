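default_label_schemes <- function(n_archetypes) {
  ## each archetype strongly favors one level of each clinical factor, so
  ## group-by-factor association tests have signal to find
  karyotype_levels <- c("MLL", "NK", "+8", "CBF", "OtherHR")
  kary <- lapply(seq_len(n_archetypes), function(k) {
    p <- rep(0.4 / (length(karyotype_levels) - 1), length(karyotype_levels))
    p[(k - 1L) %% length(karyotype_levels) + 1L] <- 0.6
    stats::setNames(p, karyotype_levels)
  })
  npm1 <- lapply(seq_len(n_archetypes), function(k) {
    p_mut <- c(0.8, 0.7, 0.2, 0.1, 0.5, 0.3)[(k - 1L) %% 6L + 1L]
    c(mut = p_mut, wt = 1 - p_mut)
  })
  flt3 <- lapply(seq_len(n_archetypes), function(k) {
    p_pos <- c(0.6, 0.2, 0.5, 0.1, 0.3, 0.4)[(k - 1L) %% 6L + 1L]
    c(pos = p_pos, neg = 1 - p_pos)
  })
  list(karyotype = kary, NPM1c = npm1, FLT3_ITD = flt3)
}

#' Design of the synthetic patient cohort
#'
#' Describes the signature-gene expression cohort the generator emulates:
#' `n_patients` patients drawn from `n_archetypes` molecular-subgroup
#' archetypes over `n_signature_genes` genes, with categorical clinical
#' labels drawn from per-archetype probability vectors.
#'
#' @param n_patients cohort size (default 436).
#' @param n_signature_genes measured signature genes (default 18).
#' @param n_archetypes planted subgroups (default 6).
#' @param archetype_separation standard deviation of per-gene archetype
#'   means (between-group mean shift; default 3).
#' @param within_sd within-archetype noise (default 1).
#' @param label_schemes named list: factor -> list of per-archetype named
#'   probability vectors (must each sum to 1); defaults emulate karyotype,
#'   NPM1c and FLT3-ITD factors.
#' @param seed integer seed.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 436,
                          n_signature_genes = 18,
                          n_archetypes = 6,
                          archetype_separation = 3.0,
                          within_sd = 1.0,
                          label_schemes = NULL,
                          seed = 1L) {
  cfg <- list(
    n_patients = check_count(n_patients, "n_patients", min = 1L),
    n_signature_genes = check_count(n_signature_genes, "n_signature_genes", min = 1L),
    n_archetypes = check_count(n_archetypes, "n_archetypes", min = 1L),
    archetype_separation = check_real(archetype_separation, "archetype_separation"),
    within_sd = check_real(within_sd, "within_sd"),
    label_schemes = label_schemes %||% default_label_schemes(n_archetypes),
    seed = check_count(seed, "seed")
  )
  if (cfg$n_patients < cfg$n_archetypes)
    stop("n_patients must be at least n_archetypes", call. = FALSE)
  for (factor_name in names(cfg$label_schemes)) {
    scheme <- cfg$label_schemes[[factor_name]]
    if (length(scheme) < cfg$n_archetypes)
      stop(sprintf("label scheme '%s' needs one probability vector per archetype",
                   factor_name), call. = FALSE)
    for (p in scheme)
      if (abs(sum(p) - 1) > 1e-8)
        stop(sprintf("label scheme '%s' probabilities must sum to 1", factor_name),
             call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic patient cohort with planted archetypes
#'
#' Each patient is assigned an archetype uniformly at random and their
#' signature-gene expression drawn as the archetype's mean vector (per-gene
#' i.i.d. `N(0, archetype_separation^2)`) plus `N(0, within_sd^2)` noise.
#' Clinical labels are drawn per patient from the archetype's categorical
#' distributions.
#'
#' @param config a [cohort_config()].
#' @param gene_ids optional row names for the expression matrix (defaults
#'   to `ps_01`, `ps_02`, ... probeset-style ids).
#' @return list with `matrix` (genes x patients), `labels` (data.frame:
#'   `patient_id` plus one column per clinical factor) and `truth`
#'   (`patient_archetype`).
#' @export
generate_cohort <- function(config = cohort_config(), gene_ids = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed + 2L, {
    ng <- config$n_signature_genes
    np <- config$n_patients
    gene_ids <- gene_ids %||% sprintf("ps_%02d", seq_len(ng))
    stopifnot(length(gene_ids) == ng)
    patient_ids <- sprintf("pt_%04d", seq_len(np))

    archetype_means <- matrix(rnorm(config$n_archetypes * ng,
                                    sd = config$archetype_separation),
                              nrow = config$n_archetypes)
    archetype <- sample.int(config$n_archetypes, np, replace = TRUE)
    x <- t(archetype_means[archetype, , drop = FALSE]) +
      matrix(rnorm(ng * np, sd = config$within_sd), nrow = ng)
    dimnames(x) <- list(gene_ids, patient_ids)

    labels <- data.frame(patient_id = patient_ids, stringsAsFactors = FALSE)
    for (factor_name in names(config$label_schemes)) {
      scheme <- config$label_schemes[[factor_name]]
      labels[[factor_name]] <- vapply(archetype, function(k) {
        p <- scheme[[k]]
        sample(names(p), 1L, prob = p)
      }, character(1))
    }
    list(matrix = x, labels = labels,
         truth = list(patient_archetype = stats::setNames(archetype, patient_ids)))
  })
}
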