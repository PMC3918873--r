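#' Construct an expression bundle
#'
#' Container for a probes x samples intensity matrix with matched detection
#' p-values, per-sample annotations and a probe-to-gene map.
#'
#' @param intensities non-negative numeric matrix, probes x samples.
#' @param detection_p matrix of detection p-values in `[0,1]`, same shape.
#' @param samples data.frame with columns `sample_id`, `cell_line`,
#'   `treatment` (one of `"vehicle"`, `"treated"`), `replicate`.
#' @param probe_to_gene data.frame with columns `probe_id`, `gene_id`.
#' @return An object of class `expression_bundle`.
#' @export
expression_bundle <- function(intensities, detection_p, samples, probe_to_gene) {
  intensities <- as.matrix(intensities)
  detection_p <- as.matrix(detection_p)
  if (!identical(dim(intensities), dim(detection_p)))
    stop("intensities and detection_p must have identical shape", call. = FALSE)
  if (any(intensities < 0)) stop("intensities must be non-negative", call. = FALSE)
  if (any(detection_p < 0 | detection_p > 1))
    stop("detection p-values must lie in [0,1]", call. = FALSE)
  required <- c("sample_id", "cell_line", "treatment", "replicate")
  if (!all(required %in% names(samples)))
    stop("samples must have columns sample_id, cell_line, treatment, replicate",
         call. = FALSE)
  if (nrow(samples) != ncol(intensities))
    stop("every sample column must be annotated", call. = FALSE)
  if (!all(samples$treatment %in% c("vehicle", "treated")))
    stop("treatment must be 'vehicle' or 'treated'", call. = FALSE)
  if (!is.null(colnames(intensities)) &&
      !identical(colnames(intensities), samples$sample_id))
    stop("column names must match samples$sample_id", call. = FALSE)
  colnames(intensities) <- samples$sample_id
  colnames(detection_p) <- samples$sample_id
  if (!all(rownames(intensities) %in% probe_to_gene$probe_id))
    stop("every probe must appear in probe_to_gene", call. = FALSE)
  structure(list(intensities = intensities, detection_p = detection_p,
                 samples = samples, probe_to_gene = probe_to_gene),
            class = "expression_bundle")
}

#' @export
print.expression_bundle <- function(x, ...) {
  cat(sprintf("expression_bundle: %d probes x %d samples (%d cell lines)\n",
              nrow(x$intensities), ncol(x$intensities),
              length(unique(x$samples$cell_line))))
  invisible(x)
}

#' Remove probes undetected in every sample
#'
#' A probe is dropped when its detection p-value exceeds `alpha` in *all*
#' samples; a probe detected in even one sample is retained.
#'
#' @param bundle an [expression_bundle()].
#' @param alpha detection threshold in (0,1); default 0.01.
#' @return The filtered bundle; the sample set is unchanged.
#' @export
filter_probes <- function(bundle, alpha = 0.01) {
  stopifnot(inherits(bundle, "expression_bundle"))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0,1)", call. = FALSE)
  if (ncol(bundle$intensities) == 0L) stop("empty sample set", call. = FALSE)
  undetected <- rowSums(bundle$detection_p <= alpha) == 0L
  keep <- !undetected
  bundle$intensities <- bundle$intensities[keep, , drop = FALSE]
  bundle$detection_p <- bundle$detection_p[keep, , drop = FALSE]
  bundle$probe_to_gene <- bundle$probe_to_gene[
    bundle$probe_to_gene$probe_id %in% rownames(bundle$intensities), , drop = FALSE]
  bundle
}

#' Variance-stabilizing transform
#'
#' Applies `asinh(x / c) / log(2)` elementwise, with `c` set per sample from
#' a low-intensity quantile. For intensities well above `c` this behaves as
#' `log2(x)` up to an additive constant, so multiplicative (log-normal)
#' noise attains near-constant variance across the intensity range, while
#' values near zero are handled smoothly. The transform is strictly
#' monotone within each sample.
#'
#' @param bundle an [expression_bundle()].
#' @param ref_quantile quantile of each sample's intensities used as the
#'   scale `c` (default 0.05).
#' @return The transformed bundle.
#' @export
vst_transform <- function(bundle, ref_quantile = 0.05) {
  stopifnot(inherits(bundle, "expression_bundle"))
  if (any(bundle$intensities < 0)) stop("negative intensity", call. = FALSE)
  x <- bundle$intensities
  if (nrow(x)) {
    for (j in seq_len(ncol(x))) {
      cj <- stats::quantile(x[, j], ref_quantile, names = FALSE)
      if (!is.finite(cj) || cj <= 0) cj <- max(mean(x[, j]), .Machine$double.eps)
      x[, j] <- asinh(x[, j] / cj) / log(2)
    }
  }
  bundle$intensities <- x
  bundle
}

#' Quantile normalization across samples
#'
#' Forces every sample to share the same empirical distribution: each
#' sample's sorted values are replaced by the across-sample mean of sorted
#' values; ties within a sample receive the mean of the normalized values at
#' their tied ranks. Delegates to [limma::normalizeQuantiles()].
#'
#' @param bundle an [expression_bundle()].
#' @return The normalized bundle. With a single sample the data are returned
#'   unchanged with a warning.
#' @export
quantile_normalize <- function(bundle) {
  stopifnot(inherits(bundle, "expression_bundle"))
  if (ncol(bundle$intensities) < 2L) {
    warning("quantile normalization needs >= 2 samples; returning input unchanged")
    return(bundle)
  }
  dn <- dimnames(bundle$intensities)
  bundle$intensities <- limma::normalizeQuantiles(bundle$intensities, ties = TRUE)
  dimnames(bundle$intensities) <- dn
  bundle
}

## ---- empirical-Bayes variance shrinkage -----------------------------------

## Newton solve of trigamma(y) = x, vectorized; x > 0
trigamma_inverse <- function(x) {
  stopifnot(all(x > 0))
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

## method-of-moments fit of the scaled-F model for gene-wise sample
## variances: s2 ~ s0^2 * chisq_df / df. Returns prior df (possibly Inf)
## and prior variance. With no excess spread in log(s2) beyond chi-square
## sampling noise, the prior df is infinite and the prior variance is the
## geometric mean of s2, which reduces shrinkage to the identity when all
## gene variances are equal.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  if (length(z) < 2L)
    return(list(df_prior = Inf, var_prior = mean(s2[ok])))
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    var_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    var_prior <- exp(mean(z))
  }
  list(df_prior = df_prior, var_prior = var_prior)
}

#' Moderated differential expression for one cell line
#'
#' Treated-vs-vehicle two-sample comparison per gene with empirical-Bayes
#' variance shrinkage. The per-gene pooled variance is shrunk toward a prior
#' variance estimated across genes by method of moments on the log sample
#' variances (scaled-F model), the moderated t is the log2 fold change over
#' the shrunken standard error, and two-sided p-values use the t
#' distribution with residual plus prior degrees of freedom. Multiplicity is
#' handled by Benjamini-Hochberg ([bh_adjust()]).
#'
#' When several probes map to one gene, the probe with the highest mean
#' expression is kept before testing.
#'
#' @param bundle an [expression_bundle()], normally filtered, transformed
#'   and quantile-normalized.
#' @param cell_line which cell line to test.
#' @param prior_df override for the prior degrees of freedom; `NULL`
#'   (default) estimates it from the data, `0` disables shrinkage and
#'   reproduces the ordinary two-sample t.
#' @return A `de_result` data.frame with columns `gene`, `log2fc`, `t_mod`,
#'   `p`, `q`, `mean_expr`.
#' @export
moderated_de <- function(bundle, cell_line, prior_df = NULL) {
  stopifnot(inherits(bundle, "expression_bundle"))
  sel <- bundle$samples$cell_line == cell_line
  if (!any(sel)) stop(sprintf("unknown cell line '%s'", cell_line), call. = FALSE)
  samp <- bundle$samples[sel, ]
  treated <- samp$sample_id[samp$treatment == "treated"]
  vehicle <- samp$sample_id[samp$treatment == "vehicle"]
  n1 <- length(vehicle); n2 <- length(treated)
  if (n1 < 2L || n2 < 2L)
    stop("need >= 2 replicates in each arm (variance undefined otherwise)",
         call. = FALSE)

  x <- collapse_probes(bundle)
  xt <- x[, treated, drop = FALSE]
  xv <- x[, vehicle, drop = FALSE]

  m_t <- rowMeans(xt)
  m_v <- rowMeans(xv)
  lfc <- m_t - m_v
  df_resid <- n1 + n2 - 2L
  pooled_s2 <- (rowSums((xv - m_v)^2) + rowSums((xt - m_t)^2)) / df_resid

  if (is.null(prior_df)) {
    prior <- fit_variance_prior(pooled_s2, df_resid)
  } else if (prior_df == 0) {
    prior <- list(df_prior = 0, var_prior = 0)
  } else {
    prior <- list(df_prior = prior_df,
                  var_prior = fit_variance_prior(pooled_s2, df_resid)$var_prior)
  }
  s2_shrunk <- if (is.infinite(prior$df_prior)) {
    rep(prior$var_prior, length(pooled_s2))
  } else {
    (prior$df_prior * prior$var_prior + df_resid * pooled_s2) /
      (prior$df_prior + df_resid)
  }
  se <- sqrt(s2_shrunk * (1 / n1 + 1 / n2))
  t_mod <- ifelse(lfc == 0, 0, lfc / se)
  df_total <- df_resid + prior$df_prior
  p <- 2 * pt(-abs(t_mod), df = df_total)
  p[lfc == 0] <- 1

  res <- data.frame(gene = rownames(x), log2fc = lfc, t_mod = t_mod, p = p,
                    q = bh_adjust(p), mean_expr = rowMeans(x),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "cell_line") <- cell_line
  attr(res, "prior") <- prior
  class(res) <- c("de_result", "data.frame")
  res
}

## probe -> gene collapse: keep the probe with highest mean expression
collapse_probes <- function(bundle) {
  x <- bundle$intensities
  map <- bundle$probe_to_gene
  map <- map[match(rownames(x), map$probe_id), ]
  if (anyDuplicated(map$gene_id)) {
    means <- rowMeans(x)
    ord <- order(map$gene_id, -means)
    keep <- ord[!duplicated(map$gene_id[ord])]
    x <- x[keep, , drop = FALSE]
    map <- map[keep, , drop = FALSE]
  }
  rownames(x) <- map$gene_id
  x
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement (delegates to
#' [stats::p.adjust()]). `NaN` entries are propagated with a warning.
#'
#' @param p vector of p-values in `[0,1]` (NaN allowed).
#' @return Adjusted q-values in `[0,1]`.
#' @export
bh_adjust <- function(p) {
  nan <- is.nan(p)
  if (any(!nan & (p < 0 | p > 1), na.rm = TRUE))
    stop("p-values must lie in [0,1]", call. = FALSE)
  if (any(nan)) warning("NaN p-values propagated unchanged")
  q <- rep(NaN, length(p))
  q[!nan] <- p.adjust(p[!nan], method = "BH")
  q
}

#' Call significant genes at FDR and fold-change thresholds
#'
#' A gene is called down when `q < fdr` and its linear-scale fold change
#' `2^(-log2fc)` exceeds `fc`; up symmetrically. The rule mirrors "a false
#' discovery rate below 5% and a fold-change greater than two".
#'
#' @param de a `de_result` from [moderated_de()].
#' @param fdr FDR threshold (default 0.05).
#' @param fc linear fold-change threshold (default 2).
#' @return A list with disjoint character vectors `up` and `down`.
#' @export
call_significant <- function(de, fdr = 0.05, fc = 2) {
  stopifnot(is.data.frame(de), fdr > 0, fc > 0)
  sig <- !is.na(de$q) & de$q < fdr
  list(up = de$gene[sig & 2^(de$log2fc) > fc],
       down = de$gene[sig & 2^(-de$log2fc) > fc])
}
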