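# betcore

Inhibiting BET bromodomain proteins (BRD2/3/4) in acute myeloid leukemia
collapses the expression of a small, consistent set of genes — a **core
transcriptional program** — rather than perturbing the transcriptome at
large. `betcore` is an R implementation of the full computational path by
which such a program is derived and characterized:

1. **Differential expression per cell line.** Bead-array intensities are
   filtered on detection p-values (removed only when p > 0.01 in *all*
   samples), variance-stabilized, quantile-normalized, and tested
   treated-vs-vehicle with an empirical-Bayes moderated t:

   s̃²ᵍ = (d₀·s₀² + d·s²ᵍ) / (d₀ + d),  tᵍ = Δ̂ᵍ / (s̃ᵍ·√(1/n₁ + 1/n₂))

   with the prior (d₀, s₀²) fit by method of moments on log s²ᵍ, p-values
   on d + d₀ df and Benjamini–Hochberg FDR. A gene is *down* when
   q < 0.05 and its linear fold change exceeds 2.
2. **Core signature.** The exact intersection of the downregulated sets
   across all cell lines, with pairwise overlap counts and fold-change
   correlations, plus complete-linkage gene clustering with a height-10
   dendrogram cut.
3. **ChIP-seq coverage.** BED-level aligned reads filtered at MAPQ > 10,
   deduplicated on the strand-aware 5' key, extended to 300 bp, binned
   into coverage tracks, summarized as TSS-centered (±5 kb) heatmaps and
   mean profiles, with a calibrated local-Poisson peak caller.
4. **Super-enhancers.** Reads-per-million over enhancer regions, regions
   ranked by increasing signal, both axes scaled to [0, 1], and the cutoff
   placed where the tangent slope of the scaled curve first exceeds 1 (the
   hockey-stick inflection); genes are assigned to regions whose edge lies
   within 50 kb of the TSS, and per-region ΔRPM contrasts conditions.
5. **Cohort classification.** The signature genes measurable on an
   expression platform are extracted from a patient cohort matrix
   (multi-probe rows averaged), patients clustered by complete-linkage
   Euclidean distance on per-gene z-scores, the dendrogram cut at the
   strongest relative height gap, and group-by-clinical-factor
   associations tested by Pearson chi-square.

Because the original microarray, ChIP-seq and patient datasets are not
redistributable, the package ships seeded **synthetic-data generators with
recorded planted truth** at the reference experiment's structural scale
(4 cell lines × 3+3 replicates × 10,000 genes with a 26-gene planted core
block; 500 enhancers with 30 super-enhancers, 12 of them placed at core
genes; a 436-patient, 18-gene cohort with 6 archetypes). Every stage is
tested as a recovery problem against that truth. See the methods vignette
(`vignettes/core-transcriptional-program.Rmd`) for the models, parameter
choices and limitations.

## Worked example

```r
library(betcore)

## four-line expression bundle with a planted 26-gene core block
gen <- generate_expression_bundle(experiment_config(seed = 1))
bundle <- quantile_normalize(vst_transform(filter_probes(gen$bundle, 0.01)))
de <- lapply(unique(bundle$samples$cell_line),
             function(cl) moderated_de(bundle, cl))
down <- lapply(de, function(d) call_significant(d, fdr = 0.05, fc = 2)$down)
sig <- intersect_down(down, de)
length(sig$gene_ids)
#> [1] 26
setequal(sig$gene_ids, gen$truth$core_gene_ids)
#> [1] TRUE

## paired ChIP-seq bundle: quantify, rank, call, assign
chip <- generate_chip_bundle(chip_config(seed = 1), gen$truth)
rpm <- lapply(chip$reads, function(r) {
  f <- filter_reads(r, mapq_min = 10, dedup = TRUE)
  quantify_rpm(extend_reads(f, 300, chip$genome), chip$regions,
               attr(f, "library_size"))
})
tab <- build_enhancer_table(chip$regions, rpm, chip$genes,
                            reference = "vehicle", window = 50000)
se_genes <- unique(unlist(strsplit(tab$assigned_genes[tab$is_super], ";")))
length(intersect(se_genes, gen$truth$core_gene_ids))
#> [1] 12

## cohort: 18 measurable signature genes classify patients into 6 groups
co <- generate_cohort(cohort_config(seed = 1))
ex <- extract_signature(co$matrix, sig$gene_ids,
                        default_platform_map(sig$gene_ids, rownames(co$matrix)))
ex$mapped_genes
#> [1] 18
cls <- classify_patients(ex$matrix)
cls$k
#> [1] 6
round(archetype_agreement(cls$groups, co$truth$patient_archetype), 2)
#> [1] 1
```

The printed numbers read as: the full expression pipeline recovers exactly
the 26 planted core genes; the ChIP pipeline places super-enhancers at
exactly the 12 designated core genes; the platform fixture covers 18 of
the 26 signature genes; and complete-linkage clustering of those profiles
recovers the six planted patient subgroups with perfect chance-corrected
agreement.

`run_pipeline(run_config(seed = 1), "out_dir")` orchestrates all six
stages (simulate → de → signature → chip → superenh → classify) into an
output directory with a checksummed `manifest.json`;
`inst/scripts/betcore-pipeline.R` is a thin command-line wrapper around it.

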