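test_that("RPM quantification matches brute-force overlap counting", {
  regions <- data.frame(region_id = "r1", chrom = "chrA", start = 1000, end = 2000)
  one <- data.frame(chrom = "chrA", start = 1500, end = 1800, strand = "+")
  expect_equal(unname(quantify_rpm(one, regions, library_size = 1e6)), 1.0)
  none <- data.frame(chrom = "chrA", start = 5000, end = 5300, strand = "+")
  expect_equal(unname(quantify_rpm(none, regions, library_size = 1e6)), 0)

  set.seed(21)
  regs <- data.frame(region_id = sprintf("r%02d", 1:10), chrom = "chrA",
                     start = seq(0, 9000, by = 1000) + 100)
  regs$end <- regs$start + 500
  s <- sample(0:9700, 50, replace = TRUE)
  frags <- data.frame(chrom = "chrA", start = s, end = s + 300, strand = "+")
  rpm <- quantify_rpm(frags, regs, library_size = 50)
  brute <- vapply(seq_len(nrow(regs)), function(i)
    sum(frags$start < regs$end[i] & frags$end > regs$start[i]), numeric(1))
  expect_equal(unname(rpm), brute * 1e6 / 50)
  expect_error(quantify_rpm(frags, regs, library_size = 0), "positive")
})

test_that("slope-1 cutoff flags the geometric outlier set and nothing on flat input", {
  ## all equal: the scaled curve never exceeds slope 1
  flat <- call_super_enhancers(rep(3.7, 100))
  expect_false(any(flat$is_super))
  expect_equal(flat$cutoff_value, Inf)

  ## 99 ones and a single 100: exactly the outlier (brute-force slope scan
  ## over the scaled curve puts the first crossing at the last segment)
  sig <- c(rep(1, 99), 100)
  out <- call_super_enhancers(sig)
  expect_equal(which(out$is_super), 100)
  expect_equal(out$cutoff_value, 100)

  ## flags invariant under positive rescaling and monotone relabeling
  set.seed(31)
  x <- c(rexp(80), 40 + rexp(8) * 5)
  a <- call_super_enhancers(x)
  expect_equal(call_super_enhancers(x * 1e4)$is_super, a$is_super)
  expect_equal(call_super_enhancers(x * 0.003)$is_super, a$is_super)
  perm <- sample(length(x))
  expect_equal(call_super_enhancers(x[perm])$is_super, a$is_super[perm])
  expect_error(call_super_enhancers(5), "two regions")
})

test_that("gene assignment respects the 50 kb TSS-to-edge window", {
  regions <- data.frame(region_id = c("e1", "e2"), chrom = "chrA",
                        start = c(100000, 190000), end = c(110000, 200000))
  genes <- data.frame(
    gene_id = c("near", "far", "inside", "between", "orphan"),
    chrom = c("chrA", "chrA", "chrA", "chrA", "chrZ"),
    tss = c(100000 - 49999, 100000 - 50001, 105000, 145000, 1000))
  expect_warning(asn <- assign_genes(regions, genes, 50000), "chrZ")
  expect_setequal(asn$gene_id[asn$region_id == "e1"],
                  c("near", "inside", "between"))
  expect_equal(asn$distance[asn$gene_id == "inside"], 0)
  expect_false("far" %in% asn$gene_id)
  ## a TSS within 50 kb of two regions appears in both lists
  expect_setequal(asn$region_id[asn$gene_id == "between"], c("e1", "e2"))
  ## exact boundary: distance == window is assigned
  g50 <- data.frame(gene_id = "edge", chrom = "chrA", tss = 100000 - 50000)
  expect_equal(nrow(suppressWarnings(assign_genes(regions, g50, 50000))), 1)
})

test_that("condition deltas isolate the planted super-enhancer depletion", {
  regions <- data.frame(region_id = sprintf("r%d", 1:4), chrom = "chrA",
                        start = c(0, 1000, 2000, 3000),
                        end = c(500, 1500, 2500, 3500))
  rpm <- list(vehicle = c(5, 6, 100, 110), treated = c(5.5, 6.2, 30, 35))
  genes <- data.frame(gene_id = "g", chrom = "chrA", tss = 10)
  tab <- suppressWarnings(
    build_enhancer_table(regions, rpm, genes, reference = "vehicle"))
  expect_equal(tab$rank, rank(rpm$vehicle))
  d <- condition_delta(tab, "vehicle", "treated")
  expect_equal(nrow(d$delta_table), 4)
  expect_lt(mean(d$delta_table$delta[d$delta_table$is_super]),
            mean(d$delta_table$delta[!d$delta_table$is_super]))
  same <- condition_delta(tab, "vehicle", "vehicle")
  expect_true(all(same$delta_table$delta == 0))
  expect_error(condition_delta(tab, "vehicle", "missing"), "not quantified")
  ## single-region table
  one <- suppressWarnings(build_enhancer_table(
    regions[3, ], list(vehicle = 10, treated = 4), genes))
  expect_equal(nrow(condition_delta(one, "vehicle", "treated")$delta_table), 1)
})

test_that("region stitching merges within the gap and preserves coordinates", {
  regs <- data.frame(region_id = c("a", "b", "c"), chrom = "chrA",
                     start = c(0, 1500, 40000), end = c(1000, 2500, 41000))
  st <- stitch_regions(regs, distance = 600)
  expect_equal(nrow(st), 2)
  expect_equal(st$region_id[1], "a+b")
  expect_equal(st$start[1], 0)
  expect_equal(st$end[1], 2500)
  ## far region untouched; zero distance leaves disjoint regions alone
  expect_equal(st[2, c("start", "end")], data.frame(start = 40000, end = 41000,
                                                    row.names = 2L))
  expect_equal(nrow(stitch_regions(regs, 0)), 3)
})

test_that("planted super-enhancers are recovered with high precision and recall", {
  stats <- t(vapply(1:10, function(s) {
    g <- generate_expression_bundle(
      experiment_config(n_genes = 400, private_de_per_line = 0, seed = 40 + s))
    ch <- generate_chip_bundle(small_chip_config(seed = 40 + s), g$truth)
    rpm <- chip_pipeline_rpm(ch, "vehicle")
    called <- names(rpm)[call_super_enhancers(rpm)$is_super]
    truth <- ch$truth$se_region_ids
    c(precision = mean(called %in% truth), recall = mean(truth %in% called))
  }, c(precision = 0, recall = 0)))
  expect_gte(mean(stats[, "precision"]), 0.9)
  expect_gte(mean(stats[, "recall"]), 0.9)
  ## treated condition depletes supers specifically
  g <- generate_expression_bundle(
    experiment_config(n_genes = 400, private_de_per_line = 0, seed = 77))
  ch <- generate_chip_bundle(small_chip_config(seed = 77), g$truth)
  rpm <- list(vehicle = chip_pipeline_rpm(ch, "vehicle"),
              treated = chip_pipeline_rpm(ch, "treated"))
  tab <- build_enhancer_table(ch$regions, rpm, ch$genes)
  d <- condition_delta(tab, "vehicle", "treated")$delta_table
  expect_lt(mean(d$delta[d$is_super]), mean(d$delta[!d$is_super]))
})

test_that("without signal amplification the planted set is not recovered", {
  f1 <- vapply(1:10, function(s) {
    g <- generate_expression_bundle(
      experiment_config(n_genes = 400, private_de_per_line = 0, seed = 60 + s))
    ch <- generate_chip_bundle(
      small_chip_config(seed = 60 + s, super_multiplier = 1), g$truth)
    rpm <- chip_pipeline_rpm(ch, "vehicle")
    called <- names(rpm)[call_super_enhancers(rpm)$is_super]
    truth <- ch$truth$se_region_ids
    if (!length(called)) return(0)
    prec <- mean(called %in% truth); rec <- mean(truth %in% called)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  expect_lt(mean(f1), 0.5)
})
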