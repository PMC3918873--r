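toy_genome <- c(chrA = 20000, chrB = 10000)

test_that("read filtering applies the strict MAPQ rule and strand-aware dedup", {
  r <- make_reads("chrA", c(100, 100, 100, 500, 500),
                  c(136, 136, 136, 536, 536),
                  c("+", "+", "-", "+", "+"),
                  c(10, 30, 30, 60, 5))
  out <- filter_reads(r, mapq_min = 10, dedup = FALSE)
  expect_equal(nrow(out), 3)          # mapq 10 and 5 removed (strict >)
  out2 <- filter_reads(r, mapq_min = 10, dedup = TRUE)
  expect_equal(nrow(out2), 3)         # +/- at same start are distinct loci
  ## hand enumeration: mapqs {5,11,30,30,60}, two of the >10 reads share
  ## (chrom, 5' position, strand) -> 3 retained
  r2 <- make_reads("chrA", c(0, 10, 20, 20, 30), c(36, 46, 56, 56, 66),
                   c("+", "+", "+", "+", "+"), c(5, 11, 30, 30, 60))
  out3 <- filter_reads(r2, 10, TRUE)
  expect_equal(nrow(out3), 3)
  expect_equal(attr(out3, "library_size"), 3)
  ## duplicates on opposite strands share no 5' key
  r3 <- make_reads("chrA", c(100, 100), c(136, 136), c("+", "+"), c(60, 60))
  expect_equal(nrow(filter_reads(r3, 10, TRUE)), 1)
})

test_that("reads extend along their strand and clip at chromosome bounds", {
  r <- make_reads("chrA", c(1000, 1964, 64), c(1036, 2000, 100),
                  c("+", "-", "-"), c(60, 60, 60))
  f <- extend_reads(r, 300, toy_genome)
  expect_equal(f$start, c(1000, 1700, 0))
  expect_equal(f$end, c(1300, 2000, 100))
  ## right-edge clipping
  r2 <- make_reads("chrB", 9900, 9936, "+", 60)
  f2 <- extend_reads(r2, 300, toy_genome)
  expect_equal(f2$end, 10000)
  expect_error(extend_reads(make_reads("chrA", 0, 400, "+", 60), 300), "fragment_len")
})

test_that("binned coverage matches the brute-force oracle and conserves mass", {
  one <- data.frame(chrom = "chrA", start = 0, end = 300, strand = "+")
  tr <- coverage_track(one, 100, toy_genome, mode = "fragments")
  expect_equal(tr$bins$chrA[1:4], c(1, 1, 1, 0))
  empty <- coverage_track(one[0, ], 100, toy_genome)
  expect_true(all(unlist(empty$bins) == 0))

  set.seed(12)
  s <- sample(0:19000, 200, replace = TRUE)
  frags <- data.frame(chrom = "chrA", start = s, end = s + sample(50:400, 200, TRUE),
                      strand = "+")
  frags$end <- pmin(frags$end, 20000)
  for (bs in c(73, 100, 250)) {
    tr <- coverage_track(frags, bs, toy_genome["chrA"], mode = "depth")
    expect_equal(tr$bins$chrA, bf_depth_bins(frags, bs, 20000), tolerance = 1e-9)
    ## conservation: sum(bins) * binsize = total fragment length
    expect_equal(sum(tr$bins$chrA) * bs, sum(frags$end - frags$start),
                 tolerance = 1e-9)
  }
  ## order invariance of filter -> extend -> coverage
  perm <- sample(nrow(frags))
  tr1 <- coverage_track(frags, 100, toy_genome["chrA"])
  tr2 <- coverage_track(frags[perm, ], 100, toy_genome["chrA"])
  expect_equal(tr1$bins, tr2$bins)
  expect_error(coverage_track(data.frame(chrom = "chrA", start = 0, end = 30000,
                                         strand = "+"), 100, toy_genome),
               "outside genome")
})

test_that("TSS matrix orients rows 5' to 3' and averages into the profile", {
  ## symmetric peak at a plus-strand TSS
  genome <- c(chrA = 40000)
  tss <- 20000
  d <- seq(0, 300, by = 20)
  s <- c(tss - 50 - d, tss - 50 + d)   # fragment centers pile up at the TSS
  frags <- data.frame(chrom = "chrA", start = s, end = s + 100, strand = "+")
  tr <- coverage_track(frags, 100, genome)
  genes <- data.frame(gene_id = "gp", chrom = "chrA", tss = tss, strand = "+")
  tm <- tss_matrix(tr, genes, flank = 2000)
  expect_equal(ncol(tm$heatmap), 40)
  centre <- which.max(tm$mean_profile)
  expect_true(abs(centre - 20.5) <= 1.5)

  ## minus-strand gene with signal 1 kb on its 5' side (higher genome
  ## coordinates) must appear upstream (left of centre) after orientation
  s2 <- seq(21000, 21100, by = 10)
  tr2 <- coverage_track(data.frame(chrom = "chrA", start = s2, end = s2 + 100,
                                   strand = "-"), 100, genome)
  gm <- data.frame(gene_id = "gm", chrom = "chrA", tss = tss, strand = "-")
  tm2 <- tss_matrix(tr2, gm, flank = 2000)
  expect_lt(which.max(tm2$heatmap[1, ]), 20)
  ## mirrored-signal symmetry: a plus-strand gene with the same signal on
  ## its own 5' side gives the identical row
  s3 <- seq(18900, 19000, by = 10)
  tr3 <- coverage_track(data.frame(chrom = "chrA", start = s3, end = s3 + 100,
                                   strand = "+"), 100, genome)
  gp <- data.frame(gene_id = "gp", chrom = "chrA", tss = tss, strand = "+")
  tm3 <- tss_matrix(tr3, gp, flank = 2000)
  expect_equal(sum(tm3$heatmap), sum(tm2$heatmap))

  ## no reads -> zero matrix; off-chromosome window -> clipped and flagged
  tr0 <- coverage_track(frags[0, ], 100, genome)
  expect_true(all(tss_matrix(tr0, genes, 2000)$heatmap == 0))
  edge <- data.frame(gene_id = "ge", chrom = "chrA", tss = 500, strand = "+")
  tme <- tss_matrix(tr, edge, flank = 2000)
  expect_equal(tme$clipped_genes, "ge")
  expect_error(tss_matrix(tr, genes, flank = 1234), "multiple")
})

test_that("peak caller is calibrated on uniform noise and finds planted spikes", {
  genome <- c(chrA = 200000)
  ## calibration: pure Poisson background, fraction of bins in peaks stays
  ## below the nominal threshold across seeds
  frac <- vapply(1:20, function(s) {
    set.seed(700 + s)
    track <- structure(list(bins = list(chrA = rpois(2000, 5)), binsize = 100,
                            mode = "fragments", library_size = 10000,
                            genome = genome),
                       class = "coverage_track")
    pk <- call_peaks(track, alpha = 0.05)
    if (nrow(pk)) sum(pk$n_bins) / 2000 else 0
  }, numeric(1))
  expect_lte(mean(frac), 0.05)

  ## single hot bin
  bins <- rep(1, 500); bins[250] <- 100
  track <- structure(list(bins = list(chrA = bins), binsize = 100,
                          mode = "fragments", library_size = 1000,
                          genome = c(chrA = 50000)),
                     class = "coverage_track")
  pk <- call_peaks(track, lambda_bg = 1)
  expect_equal(nrow(pk), 1)
  expect_true(pk$start <= 24900 && pk$end >= 25000)

  ## two significant bins bridged across one sub-threshold bin merge
  bins2 <- rep(1, 500); bins2[c(250, 252)] <- 100
  track2 <- structure(list(bins = list(chrA = bins2), binsize = 100,
                           mode = "fragments", library_size = 1000,
                           genome = c(chrA = 50000)),
                      class = "coverage_track")
  pk2 <- call_peaks(track2, lambda_bg = 1, merge_gap = 1)
  expect_equal(nrow(pk2), 1)
  expect_equal(pk2$n_bins, 2)

  ## all-zero track -> empty peak list
  z <- structure(list(bins = list(chrA = rep(0, 100)), binsize = 100,
                      mode = "fragments", library_size = 0,
                      genome = c(chrA = 10000)),
                 class = "coverage_track")
  expect_equal(nrow(call_peaks(z)), 0)
})
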