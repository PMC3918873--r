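test_that("detection filter removes only probes undetected in all samples", {
  x <- matrix(100, 3, 3, dimnames = list(c("p1", "p2", "p3"), NULL))
  dp <- rbind(p1 = c(0.5, 0.2, 0.9),    # above alpha everywhere -> removed
              p2 = c(0.5, 0.005, 0.9),  # detected once -> retained
              p3 = c(0.001, 0.001, 0.001))
  b <- make_bundle(x, c("vehicle", "vehicle", "treated"))
  b$detection_p <- dp
  colnames(b$detection_p) <- colnames(b$intensities)
  out <- filter_probes(b, 0.01)
  expect_setequal(rownames(out$intensities), c("p2", "p3"))
  expect_equal(out$samples, b$samples)

  empty <- b
  empty$intensities <- b$intensities[0, , drop = FALSE]
  empty$detection_p <- b$detection_p[0, , drop = FALSE]
  expect_equal(nrow(filter_probes(empty, 0.01)$intensities), 0)
})

test_that("vst is strictly monotone and stabilizes multiplicative noise", {
  set.seed(42)
  ## low anchor block sets the scale quantile; two log-normal blocks with
  ## equal multiplicative noise should come out with near-equal variance
  x <- rbind(matrix(2^6, 100, 4),
             2^(10 + matrix(rnorm(400, 0, 0.3), 100)),
             2^(14 + matrix(rnorm(400, 0, 0.3), 100)))
  b <- make_bundle(x, c("vehicle", "vehicle", "treated", "treated"))
  v <- vst_transform(b)$intensities
  expect_true(all(diff(v[order(x[, 1]), 1]) >= 0))
  var_mid <- var(v[101:200, 1])
  var_high <- var(v[201:300, 1])
  expect_lt(abs(var_high - var_mid) / var_mid, 0.2)
  ## all-equal column stays all-equal; negative input errors
  xb <- make_bundle(matrix(5, 4, 2), c("vehicle", "treated"))
  expect_equal(length(unique(vst_transform(xb)$intensities[, 1])), 1)
  xb$intensities[1, 1] <- -1
  expect_error(vst_transform(xb), "negative")
})

test_that("quantile normalization equalizes sorted columns and is idempotent", {
  b <- make_bundle(cbind(c(1, 2, 3), c(4, 5, 6)), c("vehicle", "treated"))
  q <- quantile_normalize(b)$intensities
  expect_equal(unname(q), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))

  set.seed(7)
  m <- matrix(rexp(200), 50, 4)
  b2 <- make_bundle(m, c("vehicle", "vehicle", "treated", "treated"))
  q1 <- quantile_normalize(b2)
  sorted <- apply(q1$intensities, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  ## rank order preserved within sample, and a second pass changes nothing
  expect_equal(order(q1$intensities[, 2]), order(m[, 2]))
  expect_equal(quantile_normalize(q1)$intensities, q1$intensities,
               tolerance = 1e-12)
  ## single sample: warning, unchanged
  b1 <- make_bundle(matrix(1:4, 4, 1), "vehicle")
  expect_warning(out <- quantile_normalize(b1), ">= 2 samples")
  expect_equal(out$intensities, b1$intensities)
})

test_that("moderated t reduces to the ordinary t without shrinkage and handles edge genes", {
  set.seed(1)
  x <- matrix(rnorm(60, 8, 0.5), 10, 6)
  x[1, ] <- 8  # identical arm means, zero variance
  b <- make_bundle(x, rep(c("vehicle", "treated"), each = 3))
  de0 <- moderated_de(b, "lineA", prior_df = 0)
  ## brute-force two-sample equal-variance t
  tt <- apply(x[-1, ], 1, function(v) {
    a <- v[1:3]; c <- v[4:6]
    sp <- sqrt(((2 * var(a) + 2 * var(c)) / 4) * (2 / 3))
    (mean(c) - mean(a)) / sp
  })
  expect_equal(de0$t_mod[-1], unname(tt), tolerance = 1e-10)
  expect_equal(de0$log2fc[1], 0)
  expect_equal(de0$t_mod[1], 0)
  expect_equal(de0$p[1], 1)

  ## equal gene variances: shrinkage is the identity
  y <- rbind(c(1, 2, 3, 4, 5, 6), c(2, 3, 4, 5, 6, 7), c(0, 1, 2, 3, 4, 5))
  b2 <- make_bundle(y, rep(c("vehicle", "treated"), each = 3))
  expect_equal(moderated_de(b2, "lineA")$t_mod,
               moderated_de(b2, "lineA", prior_df = 0)$t_mod,
               tolerance = 1e-8)

  ## fewer than 2 replicates per arm is an error
  b3 <- make_bundle(x[, 1:4], c("vehicle", "treated", "treated", "treated"))
  expect_error(moderated_de(b3, "lineA"), "2 replicates")
})

test_that("variance shrinkage matches limma's empirical-Bayes fit", {
  set.seed(33)
  n1 <- 3; n2 <- 3
  sds <- sqrt(0.1 * rchisq(300, df = 5) / 5)
  x <- t(sapply(sds, function(s) rnorm(n1 + n2, 8, s)))
  x[, 4:6] <- x[, 4:6] + rep(c(0, -2), c(250, 50))[seq_len(300)]
  b <- make_bundle(x, rep(c("vehicle", "treated"), each = 3))
  de <- moderated_de(b, "lineA")
  prior <- attr(de, "prior")

  s2 <- apply(x, 1, function(v) (2 * var(v[1:3]) + 2 * var(v[4:6])) / 4)
  ff <- limma::fitFDist(s2, df1 = 4)
  expect_equal(prior$df_prior, ff$df2, tolerance = 1e-6)
  expect_equal(prior$var_prior, ff$scale, tolerance = 1e-6)

  design <- cbind(intercept = 1, treated = rep(c(0, 1), each = 3))
  fit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(unname(de$t_mod), unname(fit$t[, "treated"]), tolerance = 1e-8)
  expect_equal(unname(de$p), unname(fit$p.value[, "treated"]), tolerance = 1e-8)
})

test_that("detection power on strongly planted genes is essentially complete", {
  set.seed(10)
  hits <- 0; total <- 0
  for (sim in 1:100) {
    x <- matrix(rnorm(50 * 6, 8, 0.1), 50, 6)
    x[1:5, 4:6] <- x[1:5, 4:6] - 2
    b <- make_bundle(x, rep(c("vehicle", "treated"), each = 3))
    de <- moderated_de(b, "lineA")
    hits <- hits + sum(de$q[1:5] < 0.05)
    total <- total + 5
  }
  expect_gt(hits / total, 0.99)
})

test_that("BH adjustment equals the step-up oracle and handles edge inputs", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(7)
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  expect_warning(q <- bh_adjust(c(0.1, NaN, 0.5)), "NaN")
  expect_true(is.nan(q[2]))
  expect_equal(q[c(1, 3)], bh_oracle(c(0.1, 0.5)))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("significance calls apply the joint FDR and fold-change gate", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   log2fc = c(-1.1, -0.9, -3.0, 1.2),
                   q = c(0.04, 0.04, 0.06, 0.01))
  sig <- call_significant(de, fdr = 0.05, fc = 2)
  expect_equal(sig$down, "a")   # fold 2.14 > 2, q ok
  expect_equal(sig$up, "d")
  expect_length(intersect(sig$up, sig$down), 0)
})

test_that("the pipeline is calibrated under the complete null", {
  ## no planted effects anywhere: genome-wide significant-call rate at
  ## FDR 5% stays at or below the nominal level
  rates <- vapply(1:20, function(s) {
    g <- generate_expression_bundle(
      experiment_config(n_cell_lines = 1, n_genes = 400, core_block_size = 0,
                        private_de_per_line = 0, seed = 500 + s))
    res <- expression_down_sets(g$bundle)
    de <- res$de[[1]]
    mean(de$q < 0.05)
  }, numeric(1))
  expect_lte(mean(rates), 0.05)
})
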