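baseline_fixture <- function(seed = 40, n = 120) {
  set.seed(seed)
  counts <- cbind(rbinom(n, 2, 0.3), rbinom(n, 2, 0.2),
                  sapply(1:6, function(i) rbinom(n, 2, 0.03)))
  gm <- make_geno(counts)
  gene <- structure(list(gene_id = "g", common = 1:2, rare = 3:8),
                    class = "GeneRegion")
  list(gm = gm, gene = gene, counts = counts)
}

test_that("T_ind and T_sum collapse all rare variants and match a regression oracle", {
  f <- baseline_fixture()
  carriers <- rowSums(f$counts[, 3:8]) > 0
  y <- rnorm(120) + 1.2 * carriers   # shifted carrier phenotype
  ind <- t_ind(y, f$gm, f$gene)
  expect_gt(ind$statistic, 2)
  expect_lt(ind$p_value, 0.05)
  # closed-form oracle via lm on the indicator score
  o <- summary(lm(y ~ as.numeric(carriers)))
  expect_equal(ind$statistic, abs(o$coefficients[2, 3]), tolerance = 1e-8)
  expect_equal(ind$p_value, o$coefficients[2, 4], tolerance = 1e-8)

  sm <- t_sum(y, f$gm, f$gene)
  o2 <- summary(lm(y ~ rowSums(f$counts[, 3:8])))
  expect_equal(sm$statistic, abs(o2$coefficients[2, 3]), tolerance = 1e-8)

  # no rare carriers at all: degenerate
  gm0 <- make_geno(cbind(rbinom(30, 2, 0.3), rep(0, 30)))
  gene0 <- structure(list(gene_id = "g", common = 1, rare = 2),
                     class = "GeneRegion")
  expect_error(t_ind(rnorm(30), gm0, gene0), "degenerate")
})

test_that("T_sum equals T_ind on singleton carriers but not on doubled counts", {
  set.seed(44)
  n <- 40
  counts <- cbind(rbinom(n, 2, 0.3), diag(1, n)[, 1:3])
  counts[1:3, 2:4] <- diag(1, 3)   # three singleton carriers
  gm <- make_geno(counts)
  gene <- structure(list(gene_id = "g", common = 1, rare = 2:4),
                    class = "GeneRegion")
  y <- rnorm(n)
  expect_equal(t_sum(y, gm, gene)$statistic, t_ind(y, gm, gene)$statistic,
               tolerance = 1e-10)

  counts2 <- counts
  counts2[1, 2] <- 2               # a homozygous carrier
  gm2 <- make_geno(counts2)
  expect_equal(t_ind(y, gm2, gene)$statistic, t_ind(y, gm, gene)$statistic,
               tolerance = 1e-10)
  expect_false(isTRUE(all.equal(t_sum(y, gm2, gene)$statistic,
                                t_sum(y, gm, gene)$statistic)))
})

test_that("T_ws spans all variants, is weight-scale invariant and reduces correctly", {
  f <- baseline_fixture(41)
  y <- rnorm(120)
  w <- compute_weights(f$gm)$w
  ws <- t_ws(y, f$gm, f$gene, w)
  # t is invariant to rescaling the predictor: single-variant gene equals raw
  gm1 <- make_geno(f$counts[, 1, drop = FALSE])
  gene1 <- structure(list(gene_id = "g", common = 1, rare = integer(0)),
                     class = "GeneRegion")
  expect_equal(t_ws(y, gm1, gene1)$statistic,
               abs(simple_linreg(y, f$counts[, 1])$t_stat), tolerance = 1e-8)
  # equal weights make the weighted sum a plain sum over all variants
  expect_equal(t_ws(y, f$gm, f$gene, rep(2, 8))$statistic,
               abs(simple_linreg(y, rowSums(f$counts))$t_stat),
               tolerance = 1e-8)
  # scale invariance of the statistic in the weights
  expect_equal(t_ws(y, f$gm, f$gene, 3.7 * w)$statistic, ws$statistic,
               tolerance = 1e-8)
})

test_that("T_com picks the strongest common variant, sharing select_base's rule", {
  f <- baseline_fixture(42)
  y <- rnorm(120) + 0.9 * f$counts[, 2]
  com <- t_com(y, f$gm, f$gene)
  expect_equal(com$members, 2)
  sb <- select_base(y, f$gene, f$gm)
  expect_equal(com$statistic^2, sb$F, tolerance = 1e-8)
  # exhaustive scan oracle
  oracle <- sapply(1:2, function(j)
    abs(summary(lm(y ~ f$counts[, j]))$coefficients[2, 3]))
  expect_equal(com$statistic, max(oracle), tolerance = 1e-8)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroni_adjust(1e-4, 553), 0.0553)
  expect_equal(bonferroni_adjust(0.01, 553), 1)
  expect_equal(bonferroni_adjust(0.2, 1), 0.2)
  expect_error(bonferroni_adjust(1.2, 10))
})

test_that("type-I error and power pool rejections with the stated denominators", {
  pv <- expand.grid(replicate = 1:100, gene_id = sprintf("g%02d", 1:10),
                    test = "T_sum", stringsAsFactors = FALSE)
  pv$p_value <- 1
  pv$p_value[seq_len(5)] <- 0.001   # 5 null-gene rejections
  s <- evaluate_tests(pv, causal_genes = character(0), alphas = 0.05)
  expect_equal(unname(s$type1["T_sum"]), 5 / (100 * 10))

  # a causal gene rejected in 190 of 200 replicates has 95% power
  pv2 <- data.frame(replicate = rep(1:200, 2),
                    gene_id = rep(c("causal", "null"), each = 200),
                    test = "FS_ind",
                    p_value = c(rep(0.01, 190), rep(0.9, 10), rep(0.5, 200)))
  s2 <- evaluate_tests(pv2, "causal", alphas = c(FS_ind = 0.05))
  expect_equal(s2$power$FS_ind[1], 0.95)
  expect_equal(unname(s2$type1["FS_ind"]), 0)

  # alpha = 0 rejects nothing
  s3 <- evaluate_tests(pv2, "causal", alphas = c(FS_ind = 0))
  expect_equal(s3$power$FS_ind[1], 0)
})

test_that("alpha calibration inverts the empirical null distribution", {
  p <- (1:1000) / 1000
  expect_equal(calibrate_alpha(p, 0.05), 0.05)
  expect_error(calibrate_alpha(rep(1, 50), 0.05), "unreachable")

  set.seed(43)
  u <- runif(10000)
  a <- calibrate_alpha(u, 0.06)
  expect_lt(abs(a - 0.06), 3 * sqrt(0.06 * 0.94 / 10000) + 1e-3)
  # re-evaluating at the calibrated level respects the target
  expect_lte(mean(u <= a), 0.06)
  # monotone in the target rate
  expect_lte(calibrate_alpha(u, 0.03), calibrate_alpha(u, 0.10))
})
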