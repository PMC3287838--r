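test_that("closed-form simple regression matches the frozen worked example", {
  fit <- simple_linreg(c(1, 2, 3, 5), c(1, 2, 3, 4))
  expect_equal(fit$slope, 1.3)
  expect_equal(fit$F_stat, 56.33333, tolerance = 1e-6)
  expect_equal(fit$t_stat, 7.5055535, tolerance = 1e-6)
  expect_equal(fit$df_resid, 2)

  perfect <- simple_linreg(c(1, 2, 3), c(1, 2, 3))
  expect_true(perfect$perfect_fit)
  expect_equal(perfect$F_stat, Inf)

  expect_error(simple_linreg(c(1, 2, 3), c(2, 2, 2)), "degenerate")
})

test_that("F equals t squared on random instances", {
  set.seed(20)
  for (i in 1:250) {
    n <- sample(5:60, 1)
    fit <- simple_linreg(rnorm(n), rnorm(n))
    expect_equal(fit$F_stat, fit$t_stat^2, tolerance = 1e-8)
    # cross-check against lm()
    if (i <= 20) {
      y <- rnorm(n); s <- rnorm(n)
      a <- simple_linreg(y, s)
      b <- summary(lm(y ~ s))
      expect_equal(a$F_stat, unname(b$fstatistic[1]), tolerance = 1e-8)
      expect_equal(a$p_value, unname(b$coefficients["s", 4]),
                   tolerance = 1e-8)
    }
  }
})

test_that("base selection maximises F with deterministic tie-breaking", {
  set.seed(21)
  y <- rnorm(60)
  x_noise <- rbinom(60, 2, 0.3)
  gm <- make_geno(cbind(round(pmin(pmax(y - min(y), 0), 2)), x_noise))
  # column 1 tracks y closely; it must win
  gene <- structure(list(gene_id = "g", common = 1:2, rare = integer(0)),
                    class = "GeneRegion")
  expect_equal(select_base(y, gene, gm)$base, 1)

  # duplicated columns have identical F: lowest index wins
  gm_dup <- make_geno(cbind(x_noise, x_noise))
  gene_dup <- structure(list(gene_id = "g", common = 1:2, rare = integer(0)),
                        class = "GeneRegion")
  expect_equal(select_base(y, gene_dup, gm_dup)$base, 1)

  # exhaustive scan oracle over a 20-variant gene
  counts <- sapply(1:20, function(i) rbinom(60, 2, runif(1, 0.1, 0.4)))
  gm20 <- make_geno(counts)
  gene20 <- structure(list(gene_id = "g", common = 1:20, rare = integer(0)),
                      class = "GeneRegion")
  oracleF <- sapply(1:20, function(j)
    unname(summary(lm(y ~ counts[, j]))$fstatistic[1]))
  got <- select_base(y, gene20, gm20)
  expect_equal(got$base, which.max(oracleF))
  expect_equal(got$F, max(oracleF), tolerance = 1e-8)

  # all-monomorphic common set is an error
  gm0 <- make_geno(matrix(0, 60, 1) + 0)
  gene0 <- structure(list(gene_id = "g", common = 1, rare = integer(0)),
                     class = "GeneRegion")
  expect_error(select_base(y, gene0, gm0), "no usable common")
})

test_that("single-step extension picks the best candidate or signals none", {
  set.seed(22)
  n <- 100
  y <- rnorm(n)
  common <- rbinom(n, 2, 0.3)
  rares <- sapply(1:5, function(i) rbinom(n, 2, 0.02))
  gm <- make_geno(cbind(common, rares))
  # single remaining candidate comes back with its own F
  one <- extend_one(y, gm, "sum", 1, 3)
  s <- collapse_sum(gm, c(1, 3))
  expect_equal(one$rare, 3)
  expect_equal(one$F_new, simple_linreg(y, s)$F_stat)

  # exhaustive scan oracle over all candidates
  best <- extend_one(y, gm, "sum", 1, 2:6)
  oracle <- sapply(2:6, function(g)
    simple_linreg(y, collapse_sum(gm, c(1, g)))$F_stat)
  expect_equal(best$rare, (2:6)[which.max(oracle)])
  expect_equal(best$F_new, max(oracle))

  # saturated indicator: every candidate yields a constant score
  gm_sat <- make_geno(cbind(rep(1, 20), rbinom(20, 2, 0.1)))
  expect_null(extend_one(rnorm(20), gm_sat, "indicator", 1, 2))
})

test_that("forward selection accepts signal and rejects noise", {
  set.seed(23)
  n <- 200
  x_common <- rbinom(n, 2, 0.25)
  g1 <- rbinom(n, 2, 0.03)      # strongly associated rare
  g2 <- rbinom(n, 2, 0.03)      # pure noise rare
  y <- 0.2 * x_common + 1.5 * g1 + rnorm(n)
  gm <- make_geno(cbind(x_common, g1, g2))
  gene <- structure(list(gene_id = "g", common = 1, rare = 2:3),
                    class = "GeneRegion")
  res <- run_forward_selection(y, gm, gene, "sum")
  expect_equal(res$base_variant, 1)
  expect_true(2 %in% res$selected_rares)
  expect_false(3 %in% res$selected_rares)
  expect_equal(length(res$f_trace), length(res$selected_rares) + 1)

  # no rare variants: the FS statistic is the base regression |t|
  gene_norare <- structure(list(gene_id = "g", common = 1, rare = integer(0)),
                           class = "GeneRegion")
  res0 <- run_forward_selection(y, gm, gene_norare, "sum")
  expect_length(res0$f_trace, 1)
  expect_length(res0$selected_rares, 0)
  expect_equal(res0$fs_stat, abs(simple_linreg(y, x_common)$t_stat))

  # when no candidate improves F the trace stays at length 1
  set.seed(24)
  repeat {
    y_null <- rnorm(n)
    baseF <- simple_linreg(y_null, x_common)$F_stat
    candF <- sapply(2:3, function(g)
      simple_linreg(y_null, collapse_sum(gm, c(1, g)))$F_stat)
    if (all(candF <= baseF)) break
  }
  res_null <- run_forward_selection(y_null, gm, gene, "sum")
  expect_length(res_null$f_trace, 1)
  expect_length(res_null$selected_rares, 0)
})

test_that("the F trace increases strictly and fs_stat^2 is the final F", {
  set.seed(25)
  for (i in 1:30) {
    counts <- random_gene_counts(80, 2, 8)
    gm <- make_geno(counts)
    gene <- structure(list(gene_id = "g", common = 1:2, rare = 3:10),
                      class = "GeneRegion")
    y <- rnorm(80)
    m <- c("indicator", "sum", "weighted_sum")[(i %% 3) + 1]
    res <- run_forward_selection(y, gm, gene, m)
    if (length(res$f_trace) > 1) expect_true(all(diff(res$f_trace) > 0))
    expect_equal(res$fs_stat^2, res$f_trace[length(res$f_trace)],
                 tolerance = 1e-8)
  }
})

test_that("selection is invariant under simultaneous sample relabeling", {
  set.seed(26)
  n <- 70
  counts <- random_gene_counts(n, 2, 6)
  gm <- make_geno(counts)
  gene <- structure(list(gene_id = "g", common = 1:2, rare = 3:8),
                    class = "GeneRegion")
  y <- rnorm(n) + 0.8 * counts[, 3]
  perm <- sample(n)
  gm_p <- genotype_matrix(counts[perm, ], samples = gm$samples,
                          variants = gm$variants)
  for (m in c("indicator", "sum", "weighted_sum")) {
    a <- run_forward_selection(y, gm, gene, m)
    b <- run_forward_selection(y[perm], gm_p, gene, m)
    expect_equal(a$base_variant, b$base_variant)
    expect_equal(a$selected_rares, b$selected_rares)
    expect_equal(a$fs_stat, b$fs_stat, tolerance = 1e-10)
  }
})

test_that("the compiled engine reproduces the R selection path exactly", {
  set.seed(27)
  n <- 90
  counts <- random_gene_counts(n, 3, 8)
  gm <- make_geno(counts)
  gene <- structure(list(gene_id = "g", common = 1:3, rare = 4:11),
                    class = "GeneRegion")
  w <- compute_weights(gm)$w
  for (i in 1:15) {
    y <- rnorm(n) + (i %% 2) * 0.9 * counts[, 5]
    for (m in c("indicator", "sum", "weighted_sum")) {
      r_res <- run_forward_selection(y, gm, gene, m, w)
      c_res <- fscollapse:::cpp_fs_single(
        y, gm$counts, gene$common, gene$rare, w,
        match(m, c("indicator", "sum", "weighted_sum")))
      expect_equal(r_res$base_variant, c_res$base_variant)
      expect_equal(as.integer(r_res$selected_rares),
                   as.integer(c_res$selected_rares))
      expect_equal(r_res$fs_stat, c_res$fs_stat, tolerance = 1e-10)
      expect_equal(r_res$f_trace, c_res$f_trace, tolerance = 1e-10)
    }
  }
})
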