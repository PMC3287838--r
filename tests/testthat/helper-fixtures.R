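# Shared fixtures and independent reference implementations used as oracles.

make_geno <- function(counts) {
  counts <- as.matrix(counts)
  genotype_matrix(counts,
                  samples = sprintf("s%03d", seq_len(nrow(counts))),
                  variants = sprintf("v%03d", seq_len(ncol(counts))))
}

# Random polymorphic gene: raw count matrix plus common/rare column splits.
random_gene_counts <- function(n, n_common, n_rare,
                               common_maf = c(0.05, 0.4),
                               rare_maf = c(0.005, 0.05)) {
  draw <- function(maf_rng) {
    repeat {
      x <- rbinom(n, 2, runif(1, maf_rng[1], maf_rng[2]))
      if (var(x) > 0) return(x)
    }
  }
  cbind(
    if (n_common > 0) sapply(seq_len(n_common), function(i) draw(common_maf)),
    if (n_rare > 0) sapply(seq_len(n_rare), function(i) draw(rare_maf)))
}

# From-scratch collapsed score, independent of the package's collapse_*().
naive_score <- function(counts, members, method, weights = NULL) {
  sub <- counts[, members, drop = FALSE]
  switch(method,
         indicator = apply(sub, 1, function(r) as.numeric(any(r > 0))),
         sum = apply(sub, 1, sum),
         weighted_sum = apply(sweep(sub, 2, weights[members], "/"), 1, sum))
}

# Naive greedy forward selection: materialises every candidate score at
# every step from scratch and uses lm() for all fits.
naive_fs <- function(y, counts, common, rare, method, weights = NULL) {
  lm_F <- function(s) {
    if (var(s) == 0) return(NULL)
    fs <- summary(lm(y ~ s))$fstatistic
    unname(fs[1])
  }
  Fs <- vapply(common, function(j) {
    f <- lm_F(counts[, j]); if (is.null(f)) -Inf else f
  }, numeric(1))
  if (all(!is.finite(Fs) & Fs < 0)) stop("no usable common variant")
  base <- common[which.max(Fs)]
  members <- base
  f_trace <- max(Fs)
  pool <- rare
  repeat {
    if (length(pool) == 0) break
    candF <- vapply(pool, function(g) {
      s <- naive_score(counts, c(members, g), method, weights)
      f <- lm_F(s); if (is.null(f)) -Inf else f
    }, numeric(1))
    best <- which.max(candF)
    if (!(candF[best] > f_trace[length(f_trace)])) break
    members <- c(members, pool[best])
    f_trace <- c(f_trace, candF[best])
    pool <- pool[-best]
  }
  list(base = base, selected = members[-1], f_trace = f_trace)
}

# All permutations of 1..n (small n only).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- setdiff(seq_len(n), k)
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

# Small end-to-end dataset for pipeline tests.
tiny_dataset <- function(seed = 7, n = 150, n_genes = 20,
                         causal = "gene003", beta_rare = 1.5,
                         beta_common = 0.4, n_replicates = 1) {
  cfg <- sim_config(n_individuals = n, n_genes = n_genes,
                    causal_genes = causal, beta_rare = beta_rare,
                    beta_common = beta_common,
                    n_replicates = n_replicates, seed = seed)
  sim <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(sim, cfg, 1)
  list(cfg = cfg, sim = sim, ph = ph)
}
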