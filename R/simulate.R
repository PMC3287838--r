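#' Simulation configuration
#'
#' Defines a synthetic study: independent biallelic variants grouped into
#' genes with a rare-dominated frequency spectrum plus at least one common
#' SNP per gene, and quantitative traits linear in a subset of causal
#' variants, optional covariates and Gaussian noise.  Genotypes (and
#' covariates) are fixed across phenotype replicates; only the effect
#' noise is redrawn — the fixed-genotype, replicated-phenotype design of
#' the benchmark the method was evaluated on.
#'
#' @param n_individuals number of samples, default 300.
#' @param n_genes number of genes, default 200.
#' @param variants_per_gene variants per gene, default 12.
#' @param n_common_per_gene length-1 or length-2 (range) count of common
#'   variants per gene, default `c(1, 2)`.
#' @param common_maf_range designed MAF interval of common variants,
#'   default `c(0.05, 0.3)`.
#' @param rare_maf_range designed MAF interval of rare variants, default
#'   `c(0.001, 0.009)`.
#' @param causal_genes gene ids (e.g. `"gene007"`) carrying genetic
#'   effects; default none (a fully null scenario).
#' @param causal_rare_fraction fraction of a causal gene's rare variants
#'   that carry an effect, default 0.5 (the misclassification regime:
#'   half of the collapsed variants are noise).
#' @param beta_common trait-unit effect per minor allele of a causal
#'   gene's first common variant, default 0.15 (a weak common effect).
#' @param beta_rare trait-unit effect per minor allele of each causal
#'   rare variant, default 1 (rare variants of moderate-to-high effect).
#' @param effect_sign_mix fraction of causal rare variants whose effect
#'   sign is flipped to negative, default 0 (concordant effects).
#' @param noise_sd residual sd of the trait, default 1.
#' @param covariate_effects named numeric vector of effects for the two
#'   generated covariates `age` (standard normal) and `sex` (binary),
#'   e.g. `c(age = 0.5, sex = 0.3)`; default none.
#' @param n_replicates phenotype replicates, default 1.
#' @param seed RNG seed fixing the complete output stream.
#' @return a `SimulationConfig` list.
#' @export
sim_config <- function(n_individuals = 300, n_genes = 200,
                       variants_per_gene = 12, n_common_per_gene = c(1, 2),
                       common_maf_range = c(0.05, 0.3),
                       rare_maf_range = c(0.001, 0.009),
                       causal_genes = character(0),
                       causal_rare_fraction = 0.5,
                       beta_common = 0.15, beta_rare = 1,
                       effect_sign_mix = 0, noise_sd = 1,
                       covariate_effects = NULL,
                       n_replicates = 1, seed = 1) {
  stopifnot(n_individuals >= 2, n_genes >= 1, variants_per_gene >= 1,
            all(n_common_per_gene >= 1),
            max(n_common_per_gene) <= variants_per_gene,
            common_maf_range[1] <= common_maf_range[2],
            common_maf_range[1] >= 0.01, common_maf_range[2] <= 0.5,
            rare_maf_range[1] > 0, rare_maf_range[2] < 0.01,
            causal_rare_fraction >= 0, causal_rare_fraction <= 1,
            effect_sign_mix >= 0, effect_sign_mix <= 1,
            noise_sd >= 0, n_replicates >= 1)
  structure(as.list(environment()), class = "SimulationConfig")
}

## deterministic sub-seed per purpose/replicate, kept inside 32-bit range
sub_seed <- function(seed, offset) (seed * 48271 + offset) %% 2147483647L

#' Simulate a genotype panel with gene structure
#'
#' Per variant a designed MAF is drawn uniformly from its class range and
#' genotypes are Binomial(2, MAF), independent across variants (no LD).
#' Monomorphic draws are redrawn so every gene keeps its full polymorphic
#' variant count and passes the analyzability filter.  Causal variants
#' (for later phenotype simulation) are chosen here so they are fixed
#' across replicates: in each causal gene, the first common variant plus a
#' random `causal_rare_fraction` of the rare variants.
#'
#' @param config a [sim_config()].
#' @return list with `genotypes` (a [genotype_matrix()]), `gene_map`
#'   (variant_id/gene_id data frame), `annotations` (variant_id, gene_id,
#'   designed maf, empirical maf and class) , `effects` (per-variant trait
#'   effect vector, 0 for non-causal) and `covariates` (data frame with
#'   `age`, `sex`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(sub_seed(config$seed, 0L))
  n <- config$n_individuals
  gene_ids <- sprintf("gene%03d", seq_len(config$n_genes))
  if (!all(config$causal_genes %in% gene_ids))
    stop("causal_genes must be among the generated gene ids: ",
         paste(gene_ids[1:2], collapse = ", "), ", ...")
  ncpg_rng <- range(config$n_common_per_gene)
  cols <- list(); ids <- character(0); genes <- character(0)
  designed_maf <- numeric(0); designed_class <- character(0)
  effects <- numeric(0)
  for (g in seq_len(config$n_genes)) {
    ncom <- if (ncpg_rng[1] == ncpg_rng[2]) ncpg_rng[1] else
      sample(ncpg_rng[1]:ncpg_rng[2], 1)
    nrare <- config$variants_per_gene - ncom
    cls <- c(rep("common", ncom), rep("rare", nrare))
    maf <- c(stats::runif(ncom, config$common_maf_range[1], config$common_maf_range[2]),
             stats::runif(nrare, config$rare_maf_range[1], config$rare_maf_range[2]))
    gmat <- matrix(0, n, length(maf))
    for (j in seq_along(maf)) {
      repeat {
        x <- stats::rbinom(n, 2, maf[j])
        if (stats::var(x) > 0) break
      }
      gmat[, j] <- x
    }
    eff <- numeric(length(maf))
    if (gene_ids[g] %in% config$causal_genes) {
      eff[1] <- config$beta_common
      n_causal_rare <- round(config$causal_rare_fraction * nrare)
      if (n_causal_rare > 0) {
        pick <- ncom + sort(sample.int(nrare, n_causal_rare))
        sgn <- rep(1, n_causal_rare)
        n_neg <- round(config$effect_sign_mix * n_causal_rare)
        if (n_neg > 0) sgn[seq_len(n_neg)] <- -1
        eff[pick] <- sgn * config$beta_rare
      }
    }
    vid <- sprintf("%s_v%02d", gene_ids[g], seq_along(maf))
    cols <- c(cols, list(gmat))
    ids <- c(ids, vid)
    genes <- c(genes, rep(gene_ids[g], length(maf)))
    designed_maf <- c(designed_maf, maf)
    designed_class <- c(designed_class, cls)
    effects <- c(effects, eff)
  }
  counts <- do.call(cbind, cols)
  gm <- genotype_matrix(counts,
                        samples = sprintf("ind%04d", seq_len(n)),
                        variants = ids)
  emp_maf <- compute_maf(gm)
  covariates <- data.frame(age = stats::rnorm(n),
                           sex = stats::rbinom(n, 1, 0.5),
                           row.names = gm$samples)
  list(genotypes = gm,
       gene_map = data.frame(variant_id = ids, gene_id = genes,
                             stringsAsFactors = FALSE),
       annotations = data.frame(variant_id = ids, gene_id = genes,
                                designed_maf = designed_maf,
                                designed_class = designed_class,
                                maf = unname(emp_maf),
                                variant_class = unname(classify_variants(emp_maf)),
                                stringsAsFactors = FALSE),
       effects = stats::setNames(effects, ids),
       covariates = covariates)
}

#' Simulate one phenotype replicate
#'
#' `y_i = sum_v beta_v g_iv + sum_c gamma_c C_ic + eps_i` with
#' `eps ~ Normal(0, noise_sd^2)`.  Genotypes, covariates and causal-variant
#' assignments come from [simulate_genotypes()] and stay fixed; each
#' replicate redraws only the noise.
#'
#' @param sim output of [simulate_genotypes()].
#' @param config the same [sim_config()].
#' @param replicate_index replicate number (1-based); determines the
#'   replicate's RNG substream.
#' @return list with `y` (named numeric trait vector), `covariates`
#'   (data frame) and `causal_genes` (truth labels).
#' @export
simulate_phenotype <- function(sim, config, replicate_index = 1) {
  stopifnot(inherits(config, "SimulationConfig"), replicate_index >= 1)
  set.seed(sub_seed(config$seed, as.integer(replicate_index)))
  n <- config$n_individuals
  y <- drop(sim$genotypes$counts %*% sim$effects)
  if (!is.null(config$covariate_effects)) {
    for (nm in names(config$covariate_effects))
      y <- y + config$covariate_effects[[nm]] * sim$covariates[[nm]]
  }
  y <- y + stats::rnorm(n, 0, config$noise_sd)
  list(y = stats::setNames(y, sim$genotypes$samples),
       covariates = sim$covariates,
       causal_genes = config$causal_genes)
}
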