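#' Run the full association workflow on one dataset
#'
#' read -> MAF / classification / gene filter -> covariate selection +
#' ancestry PCs + phenotype adjustment -> forward-selection tests per
#' collapsing method -> baseline tests -> genome-wide permutation null ->
#' normalised statistics and global p-values -> report.
#'
#' @param genotypes a [genotype_matrix()] or path to a genotype file.
#' @param gene_map data frame or path to a variant-to-gene map TSV.
#' @param phenotypes data frame (with `sample_id`) or path to a phenotype
#'   TSV.
#' @param covariates optional data frame or path to a covariate TSV.
#' @param trait name of the trait column; default the first non-id column.
#' @param format genotype file format when `genotypes` is a path.
#' @param rare_threshold MAF boundary, default 0.01.
#' @param min_region_size minimum variants per analyzable gene, default 10.
#' @param methods collapsing methods to run forward selection with.
#' @param baselines also run the non-selective tests, default `TRUE`.
#' @param n_permutations permutations for the genome-wide null, default 1000.
#' @param n_pcs ancestry principal components appended to the selected
#'   covariates, default 5; 0 disables.
#' @param alpha_cov covariate-screening level, default 0.05.
#' @param smoothing add-one smoothing of global p-values, default `FALSE`.
#' @param seed RNG seed for the permutation stream.
#' @param out_dir optional output directory for `report.tsv` and a
#'   provenance record; created if missing.
#' @return list with `report` (data frame), `nulls` (per-method
#'   `PermutationNull`s), `y_adj`, `selected_covariates`, `regions` and
#'   `n_genes` (gene counts at each filtering stage).
#' @export
run_analysis <- function(genotypes, gene_map, phenotypes, covariates = NULL,
                         trait = NULL, format = "tsv",
                         rare_threshold = 0.01, min_region_size = 10,
                         methods = c("indicator", "sum", "weighted_sum"),
                         baselines = TRUE, n_permutations = 1000,
                         n_pcs = 5, alpha_cov = 0.05, smoothing = FALSE,
                         seed = 1, out_dir = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE))
  }
  if (is.character(genotypes))
    genotypes <- stage("read genotypes", read_genotypes(genotypes, format))
  if (is.character(gene_map))
    gene_map <- stage("read gene map", read_gene_map(gene_map))
  if (is.character(phenotypes))
    phenotypes <- stage("read phenotypes", read_phenotypes(phenotypes))
  if (is.character(covariates))
    covariates <- stage("read covariates", read_covariates(covariates))

  phenotypes <- stage("align samples", align_samples(phenotypes, genotypes))
  if (is.null(trait)) trait <- setdiff(names(phenotypes), "sample_id")[1]
  y <- phenotypes[[trait]]
  if (is.null(y)) stop("[align samples] trait column not found: ", trait)

  regions <- stage("gene regions",
                   build_gene_regions(genotypes, gene_map, rare_threshold))
  analyzable <- filter_genes(regions, min_region_size)
  message(sprintf("genes: %d mapped, %d analyzable (>= %d variants, >= 1 common)",
                  length(regions), length(analyzable), min_region_size))
  if (length(analyzable) == 0) stop("[gene filter] no analyzable genes")

  cand <- NULL
  if (!is.null(covariates)) {
    covariates <- stage("align samples", align_samples(covariates, genotypes))
    cand <- covariates[, setdiff(names(covariates), "sample_id"), drop = FALSE]
  }
  sel <- character(0)
  design <- NULL
  if (!is.null(cand) && ncol(cand) > 0) {
    sel <- stage("covariate selection", select_covariates(y, cand, alpha_cov))
    design <- cand[, sel, drop = FALSE]
  }
  if (n_pcs > 0) {
    pcs <- stage("PCA", compute_pcs(genotypes, n_pcs))
    design <- if (is.null(design)) pcs else cbind(design, pcs)
  }
  y_adj <- stage("phenotype adjustment", adjust_phenotype(y, design))
  message(sprintf("selected covariates: %s; %d PCs appended",
                  if (length(sel)) paste(sel, collapse = ", ") else "(none)",
                  n_pcs))

  weights <- compute_weights(genotypes)$w
  k <- length(analyzable)
  rows <- list()
  nulls <- list()
  for (m in methods) {
    null <- stage(paste0("permutation (", m, ")"),
                  build_null(y_adj, genotypes, analyzable, m,
                             M = n_permutations, seed = seed,
                             weights = weights))
    nulls[[m]] <- null
    rep_m <- gene_test_report(null, smoothing)
    paths <- lapply(analyzable, function(gr)
      run_forward_selection(y_adj, genotypes, gr, m, weights))
    rep_m$selected_variants <- vapply(paths, function(p)
      paste(genotypes$variants[p$selected_rares], collapse = ","), character(1))
    rep_m$f_trace_length <- vapply(paths, function(p)
      length(p$f_trace), numeric(1))
    rep_m$p_value <- rep_m$global_p
    rows[[m]] <- rep_m[, c("gene_id", "test", "statistic", "adj_statistic",
                           "p_value", "selected_variants", "f_trace_length")]
  }
  if (baselines) {
    base_rows <- lapply(analyzable, function(gr) {
      out <- list()
      for (tt in c("T_ind", "T_sum", "T_ws", "T_com")) {
        fit <- tryCatch(switch(tt,
                               T_ind = t_ind(y_adj, genotypes, gr),
                               T_sum = t_sum(y_adj, genotypes, gr),
                               T_ws = t_ws(y_adj, genotypes, gr, weights),
                               T_com = t_com(y_adj, genotypes, gr)),
                        error = function(e) NULL)
        if (is.null(fit)) next
        out[[tt]] <- data.frame(
          gene_id = gr$gene_id, test = tt, statistic = fit$statistic,
          adj_statistic = NA_real_,
          p_value = bonferroni_adjust(fit$p_value, k),
          selected_variants = "", f_trace_length = NA_real_,
          stringsAsFactors = FALSE)
      }
      do.call(rbind, out)
    })
    rows$baselines <- do.call(rbind, base_rows)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_report(report, file.path(out_dir, "report.tsv"))
    prov <- data.frame(
      package = "fscollapse",
      version = as.character(utils::packageVersion("fscollapse")),
      trait = trait, rare_threshold = rare_threshold,
      min_region_size = min_region_size,
      methods = paste(methods, collapse = ","),
      n_permutations = n_permutations, n_pcs = n_pcs,
      alpha_cov = alpha_cov, seed = seed,
      selected_covariates = paste(sel, collapse = ","))
    utils::write.table(prov, file.path(out_dir, "provenance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(report = report, nulls = nulls, y_adj = y_adj,
                 selected_covariates = sel, regions = analyzable,
                 n_genes = c(mapped = length(regions),
                             analyzable = length(analyzable))))
}

#' Simulation-based type-I-error / power evaluation
#'
#' Simulates a genotype panel once, then for each phenotype replicate runs
#' the requested forward-selection and baseline tests on the adjusted
#' trait and collects per-gene p-values.  Covariates are screened on the
#' first replicate only and the same selection reused afterwards.  With
#' `target_rate` set, each test's significance level is calibrated to that
#' pooled null-gene rejection rate before power is computed, so tests with
#' differently behaved p-values are compared at matched type-I error.
#'
#' @param config a [sim_config()].
#' @param methods forward-selection collapsing methods to run.
#' @param baselines also run `T_ind`, `T_sum`, `T_ws`, `T_com`.
#' @param n_permutations permutations per replicate for the FS tests; 0
#'   (default) skips the permutation machinery and assigns FS tests their
#'   nominal t-distribution p-values (meaningful only after calibration,
#'   since selection inflates the nominal statistic).
#' @param fs_pvalue which FS p-value to record when permuting:
#'   `"perm"` (per-gene marginal permutation p, default) or `"global"`
#'   (family-wise max-statistic p).
#' @param target_rate optional pooled null-gene type-I error target used
#'   to calibrate per-test alphas.
#' @param alphas optional named per-test significance levels (used as-is,
#'   overrides `target_rate`).
#' @param min_region_size,rare_threshold gene filter parameters.
#' @param out_dir optional directory for `type1.tsv` and `power.tsv`.
#' @return list with `pvalues` (long data frame: replicate, gene_id, test,
#'   statistic, p_value), `summary` (an `EvaluationSummary`, when alphas
#'   were given or calibrated), `alphas`, `sim` and `regions`.
#' @export
run_simulation <- function(config,
                           methods = c("indicator", "sum", "weighted_sum"),
                           baselines = TRUE, n_permutations = 0,
                           fs_pvalue = c("perm", "global"),
                           target_rate = NULL, alphas = NULL,
                           min_region_size = 10, rare_threshold = 0.01,
                           out_dir = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  fs_pvalue <- match.arg(fs_pvalue)
  sim <- simulate_genotypes(config)
  genotypes <- sim$genotypes
  regions <- build_gene_regions(genotypes, sim$gene_map, rare_threshold)
  analyzable <- filter_genes(regions, min_region_size)
  weights <- compute_weights(genotypes)$w
  n <- config$n_individuals
  k <- length(analyzable)
  gene_ids <- vapply(analyzable, function(r) r$gene_id, character(1))
  sel <- NULL
  out <- list()
  for (r in seq_len(config$n_replicates)) {
    ph <- simulate_phenotype(sim, config, r)
    if (is.null(sel))
      sel <- select_covariates(ph$y, sim$covariates)
    y_adj <- adjust_phenotype(ph$y, if (length(sel))
      sim$covariates[, sel, drop = FALSE] else NULL)
    for (m in methods) {
      test_name <- paste0("FS_", method_suffix(m))
      if (n_permutations > 0) {
        null <- build_null(y_adj, genotypes, analyzable, m,
                           M = n_permutations,
                           seed = sub_seed(config$seed,
                                           100000L + 101L * r +
                                             match(m, methods)),
                           weights = weights)
        pv <- if (fs_pvalue == "perm") perm_pvalues(null) else {
          gp <- global_pvalues(null$adj_stats, null$max_stats)
          gp[null$degenerate] <- 1
          gp
        }
        stat <- null$obs_stats
      } else {
        stat <- drop(fs_stat_matrix(y_adj, genotypes, analyzable, m, weights))
        pv <- 2 * stats::pt(-abs(stat), df = n - 2)
        pv[is.na(pv)] <- 1
      }
      out[[length(out) + 1L]] <- data.frame(
        replicate = r, gene_id = gene_ids, test = test_name,
        statistic = unname(stat), p_value = unname(pv),
        stringsAsFactors = FALSE)
    }
    if (baselines) {
      for (tt in c("T_ind", "T_sum", "T_ws", "T_com")) {
        res <- vapply(analyzable, function(gr) {
          fit <- tryCatch(switch(tt,
                                 T_ind = t_ind(y_adj, genotypes, gr),
                                 T_sum = t_sum(y_adj, genotypes, gr),
                                 T_ws = t_ws(y_adj, genotypes, gr, weights),
                                 T_com = t_com(y_adj, genotypes, gr)),
                          error = function(e) NULL)
          if (is.null(fit)) return(c(NA_real_, 1))
          c(fit$statistic, fit$p_value)
        }, numeric(2))
        out[[length(out) + 1L]] <- data.frame(
          replicate = r, gene_id = gene_ids, test = tt,
          statistic = res[1, ], p_value = res[2, ],
          stringsAsFactors = FALSE)
      }
    }
  }
  pvalues <- do.call(rbind, out)
  summary <- NULL
  if (is.null(alphas) && !is.null(target_rate)) {
    null_genes <- setdiff(gene_ids, config$causal_genes)
    tests <- unique(pvalues$test)
    alphas <- vapply(tests, function(tt)
      calibrate_alpha(pvalues$p_value[pvalues$test == tt &
                                        pvalues$gene_id %in% null_genes],
                      target_rate), numeric(1))
  }
  if (!is.null(alphas))
    summary <- evaluate_tests(pvalues, config$causal_genes, alphas)
  if (!is.null(out_dir) && !is.null(summary)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(
      data.frame(test = names(summary$type1), alpha = summary$alphas,
                 type1 = summary$type1),
      file.path(out_dir, "type1.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    if (!is.null(summary$power))
      utils::write.table(summary$power, file.path(out_dir, "power.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(pvalues = pvalues, summary = summary, alphas = alphas,
                 sim = sim, regions = analyzable))
}
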