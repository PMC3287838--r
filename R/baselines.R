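#' Non-selective baseline burden tests
#'
#' The baseline statistics collapse a fixed member set without any
#' selection and test it by simple linear regression of the adjusted trait
#' on the collapsed score:
#'
#' * `t_ind` — indicator (CAST-style) score over **all** the gene's rare
#'   variants;
#' * `t_sum` — minor-allele count over all the gene's rare variants;
#' * `t_ws` — Madsen-Browning weighted sum over **all** the gene's
#'   variants, common and rare;
#' * `t_com` — single-marker test on the most significant common variant
#'   (the same choice rule as the forward-selection base).
#'
#' Each returns the regression result augmented with `statistic = |t|` and
#' a two-sided p-value from the t distribution with N-2 df.
#'
#' @param y_adj adjusted phenotype values.
#' @param genotypes a [genotype_matrix()].
#' @param gene a `GeneRegion`.
#' @param weights optional full-length weight vector (for `t_ws`).
#' @return list as from [simple_linreg()] plus `statistic`, `members`.
#' @name baselines
NULL

finish_test <- function(fit, members) {
  fit$statistic <- abs(fit$t_stat)
  fit$members <- members
  fit
}

#' @rdname baselines
#' @export
t_ind <- function(y_adj, genotypes, gene) {
  if (length(gene$rare) == 0) stop("gene has no rare variants")
  s <- collapse_indicator(genotypes, gene$rare)
  finish_test(simple_linreg(y_adj, s), gene$rare)
}

#' @rdname baselines
#' @export
t_sum <- function(y_adj, genotypes, gene) {
  if (length(gene$rare) == 0) stop("gene has no rare variants")
  s <- collapse_sum(genotypes, gene$rare)
  finish_test(simple_linreg(y_adj, s), gene$rare)
}

#' @rdname baselines
#' @export
t_ws <- function(y_adj, genotypes, gene, weights = NULL) {
  members <- c(gene$common, gene$rare)
  if (length(members) == 0) stop("empty gene")
  if (is.null(weights)) weights <- compute_weights(genotypes)$w
  s <- collapse_weighted_sum(genotypes, members, weights)
  finish_test(simple_linreg(y_adj, s), members)
}

#' @rdname baselines
#' @export
t_com <- function(y_adj, genotypes, gene) {
  base <- select_base(y_adj, gene, genotypes)
  fit <- simple_linreg(y_adj, genotypes$counts[, base$base])
  finish_test(fit, base$base)
}

#' Bonferroni adjustment
#'
#' @param p p-value(s) in `[0, 1]`.
#' @param k number of tests (analyzable genes), `>= 1`.
#' @return `min(1, k * p)`, vectorised.
#' @export
bonferroni_adjust <- function(p, k) {
  stopifnot(all(p >= 0 & p <= 1), k >= 1)
  pmin(1, k * p)
}

#' Empirical significance-level calibration
#'
#' Returns the largest threshold `alpha` such that the empirical rejection
#' rate of the pooled null p-values at `alpha` does not exceed
#' `target_rate`.  Used to put tests with differently calibrated (or
#' selection-inflated) p-values on the same type-I-error footing before
#' comparing power.
#'
#' @param null_pvals pooled p-values of null genes for one test.
#' @param target_rate desired type-I error rate in (0, 1).
#' @return the calibrated alpha.
#' @export
calibrate_alpha <- function(null_pvals, target_rate) {
  stopifnot(length(null_pvals) > 0, target_rate > 0, target_rate < 1)
  cand <- sort(unique(null_pvals))
  rate <- vapply(cand, function(a) mean(null_pvals <= a), numeric(1))
  ok <- rate <= target_rate
  if (!any(ok)) stop("target unreachable: smallest attainable rejection ",
                     "rate exceeds target_rate")
  max(cand[ok])
}

#' Type-I error and power summary over simulation replicates
#'
#' Pools null-gene rejections over genes x replicates for the type-I error
#' rate of each test, and computes per-causal-gene power as the rejection
#' proportion over replicates.  A gene is rejected when its p-value is
#' `<= ` the test's significance level.
#'
#' @param pvalues long data frame with columns `replicate`, `gene_id`,
#'   `test`, `p_value`.
#' @param causal_genes character vector of causal gene ids (all other
#'   genes are null).
#' @param alphas named numeric vector of per-test significance levels; a
#'   single unnamed value is recycled for all tests.
#' @return `EvaluationSummary`: list with `alphas`, `type1` (named per-test
#'   rates), `power` (data frame gene x test), `n_replicates`, `n_null_genes`
#'   and the raw rejection table.
#' @export
evaluate_tests <- function(pvalues, causal_genes, alphas) {
  stopifnot(all(c("replicate", "gene_id", "test", "p_value") %in%
                  names(pvalues)))
  tests <- unique(pvalues$test)
  if (is.null(names(alphas)) && length(alphas) == 1L)
    alphas <- stats::setNames(rep(alphas, length(tests)), tests)
  stopifnot(all(tests %in% names(alphas)))
  genes <- unique(pvalues$gene_id)
  if (!all(causal_genes %in% genes) && length(causal_genes) > 0)
    stopifnot(all(causal_genes %in% genes))
  R <- length(unique(pvalues$replicate))
  null_genes <- setdiff(genes, causal_genes)
  pvalues$reject <- pvalues$p_value <= alphas[pvalues$test]
  nul <- pvalues[pvalues$gene_id %in% null_genes, ]
  type1 <- vapply(tests, function(tt) {
    sub <- nul[nul$test == tt, ]
    if (nrow(sub) == 0) return(NA_real_)
    sum(sub$reject) / (R * length(null_genes))
  }, numeric(1))
  power <- NULL
  if (length(causal_genes) > 0) {
    cz <- pvalues[pvalues$gene_id %in% causal_genes, ]
    power <- do.call(rbind, lapply(causal_genes, function(g) {
      row <- vapply(tests, function(tt)
        mean(cz$reject[cz$gene_id == g & cz$test == tt]), numeric(1))
      data.frame(gene_id = g, t(row), check.names = FALSE)
    }))
  }
  structure(list(alphas = alphas[tests], type1 = type1, power = power,
                 n_replicates = R, n_null_genes = length(null_genes),
                 rejections = pvalues),
            class = "EvaluationSummary")
}

#' @export
print.EvaluationSummary <- function(x, ...) {
  cat(sprintf("EvaluationSummary: %d replicates, %d null genes\n",
              x$n_replicates, x$n_null_genes))
  cat("Per-test alpha / type-I error:\n")
  for (tt in names(x$type1))
    cat(sprintf("  %-8s alpha = %-8.4g type-I = %.4g\n",
                tt, x$alphas[tt], x$type1[tt]))
  if (!is.null(x$power)) {
    cat("Power (per causal gene):\n")
    print(x$power, row.names = FALSE)
  }
  invisible(x)
}
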