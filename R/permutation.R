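#' Genome-wide permutation null for forward-selection statistics
#'
#' Draws `M` uniform random permutations of the adjusted phenotype and
#' recomputes the full forward-selection statistic of every gene on each
#' permuted phenotype.  One shared permutation stream is used by all genes
#' within each permutation — required for the per-permutation maximum to be
#' a valid family-wise null.  The whole selection path is re-run on every
#' permutation, so the null carries the same selection bias as the observed
#' statistic.
#'
#' @param y_adj adjusted phenotype values.
#' @param genotypes a [genotype_matrix()].
#' @param regions list of analyzable `GeneRegion` objects.
#' @param method collapsing method name.
#' @param M number of permutations (>= 2), default 1000.
#' @param seed RNG seed; the null is bit-reproducible given the seed.
#' @param weights optional precomputed weight vector (weighted sum only).
#' @return `PermutationNull`: list with `M`, `seed`, `method`, `perm_stats`
#'   (genes x M matrix of FS statistics), `obs_stats` (observed per-gene
#'   statistics on `y_adj` itself), `mu` and `sigma` (per-gene mean and
#'   sd of the permuted statistics, sd with M-1 denominator), `degenerate`
#'   (genes whose permutation sd is zero or undefined), `adj_stats`
#'   (normalised observed statistics) and `max_stats` (per-permutation
#'   maxima of the normalised statistics over non-degenerate genes).
#' @export
build_null <- function(y_adj, genotypes, regions,
                       method = c("indicator", "sum", "weighted_sum"),
                       M = 1000, seed = 1, weights = NULL) {
  method <- match.arg(method)
  stopifnot(M >= 2)
  n <- length(y_adj)
  stopifnot(n == nrow(genotypes$counts))
  if (method == "weighted_sum" && is.null(weights))
    weights <- compute_weights(genotypes)$w
  set.seed(seed)
  Yperm <- vapply(seq_len(M), function(j) y_adj[sample.int(n)],
                  numeric(n))
  perm_stats <- fs_stat_matrix(Yperm, genotypes, regions, method, weights)
  obs_stats <- drop(fs_stat_matrix(y_adj, genotypes, regions, method, weights))
  mu <- rowMeans(perm_stats)
  sigma <- apply(perm_stats, 1, stats::sd)
  degenerate <- !is.finite(sigma) | sigma == 0 | is.na(mu)
  norm <- (perm_stats - mu) / sigma
  norm[degenerate, ] <- 0
  adj_stats <- normalize_stat(obs_stats, mu, sigma)
  if (all(degenerate)) stop("all genes have a degenerate permutation null")
  mx <- apply(norm[!degenerate, , drop = FALSE], 2, max)
  structure(list(M = M, seed = seed, method = method,
                 perm_stats = perm_stats, obs_stats = obs_stats,
                 mu = mu, sigma = sigma, degenerate = degenerate,
                 adj_stats = adj_stats, max_stats = mx),
            class = "PermutationNull")
}

#' @export
print.PermutationNull <- function(x, ...) {
  cat(sprintf("PermutationNull (%s): %d genes x %d permutations, seed %d\n",
              x$method, nrow(x$perm_stats), x$M, x$seed))
  if (any(x$degenerate))
    cat(sprintf("  %d degenerate gene(s)\n", sum(x$degenerate)))
  invisible(x)
}

#' Normalise statistics by their permutation mean and sd
#'
#' `(raw - mu) / sigma`; genes with `sigma = 0` (or an undefined null) get
#' the value 0 and are flagged via the `"degenerate"` attribute.
#'
#' @param raw raw statistic(s).
#' @param mu permutation mean(s).
#' @param sigma permutation sd(s), `>= 0`.
#' @return numeric vector of adjusted statistics with a logical
#'   `"degenerate"` attribute.
#' @export
normalize_stat <- function(raw, mu, sigma) {
  stopifnot(all(sigma >= 0 | is.na(sigma)))
  deg <- is.na(sigma) | sigma == 0 | is.na(raw) | is.na(mu)
  out <- ifelse(deg, 0, (raw - mu) / sigma)
  attr(out, "degenerate") <- deg
  out
}

#' Per-permutation maxima of normalised statistics
#'
#' `m_j` is the maximum over non-degenerate genes of the normalised
#' permuted statistics in permutation `j`; its distribution yields
#' family-wise global p-values.
#'
#' @param null a `PermutationNull`.
#' @return numeric vector of length `M`.
#' @export
max_stats <- function(null) {
  keep <- !null$degenerate
  if (!any(keep)) stop("all genes degenerate: no maximum defined")
  norm <- (null$perm_stats[keep, , drop = FALSE] - null$mu[keep]) /
    null$sigma[keep]
  apply(norm, 2, max)
}

#' Global (family-wise) p-values from the max-statistic distribution
#'
#' `p_i` is the proportion of per-permutation maxima strictly greater than
#' the gene's adjusted statistic.  `smoothing = TRUE` uses the add-one
#' estimate `(1 + count) / (1 + M)`, which avoids exact zeros.
#'
#' @param adj_stats per-gene adjusted (normalised) statistics.
#' @param m per-permutation maxima from [max_stats()].
#' @param smoothing use add-one smoothing, default `FALSE`.
#' @return numeric vector of global p-values in `[0, 1]`.
#' @export
global_pvalues <- function(adj_stats, m, smoothing = FALSE) {
  stopifnot(length(m) > 0)
  cnt <- vapply(adj_stats, function(a) sum(m > a), numeric(1))
  if (smoothing) (1 + cnt) / (1 + length(m)) else cnt / length(m)
}

#' Per-gene marginal permutation p-values
#'
#' The rank-based permutation p-value of each gene's own statistic within
#' its own permutation distribution, `(1 + #\{FS*_ij >= FS_i\}) / (M + 1)`.
#' Unlike the family-wise global p of [global_pvalues()], this is a
#' per-gene test whose null distribution is (discretely) uniform, so its
#' per-gene type-I error at level alpha is close to alpha.  Degenerate
#' genes get p = 1.
#'
#' @param null a `PermutationNull`.
#' @return numeric vector of per-gene p-values.
#' @export
perm_pvalues <- function(null) {
  M <- null$M
  p <- vapply(seq_len(nrow(null$perm_stats)), function(i) {
    if (null$degenerate[i] || is.na(null$obs_stats[i])) return(1)
    (1 + sum(null$perm_stats[i, ] >= null$obs_stats[i])) / (M + 1)
  }, numeric(1))
  stats::setNames(p, rownames(null$perm_stats))
}

#' Per-gene test report from a permutation null
#'
#' @param null a `PermutationNull`.
#' @param smoothing passed to [global_pvalues()].
#' @return data frame with one row per gene: raw statistic, adjusted
#'   statistic, global (family-wise) p, marginal permutation p and the
#'   degeneracy flag (degenerate genes are reported with p = 1).
#' @export
gene_test_report <- function(null, smoothing = FALSE) {
  gp <- global_pvalues(null$adj_stats, null$max_stats, smoothing)
  gp[null$degenerate] <- 1
  data.frame(gene_id = rownames(null$perm_stats),
             test = paste0("FS_", method_suffix(null$method)),
             statistic = unname(null$obs_stats),
             adj_statistic = as.numeric(null$adj_stats),
             global_p = unname(gp),
             perm_p = unname(perm_pvalues(null)),
             degenerate = unname(null$degenerate),
             stringsAsFactors = FALSE)
}

method_suffix <- function(method)
  c(indicator = "ind", sum = "sum", weighted_sum = "ws")[[method]]
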