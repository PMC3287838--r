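#' Simple linear regression by closed form
#'
#' Ordinary least squares of `y` on a single score vector `s` with
#' intercept.  Returns the slope `t` statistic and the model `F` statistic
#' with (1, N-2) degrees of freedom; for a single predictor `F = t^2`.
#'
#' @param y numeric response (length >= 3).
#' @param s numeric predictor with nonzero variance.
#' @return list with `slope`, `intercept`, `t_stat`, `F_stat`, `p_value`,
#'   `df_resid` and logical `perfect_fit` (TRUE when the residual mean
#'   square is zero, in which case `F_stat` and `t_stat` are `Inf`).
#' @export
simple_linreg <- function(y, s) {
  n <- length(y)
  stopifnot(length(s) == n, n >= 3)
  sx <- s - mean(s)
  sy <- y - mean(y)
  Sxx <- sum(sx * sx)
  if (Sxx <= 0) stop("degenerate predictor: zero variance")
  Sxy <- sum(sx * sy)
  Syy <- sum(sy * sy)
  slope <- Sxy / Sxx
  intercept <- mean(y) - slope * mean(s)
  df <- n - 2L
  sse <- Syy - slope * Sxy
  ssr <- slope * Sxy
  ## guard tiny negative sse from cancellation
  if (sse < .Machine$double.eps * Syy * 4) {
    return(list(slope = slope, intercept = intercept,
                t_stat = sign(slope) * Inf, F_stat = Inf,
                p_value = 0, df_resid = df, perfect_fit = TRUE))
  }
  mse <- sse / df
  F_stat <- ssr / mse
  t_stat <- slope / sqrt(mse / Sxx)
  list(slope = slope, intercept = intercept, t_stat = t_stat,
       F_stat = F_stat,
       p_value = stats::pf(F_stat, 1, df, lower.tail = FALSE),
       df_resid = df, perfect_fit = FALSE)
}

#' Choose the base common SNP of a gene
#'
#' Regresses the trait on each common variant's raw minor-allele counts and
#' returns the variant with the largest regression `F`; ties go to the
#' lowest column index.  Zero-variance columns are skipped.
#'
#' @param y adjusted phenotype values.
#' @param gene a `GeneRegion`.
#' @param genotypes a [genotype_matrix()].
#' @return list with `base` (column index), `F` and `t_stat`.
#' @export
select_base <- function(y, gene, genotypes) {
  best <- NULL
  for (j in gene$common) {
    x <- genotypes$counts[, j]
    if (stats::var(x) == 0) next
    fit <- simple_linreg(y, x)
    if (is.null(best) || fit$F_stat > best$F) {
      best <- list(base = j, F = fit$F_stat, t_stat = fit$t_stat)
    }
  }
  if (is.null(best)) stop("no usable common variant in gene ", gene$gene_id)
  best
}

#' One greedy accretion step
#'
#' For every remaining rare candidate, forms the collapsed score of
#' `current_members` plus that candidate and fits the simple regression;
#' returns the candidate with maximal `F`.  Candidates whose collapsed
#' score is constant (e.g. a saturated indicator) are skipped; if all
#' candidates are degenerate the result is `NULL`.
#'
#' @param y adjusted phenotype values.
#' @param genotypes a [genotype_matrix()].
#' @param method collapsing method name.
#' @param current_members current member set (base plus accepted rares).
#' @param remaining_rares candidate rare-variant column indices.
#' @param weights full-length weight vector (weighted sum only).
#' @return `NULL`, or a list with `rare` (the chosen index), `F_new` and
#'   `t_stat`.
#' @export
extend_one <- function(y, genotypes, method, current_members,
                       remaining_rares, weights = NULL) {
  stopifnot(length(remaining_rares) > 0)
  best <- NULL
  for (g in remaining_rares) {
    s <- collapse_score(genotypes, c(current_members, g), method, weights)
    if (stats::var(s) == 0) next
    fit <- simple_linreg(y, s)
    if (is.null(best) || fit$F_stat > best$F_new) {
      best <- list(rare = g, F_new = fit$F_stat, t_stat = fit$t_stat)
    }
  }
  best
}

#' Data-adaptive forward selection for one gene
#'
#' Step 1 seeds the member set with the base common SNP chosen by maximal
#' regression `F` on its raw counts.  Step 2 collapses each remaining rare
#' variant with the current members under the chosen collapsing function
#' and finds the best extension.  Step 3 accepts it iff it strictly
#' increases `F`, removes it from the pool, and repeats until no candidate
#' improves the fit or the pool is empty.  The FS statistic is the absolute
#' `t` of the final score's regression; by the single-predictor identity it
#' equals the square root of the last `F`.
#'
#' @param y adjusted phenotype values.
#' @param genotypes a [genotype_matrix()].
#' @param gene an analyzable `GeneRegion`.
#' @param method one of `"indicator"`, `"sum"`, `"weighted_sum"`.
#' @param weights optional precomputed full-length weight vector; computed
#'   once from all samples when needed and absent.  Weights are frozen for
#'   the whole selection (they are phenotype-free).
#' @return `ForwardSelectionResult`: list with `gene_id`, `method`,
#'   `base_variant` (column index), `selected_rares` (ordered indices),
#'   `f_trace` (F after each accepted step, first entry the base-only F),
#'   `fs_stat` (the absolute final t) and `final_score`.
#' @export
run_forward_selection <- function(y, genotypes, gene,
                                  method = c("indicator", "sum", "weighted_sum"),
                                  weights = NULL) {
  method <- match.arg(method)
  if (method == "weighted_sum" && is.null(weights))
    weights <- compute_weights(genotypes)$w
  base <- select_base(y, gene, genotypes)
  members <- base$base
  f_trace <- base$F
  t_final <- base$t_stat
  pool <- gene$rare
  while (length(pool) > 0) {
    cand <- extend_one(y, genotypes, method, members, pool, weights)
    if (is.null(cand) || !(cand$F_new > f_trace[length(f_trace)])) break
    members <- c(members, cand$rare)
    pool <- setdiff(pool, cand$rare)
    f_trace <- c(f_trace, cand$F_new)
    t_final <- cand$t_stat
  }
  final_score <- if (length(members) == 1L) genotypes$counts[, members]
                 else collapse_score(genotypes, members, method, weights)
  structure(list(gene_id = gene$gene_id, method = method,
                 base_variant = base$base,
                 selected_rares = members[-1L],
                 f_trace = f_trace,
                 fs_stat = abs(t_final),
                 final_score = final_score),
            class = "ForwardSelectionResult")
}

#' @export
print.ForwardSelectionResult <- function(x, ...) {
  cat(sprintf("Forward selection (%s) for gene %s\n", x$method, x$gene_id))
  cat(sprintf("  base variant column %d, %d rare variants selected\n",
              x$base_variant, length(x$selected_rares)))
  cat(sprintf("  FS = |t| = %.4f (final F = %.4f)\n",
              x$fs_stat, x$f_trace[length(x$f_trace)]))
  invisible(x)
}
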