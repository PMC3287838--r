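#' Select confounding covariates by single-model significance screening
#'
#' Fits one multivariate linear regression of the trait on all candidate
#' covariates and returns the names of those whose coefficient p-value is
#' below `alpha_cov`.  Confounder adjustment wants covariates that are
#' associated with the trait; `invert = TRUE` selects p > alpha_cov instead,
#' for strict reproduction of a screening rule stated the other way round.
#'
#' @param y numeric trait vector.
#' @param candidates data frame of candidate covariates (no sample_id
#'   column), rows aligned with `y`.
#' @param alpha_cov significance level, default 0.05.
#' @param invert select covariates with p > alpha_cov instead.
#' @return character vector of selected covariate names (possibly empty).
#' @export
select_covariates <- function(y, candidates, alpha_cov = 0.05, invert = FALSE) {
  if (is.null(candidates) || ncol(candidates) == 0L) return(character(0))
  stopifnot(nrow(candidates) == length(y), !anyNA(candidates))
  df <- data.frame(.y = y, candidates, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  if (anyNA(stats::coef(fit)))
    stop("collinear candidate covariates: singular design")
  pv <- summary(fit)$coefficients[, "Pr(>|t|)"]
  pv <- pv[setdiff(names(pv), "(Intercept)")]
  ## lm mangles factor/character columns into dummy names; map back
  sel_terms <- if (invert) names(pv)[pv > alpha_cov] else names(pv)[pv < alpha_cov]
  hits <- vapply(names(candidates), function(nm)
    any(startsWith(sel_terms, nm)), logical(1))
  names(candidates)[hits]
}

#' Ancestry principal components of a genotype matrix
#'
#' Columns are centred by their mean and scaled by `sqrt(p(1-p))` with the
#' posterior allele-frequency estimate `p = (1 + sum_i g_ij) / (2 + 2n)`
#' (the Eigenstrat convention), then the top-`k` eigenvectors of the sample
#' covariance across individuals are returned.  Eigenvectors are unit-norm
#' with sign fixed so each one's largest-magnitude entry is positive.
#'
#' @param genotypes a [genotype_matrix()].
#' @param k number of components, default 5; must be < n_samples and
#'   not exceed the number of polymorphic variants.
#' @return data frame with columns `PC1` .. `PCk` (one row per sample) and
#'   attribute `"eigenvalues"`.
#' @export
compute_pcs <- function(genotypes, k = 5) {
  G <- genotypes$counts
  n <- nrow(G)
  poly <- apply(G, 2, function(x) stats::var(x) > 0)
  if (!any(poly)) stop("all variants are monomorphic")
  G <- G[, poly, drop = FALSE]
  if (k >= n || k > ncol(G))
    stop("k must be smaller than the number of samples and not exceed the ",
         "number of polymorphic variants")
  p <- (1 + colSums(G)) / (2 + 2 * n)
  Z <- sweep(G, 2, colMeans(G), "-")
  Z <- sweep(Z, 2, sqrt(p * (1 - p)), "/")
  ## eigenvectors of Z Z^T / m == left singular vectors of Z
  sv <- svd(Z, nu = k, nv = 0)
  vec <- sv$u[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  out <- as.data.frame(vec)
  names(out) <- paste0("PC", seq_len(k))
  rownames(out) <- genotypes$samples
  attr(out, "eigenvalues") <- (sv$d[seq_len(k)]^2) / ncol(Z)
  out
}

#' Adjust a phenotype for covariates by taking regression residuals
#'
#' Ordinary least squares of `y` on an intercept plus the selected
#' covariates; the residuals are the adjusted phenotype.  With no
#' covariates this is mean-centring.
#'
#' @param y numeric trait vector.
#' @param covariates data frame of selected covariates aligned with `y`,
#'   or `NULL` for intercept-only adjustment.
#' @return numeric vector of residuals (sums to zero).
#' @export
adjust_phenotype <- function(y, covariates = NULL) {
  stopifnot(is.numeric(y), all(is.finite(y)))
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L)
    return(y - mean(y))
  covariates <- as.data.frame(covariates)
  stopifnot(nrow(covariates) == length(y), !anyNA(covariates))
  df <- data.frame(.y = y, covariates, check.names = FALSE)
  fit <- stats::lm(.y ~ ., data = df)
  if (anyNA(stats::coef(fit))) stop("singular covariate design")
  unname(stats::residuals(fit))
}
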