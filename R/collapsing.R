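#' Collapsing (burden) functions
#'
#' Each collapsing function maps a member set of variants to one
#' per-individual score.  Members are column indices into the genotype
#' matrix; order of members never matters.
#'
#' * **indicator** (CAST-style): 1 if the individual carries any minor
#'   allele among the members, else 0.
#' * **sum** (proportion coding): total minor-allele count across members.
#' * **weighted sum** (Madsen-Browning): counts divided by the per-variant
#'   weight `w_j = sqrt(n qhat_j (1 - qhat_j))`, so rarer alleles
#'   contribute more.
#'
#' @param genotypes a [genotype_matrix()].
#' @param members integer vector of variant column indices (non-empty).
#' @param weights for the weighted sum, a numeric vector of per-variant
#'   weights indexable by the member indices (e.g. from [compute_weights()]
#'   over all variants).
#' @return numeric vector of per-individual scores.
#' @name collapsing
NULL

#' @rdname collapsing
#' @export
collapse_indicator <- function(genotypes, members) {
  stopifnot(length(members) > 0)
  as.numeric(rowSums(genotypes$counts[, members, drop = FALSE]) > 0)
}

#' @rdname collapsing
#' @export
collapse_sum <- function(genotypes, members) {
  stopifnot(length(members) > 0)
  rowSums(genotypes$counts[, members, drop = FALSE])
}

#' Madsen-Browning allele-frequency weights
#'
#' `qhat_j = (1 + sum_i r_ij) / (2 + 2n)` over all subjects (quantitative
#' traits have no unaffected group to estimate from), and
#' `w_j = sqrt(n qhat_j (1 - qhat_j))`.  The pseudocount keeps every weight
#' strictly positive even for unobserved alleles.  Weights depend only on
#' genotypes, never on the phenotype, so they are invariant under phenotype
#' permutation.
#'
#' @param genotypes a [genotype_matrix()].
#' @param members variant column indices, default all variants.
#' @return list with numeric vectors `qhat` and `w`, named by variant id.
#' @export
compute_weights <- function(genotypes, members = seq_along(genotypes$variants)) {
  stopifnot(length(members) > 0)
  n <- nrow(genotypes$counts)
  stopifnot(n >= 2)
  m <- colSums(genotypes$counts[, members, drop = FALSE])
  qhat <- (1 + m) / (2 + 2 * n)
  w <- sqrt(n * qhat * (1 - qhat))
  ids <- genotypes$variants[members]
  list(qhat = stats::setNames(qhat, ids), w = stats::setNames(w, ids))
}

#' @rdname collapsing
#' @export
collapse_weighted_sum <- function(genotypes, members, weights) {
  stopifnot(length(members) > 0)
  w <- weights[members]
  if (anyNA(w) || length(w) != length(members))
    stop("missing weight for a member variant")
  drop(genotypes$counts[, members, drop = FALSE] %*% (1 / w))
}

#' Collapse a member set under a named method
#'
#' Dispatcher over the three collapsing functions.  The score is always
#' recomputed from scratch over the full member set, which makes composition
#' (growing the set one variant at a time) well defined and associative for
#' every method.
#'
#' @inheritParams collapsing
#' @param method one of `"indicator"`, `"sum"`, `"weighted_sum"`.
#' @return numeric per-individual score vector.
#' @export
collapse_score <- function(genotypes, members,
                           method = c("indicator", "sum", "weighted_sum"),
                           weights = NULL) {
  method <- match.arg(method)
  switch(method,
         indicator = collapse_indicator(genotypes, members),
         sum = collapse_sum(genotypes, members),
         weighted_sum = {
           if (is.null(weights))
             weights <- compute_weights(genotypes)$w
           collapse_weighted_sum(genotypes, members, weights)
         })
}
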