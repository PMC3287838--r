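#' Forward-selection statistics for many genes and phenotype vectors
#'
#' Thin wrapper around the compiled greedy-selection engine.  Each column
#' of `Y` is treated as an independent phenotype (observed trait, phenotype
#' replicate or permutation) and the full forward-selection path is re-run
#' for every gene on every column.
#'
#' @param Y numeric matrix, individuals x phenotype columns (a plain
#'   vector is treated as one column).
#' @param genotypes a [genotype_matrix()].
#' @param regions list of analyzable `GeneRegion` objects.
#' @param method collapsing method name.
#' @param weights optional full-length weight vector for the weighted sum;
#'   computed once from all samples when absent.
#' @return numeric matrix, genes x phenotype columns, of FS statistics
#'   (`|t|` of the final collapsed-score regression); `NA` for genes with
#'   no usable common variant.  Row names are gene ids.
#' @export
fs_stat_matrix <- function(Y, genotypes, regions,
                           method = c("indicator", "sum", "weighted_sum"),
                           weights = NULL) {
  method <- match.arg(method)
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  stopifnot(nrow(Y) == nrow(genotypes$counts))
  if (method == "weighted_sum" && is.null(weights))
    weights <- compute_weights(genotypes)$w
  if (is.null(weights)) weights <- rep(1, ncol(genotypes$counts))
  mcode <- match(method, c("indicator", "sum", "weighted_sum"))
  out <- cpp_fs_stat_matrix(Y, genotypes$counts,
                            lapply(regions, function(r) as.integer(r$common)),
                            lapply(regions, function(r) as.integer(r$rare)),
                            as.numeric(weights), mcode)
  rownames(out) <- vapply(regions, function(r) r$gene_id, character(1))
  out
}
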