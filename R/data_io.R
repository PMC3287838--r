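#' Construct a genotype matrix object
#'
#' A `GenotypeMatrix` stores per-individual minor-allele counts (0, 1 or 2)
#' for a set of biallelic variants, together with unique sample and variant
#' identifiers.
#'
#' @param counts numeric matrix, individuals in rows, variants in columns,
#'   entries in \{0, 1, 2\}.
#' @param samples character vector of unique sample identifiers
#'   (default: rownames of `counts`).
#' @param variants character vector of unique variant identifiers
#'   (default: colnames of `counts`).
#' @return An object of class `GenotypeMatrix`: a list with elements
#'   `samples`, `variants` and the integer `counts` matrix.
#' @export
genotype_matrix <- function(counts,
                            samples = rownames(counts),
                            variants = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(counts)))
  if (is.null(variants)) variants <- paste0("V", seq_len(ncol(counts)))
  samples <- as.character(samples)
  variants <- as.character(variants)
  if (length(samples) != nrow(counts))
    stop("length(samples) must equal nrow(counts)")
  if (length(variants) != ncol(counts))
    stop("length(variants) must equal ncol(counts)")
  if (anyDuplicated(samples)) stop("sample identifiers must be unique")
  if (anyDuplicated(variants)) stop("variant identifiers must be unique")
  if (anyNA(counts)) stop("missing genotypes are not allowed in a GenotypeMatrix")
  if (!all(counts %in% c(0, 1, 2)))
    stop("genotype counts must be 0, 1 or 2 minor alleles")
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(samples, variants)
  structure(list(samples = samples, variants = variants, counts = counts),
            class = "GenotypeMatrix")
}

#' @export
print.GenotypeMatrix <- function(x, ...) {
  cat(sprintf("GenotypeMatrix: %d samples x %d variants\n",
              length(x$samples), length(x$variants)))
  invisible(x)
}

#' @export
dim.GenotypeMatrix <- function(x) dim(x$counts)

## Flip columns whose coded-allele frequency exceeds 0.5 so that counts
## always refer to the minor allele.
recode_minor <- function(counts) {
  n <- nrow(counts)
  af <- colSums(counts) / (2 * n)
  flip <- af > 0.5
  if (any(flip)) counts[, flip] <- 2 - counts[, flip]
  counts
}

#' Read a genotype matrix from VCF or TSV
#'
#' Genotypes are recoded to minor-allele counts: any variant whose coded
#' (ALT or column) allele frequency exceeds 0.5 has its counts flipped
#' `2 - g`.  The TSV dialect is samples as rows, variants as columns, a
#' header row of variant ids and the first column holding sample ids.
#'
#' @param path path to the genotype file.
#' @param format `"tsv"` or `"vcf"`.
#' @param missing_policy `"error"` (default) refuses missing genotypes;
#'   `"mean"` imputes the per-variant mean count (rounded allele counts are
#'   not enforced after mean imputation only for internal use; imputed
#'   values are rounded to the nearest allele count so the matrix invariant
#'   holds).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("tsv", "vcf"),
                           missing_policy = c("error", "mean")) {
  format <- match.arg(format)
  missing_policy <- match.arg(missing_policy)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    samples <- as.character(tab[[1]])
    counts <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(counts) <- "double"
    variants <- colnames(counts)
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    multi <- grepl(",", vcf@fix[, "ALT"], fixed = TRUE)
    if (any(multi))
      stop("multi-allelic VCF records are not supported; split them upstream")
    gt <- vcfR::extract.gt(vcf, element = "GT")
    ploidy_bad <- grepl("^[0-9.]+$", gt) & !is.na(gt)  # haploid calls like "1"
    if (any(ploidy_bad)) stop("non-diploid genotype found in VCF")
    counts <- apply(gt, c(1, 2), function(g) {
      if (is.na(g) || g %in% c("./.", ".|.", ".")) return(NA_real_)
      al <- strsplit(g, "[/|]")[[1]]
      if (length(al) != 2 || any(!al %in% c("0", "1", ".")))
        stop("non-diploid or non-biallelic genotype: ", g)
      if (any(al == ".")) return(NA_real_)
      sum(al == "1")
    })
    counts <- t(counts)  # samples x variants
    variants <- colnames(counts)
    samples <- rownames(counts)
  }
  if (anyNA(counts)) {
    if (missing_policy == "error")
      stop("missing genotypes present and missing_policy = \"error\"")
    for (j in seq_len(ncol(counts))) {
      miss <- is.na(counts[, j])
      if (any(miss)) {
        m <- mean(counts[!miss, j])
        counts[miss, j] <- round(m)
      }
    }
  }
  counts <- recode_minor(counts)
  genotype_matrix(counts, samples = samples, variants = variants)
}

#' Minor-allele frequencies of every variant
#'
#' `maf_j = sum_i(counts_ij) / (2 n)`, folded to `min(maf, 1 - maf)` so the
#' result always lies in `[0, 0.5]`.  Frequencies are estimated jointly from
#' all samples.
#'
#' @param genotypes a [genotype_matrix()].
#' @return named numeric vector of per-variant MAFs.
#' @export
compute_maf <- function(genotypes) {
  counts <- genotypes$counts
  if (nrow(counts) == 0L || ncol(counts) == 0L) stop("empty genotype matrix")
  maf <- colSums(counts) / (2 * nrow(counts))
  maf <- pmin(maf, 1 - maf)
  stats::setNames(maf, genotypes$variants)
}

#' Classify variants as rare, common or monomorphic
#'
#' A variant is monomorphic iff its MAF is 0, rare iff `0 < maf < rare_threshold`
#' (strict, so a variant at exactly the threshold is common), common otherwise.
#'
#' @param maf numeric vector of minor-allele frequencies in `[0, 0.5]`.
#' @param rare_threshold frequency boundary, default 0.01.
#' @return character vector in \{"monomorphic", "rare", "common"\}.
#' @export
classify_variants <- function(maf, rare_threshold = 0.01) {
  stopifnot(all(maf >= 0), all(maf <= 0.5),
            rare_threshold > 0, rare_threshold < 0.5)
  out <- ifelse(maf == 0, "monomorphic",
                ifelse(maf < rare_threshold, "rare", "common"))
  stats::setNames(out, names(maf))
}

#' Build per-gene variant regions from a variant-to-gene map
#'
#' Partitions each gene's variants into common and rare member sets
#' (column indices into the genotype matrix).  Monomorphic variants are
#' excluded from both sets: zero-variance predictors are useless in the
#' downstream regressions.
#'
#' @param genotypes a [genotype_matrix()].
#' @param gene_map data frame with columns `variant_id`, `gene_id`.
#' @param rare_threshold MAF boundary between rare and common, default 0.01.
#' @return list of `GeneRegion` objects (lists with `gene_id`, `common`,
#'   `rare` integer index vectors).
#' @export
build_gene_regions <- function(genotypes, gene_map, rare_threshold = 0.01) {
  stopifnot(all(c("variant_id", "gene_id") %in% names(gene_map)))
  maf <- compute_maf(genotypes)
  cls <- classify_variants(maf, rare_threshold)
  idx <- match(gene_map$variant_id, genotypes$variants)
  keep <- !is.na(idx)
  gm <- gene_map[keep, , drop = FALSE]
  idx <- idx[keep]
  split_idx <- split(idx, gm$gene_id)
  lapply(names(split_idx), function(g) {
    j <- sort(split_idx[[g]])
    structure(list(gene_id = g,
                   common = j[cls[j] == "common"],
                   rare = j[cls[j] == "rare"]),
              class = "GeneRegion")
  })
}

#' @export
print.GeneRegion <- function(x, ...) {
  cat(sprintf("GeneRegion %s: %d common, %d rare variants\n",
              x$gene_id, length(x$common), length(x$rare)))
  invisible(x)
}

#' Filter genes for analyzability
#'
#' Keeps exactly the genes with at least `min_region_size` polymorphic
#' variants of which at least one is common.
#'
#' @param regions list of `GeneRegion` objects.
#' @param min_region_size minimum total (common + rare) variant count,
#'   default 10.
#' @return the analyzable subset of `regions`, in input order.
#' @export
filter_genes <- function(regions, min_region_size = 10) {
  keep <- vapply(regions, function(r) {
    length(r$common) + length(r$rare) >= min_region_size &&
      length(r$common) >= 1L
  }, logical(1))
  regions[keep]
}

#' Read a variant-to-gene map TSV
#' @param path TSV with columns `variant_id`, `gene_id`.
#' @return data frame.
#' @export
read_gene_map <- function(path) {
  if (!file.exists(path)) stop("gene map file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("variant_id", "gene_id") %in% names(tab)))
  tab
}

#' Read a phenotype table TSV
#'
#' First column `sample_id`, remaining columns quantitative traits.
#' @param path TSV path.
#' @return data frame with a `sample_id` column.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot("sample_id" %in% names(tab))
  tab
}

#' Read a covariate table TSV
#' @param path TSV with `sample_id` plus named covariate columns.
#' @return data frame.
#' @export
read_covariates <- function(path) read_phenotypes(path)

#' Align a table of per-sample values to the genotype sample order
#'
#' Samples are reconciled by identifier, never by position.
#'
#' @param tab data frame with a `sample_id` column.
#' @param genotypes a [genotype_matrix()].
#' @return the rows of `tab` reordered to `genotypes$samples`.
#' @export
align_samples <- function(tab, genotypes) {
  m <- match(genotypes$samples, tab$sample_id)
  if (anyNA(m)) stop("samples missing from table: ",
                     paste(utils::head(genotypes$samples[is.na(m)]), collapse = ", "))
  tab[m, , drop = FALSE]
}

#' Write a per-gene test report TSV
#'
#' One row per gene per test: gene id, test name, raw statistic, adjusted
#' (permutation-normalised) statistic, p-value, selected variant ids and the
#' length of the F trace for forward-selection tests.
#'
#' @param results data frame with columns `gene_id`, `test`, `statistic`,
#'   `adj_statistic`, `p_value`, `selected_variants`, `f_trace_length`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path) {
  cols <- c("gene_id", "test", "statistic", "adj_statistic", "p_value",
            "selected_variants", "f_trace_length")
  if (nrow(results) == 0L) {
    results <- as.data.frame(stats::setNames(rep(list(character(0)), length(cols)), cols))
  }
  stopifnot(all(cols %in% names(results)))
  utils::write.table(results[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read back a report written by [write_report()]
#' @param path report TSV path.
#' @return data frame.
#' @export
read_report <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE)

#' Write a genotype matrix in the package TSV dialect
#' @param genotypes a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  tab <- data.frame(sample_id = genotypes$samples,
                    genotypes$counts, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
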