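#' Genotype dosage container
#'
#' Holds a samples x SNPs dosage matrix (alt-allele counts 0/1/2, NA for
#' missing) together with the SNP map (id, chrom, pos, ref, alt) and the
#' per-SNP minor allele frequency recomputed from the non-missing dosages.
#'
#' @param dosage numeric matrix, samples in rows (rownames = sample ids),
#'   SNPs in columns.
#' @param snps data frame with columns id, chrom, pos, ref, alt.
#' @export
genotype_matrix <- function(dosage, snps) {
  stopifnot(ncol(dosage) == nrow(snps))
  vals <- dosage[!is.na(dosage)]
  if (length(vals) && !all(vals %in% 0:2))
    stop("dosages must be in {0, 1, 2} or NA")
  if (any(snps$pos <= 0)) stop("positions must be strictly positive")
  p <- colMeans(dosage, na.rm = TRUE) / 2
  snps$maf <- pmin(p, 1 - p)
  colnames(dosage) <- snps$id
  structure(list(sample_ids = rownames(dosage), dosage = dosage,
                 snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("Genotype matrix: %d samples x %d SNPs on chromosome(s) %s\n",
              length(x$sample_ids), nrow(x$snps),
              paste(unique(x$snps$chrom), collapse = ", ")))
  cat(sprintf("  MAF range: %.3f - %.3f; %d missing dosages\n",
              min(x$snps$maf), max(x$snps$maf), sum(is.na(x$dosage))))
  invisible(x)
}

#' Genomic interval set (BED convention)
#'
#' Intervals are stored exactly as BED encodes them: 0-based inclusive
#' start, 0-based exclusive end. A SNP at 1-based position p lies in
#' [start, end) iff start < p <= end.
#'
#' @param chrom,start,end vectors of equal length.
#' @export
interval_set <- function(chrom, start, end) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  if (any(start >= end)) stop("intervals require start < end (BED half-open)")
  structure(data.frame(chrom = as.character(chrom),
                       start = as.numeric(start), end = as.numeric(end),
                       stringsAsFactors = FALSE),
            class = c("interval_set", "data.frame"))
}

# exact chromosome matching after stripping an optional "chr" prefix
norm_chrom <- function(x) sub("^chr", "", as.character(x))

#' Align expression, covariates and genotypes on a common sample set
#'
#' Errors listing the offending ids when the expression samples are not a
#' subset of both the covariate table and the genotype matrix. Returns the
#' inputs restricted and reordered to the expression sample order.
#'
#' @param expr probes x samples matrix.
#' @param covar covariate data frame with a \code{sample_id} column.
#' @param genotypes a \code{"genotype_matrix"}.
#' @keywords internal
align_samples <- function(expr, covar, genotypes) {
  ids <- colnames(expr)
  miss_c <- setdiff(ids, covar$sample_id)
  if (length(miss_c))
    stop("samples missing from covariates: ", paste(miss_c, collapse = ", "))
  miss_g <- setdiff(ids, genotypes$sample_ids)
  if (length(miss_g))
    stop("samples missing from genotypes: ", paste(miss_g, collapse = ", "))
  list(expr = expr,
       covar = covar[match(ids, covar$sample_id), , drop = FALSE],
       dosage = genotypes$dosage[ids, , drop = FALSE])
}
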