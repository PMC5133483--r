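# File-format surface: VCF genotypes, PED pedigrees, TSV expression /
# covariates / annotation, BED intervals, the eQTL results table and the
# YAML run configuration. All readers return the package's plain
# containers; all coordinate conventions are stated on the container docs.

fc_log <- function(fmt, ...) {
  if (isTRUE(getOption("famcis.verbose", TRUE)))
    message(sprintf("[famcis %s] ", format(Sys.time(), "%H:%M:%S")),
            sprintf(fmt, ...))
}

#' Read a VCF into a genotype dosage matrix
#'
#' Parses GT fields of a VCF 4.x file into alt-allele dosages. Multi-allelic
#' records are excluded (count logged), as are SNPs whose minor allele
#' frequency — computed from non-missing genotypes — falls below
#' \code{maf_min}. Missing genotypes (\code{./.}) become NA dosages.
#'
#' @param path VCF file (plain or bgzipped).
#' @param maf_min minimum minor allele frequency retained (strict \code{<}
#'   excludes).
#' @return a \code{\link{genotype_matrix}}.
#' @export
read_vcf <- function(path, maf_min = 0.05) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!"FORMAT" %in% colnames(v@gt) ||
      !any(grepl("GT", v@gt[, "FORMAT"])))
    stop("VCF has no GT field in FORMAT")
  multi <- grepl(",", fix$ALT)
  if (any(multi))
    fc_log("excluded %d multi-allelic records", sum(multi))
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean == "1/1"] <- 2L
  bad <- !is.na(clean) & !clean %in% c("0/0", "0/1", "1/0", "1/1", "./.")
  if (any(bad)) stop("unsupported GT values: ",
                     paste(unique(clean[bad]), collapse = ", "))
  dosage <- t(dos)
  rownames(dosage) <- colnames(gt)
  ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                sprintf("snp_%s_%s", fix$CHROM, fix$POS), fix$ID)
  snps <- data.frame(id = ids, chrom = fix$CHROM,
                     pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  g <- genotype_matrix(dosage, snps)
  keep <- !is.na(g$snps$maf) & g$snps$maf >= maf_min
  fc_log("read %d samples x %d biallelic SNPs; %d below MAF %.3f excluded",
         length(g$sample_ids), nrow(g$snps), sum(!keep), maf_min)
  genotype_matrix(g$dosage[, keep, drop = FALSE],
                  g$snps[keep, setdiff(names(g$snps), "maf"), drop = FALSE])
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' Inverse of \code{\link{read_vcf}} for round-tripping synthetic data;
#' emits unphased GT-only records.
#'
#' @param genotypes a \code{"genotype_matrix"}.
#' @param path output file.
#' @export
write_vcf <- function(genotypes, path) {
  gtxt <- matrix(".", nrow(genotypes$snps), length(genotypes$sample_ids))
  d <- t(genotypes$dosage)
  gtxt[] <- c("0/0", "0/1", "1/1")[d + 1L]
  gtxt[is.na(d)] <- "./."
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", genotypes$sample_ids), collapse = "\t"))
  body <- apply(cbind(genotypes$snps$chrom, genotypes$snps$pos,
                      genotypes$snps$id, genotypes$snps$ref,
                      genotypes$snps$alt, ".", "PASS", ".", "GT", gtxt),
                1, paste, collapse = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a 6-column PED/FAM pedigree file
#'
#' Columns: family, individual, father, mother, sex (phenotype column, if
#' present, is ignored). Parents must be both known or both coded 0;
#' records with exactly one known parent are rejected.
#'
#' @param path PED/FAM file (whitespace-delimited).
#' @return a \code{"pedigree"}.
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 5) stop("PED file needs at least 5 columns")
  ped <- as_pedigree(data.frame(family_id = tab[[1]],
                                individual_id = tab[[2]],
                                father_id = tab[[3]], mother_id = tab[[4]],
                                sex = tab[[5]], stringsAsFactors = FALSE))
  fc_log("read pedigree: %d individuals, %d families", nrow(ped),
         length(unique(ped$family_id)))
  ped
}

#' @rdname read_pedigree
#' @param ped pedigree to write.
#' @export
write_pedigree <- function(ped, path) {
  out <- data.frame(ped$family_id, ped$individual_id,
                    ifelse(is.na(ped$father_id), "0", ped$father_id),
                    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
                    ped$sex, 0)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3+ interval file
#'
#' The BED convention (0-based start, half-open) is preserved verbatim in
#' the returned \code{\link{interval_set}}.
#'
#' @param path BED file.
#' @export
read_bed <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  interval_set(tab[[1]], tab[[2]], tab[[3]])
}

#' Read an expression matrix with its probe annotation
#'
#' The expression TSV has probes as rows (first column = probe id) and
#' samples as columns. The annotation TSV has columns probe_id,
#' gene_symbol, chromosome, tx_start, tx_end; it is reordered to the
#' expression probe order and must cover every probe.
#'
#' @param path expression TSV.
#' @param annotation_path probe annotation TSV.
#' @return list(expression = matrix, annotation = data.frame).
#' @export
read_expression <- function(path, annotation_path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  expr <- as.matrix(tab[, -1, drop = FALSE])
  rownames(expr) <- tab[[1]]
  if (anyDuplicated(colnames(expr))) stop("duplicated sample ids")
  if (any(apply(expr, 1, function(r) all(is.na(r)))))
    stop("expression rows entirely missing")
  ann <- utils::read.table(annotation_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  miss <- setdiff(rownames(expr), ann$probe_id)
  if (length(miss))
    stop("probes missing from annotation: ", paste(miss, collapse = ", "))
  ann <- ann[match(rownames(expr), ann$probe_id), , drop = FALSE]
  rownames(ann) <- NULL
  list(expression = expr, annotation = ann)
}

#' @rdname read_expression
#' @param expr probes x samples matrix to write.
#' @export
write_expression <- function(expr, path) {
  out <- data.frame(probe_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the covariate table (sample_id, age, sex, smoking)
#' @param path TSV file.
#' @export
read_covariates <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("sample_id", "age", "sex", "smoking")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("covariates missing columns: ",
                         paste(miss, collapse = ", "))
  tab$sample_id <- as.character(tab$sample_id)
  tab
}

#' @rdname read_covariates
#' @param covar covariate data frame.
#' @export
write_covariates <- function(covar, path) {
  utils::write.table(covar, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

eqtl_table_cols <- c("probe", "gene", "snp", "chrom", "pos", "beta_snp",
                     "raw_p", "adjusted_p", "empirical_p", "fdr_significant")

#' Read / write the eQTL results table
#'
#' Tab-delimited with columns probe, gene, snp, chrom, pos, beta_snp,
#' raw_p, adjusted_p, empirical_p, fdr_significant.
#'
#' @param records data frame of eQTL records.
#' @param path TSV file.
#' @export
write_eqtl_table <- function(records, path) {
  miss <- setdiff(eqtl_table_cols, names(records))
  if (length(miss)) stop("records missing columns: ",
                         paste(miss, collapse = ", "))
  utils::write.table(records[, eqtl_table_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_eqtl_table
#' @export
read_eqtl_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  tab$chrom <- as.character(tab$chrom)
  tab$fdr_significant <- as.logical(tab$fdr_significant)
  tab
}

#' Read a YAML run configuration
#'
#' Expected sections: inputs (vcf, ped, expression, annotation,
#' covariates), model (window_bp, maf_min, cis_anchor), permutation
#' (n_perm, bin_edges), enrichment (bed, gwas_list), output (dir), seed.
#' Missing sections fall back to the documented defaults.
#'
#' @param path YAML file.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(model = list(window_bp = 1e6, maf_min = 0.05,
                                cis_anchor = "span"),
                   permutation = list(n_perm = 3,
                                      bin_edges = c(0, .1, .2, .3, .4, .5,
                                                    .6, 1)),
                   enrichment = list(max_dist = 1000, r2_min = 0.9),
                   output = list(dir = "."),
                   seed = 1)
  for (s in names(defaults)) {
    if (is.null(cfg[[s]])) cfg[[s]] <- defaults[[s]]
    else if (is.list(defaults[[s]]))
      for (k in names(defaults[[s]]))
        if (is.null(cfg[[s]][[k]])) cfg[[s]][[k]] <- defaults[[s]][[k]]
  }
  cfg
}
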