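# eSNP enrichment in GWAS loci and regulatory intervals, LD-proxy
# expansion, and the expression-to-trait association scan.

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p by the point-probability criterion: the sum of
#' hypergeometric probabilities of all tables (with the observed margins)
#' whose probability does not exceed that of the observed table. Reports
#' the sample odds ratio (ad/bc) and the fold enrichment
#' (a/(a+b)) / (c/(c+d)).
#'
#' @param table 2x2 matrix of non-negative counts, rows = condition
#'   (e.g. eSNP yes/no), columns = annotation (yes/no).
#' @return object of class \code{"fisher_result"} with \code{table},
#'   \code{p_two_sided}, \code{odds_ratio} (sample OR), \code{fold_enrichment},
#'   \code{degenerate} flag for zero margins.
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- matrix(as.numeric(table), 2, 2)
  if (any(tab < 0) || sum(tab) == 0 || any(tab != round(tab)))
    stop("need a 2x2 table of non-negative counts")
  m <- sum(tab[, 1]); n2 <- sum(tab[, 2]); k <- sum(tab[1, ])
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (degenerate) {
    p <- 1
    or <- NA_real_
  } else {
    x <- tab[1, 1]
    support <- max(0, k - n2):min(k, m)
    dens <- stats::dhyper(support, m, n2, k)
    # relative guard against ties lost to floating point (conventional)
    p <- min(1, sum(dens[dens <= dens[support == x] * (1 + 1e-7)]))
    or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  }
  fold <- (tab[1, 1] / sum(tab[1, ])) / (tab[2, 1] / sum(tab[2, ]))
  structure(list(table = tab, p_two_sided = p, odds_ratio = or,
                 odds_ratio_type = "sample",
                 fold_enrichment = fold, degenerate = degenerate),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("Fisher's exact test (two-sided, point-probability criterion)\n")
  print(x$table)
  cat(sprintf("  p = %.4g, sample OR = %.4g, fold enrichment = %.4g%s\n",
              x$p_two_sided, x$odds_ratio, x$fold_enrichment,
              if (x$degenerate) " [degenerate margin]" else ""))
  invisible(x)
}

#' Squared dosage correlation (LD r^2) between two SNPs
#'
#' @param dosage_a,dosage_b numeric dosage vectors over the same samples.
#' @return squared Pearson correlation; \code{NA} with a warning if either
#'   vector is constant.
#' @export
ld_r2 <- function(dosage_a, dosage_b) {
  stopifnot(length(dosage_a) == length(dosage_b))
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  if (stats::sd(dosage_a[ok]) == 0 || stats::sd(dosage_b[ok]) == 0) {
    warning("constant dosage vector: r2 undefined")
    return(NA_real_)
  }
  stats::cor(dosage_a[ok], dosage_b[ok])^2
}

#' Expand a GWAS SNP list by LD proxies
#'
#' Returns the union of the seed SNPs present in the genotype matrix and
#' every SNP on the same chromosome at distance strictly less than
#' \code{max_dist} bp with r^2 strictly greater than \code{r2_min} with a
#' seed. Seeds absent from the genotypes (e.g. not directly sequenced) are
#' logged and contribute only if a typed proxy qualifies via another seed.
#'
#' @param seed_snps character SNP ids.
#' @param genotypes a \code{"genotype_matrix"}.
#' @param max_dist proxy distance bound in bp (exclusive).
#' @param r2_min r^2 bound (exclusive).
#' @return character vector of SNP ids.
#' @export
expand_by_ld <- function(seed_snps, genotypes, max_dist = 1000,
                         r2_min = 0.9) {
  sp <- genotypes$snps
  present <- intersect(seed_snps, sp$id)
  absent <- setdiff(seed_snps, sp$id)
  if (length(absent))
    fc_log("%d seed SNPs not in genotypes: %s", length(absent),
           paste(utils::head(absent, 5), collapse = ", "))
  out <- present
  for (s in present) {
    i <- match(s, sp$id)
    near <- which(norm_chrom(sp$chrom) == norm_chrom(sp$chrom[i]) &
                    abs(sp$pos - sp$pos[i]) < max_dist & sp$id != s)
    for (j in near) {
      r2 <- suppressWarnings(ld_r2(genotypes$dosage[, i],
                                   genotypes$dosage[, j]))
      if (!is.na(r2) && r2 > r2_min) out <- c(out, sp$id[j])
    }
  }
  sort(unique(out))
}

#' Flag SNPs falling in a BED interval set
#'
#' A SNP at 1-based position p is inside a BED interval [start, end) iff
#' start < p <= end; overlapping intervals flag a SNP once.
#'
#' @param snps data frame with columns chrom, pos (1-based), e.g.
#'   \code{genotypes$snps}.
#' @param intervals an \code{\link{interval_set}}.
#' @return logical vector, one flag per SNP.
#' @export
snp_in_intervals <- function(snps, intervals) {
  flags <- logical(nrow(snps))
  sc <- norm_chrom(snps$chrom)
  ic <- norm_chrom(intervals$chrom)
  for (ch in unique(sc)) {
    si <- which(sc == ch)
    ii <- which(ic == ch)
    if (!length(ii)) next
    q <- IRanges::IRanges(start = snps$pos[si] - 1L,
                          width = 1L)               # 0-based position
    s <- IRanges::IRanges(start = intervals$start[ii],
                          end = intervals$end[ii] - 1L)
    flags[si] <- IRanges::overlapsAny(q, s)
  }
  flags
}

#' Enrichment of eSNPs in an annotation
#'
#' Builds the 2x2 table of eSNP status against annotation status over the
#' tested-SNP universe and applies \code{\link{fisher_exact_2x2}}. The
#' table is oriented with annotation status in rows, so the reported fold
#' enrichment is the eSNP rate inside the annotation divided by the eSNP
#' rate outside it ("x times more eQTLs than random variants").
#'
#' @param esnp_flags logical vector over the tested SNPs.
#' @param annotation_flags logical vector over the same SNPs.
#' @export
enrichment_test <- function(esnp_flags, annotation_flags) {
  stopifnot(length(esnp_flags) == length(annotation_flags))
  tab <- matrix(c(sum(annotation_flags & esnp_flags),
                  sum(annotation_flags & !esnp_flags),
                  sum(!annotation_flags & esnp_flags),
                  sum(!annotation_flags & !esnp_flags)),
                2, 2, byrow = TRUE,
                dimnames = list(c("annotated", "not"),
                                c("eSNP", "non-eSNP")))
  fisher_exact_2x2(tab)
}

#' Association of a trait with every expression probe
#'
#' For each probe, fits the kinship mixed model of the trait on the
#' covariates (age, sex, smoking, Pc1, Pc2) plus the probe's expression,
#' and reports the Wald p-value for the expression coefficient, with
#' Bonferroni and BH summaries. Constant probes are skipped (logged).
#'
#' @param trait numeric phenotype vector named by sample id (e.g. systolic
#'   blood pressure).
#' @param expr probes x samples expression matrix.
#' @param covariates data frame with sample_id, age, sex, smoking.
#' @param kinship a \code{"kinship_matrix"}.
#' @param alpha significance level for the Bonferroni flag.
#' @param fdr FDR level for the BH flag.
#' @return data frame (probe_id, beta, se, p, bonferroni, bh).
#' @export
trait_association_scan <- function(trait, expr, covariates, kinship,
                                   alpha = 0.05, fdr = 0.05) {
  ids <- colnames(expr)
  stopifnot(!is.null(names(trait)))
  miss <- setdiff(ids, names(trait))
  if (length(miss)) stop("trait missing for samples: ",
                         paste(miss, collapse = ", "))
  trait <- trait[ids]
  covar <- covariates[match(ids, covariates$sample_id), , drop = FALSE]
  pcs <- pca_covariates(expr, 2)
  X <- cbind(`(Intercept)` = 1, age = covar$age, sex = covar$sex,
             smoking = covar$smoking, Pc1 = pcs[, 1], Pc2 = pcs[, 2])
  ke <- kinship_eigen(block_view(kinship, ids))
  ytil <- crossprod(ke$U, trait)
  Xtil <- crossprod(ke$U, X)
  out <- data.frame(probe_id = rownames(expr), beta = NA_real_,
                    se = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  skipped <- 0L
  for (i in seq_len(nrow(expr))) {
    e <- expr[i, ]
    if (stats::sd(e) == 0) { skipped <- skipped + 1L; next }
    sc <- scan_snps(ytil, Xtil, crossprod(ke$U, e), ke$d)
    out$beta[i] <- sc$beta[1]; out$se[i] <- sc$se[1]; out$p[i] <- sc$p[1]
  }
  if (skipped) fc_log("skipped %d constant probes", skipped)
  tested <- !is.na(out$p)
  out$bonferroni <- tested & out$p < alpha / sum(tested)
  out$bh <- FALSE
  out$bh[tested] <- bh_fdr(out$p[tested], fdr)
  out
}
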