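#' Simulate a multigenerational family sample
#'
#' Builds \code{n_families} independent families. Each family starts from a
#' founder couple; every generation after the first adds \code{n_children}
#' offspring to the reproducing couple, and from the third generation on the
#' eldest child of the previous sibship marries a new unrelated founder
#' ("immigrant") and becomes the next reproducing couple. Family size is
#' therefore deterministic:
#' 2 + c_1 + sum over later generations of (1 + c_g).
#'
#' @param n_families number of families.
#' @param n_children offspring per reproducing couple; scalar or vector of
#'   length \code{n_generations - 1}.
#' @param n_generations total generations (>= 2).
#' @param seed optional integer seed.
#' @return a \code{"pedigree"} with a \code{generation} column.
#' @export
simulate_pedigree <- function(n_families = 50, n_children = 4,
                              n_generations = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_generations < 2)
    stop("need at least 2 generations (a founder couple and offspring)")
  nc <- rep_len(n_children, n_generations - 1)
  if (any(nc < 1)) stop("each generation needs at least one child")
  rows <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    fam <- sprintf("F%03d", f)
    iid <- function(k) sprintf("%s_I%02d", fam, k)
    k <- 0L
    rec <- list()
    add <- function(father, mother, sex, gen) {
      k <<- k + 1L
      rec[[k]] <<- data.frame(family_id = fam, individual_id = iid(k),
                              father_id = father, mother_id = mother,
                              sex = sex, generation = gen,
                              stringsAsFactors = FALSE)
      iid(k)
    }
    dad <- add(NA, NA, 1L, 1L)
    mom <- add(NA, NA, 2L, 1L)
    for (g in seq_len(n_generations - 1)) {
      kids <- character(nc[g])
      sexes <- sample(1:2, nc[g], replace = TRUE)
      for (j in seq_len(nc[g])) kids[j] <- add(dad, mom, sexes[j], g + 1L)
      if (g < n_generations - 1) {
        heir <- kids[1]
        spouse <- add(NA, NA, if (sexes[1] == 1L) 2L else 1L, g + 1L)
        if (sexes[1] == 1L) { dad <- heir; mom <- spouse }
        else { dad <- spouse; mom <- heir }
      }
    }
    rows[[f]] <- do.call(rbind, rec)
  }
  as_pedigree(do.call(rbind, rows))
}

#' Mendelian gene drop of genotypes through a pedigree
#'
#' Founders receive two alleles i.i.d. Bernoulli(maf); every offspring
#' receives one uniformly chosen allele from each parent. Dosage is the
#' alt-allele count (0/1/2). The stored per-SNP MAF is the realized minor
#' allele frequency computed from the dropped dosages.
#'
#' @param ped a \code{"pedigree"}.
#' @param snp_spec data frame with columns \code{chrom}, \code{pos},
#'   \code{maf} (and optionally \code{id}, \code{ref}, \code{alt}).
#' @param seed optional integer seed.
#' @return a \code{"genotype_matrix"}; see \code{\link{genotype_matrix}}.
#' @export
drop_genotypes <- function(ped, snp_spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!inherits(ped, "pedigree")) ped <- as_pedigree(ped)
  if (any(snp_spec$maf < 0 | snp_spec$maf > 0.5))
    stop("maf must be in [0, 0.5]")
  n <- nrow(ped); S <- nrow(snp_spec)
  id <- ped$individual_id
  fi <- match(ped$father_id, id)
  mi <- match(ped$mother_id, id)
  a1 <- matrix(0L, n, S); a2 <- matrix(0L, n, S)
  for (i in seq_len(n)) {          # pedigree is topologically sorted
    if (is.na(fi[i])) {
      a1[i, ] <- stats::rbinom(S, 1L, snp_spec$maf)
      a2[i, ] <- stats::rbinom(S, 1L, snp_spec$maf)
    } else {
      pickf <- stats::runif(S) < 0.5
      pickm <- stats::runif(S) < 0.5
      a1[i, ] <- ifelse(pickf, a1[fi[i], ], a2[fi[i], ])
      a2[i, ] <- ifelse(pickm, a1[mi[i], ], a2[mi[i], ])
    }
  }
  dosage <- a1 + a2
  dimnames(dosage) <- list(id, NULL)
  snps <- data.frame(
    id = if (!is.null(snp_spec$id)) as.character(snp_spec$id)
         else sprintf("snp_%s_%d", snp_spec$chrom, snp_spec$pos),
    chrom = as.character(snp_spec$chrom),
    pos = as.integer(snp_spec$pos),
    ref = if (!is.null(snp_spec$ref)) snp_spec$ref else "A",
    alt = if (!is.null(snp_spec$alt)) snp_spec$alt else "G",
    stringsAsFactors = FALSE)
  colnames(dosage) <- snps$id
  genotype_matrix(dosage, snps)
}

#' Simulate an expression panel on top of a genotyped pedigree
#'
#' Each probe's expression follows the generative model the analysis
#' assumes: fixed covariate effects (age, sex, smoking), a batch term
#' (per-probe loadings on two latent sample factors, recoverable by
#' expression PCA), an optional cis-SNP effect, a polygenic component g ~
#' MVN(0, sigma_g^2 * 2 Phi) drawn per family block, and i.i.d. Gaussian
#' noise, with sigma_g^2 / (sigma_g^2 + sigma_e2) equal to the target
#' heritability (the non-SNP, non-batch variance is normalised to 1).
#'
#' For probes selected as causal, the cis-SNP effect size is calibrated so
#' the SNP explains the fraction \code{pve_snp} of that probe's total
#' variance, given the realized dosage variance of the chosen SNP.
#'
#' @param ped pedigree.
#' @param kinship matching \code{"kinship_matrix"}.
#' @param genotypes \code{"genotype_matrix"} from \code{\link{drop_genotypes}}.
#' @param n_probes number of probes.
#' @param causal_fraction fraction of probes given one causal cis SNP.
#' @param pve_snp fraction of total probe variance explained by the causal
#'   SNP.
#' @param h2 target narrow-sense heritability; scalar, vector (recycled to
#'   \code{n_probes}), or a function of n returning draws.
#' @param batch_sd standard deviation of per-probe loadings on the two
#'   latent batch factors (0 disables the batch term).
#' @param beta_covar fixed effects for (age, sex, smoking).
#' @param annotation optional probe annotation; if \code{NULL} probes are
#'   laid out over the genotype map so that consecutive blocks of SNPs fall
#'   in each probe's cis window.
#' @param window_bp cis window half-width used when choosing causal SNPs.
#' @param seed optional integer seed.
#' @return list with \code{expression} (probes x samples matrix),
#'   \code{annotation}, \code{covariates}, \code{truth} (one row per probe:
#'   causal_snp_id, beta_snp, h2_true, batch loadings).
#' @export
simulate_expression_panel <- function(ped, kinship, genotypes,
                                      n_probes = 200,
                                      causal_fraction = 0.1,
                                      pve_snp = 0.2,
                                      h2 = function(n) stats::runif(n, 0, 0.8),
                                      batch_sd = 0.5,
                                      beta_covar = c(age = 0.01, sex = 0.2,
                                                     smoking = 0.2),
                                      annotation = NULL,
                                      window_bp = 1e6,
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  ids <- ped$individual_id
  h2v <- if (is.function(h2)) h2(n_probes) else rep_len(h2, n_probes)
  if (any(h2v >= 1) || any(h2v < 0)) stop("h2 must lie in [0, 1)")

  covar <- data.frame(sample_id = ids,
                      age = stats::runif(n, 20, 80),
                      sex = stats::rbinom(n, 1, 0.5),
                      smoking = stats::rbinom(n, 1, 0.5),
                      stringsAsFactors = FALSE)
  fixed <- beta_covar["age"] * covar$age + beta_covar["sex"] * covar$sex +
    beta_covar["smoking"] * covar$smoking

  if (is.null(annotation))
    annotation <- layout_probes(genotypes, n_probes)
  if (nrow(annotation) != n_probes)
    stop("annotation must have one row per probe")

  # polygenic draws: one Cholesky of K = 2 Phi, shared across probes
  K <- additive_relationship(kinship)[ids, ids]
  L <- tryCatch(chol(K), error = function(e) chol(K + diag(1e-8, n)))
  G <- crossprod(L, matrix(stats::rnorm(n * n_probes), n, n_probes))

  f1 <- stats::rnorm(n); f2 <- stats::rnorm(n)
  load1 <- stats::rnorm(n_probes, 0, batch_sd)
  load2 <- stats::rnorm(n_probes, 0, batch_sd)

  causal <- sort(sample.int(n_probes, round(causal_fraction * n_probes)))
  truth <- data.frame(probe_id = annotation$probe_id,
                      causal_snp_id = NA_character_,
                      beta_snp = 0, h2_true = h2v,
                      load1 = load1, load2 = load2,
                      stringsAsFactors = FALSE)

  expr <- matrix(NA_real_, n_probes, n,
                 dimnames = list(annotation$probe_id, ids))
  dos <- genotypes$dosage[ids, , drop = FALSE]
  for (j in seq_len(n_probes)) {
    sg <- sqrt(h2v[j]); se <- sqrt(1 - h2v[j])
    base <- fixed + load1[j] * f1 + load2[j] * f2 +
      sg * G[, j] + se * stats::rnorm(n)
    if (j %in% causal) {
      cs <- cis_window_snps(annotation[j, ], genotypes, window_bp = window_bp)
      ok <- cs$snp_ids[apply(dos[, cs$snp_ids, drop = FALSE], 2,
                             stats::var) > 0]
      if (length(ok)) {
        snp <- if (length(ok) == 1) ok else sample(ok, 1)
        g <- dos[, snp]
        v0 <- stats::var(base)
        b <- sample(c(-1, 1), 1) *
          sqrt(pve_snp / (1 - pve_snp) * v0 / stats::var(g))
        base <- base + b * g
        truth$causal_snp_id[j] <- snp
        truth$beta_snp[j] <- b
      }
    }
    expr[j, ] <- base
  }
  list(expression = expr, annotation = annotation, covariates = covar,
       truth = truth,
       batch_factors = cbind(f1 = f1, f2 = f2))
}

# Lay probes over the genotype map: SNPs are grouped into clusters split
# at position gaps larger than 1 Mb, and the probe transcript is placed at
# each cluster's midpoint so its 1 Mb cis window covers the cluster.
# Matches the clustered maps produced by snp_layout(); falls back to
# consecutive chunking when the gap structure does not yield n_probes
# clusters.
layout_probes <- function(genotypes, n_probes) {
  sp <- genotypes$snps
  ord <- order(match(sp$chrom, unique(sp$chrom)), sp$pos)
  new_cluster <- c(TRUE, sp$chrom[ord][-1] != sp$chrom[ord][-length(ord)] |
                     diff(sp$pos[ord]) > 1e6)
  grp <- cumsum(new_cluster)
  clusters <- split(ord, grp)
  blocks <- if (length(clusters) >= n_probes)
    clusters[seq_len(n_probes)]
  else  # more probes than loci: probes share cluster windows
    clusters[rep_len(seq_along(clusters), n_probes)]
  ann <- do.call(rbind, lapply(seq_along(blocks), function(j) {
    b <- blocks[[j]]
    data.frame(probe_id = sprintf("probe_%04d", j),
               gene_symbol = sprintf("GENE%04d", j),
               chromosome = sp$chrom[b[1]],
               tx_start = as.integer(round(mean(range(sp$pos[b])))),
               tx_end = as.integer(round(mean(range(sp$pos[b])))) + 999L,
               stringsAsFactors = FALSE)
  }))
  ann
}

#' SNP map with one cluster of cis SNPs per future probe
#'
#' Generates a synthetic SNP specification: \code{n_probes} loci spaced
#' \code{spacing} bp apart (alternating across two chromosomes), each with
#' \code{snps_per_probe} SNPs scattered within \code{cluster_bp} of the
#' locus centre and MAFs drawn uniformly from \code{maf_range}. The spacing
#' default keeps neighbouring clusters more than 2 Mb apart so each probe's
#' 1 Mb cis window contains exactly its own cluster.
#'
#' @param n_probes number of loci.
#' @param snps_per_probe SNPs per cluster.
#' @param maf_range range for uniform MAF draws.
#' @param spacing distance between locus centres on a chromosome.
#' @param cluster_bp half-width of the SNP scatter around each centre.
#' @param n_chrom number of synthetic chromosomes; grows with
#'   \code{n_probes} so positions stay within 32-bit coordinates.
#' @param seed optional integer seed.
#' @export
snp_layout <- function(n_probes, snps_per_probe = 20,
                       maf_range = c(0.1, 0.5), spacing = 4e6,
                       cluster_bp = 5e5,
                       n_chrom = max(2, ceiling(n_probes / 200)),
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chrom <- rep(as.character(seq_len(n_chrom)), length.out = n_probes)
  idx_on_chrom <- stats::ave(seq_len(n_probes), chrom, FUN = seq_along)
  centre <- 2e6 + (idx_on_chrom - 1) * spacing
  out <- do.call(rbind, lapply(seq_len(n_probes), function(j) {
    pos <- sort(unique(round(centre[j] +
                               stats::runif(snps_per_probe, -cluster_bp,
                                            cluster_bp))))
    data.frame(chrom = chrom[j], pos = as.integer(pos),
               maf = stats::runif(length(pos), maf_range[1], maf_range[2]),
               stringsAsFactors = FALSE)
  }))
  out$id <- sprintf("snp_%s_%d", out$chrom, out$pos)
  out
}

#' One-call synthetic eQTL study
#'
#' Convenience wrapper chaining \code{\link{simulate_pedigree}},
#' \code{\link{kinship_from_pedigree}}, \code{\link{snp_layout}},
#' \code{\link{drop_genotypes}} and \code{\link{simulate_expression_panel}}
#' into a complete, aligned dataset ready for
#' \code{\link{run_cis_eqtl_scan}}.
#'
#' @param n_families,n_children,n_generations pedigree structure.
#' @param n_probes,snps_per_probe,maf_range genotype/probe layout.
#' @param ... passed to \code{\link{simulate_expression_panel}}.
#' @param seed integer seed driving the whole scenario.
#' @export
simulate_eqtl_study <- function(n_families = 50, n_children = 4,
                                n_generations = 2, n_probes = 200,
                                snps_per_probe = 20,
                                maf_range = c(0.1, 0.5), ...,
                                seed = 1) {
  set.seed(seed)
  ped <- simulate_pedigree(n_families, n_children, n_generations)
  kin <- kinship_from_pedigree(ped)
  spec <- snp_layout(n_probes, snps_per_probe, maf_range)
  geno <- drop_genotypes(ped, spec)
  panel <- simulate_expression_panel(ped, kin, geno, n_probes = n_probes, ...)
  c(list(pedigree = ped, kinship = kin, genotypes = geno), panel)
}
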