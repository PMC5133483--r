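# The cis scan: window construction, per-probe association across cis
# SNPs, the heritability-binned surrogate permutation null, the effective
# number-of-tests adjustment, pooled empirical p-values and BH FDR.

#' SNPs in a probe's cis window
#'
#' With \code{anchor = "span"} (default) a SNP is cis if it lies on the
#' probe's chromosome with tx_start - window <= pos <= tx_end + window,
#' boundaries inclusive. \code{anchor = "tss"} anchors the window on the
#' transcript start site only. Chromosome names match exactly after
#' stripping an optional "chr" prefix.
#'
#' @param probe one row of a probe annotation (probe_id, chromosome,
#'   tx_start, tx_end).
#' @param genotypes a \code{"genotype_matrix"}.
#' @param window_bp window half-width in bp (default 1 Mb).
#' @param anchor \code{"span"} or \code{"tss"}.
#' @return list(probe_id, snp_ids, n_g).
#' @export
cis_window_snps <- function(probe, genotypes, window_bp = 1e6,
                            anchor = c("span", "tss")) {
  anchor <- match.arg(anchor)
  stopifnot(window_bp > 0)
  lo <- probe$tx_start - window_bp
  hi <- (if (anchor == "span") probe$tx_end else probe$tx_start) + window_bp
  sp <- genotypes$snps
  sel <- norm_chrom(sp$chrom) == norm_chrom(probe$chromosome) &
    sp$pos >= lo & sp$pos <= hi
  list(probe_id = probe$probe_id, snp_ids = sp$id[sel], n_g = sum(sel))
}

#' Assign heritability bins
#'
#' Fixed edges \{0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 1\}: seven bins, closed
#' on the left, with the last bin closed on both ends.
#'
#' @param h2 vector of heritability estimates in [0, 1].
#' @param edges bin boundaries.
#' @return integer bin labels 1..7.
#' @export
assign_h2_bins <- function(h2, edges = c(0, .1, .2, .3, .4, .5, .6, 1)) {
  stopifnot(all(h2 >= edges[1]), all(h2 <= edges[length(edges)]))
  findInterval(h2, edges, rightmost.closed = TRUE)
}

#' Surrogate rank permutation
#'
#' Reorders \code{y_target} by the ranking of a surrogate transcript: the
#' sample holding the surrogate's rank-r value receives the target's
#' rank-r value. The output is a permutation of the input (same multiset)
#' whose familial correlation structure mimics the surrogate's. Ties in
#' the surrogate are broken by sample index (deterministic).
#'
#' @param y_target numeric vector to permute.
#' @param surrogate numeric vector of the same length.
#' @export
surrogate_reorder <- function(y_target, surrogate) {
  stopifnot(length(y_target) == length(surrogate))
  out <- sort(y_target)[rank(surrogate, ties.method = "first")]
  names(out) <- names(y_target)
  out
}

#' @rdname surrogate_reorder
#' @param candidates character ids of same-bin probes to draw the
#'   surrogate from; the target itself is excluded.
#' @param target_id id of the probe being permuted.
#' @return \code{surrogate_pick}: one id drawn uniformly.
#' @export
surrogate_pick <- function(candidates, target_id) {
  pool <- setdiff(candidates, target_id)
  if (!length(pool))
    stop("no surrogate candidates in the heritability bin of '", target_id,
         "'; merge bins or add probes")
  pool[sample.int(length(pool), 1)]
}

#' Effective-number-of-tests adjustment
#'
#' Multiplies a probe's minimum raw p-value by (N_g + 1) / 2 — the
#' effective number of tests for N_g correlated cis SNPs — and caps at 1.
#'
#' @param p_min raw p-value(s).
#' @param n_g number of cis SNPs tested for the gene.
#' @export
effective_test_adjust <- function(p_min, n_g) {
  stopifnot(all(p_min > 0 & p_min <= 1, na.rm = TRUE), all(n_g >= 1))
  pmin(1, p_min * (n_g + 1) / 2)
}

# Uncapped comparison statistic for the permutation machinery. Reported
# adjusted p-values are capped at 1, but capping ties every weak result at
# exactly 1 and the resulting atom breaks the uniformity of the rank-based
# empirical p; the pool comparison therefore uses the raw product.
eff_stat <- function(p_min, n_g) p_min * (n_g + 1) / 2

#' Pooled empirical p-value
#'
#' (r + 1) / (B + 1) with r the number of null statistics less than or
#' equal to the observed value; always positive, valid under the null.
#'
#' @param observed observed adjusted p-value(s).
#' @param null_pool vector of null minimum adjusted p-values.
#' @export
empirical_p <- function(observed, null_pool) {
  if (!length(null_pool)) stop("empty permutation null pool")
  vapply(observed, function(o) (sum(null_pool <= o) + 1) /
           (length(null_pool) + 1), numeric(1))
}

#' Benjamini-Hochberg significance flags
#'
#' Step-up rule at level \code{q}: reject all p-values at or below the
#' largest p_(k) with p_(k) <= k q / m. Ties share fate.
#'
#' @param p_values vector of p-values.
#' @param q FDR level.
#' @return logical flags.
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE))
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Precompute the shared state of a cis scan
#'
#' Aligns samples, mean-imputes missing dosages, appends the first two
#' expression principal components to the covariates, eigendecomposes the
#' kinship structure once, rotates phenotypes / design / dosages into the
#' eigenbasis, estimates per-probe heritability from the SNP-free model and
#' assigns heritability bins, and builds every probe's cis SNP set. The
#' returned context is what \code{\link{run_cis_eqtl_scan}} and
#' \code{\link{build_null}} operate on.
#'
#' @inheritParams run_cis_eqtl_scan
#' @return list with \code{probe_ids}, \code{expr}, \code{ke}, \code{U},
#'   \code{d}, \code{Xtil}, \code{Gtil}, \code{Ytil}, \code{h2},
#'   \code{bins}, \code{cis}, \code{bin_edges}.
#' @export
scan_context <- function(expr, annotation, genotypes, covariates, kinship,
                         window_bp = 1e6, anchor = c("span", "tss"),
                         bin_edges = c(0, .1, .2, .3, .4, .5, .6, 1)) {
  anchor <- match.arg(anchor)
  al <- align_samples(expr, covariates, genotypes)
  expr <- al$expr; covar <- al$covar; dosage <- al$dosage
  ids <- colnames(expr)

  n_missing <- sum(is.na(dosage))
  if (n_missing) {
    fc_log("mean-imputing %d missing dosages", n_missing)
    mu <- colMeans(dosage, na.rm = TRUE)
    idx <- which(is.na(dosage), arr.ind = TRUE)
    dosage[idx] <- mu[idx[, 2]]
  }

  pcs <- pca_covariates(expr, 2)
  X <- cbind(`(Intercept)` = 1, age = covar$age, sex = covar$sex,
             smoking = covar$smoking, Pc1 = pcs[, 1], Pc2 = pcs[, 2])

  ke <- kinship_eigen(block_view(kinship, ids))
  Xtil <- crossprod(ke$U, X)
  Gtil <- crossprod(ke$U, dosage)
  Ytil <- crossprod(ke$U, t(expr))

  fc_log("estimating heritability for %d probes", nrow(expr))
  h2 <- vapply(seq_len(nrow(expr)), function(i) {
    fit <- cpp_reml_fit(Ytil[, i], Xtil, ke$d, 1e-6, 1e6, 1e-8, 33L)
    if (isTRUE(fit$at_lower)) 0 else fit$sigma_g2 /
      (fit$sigma_g2 + fit$sigma_e2)
  }, numeric(1))
  bins <- assign_h2_bins(h2, bin_edges)

  cis <- lapply(seq_len(nrow(annotation)), function(i)
    cis_window_snps(annotation[i, ], genotypes, window_bp, anchor))

  list(probe_ids = annotation$probe_id, expr = expr, ke = ke,
       U = ke$U, d = ke$d, Xtil = Xtil, Gtil = Gtil, Ytil = Ytil,
       h2 = h2, bins = bins, cis = cis, bin_edges = bin_edges)
}

# Wald scan of one phenotype vector against a set of rotated SNP columns.
# ytil, Xtil, Gtil live in the eigenbasis of K; the per-SNP design is
# [Xtil, Gtil[, j]]. Returns beta, se, p per SNP (NA for degenerate SNPs).
scan_snps <- function(ytil, Xtil, Gtil, d, lambda_range = c(1e-6, 1e6),
                      tol = 1e-8) {
  m <- ncol(Gtil)
  beta <- se <- p <- rep(NA_real_, m)
  p_col <- ncol(Xtil) + 1L
  X <- cbind(Xtil, 0)
  for (j in seq_len(m)) {
    g <- Gtil[, j]
    X[, p_col] <- g
    fit <- tryCatch(
      cpp_reml_fit(ytil, X, d, lambda_range[1], lambda_range[2], tol, 33L),
      error = function(e) NULL)
    if (is.null(fit) || !isTRUE(fit$converged)) next
    b <- fit$beta[p_col]; s <- fit$se[p_col]
    if (!is.finite(s) || s <= 0) next
    beta[j] <- b; se[j] <- s
    p[j] <- stats::pchisq((b / s)^2, 1, lower.tail = FALSE)
  }
  list(beta = beta, se = se, p = p)
}

#' Permutation null distribution per heritability bin
#'
#' For every probe and permutation: draw a surrogate from the probe's
#' heritability bin, reorder the probe's expression by the surrogate's
#' ranking, rerun the cis-SNP scan on the permuted phenotype, take the
#' minimum raw p across the probe's cis SNPs, apply the effective-tests
#' factor (uncapped, so weak results keep their ordering instead of tying
#' at 1) and deposit the statistic into the probe's bin pool. A probe
#' alone in its bin draws surrogates from the nearest populated bins
#' (logged); its statistics still pool in its own bin.
#'
#' @param scan_ctx internal scan context built by
#'   \code{\link{run_cis_eqtl_scan}} (rotated phenotypes, designs, cis
#'   sets).
#' @param bins integer bin label per probe.
#' @param n_perm permutations per probe (default 3).
#' @return object of class \code{"permutation_null"}: list with
#'   \code{pools} (per-bin numeric vectors), \code{bin_edges},
#'   \code{counts}.
#' @export
build_null <- function(scan_ctx, bins, n_perm = 3) {
  probes <- scan_ctx$probe_ids
  pools <- vector("list", 7)
  draws <- data.frame(probe = character(0), surrogate = character(0),
                      stat = numeric(0))
  widened <- 0L
  for (i in seq_along(probes)) {
    cs <- scan_ctx$cis[[i]]
    if (cs$n_g == 0) next
    # same-bin candidates; a singleton bin widens to the nearest bins so
    # every probe has a surrogate (its statistics still pool in its own bin)
    width <- 0L
    repeat {
      mates <- probes[abs(bins - bins[i]) <= width]
      if (length(setdiff(mates, probes[i])) > 0 || width >= 7L) break
      width <- width + 1L
    }
    if (width > 0L) widened <- widened + 1L
    for (t in seq_len(n_perm)) {
      sid <- surrogate_pick(mates, probes[i])
      yperm <- surrogate_reorder(scan_ctx$expr[i, ],
                                 scan_ctx$expr[match(sid, probes), ])
      ytil <- crossprod(scan_ctx$U, yperm)
      sc <- scan_snps(ytil, scan_ctx$Xtil,
                      scan_ctx$Gtil[, cs$snp_ids, drop = FALSE],
                      scan_ctx$d)
      pm <- suppressWarnings(min(sc$p, na.rm = TRUE))
      if (!is.finite(pm)) next
      stat <- eff_stat(max(pm, 1e-300), cs$n_g)
      b <- bins[i]
      pools[[b]] <- c(pools[[b]], stat)
      draws <- rbind(draws, data.frame(probe = probes[i], surrogate = sid,
                                       stat = stat))
    }
  }
  if (widened > 0L)
    fc_log("surrogate bin widened to neighbours for %d singleton-bin probes",
           widened)
  ng <- vapply(scan_ctx$cis, function(z) as.numeric(z$n_g), numeric(1))
  empty <- which(lengths(pools) == 0 & tabulate(bins[ng > 0], 7) > 0)
  if (length(empty))
    stop("heritability bin(s) ", paste(empty, collapse = ", "),
         " received no permutation statistics; merge bins")
  structure(list(pools = pools,
                 bin_edges = scan_ctx$bin_edges,
                 counts = lengths(pools), draws = draws),
            class = "permutation_null")
}

#' @export
print.permutation_null <- function(x, ...) {
  cat("Permutation null pools by heritability bin\n")
  lab <- paste0("[", utils::head(x$bin_edges, -1), ",",
                utils::tail(x$bin_edges, -1), ")")
  lab[length(lab)] <- sub(")$", "]", lab[length(lab)])
  for (b in seq_along(x$pools))
    cat(sprintf("  bin %d %-10s: %5d statistics\n", b, lab[b], x$counts[b]))
  invisible(x)
}

#' Run the full family-based cis-eQTL scan
#'
#' Orchestrates the analysis: expression PCs are appended to the
#' covariates; per-transcript heritability is estimated from the SNP-free
#' mixed model and binned; every probe's cis SNPs are tested with the
#' kinship mixed model (Wald test on the dosage coefficient); the minimum
#' raw p per probe is adjusted by the effective number of tests
#' (N_g + 1) / 2 and compared with the probe's heritability-bin permutation
#' pool to give an empirical p; Benjamini-Hochberg FDR across probes flags
#' eGenes, and every cis SNP of a significant probe whose own empirical p
#' passes the BH critical threshold is reported as an eSNP.
#'
#' Missing dosages are mean-imputed per SNP at association time (counts
#' logged).
#'
#' @param expr probes x samples expression matrix.
#' @param annotation probe annotation (probe_id, gene_symbol, chromosome,
#'   tx_start, tx_end).
#' @param genotypes a \code{"genotype_matrix"}.
#' @param covariates data frame with sample_id, age, sex, smoking.
#' @param kinship a \code{"kinship_matrix"} covering the samples.
#' @param window_bp cis window half-width (default 1 Mb).
#' @param anchor cis window anchor, \code{"span"} or \code{"tss"}.
#' @param bin_edges heritability bin boundaries (seven bins).
#' @param n_perm surrogate permutations per probe (default 3).
#' @param fdr FDR level for the BH step (default 0.05).
#' @param seed integer seed controlling surrogate draws.
#' @return object of class \code{"eqtl_scan"}: \code{records} (one row per
#'   probe-SNP test), \code{probes} (probe-level results incl. h2, bin,
#'   min raw p, adjusted p, empirical p, eGene flag), \code{null}
#'   (\code{"permutation_null"}), \code{summary} (per-bin breakdown),
#'   \code{counts} (n_esnps, n_egenes, n_eqtls).
#' @export
run_cis_eqtl_scan <- function(expr, annotation, genotypes, covariates,
                              kinship, window_bp = 1e6,
                              anchor = c("span", "tss"),
                              bin_edges = c(0, .1, .2, .3, .4, .5, .6, 1),
                              n_perm = 3, fdr = 0.05, seed = 1) {
  anchor <- match.arg(anchor)
  set.seed(seed)
  scan_ctx <- scan_context(expr, annotation, genotypes, covariates, kinship,
                           window_bp, anchor, bin_edges)
  expr <- scan_ctx$expr
  ke <- scan_ctx$ke
  Xtil <- scan_ctx$Xtil; Gtil <- scan_ctx$Gtil; Ytil <- scan_ctx$Ytil
  h2 <- scan_ctx$h2
  bins <- scan_ctx$bins
  cis <- scan_ctx$cis
  ids <- colnames(expr)
  n <- length(ids)

  fc_log("observed cis scan (%d probe windows)", length(cis))
  obs <- vector("list", nrow(expr))
  for (i in seq_len(nrow(expr))) {
    cs <- cis[[i]]
    if (cs$n_g == 0) next
    sc <- scan_snps(Ytil[, i], Xtil, Gtil[, cs$snp_ids, drop = FALSE], ke$d)
    obs[[i]] <- data.frame(probe_id = annotation$probe_id[i],
                           gene_symbol = annotation$gene_symbol[i],
                           snp_id = cs$snp_ids,
                           beta_snp = sc$beta, se = sc$se, raw_p = sc$p,
                           n_g = cs$n_g, stringsAsFactors = FALSE)
  }

  fc_log("building permutation null (%d perms/probe)", n_perm)
  null <- build_null(scan_ctx, bins, n_perm)

  tested <- which(!vapply(obs, is.null, logical(1)))
  probe_tab <- data.frame(probe_id = annotation$probe_id,
                          gene_symbol = annotation$gene_symbol,
                          h2 = h2, bin = bins,
                          n_g = vapply(cis, function(z) as.numeric(z$n_g),
                                       numeric(1)),
                          min_raw_p = NA_real_, adjusted_p = NA_real_,
                          empirical_p = NA_real_, egene = FALSE,
                          stringsAsFactors = FALSE)
  for (i in tested) {
    pm <- suppressWarnings(min(obs[[i]]$raw_p, na.rm = TRUE))
    if (!is.finite(pm)) next
    probe_tab$min_raw_p[i] <- pm
    stat <- eff_stat(max(pm, 1e-300), cis[[i]]$n_g)
    probe_tab$adjusted_p[i] <- min(1, stat)
    probe_tab$empirical_p[i] <- empirical_p(stat, null$pools[[bins[i]]])
  }
  scanned <- !is.na(probe_tab$empirical_p)
  probe_tab$egene[scanned] <- bh_fdr(probe_tab$empirical_p[scanned], fdr)
  # BH critical threshold on the empirical-p scale: the largest rejected
  # empirical p (SNP-level eSNP calls reuse it)
  crit <- if (any(probe_tab$egene)) max(probe_tab$empirical_p[probe_tab$egene])
          else -Inf

  records <- do.call(rbind, obs[tested])
  if (is.null(records))
    records <- data.frame(probe_id = character(0), gene_symbol = character(0),
                          snp_id = character(0), beta_snp = numeric(0),
                          se = numeric(0), raw_p = numeric(0),
                          n_g = integer(0))
  rec_stat <- eff_stat(pmax(records$raw_p, 1e-300), records$n_g)
  records$adjusted_p <- pmin(1, rec_stat)
  rec_bin <- bins[match(records$probe_id, annotation$probe_id)]
  records$empirical_p <- NA_real_
  for (b in unique(rec_bin)) {
    sel <- rec_bin == b & !is.na(rec_stat)
    records$empirical_p[sel] <- empirical_p(rec_stat[sel], null$pools[[b]])
  }
  probe_sig <- probe_tab$egene[match(records$probe_id, probe_tab$probe_id)]
  records$esnp <- probe_sig & !is.na(records$empirical_p) &
    records$empirical_p <= crit
  sp <- genotypes$snps[match(records$snp_id, genotypes$snps$id), ]
  records$chrom <- sp$chrom; records$pos <- sp$pos

  sig <- records[records$esnp, , drop = FALSE]
  counts <- c(n_esnps = length(unique(sig$snp_id)),
              n_egenes = sum(probe_tab$egene),
              n_eqtls = nrow(sig))

  bin_lab <- seq_len(length(bin_edges) - 1)
  summary_tab <- data.frame(
    bin = bin_lab,
    h2_range = paste0(utils::head(bin_edges, -1), "-",
                      utils::tail(bin_edges, -1)),
    esnps = vapply(bin_lab, function(b)
      length(unique(sig$snp_id[rec_bin[records$esnp] == b])), numeric(1)),
    genes_tested = vapply(bin_lab, function(b)
      sum(bins == b & probe_tab$n_g > 0), numeric(1)),
    snps_per_gene_mean = vapply(bin_lab, function(b) {
      s <- probe_tab$n_g[bins == b & probe_tab$n_g > 0]
      if (length(s)) mean(s) else NA_real_
    }, numeric(1)))

  structure(list(records = records, probes = probe_tab, null = null,
                 summary = summary_tab, counts = counts,
                 params = list(window_bp = window_bp, anchor = anchor,
                               bin_edges = bin_edges, n_perm = n_perm,
                               fdr = fdr, seed = seed),
                 sample_ids = ids, n_samples = n),
            class = "eqtl_scan")
}

#' @export
print.eqtl_scan <- function(x, ...) {
  cat("Family-based cis-eQTL scan\n")
  cat(sprintf("  %d samples, %d probes (%d with cis SNPs), %d probe-SNP tests\n",
              x$n_samples, nrow(x$probes), sum(x$probes$n_g > 0),
              nrow(x$records)))
  cat(sprintf("  eGenes (BH q = %.2f): %d; eSNPs: %d; eQTL pairs: %d\n",
              x$params$fdr, x$counts["n_egenes"], x$counts["n_esnps"],
              x$counts["n_eqtls"]))
  invisible(x)
}

#' @export
summary.eqtl_scan <- function(object, ...) {
  print(object)
  cat("\nBreakdown by heritability bin:\n")
  print(object$summary, row.names = FALSE)
  invisible(object$summary)
}

#' Export an eQTL scan's record table in the standard column layout
#' @param scan an \code{"eqtl_scan"}.
#' @param path output TSV.
#' @export
write_scan <- function(scan, path) {
  r <- scan$records
  out <- data.frame(probe = r$probe_id, gene = r$gene_symbol, snp = r$snp_id,
                    chrom = r$chrom, pos = r$pos, beta_snp = r$beta_snp,
                    raw_p = r$raw_p, adjusted_p = r$adjusted_p,
                    empirical_p = r$empirical_p, fdr_significant = r$esnp,
                    stringsAsFactors = FALSE)
  write_eqtl_table(out, path)
}
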