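test_that("Fisher's exact p matches enumeration on canonical tables", {
  expect_equal(fisher_exact_2x2(matrix(1, 2, 2))$p_two_sided, 1)

  t1 <- matrix(c(2, 4, 3, 5), 2, 2)   # [[2,3],[4,5]] row-major
  expect_lt(abs(fisher_exact_2x2(t1)$p_two_sided - fisher_oracle_p(t1)),
            1e-12)
  expect_lt(abs(fisher_exact_2x2(t1)$p_two_sided -
                  stats::fisher.test(t1)$p.value), 1e-12)

  t2 <- matrix(c(10, 0, 0, 10), 2, 2)
  expect_lt(abs(fisher_exact_2x2(t2)$p_two_sided - fisher_oracle_p(t2)),
            1e-12)

  # transpose invariance
  set.seed(25)
  for (rep in 1:20) {
    tab <- matrix(rpois(4, 6), 2, 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab)$p_two_sided,
                 fisher_exact_2x2(t(tab))$p_two_sided)
  }

  # zero margin: degenerate, p = 1
  d <- fisher_exact_2x2(matrix(c(3, 5, 0, 0), 2, 2))
  expect_equal(d$p_two_sided, 1)
  expect_true(d$degenerate)
  expect_true(is.na(d$odds_ratio))
})

test_that("LD r2 is the squared dosage correlation", {
  set.seed(26)
  a <- sample(0:2, 100, TRUE)
  expect_equal(ld_r2(a, a), 1)
  b <- sample(0:2, 100, TRUE)
  expect_equal(ld_r2(a, b), ld_r2(b, a))
  expect_warning(r <- ld_r2(a, rep(1, 100)), "constant")
  expect_true(is.na(r))

  # null expectation of r2 between independent SNPs is ~ 1/(n-1)
  n <- 300
  r2 <- replicate(400, ld_r2(rbinom(n, 2, 0.3), rbinom(n, 2, 0.3)))
  expect_lt(abs(mean(r2) - 1 / (n - 1)), 2e-3)
})

test_that("LD proxy expansion honours its distance and r2 bounds", {
  set.seed(27)
  base <- rbinom(60, 2, 0.4)
  snps <- data.frame(id = c("seed1", "dup", "far", "indep"),
                     chrom = "1", pos = c(10000L, 10500L, 11500L, 10200L),
                     ref = "A", alt = "G")
  dos <- cbind(base, base, base, rbinom(60, 2, 0.4))
  rownames(dos) <- paste0("s", 1:60)
  g <- genotype_matrix(dos, snps)

  got <- expand_by_ld("seed1", g)
  expect_true("dup" %in% got)          # 500 bp away, r2 = 1
  expect_false("far" %in% got)         # 1500 bp: distance >= 1 kb bound
  expect_false("indep" %in% got)       # close but unlinked
  expect_equal(expand_by_ld("absent", g), character(0))

  # monotone in both bounds
  wide <- expand_by_ld("seed1", g, max_dist = 2000, r2_min = 0.5)
  expect_true(all(got %in% wide))
})

test_that("LD proxy expansion agrees with a brute-force all-pairs scan", {
  set.seed(28)
  st <- small_study(seed = 28, n_probes = 6, snps_per_probe = 20)
  g <- st$genotypes
  seeds <- sample(g$snps$id, 15)
  got <- expand_by_ld(seeds, g, max_dist = 5e5, r2_min = 0.2)
  present <- intersect(seeds, g$snps$id)
  brute <- present
  for (s in present) {
    i <- match(s, g$snps$id)
    for (j in seq_len(nrow(g$snps))[-i]) {
      if (g$snps$chrom[j] == g$snps$chrom[i] &&
          abs(g$snps$pos[j] - g$snps$pos[i]) < 5e5) {
        r2 <- suppressWarnings(
          stats::cor(g$dosage[, i], g$dosage[, j])^2)
        if (!is.na(r2) && r2 > 0.2) brute <- c(brute, g$snps$id[j])
      }
    }
  }
  expect_equal(got, sort(unique(brute)))
})

test_that("planted annotation enrichment is detected at the right fold", {
  set.seed(29)
  n_snps <- 4000
  esnp <- rep(FALSE, n_snps)
  annotated <- runif(n_snps) < 0.2
  # eSNPs 10x as likely inside the annotation
  esnp[annotated] <- runif(sum(annotated)) < 0.10
  esnp[!annotated] <- runif(sum(!annotated)) < 0.01
  fr <- enrichment_test(esnp, annotated)
  expect_lt(fr$p_two_sided, 0.01)
  expect_lt(abs(fr$fold_enrichment - 10) / 10, 0.35)

  # degenerate: everything annotated
  fr_all <- enrichment_test(esnp, rep(TRUE, n_snps))
  expect_equal(fr_all$p_two_sided, 1)
  expect_true(fr_all$degenerate)

  # invariance to SNP order
  p <- sample(n_snps)
  fr_p <- enrichment_test(esnp[p], annotated[p])
  expect_equal(fr_p$p_two_sided, fr$p_two_sided)
  expect_equal(fr_p$fold_enrichment, fr$fold_enrichment)
})

test_that("null enrichment p-values are roughly uniform", {
  set.seed(30)
  pvals <- replicate(200, {
    esnp <- runif(400) < 0.1
    annot <- runif(400) < 0.3
    enrichment_test(esnp, annot)$p_two_sided
  })
  # exact-test conservatism allowed; gross anti-conservatism is not
  expect_gt(mean(pvals), 0.40)
  expect_lt(mean(pvals < 0.05), 0.08)
})

test_that("the trait scan pinpoints a truly associated probe", {
  st <- small_study(seed = 31, n_families = 20, n_probes = 30,
                    snps_per_probe = 4, causal_fraction = 0, h2 = 0.4)
  ids <- colnames(st$expression)
  set.seed(32)
  trait <- 2 * st$expression[5, ] + rnorm(length(ids))
  names(trait) <- ids
  res <- trait_association_scan(trait, st$expression, st$covariates,
                                st$kinship)
  expect_equal(which.min(res$p), 5)
  expect_true(res$bonferroni[5])

  # constant probe skipped, others unaffected
  expr2 <- st$expression
  expr2[7, ] <- 3
  res2 <- trait_association_scan(trait, expr2, st$covariates, st$kinship)
  expect_true(is.na(res2$p[7]))

  # null trait: no systematic signal
  set.seed(33)
  null_trait <- rnorm(length(ids))
  names(null_trait) <- ids
  res0 <- trait_association_scan(null_trait, st$expression, st$covariates,
                                 st$kinship)
  expect_gt(suppressWarnings(ks.test(res0$p, "punif"))$p.value, 0.01)
})
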