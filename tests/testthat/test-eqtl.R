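test_that("cis windows are inclusive at 1 Mb from transcript start and end", {
  probe <- data.frame(probe_id = "p", gene_symbol = "G", chromosome = "1",
                      tx_start = 5e6, tx_end = 5.01e6)
  snps <- data.frame(id = paste0("s", 1:5), chrom = c("1", "1", "1", "1", "2"),
                     pos = c(4e6, 3999999L, 6.01e6, 6010001L, 4.5e6),
                     ref = "A", alt = "G")
  dos <- matrix(rep(0:2, 5), 3, 5)
  rownames(dos) <- c("a", "b", "c")
  g <- genotype_matrix(dos, snps)
  cs <- cis_window_snps(probe, g)
  expect_equal(cs$snp_ids, c("s1", "s3"))
  expect_equal(cs$n_g, 2)

  # tss anchor narrows the downstream edge
  cs_tss <- cis_window_snps(probe, g, anchor = "tss")
  expect_equal(cs_tss$snp_ids, "s1")
})

test_that("windowed cis lookup matches a brute-force linear scan", {
  set.seed(14)
  snps <- data.frame(id = sprintf("s%05d", 1:10000),
                     chrom = sample(c("1", "2", "chr3"), 10000, TRUE),
                     pos = sample.int(2e7, 10000), ref = "A", alt = "G")
  dos <- matrix(sample(0:2, 2 * 10000, TRUE), 2, 10000,
                dimnames = list(c("a", "b"), NULL))
  g <- genotype_matrix(dos, snps)
  for (rep in 1:10) {
    probe <- data.frame(probe_id = "p", chromosome = sample(c("1", "3"), 1),
                        tx_start = ts <- sample.int(1.8e7, 1),
                        tx_end = ts + sample.int(1e5, 1))
    w <- sample(c(1e5, 1e6), 1)
    cs <- cis_window_snps(probe, g, window_bp = w)
    brute <- snps$id[sub("^chr", "", snps$chrom) == probe$chromosome &
                       snps$pos >= probe$tx_start - w &
                       snps$pos <= probe$tx_end + w]
    expect_equal(cs$snp_ids, brute)
  }
})

test_that("doubling the window can only grow a probe's cis set", {
  set.seed(15)
  st <- small_study(seed = 15)
  for (i in seq_len(nrow(st$annotation))) {
    n1 <- cis_window_snps(st$annotation[i, ], st$genotypes, 1e6)$n_g
    n2 <- cis_window_snps(st$annotation[i, ], st$genotypes, 2e6)$n_g
    expect_gte(n2, n1)
  }
})

test_that("heritability bins use the fixed left-closed edges", {
  expect_equal(assign_h2_bins(c(0.05, 0.55, 0.95)), c(1, 6, 7))
  expect_equal(assign_h2_bins(0.1), 2)
  expect_equal(assign_h2_bins(c(0, 1)), c(1, 7))
  expect_equal(assign_h2_bins(c(0.1 - 1e-12, 0.6)), c(1, 7))
})

test_that("surrogate reordering preserves values and copies rank structure", {
  set.seed(16)
  y <- rnorm(30)
  expect_equal(surrogate_reorder(y, y), y)          # self-surrogate
  for (rep in 1:50) {
    s <- rnorm(30)
    out <- surrogate_reorder(y, s)
    expect_equal(sort(out), sort(y))                # multiset preserved
    expect_equal(cor(rank(out), rank(s)), 1)        # rank structure copied
  }
  expect_error(surrogate_pick("p1", "p1"), "surrogate")
  set.seed(1)
  expect_true(surrogate_pick(c("p1", "p2", "p3"), "p1") %in% c("p2", "p3"))
})

test_that("the effective-tests factor is (n_g + 1) / 2 with a cap", {
  expect_equal(effective_test_adjust(0.001, 1), 0.001)
  expect_equal(effective_test_adjust(0.001, 99), 0.05)
  expect_equal(effective_test_adjust(0.5, 9), 1)
  expect_error(effective_test_adjust(0.01, 0))
})

test_that("pooled empirical p-values count ties and stay in (0, 1]", {
  pool <- seq(0.01, 0.99, length.out = 99)
  expect_equal(empirical_p(0.001, pool), 0.01)
  expect_equal(empirical_p(1, pool), 1)
  set.seed(17)
  for (rep in 1:20) {
    pool <- runif(sample(5:200, 1))
    obs <- runif(1)
    expect_equal(empirical_p(obs, pool),
                 (sum(pool <= obs) + 1) / (length(pool) + 1))
  }
  # monotone in the observed statistic
  obs <- sort(runif(20))
  expect_true(all(diff(empirical_p(obs, pool)) >= 0))
  expect_error(empirical_p(0.5, numeric(0)), "empty")
})

test_that("BH flags match the step-up definition", {
  expect_equal(bh_fdr(rep(1, 10)), rep(FALSE, 10))
  expect_equal(bh_fdr(rep(0.001, 10)), rep(TRUE, 10))
  set.seed(18)
  for (rep in 1:50) {
    p <- runif(sample(3:60, 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.2), 1)
    expect_equal(bh_fdr(p, q), bh_oracle(p, q))
  }
})

test_that("permutation pools have n_probes x n_perm statistics per bin", {
  st <- small_study(seed = 19, n_probes = 10, h2 = 0.45)
  ctx <- scan_context(st$expression, st$annotation, st$genotypes,
                      st$covariates, st$kinship)
  ctx$bins <- rep(5L, 10)   # force one bin
  set.seed(20)
  null <- build_null(ctx, ctx$bins, n_perm = 3)
  expect_equal(null$counts[5], 30L, ignore_attr = TRUE)
  expect_true(all(unlist(null$pools) > 0 & is.finite(unlist(null$pools))))

  set.seed(20)
  null2 <- build_null(ctx, ctx$bins, n_perm = 3)
  expect_identical(null$pools, null2$pools)
})

test_that("planted signals sit below the permutation null", {
  st <- small_study(seed = 21, n_families = 25, n_probes = 12,
                    snps_per_probe = 8, causal_fraction = 0.5,
                    pve_snp = 0.3, h2 = 0.4)
  scan <- run_cis_eqtl_scan(st$expression, st$annotation, st$genotypes,
                            st$covariates, st$kinship, seed = 22)
  causal <- st$truth$probe_id[st$truth$beta_snp != 0]
  obs_causal <- scan$probes$adjusted_p[scan$probes$probe_id %in% causal]
  pool <- unlist(scan$null$pools)
  # observed statistics with planted effects are stochastically smaller
  expect_lt(median(obs_causal), median(pool))
  expect_lt(mean(obs_causal), 0.05)
})

test_that("scan output is internally consistent and reproducible", {
  st <- small_study(seed = 23, n_probes = 14, h2 = 0.5)
  scan <- run_cis_eqtl_scan(st$expression, st$annotation, st$genotypes,
                            st$covariates, st$kinship, seed = 24)

  expect_true(all(scan$records$adjusted_p >= scan$records$raw_p,
                  na.rm = TRUE))
  expect_equal(sum(scan$summary$genes_tested),
               sum(scan$probes$n_g > 0))
  expect_equal(sum(scan$summary$esnps), scan$counts[["n_esnps"]])
  expect_equal(sum(scan$probes$egene), scan$counts[["n_egenes"]])
  expect_true(all(scan$records$empirical_p > 0 &
                    scan$records$empirical_p <= 1, na.rm = TRUE))

  scan2 <- run_cis_eqtl_scan(st$expression, st$annotation, st$genotypes,
                             st$covariates, st$kinship, seed = 24)
  expect_identical(scan$records, scan2$records)
  expect_identical(scan$counts, scan2$counts)

  # table round trip through the writer
  path <- tempfile(fileext = ".tsv")
  write_scan(scan, path)
  tab <- read_eqtl_table(path)
  expect_equal(nrow(tab), nrow(scan$records))
  expect_output(print(scan), "cis-eQTL scan")
})
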