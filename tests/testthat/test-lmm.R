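make_fit_inputs <- function(seed = 1, n_families = 6, h2 = 0.5) {
  set.seed(seed)
  ped <- simulate_pedigree(n_families, 4, 2)
  kin <- kinship_from_pedigree(ped)
  n <- nrow(ped)
  X <- cbind(`(Intercept)` = 1, age = runif(n, 20, 80),
             sex = rbinom(n, 1, 0.5))
  K <- 2 * kin$phi
  L <- chol(K)
  y <- drop(X %*% c(1, 0.02, 0.5)) +
    sqrt(h2) * drop(crossprod(L, rnorm(n))) + sqrt(1 - h2) * rnorm(n)
  list(ped = ped, kin = kin, X = X, y = y, K = K)
}

test_that("a noiseless linear signal is recovered exactly", {
  d <- make_fit_inputs(seed = 2)
  beta <- c(2, -0.01, 0.3)
  y <- drop(d$X %*% beta)
  fit <- reml_fit(y, d$X, d$kin)
  expect_lt(max(abs(fit$beta - beta)), 1e-8)
  expect_lt(fit$sigma_e2, 1e-10)
})

test_that("with an identity covariance the GLS estimate collapses to OLS", {
  d <- make_fit_inputs(seed = 3)
  fit <- reml_fit(d$y, d$X, diag(nrow(d$X)))
  ols <- coef(lm(d$y ~ d$X - 1))
  expect_lt(max(abs(fit$beta - ols)), 1e-8)
})

test_that("rank-deficient designs are rejected with the offending column", {
  d <- make_fit_inputs(seed = 4)
  X2 <- cbind(d$X, age2 = d$X[, "age"])
  expect_error(reml_fit(d$y, X2, d$kin), "age2")
})

test_that("the REML optimum dominates random admissible variance ratios", {
  d <- make_fit_inputs(seed = 5)
  ke <- kinship_eigen(d$kin)
  fit <- reml_fit(d$y, d$X, ke)
  ytil <- crossprod(ke$U, d$y)
  Xtil <- crossprod(ke$U, d$X)
  set.seed(6)
  for (ll in runif(50, log(1e-6), log(1e6))) {
    expect_gte(fit$loglik_reml + 1e-9,
               -famcis:::cpp_reml_nll(ll, ytil, Xtil, ke$d))
  }
})

test_that("fits are invariant under consistent sample permutation", {
  d <- make_fit_inputs(seed = 7)
  fit1 <- reml_fit(d$y, d$X, kinship_eigen(d$K))
  set.seed(8)
  p <- sample(length(d$y))
  fit2 <- reml_fit(d$y[p], d$X[p, ], kinship_eigen(d$K[p, p]))
  expect_lt(abs(fit1$loglik_reml - fit2$loglik_reml), 1e-8)
  expect_lt(max(abs(fit1$beta - fit2$beta)), 1e-7)
  # variance components are identified to optimizer tolerance only
  expect_lt(abs(fit1$sigma_g2 - fit2$sigma_g2), 1e-6)
})

test_that("Wald p-values follow the chi-square reference", {
  fake <- structure(list(beta = c(snp = 0), se = c(snp = 1),
                         converged = TRUE), class = "lmmkin")
  expect_equal(wald_p(fake, "snp"), 1)
  fake$beta <- c(snp = 1.959964)
  expect_equal(wald_p(fake, "snp"), 0.05, tolerance = 1e-6)
  fake$converged <- FALSE
  expect_true(is.na(wald_p(fake, "snp")))
  expect_error(wald_p(fake, "nope"), "nope")
})

test_that("null-SNP Wald p-values are uniform", {
  set.seed(9)
  ped <- simulate_pedigree(25, 4, 2)
  kin <- kinship_from_pedigree(ped)
  ke <- kinship_eigen(kin)
  n <- nrow(ped)
  X <- cbind(`(Intercept)` = 1, age = runif(n, 20, 80))
  K <- 2 * kin$phi
  L <- chol(K)
  spec <- data.frame(chrom = "1", pos = seq_len(2000), maf = 0.3)
  g <- drop_genotypes(ped, spec)
  pvals <- numeric(2000)
  for (r in seq_len(2000)) {
    y <- sqrt(0.5) * drop(crossprod(L, rnorm(n))) + sqrt(0.5) * rnorm(n)
    fit <- reml_fit(y, cbind(X, snp = g$dosage[, r]), ke)
    pvals[r] <- wald_p(fit, "snp")
  }
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
  reject <- mean(pvals < 0.05)
  expect_gte(reject, 0.03)
  expect_lte(reject, 0.07)
})

test_that("heritability estimates are near zero when none was simulated", {
  set.seed(10)
  ped <- simulate_pedigree(20, 4, 2)
  kin <- kinship_from_pedigree(ped)
  ke <- kinship_eigen(kin)
  n <- nrow(ped)
  X <- matrix(1, n, 1)
  h2 <- vapply(seq_len(500), function(i)
    estimate_h2(rnorm(n), X, ke), numeric(1))
  expect_lte(mean(h2), 0.05)
})

test_that("clonal duplication drives heritability to the upper boundary", {
  K <- kronecker(diag(10), matrix(1, 2, 2))
  y0 <- rnorm(10)
  y <- rep(y0, each = 2)
  fit <- reml_fit(y, matrix(1, 20, 1), kinship_eigen(K))
  expect_gt(fit$h2, 0.99)
  expect_true(fit$boundary)
})

test_that("expression PCs recover a planted batch factor", {
  set.seed(11)
  batch <- rnorm(40)
  load <- rnorm(300)
  expr <- outer(load, batch) + matrix(rnorm(300 * 40, sd = 0.05), 300, 40)
  rownames(expr) <- paste0("p", 1:300)
  colnames(expr) <- paste0("s", 1:40)
  pcs <- pca_covariates(expr, 2)
  expect_gt(abs(cor(pcs[, "Pc1"], batch)), 0.99)
  expect_lt(abs(sum(pcs[, 1] * pcs[, 2])), 1e-10)

  # permuting samples permutes scores identically
  p <- sample(40)
  pcs_p <- pca_covariates(expr[, p], 2)
  expect_equal(unname(pcs_p), unname(pcs[p, ]), tolerance = 1e-6)

  expect_error(pca_covariates(matrix(1, 5, 5)), "constant")
})

test_that("the normality scan flags heavy-tailed probes only", {
  set.seed(12)
  expr <- matrix(rnorm(1000 * 100), 1000, 100,
                 dimnames = list(paste0("p", 1:1000), NULL))
  ns <- normality_scan(expr)
  expect_lte(sum(ns$flagged), 2)

  expr2 <- rbind(gauss = rnorm(267), expo = rexp(267))
  ns2 <- normality_scan(expr2)
  expect_true(ns2$flagged[ns2$probe_id == "expo"])
  expect_equal(attr(ns2, "bonferroni_threshold"), 0.025)

  one <- matrix(rnorm(50), 1, dimnames = list("p1", NULL))
  expect_equal(attr(normality_scan(one), "bonferroni_threshold"), 0.05)

  const <- rbind(flat = rep(1, 50), ok = rnorm(50))
  nsc <- normality_scan(const)
  expect_false(nsc$testable[nsc$probe_id == "flat"])
  expect_equal(attr(nsc, "bonferroni_threshold"), 0.05)
})

test_that("the formula interface and its methods are coherent", {
  d <- make_fit_inputs(seed = 13)
  df <- data.frame(y = d$y, age = d$X[, "age"], sex = d$X[, "sex"])
  rownames(df) <- d$ped$individual_id
  fit <- lmmkin(y ~ age + sex, df, d$kin)
  expect_s3_class(fit, "lmmkin")
  expect_equal(length(coef(fit)), 3)
  expect_equal(unname(fitted(fit) + residuals(fit)), unname(d$y))
  expect_equal(predict(fit, df[1:5, ]), fitted(fit)[1:5])
  expect_equal(dim(vcov(fit)), c(3, 3))
  expect_output(print(summary(fit)), "Kinship linear mixed model")
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sims), c(nrow(df), 3))
})
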