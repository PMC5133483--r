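# Independent oracles used across the suite. Each reimplements the target
# quantity by a different route than the package (dense linear algebra,
# Monte-Carlo gene dropping, explicit enumeration, brute-force scans).

options(famcis.verbose = FALSE)

# --- gene-dropping kinship oracle ------------------------------------------
# Founder alleles get unique labels; transmission is resampled per locus.
# phi_hat(i, j) = mean over loci of the IBD probability of one random
# allele from each (average of the four allele-pair indicators).
gene_drop_kinship <- function(ped, n_loci) {
  n <- nrow(ped)
  id <- ped$individual_id
  fi <- match(ped$father_id, id)
  mi <- match(ped$mother_id, id)
  a1 <- matrix(0L, n, n_loci)
  a2 <- matrix(0L, n, n_loci)
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      a1[i, ] <- 2L * i - 1L
      a2[i, ] <- 2L * i
    } else {
      pf <- stats::runif(n_loci) < 0.5
      pm <- stats::runif(n_loci) < 0.5
      a1[i, ] <- ifelse(pf, a1[fi[i], ], a2[fi[i], ])
      a2[i, ] <- ifelse(pm, a1[mi[i], ], a2[mi[i], ])
    }
  }
  phi <- matrix(0, n, n, dimnames = list(id, id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      p <- (mean(a1[i, ] == a1[j, ]) + mean(a1[i, ] == a2[j, ]) +
              mean(a2[i, ] == a1[j, ]) + mean(a2[i, ] == a2[j, ])) / 4
      phi[i, j] <- phi[j, i] <- p
    }
  }
  phi
}

# --- dense multivariate-normal REML oracle ---------------------------------
# Same restricted-likelihood convention as the package documents, but
# evaluated with dense solve()/determinant() on the unrotated matrices.
dense_reml_loglik <- function(loglam, y, X, K) {
  n <- length(y); p <- ncol(X)
  V <- exp(loglam) * K + diag(n)
  Vi <- solve(V)
  A <- t(X) %*% Vi %*% X
  beta <- solve(A, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  s2 <- drop(t(r) %*% Vi %*% r) / (n - p)
  -0.5 * ((n - p) * log(2 * pi * s2) +
            as.numeric(determinant(V, logarithm = TRUE)$modulus) +
            as.numeric(determinant(A, logarithm = TRUE)$modulus) + (n - p))
}

dense_reml_optimum <- function(y, X, K) {
  grid <- seq(log(1e-6), log(1e6), length.out = 201)
  vals <- vapply(grid, function(ll) dense_reml_loglik(ll, y, X, K),
                 numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(dense_reml_loglik, c(lo, hi), y = y, X = X, K = K,
                         maximum = TRUE, tol = 1e-10)
  lam <- exp(opt$maximum)
  Vi <- solve(lam * K + diag(length(y)))
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  list(loglik = opt$objective, lambda = lam, beta = drop(beta))
}

# --- Fisher exact enumeration oracle ---------------------------------------
# Hypergeometric probabilities from log-binomial coefficients; two-sided p
# sums all tables (fixed margins) with probability <= observed, with the
# same (1 + 1e-7) relative tie guard the convention uses.
fisher_oracle_p <- function(tab) {
  m <- sum(tab[, 1]); n2 <- sum(tab[, 2]); k <- sum(tab[1, ])
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  support <- max(0, k - n2):min(k, m)
  logp <- lchoose(m, support) + lchoose(n2, k - support) -
    lchoose(m + n2, k)
  pr <- exp(logp)
  obs <- pr[support == tab[1, 1]]
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

# --- BH step-up oracle ------------------------------------------------------
bh_oracle <- function(p, q) {
  m <- length(p)
  ps <- sort(p)
  k <- which(ps <= q * seq_len(m) / m)
  if (!length(k)) return(rep(FALSE, m))
  p <= ps[max(k)]
}

# --- fixture: printed 12-member, 3-generation pedigree ----------------------
# Two founder couples; their children marry; one uncle marries an immigrant.
# Relationships covered: parent-offspring, full sibs, grandparent-
# grandchild, avuncular, first cousins, unrelated founders.
pedigree_12 <- function() {
  as_pedigree(data.frame(
    family_id = "FAM1",
    individual_id = c("gp1", "gp2", "gp3", "gp4",
                      "dad", "unc", "mom", "aunt",
                      "c1", "c2", "c3", "k1"),
    father_id = c(NA, NA, NA, NA,
                  "gp1", "gp1", "gp3", NA,
                  "dad", "dad", "dad", "unc"),
    mother_id = c(NA, NA, NA, NA,
                  "gp2", "gp2", "gp4", NA,
                  "mom", "mom", "mom", "aunt"),
    sex = c(1, 2, 1, 2, 1, 1, 2, 2, 1, 2, 1, 2),
    stringsAsFactors = FALSE))
}

# small aligned study used by several tests
small_study <- function(seed = 101, n_families = 10, n_probes = 12,
                        snps_per_probe = 6, ...) {
  simulate_eqtl_study(n_families = n_families, n_children = 4,
                      n_generations = 2, n_probes = n_probes,
                      snps_per_probe = snps_per_probe, seed = seed, ...)
}
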