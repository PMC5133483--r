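# famcis

Family-based *cis*-eQTL mapping with kinship-aware linear mixed models.

Expression quantitative trait loci (eQTLs) are genomic loci whose genotype
associates with transcript abundance. Mapping them in **family samples**
requires accounting for the correlation between relatives: treating kin as
independent inflates the association statistics, and naive sample
permutations destroy the familial structure the null distribution must
keep. `famcis` implements the complete analysis for this setting, for
statistical geneticists working with pedigree cohorts (and for anyone who
wants a tested, self-contained reference implementation on synthetic data):

* **Mixed model.** For probe expression *Y<sub>ij</sub>* (individual *j*
  in family *i*) and dosage *SNP<sub>ij</sub>*,

  *Y<sub>ij</sub>* = β₀ + β₁ age + β₂ sex + β₃ smoking + β₄ Pc1 + β₅ Pc2 +
  β<sub>s</sub> SNP<sub>ij</sub> + α<sub>ij</sub> + ε<sub>ij</sub>,

  with random genetic effect α ~ MVN(0, σ²·2Φ) (Φ the pedigree kinship
  matrix, block diagonal by family), ε ~ N(0, σ<sub>ε</sub>²), and Pc1/Pc2
  the first two expression principal components (batch surrogates). The
  model is fitted by REML via a one-time eigendecomposition of 2Φ and a 1-D
  profile optimisation over the variance ratio (compiled with
  RcppArmadillo); β<sub>s</sub> is tested with a 1-df Wald chi-square.
* **Heritability.** h² = σ²/(σ² + σ<sub>ε</sub>²) from the SNP-free model,
  per transcript.
* **Permutation null preserving familial correlation.** Transcripts are
  split into seven h² bins ({0, .1, .2, .3, .4, .5, .6, 1}); each
  transcript is re-ordered by the ranking of a random *surrogate*
  transcript from its bin (three times), the cis scan is re-run, and the
  minimum *p* across the window — scaled by the effective-number-of-tests
  factor (N<sub>g</sub>+1)/2 — is pooled per bin. Observed statistics get
  empirical p-values (r+1)/(B+1) against their bin's pool, and
  Benjamini–Hochberg FDR across probes calls eGenes/eSNPs.
* **Enrichment.** Fisher's exact tests of eSNPs in regulatory intervals
  (BED) and GWAS SNP lists (with LD-proxy expansion: distance < 1 kb,
  r² > 0.9), plus an expression-to-trait association scan under the same
  mixed model.
* **Synthetic data.** Multigenerational pedigrees, Mendelian gene-drop
  genotypes, and expression with polygenic (kinship-structured), cis-SNP,
  covariate and latent batch components — with a ground-truth table, so the
  whole pipeline is testable end to end.

## Worked example

```r
library(famcis)

study <- simulate_eqtl_study(n_families = 30, n_children = 4, n_probes = 100,
                             snps_per_probe = 15, causal_fraction = 0.1,
                             pve_snp = 0.2, h2 = function(n) runif(n, 0.6, 0.8),
                             seed = 1)
scan <- run_cis_eqtl_scan(study$expression, study$annotation, study$genotypes,
                          study$covariates, study$kinship, seed = 2)
summary(scan)
```

```
Family-based cis-eQTL scan
  180 samples, 100 probes (100 with cis SNPs), 1500 probe-SNP tests
  eGenes (BH q = 0.05): 10; eSNPs: 10; eQTL pairs: 10

Breakdown by heritability bin:
 bin h2_range esnps genes_tested snps_per_gene_mean
   1    0-0.1     0            0                 NA
   2  0.1-0.2     0            0                 NA
   3  0.2-0.3     0            1                 15
   4  0.3-0.4     0            0                 NA
   5  0.4-0.5     0            6                 15
   6  0.5-0.6     0           14                 15
   7    0.6-1    10           79                 15
```

The ten probes simulated with a causal cis SNP (10% of 100, each SNP
explaining 20% of probe variance) are exactly the ten eGenes called at
FDR 0.05; the per-bin table mirrors the usual summary layout (eSNPs, genes
tested, mean SNPs per gene). Individual records carry the raw Wald p, the
(N_g+1)/2-adjusted p and the permutation empirical p, e.g.

```
      probe_id          snp_id  beta_snp        raw_p   adjusted_p empirical_p
    probe_0043 snp_1_169818762  1.609468 1.620208e-19 1.296167e-18 0.004201681
```

(0.0042 = 1/(B+1) for this bin's pool — the empirical-p resolution at 79
probes × 3 permutations.)

A thin command-line front end over the same functions ships in
`inst/exec/famcis.R` with subcommands `simulate`, `scan`, `enrich` and
`trait-scan`; every subcommand takes `--seed` and is bit-reproducible.

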