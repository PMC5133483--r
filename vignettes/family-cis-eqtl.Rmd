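---
title: "Family-based cis-eQTL mapping: model, permutation scheme, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Family-based cis-eQTL mapping: model, permutation scheme, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famcis)
options(famcis.verbose = FALSE)
```

## The problem

In a cohort of families, transcript abundance is correlated between
relatives through shared polygenic background, and genotypes are correlated
through Mendelian transmission. A cis-eQTL scan that ignores either
correlation produces inflated association statistics, and an ordinary
sample permutation — which breaks the phenotype's familial structure —
produces a null distribution that is too well-behaved, again inflating
significance. `famcis` addresses both with (i) a kinship linear mixed model
for every probe–SNP test and (ii) a surrogate permutation scheme that
preserves familial correlation under the null.

## The model

For individual $j$ in family $i$,

$$Y_{ij} = \beta_0 + \beta_1\,\mathrm{age}_{ij} + \beta_2\,\mathrm{sex}_{ij}
  + \beta_3\,\mathrm{smoking}_{ij} + \beta_4\,Pc1_{ij} + \beta_5\,Pc2_{ij}
  + \beta_s\,\mathrm{SNP}_{ij} + \alpha_{ij} + \varepsilon_{ij},$$

where $\alpha \sim \mathrm{MVN}(0,\ \sigma_g^2 K)$ with $K = 2\Phi$ the
expected additive relationship matrix, and
$\varepsilon \sim N(0, \sigma_\varepsilon^2)$ i.i.d. $\Phi$ is computed from
the pedigree by the standard recursion (founders unrelated,
$\phi_{ii} = \tfrac12(1+\phi_{fm})$,
$\phi_{ij} = \tfrac12(\phi_{fj}+\phi_{mj})$) and is block diagonal with one
block per family; samples are kept family-major so the blocks are literal.

**Why $2\Phi$.** The kinship coefficient itself has diagonal $1/2$ for
non-inbred individuals; scaling by 2 gives the additive relationship
(diagonal 1), under which $h^2 = \sigma_g^2/(\sigma_g^2+\sigma_\varepsilon^2)$
has its usual narrow-sense meaning. The synthetic-data generator and the
fitter use the *same* matrix, so inference is self-consistent regardless of
the scaling convention.

**Fitting.** REML (the standard choice for variance components and
heritability). $K$ is eigendecomposed once per sample set; in the rotated
basis the covariance is diagonal in the variance ratio
$\lambda = \sigma_g^2/\sigma_\varepsilon^2$, and the restricted likelihood
is profiled down to a 1-D function of $\log\lambda$, maximised on
$[10^{-6}, 10^6]$ by a 33-point grid followed by golden-section refinement
to $10^{-8}$ (the grid guards against flat or multimodal profiles; boundary
hits are reported, not errors — $\lambda$ at the lower bound is read as
$\sigma_g^2 = 0$). $\beta$ is the GLS estimate at the optimum, computed in
compiled code (RcppArmadillo). The rotation is the decisive performance
choice: every probe, SNP and permutation re-fit reuses it, so one fit costs
one small weighted least squares per objective evaluation.

**Test statistic.** The per-SNP test is a 1-df Wald chi-square on
$\beta_s$. (A likelihood-ratio variant would require refitting the null per
SNP; the Wald test is what comparable pipelines use and its null uniformity
is verified by simulation in the test suite.) Variance components are
identified to optimizer tolerance only (~$10^{-7}$), which is irrelevant at
the scale of the test statistic.

**Covariates.** Age, sex, smoking, plus the first two principal components
of the per-probe-centred expression matrix (computed on the raw centred
matrix, before any covariate adjustment; sign fixed by the largest
loading). The PCs are batch surrogates: the generator plants two latent
sample factors, and a rank-1 recovery test confirms Pc1 tracks them with
$|r| > 0.99$. Missing dosages are mean-imputed per SNP at association time;
missing covariates drop samples listwise, with logged counts.

**Normality.** A Shapiro–Wilk scan with Bonferroni flagging
(`normality_scan`) quantifies how non-Gaussian the probes are; the pipeline
does not transform expression (no inverse-normal), because significance is
taken from the permutation scheme below rather than from the Gaussian
reference alone.

## The permutation scheme

1. Estimate $h^2$ per transcript from the SNP-free model and bin into the
   seven fixed intervals $\{0, .1, .2, .3, .4, .5, .6, 1\}$ (left-closed;
   the last bin closed on both ends).
2. For each transcript, three times: draw a surrogate transcript uniformly
   from the same bin (excluding itself), reorder the transcript's values by
   the surrogate's ranking (ties broken by sample index, so runs are
   deterministic given the seed), and re-run the cis scan on the permuted
   phenotype.
3. Deposit the minimum raw $p$ times $(N_g+1)/2$ into the bin's pool;
   compare each observed statistic with its bin pool via
   $\hat p = (r+1)/(B+1)$; apply Benjamini–Hochberg across probes.

Because the permuted phenotype inherits the rank structure of a transcript
of similar heritability, the null preserves familial correlation instead of
destroying it. The $(N_g+1)/2$ factor approximates the effective number of
tests among $N_g$ partially correlated cis SNPs.

Three numerical choices deserve justification:

* **Uncapped comparison statistic.** Reported adjusted p-values are capped
  at 1 (a p-value must not exceed 1), but the statistic entering the pools
  and the empirical-p comparison is the *uncapped* product
  $p_{\min}(N_g+1)/2$. Capping ties every weak result at exactly 1; with
  $N_g \approx 20$ that atom holds ~15% of the mass, and the rank-based
  empirical p is then visibly non-uniform in well-populated bins (a gap
  below 1 plus a point mass at 1). The uncapped comparison preserves the
  ordering, and per-bin uniformity holds (KS checks in the test suite).
* **Empirical-p estimator.** $(r+1)/(B+1)$ is strictly positive and valid
  (conservative) at any pool size; its resolution is $1/(B+1)$ with
  $B = 3 \times$ bin size. This resolution is the binding constraint for
  discovery at small probe counts — see the power analysis below.
* **Singleton bins.** A probe alone in its bin has no surrogate; rather
  than abort, the surrogate is drawn from the nearest populated bins
  (logged), while the probe's statistics still pool in its own bin. Dense
  designs never hit this path.

**eGene / eSNP mapping.** Significance is assessed at the probe level (BH
on the pooled empirical p of each probe's minimum adjusted statistic); then
every cis SNP of a significant probe whose own empirical p passes the BH
critical threshold is reported as an eSNP. Both the pair count and the
distinct-SNP count are emitted, since an eSNP may target several eGenes.

## The synthetic-data generator

`simulate_eqtl_study` chains pedigree simulation (founder couples,
configurable children per generation, the eldest child marrying an
immigrant founder in deeper pedigrees), Mendelian gene drop (founder
alleles i.i.d. Bernoulli(MAF), one uniformly chosen allele per parent), and
an expression panel with exactly the structure the model assumes:
covariate effects (defaults: age 0.01/yr, sex and smoking 0.2 — small but
nonzero so adjustment is exercised), two latent batch factors with
$N(0, 0.5^2)$ loadings, a polygenic term drawn per family block from
$\mathrm{MVN}(0, h^2\,K)$, and $N(0, 1-h^2)$ noise (non-SNP, non-batch
variance normalised to 1). Causal probes get one cis SNP whose effect size
is calibrated against the realized dosage variance so the SNP explains a
target fraction (default 20%) of total probe variance. SNPs are laid out in
per-probe clusters spaced 4 Mb apart on synthetic chromosomes, so each 1 Mb
cis window contains a controllable SNP count. Covariates: age ~ U(20, 80),
sex and smoking ~ Bernoulli(0.5); MAFs ~ U(0.1, 0.5).

What the generator does *not* emulate: array amplification noise beyond
Gaussian error, inbreeding, X-linked dosage, multi-SNP or trans
architecture, LD beyond what gene drop induces within families. Passing
tests therefore validate the statistical machinery under the model's own
assumptions, not robustness to every feature of real array data.

## Validation scenarios and their sizes

The test suite and `scripts/acceptance.R` use scenarios sized to be
informative while remaining desk-scale:

* *Kinship*: a printed 12-member, 3-generation family checked against
  200,000-locus gene dropping (max |error| < 0.005), plus 8 random
  pedigrees at 50,000 loci.
* *REML*: n = 12 fixture against a dense-likelihood grid/optimize oracle
  (log-likelihood to $10^{-6}$, $\beta$ to $10^{-8}$ of dense GLS).
* *Heritability recovery*: 1000 probes, 50 families × 6, $h^2 = 0.5$;
  mean $\hat h^2$ required in [0.45, 0.55].
* *Global-null calibration*: 500 probes, $h^2 \sim U(0, 0.95)$ to span all
  seven bins, 20 cis SNPs per probe, 3 permutations; per-bin KS uniformity
  and probe-level type-I error in [0.03, 0.07] at nominal 0.05.
* *Planted-eQTL power*: 10 replicate studies of 200 probes (20 causal, SNP
  PVE 20%, n = 300), aggregate power ≥ 0.90 at BH q = 0.05 with
  false-discovery proportion ≤ 0.10.

**Why the power scenario uses $h^2 \sim U(0.6, 0.8)$.** Two reasons, both
fixed before the scenario was ever run. Scientifically, transcripts under
strong cis control are observed to have moderate-to-high heritability, so
the high-$h^2$ regime is where a cis scan earns its keep. Statistically,
the pooled empirical p cannot fall below $1/(3m_b+1)$ for a bin of $m_b$
probes, and BH at $q = 0.05$ with $K \approx 20$ expected discoveries among
$m = 200$ probes rejects only below $qK/m \approx 0.005$; discovery is
therefore only possible at all when probes concentrate in bins of
$m_b \gtrsim 70$. A narrow high-$h^2$ band achieves that with 200 probes —
note also that a causal SNP's variance loads on $\sigma_g^2$ in the
SNP-free model (dosage covariance between relatives is proportional to
$2\Phi$), pushing causal probes' $\hat h^2$ *up*, into the well-populated
top bins. At the paper-scale of ~20,000 probes every bin is dense and this
consideration disappears.

## Known limitations

* Single variance component; no dominance, no GxE, no multiple random
  effects.
* The Wald test can be slightly anti-conservative at very small n; the
  permutation layer is the guard.
* Pooled empirical p assumes probes within a bin share a null distribution;
  the wide top bin (0.6–1) is the most heterogeneous, which is visible only
  as a second-order effect once the capping artifact (above) is removed.
* Trans-eQTLs, conditional multi-SNP analysis, and probe remapping are out
  of scope.

## A short run

```{r example, eval = FALSE}
study <- simulate_eqtl_study(n_families = 30, n_children = 4,
                             n_probes = 100, snps_per_probe = 15,
                             causal_fraction = 0.1, pve_snp = 0.2,
                             h2 = function(n) runif(n, 0.6, 0.8), seed = 1)
scan <- run_cis_eqtl_scan(study$expression, study$annotation,
                          study$genotypes, study$covariates, study$kinship,
                          seed = 2)
summary(scan)
```
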