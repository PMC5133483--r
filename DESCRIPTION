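Package: famcis
Title: Family-Based cis-eQTL Mapping with Kinship-Aware Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Cis expression quantitative trait locus (eQTL) mapping for
    family samples. Associates SNP dosages with transcript expression using
    a linear mixed model with a pedigree kinship random effect fitted by
    restricted maximum likelihood (REML), estimates per-transcript
    heritability, and assesses significance with a surrogate permutation
    procedure that preserves familial correlation within heritability bins,
    an effective-number-of-tests p-value adjustment, and Benjamini-Hochberg
    false discovery rate control. Includes Fisher's-exact enrichment of
    eSNPs in GWAS loci (with linkage-disequilibrium proxy expansion) and
    regulatory intervals, an expression-to-trait association scan, and a
    pedigree-aware synthetic data generator (Mendelian gene drop, polygenic
    plus cis-SNP plus batch expression components) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    IRanges,
    vcfR,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
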