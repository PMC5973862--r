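Package: apoeld
Title: Long-Range Linkage Disequilibrium Analysis of the APOE Region
Version: 0.1.0
Authors@R: person("Fundacio", "Analyst", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying long-range linkage disequilibrium (LRLD)
    between the APOE locus and other chromosome 19 loci in case-control
    genotype data. Implements two-locus haplotype frequency estimation by
    EM from unphased genotypes with D, D', r-squared and a chi-square
    significance test; an LRLD decision rule with a MAF-matched bootstrap
    null; a sliding-window chromosome LD profile; APOE epsilon diplotype
    calling from rs429358/rs7412 and stratified case-control association;
    fixed-effect and DerSimonian-Laird random-effects meta-analysis of
    study odds ratios; Wright's inbreeding coefficient and principal
    components for structure diagnostics; PLINK bed/bim/fam input and
    output; and a synthetic genotype generator producing datasets with
    specified pairwise LD, an APOE-like two-SNP region and case-control
    labels from an additive logistic model.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
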