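---
title: "Methods: long-range LD analysis around APOE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-range LD analysis around APOE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apoeld)
```

# The problem

The APOE locus dominates the genetics of late-onset Alzheimer's disease,
and candidate loci elsewhere on chromosome 19 (CD33 among them) have
replicated inconsistently across populations. One candidate explanation is
long-range linkage disequilibrium (LRLD): allelic association between loci
separated by megabases, segregating in some populations only. Testing that
hypothesis needs a specific toolkit — two-locus LD estimation from unphased
genotypes with a significance test, a way to calibrate an observed
long-range signal against matched random markers, a chromosome-wide LD
profile, APOE-stratified association, and meta-analysis across cohorts.
`apoeld` implements that toolkit end to end, with a synthetic genotype
generator standing in for access-restricted cohort data.

# Two-locus LD from unphased genotypes

## The EM estimator

For two biallelic markers the data reduce to a 3×3 table of counted-allele
copy numbers over samples non-missing at *both* loci (pairwise-complete
cases; there is no missing-data augmentation). Every genotype cell except
the double heterozygote has a determined gamete composition. The EM
iteration holds the determined gamete counts fixed and splits the
double-heterozygote cell between the AB/ab and Ab/aB phases in ratio
`pAB*pab : pAb*paB`.

Numerical conventions:

* **Initialisation** at linkage equilibrium (products of observed allele
  frequencies). This matters for one degenerate input: a table that is
  all double heterozygotes has a likelihood ridge, and the LE start
  resolves it deterministically to D = 0. No random restarts are used, so
  results are reproducible by construction.
* **Convergence**: maximum absolute change of any haplotype frequency
  below `tol = 1e-10`, capped at `max_iter = 1000`. The observed-data
  log-likelihood is non-decreasing across iterations (tested property).
* **Degenerate inputs**: a locus monomorphic among the pairwise-complete
  samples raises a typed condition (`apoeld_monomorphic_error`); callers
  that scan many pairs skip such pairs rather than abort.

## LD coefficients and the significance test

From haplotype frequencies: `D = pAB - pA*pB`; signed
`D' = D / Dmax` with the branch of `Dmax` chosen by the sign of D; and
`r2 = D^2 / (pA(1-pA) pB(1-pB))`. The LD test statistic is
`chi2 = 2*N*r2` with 1 df — the haplotype-level allelic test, which
reproduces the printed statistics of the cohort LD tables this package
mirrors to within rounding of their printed r². D' is reported *signed*
in pairwise output (the sign is anchored to the counted-allele coding and
flips coherently if a marker's alleles are relabelled); the window scan
averages |D'| because pair-specific anchoring makes signs incomparable
across pairs.

No continuity corrections are applied to LD tables. The Haldane–Anscombe
0.5 correction appears only in the case-control allelic odds ratio, only
when a zero cell occurs, and only for the OR/CI (the chi-square p keeps
the raw table).

## Finite-sample behaviour of D'

The ML estimator of D' is consistent but carries a small upward
finite-sample inflation, because the estimated `Dmax` appears in the
denominator. Measured by simulation at n = 5000 it is about +0.002 at
D' = 0.2 and +0.005 at D' = 0.8 — far below scientific relevance but
above Monte-Carlo resolution at a few hundred replicates. The recovery
tests therefore bound the mean estimate by
`max(3 MC-SE of the mean, 0.01)`: the 0.01 floor is an a-priori ceiling
on the intrinsic O(1/n) bias (twice its measured maximum), tight enough
that any implementation defect — a sign error, a wrong `Dmax` branch, a
bad EM fixed point — still fails. `r2` gets the analogous `+1/n`
allowance.

# The LRLD procedures

* **Decision rule**: a pair is LRLD when `|D'| >= 0.2` and `p < 0.05`
  (both thresholds exposed as arguments).
* **Bootstrap null**: B markers (default 10000) drawn uniformly *with
  replacement* from the pool with MAF in [0.20, 0.40] — bracketing a
  MAF-0.30 target SNP — and not on the anchor/target chromosome;
  `|D'|`(anchor, draw) computed for each;
  `p_emp = (n_exceed + 1)/(n_used + 1)`, never exactly zero. Because
  draws are with replacement, LD is computed once per unique drawn
  marker and indexed per draw — identical output, much faster. The
  exceedance statistic is `|D'|` alone, not joint with the test p.
* **Sliding-window profile**: 1.7 Mb windows advancing by 0.1 Mb
  (1.6 Mb overlap), anchored at the chromosome's first marker (the grid
  origin is a free choice; the first marker makes the output independent
  of how coordinates were shifted). Within a window, pairs of markers
  with MAF ≥ 0.2 separated by 50–500 kb contribute; the per-window mean
  of |D'| and of r² is emitted; zero-pair windows are omitted.
* **ε2-carrier scan**: per marker, a 2×2 allelic chi-square comparing
  counted-allele frequencies between carriers and non-carriers of ε2,
  Bonferroni-corrected over markers tested. Markers in strong LD with
  the ε2-defining SNP rank first.

# APOE diplotypes and strata

ε4 is the rs429358 minor (T) allele, ε2 the rs7412 minor (T) allele, ε3
neither. The caller assumes the T–T haplotype (ε1) is absent: it is
vanishingly rare, and the two SNPs show signed D' = −1 in every cohort
this package models — an empty haplotype cell. Under that assumption the
unphased genotype pair determines the diplotype; the three combinations
that would require a T–T haplotype return UNKNOWN rather than a forced
call, as does any missing input. Stratification maps E2E2/E2E3 to ε2
carriers, E3E4/E4E4 to ε4 carriers, E3E3 to its own stratum, and always
excludes E2E4 (it carries both alleles). A separate carrier-flag helper
exposes the presence/absence convention (E2E4 counts as both an ε2 and an
ε4 carrier) used by the marker scan and covariate adjustment, since both
conventions are legitimate and published analyses are ambiguous about
which one stratified tables use.

# Association models

The allelic test is the exact cross-ratio OR with Wald 95% CI on the log
scale (`z = 1.959964` throughout the package, matching the CI arithmetic
of the meta-analysis module) and a Pearson chi-square p. The logistic
model is maximum likelihood via IRLS (`stats::glm`, epsilon 1e-8, max 50
iterations) on the additive 0/1/2 genotype, with optional sex, centered
age, and ε4-carrier covariates; fits with any |beta| > 15 are rejected as
separated rather than reported.

One estimand subtlety is worth stating because the synthetic world makes
it visible: with both APOE alleles generated on one haplotype block
(D' = −1), the *marginal* logistic estimate for one APOE SNP does not
equal the generating conditional per-allele effect — the other allele is
a correlated strong risk factor, and omitting it shifts the estimate
(measured at n = 80000: marginal ε4 log-OR 1.431 vs generating 1.386;
marginal ε2 −0.758 vs generating −0.511). In the subpopulation carrying
zero copies of the other allele the additive model is exactly specified
and recovery is unbiased; the end-to-end recovery test estimates each
allele effect there, mirroring the APOE-stratified practice of the
analyses this package supports.

# Meta-analysis

Per-study effects enter as OR with 95% CI;
`se = (ln hi − ln lo) / (2 × 1.959964)`. Fixed-effect pooling is inverse
variance; Cochran's Q, its chi-square(k−1) p, and
`I² = max(0, (Q−(k−1))/Q)·100` quantify heterogeneity; DerSimonian–Laird
estimates `tau²` by moments (floored at 0) and re-pools with weights
`1/(se² + tau²)`. Model selection is automatic: random effects iff
I² > 50% *and* Q's p < 0.05, else fixed. No Knapp–Hartung adjustment.
The shipped per-study CD33 effect table reproduces its published pooled
rows to printed precision in three of four strata; the ε2-carrier pooled
row is not reproducible from its five printed per-study CIs under either
fixed or DL pooling (fixed gives ≈0.82 against a printed 0.850), so that
one cell is shipped as input but never asserted.

# Structure diagnostics

Wright's F is `1 − Ho/He` per marker with plug-in `He = 2p(1−p)` (no
small-sample correction — the defining formula is stated without one),
averaged over markers passing MAF > 0.2 and HWE p > 0.001 after removing
samples with call rate < 0.99. HWE uses the exact conditional test,
two-sided by probability mass — stable at extreme MAF, where the
chi-square approximation is not. Principal components run on an
LD-pruned set (greedy within sliding marker windows, dropping the later
marker of any pair with r² above 0.3), with missing genotypes imputed to
the marker mean and markers scaled by `sqrt(2p(1−p))`; component signs
are fixed by forcing the largest-magnitude loading positive, so results
are fully deterministic.

# The synthetic world

The generator draws two haplotypes per individual within each configured
block — marker pairs at an exact target signed D', and an APOE block
with haplotype frequencies ε4 = 0.14, ε2 = 0.07, ε1 = 0 (typical
European-ancestry values; the ε1 zero is the structural assumption the
caller relies on) — and independent Hardy–Weinberg genotypes elsewhere.
Background MAFs default to Uniform(0.05, 0.5) so the bootstrap pool
(0.20–0.40) is well populated. Disease status is additive logistic:
baseline prevalence 0.15, per-ε4-allele OR 4.0 (the canonical APOE risk
magnitude), per-ε2-allele OR 0.6 (protective), optional per-allele OR
for a named SNP; case-control targets are met by rejection sampling
capped at 1000×(n_cases+n_controls) draws. Everything is a deterministic
function of the seed.

What the generator deliberately does *not* emulate: recombination maps
and LD decay with distance (blocks are exact and everything else is
independent), allele-frequency drift between cohorts, genotyping error,
and ascertainment beyond simple case-control sampling. A green test
therefore establishes that the estimators recover the parameters of this
stated world — not that real cohorts satisfy its assumptions.

# Known limitations

* PLINK v1 bed/bim/fam is the only genotype format (no VCF/BGEN/dosage
  path); positions are taken as given, with the assembly label carried
  as metadata only.
* The exceedance rule of the bootstrap null (|D'| alone, with
  replacement, off-chromosome pool) is one reasonable formalisation of
  an under-specified published procedure; published empirical
  probabilities are therefore not comparison targets.
* The window grid origin (first marker) is a convention; profiles from
  differently-anchored implementations differ in window labels, not
  substance.
* D' signs in pairwise reports depend on counted-allele anchoring and
  may flip coherently against other tools' output.
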