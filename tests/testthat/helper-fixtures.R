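# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

# dataset from a samples x markers genotype matrix
make_dataset <- function(calls, bp = NULL, chrom = "1", phenotype = NULL,
                         ids = NULL) {
  calls <- as.matrix(calls)
  m <- ncol(calls); n <- nrow(calls)
  if (is.null(bp)) bp <- seq_len(m) * 1000L
  if (is.null(ids))
    ids <- if (m == 0) character(0) else paste0("snp", seq_len(m))
  markers <- data.frame(id = ids, chrom = rep_len(chrom, max(m, 0)),
                        bp = bp, allele_counted = rep("A", m),
                        allele_other = rep("G", m),
                        stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = paste0("s", seq_len(n)),
                        phenotype = if (is.null(phenotype))
                          NA_character_ else phenotype,
                        sex = NA_character_, age = NA_real_,
                        stringsAsFactors = FALSE)
  genotype_dataset(markers, samples, calls)
}

# random dataset of independent HWE markers
random_dataset <- function(n, m, maf = NULL, seed = 1, chrom = "1",
                           missing_rate = 0) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(m, 0.1, 0.5)
  calls <- sapply(maf, function(p) rbinom(n, 1, p) + rbinom(n, 1, p))
  if (missing_rate > 0)
    calls[runif(length(calls)) < missing_rate] <- NA_integer_
  make_dataset(calls, chrom = chrom)
}

# draw a genotype table of n individuals from true haplotype frequencies
sample_pair_genotypes <- function(n, hf) {
  p <- c(hf$pAB, hf$pAb, hf$paB, hf$pab)
  h1 <- sample.int(4, n, replace = TRUE, prob = p)
  h2 <- sample.int(4, n, replace = TRUE, prob = p)
  hA <- c(1L, 1L, 0L, 0L); hB <- c(1L, 0L, 1L, 0L)
  cbind(g1 = hA[h1] + hA[h2], g2 = hB[h1] + hB[h2])
}

table_from_pair <- function(g) {
  counts <- matrix(tabulate(3L * g[, 1] + g[, 2] + 1L, nbins = 9L),
                   nrow = 3, byrow = TRUE)
  list(counts = counts, n_samples = nrow(g))
}

# path of the shipped per-study CD33 effect table
cd33_effects_path <- function()
  system.file("extdata", "cd33_study_effects.tsv", package = "apoeld",
              mustWork = TRUE)
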