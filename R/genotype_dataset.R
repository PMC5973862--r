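#' Construct a genotype dataset
#'
#' The central container of the package: a samples-by-markers matrix of
#' unphased minor-allele counts plus marker and sample metadata. Genotype
#' values count copies of each marker's `allele_counted` (the PLINK A1
#' allele, conventionally the minor allele); `NA` marks a missing call.
#' Markers are sorted by (chromosome, position) on construction.
#'
#' @param markers data.frame with columns `id`, `chrom`, `bp`,
#'   `allele_counted`, `allele_other` and optionally `build` (assembly
#'   label, metadata only, e.g. "hg18").
#' @param samples data.frame with columns `sample_id`, `phenotype`
#'   (`"case"`, `"control"` or `NA`), `sex` (`"M"`, `"F"` or `NA`) and
#'   `age` (years or `NA`).
#' @param calls integer matrix, `nrow(samples)` x `nrow(markers)`, entries
#'   in `{0, 1, 2, NA}`.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(markers, samples, calls) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (!"build" %in% names(markers))
    markers[["build"]] <- rep(NA_character_, nrow(markers))
  req_m <- c("id", "chrom", "bp", "allele_counted", "allele_other")
  if (!all(req_m %in% names(markers)))
    stop("markers must have columns: ", paste(req_m, collapse = ", "))
  req_s <- c("sample_id", "phenotype", "sex", "age")
  for (col in setdiff(req_s, names(samples))) samples[[col]] <- NA
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(samples) || ncol(calls) != nrow(markers))
    stop("calls must be a ", nrow(samples), " x ", nrow(markers), " matrix")
  vals <- calls[!is.na(calls)]
  if (length(vals) && (min(vals) < 0L || max(vals) > 2L))
    stop("genotype calls must be in {0, 1, 2, NA}")
  if (anyDuplicated(markers$id))
    stop("marker ids must be unique")
  if (any(markers$bp < 1))
    stop("marker positions are 1-based: bp >= 1")
  if (any(markers$allele_counted == markers$allele_other))
    stop("allele_counted must differ from allele_other")
  ord <- order(markers$chrom, markers$bp)
  markers <- markers[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  rownames(markers) <- NULL
  rownames(samples) <- NULL
  dimnames(calls) <- list(samples$sample_id, markers$id)
  structure(list(markers = markers, samples = samples, calls = calls),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d markers\n",
              nrow(x$samples), nrow(x$markers)))
  ph <- table(factor(x$samples$phenotype, levels = c("case", "control")),
              useNA = "ifany")
  cat(sprintf("  cases: %d  controls: %d  missing phenotype: %d\n",
              ph[["case"]], ph[["control"]],
              sum(is.na(x$samples$phenotype))))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$markers$chrom), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$calls)

marker_index <- function(dataset, marker_id) {
  i <- match(marker_id, dataset$markers$id)
  if (is.na(i)) stop("marker not found: ", marker_id, call. = FALSE)
  i
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on the genotype counts, two-sided by probability
#' mass: the p-value is the total conditional probability (given the allele
#' counts) of all heterozygote counts whose probability does not exceed
#' that of the observed table. Monomorphic markers return 1.
#'
#' @param n_hom_counted,n_het,n_hom_other genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_hom_counted, n_het, n_hom_other) {
  stopifnot(n_hom_counted >= 0, n_het >= 0, n_hom_other >= 0)
  n <- n_hom_counted + n_het + n_hom_other
  if (n == 0) stop("no genotypes")
  n_a <- 2L * n_hom_counted + n_het   # copies of counted allele
  n_b <- 2L * n_hom_other + n_het
  if (n_a == 0L || n_b == 0L) return(1)
  n_rare <- min(n_a, n_b)
  # feasible heterozygote counts share the parity of the rare allele count
  hets <- seq(n_rare %% 2L, n_rare, by = 2L)
  # log conditional probability of each table given allele counts
  logp <- lfactorial(n) + hets * log(2) + lfactorial(n_a) + lfactorial(n_b) -
    (lfactorial((n_a - hets) / 2) + lfactorial(hets) +
       lfactorial((n_b - hets) / 2) + lfactorial(2L * n))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-12)]))
}

#' Per-marker summary statistics
#'
#' Minor allele frequency, call rate, observed heterozygosity and the
#' Hardy-Weinberg exact-test p-value, all computed over non-missing calls.
#'
#' @param dataset a [genotype_dataset()].
#' @param marker_id rsID of the marker.
#' @return list with `maf`, `call_rate`, `het_obs`, `hwe_p`.
#' @export
marker_stats <- function(dataset, marker_id) {
  g <- dataset$calls[, marker_index(dataset, marker_id)]
  ok <- !is.na(g)
  if (!any(ok)) stop("all calls missing for marker ", marker_id)
  g <- g[ok]
  p <- mean(g) / 2
  n2 <- sum(g == 2L); n1 <- sum(g == 1L); n0 <- sum(g == 0L)
  list(maf = min(p, 1 - p),
       call_rate = mean(ok),
       het_obs = n1 / length(g),
       hwe_p = hwe_exact_p(n2, n1, n0))
}

marker_stats_all <- function(dataset) {
  g <- dataset$calls
  miss <- is.na(g)
  n_ok <- colSums(!miss)
  s <- colSums(g, na.rm = TRUE)
  p <- ifelse(n_ok > 0, s / (2 * n_ok), NA_real_)
  data.frame(id = dataset$markers$id,
             maf = pmin(p, 1 - p),
             call_rate = n_ok / nrow(g),
             het_obs = colSums(g == 1L, na.rm = TRUE) / pmax(n_ok, 1L),
             stringsAsFactors = FALSE)
}

#' Filter markers on MAF, HWE and call rate
#'
#' Retains markers with `maf > maf_min`, `hwe_p > hwe_p_min` and
#' `call_rate >= call_rate_min`. Thresholds of 0 therefore keep
#' everything except markers that fail a strict inequality at 0
#' (none, since maf and hwe_p are non-negative and hwe_p > 0).
#'
#' @param dataset a [genotype_dataset()].
#' @param maf_min,hwe_p_min,call_rate_min thresholds in `[0, 1]`.
#' @return the filtered `genotype_dataset` (possibly with zero markers).
#' @export
filter_markers <- function(dataset, maf_min = 0, hwe_p_min = 0,
                           call_rate_min = 0) {
  stopifnot(maf_min >= 0, maf_min <= 1, hwe_p_min >= 0, hwe_p_min <= 1,
            call_rate_min >= 0, call_rate_min <= 1)
  st <- marker_stats_all(dataset)
  hwe <- if (hwe_p_min > 0) {
    vapply(st$id, function(id) marker_stats(dataset, id)$hwe_p, numeric(1))
  } else rep(1, nrow(st))
  keep <- !is.na(st$maf) & st$maf > maf_min & hwe > hwe_p_min &
    st$call_rate >= call_rate_min
  subset_markers(dataset, which(keep))
}

subset_markers <- function(dataset, idx) {
  structure(list(markers = dataset$markers[idx, , drop = FALSE],
                 samples = dataset$samples,
                 calls = dataset$calls[, idx, drop = FALSE]),
            class = "genotype_dataset")
}

subset_samples <- function(dataset, idx) {
  structure(list(markers = dataset$markers,
                 samples = dataset$samples[idx, , drop = FALSE],
                 calls = dataset$calls[idx, , drop = FALSE]),
            class = "genotype_dataset")
}

#' Remove samples with low per-individual call rate
#'
#' @param dataset a [genotype_dataset()].
#' @param call_rate_min minimum fraction of non-missing genotypes
#'   (default 0.99, i.e. individuals with less than 99% of genotypes
#'   available are excluded).
#' @return the filtered `genotype_dataset`.
#' @export
filter_samples <- function(dataset, call_rate_min = 0.99) {
  cr <- rowMeans(!is.na(dataset$calls))
  subset_samples(dataset, which(cr >= call_rate_min))
}
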