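#' Long-range LD decision rule
#'
#' A pair is called LRLD when `|D'| >= dprime_min` and the LD test
#' p-value is below `p_max` (defaults 0.2 and 0.05).
#'
#' @param ld an LD result from [ld_pair()] / [ld_from_haplofreqs()].
#' @param dprime_min minimum `|D'|` (default 0.2).
#' @param p_max significance threshold (default 0.05).
#' @return logical.
#' @export
lrld_decision <- function(ld, dprime_min = 0.2, p_max = 0.05) {
  abs(ld$dprime) >= dprime_min && ld$p < p_max
}

#' MAF-matched bootstrap null for an observed LRLD signal
#'
#' Draws `B` markers uniformly with replacement from the pool of markers
#' whose MAF lies in `[maf_min, maf_max]` and that do not map to the
#' excluded chromosome(s) (by default the anchor's and target's own
#' chromosome), computes `|D'|` between the anchor and each draw, and
#' reports the empirical probability that a random MAF-matched marker
#' shows LD at least as strong as the observed anchor-target pair:
#' `(n_exceed + 1) / (n_used + 1)` (never exactly 0).
#'
#' @param dataset a [genotype_dataset()].
#' @param anchor,target marker rsIDs; the observed statistic is
#'   `|D'|(anchor, target)`.
#' @param B number of null draws (default 10000).
#' @param maf_min,maf_max MAF bounds of the matched pool (defaults 0.20
#'   and 0.40, bracketing a MAF-0.30 target).
#' @param exclude_chrom chromosomes excluded from the pool; default the
#'   chromosomes of anchor and target.
#' @param seed integer seed; the result is fully reproducible from it.
#' @return list with `anchor_id`, `target_id`, `observed_abs_dprime`,
#'   `B`, `n_used` (draws with computable LD), `n_exceed`, `empirical_p`,
#'   `seed`.
#' @export
bootstrap_null_pvalue <- function(dataset, anchor, target, B = 10000,
                                  maf_min = 0.20, maf_max = 0.40,
                                  exclude_chrom = NULL, seed) {
  stopifnot(B >= 1)
  if (missing(seed)) stop("seed is mandatory for the bootstrap null")
  ai <- marker_index(dataset, anchor)
  ti <- marker_index(dataset, target)
  if (is.null(exclude_chrom))
    exclude_chrom <- unique(dataset$markers$chrom[c(ai, ti)])
  st <- marker_stats_all(dataset)
  pool <- which(!is.na(st$maf) & st$maf >= maf_min & st$maf <= maf_max &
                  !(dataset$markers$chrom %in% exclude_chrom))
  pool <- setdiff(pool, c(ai, ti))
  if (!length(pool))
    stop("no eligible null markers (MAF in [", maf_min, ", ", maf_max,
         "] off chromosome(s) ", paste(exclude_chrom, collapse = ","), ")")
  observed <- abs(ld_pair(dataset, anchor, target)$dprime)
  set.seed(seed)
  draws <- pool[sample.int(length(pool), B, replace = TRUE)]
  # with-replacement draws: compute LD once per unique marker, then index
  uniq <- unique(draws)
  absd <- vapply(uniq, function(j) {
    tryCatch({
      tab <- two_locus_table_from_calls(dataset$calls[, ai],
                                        dataset$calls[, j])
      h <- em_haplotype_freqs(tab)
      abs(ld_from_haplofreqs(h, tab$n_samples)$dprime)
    }, apoeld_monomorphic_error = function(e) NA_real_,
       error = function(e) NA_real_)
  }, numeric(1))
  vals <- absd[match(draws, uniq)]
  n_used <- sum(!is.na(vals))
  n_exceed <- sum(vals >= observed, na.rm = TRUE)
  list(anchor_id = anchor, target_id = target,
       observed_abs_dprime = observed, B = B, n_used = n_used,
       n_exceed = n_exceed, empirical_p = (n_exceed + 1) / (n_used + 1),
       seed = seed)
}

#' Sliding-window chromosome LD profile
#'
#' Windows of `window_bp` base pairs advance by `step_bp` from the
#' chromosome's first marker position. Within each window, every pair of
#' markers with MAF `>= maf_min` separated by `min_sep_bp` to
#' `max_sep_bp` contributes; the window mean of `|D'|` and of `r2` is
#' reported. Windows with no admissible pair are omitted. Defaults: 1.7
#' Mb windows, 0.1 Mb step (1.6 Mb overlap), pair separation 50-500 kb,
#' MAF >= 0.2.
#'
#' @param dataset a [genotype_dataset()].
#' @param chrom chromosome label to scan.
#' @param window_bp,step_bp window length and step in base pairs.
#' @param min_sep_bp,max_sep_bp admissible pair separation in base pairs
#'   (inclusive).
#' @param maf_min minimum MAF of contributing markers.
#' @return data.frame with columns `chrom`, `start_bp`, `end_bp`
#'   (inclusive), `n_pairs`, `mean_abs_dprime`, `mean_r2`.
#' @export
sliding_window_ld <- function(dataset, chrom, window_bp = 1700000,
                              step_bp = 100000, min_sep_bp = 50000,
                              max_sep_bp = 500000, maf_min = 0.2) {
  on_chrom <- which(dataset$markers$chrom == chrom)
  if (!length(on_chrom)) stop("chromosome not present: ", chrom)
  st <- marker_stats_all(dataset)
  idx <- on_chrom[!is.na(st$maf[on_chrom]) & st$maf[on_chrom] >= maf_min]
  empty <- data.frame(chrom = character(0), start_bp = integer(0),
                      end_bp = integer(0), n_pairs = integer(0),
                      mean_abs_dprime = numeric(0), mean_r2 = numeric(0))
  if (length(idx) < 2) return(empty)
  pos <- dataset$markers$bp[idx]
  o <- order(pos); idx <- idx[o]; pos <- pos[o]
  cache <- new.env(parent = emptyenv())
  pair_ld <- function(a, b) {  # a, b index into idx/pos
    key <- paste0(a, ":", b)
    hit <- get0(key, envir = cache, ifnotfound = NULL)
    if (!is.null(hit)) return(hit)
    val <- tryCatch({
      tab <- two_locus_table_from_calls(dataset$calls[, idx[a]],
                                        dataset$calls[, idx[b]])
      h <- em_haplotype_freqs(tab)
      ld <- ld_from_haplofreqs(h, tab$n_samples)
      c(abs(ld$dprime), ld$r2)
    }, apoeld_monomorphic_error = function(e) c(NA_real_, NA_real_))
    cache[[key]] <- val
    val
  }
  starts <- seq(min(pos), max(pos), by = step_bp)
  rows <- lapply(starts, function(s) {
    e <- s + window_bp - 1
    inw <- which(pos >= s & pos <= e)
    if (length(inw) < 2) return(NULL)
    absd <- numeric(0); r2 <- numeric(0)
    for (u in seq_len(length(inw) - 1L)) for (v in (u + 1L):length(inw)) {
      a <- inw[u]; b <- inw[v]
      sep <- abs(pos[b] - pos[a])
      if (sep < min_sep_bp || sep > max_sep_bp) next
      val <- pair_ld(a, b)
      if (is.na(val[1])) next
      absd <- c(absd, val[1]); r2 <- c(r2, val[2])
    }
    if (!length(absd)) return(NULL)
    data.frame(chrom = chrom, start_bp = s, end_bp = e,
               n_pairs = length(absd), mean_abs_dprime = mean(absd),
               mean_r2 = mean(r2))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Marker scan stratified by epsilon2-carrier status
#'
#' Per-marker 2x2 allelic chi-square test comparing counted-allele
#' frequencies between carriers and non-carriers of the APOE epsilon2
#' allele, with Bonferroni correction over the markers tested. Markers
#' in strong LD with the epsilon2-defining SNP surface with the smallest
#' corrected p-values.
#'
#' @param dataset a [genotype_dataset()].
#' @param e2_carrier logical per sample (`NA` samples are dropped).
#' @param alpha nominal significance level carried in the output
#'   attribute `alpha` (default 0.05).
#' @return data.frame with `marker_id`, `chi2`, `p`, `p_bonferroni`,
#'   sorted by `p` ascending.
#' @export
e2_association_scan <- function(dataset, e2_carrier, alpha = 0.05) {
  stopifnot(length(e2_carrier) == nrow(dataset$samples))
  keep <- !is.na(e2_carrier)
  carrier <- e2_carrier[keep]
  if (!any(carrier) || all(carrier))
    stop("both carrier classes must be non-empty")
  g <- dataset$calls[keep, , drop = FALSE]
  scan_one <- function(j) {
    gj <- g[, j]
    ok <- !is.na(gj)
    a1 <- sum(gj[ok & carrier]);  n1 <- 2 * sum(ok & carrier)
    a0 <- sum(gj[ok & !carrier]); n0 <- 2 * sum(ok & !carrier)
    tab <- matrix(c(a1, n1 - a1, a0, n0 - a0), nrow = 2, byrow = TRUE)
    chi2_2x2(tab)
  }
  chi2 <- vapply(seq_len(ncol(g)), scan_one, numeric(1))
  p <- chi2_upper_tail_p(chi2, 1L)
  m <- length(p)
  out <- data.frame(marker_id = dataset$markers$id, chi2 = chi2, p = p,
                    p_bonferroni = pmin(1, p * m),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

# Pearson chi-square on a 2x2 table, df = 1, no continuity correction;
# 0 when a margin is degenerate (statistic undefined -> no evidence)
chi2_2x2 <- function(tab) {
  N <- sum(tab)
  r <- rowSums(tab); c <- colSums(tab)
  if (any(r == 0) || any(c == 0)) return(0)
  e <- outer(r, c) / N
  sum((tab - e)^2 / e)
}
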