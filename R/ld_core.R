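#' Two-locus genotype table
#'
#' Cross-tabulates counted-allele copy numbers at two markers over the
#' samples that are non-missing at BOTH loci (pairwise-complete). The
#' 3x3 table is the sufficient statistic for the two-locus EM.
#'
#' @param dataset a [genotype_dataset()].
#' @param m1,m2 marker rsIDs.
#' @return list with `counts` (3x3 integer matrix, rows = copies at `m1`,
#'   cols = copies at `m2`) and `n_samples`.
#' @export
two_locus_table <- function(dataset, m1, m2) {
  g1 <- dataset$calls[, marker_index(dataset, m1)]
  g2 <- dataset$calls[, marker_index(dataset, m2)]
  two_locus_table_from_calls(g1, g2)
}

two_locus_table_from_calls <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok))
    stop("no samples jointly non-missing at both loci", call. = FALSE)
  idx <- 3L * g1[ok] + g2[ok] + 1L
  counts <- matrix(tabulate(idx, nbins = 9L), nrow = 3, byrow = TRUE,
                   dimnames = list(c("0", "1", "2"), c("0", "1", "2")))
  list(counts = counts, n_samples = sum(ok))
}

monomorphic_error <- function(msg) {
  stop(errorCondition(msg, class = c("apoeld_monomorphic_error", "error")))
}

#' EM estimate of two-locus haplotype frequencies
#'
#' Standard EM for the two-locus phase-ambiguity model on unphased
#' diploid genotypes: every genotype cell except the double heterozygote
#' has a determined gamete composition; the double-heterozygote cell is
#' split each iteration between AB/ab and Ab/aB in the ratio
#' `pAB*pab : pAb*paB`. Frequencies are initialised at linkage
#' equilibrium (products of the observed allele frequencies), which
#' resolves the all-double-heterozygote likelihood ridge to D = 0.
#'
#' @param table a two-locus table from [two_locus_table()].
#' @param tol convergence threshold on the maximum absolute change of any
#'   haplotype frequency (default 1e-10).
#' @param max_iter maximum EM iterations (default 1000).
#' @param trace if `TRUE`, the result carries `loglik_trace`, the
#'   observed-data log-likelihood after every iteration (used to check EM
#'   monotonicity).
#' @return list with `pAB`, `pAb`, `paB`, `pab` (A/a = counted/other
#'   allele at locus 1, B/b at locus 2), `loglik`, `n_iter`, `converged`.
#' @export
em_haplotype_freqs <- function(table, tol = 1e-10, max_iter = 1000,
                               trace = FALSE) {
  n <- table$counts
  N <- table$n_samples
  stopifnot(N >= 1)
  pA <- sum(n * c(0, 1, 2)[row(n)]) / (2 * N)
  pB <- sum(n * c(0, 1, 2)[col(n)]) / (2 * N)
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    monomorphic_error("locus monomorphic among pairwise-complete samples; LD undefined")
  # determined gamete counts (double heterozygote n[2,2] excluded)
  xAB <- 2 * n[3, 3] + n[3, 2] + n[2, 3]
  xAb <- 2 * n[3, 1] + n[3, 2] + n[2, 1]
  xaB <- 2 * n[1, 3] + n[1, 2] + n[2, 3]
  xab <- 2 * n[1, 1] + n[1, 2] + n[2, 1]
  ndh <- n[2, 2]
  p <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
  n_iter <- 0L
  converged <- FALSE
  ll_trace <- if (trace) numeric(0) else NULL
  while (n_iter < max_iter) {
    n_iter <- n_iter + 1L
    denom <- p[1] * p[4] + p[2] * p[3]
    f <- if (denom > 0) p[1] * p[4] / denom else 0.5
    p_new <- c(xAB + ndh * f, xAb + ndh * (1 - f),
               xaB + ndh * (1 - f), xab + ndh * f) / (2 * N)
    delta <- max(abs(p_new - p))
    p <- p_new
    if (trace) ll_trace <- c(ll_trace, two_locus_loglik(n, p))
    if (delta < tol) { converged <- TRUE; break }
  }
  out <- list(pAB = p[1], pAb = p[2], paB = p[3], pab = p[4],
              loglik = two_locus_loglik(n, p), n_iter = n_iter,
              converged = converged)
  if (trace) out$loglik_trace <- ll_trace
  out
}

# observed-data multinomial log-likelihood of a 3x3 genotype table given
# haplotype frequencies p = (pAB, pAb, paB, pab), assuming random union
two_locus_loglik <- function(counts, p) {
  P <- two_locus_geno_probs(p)
  sum(counts[counts > 0] * log(P[counts > 0]))
}

two_locus_geno_probs <- function(p) {
  hA <- c(1L, 1L, 0L, 0L)  # copies of counted allele at locus 1 per haplotype
  hB <- c(1L, 0L, 1L, 0L)
  P <- matrix(0, 3, 3)
  for (h1 in 1:4) for (h2 in 1:4) {
    i <- hA[h1] + hA[h2] + 1L
    j <- hB[h1] + hB[h2] + 1L
    P[i, j] <- P[i, j] + p[h1] * p[h2]
  }
  P
}

#' LD coefficients from haplotype frequencies
#'
#' Computes the disequilibrium coefficient `D = pAB - pA*pB`, signed
#' `D'` (D scaled by its maximum attainable magnitude given the allele
#' frequencies), `r2` (squared allelic correlation), the chi-square LD
#' statistic `2*N*r2` (1 df) and its upper-tail p-value.
#'
#' @param h haplotype frequencies as returned by [em_haplotype_freqs()].
#' @param n_samples number of individuals the frequencies were estimated
#'   from (enters the chi-square statistic).
#' @return list with `D`, `dprime`, `r2`, `chi2`, `p`, `n_samples`.
#' @export
ld_from_haplofreqs <- function(h, n_samples) {
  pA <- h$pAB + h$pAb
  pB <- h$pAB + h$paB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    monomorphic_error("monomorphic marginal; LD undefined")
  D <- h$pAB - pA * pB
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else       min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (D == 0) 0 else D / dmax
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  chi2 <- 2 * n_samples * r2
  list(D = D, dprime = dprime, r2 = r2, chi2 = chi2,
       p = chi2_upper_tail_p(chi2, 1L), n_samples = n_samples)
}

#' Pairwise LD between two markers
#'
#' Composition of [two_locus_table()], [em_haplotype_freqs()] and
#' [ld_from_haplofreqs()]: the machinery behind a pairwise LD report row
#' (N, D', r2, chi-square, p).
#'
#' @inheritParams two_locus_table
#' @inheritParams em_haplotype_freqs
#' @return list as in [ld_from_haplofreqs()].
#' @export
ld_pair <- function(dataset, m1, m2, tol = 1e-10, max_iter = 1000) {
  tab <- two_locus_table(dataset, m1, m2)
  h <- em_haplotype_freqs(tab, tol = tol, max_iter = max_iter)
  ld_from_haplofreqs(h, tab$n_samples)
}

#' Upper-tail chi-square probability
#'
#' @param chi2 statistic, `>= 0`.
#' @param df degrees of freedom.
#' @return `P(X >= chi2)` for `X ~ chi-square(df)`.
#' @export
chi2_upper_tail_p <- function(chi2, df = 1L) {
  if (any(chi2 < 0)) stop("chi2 must be non-negative")
  stats::pchisq(chi2, df = df, lower.tail = FALSE)
}

#' Greedy LD pruning
#'
#' Greedy left-to-right pass over sliding marker windows: whenever a pair
#' of still-retained markers inside the current window has `r2 > r2_max`,
#' the later-positioned marker is dropped. Deterministic; monomorphic
#' pairs contribute no LD and are never pruned on.
#'
#' @param dataset a [genotype_dataset()].
#' @param r2_max r-squared threshold above which the later marker of a
#'   pair is removed (default 0.3, i.e. retained set has pairwise
#'   `r2 <= 0.3` within windows).
#' @param window_markers window width in markers (default 50).
#' @param step_markers step between window starts in markers (default 5).
#' @return character vector of retained marker ids, in map order.
#' @export
ld_prune <- function(dataset, r2_max = 0.3, window_markers = 50,
                     step_markers = 5) {
  m <- nrow(dataset$markers)
  stopifnot(m >= 1, window_markers >= 2, step_markers >= 1)
  keep <- rep(TRUE, m)
  for (start in seq(1L, m, by = step_markers)) {
    end <- min(start + window_markers - 1L, m)
    if (end <= start) next
    for (i in start:(end - 1L)) {
      if (!keep[i]) next
      for (j in (i + 1L):end) {
        if (!keep[j]) next
        r2 <- pair_r2_safe(dataset, i, j)
        if (!is.na(r2) && r2 > r2_max) keep[j] <- FALSE
      }
    }
    if (end == m) break
  }
  dataset$markers$id[keep]
}

pair_r2_safe <- function(dataset, i, j) {
  tryCatch({
    tab <- two_locus_table_from_calls(dataset$calls[, i], dataset$calls[, j])
    h <- em_haplotype_freqs(tab)
    ld_from_haplofreqs(h, tab$n_samples)$r2
  }, apoeld_monomorphic_error = function(e) NA_real_)
}
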