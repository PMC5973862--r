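#' Wright's inbreeding coefficient
#'
#' Per-marker `F = 1 - Ho/He`, where `Ho` is the observed heterozygote
#' frequency and `He = 2p(1-p)` the Hardy-Weinberg expectation with the
#' plug-in allele frequency; the dataset-level coefficient is the mean
#' of `F` over the markers analysed. Before computing, samples with a
#' per-individual call rate below `sample_call_rate_min` are removed,
#' then markers are filtered to `maf > maf_min` and `hwe_p > hwe_p_min`
#' (defaults: MAF > 0.2, HWE p > 0.001, call rate >= 0.99).
#'
#' @param dataset a [genotype_dataset()].
#' @param maf_min,hwe_p_min,sample_call_rate_min filters as above.
#' @param marker_subset optional character vector of marker ids to
#'   intersect with before filtering (e.g. markers common to several
#'   cohorts).
#' @return list with `f_mean`, `per_marker_f` (data.frame `marker_id`,
#'   `f`), `n_markers`, `n_samples`.
#' @export
wrights_f <- function(dataset, maf_min = 0.2, hwe_p_min = 0.001,
                      sample_call_rate_min = 0.99, marker_subset = NULL) {
  if (!is.null(marker_subset))
    dataset <- subset_markers(dataset,
                              which(dataset$markers$id %in% marker_subset))
  dataset <- filter_samples(dataset, sample_call_rate_min)
  dataset <- filter_markers(dataset, maf_min = maf_min,
                            hwe_p_min = hwe_p_min)
  if (nrow(dataset$markers) == 0)
    stop("no markers survive the inbreeding filters")
  g <- dataset$calls
  n_ok <- colSums(!is.na(g))
  p <- colSums(g, na.rm = TRUE) / (2 * n_ok)
  ho <- colSums(g == 1L, na.rm = TRUE) / n_ok
  he <- 2 * p * (1 - p)
  f <- 1 - ho / he
  list(f_mean = mean(f),
       per_marker_f = data.frame(marker_id = dataset$markers$id, f = f,
                                 stringsAsFactors = FALSE),
       n_markers = ncol(g), n_samples = nrow(g))
}

#' Principal components on an LD-pruned marker set
#'
#' LD-prunes the markers (r-squared below `prune_r2` retained, via
#' [ld_prune()]), replaces missing genotypes by the marker mean, centers
#' each marker and scales it by `sqrt(2p(1-p))`, and takes the top
#' components of the singular decomposition. Component signs are fixed
#' by forcing the largest-magnitude marker loading positive.
#'
#' @param dataset a [genotype_dataset()].
#' @param n_components number of components, at most
#'   `min(n_samples, n_retained_markers)`.
#' @param prune_r2 pruning threshold (default 0.3).
#' @param window_markers,step_markers pruning window geometry, see
#'   [ld_prune()].
#' @return list with `scores` (samples x components), `sdev` (singular
#'   values / sqrt(n-1)), `markers_used`.
#' @export
principal_components <- function(dataset, n_components, prune_r2 = 0.3,
                                 window_markers = 50, step_markers = 5) {
  stopifnot(nrow(dataset$markers) >= 1, n_components >= 1)
  kept <- ld_prune(dataset, r2_max = prune_r2,
                   window_markers = window_markers,
                   step_markers = step_markers)
  ds <- subset_markers(dataset, match(kept, dataset$markers$id))
  X <- ds$calls
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  p <- mu / 2
  sc <- sqrt(2 * p * (1 - p))
  poly <- sc > 0
  if (!any(poly)) stop("all retained markers are constant; cannot decompose")
  X <- sweep(X[, poly, drop = FALSE], 2, mu[poly], "-")
  X <- sweep(X, 2, sc[poly], "/")
  if (n_components > min(nrow(X), ncol(X)))
    stop("n_components exceeds min(n_samples, n_retained_markers)")
  sv <- svd(X, nu = n_components, nv = n_components)
  flip <- vapply(seq_len(n_components), function(k) {
    v <- sv$v[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(sv$u, 2, sv$d[seq_len(n_components)] * flip, "*")
  rownames(scores) <- ds$samples$sample_id
  colnames(scores) <- paste0("PC", seq_len(n_components))
  list(scores = scores, sdev = sv$d / sqrt(max(1, nrow(X) - 1)),
       markers_used = ds$markers$id[poly])
}
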