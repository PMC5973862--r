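# Independent oracles. These reimplement the mathematics from scratch
# (no calls into the code paths they check).

# -- HWE enumeration oracle -------------------------------------------------
# exact conditional distribution of the heterozygote count given allele
# counts, built from first-principles table probabilities
hwe_enum_oracle <- function(n_hom_a, n_het, n_hom_b) {
  n <- n_hom_a + n_het + n_hom_b
  na <- 2 * n_hom_a + n_het
  nb <- 2 * n_hom_b + n_het
  if (na == 0 || nb == 0) return(1)
  hets <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
  # unnormalised: multinomial ways for the genotype table times 2^het
  lw <- lchoose(n, (na - hets) / 2) +
    lchoose(n - (na - hets) / 2, hets) + hets * log(2)
  w <- exp(lw - max(lw))
  w <- w / sum(w)
  obs <- w[match(n_het, hets)]
  sum(w[w <= obs * (1 + 1e-12)])
}

# -- EM oracle: multi-resolution grid search of the likelihood --------------
# observed-data multinomial log-likelihood of a 3x3 genotype table at
# haplotype frequencies (pAB, pAb, paB, pab), vectorised over candidates
grid_loglik <- function(counts, p1, p2, p3, p4) {
  P <- cbind(p4^2, 2 * p3 * p4, p3^2,                     # row g1 = 0
             2 * p2 * p4, 2 * (p1 * p4 + p2 * p3), 2 * p1 * p3,
             p2^2, 2 * p1 * p2, p1^2)                     # row g1 = 2
  n <- as.vector(t(counts))                               # (0,0),(0,1),...
  lp <- log(pmax(P, 1e-300))
  as.vector(lp %*% n)
}

# grid search over the haplotype simplex, refined around the incumbent;
# final resolution ~2e-4 per frequency
grid_em_oracle <- function(counts) {
  best <- c(0.5, 0.5, 0.5)   # first box covers the whole simplex
  step <- 0.025
  span <- 0.5   # half-width of the search box around the incumbent
  for (pass in 1:4) {
    s1 <- seq(max(0, best[1] - span), min(1, best[1] + span), by = step)
    s2 <- seq(max(0, best[2] - span), min(1, best[2] + span), by = step)
    s3 <- seq(max(0, best[3] - span), min(1, best[3] + span), by = step)
    g <- expand.grid(p1 = s1, p2 = s2, p3 = s3)
    g <- g[g$p1 + g$p2 + g$p3 <= 1, ]
    ll <- grid_loglik(counts, g$p1, g$p2, g$p3, 1 - g$p1 - g$p2 - g$p3)
    best <- as.numeric(g[which.max(ll), ])
    span <- 2 * step
    step <- step / 5
  }
  c(pAB = best[1], pAb = best[2], paB = best[3],
    pab = 1 - sum(best))
}

# -- meta-analysis oracle ---------------------------------------------------
# independent one-shot reimplementation of fixed + DL pooling
meta_oracle <- function(log_or, se) {
  z <- qnorm(0.975)
  w <- se^-2
  fixed <- sum(w * log_or) / sum(w)
  k <- length(w)
  q <- sum(w * (log_or - fixed)^2)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  rand <- sum(wr * log_or) / sum(wr)
  list(fixed = fixed, fixed_se = sum(w)^-0.5,
       q = q, tau2 = tau2,
       random = rand, random_se = sum(wr)^-0.5)
}

# -- greedy LD-prune oracle -------------------------------------------------
# same greedy contract, written as an explicit brute-force double loop
ld_prune_oracle <- function(dataset, r2_max, window_markers, step_markers) {
  m <- nrow(dataset$markers)
  keep <- rep(TRUE, m)
  starts <- seq(1, m, by = step_markers)
  for (s in starts) {
    e <- min(s + window_markers - 1, m)
    if (e <= s) next
    for (i in s:(e - 1)) for (j in (i + 1):e) {
      if (!keep[i] || !keep[j]) next
      r2 <- tryCatch(
        ld_pair(dataset, dataset$markers$id[i], dataset$markers$id[j])$r2,
        error = function(e) NA_real_)
      if (!is.na(r2) && r2 > r2_max) keep[j] <- FALSE
    }
    if (e == m) break
  }
  dataset$markers$id[keep]
}

# -- sliding-window oracle --------------------------------------------------
# brute-force double loop over all marker pairs for every window
sliding_window_oracle <- function(dataset, chrom, window_bp, step_bp,
                                  min_sep_bp, max_sep_bp, maf_min) {
  idx <- which(dataset$markers$chrom == chrom)
  mafs <- vapply(dataset$markers$id[idx],
                 function(id) marker_stats(dataset, id)$maf, numeric(1))
  idx <- idx[mafs >= maf_min]
  pos <- dataset$markers$bp[idx]
  o <- order(pos); idx <- idx[o]; pos <- pos[o]
  res <- NULL
  for (s in seq(min(pos), max(pos), by = step_bp)) {
    e <- s + window_bp - 1
    absd <- c(); r2 <- c()
    k <- which(pos >= s & pos <= e)
    if (length(k) >= 2)
      for (a in 1:(length(k) - 1)) for (b in (a + 1):length(k)) {
        sep <- pos[k[b]] - pos[k[a]]
        if (sep < min_sep_bp || sep > max_sep_bp) next
        ld <- tryCatch(ld_pair(dataset, dataset$markers$id[idx[k[a]]],
                               dataset$markers$id[idx[k[b]]]),
                       error = function(err) NULL)
        if (is.null(ld)) next
        absd <- c(absd, abs(ld$dprime)); r2 <- c(r2, ld$r2)
      }
    if (length(absd))
      res <- rbind(res, data.frame(start_bp = s, n_pairs = length(absd),
                                   mean_abs_dprime = mean(absd),
                                   mean_r2 = mean(r2)))
  }
  res
}
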