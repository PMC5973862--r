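test_that("two_locus_table tallies pairwise-complete samples", {
  ds <- make_dataset(cbind(rep(0L, 7), rep(0L, 7)))
  tab <- two_locus_table(ds, "snp1", "snp2")
  expect_identical(tab$counts[1, 1], 7L)
  expect_identical(sum(tab$counts), 7L)
  # one missing call drops exactly that sample
  calls <- cbind(c(0L, 1L, 2L, 1L, 0L, NA), c(0L, 1L, 2L, 0L, 1L, 2L))
  ds <- make_dataset(calls)
  tab <- two_locus_table(ds, "snp1", "snp2")
  expect_identical(tab$n_samples, 5L)
  # random fixture against an independent tally
  set.seed(2)
  g1 <- sample(c(0:2, NA), 50, replace = TRUE)
  g2 <- sample(c(0:2, NA), 50, replace = TRUE)
  tab <- two_locus_table(make_dataset(cbind(g1, g2)), "snp1", "snp2")
  for (i in 0:2) for (j in 0:2)
    expect_identical(tab$counts[i + 1, j + 1],
                     sum(g1 == i & g2 == j, na.rm = TRUE))
  expect_error(
    two_locus_table(make_dataset(cbind(c(NA, 0L), c(1L, NA))),
                    "snp1", "snp2"), "non-missing")
})

test_that("EM recovers determined tables and holds the double-het ridge", {
  # no phase ambiguity: frequencies equal direct gamete counts
  g <- cbind(c(rep(2L, 25), rep(0L, 75)), c(rep(2L, 25), rep(0L, 75)))
  h <- em_haplotype_freqs(table_from_pair(g))
  expect_true(h$converged)
  expect_equal(c(h$pAB, h$pAb, h$paB, h$pab), c(0.25, 0, 0, 0.75))
  # a general unambiguous (no double-het) table
  tab <- list(counts = matrix(c(10L, 5L, 2L, 3L, 0L, 1L, 4L, 2L, 6L),
                              nrow = 3, byrow = TRUE), n_samples = 33L)
  h <- em_haplotype_freqs(tab)
  n <- tab$counts
  xAB <- 2 * n[3, 3] + n[3, 2] + n[2, 3]
  xAb <- 2 * n[3, 1] + n[3, 2] + n[2, 1]
  xaB <- 2 * n[1, 3] + n[1, 2] + n[2, 3]
  xab <- 2 * n[1, 1] + n[1, 2] + n[2, 1]
  expect_equal(c(h$pAB, h$pAb, h$paB, h$pab),
               c(xAB, xAb, xaB, xab) / 66)
  # all-double-heterozygote table: the LE start resolves the likelihood
  # ridge to D = 0
  tab <- list(counts = matrix(c(0L, 0L, 0L, 0L, 40L, 0L, 0L, 0L, 0L),
                              nrow = 3, byrow = TRUE), n_samples = 40L)
  h <- em_haplotype_freqs(tab)
  expect_equal(c(h$pAB, h$pAb, h$paB, h$pab), rep(0.25, 4))
  expect_error(em_haplotype_freqs(table_from_pair(
    cbind(rep(0L, 5), c(0L, 1L, 2L, 1L, 0L)))),
    class = "apoeld_monomorphic_error")
})

test_that("EM frequencies sum to one, reproduce margins, loglik monotone", {
  set.seed(21)
  for (i in 1:40) {
    repeat {
      hf_true <- as.list(setNames(as.vector(rmultinom(1, 40, runif(4))) / 40,
                                  c("pAB", "pAb", "paB", "pab")))
      g <- sample_pair_genotypes(sample(10:60, 1), hf_true)
      if (var(g[, 1]) > 0 && var(g[, 2]) > 0) break
    }
    tab <- table_from_pair(g)
    h <- em_haplotype_freqs(tab, trace = TRUE)
    p <- c(h$pAB, h$pAb, h$paB, h$pab)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    # marginals reproduce the observed allele frequencies
    expect_equal(h$pAB + h$pAb, mean(g[, 1]) / 2, tolerance = 1e-9)
    expect_equal(h$pAB + h$paB, mean(g[, 2]) / 2, tolerance = 1e-9)
    # observed-data log-likelihood never decreases
    expect_true(all(diff(h$loglik_trace) > -1e-9))
  }
})

test_that("ld_from_haplofreqs matches closed-form arithmetic", {
  # independence
  ld <- ld_from_haplofreqs(list(pAB = 0.12, pAb = 0.18, paB = 0.28,
                                pab = 0.42), 100)
  expect_equal(ld$D, 0); expect_equal(ld$dprime, 0)
  expect_equal(ld$r2, 0); expect_equal(ld$p, 1)
  # full coupling
  ld <- ld_from_haplofreqs(list(pAB = 0.25, pAb = 0, paB = 0, pab = 0.75),
                           100)
  expect_equal(ld$D, 0.1875)
  expect_equal(ld$dprime, 1)
  expect_equal(ld$r2, 1)
  # APOE-like: counted-allele (T) frequencies 0.14 / 0.07, T-T absent
  ld <- ld_from_haplofreqs(list(pAB = 0, pAb = 0.14, paB = 0.07,
                                pab = 0.79), 1789)
  expect_equal(ld$dprime, -1)
  expect_error(ld_from_haplofreqs(list(pAB = 0.5, pAb = 0.5, paB = 0,
                                       pab = 0), 10),
               class = "apoeld_monomorphic_error")
})

test_that("LD identities and allele-relabel equivariance (property)", {
  set.seed(31)
  for (i in 1:50) {
    repeat {
      g <- sample_pair_genotypes(
        40, haplofreqs_from_dprime(runif(1, 0.05, 0.5), runif(1, 0.05, 0.5),
                                   runif(1, -1, 1)))
      if (var(g[, 1]) > 0 && var(g[, 2]) > 0) break
    }
    ds <- make_dataset(g)
    ld <- tryCatch(ld_pair(ds, "snp1", "snp2"),
                   apoeld_monomorphic_error = function(e) NULL)
    if (is.null(ld)) next
    h <- em_haplotype_freqs(two_locus_table(ds, "snp1", "snp2"))
    pA <- h$pAB + h$pAb; pB <- h$pAB + h$paB
    expect_equal(ld$r2 * pA * (1 - pA) * pB * (1 - pB), ld$D^2,
                 tolerance = 1e-12)
    expect_lte(abs(ld$dprime), 1 + 1e-12)
    expect_identical(sign(ld$dprime), sign(ld$D))
    # flipping counted/other at one locus negates D and D'
    ld_f <- ld_pair(make_dataset(cbind(2L - g[, 1], g[, 2])),
                    "snp1", "snp2")
    expect_equal(ld_f$D, -ld$D, tolerance = 1e-9)
    expect_equal(ld_f$dprime, -ld$dprime, tolerance = 1e-9)
    expect_equal(ld_f$r2, ld$r2, tolerance = 1e-9)
    expect_equal(ld_f$p, ld$p, tolerance = 1e-9)
  }
})

test_that("chi-square tail probabilities behave", {
  expect_equal(chi2_upper_tail_p(0, 1), 1)
  # quantile-inversion oracle
  expect_equal(chi2_upper_tail_p(qchisq(0.95, 1), 1), 0.05)
  expect_equal(chi2_upper_tail_p(3.841459, 1), 0.05, tolerance = 1e-6)
  x <- seq(0, 50, by = 0.5)
  expect_true(all(diff(chi2_upper_tail_p(x, 1)) < 0))
  expect_error(chi2_upper_tail_p(-1, 1), "non-negative")
})

test_that("ld_pair: self-pair, and D' estimator consistency at n=5000", {
  set.seed(41)
  ds <- random_dataset(60, 1, maf = 0.3, seed = 41)
  ds2 <- make_dataset(cbind(ds$calls[, 1], ds$calls[, 1]))
  ld <- ld_pair(ds2, "snp1", "snp2")
  expect_equal(ld$dprime, 1, tolerance = 1e-6)
  expect_equal(ld$r2, 1, tolerance = 1e-6)
  # simulation oracle: mean estimated D' within 3 MC SEs of the target
  set.seed(42)
  hf <- haplofreqs_from_dprime(0.3, 0.3, 0.5)
  est <- replicate(50, {
    g <- sample_pair_genotypes(5000, hf)
    ld_pair(make_dataset(g), "snp1", "snp2")$dprime
  })
  expect_lt(abs(mean(est) - 0.5), 3 * sd(est) / sqrt(length(est)))
})

test_that("ld_prune is greedy, deterministic and matches the oracle", {
  ds <- random_dataset(100, 8, seed = 5)      # independent markers
  expect_identical(ld_prune(ds, r2_max = 0.99), ds$markers$id)
  # duplicated marker column: exactly one of the two retained
  g <- random_dataset(100, 1, maf = 0.4, seed = 6)$calls
  ds2 <- make_dataset(cbind(g, g))
  expect_identical(ld_prune(ds2, r2_max = 0.3), "snp1")
  # 20-marker fixture with planted LD blocks vs brute-force oracle
  set.seed(7)
  cols <- list()
  i <- 1
  while (i <= 20) {
    if (i < 20 && runif(1) < 0.4) {
      g <- sample_pair_genotypes(150, haplofreqs_from_dprime(0.4, 0.4, 0.95))
      cols[[i]] <- g[, 1]; cols[[i + 1]] <- g[, 2]; i <- i + 2
    } else {
      cols[[i]] <- rbinom(150, 1, 0.4) + rbinom(150, 1, 0.4); i <- i + 1
    }
  }
  ds3 <- make_dataset(do.call(cbind, cols))
  for (w in c(5, 20)) {
    expect_identical(ld_prune(ds3, 0.3, window_markers = w,
                              step_markers = 2),
                     ld_prune_oracle(ds3, 0.3, w, 2))
  }
})
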