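# dataset with a single marker kept (local convenience)
subset_markers_for_test <- function(ds, j) {
  make_dataset(ds$calls[, j, drop = FALSE], bp = ds$markers$bp[j],
               chrom = ds$markers$chrom[j], ids = ds$markers$id[j])
}

test_that("LRLD decision rule", {
  mk <- function(dprime, p) list(dprime = dprime, p = p)
  expect_true(lrld_decision(mk(-0.312, 0.016)))   # strong negative D'
  expect_false(lrld_decision(mk(-0.105, 0.020)))  # below the D' threshold
  expect_false(lrld_decision(mk(0.5, 0.2)))       # not significant
  expect_true(lrld_decision(mk(0.2, 0.049)))      # boundary: |D'| >= 0.2
  expect_false(lrld_decision(mk(0.3, 0.05)))      # boundary: p < 0.05 strict
})

test_that("bootstrap null: observed zero, reproducibility, p lower bound", {
  # anchor-target pair in exact equilibrium (balanced 3x3 table) -> D' = 0
  anchor <- rep(0:2, each = 12)
  target <- rep(rep(0:2, times = 3), 4)
  set.seed(8)
  pool <- sapply(runif(12, 0.25, 0.35),
                 function(p) rbinom(36, 1, p) + rbinom(36, 1, p))
  ds <- make_dataset(cbind(anchor, target, pool),
                     chrom = c("19", "19", rep("2", 12)),
                     ids = c("anchor", "target", paste0("n", 1:12)))
  r <- bootstrap_null_pvalue(ds, "anchor", "target", B = 200, seed = 1)
  expect_equal(r$observed_abs_dprime, 0)
  expect_equal(r$empirical_p, 1)          # every null draw ties or exceeds
  r2 <- bootstrap_null_pvalue(ds, "anchor", "target", B = 200, seed = 1)
  expect_identical(r, r2)                 # same seed, identical result
  r3 <- bootstrap_null_pvalue(ds, "anchor", "target", B = 200, seed = 2)
  expect_identical(r3$seed, 2)            # seed is carried in the result
  expect_gte(r$empirical_p, 1 / (r$n_used + 1))
  expect_lte(r$n_used, 200)
  # chromosome-19 markers are never in the pool
  expect_error(bootstrap_null_pvalue(
    subset_chrom19 <- make_dataset(cbind(anchor, target),
                                   chrom = c("19", "19"),
                                   ids = c("anchor", "target")),
    "anchor", "target", B = 10, seed = 1), "eligible")
  expect_error(bootstrap_null_pvalue(ds, "anchor", "target", B = 10),
               "seed")
})

test_that("sliding windows enumerate the admissible pair set", {
  # 5-marker toy map; first window holds all markers, pair separations
  # select exactly {(1,2),(1,3),(2,3),(4,5)}
  set.seed(9)
  calls <- sapply(rep(0.4, 5), function(p) rbinom(200, 1, p) + rbinom(200, 1, p))
  bp <- c(1, 60001, 130001, 700001, 1200001)
  ds <- make_dataset(calls, bp = bp, chrom = "19")
  win <- sliding_window_ld(ds, "19")
  first <- win[win$start_bp == 1, ]
  expect_identical(first$n_pairs, 4L)
  want <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5))
  lds <- apply(want, 1, function(pr)
    ld_pair(ds, paste0("snp", pr[1]), paste0("snp", pr[2])))
  expect_equal(first$mean_abs_dprime,
               mean(sapply(lds, function(l) abs(l$dprime))))
  expect_equal(first$mean_r2, mean(sapply(lds, function(l) l$r2)))
  expect_true(all(win$end_bp - win$start_bp == 1700000 - 1))
  # two markers 10 kb apart: below min separation, empty output
  ds2 <- make_dataset(calls[, 1:2], bp = c(1, 10001), chrom = "19")
  expect_identical(nrow(sliding_window_ld(ds2, "19")), 0L)
  # marker input order does not change window means
  perm <- sample(5)
  dsp <- make_dataset(calls[, perm], bp = bp[perm], chrom = "19",
                      ids = paste0("snp", perm))
  expect_equal(sliding_window_ld(dsp, "19")[c("n_pairs", "mean_abs_dprime",
                                              "mean_r2")],
               win[c("n_pairs", "mean_abs_dprime", "mean_r2")])
})

test_that("sliding windows agree with the brute-force oracle", {
  set.seed(10)
  m <- 30
  bp <- sort(sample.int(3000000, m))
  calls <- sapply(runif(m, 0.25, 0.5),
                  function(p) rbinom(120, 1, p) + rbinom(120, 1, p))
  ds <- make_dataset(calls, bp = bp, chrom = "19")
  got <- sliding_window_ld(ds, "19", window_bp = 800000, step_bp = 200000,
                           min_sep_bp = 20000, max_sep_bp = 400000,
                           maf_min = 0.2)
  want <- sliding_window_oracle(ds, "19", 800000, 200000, 20000, 400000, 0.2)
  expect_equal(got$start_bp, want$start_bp)
  expect_identical(got$n_pairs, want$n_pairs)
  expect_equal(got$mean_abs_dprime, want$mean_abs_dprime)
  expect_equal(got$mean_r2, want$mean_r2)
})

test_that("epsilon2-carrier scan ranks a tagging marker first", {
  set.seed(12)
  n <- 2000
  e2count <- rbinom(n, 1, 0.07) + rbinom(n, 1, 0.07)
  tag <- e2count                           # perfect LD with the e2 SNP
  noise <- sapply(runif(30, 0.2, 0.4),
                  function(p) rbinom(n, 1, p) + rbinom(n, 1, p))
  ds <- make_dataset(cbind(tag, noise),
                     ids = c("tag", paste0("n", 1:30)))
  hits <- e2_association_scan(ds, e2count > 0)
  expect_identical(hits$marker_id[1], "tag")
  expect_lt(hits$p_bonferroni[1], 0.05)
  # Bonferroni properties
  expect_true(all(hits$p_bonferroni >= hits$p))
  expect_true(all(hits$p_bonferroni <= 1))
  expect_false(is.unsorted(hits$p))
  # m = 1: corrected p equals raw p
  one <- e2_association_scan(subset_markers_for_test(ds, 2), e2count > 0)
  expect_equal(one$p_bonferroni, one$p)
  expect_error(e2_association_scan(ds, rep(TRUE, n)), "carrier")
})
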