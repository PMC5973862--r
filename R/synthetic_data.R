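#' Haplotype frequencies realising a target signed D'
#'
#' Inverts the signed D' definition used by [ld_from_haplofreqs()]:
#' `D = d * Dmax(d)` with `Dmax = min(pA(1-pB), (1-pA)pB)` for positive
#' `d` and `min(pA pB, (1-pA)(1-pB))` for negative `d`, then
#' `pAB = pA pB + D`. The counted alleles are the minor alleles, so
#' `pA = mafA`, `pB = mafB`.
#'
#' @param mafA,mafB minor allele frequencies in `(0, 0.5]`.
#' @param target_dprime signed D' in `[-1, 1]`.
#' @return list with `pAB`, `pAb`, `paB`, `pab`.
#' @export
haplofreqs_from_dprime <- function(mafA, mafB, target_dprime) {
  stopifnot(mafA > 0, mafA <= 0.5, mafB > 0, mafB <= 0.5,
            abs(target_dprime) <= 1)
  pA <- mafA; pB <- mafB
  dmax <- if (target_dprime > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else                   min(pA * pB, (1 - pA) * (1 - pB))
  D <- target_dprime * dmax
  p <- c(pAB = pA * pB + D, pAb = pA * (1 - pB) - D,
         paB = (1 - pA) * pB - D, pab = (1 - pA) * (1 - pB) + D)
  if (any(p < -1e-12) || any(p > 1 + 1e-12))
    stop("target D' infeasible at these allele frequencies")
  p <- pmin(pmax(p, 0), 1)
  as.list(p)
}

#' Simulation configuration
#'
#' Describes a synthetic diploid cohort: a marker map with per-marker
#' MAFs, optional marker pairs constrained to a target signed D', an
#' APOE-like two-SNP block whose T-T (epsilon1) haplotype is absent, and
#' an additive logistic disease model with case-control ascertainment.
#' Defaults state the world the package models: epsilon4 haplotype
#' frequency 0.14, epsilon2 haplotype frequency 0.07, both APOE SNPs on
#' chromosome 19 near 50.1 Mb.
#'
#' @param n_samples cohort size when no case-control targets are given.
#' @param markers data.frame with `id`, `chrom`, `bp`, `maf` for
#'   background (and pair-spec) markers; may be empty.
#' @param pair_specs list of `list(idA=, idB=, dprime=)`; each couples
#'   two markers of `markers` into a haplotype block at the target D'.
#' @param apoe_spec `NULL`, or a list with `p_e4`, `p_e2` haplotype
#'   frequencies (T-T fixed at 0) and optionally `id_429358`, `id_7412`,
#'   `chrom`, `bp_429358`, `bp_7412`.
#' @param effect_spec `NULL`, or a list with `beta0` (baseline
#'   log-odds), `beta_e4`, `beta_e2` (per epsilon allele), `beta_snp`
#'   and `snp_id` (per counted allele of a named marker).
#' @param n_cases,n_controls case-control sampling targets; `NULL` for a
#'   cohort of `n_samples` without ascertainment.
#' @param missing_rate genotype missingness rate in `[0, 1)`.
#' @param seed integer seed; the dataset is a deterministic function of
#'   the configuration.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_samples = 1000, markers = NULL,
                       pair_specs = list(), apoe_spec = NULL,
                       effect_spec = NULL, n_cases = NULL,
                       n_controls = NULL, missing_rate = 0, seed = 1) {
  if (is.null(markers))
    markers <- data.frame(id = character(0), chrom = character(0),
                          bp = integer(0), maf = numeric(0))
  stopifnot(missing_rate >= 0, missing_rate < 1)
  if (!is.null(apoe_spec)) {
    defaults <- list(id_429358 = "rs429358", id_7412 = "rs7412",
                     chrom = "19", bp_429358 = 50103781L,
                     bp_7412 = 50103919L, p_e4 = 0.14, p_e2 = 0.07)
    apoe_spec <- utils::modifyList(defaults, apoe_spec)
    stopifnot(apoe_spec$p_e4 > 0, apoe_spec$p_e2 > 0,
              apoe_spec$p_e4 + apoe_spec$p_e2 < 1)
  }
  for (ps in pair_specs) {
    stopifnot(all(c(ps$idA, ps$idB) %in% markers$id))
    mafs <- markers$maf[match(c(ps$idA, ps$idB), markers$id)]
    haplofreqs_from_dprime(mafs[1], mafs[2], ps$dprime)  # feasibility
  }
  if (xor(is.null(n_cases), is.null(n_controls)))
    stop("give both n_cases and n_controls, or neither")
  if (!is.null(n_cases) && is.null(effect_spec))
    effect_spec <- list(beta0 = 0, beta_e4 = 0, beta_e2 = 0,
                        beta_snp = 0, snp_id = NULL)
  structure(list(n_samples = n_samples, markers = markers,
                 pair_specs = pair_specs, apoe_spec = apoe_spec,
                 effect_spec = effect_spec, n_cases = n_cases,
                 n_controls = n_controls, missing_rate = missing_rate,
                 seed = seed),
            class = "sim_config")
}

# draw n diploid genotypes for a two-marker haplotype block
draw_block <- function(n, hf) {
  p <- c(hf$pAB, hf$pAb, hf$paB, hf$pab)
  h1 <- sample.int(4, n, replace = TRUE, prob = p)
  h2 <- sample.int(4, n, replace = TRUE, prob = p)
  hA <- c(1L, 1L, 0L, 0L); hB <- c(1L, 0L, 1L, 0L)
  cbind(hA[h1] + hA[h2], hB[h1] + hB[h2])
}

# genotype matrix for one batch of individuals (no phenotype, no masking)
draw_genotypes <- function(config, n) {
  mk <- config$markers
  ids <- mk$id
  g <- matrix(0L, nrow = n, ncol = length(ids))
  colnames(g) <- ids
  in_pair <- unlist(lapply(config$pair_specs, function(ps) c(ps$idA, ps$idB)))
  for (id in setdiff(ids, in_pair)) {
    p <- mk$maf[match(id, ids)]
    g[, id] <- stats::rbinom(n, 1L, p) + stats::rbinom(n, 1L, p)
  }
  for (ps in config$pair_specs) {
    mafs <- mk$maf[match(c(ps$idA, ps$idB), ids)]
    blk <- draw_block(n, haplofreqs_from_dprime(mafs[1], mafs[2], ps$dprime))
    g[, ps$idA] <- blk[, 1]; g[, ps$idB] <- blk[, 2]
  }
  ap <- config$apoe_spec
  if (!is.null(ap)) {
    # haplotypes over (rs429358, rs7412): T-C = e4, C-T = e2, C-C = e3,
    # T-T (e1) has frequency 0
    hf <- list(pAB = 0, pAb = ap$p_e4, paB = ap$p_e2,
               pab = 1 - ap$p_e4 - ap$p_e2)
    blk <- draw_block(n, hf)
    g <- cbind(g, blk)
    colnames(g)[ncol(g) - 1:0] <- c(ap$id_429358, ap$id_7412)
  }
  g
}

case_probability <- function(config, g) {
  es <- config$effect_spec
  eta <- rep(es$beta0, nrow(g))
  ap <- config$apoe_spec
  if (!is.null(ap)) {
    # epsilon1 absent, so allele counts are the SNP minor-allele counts
    eta <- eta + es$beta_e4 * g[, ap$id_429358] +
      es$beta_e2 * g[, ap$id_7412]
  }
  if (!is.null(es$snp_id) && es$beta_snp != 0)
    eta <- eta + es$beta_snp * g[, es$snp_id]
  stats::plogis(eta)
}

#' Simulate a genotype dataset
#'
#' Draws two haplotypes per individual within each linked block (pair
#' specs and the APOE block) and independent Hardy-Weinberg genotypes
#' for unlinked markers. With case-control targets, candidate
#' individuals are drawn in batches, disease status is Bernoulli with
#' probability `logistic(beta0 + beta_e4*nE4 + beta_e2*nE2 +
#' beta_snp*g)`, and sampling continues until `n_cases` and
#' `n_controls` are reached (capped at `1000 * (n_cases + n_controls)`
#' draws). Missing calls are masked uniformly at `missing_rate` after
#' phenotype assignment. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a [genotype_dataset()].
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  mk <- config$markers
  marker_df <- data.frame(id = as.character(mk$id),
                          chrom = as.character(mk$chrom), bp = mk$bp,
                          allele_counted = rep("A", nrow(mk)),
                          allele_other = rep("G", nrow(mk)),
                          stringsAsFactors = FALSE)
  ap <- config$apoe_spec
  if (!is.null(ap))
    marker_df <- rbind(marker_df,
                       data.frame(id = c(ap$id_429358, ap$id_7412),
                                  chrom = ap$chrom,
                                  bp = c(ap$bp_429358, ap$bp_7412),
                                  allele_counted = "T", allele_other = "C",
                                  stringsAsFactors = FALSE))
  cc <- !is.null(config$n_cases)
  if (cc) {
    need_ca <- config$n_cases; need_co <- config$n_controls
    cap <- 1000 * (need_ca + need_co)
    drawn <- 0L
    geno <- NULL; pheno <- character(0)
    while (need_ca > 0 || need_co > 0) {
      batch <- max(500L, 2L * (need_ca + need_co))
      if (drawn + batch > cap) batch <- cap - drawn
      if (batch <= 0)
        stop("case-control quotas unreachable within the draw cap")
      drawn <- drawn + batch
      g <- draw_genotypes(config, batch)
      y <- stats::rbinom(batch, 1L, case_probability(config, g))
      take_ca <- which(y == 1L)[seq_len(min(need_ca, sum(y == 1L)))]
      take_co <- which(y == 0L)[seq_len(min(need_co, sum(y == 0L)))]
      take <- sort(c(take_ca, take_co))
      geno <- rbind(geno, g[take, , drop = FALSE])
      pheno <- c(pheno, ifelse(y[take] == 1L, "case", "control"))
      need_ca <- need_ca - length(take_ca)
      need_co <- need_co - length(take_co)
    }
    n <- nrow(geno)
  } else {
    n <- config$n_samples
    geno <- draw_genotypes(config, n)
    pheno <- if (!is.null(config$effect_spec)) {
      ifelse(stats::rbinom(n, 1L, case_probability(config, geno)) == 1L,
             "case", "control")
    } else rep(NA_character_, n)
  }
  if (config$missing_rate > 0) {
    mask <- stats::runif(length(geno)) < config$missing_rate
    geno[mask] <- NA_integer_
  }
  samples <- data.frame(sample_id = sprintf("S%05d", seq_len(n)),
                        phenotype = pheno, sex = NA_character_,
                        age = NA_real_, stringsAsFactors = FALSE)
  geno <- geno[, marker_df$id, drop = FALSE]
  genotype_dataset(marker_df, samples, geno)
}

#' Simulate an APOE case-control study
#'
#' Convenience wrapper around [simulate_dataset()]: an APOE block
#' (epsilon4 haplotype 0.14, epsilon2 haplotype 0.07, epsilon1 absent),
#' a null or effect-bearing CD33-like SNP (`rs3865444`, MAF 0.30,
#' chromosome 19), and background markers with MAF drawn once from
#' Uniform(0.05, 0.5) so the MAF 0.20-0.40 bootstrap pool is populated.
#' Disease risk is additive on the log-odds scale: per-epsilon4-allele
#' odds ratio `or_e4` (risk), per-epsilon2-allele `or_e2` (protective
#' when < 1), per-minor-allele `or_snp` for the CD33-like SNP.
#'
#' @param n_cases,n_controls sampling targets.
#' @param or_e4,or_e2,or_snp per-allele odds ratios (defaults 4.0, 0.6,
#'   1.0).
#' @param n_background number of unlinked background markers spread over
#'   chromosomes 1-10 (default 200).
#' @param baseline_prev baseline (epsilon3/epsilon3, no risk allele)
#'   disease probability (default 0.15).
#' @param missing_rate genotype missingness (default 0).
#' @param seed integer seed.
#' @return a [genotype_dataset()].
#' @export
simulate_apoe_cc_study <- function(n_cases, n_controls, or_e4 = 4.0,
                                   or_e2 = 0.6, or_snp = 1.0,
                                   n_background = 200,
                                   baseline_prev = 0.15,
                                   missing_rate = 0, seed = 1) {
  stopifnot(or_e4 > 0, or_e2 > 0, or_snp > 0)
  set.seed(seed)
  bg_maf <- stats::runif(n_background, 0.05, 0.5)
  markers <- data.frame(
    id = c(sprintf("bg%04d", seq_len(n_background)), "rs3865444"),
    chrom = c(as.character(rep_len(1:10, n_background)), "19"),
    bp = c(1000000L + 50000L * seq_len(n_background), 51727962L),
    maf = c(bg_maf, 0.30), stringsAsFactors = FALSE)
  cfg <- sim_config(
    markers = markers, apoe_spec = list(),
    effect_spec = list(beta0 = stats::qlogis(baseline_prev),
                       beta_e4 = log(or_e4), beta_e2 = log(or_e2),
                       beta_snp = log(or_snp), snp_id = "rs3865444"),
    n_cases = n_cases, n_controls = n_controls,
    missing_rate = missing_rate,
    seed = sample.int(.Machine$integer.max, 1))
  simulate_dataset(cfg)
}
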