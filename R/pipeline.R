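#' Parse a plain key-value pipeline configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; list-valued
#' keys use commas (and `:` to separate the two members of an LD pair,
#' e.g. `ld_pairs = rs429358:rs7412,rs7412:rs3865444`). Values that
#' parse as numbers are converted.
#'
#' @param path configuration file.
#' @return named list suitable for [run_pipeline()].
#' @export
parse_pipeline_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(kv) != 3) stop("malformed config line: ", ln)
    key <- trimws(kv[2]); val <- trimws(kv[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

pipeline_defaults <- function() {
  list(apoe_rs429358 = "rs429358", apoe_rs7412 = "rs7412",
       ld_pairs = "rs429358:rs7412",
       assoc_snp = NULL, scan_chrom = NULL,
       window_bp = 1700000, step_bp = 100000,
       min_sep_bp = 50000, max_sep_bp = 500000, scan_maf_min = 0.2,
       boot_anchor = NULL, boot_target = NULL, boot_B = 10000,
       boot_maf_min = 0.20, boot_maf_max = 0.40,
       inbreeding_maf_min = 0.2, inbreeding_hwe_min = 0.001,
       sample_call_rate_min = 0.99, prune_r2 = 0.3, n_components = 0,
       meta_file = NULL, seed = NULL)
}

#' Run the full LRLD analysis pipeline
#'
#' Orchestrates, on one dataset, the stages of the analysis in order:
#' APOE diplotype calling and stratum assignment; unadjusted, adjusted
#' and stratified association for a focal SNP; pairwise LD for the
#' configured pairs; the sliding-window chromosome LD profile; the
#' MAF-matched bootstrap null; the epsilon2-carrier marker scan;
#' inbreeding and principal components; and meta-analysis of a supplied
#' per-study effect table. Every stage writes a TSV under `out_dir` and
#' the run log records seeds and counts. Re-running an identical
#' configuration reproduces identical outputs. A stage error aborts the
#' run, names the stage, and removes the partial outputs of this run.
#'
#' @param config named list (see [parse_pipeline_config()] and
#'   `pipeline_defaults`): `bfile` (PLINK prefix) or `dataset` (a
#'   [genotype_dataset()]), `out_dir`, APOE marker ids, `ld_pairs`,
#'   scan/bootstrap/filter parameters, optional `assoc_snp`,
#'   `scan_chrom`, `boot_anchor`/`boot_target`, `n_components`,
#'   `meta_file`; `seed` is mandatory when a bootstrap stage is
#'   configured.
#' @return named list of output file paths, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(pipeline_defaults(), config)
  if (is.null(cfg$out_dir)) stop("config needs out_dir")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "run.log")
  written <- character(0)
  logf <- function(...) {
    msg <- sprintf(...)
    cat(msg, "\n", sep = "", file = log_path, append = TRUE)
    message(msg)
  }
  emit <- function(df, name) {
    path <- file.path(cfg$out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <<- c(written, path)
    path
  }
  if (file.exists(log_path)) unlink(log_path)
  stage <- "load"
  out <- tryCatch({
    logf("apoeld pipeline | package %s",
         as.character(utils::packageVersion("apoeld")))
    ds <- if (!is.null(cfg$dataset)) cfg$dataset else read_plink(cfg$bfile)
    logf("loaded: %d samples x %d markers", nrow(ds$samples),
         nrow(ds$markers))
    files <- list()

    stage <- "apoe-call"
    calls <- apoe_calls(ds, cfg$apoe_rs429358, cfg$apoe_rs7412)
    files$apoe <- emit(calls, "apoe_calls.tsv")
    logf("apoe strata: %s",
         paste(names(table(calls$stratum)), table(calls$stratum),
               sep = "=", collapse = " "))

    stage <- "ld-pair"
    pairs <- strsplit(strsplit(cfg$ld_pairs, ",")[[1]], ":")
    ld_rows <- do.call(rbind, lapply(pairs, function(pr) {
      ld <- ld_pair(ds, pr[1], pr[2])
      data.frame(snp1 = pr[1], snp2 = pr[2], n = ld$n_samples, D = ld$D,
                 dprime = ld$dprime, r2 = ld$r2, chi2 = ld$chi2, p = ld$p,
                 lrld = lrld_decision(ld))
    }))
    files$ld_pairs <- emit(ld_rows, "ld_pairs.tsv")

    if (!is.null(cfg$assoc_snp)) {
      stage <- "assoc"
      g <- ds$calls[, marker_index(ds, cfg$assoc_snp)]
      ph <- ds$samples$phenotype
      ok <- !is.na(g) & !is.na(ph)
      ca <- ok & ph == "case"; co <- ok & ph == "control"
      unadj <- allelic_assoc(sum(g[ca]), 2 * sum(ca) - sum(g[ca]),
                             sum(g[co]), 2 * sum(co) - sum(g[co]))
      strat <- stratified_assoc(ds, cfg$assoc_snp, calls$stratum)
      rows <- c(list(unadjusted = unadj), strat)
      files$assoc <- emit(
        data.frame(analysis = names(rows),
                   or_ = vapply(rows, `[[`, 0, "or_"),
                   ci_low = vapply(rows, `[[`, 0, "ci_low"),
                   ci_high = vapply(rows, `[[`, 0, "ci_high"),
                   p = vapply(rows, `[[`, 0, "p"),
                   n_cases = vapply(rows, `[[`, 0, "n_cases"),
                   n_controls = vapply(rows, `[[`, 0, "n_controls")),
        "association.tsv")
    }

    if (!is.null(cfg$scan_chrom)) {
      stage <- "ld-scan"
      files$scan <- emit(
        sliding_window_ld(ds, as.character(cfg$scan_chrom),
                          cfg$window_bp, cfg$step_bp, cfg$min_sep_bp,
                          cfg$max_sep_bp, cfg$scan_maf_min),
        "window_ld.tsv")
    }

    if (!is.null(cfg$boot_anchor)) {
      stage <- "lrld-null"
      if (is.null(cfg$seed)) stop("seed is mandatory for the bootstrap null")
      logf("bootstrap null: B=%d seed=%d", cfg$boot_B, cfg$seed)
      bn <- bootstrap_null_pvalue(ds, cfg$boot_anchor, cfg$boot_target,
                                  B = cfg$boot_B,
                                  maf_min = cfg$boot_maf_min,
                                  maf_max = cfg$boot_maf_max,
                                  seed = cfg$seed)
      files$bootstrap <- emit(as.data.frame(bn), "bootstrap_null.tsv")
    }

    stage <- "e2-scan"
    if (any(calls$e2_carrier, na.rm = TRUE) &&
        any(!calls$e2_carrier, na.rm = TRUE)) {
      files$e2_scan <- emit(e2_association_scan(ds, calls$e2_carrier),
                            "e2_scan.tsv")
    } else logf("e2 scan skipped: a carrier class is empty")

    stage <- "inbreeding"
    fr <- wrights_f(ds, cfg$inbreeding_maf_min, cfg$inbreeding_hwe_min,
                    cfg$sample_call_rate_min)
    logf("inbreeding: F_mean=%.5f over %d markers", fr$f_mean,
         fr$n_markers)
    files$inbreeding <- emit(fr$per_marker_f, "inbreeding.tsv")

    if (cfg$n_components >= 1) {
      stage <- "pca"
      pcs <- principal_components(ds, cfg$n_components, cfg$prune_r2)
      files$pca <- emit(data.frame(sample_id = rownames(pcs$scores),
                                   pcs$scores), "pca.tsv")
    }

    if (!is.null(cfg$meta_file)) {
      stage <- "meta"
      eff <- read_study_effects(cfg$meta_file)
      if (!is.null(names(eff)) && is.list(eff[[1]][[1]])) {
        groups <- eff
      } else groups <- list(all = eff)
      files$meta <- emit(do.call(rbind, lapply(names(groups), function(nm) {
        mr <- meta_analyze(groups[[nm]])
        data.frame(stratum = nm, k = mr$k, pooled_or = mr$pooled_or,
                   ci_low = mr$ci_low, ci_high = mr$ci_high, p = mr$p,
                   q = mr$q, q_p = mr$q_p, i2 = mr$i2, tau2 = mr$tau2,
                   model = mr$model)
      })), "meta_analysis.tsv")
    }

    logf("pipeline complete: %d output tables", length(files))
    files
  }, error = function(e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(out)
}
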