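#' Allelic case-control association from a 2x2 allele table
#'
#' Odds ratio as the exact cross-ratio of the allele-count table, Wald
#' 95% CI on the log scale (`z = 1.959964`), and a Pearson chi-square
#' (1 df) p-value on the uncorrected table. When any cell is zero, 0.5
#' is added to every cell (Haldane-Anscombe) for the OR and CI only;
#' the chi-square keeps the raw table.
#'
#' @param case_minor,case_major minor/major allele counts in cases.
#' @param ctrl_minor,ctrl_major minor/major allele counts in controls.
#' @return list with `or_`, `ci_low`, `ci_high`, `p`, `chi2`, `model`
#'   (`"allelic"`), `n_cases`, `n_controls` (individuals, allele
#'   counts / 2).
#' @export
allelic_assoc <- function(case_minor, case_major, ctrl_minor, ctrl_major) {
  cnt <- c(case_minor, case_major, ctrl_minor, ctrl_major)
  stopifnot(all(cnt >= 0))
  if (case_minor + case_major == 0 || ctrl_minor + ctrl_major == 0)
    stop("a zero row total leaves the allelic test undefined")
  if (case_minor + ctrl_minor == 0 || case_major + ctrl_major == 0)
    stop("a zero column total leaves the allelic test undefined")
  tab <- matrix(cnt, nrow = 2, byrow = TRUE)
  chi2 <- chi2_2x2(tab)
  p <- chi2_upper_tail_p(chi2, 1L)
  w <- if (any(cnt == 0)) cnt + 0.5 else cnt
  log_or <- log(w[1]) - log(w[2]) - log(w[3]) + log(w[4])
  se <- sqrt(sum(1 / w))
  z <- 1.959964
  list(or_ = exp(log_or), ci_low = exp(log_or - z * se),
       ci_high = exp(log_or + z * se), p = p, chi2 = chi2,
       model = "allelic",
       n_cases = (case_minor + case_major) / 2,
       n_controls = (ctrl_minor + ctrl_major) / 2)
}

#' Additive logistic regression for one marker
#'
#' Maximum-likelihood logistic fit (IRLS via [stats::glm()]) of
#' case/control status on the additive genotype (0/1/2 copies of the
#' counted allele), optionally adjusted for sex, centered age and
#' epsilon4-carrier status. Complete cases on the included covariates;
#' Wald CI and p-value for the marker effect.
#'
#' @param dataset a [genotype_dataset()].
#' @param marker marker rsID.
#' @param covariates subset of `c("sex", "age", "e4_carrier")`.
#' @param e4_carrier logical per sample; required when `"e4_carrier"` is
#'   among `covariates`. Typically `apoe_calls(dataset)$e4_carrier`.
#' @return list as in [allelic_assoc()] with `model =
#'   "logistic_additive"` and `beta`, `se` for the marker term.
#' @export
logistic_additive <- function(dataset, marker, covariates = character(0),
                              e4_carrier = NULL) {
  stopifnot(all(covariates %in% c("sex", "age", "e4_carrier")))
  df <- data.frame(
    y = ifelse(dataset$samples$phenotype == "case", 1L, 0L),
    g = dataset$calls[, marker_index(dataset, marker)])
  if ("sex" %in% covariates)
    df$sex <- factor(dataset$samples$sex, levels = c("F", "M"))
  if ("age" %in% covariates) {
    age <- dataset$samples$age
    df$age <- age - mean(age, na.rm = TRUE)   # centered before fitting
  }
  if ("e4_carrier" %in% covariates) {
    if (is.null(e4_carrier))
      stop("e4_carrier vector required when adjusting for e4_carrier")
    df$e4_carrier <- as.logical(e4_carrier)
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (sum(df$y == 1L) < 10 || sum(df$y == 0L) < 10)
    stop("need at least 10 cases and 10 controls with complete data")
  fit <- stats::glm(y ~ ., family = stats::binomial(), data = df,
                    control = stats::glm.control(epsilon = 1e-8, maxit = 50))
  if (!fit$converged) stop("logistic fit did not converge")
  beta <- stats::coef(fit)
  if (any(abs(beta[-1]) > 15))
    stop("separation detected in logistic fit (|beta| > 15): ",
         paste(names(beta)[abs(beta) > 15], collapse = ", "))
  sm <- summary(fit)$coefficients
  b <- sm["g", "Estimate"]; se <- sm["g", "Std. Error"]
  z <- 1.959964
  list(or_ = exp(b), ci_low = exp(b - z * se), ci_high = exp(b + z * se),
       p = 2 * stats::pnorm(-abs(b / se)), model = "logistic_additive",
       beta = b, se = se,
       n_cases = sum(df$y == 1L), n_controls = sum(df$y == 0L))
}

#' Per-stratum allelic association
#'
#' Runs [allelic_assoc()] independently inside each APOE stratum
#' (`E2_CARRIER`, `E4_CARRIER`, `E3E3`); `EXCLUDED_E2E4` and
#' `UNASSIGNED` samples are omitted. Strata without both cases and
#' controls (or with a degenerate allele table) are skipped with a
#' warning.
#'
#' @param dataset a [genotype_dataset()].
#' @param marker marker rsID.
#' @param strata character per sample, as from [assign_strata()].
#' @return named list of [allelic_assoc()] results, one per analysable
#'   stratum.
#' @export
stratified_assoc <- function(dataset, marker, strata) {
  stopifnot(length(strata) == nrow(dataset$samples))
  g <- dataset$calls[, marker_index(dataset, marker)]
  ph <- dataset$samples$phenotype
  out <- list()
  for (s in c("E2_CARRIER", "E4_CARRIER", "E3E3")) {
    in_s <- !is.na(strata) & strata == s & !is.na(ph) & !is.na(g)
    ca <- in_s & ph == "case"; co <- in_s & ph == "control"
    if (!any(ca) || !any(co)) {
      warning("stratum ", s, " has no cases or no controls; skipped")
      next
    }
    res <- tryCatch(
      allelic_assoc(sum(g[ca]), 2 * sum(ca) - sum(g[ca]),
                    sum(g[co]), 2 * sum(co) - sum(g[co])),
      error = function(e) {
        warning("stratum ", s, " skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(res)) out[[s]] <- res
  }
  out
}
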