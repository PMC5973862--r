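#' Study effect from an odds ratio and its 95% confidence interval
#'
#' Converts a reported OR with 95% CI to a log-OR and standard error:
#' `se = (ln(ci_high) - ln(ci_low)) / (2 * 1.959964)`. This is the
#' standard back-calculation when only OR and CI are published.
#'
#' @param or_ odds ratio.
#' @param ci_low,ci_high 95% confidence bounds, `0 < ci_low <= or_ <=
#'   ci_high` and `ci_low < ci_high`.
#' @param label study name.
#' @return list with `label`, `log_or`, `se`.
#' @export
se_from_ci <- function(or_, ci_low, ci_high, label = NA_character_) {
  if (!is.finite(or_) || !is.finite(ci_low) || !is.finite(ci_high) ||
      or_ <= 0 || ci_low <= 0 || ci_high <= 0)
    stop("odds ratio and CI bounds must be positive and finite")
  if (ci_low > or_ || or_ > ci_high)
    stop("confidence bounds must bracket the odds ratio")
  if (ci_low >= ci_high)
    stop("degenerate confidence interval (ci_low >= ci_high)")
  list(label = label, log_or = log(or_),
       se = (log(ci_high) - log(ci_low)) / (2 * 1.959964))
}

effects_matrix <- function(effects) {
  stopifnot(length(effects) >= 1)
  th <- vapply(effects, function(e) e$log_or, numeric(1))
  se <- vapply(effects, function(e) e$se, numeric(1))
  if (any(!is.finite(th)) || any(se <= 0))
    stop("each study effect needs a finite log_or and se > 0")
  list(theta = th, se = se)
}

meta_result <- function(theta, se_pooled, q, q_p, i2, tau2, model, k) {
  z <- 1.959964
  list(pooled_or = exp(theta),
       ci_low = exp(theta - z * se_pooled),
       ci_high = exp(theta + z * se_pooled),
       p = 2 * stats::pnorm(-abs(theta / se_pooled)),
       q = q, q_p = q_p, i2 = i2, tau2 = tau2, model = model, k = k)
}

#' Fixed-effect (inverse-variance) pooling
#'
#' @param effects list of study effects from [se_from_ci()] (or any
#'   list of `list(log_or=, se=)`).
#' @return a meta-analysis result: `pooled_or`, `ci_low`, `ci_high`,
#'   `p`, `q`, `q_p`, `i2`, `tau2` (0 under the fixed model), `model`,
#'   `k`. Heterogeneity fields are `NA` for a single study.
#' @export
pool_fixed <- function(effects) {
  em <- effects_matrix(effects)
  w <- 1 / em$se^2
  theta <- sum(w * em$theta) / sum(w)
  k <- length(w)
  if (k >= 2) {
    het <- heterogeneity(effects)
    q <- het$q; q_p <- het$q_p; i2 <- het$i2
  } else {
    q <- NA_real_; q_p <- NA_real_; i2 <- NA_real_
  }
  meta_result(theta, 1 / sqrt(sum(w)), q, q_p, i2, 0, "fixed", k)
}

#' Cochran's Q, its p-value and I-squared
#'
#' `Q = sum w_i (theta_i - theta_fixed)^2` with inverse-variance weights;
#' `q_p` is the upper chi-square tail on `k - 1` df;
#' `I2 = max(0, (Q - (k-1)) / Q) * 100` percent (0 when Q = 0).
#'
#' @inheritParams pool_fixed
#' @return list with `q`, `q_p`, `i2`.
#' @export
heterogeneity <- function(effects) {
  em <- effects_matrix(effects)
  k <- length(em$se)
  if (k < 2) stop("heterogeneity requires at least 2 studies")
  w <- 1 / em$se^2
  theta <- sum(w * em$theta) / sum(w)
  q <- sum(w * (em$theta - theta)^2)
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) * 100 else 0
  list(q = q, q_p = chi2_upper_tail_p(q, k - 1), i2 = i2)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment estimate of the between-study variance
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with fixed
#' weights `w = 1/se^2`, then inverse-variance pooling with weights
#' `1 / (se^2 + tau2)`.
#'
#' @inheritParams pool_fixed
#' @return a meta-analysis result as in [pool_fixed()], `model =
#'   "random"`.
#' @export
pool_random_dl <- function(effects) {
  em <- effects_matrix(effects)
  k <- length(em$se)
  if (k < 2) stop("random-effects pooling requires at least 2 studies")
  w <- 1 / em$se^2
  het <- heterogeneity(effects)
  tau2 <- max(0, (het$q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (em$se^2 + tau2)
  theta <- sum(wr * em$theta) / sum(wr)
  meta_result(theta, 1 / sqrt(sum(wr)), het$q, het$q_p, het$i2, tau2,
              "random", k)
}

#' Meta-analysis with heterogeneity-driven model selection
#'
#' Pools by fixed-effect inverse variance unless heterogeneity is
#' significant — `I2 > 50` percent AND `q_p < 0.05` — in which case the
#' DerSimonian-Laird random-effects model is used.
#'
#' @inheritParams pool_fixed
#' @param i2_threshold,q_p_threshold the model-selection rule (defaults
#'   50 percent and 0.05).
#' @return a meta-analysis result labeled with the chosen `model`.
#' @export
meta_analyze <- function(effects, i2_threshold = 50, q_p_threshold = 0.05) {
  if (length(effects) < 2) return(pool_fixed(effects))
  het <- heterogeneity(effects)
  if (het$i2 > i2_threshold && het$q_p < q_p_threshold)
    pool_random_dl(effects)
  else
    pool_fixed(effects)
}

#' Read study effects from a table of OR and CI columns
#'
#' @param path TSV with header columns `label`, `or`, `ci_low`,
#'   `ci_high`; an optional `stratum` column splits the file into one
#'   effect list per stratum.
#' @return list of study effects, or a named list of such lists when a
#'   `stratum` column is present.
#' @export
read_study_effects <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("label", "or", "ci_low", "ci_high")
  if (!all(req %in% names(df)))
    stop("study-effect table needs columns: ", paste(req, collapse = ", "))
  to_effects <- function(d)
    lapply(seq_len(nrow(d)), function(i)
      se_from_ci(d$or[i], d$ci_low[i], d$ci_high[i], d$label[i]))
  if ("stratum" %in% names(df))
    lapply(split(df, df$stratum), to_effects)
  else
    to_effects(df)
}
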