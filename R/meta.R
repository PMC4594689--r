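#' @title Pooling engine: fixed-effect and random-effects meta-analysis
#' @description Internal helpers shared by the pooling front-ends.
#' @name meta-engine
#' @keywords internal
NULL

# Normalize 'effects' input: a single effect_estimate or a list of them.
as_effect_list <- function(effects) {
  if (inherits(effects, "effect_estimate")) effects <- list(effects)
  if (!is.list(effects) || length(effects) == 0L ||
      !all(vapply(effects, inherits, logical(1), "effect_estimate")))
    stop_validation("'effects' must be one or more effect_estimate objects")
  effects
}

effect_vectors <- function(effects) {
  list(theta = vapply(effects, `[[`, 0, "log_or"),
       se = vapply(effects, `[[`, 0, "se_log_or"),
       label = vapply(effects, `[[`, "", "label"))
}

new_meta_result <- function(snp, k, n_cases, n_controls, pooled_log_or,
                            pooled_se, z, het, tau_squared, model, weights,
                            labels, method = "inverse_variance") {
  z_stat <- pooled_log_or / pooled_se
  structure(
    list(snp = snp, k = k, n_cases = n_cases, n_controls = n_controls,
         pooled_log_or = pooled_log_or, pooled_se = pooled_se,
         pooled_or = exp(pooled_log_or),
         ci_low = exp(pooled_log_or - z * pooled_se),
         ci_high = exp(pooled_log_or + z * pooled_se),
         z_stat = z_stat,
         p_value = 2 * stats::pnorm(-abs(z_stat)),
         q_stat = het$q_stat, q_df = het$q_df, p_q = het$p_q,
         i_squared = het$i_squared,
         tau_squared = tau_squared, model = model,
         weights = stats::setNames(weights, labels),
         z = z, method = method),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("%s pooled OR (%s%s): %.2f (%.2f-%.2f), k = %d\n",
              x$model, x$method,
              if (!is.na(x$snp)) paste0(", ", x$snp) else "",
              x$pooled_or, x$ci_low, x$ci_high, x$k))
  cat(sprintf("  Z = %.2f, p = %s\n", x$z_stat, format_p(x$p_value)))
  if (!is.na(x$q_stat))
    cat(sprintf("  heterogeneity: Q = %.3f (df %d, p = %.3f), I2 = %.1f%%, tau2 = %.4f\n",
                x$q_stat, x$q_df, x$p_q, x$i_squared, x$tau_squared))
  invisible(x)
}

#' Format a p-value the way the summary tables print it
#'
#' Values below 1e-6 render as `"<10^-6"`; others in compact scientific
#' notation.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_p <- function(p) {
  ifelse(p < 1e-6, "<10^-6", formatC(p, format = "g", digits = 3))
}

#' Cochran's Q and the I-squared heterogeneity metric
#'
#' Q is the inverse-variance weighted sum of squared deviations of the study
#' log odds ratios from the fixed-effect pooled value; under homogeneity it
#' is chi-square with k - 1 degrees of freedom. I2 = max(0, (Q - df)/Q) * 100
#' expresses the share of total variability attributable to between-study
#' heterogeneity, in percent.
#'
#' @param effects One or more [effect_estimate()] objects (k >= 2).
#' @return A list of class `heterogeneity` with `q_stat`, `q_df`, `p_q`,
#'   `i_squared`.
#' @export
cochran_q <- function(effects) {
  effects <- as_effect_list(effects)
  k <- length(effects)
  if (k < 2L)
    stop_computation("heterogeneity undefined for fewer than two studies")
  ev <- effect_vectors(effects)
  w <- 1 / ev$se^2
  theta_bar <- sum(w * ev$theta) / sum(w)
  q <- sum(w * (ev$theta - theta_bar)^2)
  df <- k - 1L
  structure(
    list(q_stat = q, q_df = df,
         p_q = stats::pchisq(q, df = df, lower.tail = FALSE),
         i_squared = if (q > 0) max(0, (q - df) / q) * 100 else 0),
    class = "heterogeneity"
  )
}

no_heterogeneity <- function(k) {
  list(q_stat = NA_real_, q_df = as.integer(k - 1L), p_q = NA_real_,
       i_squared = NA_real_)
}

#' Fixed-effect inverse-variance pooling
#'
#' Weights each study by the reciprocal of its log-OR variance:
#' `w_i = 1/se_i^2`, pooled log OR = `sum(w * theta)/sum(w)`, pooled SE =
#' `1/sqrt(sum(w))`. The pooled effect is tested against zero with a
#' two-sided normal Z-test. Heterogeneity (Q, I2) is attached when k >= 2.
#'
#' @param effects One or more [effect_estimate()] objects.
#' @param z Normal quantile for confidence bounds (default 1.96).
#' @param snp Optional rsID carried into the result.
#' @param n_cases,n_controls Optional summed sample sizes carried through.
#' @return A `meta_result` with `model = "FEM"` and `tau_squared = 0`.
#' @export
fixed_effect_inverse_variance <- function(effects, z = 1.96, snp = NA_character_,
                                          n_cases = NA_integer_,
                                          n_controls = NA_integer_) {
  effects <- as_effect_list(effects)
  k <- length(effects)
  ev <- effect_vectors(effects)
  w <- 1 / ev$se^2
  pooled <- sum(w * ev$theta) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  het <- if (k >= 2L) cochran_q(effects) else no_heterogeneity(k)
  new_meta_result(snp, k, n_cases, n_controls, pooled, pooled_se, z, het,
                  tau_squared = 0, model = "FEM", weights = w,
                  labels = ev$label)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Estimates the between-study variance of true log odds ratios by the
#' moment method, `tau2 = max(0, (Q - df) / (sum(w) - sum(w^2)/sum(w)))`
#' with fixed-effect weights `w`, then pools with random-effects weights
#' `1/(se_i^2 + tau2)`. When Q <= df the estimate truncates to zero and the
#' result coincides with the fixed-effect pooling.
#'
#' @inheritParams fixed_effect_inverse_variance
#' @return A `meta_result` with `model = "REM"`.
#' @export
dersimonian_laird <- function(effects, z = 1.96, snp = NA_character_,
                              n_cases = NA_integer_, n_controls = NA_integer_) {
  effects <- as_effect_list(effects)
  k <- length(effects)
  if (k < 2L)
    stop_computation("random-effects pooling requires at least two studies")
  ev <- effect_vectors(effects)
  w <- 1 / ev$se^2
  het <- cochran_q(effects)
  tau2 <- max(0, (het$q_stat - het$q_df) / (sum(w) - sum(w^2) / sum(w)))
  w_star <- 1 / (ev$se^2 + tau2)
  pooled <- sum(w_star * ev$theta) / sum(w_star)
  pooled_se <- 1 / sqrt(sum(w_star))
  new_meta_result(snp, k, n_cases, n_controls, pooled, pooled_se, z, het,
                  tau_squared = tau2, model = "REM", weights = w_star,
                  labels = ev$label)
}

#' Mantel-Haenszel fixed-effect pooling of 2x2 allele tables
#'
#' Stratified odds-ratio estimator
#' `OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i)` over per-study allele
#' tables, with the Robins-Breslow-Greenland variance for its logarithm.
#' Requires genotype counts for every study; confidence-interval-only
#' studies must go through the inverse-variance path
#' ([fixed_effect_inverse_variance()]).
#'
#' @param tables A list of 2x2 matrices as produced by [allele_table()]
#'   (rows case/control, columns effect/other allele), or a list of
#'   [study_outcome()] objects all carrying genotype counts.
#' @inheritParams fixed_effect_inverse_variance
#' @return A `meta_result` with `model = "FEM"` and
#'   `method = "mantel_haenszel"`. Heterogeneity is computed from the
#'   per-table Woolf effects when k >= 2.
#' @export
mantel_haenszel <- function(tables, z = 1.96, snp = NA_character_,
                            n_cases = NA_integer_, n_controls = NA_integer_) {
  if (inherits(tables, "study_outcome")) tables <- list(tables)
  if (!is.list(tables) || length(tables) == 0L)
    stop_validation("'tables' must be a non-empty list")
  labels <- names(tables)
  if (all(vapply(tables, inherits, logical(1), "study_outcome"))) {
    missing <- vapply(tables, function(o)
      is.null(o$case_counts) || is.null(o$control_counts), logical(1))
    if (any(missing))
      stop_computation(sprintf(
        "Mantel-Haenszel requires genotype counts for every study; %s lack(s) them - use the inverse-variance fixed-effect path instead",
        paste(vapply(tables[missing], `[[`, "", "study_id"), collapse = ", ")))
    labels <- vapply(tables, `[[`, "", "study_id")
    tables <- lapply(tables, function(o)
      allele_table(o$case_counts, o$control_counts, o$orientation))
  }
  ok <- vapply(tables, function(t) is.matrix(t) && all(dim(t) == c(2L, 2L)),
               logical(1))
  if (!all(ok)) stop_validation("each table must be a 2x2 matrix")
  if (is.null(labels)) labels <- rep(NA_character_, length(tables))

  a <- vapply(tables, function(t) t[1, 1], 0)
  b <- vapply(tables, function(t) t[1, 2], 0)
  cc <- vapply(tables, function(t) t[2, 1], 0)
  d <- vapply(tables, function(t) t[2, 2], 0)
  n <- a + b + cc + d
  R <- a * d / n
  S <- b * cc / n
  if (sum(R) <= 0 || sum(S) <= 0)
    stop_computation("Mantel-Haenszel odds ratio not estimable (empty margins)")
  or_mh <- sum(R) / sum(S)
  P <- (a + d) / n
  Q <- (b + cc) / n
  var_log <- sum(P * R) / (2 * sum(R)^2) +
    sum(P * S + Q * R) / (2 * sum(R) * sum(S)) +
    sum(Q * S) / (2 * sum(S)^2)
  woolf <- mapply(function(ai, bi, ci, di, lab) {
    effect_estimate(log((ai * di) / (bi * ci)), sqrt(1/ai + 1/bi + 1/ci + 1/di),
                    source = "counts", z = z, label = lab)
  }, a, b, cc, d, labels, SIMPLIFY = FALSE)
  het <- if (length(tables) >= 2L) cochran_q(woolf)
         else no_heterogeneity(length(tables))
  new_meta_result(snp, length(tables), n_cases, n_controls, log(or_mh),
                  sqrt(var_log), z, het, tau_squared = 0, model = "FEM",
                  weights = S / sum(S), labels = labels,
                  method = "mantel_haenszel")
}

#' Heterogeneity-driven model selection
#'
#' The disjunctive rule used throughout: random effects when the Q-test
#' p-value falls below `pq_threshold` OR I-squared exceeds `i2_threshold`;
#' fixed effect otherwise. Either trigger alone selects the random-effects
#' model (a set can show I2 > 50% while its Q-test stays above 0.05 at
#' small k, and still calls for random effects).
#'
#' @param het A `heterogeneity` object from [cochran_q()] (or any list with
#'   `p_q` and `i_squared`).
#' @param pq_threshold Q-test significance threshold (default 0.05).
#' @param i2_threshold I-squared threshold in percent (default 50).
#' @return `"REM"` or `"FEM"`.
#' @export
select_model <- function(het, pq_threshold = 0.05, i2_threshold = 50) {
  if (is.na(het$p_q) || is.na(het$i_squared))
    stop_computation("heterogeneity must be computed before model selection")
  if (het$p_q < pq_threshold || het$i_squared > i2_threshold) "REM" else "FEM"
}

#' Pool all outcomes for one SNP
#'
#' End-to-end pooling for a single SNP's study set: extracts per-study
#' effects under the configured source policy, computes heterogeneity,
#' applies the model selector, and returns the selected model's result with
#' the other model's result attached as `attr(result, "alternate")` (the
#' two are routinely compared: conclusions should not hinge on the model).
#'
#' @param outcomes A `study_table` or list of [study_outcome()] objects,
#'   all for the same SNP.
#' @param effect_source `"reported"` (default: published OR/CI preferred,
#'   genotype counts as fallback) or `"counts"` (the reverse).
#' @param z Normal quantile for confidence bounds.
#' @param pq_threshold,i2_threshold Model-selection thresholds, see
#'   [select_model()].
#' @return A `meta_result` for the selected model; single-outcome input
#'   returns that study's effect as a degenerate pooled result, flagged via
#'   `attr(result, "single_study")`. Fewer than three outcomes raises a
#'   warning (the design calls for at least three studies per SNP), not an
#'   error.
#' @examples
#' pool_snp(il2ra_studies("rs706778"))
#' @export
pool_snp <- function(outcomes, effect_source = c("reported", "counts"),
                     z = 1.96, pq_threshold = 0.05, i2_threshold = 50) {
  effect_source <- match.arg(effect_source)
  if (inherits(outcomes, "study_outcome")) outcomes <- list(outcomes)
  if (!is.list(outcomes) || length(outcomes) == 0L ||
      !all(vapply(outcomes, inherits, logical(1), "study_outcome")))
    stop_validation("'outcomes' must be one or more study_outcome objects")
  snps <- unique(vapply(outcomes, `[[`, "", "snp"))
  if (length(snps) != 1L)
    stop_validation(sprintf("outcomes span multiple SNPs: %s",
                            paste(snps, collapse = ", ")))
  k <- length(outcomes)
  if (k < 3L)
    warning(sprintf("%s: only %d outcome(s); at least three studies per SNP are expected",
                    snps, k), call. = FALSE)
  n_cases <- sum(vapply(outcomes, `[[`, 0L, "n_cases"))
  n_controls <- sum(vapply(outcomes, `[[`, 0L, "n_controls"))
  effects <- lapply(outcomes, extract_effect, effect_source = effect_source, z = z)

  if (k == 1L) {
    res <- fixed_effect_inverse_variance(effects, z = z, snp = snps,
                                         n_cases = n_cases, n_controls = n_controls)
    attr(res, "single_study") <- TRUE
    return(res)
  }
  fem <- fixed_effect_inverse_variance(effects, z = z, snp = snps,
                                       n_cases = n_cases, n_controls = n_controls)
  rem <- dersimonian_laird(effects, z = z, snp = snps,
                           n_cases = n_cases, n_controls = n_controls)
  model <- select_model(fem, pq_threshold = pq_threshold,
                        i2_threshold = i2_threshold)
  res <- if (model == "REM") rem else fem
  attr(res, "alternate") <- if (model == "REM") fem else rem
  attr(res, "effects") <- effects
  res
}
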