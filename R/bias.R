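#' Egger's regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standardized effect `theta_i / se_i` on the
#' precision `1 / se_i`. In a symmetric funnel the intercept is zero; small-
#' study effects (e.g. publication bias) push it away from zero. The
#' intercept is tested against zero with a two-sided t-test on k - 2 degrees
#' of freedom.
#'
#' @param effects One or more [effect_estimate()] objects, k >= 3, with at
#'   least two distinct standard errors (a constant regressor leaves the
#'   design degenerate).
#' @return An object of class `egger_test`: `intercept`, `se`, `t_stat`,
#'   `df`, `p_value`, `slope`, `k`.
#' @export
egger_test <- function(effects) {
  effects <- as_effect_list(effects)
  k <- length(effects)
  if (k < 3L) stop_computation("Egger's test requires at least three studies")
  ev <- effect_vectors(effects)
  precision <- 1 / ev$se
  if (length(unique(signif(precision, 12))) < 2L)
    stop_computation("Egger's test degenerate: all standard errors identical")
  fit <- stats::lm(standardized ~ precision,
                   data = data.frame(standardized = ev$theta / ev$se,
                                     precision = precision))
  est <- summary(fit)$coefficients
  structure(
    list(intercept = est["(Intercept)", "Estimate"],
         se = est["(Intercept)", "Std. Error"],
         t_stat = est["(Intercept)", "t value"],
         df = k - 2L,
         p_value = est["(Intercept)", "Pr(>|t|)"],
         slope = est["precision", "Estimate"],
         k = k),
    class = "egger_test"
  )
}

#' @export
print.egger_test <- function(x, ...) {
  cat(sprintf("Egger's test: intercept %.4f (SE %.4f), t = %.3f on %d df, p = %.4f\n",
              x$intercept, x$se, x$t_stat, x$df, x$p_value))
  invisible(x)
}

#' Begg-Mazumdar rank-correlation test for publication bias
#'
#' Kendall rank correlation between the standardized effect deviates
#' `t_i = (theta_i - theta_bar) / sqrt(v_i - 1/sum(1/v))` (theta_bar the
#' inverse-variance pooled effect, `v_i = se_i^2`) and the variances `v_i`.
#' The normal approximation uses the Kendall score S with variance
#' `k(k-1)(2k+5)/18` (tie-corrected); by default a continuity correction of
#' one unit of S is applied, the behaviour of the "modified" variant of the
#' test as commonly implemented. The corrected variant is conservative at
#' small k; `continuity = FALSE` gives the nominally calibrated version.
#'
#' Studies whose conditional variance `v_i - 1/sum(1/v)` is non-positive
#' (possible with extreme weight concentration) have their deviate computed
#' with the absolute value and a warning.
#'
#' @param effects One or more [effect_estimate()] objects, k >= 3.
#' @param continuity Apply the continuity correction (default `TRUE`).
#' @return An object of class `begg_test`: `tau`, `s_statistic`, `z_stat`,
#'   `p_value`, `k`, `continuity`.
#' @export
begg_test <- function(effects, continuity = TRUE) {
  effects <- as_effect_list(effects)
  k <- length(effects)
  if (k < 3L) stop_computation("Begg's test requires at least three studies")
  ev <- effect_vectors(effects)
  v <- ev$se^2
  w <- 1 / v
  theta_bar <- sum(w * ev$theta) / sum(w)
  v_cond <- v - 1 / sum(w)
  if (any(v_cond <= 0)) {
    warning("non-positive conditional variance for some study; using its absolute value",
            call. = FALSE)
    v_cond <- abs(v_cond)
  }
  t_dev <- (ev$theta - theta_bar) / sqrt(v_cond)

  pairs <- utils::combn(k, 2L)
  signs <- sign((t_dev[pairs[2L, ]] - t_dev[pairs[1L, ]]) *
                  (v[pairs[2L, ]] - v[pairs[1L, ]]))
  s_stat <- sum(signs)
  tie_term <- function(x) {
    m <- table(x)
    m <- m[m > 1L]
    if (length(m) == 0L) 0 else sum(m * (m - 1) * (2 * m + 5))
  }
  var_s <- (k * (k - 1) * (2 * k + 5) - tie_term(t_dev) - tie_term(v)) / 18
  tau <- s_stat / (k * (k - 1) / 2)
  z_stat <- if (s_stat == 0L || var_s <= 0) 0
            else (s_stat - if (continuity) sign(s_stat) else 0) / sqrt(var_s)
  structure(
    list(tau = tau, s_statistic = s_stat, z_stat = z_stat,
         p_value = min(1, 2 * stats::pnorm(-abs(z_stat))),
         k = k, continuity = continuity),
    class = "begg_test"
  )
}

#' @export
print.begg_test <- function(x, ...) {
  cat(sprintf("Begg-Mazumdar test: Kendall tau %.3f (S = %d), z = %.3f, p = %.4f%s\n",
              x$tau, x$s_statistic, x$z_stat, x$p_value,
              if (x$continuity) " (continuity-corrected)" else ""))
  invisible(x)
}

#' Publication-bias report for one SNP's study set
#'
#' Runs both funnel-asymmetry tests on the effects extracted from a study
#' set.
#'
#' @param outcomes A `study_table` or list of [study_outcome()] objects for
#'   one SNP, k >= 3.
#' @inheritParams pool_snp
#' @param continuity Continuity correction for the Begg test.
#' @return An object of class `bias_report` holding `snp`, `k`, the Egger
#'   intercept/SE/p, and the Begg tau/z/p.
#' @examples
#' bias_report(il2ra_studies("rs11594656"))
#' @export
bias_report <- function(outcomes, effect_source = c("reported", "counts"),
                        z = 1.96, continuity = TRUE) {
  effect_source <- match.arg(effect_source)
  if (inherits(outcomes, "study_outcome")) outcomes <- list(outcomes)
  snp <- unique(vapply(outcomes, `[[`, "", "snp"))
  if (length(snp) != 1L)
    stop_validation("outcomes span multiple SNPs")
  effects <- lapply(outcomes, extract_effect, effect_source = effect_source, z = z)
  egger <- egger_test(effects)
  begg <- begg_test(effects, continuity = continuity)
  structure(
    list(snp = snp, k = length(effects),
         egger_intercept = egger$intercept, egger_se = egger$se,
         egger_p = egger$p_value,
         begg_tau = begg$tau, begg_z = begg$z_stat, begg_p = begg$p_value,
         egger = egger, begg = begg),
    class = "bias_report"
  )
}

#' @export
print.bias_report <- function(x, ...) {
  cat(sprintf("publication bias, %s (k = %d):\n", x$snp, x$k))
  print(x$egger)
  print(x$begg)
  invisible(x)
}

#' Funnel-plot data for one SNP's study set
#'
#' Emits the numeric content of a funnel plot (no rendering): per-study log
#' odds ratio and standard error, plus pseudo-confidence guide lines around
#' the fixed-effect pooled value over a standard-error grid.
#'
#' @inheritParams bias_report
#' @return A data frame with columns `study`, `log_or`, `se`; the guide
#'   lines are attached as `attr(x, "guides")` (columns `se`, `lower`,
#'   `upper`, centred on the pooled log OR).
#' @export
funnel_data <- function(outcomes, effect_source = c("reported", "counts"),
                        z = 1.96) {
  effect_source <- match.arg(effect_source)
  if (inherits(outcomes, "study_outcome")) outcomes <- list(outcomes)
  effects <- lapply(outcomes, extract_effect, effect_source = effect_source, z = z)
  ev <- effect_vectors(effects)
  pooled <- fixed_effect_inverse_variance(effects, z = z)
  df <- data.frame(study = ev$label, log_or = ev$theta, se = ev$se,
                   stringsAsFactors = FALSE)
  se_grid <- seq(0, max(ev$se) * 1.05, length.out = 50L)
  attr(df, "guides") <- data.frame(
    se = se_grid,
    lower = pooled$pooled_log_or - z * se_grid,
    upper = pooled$pooled_log_or + z * se_grid)
  df
}
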