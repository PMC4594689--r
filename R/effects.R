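#' Construct an effect estimate on the log odds-ratio scale
#'
#' The unit every pooling routine consumes: a log odds ratio with its
#' standard error, plus the odds-ratio point estimate and confidence bounds
#' implied by the configured normal quantile.
#'
#' @param log_or Log odds ratio.
#' @param se_log_or Standard error of the log odds ratio; finite and > 0.
#' @param source `"counts"` (Woolf, from genotype data) or `"reported_ci"`
#'   (back-derived from a published OR and CI).
#' @param z Normal quantile used for the confidence bounds. 1.96 by default:
#'   the published tables reproduce exactly under the two-decimal quantile.
#' @param label Optional study label carried through to weight tables.
#' @return An object of class `effect_estimate`.
#' @export
effect_estimate <- function(log_or, se_log_or, source = c("counts", "reported_ci"),
                            z = 1.96, label = NA_character_) {
  source <- match.arg(source)
  if (!is.finite(log_or)) stop_validation("log_or must be finite")
  if (!is.finite(se_log_or) || se_log_or <= 0)
    stop_validation("se_log_or must be finite and > 0")
  structure(
    list(log_or = log_or, se_log_or = se_log_or, source = source,
         or_point = exp(log_or),
         ci_low = exp(log_or - z * se_log_or),
         ci_high = exp(log_or + z * se_log_or),
         z = z, label = label),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("OR %.3f (%.3f-%.3f), log OR %.4f (SE %.4f), source: %s\n",
              x$or_point, x$ci_low, x$ci_high, x$log_or, x$se_log_or, x$source))
  invisible(x)
}

#' Allele-level 2x2 table from case and control genotype counts
#'
#' Each individual contributes two alleles, so the table counts
#' `2 * n_major_hom + n_het` major and `n_het + 2 * n_minor_hom` minor
#' alleles per sample. The effect allele (first column) is the minor allele
#' under the default orientation; `orientation = "major"` flips the contrast.
#'
#' @param case,control [genotype_counts()] for cases and controls.
#' @param orientation `"minor"` (default) or `"major"`: which allele is
#'   treated as the effect allele.
#' @return A 2x2 integer matrix, rows `case`/`control`, columns
#'   `effect`/`other`.
#' @export
allele_table <- function(case, control, orientation = c("minor", "major")) {
  orientation <- match.arg(orientation)
  for (gc in list(case, control)) {
    if (!inherits(gc, "genotype_counts"))
      stop_validation("'case' and 'control' must be genotype_counts objects")
    if (gc$total <= 0L)
      stop_computation("allele table undefined for zero genotype total")
  }
  minor <- function(gc) gc$n_het + 2 * gc$n_minor_hom
  major <- function(gc) 2 * gc$n_major_hom + gc$n_het
  if (orientation == "minor") {
    tab <- c(minor(case), major(case), minor(control), major(control))
  } else {
    tab <- c(major(case), minor(case), major(control), minor(control))
  }
  matrix(tab, nrow = 2, byrow = TRUE,
         dimnames = list(c("case", "control"), c("effect", "other")))
}

#' Allelic odds ratio from genotype counts (Woolf method)
#'
#' Builds the allele-level 2x2 table and computes the effect-allele odds
#' ratio with the Woolf standard error, `sqrt(1/a + 1/b + 1/c + 1/d)`. When
#' any cell is zero, 0.5 is added to all four cells (Haldane-Anscombe
#' continuity correction, signalled as a warning); with two or more zero
#' cells the effect is not estimable and an error is raised.
#'
#' @inheritParams allele_table
#' @param z Normal quantile for the confidence bounds.
#' @param label Optional study label.
#' @return An [effect_estimate()] with `source = "counts"`.
#' @examples
#' effect_from_counts(genotype_counts(273, 155, 17), genotype_counts(373, 248, 50))
#' @export
effect_from_counts <- function(case, control, orientation = c("minor", "major"),
                               z = 1.96, label = NA_character_) {
  tab <- allele_table(case, control, orientation)
  if (sum(tab == 0) >= 2L)
    stop_computation("allelic odds ratio not estimable: two or more empty cells in the 2x2 allele table")
  if (any(tab == 0)) {
    warning("zero cell in allele table: adding 0.5 to all four cells (continuity correction)",
            call. = FALSE)
    tab <- tab + 0.5
  }
  log_or <- log((tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]))
  se <- sqrt(sum(1 / tab))
  effect_estimate(log_or, se, source = "counts", z = z, label = label)
}

#' Effect estimate from a reported odds ratio and confidence interval
#'
#' Recovers the log odds ratio and its standard error from a published point
#' estimate with confidence bounds:
#' `se = (log(ci_high) - log(ci_low)) / (2 * z)`. For the default 95% level
#' the quantile is fixed at 1.96 rather than `qnorm(0.975)`; published
#' tables round to two decimals and reproduce under the rounded quantile.
#'
#' @param or_point Reported odds ratio, strictly inside the interval.
#' @param ci_low,ci_high Positive confidence bounds, `ci_low < ci_high`.
#' @param level Confidence level of the reported interval, in (0, 1).
#' @param z Normal quantile; defaults to 1.96 at level 0.95 and
#'   `qnorm(1 - (1 - level)/2)` otherwise.
#' @param label Optional study label.
#' @return An [effect_estimate()] with `source = "reported_ci"`.
#' @examples
#' effect_from_ci(0.65, 0.59, 0.71)
#' @export
effect_from_ci <- function(or_point, ci_low, ci_high, level = 0.95, z = NULL,
                           label = NA_character_) {
  if (!is.finite(level) || level <= 0 || level >= 1)
    stop_validation("'level' must lie strictly in (0, 1)")
  if (anyNA(c(or_point, ci_low, ci_high)) ||
      any(c(or_point, ci_low, ci_high) <= 0))
    stop_validation("odds ratio and confidence bounds must be positive")
  if (ci_low >= ci_high)
    stop_validation("inverted confidence bounds: ci_low must be < ci_high")
  if (or_point <= ci_low || or_point >= ci_high)
    stop_validation("reported OR must lie strictly inside its confidence interval")
  if (is.null(z)) z <- if (identical(level, 0.95)) 1.96 else stats::qnorm(1 - (1 - level) / 2)
  se <- (log(ci_high) - log(ci_low)) / (2 * z)
  effect_estimate(log(or_point), se, source = "reported_ci", z = z, label = label)
}

#' Extract the pooling effect from one study outcome
#'
#' Applies the effect-source policy. The default prefers the reported OR/CI
#' when present, falling back to genotype counts: several published ORs are
#' not the Woolf allelic ORs of their printed counts (the source studies
#' adjusted or used other denominators), and the published pooled results
#' combine the printed values. `"counts"` prefers genotype-derived Woolf
#' effects and falls back to the reported CI.
#'
#' @param outcome A [study_outcome()].
#' @param effect_source `"reported"` or `"counts"`.
#' @param z Normal quantile for confidence bounds.
#' @return An [effect_estimate()].
#' @export
extract_effect <- function(outcome, effect_source = c("reported", "counts"),
                           z = 1.96) {
  effect_source <- match.arg(effect_source)
  has_counts <- !is.null(outcome$case_counts) && !is.null(outcome$control_counts)
  has_reported <- !is.na(outcome$reported_or) && !is.na(outcome$ci_low) &&
    !is.na(outcome$ci_high)
  label <- outcome$study_id
  from_counts <- function() effect_from_counts(outcome$case_counts, outcome$control_counts,
                                               orientation = outcome$orientation,
                                               z = z, label = label)
  from_ci <- function() effect_from_ci(outcome$reported_or, outcome$ci_low,
                                       outcome$ci_high, z = z, label = label)
  if (effect_source == "reported") {
    if (has_reported) from_ci() else if (has_counts) from_counts()
    else stop_validation(sprintf("study '%s': no usable effect data", label))
  } else {
    if (has_counts) from_counts() else if (has_reported) from_ci()
    else stop_validation(sprintf("study '%s': no usable effect data", label))
  }
}
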