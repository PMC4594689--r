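#' Power of the two-sided Z-test at an alternative odds ratio
#'
#' Probability that a two-sided level-`alpha` Z-test on the log odds ratio
#' with standard error `se` rejects when the true odds ratio is `or_alt`:
#' `pnorm(-z_a + |log(or_alt)|/se) + pnorm(-z_a - |log(or_alt)|/se)` with
#' `z_a = qnorm(1 - alpha/2)`. At `or_alt = 1` this reduces to the size of
#' the test, `alpha`.
#'
#' @param se Standard error of the log odds ratio, > 0.
#' @param or_alt Alternative odds ratio, > 0.
#' @param alpha Two-sided significance level, strictly in (0, 1).
#' @return Power in `[0, 1]`.
#' @export
power_at_alternative <- function(se, or_alt, alpha) {
  if (!is.finite(se) || se <= 0) stop_validation("'se' must be finite and > 0")
  if (!is.finite(or_alt) || or_alt <= 0)
    stop_validation("'or_alt' must be a positive odds ratio")
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop_validation("'alpha' must lie strictly in (0, 1)")
  z_a <- stats::qnorm(1 - alpha / 2)
  shift <- abs(log(or_alt)) / se
  stats::pnorm(-z_a + shift) + stats::pnorm(-z_a - shift)
}

#' False-positive report probability
#'
#' The Wacholder false-positive report probability: given an observed
#' significance level `alpha`, the test's `power` against the alternative of
#' interest, and a `prior` probability that the association is real,
#'
#' `FPRP = alpha * (1 - prior) / (alpha * (1 - prior) + power * prior)`.
#'
#' It is the posterior probability that a "significant" finding is a false
#' positive. Zero power with a positive `alpha` makes the association
#' unprovable and returns 1.
#'
#' @param alpha Observed p-value or significance level, in (0, 1].
#' @param power Power against the alternative, in `[0, 1]`.
#' @param prior Prior probability of a true association, in (0, 1).
#' @return FPRP in `[0, 1]`.
#' @examples
#' fprp_value(0.05, power = 1, prior = 0.5)  # 0.025/0.525
#' @export
fprp_value <- function(alpha, power, prior) {
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop_validation("'alpha' must lie in (0, 1]")
  if (!is.finite(power) || power < 0 || power > 1)
    stop_validation("'power' must lie in [0, 1]")
  if (!is.finite(prior) || prior <= 0 || prior >= 1)
    stop_validation("'prior' must lie strictly in (0, 1)")
  if (power == 0) return(1)
  num <- alpha * (1 - prior)
  num / (num + power * prior)
}

#' FPRP grid for a pooled association
#'
#' Evaluates the false-positive report probability of a pooled result over a
#' grid of prior probabilities and alternative odds ratios, using the pooled
#' estimate's observed two-sided p-value as `alpha` and the pooled standard
#' error to compute power at each alternative. Cells below the
#' noteworthiness threshold mark findings unlikely to be false positives
#' even under sceptical priors.
#'
#' @param meta A `meta_result` (e.g. from [pool_snp()]).
#' @param priors Prior probabilities of true association, each in (0, 1).
#'   The default spans the conventional sceptical range.
#' @param alternatives Alternative odds ratios at which power is evaluated;
#'   defaults to 1.2 and 1.5 plus the observed pooled OR (rounded to 2 dp).
#' @param noteworthy_threshold FPRP below which a cell is flagged
#'   noteworthy (default 0.2).
#' @param alpha Override for the significance level; defaults to the pooled
#'   result's observed two-sided p-value.
#' @return An object of class `fprp_grid`: `alpha`, `priors`,
#'   `alternatives`, `power` (per alternative), `fprp` (matrix, rows =
#'   alternatives, columns = priors), `noteworthy` (logical matrix),
#'   `noteworthy_threshold`, `snp`.
#' @export
fprp_report <- function(meta, priors = c(0.25, 0.1, 0.01, 1e-3, 1e-4, 1e-5),
                        alternatives = NULL, noteworthy_threshold = 0.2,
                        alpha = NULL) {
  if (!inherits(meta, "meta_result"))
    stop_validation("'meta' must be a meta_result")
  if (length(priors) == 0L)
    stop_validation("'priors' must be a non-empty list of prior probabilities")
  if (any(!is.finite(priors) | priors <= 0 | priors >= 1))
    stop_validation("each prior must lie strictly in (0, 1)")
  if (is.null(alpha)) alpha <- meta$p_value
  if (!is.finite(alpha) || alpha <= 0)
    alpha <- .Machine$double.xmin  # p underflow: keep the grid defined
  if (is.null(alternatives))
    alternatives <- sort(unique(c(1.2, 1.5, round(meta$pooled_or, 2))))
  power <- vapply(alternatives, function(or_alt)
    power_at_alternative(meta$pooled_se, or_alt, min(alpha, 1)), 0)
  grid <- outer(power, priors,
                Vectorize(function(pw, pr) fprp_value(min(alpha, 1), pw, pr)))
  dimnames(grid) <- list(paste0("OR_", formatC(alternatives, format = "g")),
                         formatC(priors, format = "g"))
  structure(
    list(alpha = alpha, priors = priors, alternatives = alternatives,
         power = stats::setNames(power, rownames(grid)),
         fprp = grid, noteworthy = grid < noteworthy_threshold,
         noteworthy_threshold = noteworthy_threshold, snp = meta$snp),
    class = "fprp_grid"
  )
}

#' @export
print.fprp_grid <- function(x, ...) {
  cat(sprintf("FPRP grid%s: alpha = %.3g, noteworthy when < %.2f\n",
              if (!is.na(x$snp)) paste0(" for ", x$snp) else "",
              x$alpha, x$noteworthy_threshold))
  print(signif(x$fprp, 3))
  invisible(x)
}
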