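#' Leave-one-out influence analysis
#'
#' Repeats the pooled analysis sequentially excluding one study outcome at a
#' time, re-applying the heterogeneity-driven model selector to each reduced
#' set, and flags omissions that change the selected model or flip the
#' significance of the pooled estimate (the 95% CI crossing 1 in exactly one
#' of the full and reduced analyses).
#'
#' @param outcomes A `study_table` or list of [study_outcome()] objects for
#'   one SNP; at least three, so each reduced set still supports
#'   heterogeneity estimation.
#' @inheritParams pool_snp
#' @return An object of class `influence_table`: a list with the `full`
#'   pooled `meta_result` and one row per omitted outcome (`omitted_study`,
#'   `result`, `model_changed`, `significance_changed`), in input order.
#'   `as.data.frame()` gives the flat table.
#' @examples
#' leave_one_out(il2ra_studies("rs2104286"))
#' @export
leave_one_out <- function(outcomes, effect_source = c("reported", "counts"),
                          z = 1.96, pq_threshold = 0.05, i2_threshold = 50) {
  effect_source <- match.arg(effect_source)
  if (inherits(outcomes, "study_outcome")) outcomes <- list(outcomes)
  k <- length(outcomes)
  if (k < 3L)
    stop_computation("leave-one-out analysis requires at least three outcomes")
  pool_quiet <- function(o) suppress_small_k(
    pool_snp(o, effect_source = effect_source, z = z,
             pq_threshold = pq_threshold, i2_threshold = i2_threshold))
  full <- pool_quiet(outcomes)
  crosses_one <- function(res) res$ci_low < 1 && res$ci_high > 1
  rows <- lapply(seq_len(k), function(i) {
    reduced <- pool_quiet(outcomes[-i])
    list(omitted_study = outcomes[[i]]$study_id,
         result = reduced,
         model_changed = !identical(reduced$model, full$model),
         significance_changed = xor(crosses_one(reduced), crosses_one(full)))
  })
  structure(list(full = full, rows = rows), class = "influence_table")
}

# Leave-one-out and sensitivity scans legitimately pool k < 3 subsets;
# muffle only the small-k advisory, keep everything else.
suppress_small_k <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("at least three studies", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

#' @export
as.data.frame.influence_table <- function(x, ...) {
  do.call(rbind, lapply(x$rows, function(r) {
    data.frame(omitted = r$omitted_study,
               k = r$result$k,
               model = r$result$model,
               or = r$result$pooled_or,
               ci_low = r$result$ci_low,
               ci_high = r$result$ci_high,
               i_squared = r$result$i_squared,
               p_q = r$result$p_q,
               model_changed = r$model_changed,
               significance_changed = r$significance_changed,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.influence_table <- function(x, ...) {
  cat(sprintf("leave-one-out influence, %s (full: %s OR %.2f [%.2f-%.2f], k = %d)\n",
              x$full$snp, x$full$model, x$full$pooled_or, x$full$ci_low,
              x$full$ci_high, x$full$k))
  print(format(as.data.frame(x), digits = 3), row.names = FALSE)
  invisible(x)
}

#' Heterogeneity-targeted sensitivity scan
#'
#' When the full study set triggers the heterogeneity rule (Q-test p below
#' threshold or I-squared above threshold), scans all single omissions for
#' ones that de-trigger both rules, identifies the omission that most
#' reduces residual heterogeneity, and reports its pooled result. A
#' homogeneous full set yields an empty report (a no-op, not an error).
#'
#' @inheritParams leave_one_out
#' @return An object of class `sensitivity_report` with fields `triggered`
#'   (did the full set fire the heterogeneity rule), `candidates`
#'   (data frame of de-triggering omissions), `primary` (label of the
#'   omission minimizing residual I-squared, then Q), `result` (the pooled
#'   `meta_result` after the primary omission) and `reduced_to_single`
#'   (flag set when omission from a two-outcome set leaves a single study,
#'   where heterogeneity is undefined).
#' @export
sensitivity_scan <- function(outcomes, effect_source = c("reported", "counts"),
                             z = 1.96, pq_threshold = 0.05, i2_threshold = 50) {
  effect_source <- match.arg(effect_source)
  if (inherits(outcomes, "study_outcome")) outcomes <- list(outcomes)
  k <- length(outcomes)
  if (k < 2L)
    stop_computation("sensitivity scan requires at least two outcomes")
  pool_quiet <- function(o) suppress_small_k(
    pool_snp(o, effect_source = effect_source, z = z,
             pq_threshold = pq_threshold, i2_threshold = i2_threshold))
  full <- pool_quiet(outcomes)
  triggered <- full$p_q < pq_threshold || full$i_squared > i2_threshold
  empty <- structure(list(triggered = triggered, candidates = NULL,
                          primary = NULL, result = NULL,
                          reduced_to_single = FALSE, full = full),
                     class = "sensitivity_report")
  if (!triggered) return(empty)

  if (k == 2L) {
    # Any omission leaves one study: no heterogeneity is computable, so the
    # "source" of discordance cannot be localized. Flag rather than guess.
    empty$reduced_to_single <- TRUE
    return(empty)
  }
  rows <- lapply(seq_len(k), function(i) {
    reduced <- pool_quiet(outcomes[-i])
    data.frame(omitted = outcomes[[i]]$study_id,
               q_stat = reduced$q_stat, p_q = reduced$p_q,
               i_squared = reduced$i_squared,
               detriggered = reduced$p_q >= pq_threshold &
                 reduced$i_squared <= i2_threshold,
               stringsAsFactors = FALSE)
  })
  scan <- do.call(rbind, rows)
  candidates <- scan[scan$detriggered, , drop = FALSE]
  if (nrow(candidates) == 0L) {
    empty$candidates <- candidates
    return(empty)
  }
  best <- candidates[order(candidates$i_squared, candidates$q_stat), ][1L, ]
  idx <- match(best$omitted, vapply(outcomes, `[[`, "", "study_id"))
  structure(list(triggered = TRUE, candidates = candidates,
                 primary = best$omitted,
                 result = pool_quiet(outcomes[-idx]),
                 reduced_to_single = FALSE, full = full),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  if (!x$triggered) {
    cat("no heterogeneity trigger on the full set; nothing to scan\n")
  } else if (x$reduced_to_single) {
    cat("heterogeneity triggered, but any omission from a two-study set leaves a single study\n")
  } else if (is.null(x$primary)) {
    cat("heterogeneity triggered; no single omission de-triggers it\n")
  } else {
    cat(sprintf("heterogeneity source: omitting '%s' de-triggers (reduced I2 = %.1f%%, p_Q = %.3f)\n",
                x$primary, x$result$i_squared, x$result$p_q))
    print(x$result)
  }
  invisible(x)
}
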