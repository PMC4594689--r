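#' @title Report drivers
#' @description End-to-end pipeline stages over a study table, each writing
#'   TSV + JSON result files plus a run manifest. These back the numbered
#'   scripts under `analysis/`.
#' @name report-drivers
#' @keywords internal
NULL

ensure_dir <- function(path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  path
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

write_manifest <- function(out_dir, step, config) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               null = "null")
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  manifest <- list(
    step = step,
    package = "il2rameta",
    package_version = as.character(utils::packageVersion("il2rameta")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    config_md5 = unname(tools::md5sum(tmp)))
  unlink(tmp)
  write_json(manifest, file.path(out_dir, sprintf("manifest_%s.json", step)))
}

read_outcomes <- function(input) {
  if (inherits(input, "study_table")) return(input)
  if (is.list(input) && all(vapply(input, inherits, logical(1), "study_outcome")))
    return(structure(input, class = "study_table"))
  suppressWarnings(parse_study_table(input))
}

filter_snps <- function(outcomes, snps) {
  available <- sort(unique(vapply(outcomes, `[[`, "", "snp")))
  if (is.null(snps)) return(outcomes)
  keep <- vapply(outcomes, function(o) o$snp %in% snps, logical(1))
  if (!any(keep))
    stop_validation(sprintf("SNP filter matched nothing; available SNPs: %s",
                            paste(available, collapse = ", ")))
  structure(outcomes[keep], class = "study_table")
}

split_by_snp <- function(outcomes) {
  snps <- vapply(outcomes, `[[`, "", "snp")
  lapply(split(seq_along(outcomes), snps), function(idx)
    structure(outcomes[idx], class = "study_table"))
}

# HWE screen on controls (case HWE is informational only: case genotype
# frequencies legitimately depart from HWE under a true association).
hwe_screen <- function(outcomes) {
  status <- vapply(outcomes, function(o) {
    if (is.null(o$control_counts)) return(NA)
    hwe_test(o$control_counts, o$design)$passes
  }, logical(1))
  excluded <- which(!is.na(status) & !status)
  list(kept = structure(outcomes[setdiff(seq_along(outcomes), excluded)],
                        class = "study_table"),
       excluded = vapply(outcomes[excluded], function(o)
         sprintf("%s (%s)", o$study_id, o$snp), character(1)))
}

meta_result_row <- function(res) {
  data.frame(snp = res$snp, k_outcomes = res$k,
             n_cases = res$n_cases, n_controls = res$n_controls,
             i_squared = res$i_squared, p_q = res$p_q,
             tau_squared = res$tau_squared, model = res$model,
             or = res$pooled_or, ci_low = res$ci_low, ci_high = res$ci_high,
             z_stat = res$z_stat, p_value = res$p_value,
             p_label = format_p(res$p_value), stringsAsFactors = FALSE)
}

#' Pool every SNP in a study table and write the results
#'
#' Applies the HWE control screen, pools each SNP with at least two
#' outcomes under the heterogeneity-driven model selector, and writes the
#' pooled summary (one row per SNP), the per-study weight table, and
#' forest-plot data, each as TSV with a JSON twin, plus a run manifest.
#'
#' @param input Path to a study table, or a `study_table` object. Defaults
#'   to the packaged IL2RA/T1D table.
#' @param out_dir Output directory (created if needed).
#' @param snps Optional rsID filter.
#' @inheritParams pool_snp
#' @param hwe_screen Screen out outcomes whose control genotypes depart
#'   from HWE (default TRUE; no packaged outcome is excluded).
#' @return Named list of `meta_result`s, invisibly.
#' @export
run_pool <- function(input = il2ra_table_path(), out_dir = "results",
                     snps = NULL, effect_source = c("reported", "counts"),
                     z = 1.96, pq_threshold = 0.05, i2_threshold = 50,
                     hwe_screen = TRUE) {
  effect_source <- match.arg(effect_source)
  ensure_dir(out_dir)
  outcomes <- filter_snps(read_outcomes(input), snps)
  screened <- if (hwe_screen) hwe_screen(outcomes)
              else list(kept = outcomes, excluded = character(0))
  if (length(screened$excluded) > 0L)
    message("excluded by control HWE screen: ",
            paste(screened$excluded, collapse = ", "))
  groups <- split_by_snp(screened$kept)
  groups <- groups[vapply(groups, length, 0L) >= 2L]
  if (length(groups) == 0L)
    stop_validation("no SNP with at least two outcomes after screening")

  results <- lapply(groups, pool_snp, effect_source = effect_source, z = z,
                    pq_threshold = pq_threshold, i2_threshold = i2_threshold)
  pooled <- do.call(rbind, lapply(results, meta_result_row))
  weights <- do.call(rbind, lapply(results, function(res) {
    w <- res$weights
    data.frame(snp = res$snp, study = names(w), weight = unname(w),
               rel_weight = unname(w) / sum(w), stringsAsFactors = FALSE)
  }))
  forest <- do.call(rbind, lapply(results, function(res) {
    effs <- attr(res, "effects")
    if (is.null(effs)) return(NULL)
    ev <- effect_vectors(effs)
    data.frame(snp = res$snp, study = ev$label, log_or = ev$theta,
               se = ev$se, or = exp(ev$theta),
               ci_low = exp(ev$theta - z * ev$se),
               ci_high = exp(ev$theta + z * ev$se), stringsAsFactors = FALSE)
  }))
  write_tsv(pooled, file.path(out_dir, "pooled_results.tsv"))
  write_json(pooled, file.path(out_dir, "pooled_results.json"))
  write_tsv(weights, file.path(out_dir, "study_weights.tsv"))
  write_tsv(forest, file.path(out_dir, "forest_data.tsv"))
  write_manifest(out_dir, "pool",
                 list(input = if (is.character(input)) input else "in-memory",
                      snps = snps, effect_source = effect_source, z = z,
                      pq_threshold = pq_threshold, i2_threshold = i2_threshold,
                      hwe_screen = hwe_screen,
                      excluded = as.list(screened$excluded)))
  invisible(results)
}

#' Leave-one-out influence and sensitivity analysis for every eligible SNP
#'
#' @inheritParams run_pool
#' @return Named list with `influence` and `sensitivity` per SNP, invisibly.
#' @export
run_influence <- function(input = il2ra_table_path(), out_dir = "results",
                          snps = NULL, effect_source = c("reported", "counts"),
                          z = 1.96, pq_threshold = 0.05, i2_threshold = 50) {
  effect_source <- match.arg(effect_source)
  ensure_dir(out_dir)
  groups <- split_by_snp(filter_snps(read_outcomes(input), snps))
  groups <- groups[vapply(groups, length, 0L) >= 3L]
  if (length(groups) == 0L)
    stop_validation("no SNP with at least three outcomes")
  res <- lapply(groups, function(g) {
    list(influence = leave_one_out(g, effect_source = effect_source, z = z,
                                   pq_threshold = pq_threshold,
                                   i2_threshold = i2_threshold),
         sensitivity = sensitivity_scan(g, effect_source = effect_source, z = z,
                                        pq_threshold = pq_threshold,
                                        i2_threshold = i2_threshold))
  })
  influence_tab <- do.call(rbind, lapply(names(res), function(snp) {
    df <- as.data.frame(res[[snp]]$influence)
    cbind(snp = snp, df, stringsAsFactors = FALSE)
  }))
  write_tsv(influence_tab, file.path(out_dir, "influence.tsv"))
  write_json(influence_tab, file.path(out_dir, "influence.json"))
  sens <- lapply(res, function(r) {
    s <- r$sensitivity
    list(triggered = s$triggered, primary = s$primary,
         reduced_to_single = s$reduced_to_single,
         detriggered_result = if (!is.null(s$result)) meta_result_row(s$result))
  })
  write_json(sens, file.path(out_dir, "sensitivity.json"))
  write_manifest(out_dir, "influence",
                 list(input = if (is.character(input)) input else "in-memory",
                      snps = snps, effect_source = effect_source, z = z,
                      pq_threshold = pq_threshold, i2_threshold = i2_threshold))
  invisible(res)
}

#' Publication-bias tests and funnel data for every eligible SNP
#'
#' @inheritParams run_pool
#' @param continuity Continuity correction for the Begg test.
#' @return Named list of `bias_report`s, invisibly.
#' @export
run_bias <- function(input = il2ra_table_path(), out_dir = "results",
                     snps = NULL, effect_source = c("reported", "counts"),
                     z = 1.96, continuity = TRUE) {
  effect_source <- match.arg(effect_source)
  ensure_dir(out_dir)
  groups <- split_by_snp(filter_snps(read_outcomes(input), snps))
  too_small <- names(groups)[vapply(groups, length, 0L) < 3L]
  groups <- groups[vapply(groups, length, 0L) >= 3L]
  if (length(groups) == 0L)
    stop_computation(sprintf(
      "publication-bias tests need at least three outcomes per SNP; none eligible (too small: %s)",
      paste(too_small, collapse = ", ")))
  reports <- lapply(groups, bias_report, effect_source = effect_source, z = z,
                    continuity = continuity)
  tab <- do.call(rbind, lapply(reports, function(r)
    data.frame(snp = r$snp, k = r$k, egger_intercept = r$egger_intercept,
               egger_se = r$egger_se, egger_p = r$egger_p,
               begg_tau = r$begg_tau, begg_z = r$begg_z, begg_p = r$begg_p,
               stringsAsFactors = FALSE)))
  write_tsv(tab, file.path(out_dir, "publication_bias.tsv"))
  write_json(tab, file.path(out_dir, "publication_bias.json"))
  funnel <- do.call(rbind, lapply(groups, function(g) {
    fd <- funnel_data(g, effect_source = effect_source, z = z)
    cbind(snp = g[[1L]]$snp, fd, stringsAsFactors = FALSE)
  }))
  write_tsv(funnel, file.path(out_dir, "funnel_data.tsv"))
  write_manifest(out_dir, "bias",
                 list(input = if (is.character(input)) input else "in-memory",
                      snps = snps, effect_source = effect_source, z = z,
                      continuity = continuity))
  invisible(reports)
}

#' FPRP grids for every pooled SNP
#'
#' @inheritParams run_pool
#' @inheritParams fprp_report
#' @return Named list of `fprp_grid`s, invisibly.
#' @export
run_fprp <- function(input = il2ra_table_path(), out_dir = "results",
                     snps = NULL, effect_source = c("reported", "counts"),
                     z = 1.96, priors = c(0.25, 0.1, 0.01, 1e-3, 1e-4, 1e-5),
                     alternatives = NULL, noteworthy_threshold = 0.2) {
  effect_source <- match.arg(effect_source)
  ensure_dir(out_dir)
  groups <- split_by_snp(filter_snps(read_outcomes(input), snps))
  groups <- groups[vapply(groups, length, 0L) >= 2L]
  if (length(groups) == 0L)
    stop_validation("no SNP with at least two outcomes")
  grids <- lapply(groups, function(g) {
    fprp_report(pool_snp(g, effect_source = effect_source, z = z),
                priors = priors, alternatives = alternatives,
                noteworthy_threshold = noteworthy_threshold)
  })
  for (snp in names(grids)) {
    g <- grids[[snp]]
    df <- data.frame(alternative_or = g$alternatives, power = unname(g$power),
                     g$fprp, check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df, file.path(out_dir, sprintf("fprp_%s.tsv", snp)))
  }
  write_json(lapply(grids, function(g)
    list(snp = g$snp, alpha = g$alpha, priors = g$priors,
         alternatives = g$alternatives, power = unname(g$power),
         fprp = apply(g$fprp, 1, as.list),
         noteworthy_threshold = g$noteworthy_threshold)),
    file.path(out_dir, "fprp.json"))
  write_manifest(out_dir, "fprp",
                 list(input = if (is.character(input)) input else "in-memory",
                      snps = snps, effect_source = effect_source, z = z,
                      priors = priors, alternatives = alternatives,
                      noteworthy_threshold = noteworthy_threshold))
  invisible(grids)
}

#' Simulate a study set and write it in the exchange format
#'
#' @param config A [simulation_config()] (set its `seed` for reproducible
#'   output).
#' @param out_dir Output directory.
#' @return The `simulated_study_set`, invisibly.
#' @export
run_simulate <- function(config, out_dir = "results") {
  ensure_dir(out_dir)
  sim <- simulate_study_set(config)
  write_study_table(sim$outcomes, file.path(out_dir, "simulated_studies.tsv"))
  write_json(list(true_or = sim$truth$true_or, tau = sim$truth$tau,
                  theta = sim$truth$theta, kept = sim$truth$kept),
             file.path(out_dir, "simulation_truth.json"))
  write_manifest(out_dir, "simulate", unclass(config))
  invisible(sim)
}
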