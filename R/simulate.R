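#' Configuration for the synthetic study-set generator
#'
#' Describes the sampling model the generator emulates: each study draws a
#' true log odds ratio from `Normal(log(true_or), tau^2)`, converts the
#' control effect-allele frequency `p0 = control_maf` to the case frequency
#' implied by a multiplicative allelic model,
#' `p1 = OR * p0 / (1 + p0 * (OR - 1))`, and samples genotypes multinomially
#' under Hardy-Weinberg proportions at `p0` (controls) and `p1` (cases).
#'
#' Defaults describe a typical mid-size candidate-gene replication set:
#' five studies of 1000 cases and 1000 controls each at control MAF 0.30,
#' homogeneous (`tau = 0`), null effect.
#'
#' @param true_or True allelic odds ratio (effect allele = minor).
#' @param control_maf Control minor-allele frequency, strictly in (0, 1).
#' @param n_cases,n_controls Per-study sample sizes; a single count or a
#'   range `c(min, max)` sampled log-uniformly per study.
#' @param k_studies Number of studies, >= 1.
#' @param tau Between-study SD of the true log odds ratio, >= 0.
#' @param reporting_mode `"counts"` (genotype counts retained), `"ci_only"`
#'   (counts replaced by the Woolf OR and 95% CI rounded to 2 decimals,
#'   emulating published summary-only rows), or `"mixed"` (alternating).
#' @param censor_z Optional small-study censoring rule: studies whose signed
#'   standardized effect `log(OR)/se` falls below this cutoff are suppressed
#'   with probability `censor_prob` — the one-sided file-drawer model, in
#'   which results short of "significance in the expected direction" go
#'   unpublished. `NULL` disables censoring.
#' @param censor_prob Suppression probability for sub-threshold studies.
#' @param censor_small_n Censoring applies only to studies whose smaller
#'   group is below this size (default `Inf`, all studies): large studies
#'   get published regardless, the size-dependence that tilts the funnel.
#' @param seed Integer seed; fixed seeds give byte-identical study tables.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(true_or = 1, control_maf = 0.3,
                              n_cases = 1000, n_controls = 1000,
                              k_studies = 5, tau = 0,
                              reporting_mode = c("counts", "ci_only", "mixed"),
                              censor_z = NULL, censor_prob = 1,
                              censor_small_n = Inf, seed = NULL) {
  reporting_mode <- match.arg(reporting_mode)
  if (!is.finite(true_or) || true_or <= 0)
    stop_validation("'true_or' must be a positive odds ratio")
  if (!is.finite(control_maf) || control_maf <= 0 || control_maf >= 1)
    stop_validation("'control_maf' must lie strictly in (0, 1)")
  for (nm in c("n_cases", "n_controls")) {
    n <- get(nm)
    if (!length(n) %in% 1:2 || any(!is.finite(n)) || any(n < 2))
      stop_validation(sprintf("'%s' must be a count or range of counts >= 2", nm))
  }
  if (!is.finite(k_studies) || k_studies < 1)
    stop_validation("'k_studies' must be >= 1")
  if (!is.finite(tau) || tau < 0)
    stop_validation("'tau' must be a non-negative between-study SD")
  if (!is.null(censor_z) && !is.finite(censor_z))
    stop_validation("'censor_z' must be NULL or a finite cutoff")
  if (!is.finite(censor_prob) || censor_prob < 0 || censor_prob > 1)
    stop_validation("'censor_prob' must lie in [0, 1]")
  if (is.na(censor_small_n) || censor_small_n <= 0)
    stop_validation("'censor_small_n' must be a positive size threshold")
  structure(
    list(true_or = true_or, control_maf = control_maf,
         n_cases = n_cases, n_controls = n_controls,
         k_studies = as.integer(k_studies), tau = tau,
         reporting_mode = reporting_mode, censor_z = censor_z,
         censor_prob = censor_prob, censor_small_n = censor_small_n,
         seed = seed),
    class = "simulation_config"
  )
}

draw_n <- function(n) {
  if (length(n) == 1L) return(as.integer(n))
  as.integer(round(exp(stats::runif(1, log(n[1]), log(n[2])))))
}

hwe_genotypes <- function(n, p) {
  probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  g <- as.vector(stats::rmultinom(1, n, probs))
  genotype_counts(g[1L], g[2L], g[3L])
}

#' Simulate a synthetic study set with known truth
#'
#' Generates `k_studies` case-control study outcomes under the model
#' described in [simulation_config()], returning both the outcomes (which
#' pass [study_outcome()] validation and can be written with
#' [write_study_table()]) and the generating truth for recovery scoring.
#'
#' Studies whose expected minor-allele count falls below 5 in either group
#' raise a sparse-data warning. With censoring enabled, suppressed studies
#' are dropped, so the returned set may hold fewer than `k_studies`
#' outcomes.
#'
#' @param config A [simulation_config()].
#' @return An object of class `simulated_study_set`: `outcomes` (a
#'   `study_table`), and `truth` (`true_or`, `tau`, per-study `theta`, the
#'   retained-study index `kept`).
#' @examples
#' sim <- simulate_study_set(simulation_config(true_or = 0.8, seed = 1))
#' pool_snp(sim$outcomes)
#' @export
simulate_study_set <- function(config) {
  if (!inherits(config, "simulation_config"))
    stop_validation("'config' must be a simulation_config")
  if (!is.null(config$seed)) set.seed(config$seed)
  k <- config$k_studies
  theta <- stats::rnorm(k, log(config$true_or), config$tau)
  p0 <- config$control_maf

  outcomes <- vector("list", k)
  kept <- logical(k)
  for (i in seq_len(k)) {
    or_i <- exp(theta[i])
    p1 <- or_i * p0 / (1 + p0 * (or_i - 1))
    nca <- draw_n(config$n_cases)
    nco <- draw_n(config$n_controls)
    if (min(2 * nca * p1, 2 * nco * p0) < 5)
      warning(sprintf("study %d: expected minor-allele count below 5 (sparse-data regime)", i),
              call. = FALSE)
    case_gc <- hwe_genotypes(nca, p1)
    control_gc <- hwe_genotypes(nco, p0)
    eff <- tryCatch(
      suppressWarnings(effect_from_counts(case_gc, control_gc)),
      il2rameta_computation_error = function(e) NULL)

    if (!is.null(config$censor_z) && min(nca, nco) < config$censor_small_n) {
      z_obs <- if (is.null(eff)) 0 else eff$log_or / eff$se_log_or
      if (z_obs < config$censor_z && stats::runif(1) < config$censor_prob) next
    }
    kept[i] <- TRUE

    report_ci <- config$reporting_mode == "ci_only" ||
      (config$reporting_mode == "mixed" && i %% 2L == 0L)
    if (report_ci && !is.null(eff)) {
      # Round as a journal table would; nudge precision up if rounding
      # collapses the point estimate onto a bound.
      digits <- 2L
      repeat {
        or_r <- round(eff$or_point, digits)
        lo_r <- round(eff$ci_low, digits)
        hi_r <- round(eff$ci_high, digits)
        if (lo_r < or_r && or_r < hi_r) break
        digits <- digits + 1L
        if (digits > 6L) { report_ci <- FALSE; break }
      }
    }
    outcomes[[i]] <- if (report_ci && !is.null(eff)) {
      study_outcome(study_id = sprintf("sim_%02d", i), year = 2020L,
                    country = "simulated", ancestry = "other",
                    snp = "rs_sim", design = "case_control",
                    reported_or = or_r, ci_low = lo_r, ci_high = hi_r,
                    n_cases = nca, n_controls = nco)
    } else {
      study_outcome(study_id = sprintf("sim_%02d", i), year = 2020L,
                    country = "simulated", ancestry = "other",
                    snp = "rs_sim", design = "case_control",
                    case_counts = case_gc, control_counts = control_gc,
                    n_cases = nca, n_controls = nco)
    }
  }
  structure(
    list(outcomes = structure(outcomes[kept], class = "study_table"),
         truth = list(true_or = config$true_or, tau = config$tau,
                      theta = theta, kept = which(kept)),
         config = config),
    class = "simulated_study_set"
  )
}

#' @export
print.simulated_study_set <- function(x, ...) {
  cat(sprintf("simulated study set: %d of %d studies retained, true OR %.3f, tau %.3f\n",
              length(x$outcomes), x$config$k_studies, x$truth$true_or, x$truth$tau))
  invisible(x)
}

#' Simulate a homogeneous null set for bias-test calibration
#'
#' A null (true OR 1), homogeneous (`tau = 0`), uncensored study set with
#' deliberately heterogeneous sample sizes: per-study counts follow a
#' geometric ladder from `n_min` to `n_max`, giving at least a three-fold
#' spread in standard errors (`n_max / n_min >= 9`) so the funnel-asymmetry
#' regressions have leverage. Used to check the type-I error of the Egger
#' and Begg tests.
#'
#' @param k_studies Number of studies (default 6).
#' @param control_maf Control minor-allele frequency.
#' @param n_min,n_max Smallest and largest per-study group size;
#'   `n_max / n_min` must be >= 9.
#' @param seed Integer seed.
#' @return A `simulated_study_set` (counts reporting mode).
#' @export
simulate_null_funnel <- function(k_studies = 6, control_maf = 0.3,
                                 n_min = 200, n_max = 1800, seed = NULL) {
  if (n_max / n_min < 9)
    stop_validation("'n_max'/'n_min' must be >= 9 for a >= 3-fold standard-error spread")
  if (!is.null(seed)) set.seed(seed)
  sizes <- round(exp(seq(log(n_min), log(n_max), length.out = k_studies)))
  outcomes <- vector("list", k_studies)
  for (i in seq_len(k_studies)) {
    case_gc <- hwe_genotypes(sizes[i], control_maf)
    control_gc <- hwe_genotypes(sizes[i], control_maf)
    outcomes[[i]] <- study_outcome(
      study_id = sprintf("null_%02d", i), year = 2020L, country = "simulated",
      ancestry = "other", snp = "rs_null", design = "case_control",
      case_counts = case_gc, control_counts = control_gc,
      n_cases = sizes[i], n_controls = sizes[i])
  }
  structure(
    list(outcomes = structure(outcomes, class = "study_table"),
         truth = list(true_or = 1, tau = 0,
                      theta = rep(0, k_studies), kept = seq_len(k_studies)),
         config = simulation_config(true_or = 1, control_maf = control_maf,
                                    n_cases = c(n_min, n_max),
                                    n_controls = c(n_min, n_max),
                                    k_studies = k_studies, seed = seed)),
    class = "simulated_study_set"
  )
}
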