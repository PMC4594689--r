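fixture_effects <- function(snp, effect_source = "reported") {
  lapply(il2ra_studies(snp), extract_effect, effect_source = effect_source)
}

test_that("fixed-effect pooling reproduces the published pooled odds ratios", {
  fem656 <- fixed_effect_inverse_variance(fixture_effects("rs11594656"))
  expect_equal(round(fem656$pooled_or, 2), 0.87)
  expect_equal(round(fem656$ci_low, 2), 0.83)
  expect_equal(round(fem656$ci_high, 2), 0.91)

  fem286 <- fixed_effect_inverse_variance(fixture_effects("rs2104286"))
  expect_equal(round(fem286$pooled_or, 2), 0.81)
  expect_equal(round(fem286$ci_low, 2), 0.77)
  expect_equal(round(fem286$ci_high, 2), 0.85)

  # a single effect pools to itself exactly
  single <- make_effect(0.8, 0.7, 0.9)
  pooled <- fixed_effect_inverse_variance(list(single))
  expect_equal(pooled$pooled_log_or, single$log_or)
  expect_equal(pooled$pooled_se, single$se_log_or)
  expect_error(fixed_effect_inverse_variance(list()),
               class = "il2rameta_validation_error")
})

test_that("Cochran's Q and I-squared match the published heterogeneity figures", {
  het061 <- cochran_q(fixture_effects("rs41295061"))
  expect_equal(round(het061$i_squared, 1), 55.6)
  expect_equal(het061$p_q, 0.061, tolerance = 0.01)
  expect_identical(het061$q_df, 4L)

  het656 <- cochran_q(fixture_effects("rs11594656"))
  expect_equal(round(het656$i_squared, 1), 10.0)
  expect_equal(het656$p_q, 0.352, tolerance = 0.01)

  # identical effects with identical standard errors are exactly homogeneous
  same <- replicate(4, make_effect(1.3, 1.1, 1.54), simplify = FALSE)
  het0 <- cochran_q(same)
  expect_equal(het0$q_stat, 0, tolerance = 1e-20)
  expect_equal(het0$i_squared, 0)

  expect_error(cochran_q(list(make_effect(1.2, 1.0, 1.5))),
               class = "il2rameta_computation_error")
})

test_that("DerSimonian-Laird pooling reproduces the published random-effects result", {
  rem061 <- dersimonian_laird(fixture_effects("rs41295061"))
  expect_equal(round(rem061$pooled_or, 2), 0.67)
  expect_equal(round(rem061$ci_low, 2), 0.60)
  expect_equal(round(rem061$ci_high, 2), 0.76)
  expect_gt(rem061$tau_squared, 0)

  # Q <= df truncates tau2 to zero and collapses onto the fixed-effect result
  hom <- list(make_effect(1.10, 1.0, 1.21), make_effect(1.11, 1.02, 1.21),
              make_effect(1.09, 0.98, 1.21))
  fem <- fixed_effect_inverse_variance(hom)
  rem <- dersimonian_laird(hom)
  expect_lte(rem$q_stat, rem$q_df)
  expect_identical(rem$tau_squared, 0)
  expect_equal(rem$pooled_log_or, fem$pooled_log_or, tolerance = 1e-12)
  expect_equal(rem$pooled_se, fem$pooled_se, tolerance = 1e-12)

  # homogeneous set: REM equals FEM
  rem778 <- dersimonian_laird(fixture_effects("rs706778"))
  expect_equal(round(rem778$pooled_or, 2), 1.20)
  expect_identical(rem778$tau_squared, 0)
})

test_that("Q and tau2 match the brute-force summation oracle on small subsets", {
  for (snp in c("rs2104286", "rs706778", "rs11594656", "rs41295061", "rs3118470")) {
    effs <- fixture_effects(snp)
    k <- length(effs)
    subsets <- c(utils::combn(k, 2, simplify = FALSE),
                 utils::combn(k, 3, simplify = FALSE))
    for (idx in subsets) {
      sub <- effs[idx]
      theta <- vapply(sub, `[[`, 0, "log_or")
      se <- vapply(sub, `[[`, 0, "se_log_or")
      ref <- oracle_q_tau(theta, se)
      het <- cochran_q(sub)
      rem <- dersimonian_laird(sub)
      expect_equal(het$q_stat, ref$q, tolerance = 1e-12)
      expect_equal(het$i_squared, ref$i_squared, tolerance = 1e-12)
      expect_equal(rem$tau_squared, ref$tau2, tolerance = 1e-12)
    }
  }
})

test_that("pooled results agree with an independent meta-analysis implementation", {
  skip_if_not_installed("metafor")
  for (snp in c("rs11594656", "rs41295061", "rs3118470")) {
    effs <- fixture_effects(snp)
    theta <- vapply(effs, `[[`, 0, "log_or")
    se <- vapply(effs, `[[`, 0, "se_log_or")
    fe_ref <- metafor::rma(yi = theta, sei = se, method = "FE")
    dl_ref <- metafor::rma(yi = theta, sei = se, method = "DL")
    fem <- fixed_effect_inverse_variance(effs)
    rem <- dersimonian_laird(effs)
    expect_equal(fem$pooled_log_or, as.numeric(fe_ref$beta), tolerance = 1e-10)
    expect_equal(fem$pooled_se, fe_ref$se, tolerance = 1e-10)
    expect_equal(rem$pooled_log_or, as.numeric(dl_ref$beta), tolerance = 1e-10)
    expect_equal(rem$tau_squared, dl_ref$tau2, tolerance = 1e-10)
    expect_equal(cochran_q(effs)$q_stat, dl_ref$QE, tolerance = 1e-10)
  }
})

test_that("Mantel-Haenszel pooling is exact on single strata and symmetric", {
  fichna <- il2ra_studies("rs11594656")[[6L]]
  mh1 <- mantel_haenszel(list(fichna))
  woolf <- effect_from_counts(fichna$case_counts, fichna$control_counts)
  expect_equal(mh1$pooled_log_or, woolf$log_or, tolerance = 1e-12)
  expect_equal(round(mh1$pooled_or, 2), 0.77)

  tab <- allele_table(fichna$case_counts, fichna$control_counts)
  # two identical strata pool to the single-stratum odds ratio
  mh2 <- mantel_haenszel(list(tab, tab))
  expect_equal(mh2$pooled_log_or, mh1$pooled_log_or, tolerance = 1e-12)

  # swapping case and control rows inverts the pooled odds ratio
  swapped <- tab[c(2, 1), ]
  rownames(swapped) <- c("case", "control")
  mh_sw <- mantel_haenszel(list(swapped, swapped))
  expect_equal(mh2$pooled_or * mh_sw$pooled_or, 1, tolerance = 1e-12)

  # CI-only studies cannot enter the MH path
  expect_error(mantel_haenszel(unclass(il2ra_studies("rs2104286"))),
               "inverse-variance", class = "il2rameta_computation_error")
})

test_that("MH and inverse-variance pooling agree closely on the all-counts subsets", {
  skip_if_not_installed("metafor")
  for (snp in c("rs11594656", "rs41295061", "rs2104286", "rs3118470")) {
    with_counts <- Filter(function(o) !is.null(o$case_counts), il2ra_studies(snp))
    if (length(with_counts) < 2L) next
    mh <- mantel_haenszel(with_counts)
    iv <- fixed_effect_inverse_variance(
      lapply(with_counts, extract_effect, effect_source = "counts"))
    expect_lt(abs(mh$pooled_or - iv$pooled_or), 0.005)
    # cross-check the MH point estimate and RBG variance against metafor
    ai <- vapply(with_counts, function(o) o$case_counts$n_het + 2 * o$case_counts$n_minor_hom, 0)
    bi <- vapply(with_counts, function(o) 2 * o$case_counts$n_major_hom + o$case_counts$n_het, 0)
    ci <- vapply(with_counts, function(o) o$control_counts$n_het + 2 * o$control_counts$n_minor_hom, 0)
    di <- vapply(with_counts, function(o) 2 * o$control_counts$n_major_hom + o$control_counts$n_het, 0)
    ref <- metafor::rma.mh(ai = ai, bi = bi, ci = ci, di = di, correct = FALSE)
    expect_equal(mh$pooled_log_or, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(mh$pooled_se, ref$se, tolerance = 1e-10)
  }
})

test_that("the model selector applies the disjunctive heterogeneity rule", {
  expect_identical(select_model(list(p_q = 0.061, i_squared = 55.6)), "REM")
  expect_identical(select_model(list(p_q = 0.352, i_squared = 10.0)), "FEM")
  expect_identical(select_model(list(p_q = 0.04, i_squared = 30)), "REM")
  expect_identical(select_model(list(p_q = 0.5, i_squared = 0)), "FEM")
})

test_that("pool_snp reproduces the published per-SNP summaries with the right models", {
  res470 <- pool_snp(il2ra_studies("rs3118470"))
  expect_identical(res470$model, "FEM")
  expect_equal(round(res470$pooled_or, 2), 1.23)
  expect_equal(round(res470$ci_low, 2), 1.16)
  expect_equal(round(res470$ci_high, 2), 1.31)

  res778 <- pool_snp(il2ra_studies("rs706778"))
  expect_identical(res778$model, "FEM")
  expect_equal(round(res778$pooled_or, 2), 1.20)
  expect_equal(round(res778$ci_low, 2), 1.08)
  expect_equal(round(res778$ci_high, 2), 1.33)
  expect_identical(res778$k, 3L)
  expect_identical(res778$n_cases, 1896L)
  expect_identical(res778$n_controls, 1709L)

  res061 <- pool_snp(il2ra_studies("rs41295061"))
  expect_identical(res061$model, "REM")
  expect_s3_class(attr(res061, "alternate"), "meta_result")
  expect_identical(attr(res061, "alternate")$model, "FEM")

  # single outcome: degenerate pooling, flagged
  one <- il2ra_studies("rs706778")[1L]
  expect_warning(res1 <- pool_snp(one), "at least three")
  expect_true(isTRUE(attr(res1, "single_study")))
  expect_equal(res1$pooled_log_or, extract_effect(one[[1L]])$log_or)

  expect_error(pool_snp(unclass(il2ra_studies())),
               "multiple SNPs", class = "il2rameta_validation_error")
})

test_that("pooling precision behaves monotonically and is permutation invariant", {
  set.seed(55)
  for (rep in 1:20) {
    k <- sample(3:8, 1)
    effs <- lapply(seq_len(k), function(i) {
      s <- runif(1, 0.05, 0.5)
      theta <- rnorm(1, 0.2, 0.3)
      effect_estimate(theta, s, label = sprintf("s%02d", i))
    })
    fem <- fixed_effect_inverse_variance(effs)
    rem <- dersimonian_laird(effs)
    # pooling never loses precision; random-effects never claims more than fixed
    expect_lte(fem$pooled_se, min(vapply(effs, `[[`, 0, "se_log_or")))
    expect_gte(rem$pooled_se, fem$pooled_se)
    if (rem$tau_squared == 0)
      expect_equal(rem$pooled_se, fem$pooled_se, tolerance = 1e-12)

    perm <- sample(k)
    fem_p <- fixed_effect_inverse_variance(effs[perm])
    expect_equal(fem_p$pooled_log_or, fem$pooled_log_or, tolerance = 1e-15)
    expect_equal(fem_p$q_stat, fem$q_stat, tolerance = 1e-15)
    expect_identical(sort(names(fem_p$weights)), sort(names(fem$weights)))
  }
})

test_that("under a homogeneous null, I2 exceeds 50% at its chi-square implied rate", {
  set.seed(404)
  k <- 5
  reps <- 5000
  hits <- 0L
  for (r in seq_len(reps)) {
    se <- runif(k, 0.05, 0.2)
    effs <- lapply(seq_len(k), function(i) effect_estimate(rnorm(1, 0, se[i]), se[i]))
    if (cochran_q(effs)$i_squared > 50) hits <- hits + 1L
  }
  # I2 > 50% iff Q > 2 df; under homogeneity Q ~ chi-square(k - 1)
  implied <- pchisq(2 * (k - 1), df = k - 1, lower.tail = FALSE)
  expect_lt(abs(hits / reps - implied), 0.02)
})
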