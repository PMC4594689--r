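test_that("the packaged study table parses into 21 validated outcomes", {
  tab <- il2ra_studies()
  expect_s3_class(tab, "study_table")
  expect_length(tab, 21L)
  snps <- vapply(tab, `[[`, "", "snp")
  expect_equal(as.vector(table(snps)[c("rs11594656", "rs2104286", "rs3118470",
                                       "rs41295061", "rs706778")]),
               c(6L, 3L, 4L, 5L, 3L))
  # CI-only rows (no genotype data in the sources)
  ci_only <- vapply(tab, function(o) is.null(o$case_counts), logical(1))
  expect_setequal(unique(vapply(tab[ci_only], `[[`, "", "study_id")),
                  c("Maier", "Grant_set1", "Grant_set2", "Aminkeng",
                    "Klinker", "Yamashita", "Kisand"))
  # every outcome usable for pooling under the default policy
  for (o in tab) expect_s3_class(extract_effect(o), "effect_estimate")
})

test_that("parsing rejects malformed tables with row-numbered diagnostics", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(0), empty)
  expect_error(parse_study_table(empty), class = "il2rameta_validation_error")

  write_rows <- function(rows) {
    f <- tempfile(fileext = ".tsv")
    writeLines(c(paste(c("study_id", "year", "country", "ancestry", "snp",
                         "design", "case_counts", "control_counts",
                         "reported_or", "ci_low", "ci_high", "orientation",
                         "n_cases", "n_controls"), collapse = "\t"), rows), f)
    f
  }
  # neither counts nor reported OR+CI
  f <- write_rows("A\t2010\tX\tEuropean\trs1\tcase_control\tND\tND\tNA\tNA\tNA\tminor\t100\t100")
  expect_error(parse_study_table(f), "row 1", class = "il2rameta_validation_error")
  # zero genotype total
  f <- write_rows("A\t2010\tX\tEuropean\trs1\tcase_control\t0/0/0\t10/10/10\tNA\tNA\tNA\tminor\t100\t100")
  expect_error(parse_study_table(f), "zero", class = "il2rameta_validation_error")
  # negative count
  f <- write_rows("A\t2010\tX\tEuropean\trs1\tcase_control\t-1/5/5\t10/10/10\tNA\tNA\tNA\tminor\t100\t100")
  expect_error(parse_study_table(f), "row 1", class = "il2rameta_validation_error")
  # second of two rows bad: no partial output
  f <- write_rows(c("A\t2010\tX\tEuropean\trs1\tcase_control\t10/10/10\t10/10/10\tNA\tNA\tNA\tminor\t30\t30",
                    "B\t2010\tX\tEuropean\trs1\tcase_control\tND\tND\t1.2\t1.5\t1.9\tminor\t30\t30"))
  expect_error(parse_study_table(f), "row 2", class = "il2rameta_validation_error")
})

test_that("study_outcome enforces its invariants", {
  gc <- genotype_counts(10, 10, 10)
  expect_error(study_outcome("A", snp = "rs1", reported_or = 1.2,
                             ci_low = 1.3, ci_high = 1.5, n_cases = 1, n_controls = 1),
               class = "il2rameta_validation_error")
  expect_error(study_outcome("A", snp = "rs1", reported_or = 1.2,
                             ci_low = 1.0, ci_high = 1.4,
                             orientation = "major", n_cases = 1, n_controls = 1),
               "major", class = "il2rameta_validation_error")
  expect_warning(study_outcome("A", snp = "rs1", case_counts = gc,
                               control_counts = gc, n_cases = 30, n_controls = 30,
                               maf_cases = 0.3),
                 "recomputed MAF")
})

test_that("minor allele frequency matches the printed values and scales invariantly", {
  expect_equal(round(minor_allele_frequency(genotype_counts(153, 217, 75)), 3), 0.412)
  expect_equal(round(minor_allele_frequency(genotype_counts(273, 155, 17)), 3), 0.212)
  expect_equal(minor_allele_frequency(genotype_counts(0, 0, 10)), 1.0)
  expect_error(minor_allele_frequency(genotype_counts(0, 0, 0)),
               class = "il2rameta_computation_error")
  # invariance under scaling all three genotype classes
  set.seed(11)
  for (rep in 1:20) {
    g <- sample(0:50, 3, replace = TRUE)
    if (sum(g) == 0) g[1] <- 1
    m <- sample(2:9, 1)
    expect_identical(minor_allele_frequency(genotype_counts(g[1], g[2], g[3])),
                     minor_allele_frequency(genotype_counts(m * g[1], m * g[2], m * g[3])))
  }
})

test_that("HWE chi-square test behaves at exact equilibrium, extreme departure, and real controls", {
  at_hwe <- hwe_test(genotype_counts(25, 50, 25))
  expect_equal(at_hwe$chi_square, 0)
  expect_equal(at_hwe$p_value, 1)
  expect_true(at_hwe$passes)

  # all homozygotes at allele frequency 0.5: chi-square equals the sample size
  extreme <- hwe_test(genotype_counts(50, 0, 50))
  expect_equal(extreme$chi_square, 100)
  expect_lt(extreme$p_value, 1e-5)
  expect_false(extreme$passes)
  expect_false(hwe_test(genotype_counts(50, 0, 50), design = "gwas")$passes)

  # monomorphic sample: no departure detectable
  mono <- hwe_test(genotype_counts(100, 0, 0))
  expect_equal(mono$chi_square, 0)
  expect_equal(mono$p_value, 1)

  # the packaged control samples are all in HWE at the case-control threshold
  for (o in il2ra_studies()) {
    if (!is.null(o$control_counts))
      expect_true(hwe_test(o$control_counts, o$design)$passes,
                  label = sprintf("%s (%s) controls in HWE", o$study_id, o$snp))
  }
})

test_that("HWE p-values are uniform under multinomial sampling at equilibrium", {
  set.seed(2024)
  n <- 500
  p <- 0.3
  probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  pvals <- replicate(2000, {
    g <- as.vector(rmultinom(1, n, probs))
    hwe_test(genotype_counts(g[1], g[2], g[3]))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("allelic odds ratios from genotype counts match the printed study values", {
  fichna <- effect_from_counts(genotype_counts(273, 155, 17),
                               genotype_counts(373, 248, 50))
  expect_equal(round(fichna$or_point, 2), 0.77)
  expect_equal(round(fichna$ci_low, 2), 0.63)
  expect_equal(round(fichna$ci_high, 2), 0.94)
  expect_identical(fichna$source, "counts")

  kawasaki <- effect_from_counts(genotype_counts(307, 421, 149),
                                 genotype_counts(170, 309, 123),
                                 orientation = "major")
  expect_equal(round(kawasaki$or_point, 2), 1.23)
  expect_equal(round(kawasaki$ci_low, 2), 1.06)
  expect_equal(round(kawasaki$ci_high, 2), 1.43)

  # symmetry: identical case and control counts give the null
  same <- effect_from_counts(genotype_counts(50, 30, 20), genotype_counts(50, 30, 20))
  expect_equal(same$log_or, 0)
  expect_equal(same$or_point, 1)
})

test_that("count-derived effects match the hand 2x2 oracle and flip under orientation", {
  set.seed(21)
  for (rep in 1:25) {
    case <- genotype_counts(sample(20:200, 1), sample(20:200, 1), sample(20:200, 1))
    control <- genotype_counts(sample(20:200, 1), sample(20:200, 1), sample(20:200, 1))
    minor <- effect_from_counts(case, control)
    major <- effect_from_counts(case, control, orientation = "major")
    ref <- oracle_woolf(case, control)
    expect_equal(minor$log_or, ref$log_or, tolerance = 1e-12)
    expect_equal(minor$se_log_or, ref$se, tolerance = 1e-12)
    # major orientation negates the log OR with the same standard error
    expect_equal(major$log_or, -minor$log_or, tolerance = 1e-12)
    expect_equal(major$se_log_or, minor$se_log_or, tolerance = 1e-12)
  }
})

test_that("zero allele-table cells trigger the continuity correction or an error", {
  # one zero cell: +0.5 to all four, flagged
  expect_warning(
    eff <- effect_from_counts(genotype_counts(50, 0, 0), genotype_counts(40, 10, 2)),
    "continuity")
  expect_true(is.finite(eff$log_or))
  # monomorphic in both groups: two zero cells, not estimable
  expect_error(
    effect_from_counts(genotype_counts(50, 0, 0), genotype_counts(40, 0, 0)),
    class = "il2rameta_computation_error")
})

test_that("CI-derived effects recover the published log OR and standard error", {
  lowe <- effect_from_ci(0.65, 0.59, 0.71)
  expect_equal(round(lowe$log_or, 4), -0.4308)
  expect_equal(round(lowe$se_log_or, 5), 0.04723)

  sym <- effect_from_ci(1.0, 0.5, 2.0)
  expect_equal(sym$log_or, 0)
  expect_equal(sym$se_log_or, log(4) / 3.92, tolerance = 1e-12)

  maier <- effect_from_ci(0.80, 0.76, 0.85)
  expect_equal(maier$se_log_or, 0.02855, tolerance = 1e-4)

  expect_error(effect_from_ci(0.8, 0.9, 0.7), class = "il2rameta_validation_error")
  expect_error(effect_from_ci(0.8, 0.7, 0.9, level = 1.2),
               class = "il2rameta_validation_error")
})

test_that("effect_from_ci round-trips any (log OR, SE) pair at z = 1.96", {
  set.seed(33)
  for (rep in 1:50) {
    theta <- rnorm(1, 0, 1.5)
    s <- runif(1, 0.01, 0.8)
    eff <- effect_from_ci(exp(theta), exp(theta - 1.96 * s), exp(theta + 1.96 * s))
    expect_equal(eff$log_or, theta, tolerance = 1e-12)
    expect_equal(eff$se_log_or, s, tolerance = 1e-12)
  }
})

test_that("a study table survives a write/parse round trip", {
  tab <- il2ra_studies()
  f <- tempfile(fileext = ".tsv")
  write_study_table(tab, f)
  back <- suppressWarnings(parse_study_table(f))
  expect_equal(as.data.frame(back), as.data.frame(tab))
})
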