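#' Genotype counts for a biallelic SNP
#'
#' Container for the three genotype classes of a biallelic marker in one
#' sample: homozygous for the major allele, heterozygous, and homozygous for
#' the minor allele. The "a/b/c" string convention used by the packaged study
#' table follows the same order.
#'
#' @param n_major_hom,n_het,n_minor_hom Non-negative whole numbers of
#'   individuals in each genotype class.
#' @return An object of class `genotype_counts` with fields `n_major_hom`,
#'   `n_het`, `n_minor_hom` and `total`.
#' @examples
#' gc <- genotype_counts(273, 155, 17)
#' minor_allele_frequency(gc)
#' @export
genotype_counts <- function(n_major_hom, n_het, n_minor_hom) {
  counts <- c(n_major_hom, n_het, n_minor_hom)
  if (length(counts) != 3L || anyNA(counts) || !all(is.finite(counts)))
    stop_validation("genotype counts must be three finite numbers")
  if (any(counts < 0))
    stop_validation("genotype counts must be non-negative")
  if (any(counts != round(counts)))
    stop_validation("genotype counts must be whole numbers")
  counts <- as.integer(round(counts))
  structure(
    list(n_major_hom = counts[1L], n_het = counts[2L], n_minor_hom = counts[3L],
         total = sum(counts)),
    class = "genotype_counts"
  )
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("genotype counts (major-hom/het/minor-hom): %d/%d/%d  [n = %d]\n",
              x$n_major_hom, x$n_het, x$n_minor_hom, x$total))
  invisible(x)
}

#' Parse an "a/b/c" genotype string
#'
#' @param x A string such as `"273/155/17"`, ordered
#'   major-hom/het/minor-hom. `"NA"`, `"ND"` and empty strings yield `NULL`
#'   (no genotype data).
#' @return A [genotype_counts()] object, or `NULL` when absent.
#' @export
parse_genotype_string <- function(x) {
  if (is.null(x) || length(x) != 1L) stop_validation("expected a single genotype string")
  x <- trimws(x)
  if (is.na(x) || x %in% c("", "NA", "ND")) return(NULL)
  parts <- strsplit(x, "/", fixed = TRUE)[[1L]]
  if (length(parts) != 3L)
    stop_validation(sprintf("genotype string '%s' is not of the form a/b/c", x))
  nums <- suppressWarnings(as.numeric(parts))
  if (anyNA(nums))
    stop_validation(sprintf("genotype string '%s' contains non-numeric entries", x))
  genotype_counts(nums[1L], nums[2L], nums[3L])
}

#' Minor allele frequency from genotype counts
#'
#' MAF = (het + 2 * minor-hom) / (2 * total). Invariant under scaling all
#' three genotype classes by a common positive factor.
#'
#' @param counts A [genotype_counts()] object with positive total.
#' @return Frequency in `[0, 1]`.
#' @export
minor_allele_frequency <- function(counts) {
  if (!inherits(counts, "genotype_counts"))
    stop_validation("'counts' must be a genotype_counts object")
  if (counts$total <= 0L)
    stop_computation("minor allele frequency undefined for zero genotype total")
  (counts$n_het + 2 * counts$n_minor_hom) / (2 * counts$total)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson chi-square (1 df) of the observed genotype counts against the
#' Hardy-Weinberg expectation at the sample allele frequency. Used to screen
#' control samples: genotyping error or population stratification shows up as
#' departure from HWE in controls. The pass threshold is design specific:
#' p >= 0.05 for conventional case-control studies, p >= 1e-5 for GWAS panels.
#'
#' A monomorphic sample (allele frequency 0 or 1) carries no information about
#' HWE departure and is defined as chi-square 0, p = 1.
#'
#' @param counts A [genotype_counts()] object.
#' @param design `"case_control"` or `"gwas"`; selects the pass threshold.
#' @return An object of class `hwe_result` with fields `chi_square`,
#'   `p_value`, `passes`, `design` and `threshold`.
#' @examples
#' hwe_test(genotype_counts(373, 248, 50))
#' @export
hwe_test <- function(counts, design = c("case_control", "gwas")) {
  design <- match.arg(design)
  if (!inherits(counts, "genotype_counts"))
    stop_validation("'counts' must be a genotype_counts object")
  if (counts$total <= 0L)
    stop_computation("HWE test undefined for zero genotype total")
  q <- minor_allele_frequency(counts)
  threshold <- if (design == "case_control") 0.05 else 1e-5
  if (q == 0 || q == 1) {
    chi2 <- 0
    p <- 1
  } else {
    observed <- c(counts$n_major_hom, counts$n_het, counts$n_minor_hom)
    expected <- counts$total * c((1 - q)^2, 2 * q * (1 - q), q^2)
    chi2 <- sum((observed - expected)^2 / expected)
    p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  structure(
    list(chi_square = chi2, p_value = p, passes = p >= threshold,
         design = design, threshold = threshold),
    class = "hwe_result"
  )
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("HWE chi-square = %.4f, p = %.4g (%s threshold %g): %s\n",
              x$chi_square, x$p_value, x$design, x$threshold,
              if (x$passes) "in HWE" else "departs from HWE"))
  invisible(x)
}
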