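#' Construct a single study outcome
#'
#' One row of the study-level table: the association of one SNP with type 1
#' diabetes in one case-control sample. An outcome must carry either both
#' genotype count sets or a reported OR with both confidence bounds (it may
#' carry both, in which case the pooling effect-source policy decides which
#' is used).
#'
#' @param study_id Study label (e.g. `"Fichna"`, `"Lowe_set1"`).
#' @param year Publication year.
#' @param country Country of the sample.
#' @param ancestry `"European"`, `"Asian"` or `"other"`.
#' @param snp rsID of the polymorphism.
#' @param design `"case_control"` or `"gwas"` (affects the HWE threshold).
#' @param case_counts,control_counts [genotype_counts()] or `NULL`.
#' @param reported_or,ci_low,ci_high Published OR and 95% bounds, or `NA`.
#' @param orientation Effect-allele orientation for count-derived effects:
#'   `"minor"` (default) or `"major"`. `"major"` is only permitted when
#'   genotype counts are present, since it flips the allele contrast.
#' @param n_cases,n_controls Published sample sizes (may exceed the genotype
#'   sums when the source genotyped a subset).
#' @param maf_cases,maf_controls Published minor allele frequencies, or `NA`.
#'   When genotype counts are present the recomputed MAF is cross-checked
#'   against the printed value at 3 decimals, with a warning (not an error)
#'   on mismatch.
#' @return An object of class `study_outcome`.
#' @export
study_outcome <- function(study_id, year = NA_integer_, country = NA_character_,
                          ancestry = c("European", "Asian", "other"),
                          snp, design = c("case_control", "gwas"),
                          case_counts = NULL, control_counts = NULL,
                          reported_or = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_,
                          orientation = c("minor", "major"),
                          n_cases = NA_integer_, n_controls = NA_integer_,
                          maf_cases = NA_real_, maf_controls = NA_real_) {
  ancestry <- match.arg(ancestry)
  design <- match.arg(design)
  orientation <- match.arg(orientation)
  has_counts <- !is.null(case_counts) && !is.null(control_counts)
  if (has_counts) {
    for (gc in list(case_counts, control_counts)) {
      if (!inherits(gc, "genotype_counts"))
        stop_validation("case_counts/control_counts must be genotype_counts or NULL")
      if (gc$total <= 0L)
        stop_validation(sprintf("study '%s': genotype counts sum to zero", study_id))
    }
  }
  has_reported <- !is.na(reported_or) && !is.na(ci_low) && !is.na(ci_high)
  if (!has_counts && !has_reported)
    stop_validation(sprintf(
      "study '%s' (%s): needs genotype counts for both groups or a reported OR with both CI bounds",
      study_id, snp))
  if (has_reported) {
    if (any(c(reported_or, ci_low, ci_high) <= 0))
      stop_validation(sprintf("study '%s': OR and CI bounds must be positive", study_id))
    if (!(ci_low < reported_or && reported_or < ci_high))
      stop_validation(sprintf(
        "study '%s': reported OR %.3g not strictly inside CI (%.3g, %.3g)",
        study_id, reported_or, ci_low, ci_high))
  }
  if (orientation == "major" && !has_counts)
    stop_validation(sprintf(
      "study '%s': orientation 'major' requires genotype counts (it flips the allele contrast)",
      study_id))
  if (has_counts) {
    check_maf <- function(printed, counts, group) {
      if (is.na(printed)) return(invisible())
      recomputed <- minor_allele_frequency(counts)
      if (abs(recomputed - printed) > 0.0015)
        warning(sprintf(
          "study '%s' (%s) %s: recomputed MAF %.3f differs from printed %.3f (likely different denominators in the source)",
          study_id, snp, group, recomputed, printed), call. = FALSE)
    }
    check_maf(maf_cases, case_counts, "cases")
    check_maf(maf_controls, control_counts, "controls")
  }
  structure(
    list(study_id = study_id, year = as.integer(year), country = country,
         ancestry = ancestry, snp = snp, design = design,
         case_counts = case_counts, control_counts = control_counts,
         reported_or = reported_or, ci_low = ci_low, ci_high = ci_high,
         orientation = orientation,
         n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         maf_cases = maf_cases, maf_controls = maf_controls),
    class = "study_outcome"
  )
}

#' @export
print.study_outcome <- function(x, ...) {
  cat(sprintf("%s (%s, %s) %s: %d cases / %d controls",
              x$study_id, x$year, x$country, x$snp, x$n_cases, x$n_controls))
  if (!is.na(x$reported_or))
    cat(sprintf("; reported OR %.2f (%.2f-%.2f)", x$reported_or, x$ci_low, x$ci_high))
  if (!is.null(x$case_counts)) cat("; genotype counts present")
  cat("\n")
  invisible(x)
}

table_columns <- c("study_id", "year", "country", "ancestry", "snp", "design",
                   "case_counts", "control_counts", "reported_or", "ci_low",
                   "ci_high", "orientation", "n_cases", "n_controls",
                   "maf_cases", "maf_controls")

na_if_nd <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% c("", "NA", "ND")] <- NA_character_
  x
}

#' Read and validate a study-level table
#'
#' Reads a comma- or tab-delimited UTF-8 table, one row per study outcome,
#' with header columns `study_id, year, country, ancestry, snp, design,
#' case_counts, control_counts, reported_or, ci_low, ci_high, orientation,
#' n_cases, n_controls` and optionally `maf_cases, maf_controls`. Genotype
#' counts use the `"a/b/c"` convention (major-hom/het/minor-hom); `NA` or
#' `ND` marks absent values. Rows failing validation abort the read with a
#' row-numbered diagnostic; no partial output is returned.
#'
#' @param path Path to the delimited file.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A list of [study_outcome()] objects, classed `study_table`.
#' @seealso [il2ra_studies()] for the packaged table.
#' @export
parse_study_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop_validation(sprintf("file not found: %s", path))
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) stop_validation(sprintf("empty study table: %s", path))
  if (is.null(sep)) sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", comment.char = "",
                           fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop_validation(sprintf("study table has no data rows: %s", path))
  required <- setdiff(table_columns, c("maf_cases", "maf_controls"))
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L)
    stop_validation(sprintf("study table missing columns: %s",
                            paste(missing_cols, collapse = ", ")))
  for (col in c("maf_cases", "maf_controls"))
    if (!col %in% names(raw)) raw[[col]] <- NA_character_

  outcomes <- vector("list", nrow(raw))
  for (i in seq_len(nrow(raw))) {
    row <- lapply(raw[i, table_columns, drop = FALSE], na_if_nd)
    outcomes[[i]] <- withCallingHandlers(
      tryCatch(
        study_outcome(
          study_id = row$study_id,
          year = as.integer(row$year),
          country = row$country,
          ancestry = row$ancestry,
          snp = row$snp,
          design = row$design,
          case_counts = parse_genotype_string(row$case_counts),
          control_counts = parse_genotype_string(row$control_counts),
          reported_or = as.numeric(row$reported_or),
          ci_low = as.numeric(row$ci_low),
          ci_high = as.numeric(row$ci_high),
          orientation = if (is.na(row$orientation)) "minor" else row$orientation,
          n_cases = as.integer(row$n_cases),
          n_controls = as.integer(row$n_controls),
          maf_cases = as.numeric(row$maf_cases),
          maf_controls = as.numeric(row$maf_controls)
        ),
        il2rameta_error = function(e) {
          stop_validation(sprintf("row %d: %s", i, conditionMessage(e)))
        }
      ),
      warning = function(w) {
        warning(sprintf("row %d: %s", i, conditionMessage(w)), call. = FALSE)
        invokeRestart("muffleWarning")
      }
    )
  }
  structure(outcomes, class = "study_table")
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("study table: %d outcomes, %d SNPs (%s)\n", length(x),
              length(unique(vapply(x, `[[`, "", "snp"))),
              paste(sort(unique(vapply(x, `[[`, "", "snp"))), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.study_table <- function(x, ...) {
  fmt_counts <- function(gc) {
    if (is.null(gc)) NA_character_
    else sprintf("%d/%d/%d", gc$n_major_hom, gc$n_het, gc$n_minor_hom)
  }
  do.call(rbind, lapply(x, function(o) {
    data.frame(study_id = o$study_id, year = o$year, country = o$country,
               ancestry = o$ancestry, snp = o$snp, design = o$design,
               case_counts = fmt_counts(o$case_counts),
               control_counts = fmt_counts(o$control_counts),
               reported_or = o$reported_or, ci_low = o$ci_low,
               ci_high = o$ci_high, orientation = o$orientation,
               n_cases = o$n_cases, n_controls = o$n_controls,
               maf_cases = o$maf_cases, maf_controls = o$maf_controls,
               stringsAsFactors = FALSE)
  }))
}

#' Write a normalized study table
#'
#' Serializes a `study_table` back to the tab-delimited exchange format that
#' [parse_study_table()] reads.
#'
#' @param x A `study_table` (or list of [study_outcome()] objects).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(x, path) {
  df <- as.data.frame.study_table(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Path to the packaged IL2RA/T1D study table
#'
#' @return Path to the tab-delimited study table shipped with the package:
#'   21 study outcomes over five IL2RA SNPs from ten independent
#'   case-control studies of type 1 diabetes.
#' @export
il2ra_table_path <- function() {
  system.file("extdata", "il2ra_t1d_studies.tsv", package = "il2rameta",
              mustWork = TRUE)
}

#' The packaged IL2RA/T1D study outcomes
#'
#' Parses the packaged study table. Recomputed-MAF cross-check warnings for
#' the Lowe set-1 rows (whose printed totals exceed their genotype sums, so
#' the printed MAFs use a different denominator) are expected and suppressed
#' here; use [parse_study_table()] on [il2ra_table_path()] to see them.
#'
#' @param snp Optional rsID (or vector of rsIDs) to filter on.
#' @return A `study_table`.
#' @examples
#' studies <- il2ra_studies("rs706778")
#' length(studies)
#' @export
il2ra_studies <- function(snp = NULL) {
  tab <- suppressWarnings(parse_study_table(il2ra_table_path()))
  if (!is.null(snp)) {
    keep <- vapply(tab, function(o) o$snp %in% snp, logical(1))
    if (!any(keep))
      stop_validation(sprintf("no outcomes for SNP(s) %s; available: %s",
                              paste(snp, collapse = ", "),
                              paste(sort(unique(vapply(tab, `[[`, "", "snp"))),
                                    collapse = ", ")))
    tab <- structure(tab[keep], class = "study_table")
  }
  tab
}
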