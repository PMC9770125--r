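# Cohort-level accounting: diagnostic yields, filter-funnel summaries,
# demographic and phenotype tables.

#' Round half-up
#'
#' Presentation rounding for percentages: exact halves round away from zero
#' (5.65 -> 5.7), unlike base R's round-half-even. Internal values are kept
#' exact; rounding is applied only when a number is reported.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Diagnostic yields of a cohort
#'
#' \code{yield_plp} is the percentage of CNV-analyzed patients carrying at
#' least one CNV classified Pathogenic or Likely pathogenic. \code{yield_total}
#' adds patients with an aneuploidy finding, over the enrolled denominator.
#' The two denominators differ deliberately: aneuploid samples are excluded
#' from CNV analysis but still count among the enrolled, so conflating the
#' denominators silently changes the total yield. A patient contributes at
#' most once to each numerator, however many qualifying CNVs they carry.
#' Variants of uncertain significance never enter a numerator.
#'
#' @param findings data.frame with columns \code{sample_id},
#'   \code{classification} (may be NA) and \code{aneuploid} (logical).
#' @param n_enrolled number of enrolled patients.
#' @param n_cnv_analyzed number of patients passing into CNV analysis.
#' @return named numeric \code{c(yield_plp, yield_total)}, percentages
#'   rounded half-up to one decimal.
#' @export
diagnostic_yield <- function(findings, n_enrolled, n_cnv_analyzed) {
  if (n_enrolled <= 0 || n_cnv_analyzed <= 0) {
    stop("yield denominators must be positive", call. = FALSE)
  }
  plp <- unique(findings$sample_id[
    !is.na(findings$classification) &
      findings$classification %in% c("Pathogenic", "Likely pathogenic")])
  aneu <- unique(findings$sample_id[!is.na(findings$aneuploid) &
                                      findings$aneuploid])
  if (length(plp) > n_cnv_analyzed || length(union(plp, aneu)) > n_enrolled) {
    stop("yield numerator exceeds its denominator", call. = FALSE)
  }
  c(yield_plp = round_half_up(100 * length(plp) / n_cnv_analyzed, 1L),
    yield_total = round_half_up(100 * length(union(plp, aneu)) / n_enrolled,
                                1L))
}

freq_table <- function(v) {
  tab <- sort(table(v), decreasing = TRUE)
  out <- data.frame(level = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$pct <- round_half_up(100 * out$n / sum(out$n), 1L)
  out
}

#' Demographic and phenotype summary tables
#'
#' Counts and one-decimal percentages by sex, ancestry and primary cardiac
#' diagnosis, plus the extracardiac-anomaly split. Percentages within each
#' table sum to 100 up to rounding.
#'
#' @param metadata sample metadata table; an empty cohort is an error.
#' @return named list of data.frames (\code{sex}, \code{ancestry},
#'   \code{primary_diagnosis}, \code{extracardiac_anomalies}), each with
#'   \code{level}, \code{n}, \code{pct}.
#' @export
cohort_summary <- function(metadata) {
  if (is.null(metadata) || nrow(metadata) == 0L) {
    stop("cohort_summary: empty cohort", call. = FALSE)
  }
  list(sex = freq_table(metadata$sex),
       ancestry = freq_table(metadata$ancestry),
       primary_diagnosis = freq_table(metadata$primary_diagnosis),
       extracardiac_anomalies = freq_table(
         ifelse(metadata$extracardiac_anomalies, "with_ECA", "isolated")))
}

#' Filter-funnel summary table
#'
#' Per-stage in/out counts plus the deletion/duplication split and the size
#' range of the retained set.
#'
#' @param trace a \code{filter_trace} from [run_cascade()].
#' @param retained the retained CNV call table.
#' @return list with \code{stages}, \code{n_deletions},
#'   \code{n_duplications}, \code{min_size_bp}, \code{max_size_bp} (sizes NA
#'   for an empty retained set).
#' @export
funnel_table <- function(trace, retained) {
  validate_filter_trace(trace)
  sizes <- retained$end - retained$start
  list(stages = trace$stages,
       n_deletions = sum(retained$cnv_type == "deletion"),
       n_duplications = sum(retained$cnv_type == "duplication"),
       min_size_bp = if (length(sizes) == 0L) NA_real_ else min(sizes),
       max_size_bp = if (length(sizes) == 0L) NA_real_ else max(sizes))
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("cnvtriage cohort report\n")
  cat(sprintf("  enrolled: %d   CNV-analyzed: %d\n", x$n_enrolled,
              x$n_cnv_analyzed))
  s <- x$trace$stages
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-15s %6d -> %6d\n", s$stage[i], s$n_in[i], s$n_out[i]))
  }
  f <- funnel_table(x$trace, x$classified)
  cat(sprintf("  retained: %d (%d deletions / %d duplications)\n",
              nrow(x$classified), f$n_deletions, f$n_duplications))
  cat(sprintf("  CNVs of interest: %d (%d known-gene, %d candidate, %d both)\n",
              nrow(x$of_interest),
              sum(x$of_interest$interest_tag == "known_gene"),
              sum(x$of_interest$interest_tag == "candidate"),
              sum(x$of_interest$interest_tag == "both")))
  cat(sprintf("  candidate genes nominated: %s\n",
              paste(sort(unique(x$candidates$gene[x$candidates$nominated])),
                    collapse = ", ")))
  cat(sprintf("  aneuploid samples: %s\n",
              paste(x$qc$excluded$sample_id[x$qc$excluded$reason ==
                                              "aneuploidy"],
                    collapse = ", ")))
  cat(sprintf("  yield (P/LP): %.1f%%   yield (total): %.1f%%\n",
              x$yield_plp, x$yield_total))
  invisible(x)
}
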