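# The prioritization funnel: sample QC, then reduction of raw copy-number
# calls to large, rare CNVs, with a complete per-call audit trail.

#' Filter configuration
#'
#' Thresholds of the large/rare funnel. Defaults: retain calls of at least
#' 100 kb, remove calls matched (50\% reciprocal overlap, same type) by a
#' control region carried by more than 0.1\% of controls.
#'
#' @param min_size_bp minimum CNV size in bases (>= 0; 0 disables the size
#'   stage).
#' @param max_control_frequency maximum tolerated control carrier frequency.
#' @param reciprocal_overlap_threshold reciprocal-overlap fraction at which a
#'   case call and a control region count as the same event.
#' @param require_type_match only control regions of the same
#'   deletion/duplication type can match (default TRUE).
#' @param min_probes minimum supporting probe count (calls with missing probe
#'   counts pass).
#' @return a \code{filter_config} list.
#' @export
filter_config <- function(min_size_bp = 100000,
                          max_control_frequency = 0.001,
                          reciprocal_overlap_threshold = 0.5,
                          require_type_match = TRUE,
                          min_probes = 1L) {
  stopifnot(is.numeric(min_size_bp), length(min_size_bp) == 1L,
            min_size_bp >= 0,
            is.numeric(max_control_frequency),
            max_control_frequency >= 0, max_control_frequency <= 1,
            is.numeric(reciprocal_overlap_threshold),
            reciprocal_overlap_threshold > 0,
            reciprocal_overlap_threshold <= 1,
            is.logical(require_type_match),
            is.numeric(min_probes), min_probes >= 1)
  structure(list(min_size_bp = min_size_bp,
                 max_control_frequency = max_control_frequency,
                 reciprocal_overlap_threshold = reciprocal_overlap_threshold,
                 require_type_match = require_type_match,
                 min_probes = as.integer(min_probes)),
            class = "filter_config")
}

#' Sample-level quality gate
#'
#' Excludes samples whose upstream array QC failed (\code{qc_pass} FALSE) and
#' samples whose sex-chromosome profile implies aneuploidy (via
#' [infer_karyotype()]); aneuploid genomes violate the diploid baseline the
#' autosomal CNV analysis assumes, so they are interpreted separately.
#'
#' @param samples sample metadata table.
#' @param profiles sex-chromosome profile table; a missing profile for any
#'   sample is an error.
#' @param tolerance rounding tolerance passed to [infer_karyotype()].
#' @return \code{list(pass = <metadata>, excluded = <sample_id, reason>,
#'   karyotypes = <karyotype table>)}.
#' @export
apply_sample_qc <- function(samples, profiles, tolerance = 0.3) {
  missing_prof <- setdiff(samples$sample_id, profiles$sample_id)
  if (length(missing_prof) > 0L) {
    stop(sprintf("no sex-chromosome profile for sample(s): %s",
                 paste(utils::head(missing_prof, 5L), collapse = ", ")),
         call. = FALSE)
  }
  karyo <- infer_karyotype(profiles, tolerance = tolerance)
  karyo <- karyo[match(samples$sample_id, karyo$sample_id), , drop = FALSE]
  reason <- rep(NA_character_, nrow(samples))
  reason[!samples$qc_pass] <- "qc_fail"
  reason[is.na(reason) & karyo$aneuploid] <- "aneuploidy"
  excluded <- data.frame(sample_id = samples$sample_id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  list(pass = samples[is.na(reason), , drop = FALSE],
       excluded = excluded,
       karyotypes = karyo)
}

#' Size and probe-support filter
#'
#' Retains calls with \code{end - start >= min_size_bp} and (where a probe
#' count is present) \code{n_probes >= min_probes}. Input order is preserved.
#'
#' @param calls CNV call table.
#' @param config a [filter_config()].
#' @return the retained subset.
#' @export
filter_by_size <- function(calls, config = filter_config()) {
  validate_cnv_calls(calls)
  if (nrow(calls) == 0L) return(calls)
  keep <- (calls$end - calls$start) >= config$min_size_bp &
    (is.na(calls$n_probes) | calls$n_probes >= config$min_probes)
  calls[keep, , drop = FALSE]
}

# Logical vector: is call i matched by a control record that crosses both the
# reciprocal-overlap and the frequency thresholds?
control_matched <- function(calls, controls, config) {
  if (nrow(calls) == 0L || is.null(controls) || nrow(controls) == 0L) {
    return(rep(FALSE, nrow(calls)))
  }
  vapply(seq_len(nrow(calls)), function(i) {
    sel <- controls$chrom == calls$chrom[i]
    if (config$require_type_match) {
      sel <- sel & controls$cnv_type == calls$cnv_type[i]
    }
    if (!any(sel)) return(FALSE)
    ctl <- controls[sel, , drop = FALSE]
    ro <- reciprocal_overlap(calls[i, c("chrom", "start", "end")],
                             ctl[, c("chrom", "start", "end")])
    any(ro >= config$reciprocal_overlap_threshold &
          ctl$frequency > config$max_control_frequency)
  }, logical(1L))
}

#' Control-population rarity filter
#'
#' A call is removed iff ANY control record of matching type has reciprocal
#' overlap at least \code{reciprocal_overlap_threshold} with it AND carrier
#' frequency above \code{max_control_frequency}. Calls that survive are
#' "rare" at the run thresholds. An empty control table retains everything.
#'
#' @param calls CNV call table.
#' @param controls control frequency table ([read_control_frequencies()]).
#' @param config a [filter_config()].
#' @return the retained subset, input order preserved.
#' @export
filter_by_controls <- function(calls, controls, config = filter_config()) {
  validate_cnv_calls(calls)
  calls[!control_matched(calls, controls, config), , drop = FALSE]
}

new_filter_trace <- function(stages, removals) {
  structure(list(stages = stages, removals = removals),
            class = "filter_trace")
}

#' Validate a filter trace
#'
#' Stage counts must chain (\code{n_out[i] == n_in[i+1]}) and be
#' non-increasing, and every removed call must carry exactly one removal
#' stage.
#'
#' @param trace a \code{filter_trace}.
#' @return \code{trace} invisibly; errors on violation.
#' @export
validate_filter_trace <- function(trace) {
  s <- trace$stages
  if (nrow(s) > 1L && !all(s$n_out[-nrow(s)] == s$n_in[-1L])) {
    stop("filter trace: stage counts do not chain", call. = FALSE)
  }
  if (any(s$n_out > s$n_in)) {
    stop("filter trace: stage output exceeds input", call. = FALSE)
  }
  removed_total <- s$n_in[1L] - s$n_out[nrow(s)]
  if (removed_total != nrow(trace$removals)) {
    stop("filter trace: removal attributions do not account for all removed calls",
         call. = FALSE)
  }
  invisible(trace)
}

#' Run the full filter cascade
#'
#' Applies, in fixed order: sample QC (upstream QC flag + sex-chromosome
#' aneuploidy), the size/probe filter, and the control-population rarity
#' filter. Every removed call is attributed to exactly one stage.
#'
#' @param calls raw CNV call table for the whole cohort.
#' @param samples sample metadata.
#' @param profiles sex-chromosome profiles.
#' @param controls control frequency table (may be empty or NULL).
#' @param config a [filter_config()].
#' @param qc_tolerance karyotype rounding tolerance for the QC stage.
#' @return \code{list(retained, trace, qc)} where \code{trace} is a
#'   \code{filter_trace} and \code{qc} the result of [apply_sample_qc()].
#' @export
run_cascade <- function(calls, samples, profiles, controls = NULL,
                        config = filter_config(), qc_tolerance = 0.3) {
  validate_cnv_calls(calls)
  calls$.call_id <- seq_len(nrow(calls))
  qc <- apply_sample_qc(samples, profiles, tolerance = qc_tolerance)

  s1 <- calls[calls$sample_id %in% qc$pass$sample_id, , drop = FALSE]
  s2 <- filter_by_size(s1, config)
  s3 <- filter_by_controls(s2, controls, config)

  stage_of <- rep(NA_character_, nrow(calls))
  stage_of[!calls$.call_id %in% s1$.call_id] <- "sample_qc"
  stage_of[is.na(stage_of) & !calls$.call_id %in% s2$.call_id] <- "size_probes"
  stage_of[is.na(stage_of) & !calls$.call_id %in% s3$.call_id] <- "control_rarity"
  removed <- !is.na(stage_of)
  removals <- data.frame(
    sample_id = calls$sample_id[removed], chrom = calls$chrom[removed],
    start = calls$start[removed], end = calls$end[removed],
    cnv_type = calls$cnv_type[removed], stage = stage_of[removed],
    stringsAsFactors = FALSE
  )
  stages <- data.frame(
    stage = c("sample_qc", "size_probes", "control_rarity"),
    n_in = c(nrow(calls), nrow(s1), nrow(s2)),
    n_out = c(nrow(s1), nrow(s2), nrow(s3)),
    stringsAsFactors = FALSE
  )
  trace <- new_filter_trace(stages, removals)
  validate_filter_trace(trace)
  retained <- s3[, setdiff(names(s3), ".call_id"), drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained, trace = trace, qc = qc)
}
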