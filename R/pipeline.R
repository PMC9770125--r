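# End-to-end wiring: QC + karyotype -> filter cascade -> annotation ->
# classification -> candidate nomination -> cohort report.
#
# CNV accounting happens at two granularities, deliberately:
#   * CNVs of interest are counted on the retained CALL set as the array
#     reported it (adjacent segments of one duplication count separately);
#   * pathogenicity and patient-level yield are computed on EVENTS, i.e.
#     after merge_adjacent() joins same-type calls separated by at most
#     merge_max_gap bases.

class_rank <- c("Benign" = 1, "Likely benign" = 2,
                "Uncertain significance" = 3, "Likely pathogenic" = 4,
                "Pathogenic" = 5)

#' Read a cytoband map from a tab-separated file
#' @param path file with header \code{chrom, start, end, band}.
#' @return a [cytoband_map()].
#' @export
read_cytoband_map <- function(path) {
  x <- read_tsv(path)
  require_columns(x, c("chrom", "start", "end", "band"), path)
  cytoband_map(x$chrom, x$start, x$end, x$band)
}

#' Load pipeline inputs from a YAML configuration
#'
#' The configuration maps input names to file paths: \code{calls} (+
#' \code{calls_dialect}), \code{metadata}, \code{profiles}, \code{controls},
#' \code{gene_models}, \code{gene_curation}, and optionally \code{cytobands}
#' and \code{manual_adjustments}.
#'
#' @param path YAML file path.
#' @return an input bundle accepted by [run_pipeline()].
#' @export
load_run_inputs <- function(path) {
  cfg <- yaml::read_yaml(path)
  need <- c("calls", "metadata", "profiles", "controls", "gene_models",
            "gene_curation")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0L) {
    stop(sprintf("%s: config is missing key(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  res <- read_gene_resources(cfg$gene_models, cfg$gene_curation)
  bands <- if (!is.null(cfg$cytobands)) read_cytoband_map(cfg$cytobands)
           else NULL
  manual <- if (!is.null(cfg$manual_adjustments))
    read_tsv(cfg$manual_adjustments) else NULL
  list(
    genome = list(chromosomes = NULL, bands = bands, models = res$models,
                  curation = res$curation),
    calls = read_cnv_calls(cfg$calls,
                           dialect = cfg$calls_dialect %||% "array_export"),
    metadata = read_sample_metadata(cfg$metadata),
    profiles = read_sex_profiles(cfg$profiles),
    controls = read_control_frequencies(cfg$controls),
    manual_adjustments = manual
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full CNV prioritization and interpretation pipeline
#'
#' Executes: sample QC and karyotype inference, the large/rare filter
#' cascade, gene annotation, points-based classification, candidate-gene
#' nomination, CNV-of-interest selection, event merging, and cohort-level
#' yield accounting. Identical inputs and configuration produce identical
#' results (and, with \code{out_dir}, byte-identical files).
#'
#' @param inputs input bundle (\code{genome}, \code{calls}, \code{metadata},
#'   \code{profiles}, \code{controls}, optional \code{manual_adjustments}),
#'   e.g. from [make_paper_fixture()], [simulate_cohorts()] (which returns
#'   the same names plus \code{truth}) or [load_run_inputs()].
#' @param preset \code{"paper"} substitutes the packaged deterministic
#'   cohort fixture for \code{inputs}.
#' @param filter a [filter_config()].
#' @param classification a [classification_config()].
#' @param merge_max_gap gap (bases) below which adjacent same-type calls of
#'   one sample form a single event for classification and yield.
#' @param qc_tolerance karyotype rounding tolerance.
#' @param out_dir if non-NULL, [write_results()] is called on the report.
#' @param seed recorded in the run manifest (the pipeline itself draws no
#'   random numbers).
#' @return a \code{cohort_report} list: enrolled/analyzed counts, the
#'   classified call table (with \code{interest_tag}), classified events,
#'   candidate findings, CNVs of interest, karyotypes, filter trace, yields
#'   and summary tables.
#' @export
run_pipeline <- function(inputs = NULL, preset = NULL,
                         filter = filter_config(),
                         classification = classification_config(),
                         merge_max_gap = 50000, qc_tolerance = 0.3,
                         out_dir = NULL, seed = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, "paper")
    inputs <- make_paper_fixture()
  }
  if (is.null(inputs)) stop("run_pipeline needs inputs or a preset",
                            call. = FALSE)
  genome <- inputs$genome
  if (is.null(inputs$truth)) inputs$truth <- NULL  # simulate_cohorts extras
  manual <- inputs$manual_adjustments

  casc <- run_cascade(inputs$calls, inputs$metadata, inputs$profiles,
                      inputs$controls, config = filter,
                      qc_tolerance = qc_tolerance)
  retained <- casc$retained
  message(sprintf("cascade: %d calls -> %d large, rare CNVs",
                  nrow(inputs$calls), nrow(retained)))

  ann <- annotate_genes(retained, genome$models, genome$curation,
                        genome$bands)
  cls <- score_cnvs(ann, genome$curation, inputs$controls,
                    config = classification, filter_cfg = filter,
                    manual = manual)
  cand <- nominate_candidates(ann, genome$curation, config = classification)
  interest <- select_cnvs_of_interest(cls, cand)

  ikey <- paste(interest$sample_id, interest$chrom, interest$start,
                interest$end, interest$cnv_type, sep = "\r")
  ckey <- paste(cls$sample_id, cls$chrom, cls$start, cls$end, cls$cnv_type,
                sep = "\r")
  cls$interest_tag <- interest$interest_tag[match(ckey, ikey)]

  events <- merge_adjacent(retained, max_gap = merge_max_gap,
                           same_type = TRUE)
  ev_cls <- score_cnvs(
    annotate_genes(events, genome$models, genome$curation, genome$bands),
    genome$curation, inputs$controls, config = classification,
    filter_cfg = filter, manual = manual)

  karyo <- casc$qc$karyotypes
  best <- vapply(inputs$metadata$sample_id, function(sid) {
    cl <- ev_cls$classification[ev_cls$sample_id == sid]
    if (length(cl) == 0L) NA_character_ else cl[which.max(class_rank[cl])]
  }, character(1L))
  findings <- data.frame(
    sample_id = inputs$metadata$sample_id,
    classification = unname(best),
    aneuploid = karyo$aneuploid[match(inputs$metadata$sample_id,
                                      karyo$sample_id)],
    stringsAsFactors = FALSE
  )
  n_enrolled <- nrow(inputs$metadata)
  n_analyzed <- nrow(casc$qc$pass)
  yields <- diagnostic_yield(findings, n_enrolled, n_analyzed)
  message(sprintf(
    "yield: P/LP %.1f%% of %d analyzed; total %.1f%% of %d enrolled",
    yields[["yield_plp"]], n_analyzed, yields[["yield_total"]], n_enrolled))

  report <- structure(list(
    n_enrolled = n_enrolled,
    n_cnv_analyzed = n_analyzed,
    classified = cls,
    events = ev_cls,
    candidates = cand,
    of_interest = interest,
    findings = findings,
    karyotypes = karyo,
    qc = casc$qc,
    trace = casc$trace,
    yield_plp = yields[["yield_plp"]],
    yield_total = yields[["yield_total"]],
    summary = cohort_summary(inputs$metadata),
    filter_config = filter,
    classification_config = classification,
    merge_max_gap = merge_max_gap,
    seed = seed %||% NA_integer_,
    inputs_md5 = list(
      calls = table_md5(inputs$calls),
      metadata = table_md5(inputs$metadata),
      profiles = table_md5(inputs$profiles),
      controls = table_md5(inputs$controls),
      gene_models = table_md5(genome$models),
      gene_curation = table_md5(genome$curation)
    )
  ), class = "cohort_report")
  if (!is.null(out_dir)) write_results(report, out_dir)
  report
}
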